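#' Specification of the female-only Leslie matrix
#'
#' Describes how the age-structured projection matrix is built from herd
#' parameters. Age classes run from the calf at its first autumn (class 0)
#' through `max_age_class`; older females are culled (no survival out of the
#' last class). The sub-diagonal holds annual survival: the calf's first
#' autumn-to-autumn transition is `relative_calf_survival` times adult
#' survival, all later transitions use adult survival. The first row holds
#' fecundities -- `calving_rate * female_fraction` female calves recruited
#' to their first autumn per reproducing female per year -- for every class
#' whose members calve at age `first_repro_age` or older.
#'
#' Because the verbal description of such a matrix leaves the sex-ratio
#' handling, the first reproductive age and the census convention open,
#' these are explicit options with a documented grid (see
#' [breakpoint_grid()]). The defaults are the recorded configuration whose
#' breakpoints match the published 17% / 7.5% values: fecundity credited
#' without discounting maternal survival over the projection interval
#' (`census = "pre_breeding"`, i.e. mothers are counted immediately before
#' the birth pulse), half of calves female, first calving at age two.
#'
#' @param calving_rate Calves surviving to their first autumn per
#'   reproducing female per year (default 0.6).
#' @param female_fraction Proportion of calves that are female (grid values
#'   0.5 and 1; 1 means `calving_rate` is read as female calves directly).
#' @param first_repro_age Age in whole years at first calving (grid values
#'   2 and 3).
#' @param max_age_class Last retained age class (default 10; older females
#'   culled).
#' @param relative_calf_survival Calf first-to-second-autumn survival as a
#'   fraction of adult survival (scenarios: 0.8 high, 0.5 low).
#' @param census `"pre_breeding"` (fecundity `calving_rate *
#'   female_fraction`) or `"post_breeding"` (fecundity additionally
#'   multiplied by adult survival, charging the mother's survival over the
#'   year before her calf appears at the autumn census).
#' @return An object of class `leslie_spec`.
#' @export
leslie_spec <- function(calving_rate = 0.6, female_fraction = 0.5,
                        first_repro_age = 2, max_age_class = 10,
                        relative_calf_survival = 0.8,
                        census = c("pre_breeding", "post_breeding")) {
  census <- match.arg(census)
  if (calving_rate < 0 || calving_rate > 1)
    stop("`calving_rate` must be in [0, 1]")
  if (relative_calf_survival <= 0 || relative_calf_survival > 1)
    stop("`relative_calf_survival` must be in (0, 1]")
  if (first_repro_age < 1 || max_age_class + 1 < first_repro_age)
    stop("need at least one reproductive class: first_repro_age must be ",
         "at least 1 and at most max_age_class + 1")
  structure(
    list(calving_rate = calving_rate, female_fraction = female_fraction,
         first_repro_age = first_repro_age, max_age_class = max_age_class,
         relative_calf_survival = relative_calf_survival, census = census),
    class = "leslie_spec"
  )
}

#' @export
print.leslie_spec <- function(x, ...) {
  cat(sprintf(
    paste0("Leslie spec: calving %.2f, female fraction %.2f, first calving",
           " at age %d,\n  classes calf..%d, calf survival %.2f x adult,",
           " census %s\n"),
    x$calving_rate, x$female_fraction, x$first_repro_age, x$max_age_class,
    x$relative_calf_survival, x$census))
  invisible(x)
}

#' Build the Leslie projection matrix
#'
#' @param spec A [leslie_spec()].
#' @param adult_survival Annual adult female survival in `(0, 1)`.
#' @return A `(max_age_class + 1)`-square non-negative matrix; class `j`
#'   (column `j`) is age class `j - 1` (calf at first autumn = class 0).
#' @details A female of age class `a` at the autumn census calves the next
#'   spring at age `a + 1`; fecundity is therefore assigned to columns with
#'   `a + 1 >= first_repro_age`.
#' @export
build_leslie <- function(spec, adult_survival) {
  stopifnot(inherits(spec, "leslie_spec"))
  if (adult_survival <= 0 || adult_survival > 1)
    stop("`adult_survival` must be in (0, 1]")
  K <- spec$max_age_class + 1L
  A <- matrix(0, K, K)
  surv <- c(spec$relative_calf_survival * adult_survival,
            rep(adult_survival, K - 2))
  A[cbind(2:K, 1:(K - 1))] <- surv
  f <- spec$calving_rate * spec$female_fraction *
    (if (spec$census == "post_breeding") adult_survival else 1)
  repro <- which(seq_len(K) - 1L + 1L >= spec$first_repro_age)
  A[1, repro] <- f
  A
}

#' Dominant eigenvalue (spectral radius) of a projection matrix
#'
#' @param A Square non-negative matrix.
#' @return The spectral radius, a real number `>= 0`.
#' @export
dominant_eigenvalue <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix")
  if (any(A < 0)) stop("`A` must be non-negative")
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Maximum sustainable adult mortality
#'
#' Finds, by bisection, the adult mortality rate `m` at which the dominant
#' eigenvalue of the Leslie matrix equals one: above it the herd declines
#' irreversibly. The eigenvalue is monotonically decreasing in mortality
#' (verified on a grid before solving). If the population cannot grow even
#' without adult mortality, the breakpoint is 0 and the result is flagged.
#'
#' @param spec A [leslie_spec()].
#' @param tol Bisection tolerance on `m` (default 1e-8, so the eigenvalue at the solution is within 1e-6 of one).
#' @param upper Upper end of the mortality search interval.
#' @return An object of class `breakpoint_result`: a list with `scenario`
#'   (label from the relative calf survival), `spec`,
#'   `max_sustainable_mortality`, `eigenvalue_at_solution` and
#'   `below_unity` (`TRUE` when growth is impossible at zero mortality).
#' @export
max_sustainable_mortality <- function(spec, tol = 1e-8, upper = 0.95) {
  stopifnot(inherits(spec, "leslie_spec"))
  lam <- function(m) dominant_eigenvalue(build_leslie(spec, 1 - m))
  grid <- seq(0, upper, length.out = 9)
  lg <- vapply(grid, lam, 0)
  if (any(diff(lg) > 1e-12))
    stop("dominant eigenvalue is not decreasing in mortality")
  label <- sprintf("relative calf survival %.2f",
                   spec$relative_calf_survival)
  if (lg[1] <= 1) {
    return(structure(list(scenario = label, spec = spec,
                          max_sustainable_mortality = 0,
                          eigenvalue_at_solution = lg[1],
                          below_unity = TRUE),
                     class = "breakpoint_result"))
  }
  if (lg[length(lg)] > 1)
    stop("eigenvalue exceeds 1 across the whole mortality range")
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lam(mid) > 1) lo <- mid else hi <- mid
  }
  m <- (lo + hi) / 2
  structure(list(scenario = label, spec = spec,
                 max_sustainable_mortality = m,
                 eigenvalue_at_solution = lam(m),
                 below_unity = FALSE),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  cat(sprintf("Sustainability breakpoint (%s): %.2f%% adult mortality",
              x$scenario, 100 * x$max_sustainable_mortality))
  if (x$below_unity) cat("  [no growth even at zero mortality]")
  cat("\n")
  invisible(x)
}

#' Breakpoints over the documented construction grid
#'
#' Computes the maximum sustainable mortality for every combination of the
#' under-determined construction options (census convention, female
#' fraction, first reproductive age) and the requested calf-survival
#' scenarios. The recorded configuration reproducing the published
#' breakpoints is the [leslie_spec()] default
#' (`pre_breeding` / `female_fraction 0.5` / first calving at 2).
#'
#' @param calving_rate Calving rate passed to every configuration.
#' @param relative_calf_survival Scenario values (default the high and low
#'   scenarios 0.8 and 0.5).
#' @param max_age_class Last retained age class.
#' @param tol Bisection tolerance.
#' @return Data frame with one row per configuration x scenario:
#'   `census`, `female_fraction`, `first_repro_age`,
#'   `relative_calf_survival`, `breakpoint` (mortality), `lambda_check`
#'   (eigenvalue re-evaluated at the solution).
#' @export
breakpoint_grid <- function(calving_rate = 0.6,
                            relative_calf_survival = c(0.8, 0.5),
                            max_age_class = 10, tol = 1e-8) {
  grid <- expand.grid(
    census = c("pre_breeding", "post_breeding"),
    female_fraction = c(0.5, 1),
    first_repro_age = c(2L, 3L),
    relative_calf_survival = relative_calf_survival,
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(r) {
    spec <- leslie_spec(
      calving_rate = calving_rate,
      female_fraction = grid$female_fraction[r],
      first_repro_age = grid$first_repro_age[r],
      max_age_class = max_age_class,
      relative_calf_survival = grid$relative_calf_survival[r],
      census = grid$census[r])
    bp <- max_sustainable_mortality(spec, tol = tol)
    lam <- dominant_eigenvalue(
      build_leslie(spec, 1 - bp$max_sustainable_mortality))
    data.frame(breakpoint = bp$max_sustainable_mortality,
               lambda_check = lam)
  })
  cbind(grid, do.call(rbind, res))
}
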