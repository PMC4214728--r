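#' Fitting options for [fit_cjs()]
#'
#' @param n_starts Number of optimizer starts: one deterministic start from
#'   moment-style initial values plus `n_starts - 1` seeded random
#'   perturbations of it.
#' @param seed Seed for the random starts.
#' @param boundary_threshold Probability-scale threshold above which a free
#'   survival estimate is treated as being on the boundary, fixed to 1, and
#'   the model refit (mirroring the standard manual treatment of boundary
#'   estimates in capture-recapture practice).
#' @param max_boundary_rounds Maximum number of fix-and-refit rounds.
#' @param reltol Relative convergence tolerance on the log-likelihood passed
#'   to the quasi-Newton optimizer.
#' @param maxit Maximum BFGS iterations per start.
#' @return A list of options.
#' @export
cjs_options <- function(n_starts = 5, seed = 1,
                        boundary_threshold = 1 - 1e-4,
                        max_boundary_rounds = 5,
                        reltol = 1e-10, maxit = 1000) {
  list(n_starts = n_starts, seed = seed,
       boundary_threshold = boundary_threshold,
       max_boundary_rounds = max_boundary_rounds,
       reltol = reltol, maxit = maxit)
}

#' Fit a Cormack-Jolly-Seber model by constrained maximum likelihood
#'
#' Maximizes the m-array form of the CJS likelihood over the free parameters
#' of `structure` by quasi-Newton (BFGS) iteration on the logit scale, from
#' several starting points. Standard errors come from the inverse observed
#' information (the numerically differentiated Hessian at the optimum);
#' 95% confidence intervals are Wald intervals on the logit scale,
#' back-transformed to probabilities. Free survival estimates that land on
#' the upper boundary (above `boundary_threshold`) are flagged, fixed to 1,
#' and the model is refit without them.
#'
#' @param data An [encounter_histories()] object or a [build_marray()]
#'   result.
#' @param structure A [cjs_structure()].
#' @param options A [cjs_options()] list.
#' @return An object of class `cjs_fit` with elements `structure`, `theta`,
#'   `loglik`, `K` (free-parameter count), `n_eff` (total releases),
#'   `AICc`, `vcov` (logit-scale covariance, `NA` if the information matrix
#'   is singular), `phi` and `p` (per-cell estimate tables with columns
#'   `herd`, `interval`/`occasion`, `year`, `season`, `estimate`, `lcl`,
#'   `ucl`, `fixed`), `boundary_flags` (labels of cells refit as fixed 1)
#'   and `convergence`.
#' @examples
#' cal <- occasion_calendar(2007:2010, rep("autumn", 4),
#'                          cbind(A = rep(TRUE, 4)))
#' design <- simulation_design(
#'   cal, cohorts = data.frame(herd = "A", occasion = 1, n = 400),
#'   phi = matrix(0.9, 3, 1, dimnames = list(NULL, "A")),
#'   p = matrix(0.6, 3, 1, dimnames = list(NULL, "A")))
#' sim <- simulate_histories(design, seed = 7)
#' str3 <- cjs_structure(cal, phi = "time", p = "time",
#'                       phi_fix = data.frame(interval = 3, herd = "A",
#'                                            value = 1))
#' fit <- fit_cjs(sim$histories, str3, cjs_options(n_starts = 1))
#' fit$phi
#' @export
fit_cjs <- function(data, structure, options = cjs_options()) {
  marr <- as_marray(data)
  check_same_calendar(marr$calendar, structure$calendar)
  if (n_free_par(structure) < 1)
    stop("the structure has no free parameters")

  fit <- fit_once(marr, structure, options)
  boundary_flags <- character(0)
  round <- 0
  while (round < options$max_boundary_rounds &&
         structure$phi_form == "herd:time") {
    est <- fit$phi
    hit <- !est$fixed & est$estimate > options$boundary_threshold
    if (!any(hit)) break
    cells <- est[hit, c("interval", "herd")]
    boundary_flags <- c(boundary_flags,
                        sprintf("phi[%s,%d]", cells$herd, cells$interval))
    structure <- fix_phi_cells(structure, cells)
    fit <- fit_once(marr, structure, options)
    round <- round + 1
  }
  fit$boundary_flags <- boundary_flags
  fit
}

fit_once <- function(marr, structure, options) {
  n_phi <- ncol(structure$phi_X)
  n_p <- ncol(structure$p_X)
  hs <- structure$herds
  nll <- function(theta) {
    ll <- marray_loglik(cells_from_theta(theta, structure), marr, hs)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ngr <- function(theta) {
    g <- -cjs_score(theta, structure, marr)
    g[!is.finite(g)] <- 0
    g
  }
  theta0 <- c(init_block(structure$phi_X, 0.9),
              init_block(structure$p_X, 0.6))
  starts <- list(theta0)
  if (options$n_starts > 1) {
    rng <- local_rng(options$seed)
    for (s in seq_len(options$n_starts - 1))
      starts[[s + 1]] <- theta0 + rng$rnorm(length(theta0), sd = 0.75)
  }
  best <- NULL
  conv <- 1L
  for (st in starts) {
    op <- try(stats::optim(st, nll, gr = ngr, method = "BFGS",
                           control = list(maxit = options$maxit,
                                          reltol = options$reltol)),
              silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value - 1e-12) {
      best <- op
      conv <- op$convergence
    }
  }
  if (is.null(best)) stop("optimization failed from every start")
  hess <- stats::optimHess(best$par, nll)
  vcov <- try(solve(hess), silent = TRUE)
  singular <- inherits(vcov, "try-error") ||
    any(!is.finite(vcov)) || any(diag(vcov) < 0)
  if (singular) vcov <- matrix(NA_real_, length(best$par), length(best$par))

  theta <- best$par
  loglik <- -best$value
  K <- length(theta)
  n_eff <- total_releases(marr)
  out <- list(structure = structure, theta = theta, loglik = loglik,
              K = K, n_eff = n_eff,
              AICc = aicc(loglik, K, n_eff), vcov = vcov,
              phi = cell_table(structure, theta, vcov, "phi"),
              p = cell_table(structure, theta, vcov, "p"),
              boundary_flags = character(0),
              vcov_singular = singular,
              convergence = conv)
  class(out) <- "cjs_fit"
  out
}

# least-squares logit-scale start so that X theta ~ logit(value)
init_block <- function(X, value) {
  if (ncol(X) == 0) return(numeric(0))
  qr.solve(X, rep(stats::qlogis(value), nrow(X)))
}

# per-cell estimate table with delta-method Wald CIs on the logit scale
cell_table <- function(structure, theta, vcov, what) {
  cal <- structure$calendar
  fixed <- structure[[paste0(what, "_fixed")]]
  X <- structure[[paste0(what, "_X")]]
  off <- if (what == "phi") 0L else ncol(structure$phi_X)
  th <- theta[off + seq_len(ncol(X))]
  V <- vcov[off + seq_len(ncol(X)), off + seq_len(ncol(X)), drop = FALSE]
  free <- which(is.na(fixed))                     # column-major order
  eta <- drop(X %*% th)
  se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  est <- fixed
  est[free] <- stats::plogis(eta)
  lcl <- ucl <- matrix(NA_real_, nrow(fixed), ncol(fixed))
  lcl[free] <- stats::plogis(eta - 1.96 * se)
  ucl[free] <- stats::plogis(eta + 1.96 * se)
  idx <- seq_len(nrow(fixed))
  occ <- idx + 1L    # row i ends at (phi) / is at (p) occasion i + 1
  tab <- expand.grid(i = idx, herd = colnames(fixed),
                     stringsAsFactors = FALSE)
  tab$year <- cal$occasions$year[occ][tab$i]
  tab$season <- cal$occasions$season[occ][tab$i]
  tab$estimate <- as.vector(est)
  tab$lcl <- as.vector(lcl)
  tab$ucl <- as.vector(ucl)
  tab$fixed <- as.vector(!is.na(fixed))
  names(tab)[1] <- if (what == "phi") "interval" else "occasion"
  if (what == "p") tab$occasion <- tab$occasion + 1L
  tab
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2K + 2K(K + 1) / (n_eff - K - 1)`, with the effective
#' sample size taken as the total number of releases.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of free parameters.
#' @param n_eff Effective sample size.
#' @return The AICc value.
#' @export
aicc <- function(loglik, K, n_eff) {
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit:", x$structure$label, "\n")
  cat(sprintf("  loglik = %.3f  K = %d  n_eff = %d  AICc = %.2f\n",
              x$loglik, x$K, x$n_eff, x$AICc))
  if (length(x$boundary_flags))
    cat("  boundary cells fixed at 1:",
        paste(x$boundary_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Rank candidate model structures by AICc
#'
#' Fits each structure to the same data and returns a table sorted by AICc
#' with a `dAICc` column. A structure whose fit fails is kept in the table
#' with `NA` values and ranked last.
#'
#' @param data An [encounter_histories()] object or a [build_marray()]
#'   result.
#' @param structures Named list of [cjs_structure()] objects (at least two).
#' @param options A [cjs_options()] list.
#' @return A data frame with columns `model`, `K`, `loglik`, `AICc`,
#'   `dAICc`, `failed`; the fits themselves are attached as attribute
#'   `"fits"`.
#' @export
compare_models <- function(data, structures, options = cjs_options()) {
  if (length(structures) < 2)
    stop("supply at least two candidate structures")
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s) s$label, "")
  fits <- lapply(structures, function(s)
    tryCatch(fit_cjs(data, s, options), error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, what = "error")
  tab <- data.frame(
    model = names(structures),
    K = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "cjs_fit")) f$K else NA_integer_, 1), NA),
    loglik = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "cjs_fit")) f$loglik else NA_real_, 1), NA),
    AICc = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "cjs_fit")) f$AICc else NA_real_, 1), NA),
    failed = !ok
  )
  tab <- tab[order(tab$failed, tab$AICc), ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Survival schedule from a fitted model
#'
#' Extracts the per-interval survival estimates of a [fit_cjs()] result as a
#' schedule usable by [annual_survival()] and [accumulated_survival()].
#'
#' @param fit A `cjs_fit`.
#' @return A data frame with columns `herd`, `interval`, `year`, `season`,
#'   `estimate`, `lcl`, `ucl`, `fixed`; `year`/`season` name the occasion at
#'   which each interval ends.
#' @export
fitted_schedule <- function(fit) {
  stopifnot(inherits(fit, "cjs_fit"))
  fit$phi[c("herd", "interval", "year", "season",
            "estimate", "lcl", "ucl", "fixed")]
}
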