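#' Parameter structure for a Cormack-Jolly-Seber model
#'
#' Maps every survival cell (interval x herd) and recapture cell
#' (occasion >= 2 x herd) either to a fixed probability or to a linear
#' predictor over free parameters on the logit scale. Structural constraints
#' of the sampling design (a herd never gathered at an occasion has
#' recapture fixed at 0; the survival interval leading into such an occasion
#' cannot be separated from its neighbour and is conventionally fixed at 1)
#' are expressed as fixed cells.
#'
#' @param calendar An [occasion_calendar()].
#' @param phi Survival structure: `"herd:time"` (one free parameter per
#'   cell), `"herd+time"` (additive herd offset on the logit scale),
#'   `"time"` (shared across herds) or `"constant"`.
#' @param p Recapture structure, same options.
#' @param phi_fix Data frame with columns `interval`, `herd`, `value`:
#'   survival cells to fix (value on the probability scale).
#' @param p_fix Data frame with columns `occasion`, `herd`, `value`:
#'   recapture cells to fix.
#' @param label Optional model label used in comparison tables.
#' @return An object of class `cjs_structure`.
#' @details Free cells are filled column-major (all intervals of the first
#'   herd, then the next herd); the design matrices `phi_X` and `p_X` map
#'   the free-parameter vector to the logit of each free cell in that order.
#' @export
cjs_structure <- function(calendar,
                          phi = c("herd:time", "herd+time", "time",
                                  "constant"),
                          p = c("herd+time", "herd:time", "time",
                                "constant"),
                          phi_fix = NULL, p_fix = NULL, label = NULL) {
  stopifnot_calendar(calendar)
  phi <- match.arg(phi)
  p <- match.arg(p)
  K <- n_occasions(calendar)
  hs <- herds(calendar)

  phi_fixed <- matrix(NA_real_, K - 1, length(hs),
                      dimnames = list(NULL, hs))
  p_fixed <- matrix(NA_real_, K - 1, length(hs),
                    dimnames = list(NULL, hs))   # row j = occasion j + 1
  if (!is.null(phi_fix)) {
    for (r in seq_len(nrow(phi_fix)))
      phi_fixed[phi_fix$interval[r], phi_fix$herd[r]] <- phi_fix$value[r]
  }
  if (!is.null(p_fix)) {
    for (r in seq_len(nrow(p_fix)))
      p_fixed[p_fix$occasion[r] - 1L, p_fix$herd[r]] <- p_fix$value[r]
  }
  # recapture at non-capturable occasions is a structural zero
  for (h in hs) {
    blocked <- which(!calendar$capturable[, h])
    blocked <- blocked[blocked >= 2]
    p_fixed[blocked - 1L, h] <- 0
  }

  phi_des <- build_design(phi_fixed, phi, "phi")
  p_des <- build_design(p_fixed, p, "p")
  structure(
    list(calendar = calendar, herds = hs,
         phi_form = phi, p_form = p,
         phi_fixed = phi_fixed, p_fixed = p_fixed,
         phi_X = phi_des$X, p_X = p_des$X,
         phi_par_names = phi_des$names, p_par_names = p_des$names,
         label = label %||%
           sprintf("phi(%s) p(%s)", phi, p)),
    class = "cjs_structure"
  )
}

# Design matrix over the free cells of a fixed-value matrix. Cells are taken
# column-major; `form` chooses the logit-scale parameterization.
build_design <- function(fixed, form, prefix) {
  free <- which(is.na(fixed))                       # column-major
  time <- factor(row(fixed)[free])
  herd <- factor(colnames(fixed)[col(fixed)[free]],
                 levels = colnames(fixed))
  time <- droplevels(time); herd <- droplevels(herd)
  dummies <- function(f, lev = levels(f)) {
    X <- vapply(lev, function(l) as.numeric(f == l), numeric(length(f)))
    matrix(X, nrow = length(f), dimnames = list(NULL, lev))
  }
  if (form == "herd:time") {
    X <- diag(length(free))
    nm <- paste0(prefix, "[", colnames(fixed)[col(fixed)[free]], ",",
                 row(fixed)[free], "]")
  } else if (form == "herd+time") {
    X <- dummies(time)
    if (nlevels(herd) > 1)
      X <- cbind(X, dummies(herd, levels(herd)[-1]))
    nm <- paste0(prefix, ".", colnames(X))
  } else if (form == "time") {
    X <- dummies(time)
    nm <- paste0(prefix, ".", colnames(X))
  } else {                                          # constant
    X <- matrix(1, length(free), 1)
    nm <- paste0(prefix, ".const")
  }
  X <- unname(as.matrix(X))
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient ", prefix, " design; simplify the structure")
  list(X = X, names = nm)
}

#' @export
print.cjs_structure <- function(x, ...) {
  cat("CJS parameter structure:", x$label, "\n")
  cat("  free survival parameters: ", ncol(x$phi_X),
      " (", sum(is.na(x$phi_fixed)), " free cells)\n", sep = "")
  cat("  free recapture parameters: ", ncol(x$p_X),
      " (", sum(is.na(x$p_fixed)), " free cells)\n", sep = "")
  invisible(x)
}

n_free_par <- function(structure) ncol(structure$phi_X) + ncol(structure$p_X)

#' The headline two-herd parameter structure
#'
#' The structure used for the package's reference analysis of the 18-occasion
#' two-herd calendar: survival with a full herd-by-time interaction,
#' recapture additive in herd and occasion on the logit scale. Fixed cells:
#'
#' * herd B recaptures at every spring occasion: 0 (never gathered);
#' * herd B survival over every spring-to-July interval: 1, so that the
#'   preceding autumn-to-spring parameter carries the whole autumn-to-July
#'   survival;
#' * herd B survival before its entry at autumn 2007 (no releases): 1;
#' * boundary cells estimated at 1 in the reference analysis and refit as
#'   fixed: herd A spring-to-July 2008 and 2009, herd B July-to-autumn 2008;
#' * the final two intervals (spring-to-July and July-to-autumn 2012) for
#'   both herds: 1, because the terminal survival-recapture product is not
#'   separately identifiable and the final recapture absorbs it.
#'
#' @param calendar The [study_calendar()] (18 occasions, herds A and B).
#' @param boundary_fixes Fix the three data-driven boundary cells listed
#'   above (default `TRUE`). Set to `FALSE` to let [fit_cjs()] rediscover
#'   boundary cells from the data.
#' @return A [cjs_structure()].
#' @export
reference_structure <- function(calendar = study_calendar(),
                                boundary_fixes = TRUE) {
  stopifnot_calendar(calendar)
  if (n_occasions(calendar) != 18 ||
      !identical(herds(calendar), c("A", "B")))
    stop("`reference_structure()` is defined for the 18-occasion A/B calendar")
  spring <- season_occasions(calendar, "spring")
  K <- n_occasions(calendar)
  fix1 <- function(interval, herd)
    data.frame(interval = interval, herd = herd, value = 1)
  phi_fix <- rbind(
    fix1(spring[spring < K], "B"),      # spring -> July, herd B
    fix1(1:2, "B"),                     # before herd B entry (autumn 2007)
    fix1((K - 2):(K - 1), c("A", "A")), # terminal non-identifiable product
    fix1((K - 2):(K - 1), c("B", "B"))
  )
  if (boundary_fixes)
    phi_fix <- rbind(phi_fix,
                     fix1(c(4, 7), c("A", "A")),  # spring->July 2008, 2009
                     fix1(5, "B"))                # July->autumn 2008
  phi_fix <- phi_fix[!duplicated(phi_fix[1:2]), ]
  cjs_structure(calendar, phi = "herd:time", p = "herd+time",
                phi_fix = phi_fix,
                label = "phi(herd:time) p(herd+time)")
}

#' Default candidate model set for AICc comparison
#'
#' Four structures spanning whether survival carries a herd-by-time
#' interaction, an additive herd effect, or no herd effect, with recapture
#' additive or herd-free. All share the structural fixed cells of
#' [reference_structure()].
#'
#' @param calendar The [study_calendar()].
#' @return Named list of [cjs_structure()] objects.
#' @export
candidate_structures <- function(calendar = study_calendar()) {
  base <- reference_structure(calendar, boundary_fixes = FALSE)
  phi_fix <- fixed_as_df(base$phi_fixed, "interval")
  list(
    "phi(herd:time) p(herd+time)" =
      cjs_structure(calendar, "herd:time", "herd+time", phi_fix = phi_fix),
    "phi(herd+time) p(herd+time)" =
      cjs_structure(calendar, "herd+time", "herd+time", phi_fix = phi_fix),
    "phi(herd:time) p(time)" =
      cjs_structure(calendar, "herd:time", "time", phi_fix = phi_fix),
    "phi(time) p(herd+time)" =
      cjs_structure(calendar, "time", "herd+time", phi_fix = phi_fix)
  )
}

fixed_as_df <- function(fixed, index_name) {
  idx <- which(!is.na(fixed), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], herd = colnames(fixed)[idx[, 2]],
                    value = fixed[idx])
  names(out)[1] <- index_name
  if (index_name == "occasion") out$occasion <- out$occasion + 1L
  out
}

# Fix additional survival cells at 1 (used by the boundary-refit loop).
# Only defined for structures whose free survival cells map one-to-one to
# parameters (the herd:time interaction).
fix_phi_cells <- function(structure, cells) {
  if (structure$phi_form != "herd:time")
    stop("boundary refitting requires the herd:time survival structure")
  phi_fixed <- structure$phi_fixed
  for (r in seq_len(nrow(cells)))
    phi_fixed[cells$interval[r], cells$herd[r]] <- 1
  cjs_structure(structure$calendar, structure$phi_form, structure$p_form,
                phi_fix = fixed_as_df(phi_fixed, "interval"),
                p_fix = fixed_as_df(structure$p_fixed, "occasion"),
                label = structure$label)
}
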