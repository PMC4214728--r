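#' Reduce encounter histories to per-herd m-arrays
#'
#' The m-array is the sufficient statistic of the Cormack-Jolly-Seber
#' likelihood: for each release occasion `i` it records the number of
#' animals released (`R[i]`), how many of those were next recaptured at each
#' later occasion `j` (`m[i, j]`), and how many were never seen again
#' (`never[i] = R[i] - sum_j m[i, j]`). Every capture is a release, except
#' the final capture of a removed (harvested) animal, which is not returned
#' to the herd. Captures at the final occasion open no release row.
#'
#' @param histories An [encounter_histories()] object.
#' @return An object of class `cjs_marray`: a list with elements `calendar`
#'   and, per herd, a list holding `R` (length `K - 1`), `m`
#'   (`(K - 1) x K` matrix, entries only above the diagonal) and `never`.
#' @export
build_marray <- function(histories) {
  cal <- histories$calendar
  K <- n_occasions(cal)
  out <- list(calendar = cal)
  for (h in herds(cal)) {
    R <- integer(K - 1)
    m <- matrix(0L, K - 1, K,
                dimnames = list(release = NULL, recapture = NULL))
    idx <- which(histories$herd == h)
    for (k in idx) {
      caps <- which(histories$detections[k, ] == 1L)
      if (histories$removed[k]) caps <- caps[-length(caps)]
      caps <- caps[caps < K]            # a capture at K releases nothing
      if (!length(caps)) next
      nxt <- which(histories$detections[k, ] == 1L)
      for (i in caps) {
        R[i] <- R[i] + 1L
        j <- nxt[nxt > i]
        if (length(j)) m[i, j[1]] <- m[i, j[1]] + 1L
      }
    }
    out[[h]] <- list(R = R, m = m, never = R - rowSums(m))
  }
  class(out) <- "cjs_marray"
  out
}

#' @export
print.cjs_marray <- function(x, ...) {
  for (h in herds(x$calendar)) {
    cat("m-array, herd", h, "- releases:",
        sum(x[[h]]$R), "( per occasion:",
        paste(x[[h]]$R, collapse = " "), ")\n")
  }
  invisible(x)
}

#' Total number of releases in an m-array
#'
#' Summed over occasions and herds; used as the effective sample size in the
#' small-sample AICc correction (the convention of standard capture-recapture
#' software).
#'
#' @param marray A [build_marray()] result.
#' @return Integer total.
#' @export
total_releases <- function(marray) {
  sum(vapply(herds(marray$calendar), function(h) sum(marray[[h]]$R), 0L))
}

as_marray <- function(data) {
  if (inherits(data, "cjs_marray")) return(data)
  if (inherits(data, "encounter_histories")) return(build_marray(data))
  stop("`data` must be encounter_histories or a cjs_marray")
}
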