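# Core Cormack-Jolly-Seber likelihood machinery.
#
# All free parameters live on the logit scale; fixed cells never enter the
# parameter vector. The likelihood conditions on first release: an animal
# contributes terms only between its release occasions, plus (unless it was
# removed at its final capture) the probability of never being seen again.

`%||%` <- function(a, b) if (is.null(a)) b else a

# theta -> per-herd probability-scale cell matrices
cells_from_theta <- function(theta, structure) {
  n_phi <- ncol(structure$phi_X)
  th_phi <- theta[seq_len(n_phi)]
  th_p <- theta[n_phi + seq_len(ncol(structure$p_X))]
  phi <- structure$phi_fixed
  phi[is.na(phi)] <- stats::plogis(drop(structure$phi_X %*% th_phi))
  p <- structure$p_fixed
  p[is.na(p)] <- stats::plogis(drop(structure$p_X %*% th_p))
  list(phi = phi, p = p)
}

# Multinomial cell probabilities for one herd's m-array: row i holds
# Pr(released at i, next recaptured at j) for j = i+1..K, then chi_i.
# phi: length K-1 (interval i); p: length K-1 (occasion i+1).
marray_cell_probs <- function(phi, p) {
  Km1 <- length(phi)
  K <- Km1 + 1L
  pr <- matrix(0, Km1, K)
  chi <- numeric(Km1)
  for (i in seq_len(Km1)) {
    seg <- i:Km1
    a <- cumprod(phi[seg])                 # survival from i to j
    pv <- p[seg]                           # recapture at occasions i+1..K
    skip <- c(1, cumprod(1 - pv))[seq_along(seg)]  # missed i+1..j-1
    pr[i, seg + 1L] <- a * skip * pv
    chi[i] <- 1 - sum(pr[i, ])
  }
  list(pr = pr, chi = pmax(chi, 0))
}

#' Cormack-Jolly-Seber log-likelihood
#'
#' Evaluates the CJS log-likelihood for a free-parameter vector on the logit
#' scale, under a given parameter structure. Two algebraically equivalent
#' forms are provided: the product-multinomial over the m-array (the default,
#' and the form the optimizer uses) and the product over individual
#' histories. Removed (harvested) individuals contribute nothing after their
#' final capture in either form.
#'
#' @param theta Numeric vector of free parameters on the logit scale, length
#'   `ncol(structure$phi_X) + ncol(structure$p_X)`.
#' @param structure A [cjs_structure()].
#' @param data An [encounter_histories()] object or a [build_marray()]
#'   result (the individual form requires histories).
#' @param form `"marray"` or `"individual"`.
#' @return The log-likelihood (a scalar).
#' @export
cjs_loglik <- function(theta, structure, data,
                       form = c("marray", "individual")) {
  form <- match.arg(form)
  if (any(!is.finite(theta))) stop("non-finite parameter value")
  if (length(theta) != n_free_par(structure))
    stop("`theta` must have length ", n_free_par(structure))
  cells <- cells_from_theta(theta, structure)
  if (form == "marray") {
    marr <- as_marray(data)
    check_same_calendar(marr$calendar, structure$calendar)
    marray_loglik(cells, marr, structure$herds)
  } else {
    if (!inherits(data, "encounter_histories"))
      stop("the individual form needs encounter histories")
    check_same_calendar(data$calendar, structure$calendar)
    loglik_individual(cells, data)
  }
}

marray_loglik <- function(cells, marr, hs) {
  ll <- 0
  for (h in hs) {
    cp <- marray_cell_probs(cells$phi[, h], cells$p[, h])
    a <- marr[[h]]
    ll <- ll + count_loglik(a$m, cp$pr) + count_loglik(a$never, cp$chi)
  }
  ll
}

count_loglik <- function(counts, probs) {
  use <- counts > 0
  if (!any(use)) return(0)
  if (any(probs[use] <= 0)) return(-Inf)
  sum(counts[use] * log(probs[use]))
}

loglik_individual <- function(cells, histories) {
  cal <- histories$calendar
  K <- n_occasions(cal)
  ll <- 0
  chi_tab <- list()
  for (h in herds(cal)) {          # chi_i: never seen after release at i
    phi <- cells$phi[, h]; p <- cells$p[, h]
    chi <- numeric(K); chi[K] <- 1
    for (i in (K - 1):1)
      chi[i] <- (1 - phi[i]) + phi[i] * (1 - p[i]) * chi[i + 1]
    chi_tab[[h]] <- chi
  }
  for (k in seq_along(histories$id)) {
    h <- histories$herd[k]
    phi <- cells$phi[, h]; p <- cells$p[, h]
    caps <- which(histories$detections[k, ] == 1L)
    if (length(caps) > 1) {
      for (s in seq_len(length(caps) - 1)) {
        a <- caps[s]; b <- caps[s + 1]
        ll <- ll + sum(log(phi[a:(b - 1)])) + log(p[b - 1])
        if (b > a + 1) ll <- ll + sum(log(1 - p[a:(b - 2)]))
      }
    }
    last <- caps[length(caps)]
    if (!histories$removed[k] && last < K)
      ll <- ll + log(chi_tab[[h]][last])
    if (!is.finite(ll)) return(-Inf)
  }
  unname(ll)
}

# Analytic score (gradient of the m-array log-likelihood with respect to
# theta). Derivatives are taken cell-wise on the probability scale, mapped
# to the logit scale and through the design matrices; fixed cells drop out.
cjs_score <- function(theta, structure, marr) {
  cells <- cells_from_theta(theta, structure)
  Km1 <- nrow(structure$phi_fixed)
  K <- Km1 + 1L
  g_phi <- matrix(0, Km1, length(structure$herds))
  g_p <- matrix(0, Km1, length(structure$herds))
  for (hi in seq_along(structure$herds)) {
    h <- structure$herds[hi]
    phi <- cells$phi[, h]; p <- cells$p[, h]
    cp <- marray_cell_probs(phi, p)
    a <- marr[[h]]
    w <- ifelse(a$never > 0 & cp$chi > 0, a$never / cp$chi, 0)
    for (k in seq_len(Km1)) {            # d/d phi_k
      rows <- 1:k
      later <- (k + 1):K
      A <- sum(a$m[rows, later, drop = FALSE])
      B <- sum(w[rows] * rowSums(cp$pr[rows, later, drop = FALSE]))
      g_phi[k, hi] <- (A - B) / phi[k]
    }
    for (j in 2:K) {                     # d/d p_j (vector index j - 1)
      if (p[j - 1] <= 0 || p[j - 1] >= 1) next   # fixed structural cells
      rows <- 1:min(j - 1, Km1)
      direct <- sum(a$m[rows, j]) / p[j - 1]
      after <- if (j < K)
        sum(a$m[rows, (j + 1):K, drop = FALSE]) else 0
      chi_part <- sum(w[rows] *
        (-cp$pr[rows, j] / p[j - 1] +
           (if (j < K) rowSums(cp$pr[rows, (j + 1):K, drop = FALSE])
            else 0) / (1 - p[j - 1])))
      g_p[j - 1, hi] <- direct - after / (1 - p[j - 1]) + chi_part
    }
  }
  free_phi <- which(is.na(structure$phi_fixed))
  free_p <- which(is.na(structure$p_fixed))
  eta_phi <- g_phi[free_phi] *
    cells$phi[free_phi] * (1 - cells$phi[free_phi])
  eta_p <- g_p[free_p] * cells$p[free_p] * (1 - cells$p[free_p])
  c(drop(crossprod(structure$phi_X, eta_phi)),
    drop(crossprod(structure$p_X, eta_p)))
}

check_same_calendar <- function(a, b) {
  if (!identical(a$occasions, b$occasions) ||
      !identical(dim(a$capturable), dim(b$capturable)))
    stop("data and structure use different occasion calendars")
  invisible(TRUE)
}
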