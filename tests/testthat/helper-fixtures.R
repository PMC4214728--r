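# Shared fixtures and independent oracles used across the suite.

# single-herd calendar of all-autumn occasions
toy_calendar <- function(K, herd = "A") {
  occasion_calendar(2000 + seq_len(K), rep("autumn", K),
                    matrix(TRUE, K, 1, dimnames = list(NULL, herd)))
}

# two-herd calendar where herd B misses every "spring" occasion
two_herd_calendar <- function(years, seasons) {
  occasion_calendar(years, seasons,
                    cbind(A = rep(TRUE, length(years)),
                          B = seasons != "spring"))
}

toy_histories <- function(det, calendar, herd = "A", removed = FALSE) {
  det <- matrix(unlist(det), nrow = length(det), byrow = TRUE)
  encounter_histories(
    id = sprintf("x%03d", seq_len(nrow(det))),
    herd = rep_len(herd, nrow(det)),
    detections = det,
    removed = rep_len(removed, nrow(det)),
    calendar = calendar
  )
}

# draw a random small single-herd dataset plus its true parameters
random_dataset <- function(seed, K = 5, n = 20, herd = "A") {
  cal <- toy_calendar(K, herd)
  rng_seed <- seed * 13 + 7
  set.seed(rng_seed)
  phi <- matrix(runif(K - 1, 0.4, 0.99), ncol = 1,
                dimnames = list(NULL, herd))
  p <- matrix(runif(K - 1, 0.2, 0.95), ncol = 1,
              dimnames = list(NULL, herd))
  design <- simulation_design(
    cal, data.frame(herd = herd, occasion = 1, n = n),
    phi, p, cull_prob = 0.15)
  list(calendar = cal, design = design,
       sim = simulate_histories(design, seed = rng_seed))
}

# brute-force oracle for known_alive: literal scan of each history
known_alive_oracle <- function(histories, occasion) {
  cal <- histories$calendar
  K <- n_occasions(cal)
  counts <- stats::setNames(rep(0L, length(herds(cal))), herds(cal))
  for (i in seq_along(histories$id)) {
    if (histories$removed[i]) next
    seen <- FALSE
    for (t in occasion:K) if (histories$detections[i, t] == 1) seen <- TRUE
    if (seen) counts[histories$herd[i]] <- counts[histories$herd[i]] + 1L
  }
  counts
}

# number of (release, next-capture-or-censor) segments read directly from
# the histories: every capture before the final occasion opens a segment,
# except the terminal capture of a removed animal
count_release_segments <- function(histories) {
  K <- n_occasions(histories$calendar)
  total <- 0L
  for (i in seq_along(histories$id)) {
    caps <- which(histories$detections[i, ] == 1)
    if (histories$removed[i]) caps <- caps[-length(caps)]
    total <- total + sum(caps < K)
  }
  total
}

# independent power-iteration spectral radius
power_iteration <- function(A, iter = 10000, tol = 1e-14) {
  v <- rep(1, nrow(A))
  lam <- 0
  for (k in seq_len(iter)) {
    w <- A %*% v
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) return(0)
    v <- as.vector(w / lam_new)
    if (abs(lam_new - lam) < tol) break
    lam <- lam_new
  }
  as.numeric(t(v) %*% A %*% v)   # Rayleigh quotient, v normalized
}
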