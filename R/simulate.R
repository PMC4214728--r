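#' Design of a capture-recapture simulation
#'
#' Bundles everything the generative model needs: the occasion calendar,
#' per-herd marking cohorts, true per-interval survival and per-occasion
#' recapture probabilities, and the per-capture autumn culling probability.
#' Recapture at non-capturable occasions must be zero (it is forced to zero
#' with a check).
#'
#' @param calendar An [occasion_calendar()].
#' @param cohorts Data frame with columns `herd`, `occasion` (entry, i.e.
#'   marking occasion) and `n` (positive cohort size).
#' @param phi `(K - 1) x herds` matrix of true interval survival
#'   probabilities.
#' @param p `(K - 1) x herds` matrix of true recapture probabilities for
#'   occasions `2..K` (row `j` is occasion `j + 1`).
#' @param cull_prob Named per-herd probability that a marked female captured
#'   at an autumn occasion (after her entry) is removed (harvested); recycled
#'   if unnamed scalar.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(calendar, cohorts, phi, p, cull_prob = 0) {
  stopifnot_calendar(calendar)
  K <- n_occasions(calendar)
  hs <- herds(calendar)
  phi <- as.matrix(phi); p <- as.matrix(p)
  if (!all(dim(phi) == c(K - 1, length(hs))) ||
      !all(dim(p) == c(K - 1, length(hs))))
    stop("`phi` and `p` must be (K-1) x n_herds matrices")
  if (is.null(colnames(phi))) colnames(phi) <- hs
  if (is.null(colnames(p))) colnames(p) <- hs
  if (any(phi < 0 | phi > 1) || any(p < 0 | p > 1))
    stop("probabilities must be in [0, 1]")
  for (h in hs) {
    blocked <- which(!calendar$capturable[, h])
    blocked <- blocked[blocked >= 2]
    if (any(p[blocked - 1L, h] > 0))
      stop("recapture must be 0 at non-capturable occasions (herd ", h, ")")
  }
  if (!all(cohorts$herd %in% hs)) stop("unknown herd in `cohorts`")
  if (any(cohorts$n <= 0)) stop("cohort sizes must be positive")
  if (any(cohorts$occasion < 1 | cohorts$occasion > K))
    stop("cohort entry occasion out of range")
  if (length(cull_prob) == 1 && is.null(names(cull_prob)))
    cull_prob <- stats::setNames(rep(cull_prob, length(hs)), hs)
  if (any(cull_prob < 0 | cull_prob > 1))
    stop("`cull_prob` must be in [0, 1]")
  structure(list(calendar = calendar, cohorts = cohorts, phi = phi, p = p,
                 cull_prob = cull_prob),
            class = "simulation_design")
}

#' The reference two-herd simulation design
#'
#' The study conditions the package's simulations emulate: the 18-occasion
#' calendar, 388 herd-A females marked in spring (300) and autumn (88)
#' 2007, 335 herd-B females marked in autumn 2007, true survival and
#' recapture set to the reference estimate tables
#' ([reference_survival()], [reference_recapture()]), and per-herd culling
#' probabilities calibrated so the expected number of removals over the
#' study is about 78 (herd A) and 20 (herd B).
#'
#' @return A [simulation_design()].
#' @export
study_design <- function() {
  cal <- study_calendar()
  mats <- reference_matrices()
  cohorts <- data.frame(herd = c("A", "A", "B"),
                        occasion = c(1L, 3L, 3L),
                        n = c(300L, 88L, 335L))
  design <- simulation_design(cal, cohorts, mats$phi, mats$p, cull_prob = 0)
  design$cull_prob <- c(
    A = calibrate_cull_prob(design, "A", target_removals = 78),
    B = calibrate_cull_prob(design, "B", target_removals = 20))
  design
}

#' Calibrate the autumn culling probability
#'
#' Culling is modelled as removal-on-capture at autumn gatherings after the
#' entry occasion. This solves (deterministically, from the expected alive
#' and not-yet-removed trajectory of each cohort) for the per-capture
#' removal probability giving a target expected number of removals.
#'
#' @param design A [simulation_design()].
#' @param herd Herd label.
#' @param target_removals Expected number of removed females over the study.
#' @return The calibrated probability.
#' @export
calibrate_cull_prob <- function(design, herd, target_removals) {
  expected <- function(cull) {
    tot <- 0
    for (r in which(design$cohorts$herd == herd)) {
      entry <- design$cohorts$occasion[r]
      alive <- design$cohorts$n[r]      # expected alive & still in herd
      K <- n_occasions(design$calendar)
      if (entry >= K) next
      for (t in (entry + 1):K) {
        alive <- alive * design$phi[t - 1, herd]
        if (design$calendar$occasions$season[t] == "autumn") {
          pr_rem <- design$p[t - 1, herd] * cull
          tot <- tot + alive * pr_rem
          alive <- alive * (1 - pr_rem)
        }
      }
    }
    tot
  }
  if (expected(1) < target_removals)
    stop("target removals unreachable even with certain culling on capture")
  stats::uniroot(function(c) expected(c) - target_removals,
                 c(0, 1), tol = 1e-10)$root
}

#' Simulate encounter histories from the generative CJS process
#'
#' Each marked female enters at her cohort's marking occasion (a certain
#' detection). Her alive state then evolves by per-interval Bernoulli
#' survival draws; given alive and capturable she is detected by a
#' Bernoulli recapture draw; a detection at an autumn occasion after entry
#' removes her (harvest) with the design's culling probability, ending her
#' record. Each individual consumes its own deterministic sub-stream of the
#' seed, so results do not depend on cohort order and are bit-identical for
#' a fixed seed.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return A list with `histories` (an [encounter_histories()] object) and
#'   `truth` (data frame with one row per female: `id`, `herd`, `entry`,
#'   `death_interval` -- the interval in which she died, `NA` if she
#'   survived the study -- and `removed_at`, the culling occasion or `NA`).
#' @export
simulate_histories <- function(design, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  cal <- design$calendar
  K <- n_occasions(cal)
  autumn <- cal$occasions$season == "autumn"
  rows <- sum(design$cohorts$n)
  det <- matrix(0L, rows, K)
  id <- herd <- character(rows)
  removed <- logical(rows)
  entry_v <- integer(rows)
  death <- removed_at <- rep(NA_integer_, rows)
  k <- 0L
  for (r in seq_len(nrow(design$cohorts))) {
    h <- design$cohorts$herd[r]
    entry <- design$cohorts$occasion[r]
    for (j in seq_len(design$cohorts$n[r])) {
      k <- k + 1L
      rng <- local_rng(derive_seed(seed, k))
      id[k] <- sprintf("%s%04d", h, k)
      herd[k] <- h
      entry_v[k] <- entry
      det[k, entry] <- 1L
      if (entry < K) {
        for (t in (entry + 1):K) {
          if (rng$runif(1) > design$phi[t - 1, h]) {  # died this interval
            death[k] <- t - 1L
            break
          }
          if (cal$capturable[t, h] &&
              rng$runif(1) < design$p[t - 1, h]) {
            det[k, t] <- 1L
            if (autumn[t] &&
                rng$runif(1) < design$cull_prob[h]) {
              removed[k] <- TRUE
              removed_at[k] <- t
              break
            }
          }
        }
      }
    }
  }
  list(
    histories = encounter_histories(id, herd, det, removed, cal),
    truth = data.frame(id = id, herd = herd, entry = entry_v,
                       death_interval = death, removed_at = removed_at)
  )
}

#' Construct a herd count/harvest series from demographic rates
#'
#' Deterministic closed-loop construction: given a starting post-harvest
#' count and per-year growth, harvest-fraction and recruitment schedules,
#' builds a [herd_series()] from which [growth_rate()],
#' [recruitment_rate()] and [harvest_rate()] recover the inputs exactly.
#' Pre-harvest animals in year `t` are `N[t-1] * (1 + growth[t])`; a
#' fraction `harvest[t]` of them is harvested. The same class composition
#' (males a fixed share, calves `recruitment` per female) is applied to the
#' harvested and the counted animals, which makes the recruitment identity
#' exact. Counts are left non-integer on purpose.
#'
#' @param start_n Post-harvest count in the year before the first
#'   constructed year.
#' @param growth Per-year growth rates before harvest (vector, one per
#'   constructed year).
#' @param harvest Per-year harvested fraction of the pre-harvest herd, in
#'   `[0, 1)`.
#' @param recruitment Per-year calves per female over one year.
#' @param male_share Share of males over one year in both counted and
#'   harvested animals (default 0.1).
#' @param herd Herd label for the output.
#' @param start_year Year of `start_n`.
#' @return A [herd_series()] whose first row is the starting year (totals
#'   only).
#' @export
simulate_herd_series <- function(start_n, growth, harvest, recruitment,
                                 male_share = 0.1, herd = "A",
                                 start_year = 2007) {
  n_years <- length(growth)
  if (length(harvest) != n_years || length(recruitment) != n_years)
    stop("`growth`, `harvest` and `recruitment` must have equal length")
  if (any(harvest < 0 | harvest >= 1)) stop("`harvest` must be in [0, 1)")
  if (male_share < 0 || male_share >= 1) stop("bad `male_share`")
  rows <- list(data.frame(
    herd = herd, year = start_year, N_total = start_n, H_total = 0,
    N_calves = NA_real_, N_females = NA_real_, N_males = NA_real_,
    H_calves = NA_real_, H_females = NA_real_, H_males = NA_real_))
  N_prev <- start_n
  for (t in seq_len(n_years)) {
    pre <- N_prev * (1 + growth[t])
    H <- pre * harvest[t]
    N <- pre - H
    if (N <= 0) stop("rates produce a non-positive herd in year ", t)
    f_share <- (1 - male_share) / (1 + recruitment[t])
    c_share <- recruitment[t] * f_share
    rows[[t + 1]] <- data.frame(
      herd = herd, year = start_year + t, N_total = N, H_total = H,
      N_calves = N * c_share, N_females = N * f_share,
      N_males = N * male_share,
      H_calves = H * c_share, H_females = H * f_share,
      H_males = H * male_share)
    N_prev <- N
  }
  herd_series(do.call(rbind, rows))
}
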