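test_that("constant-parameter recovery at large n is within 0.01", {
  cal <- toy_calendar(6)
  # terminal interval simulated at 1 to match the structure convention
  # (the final survival-recapture product is absorbed by the last p)
  phi <- matrix(c(rep(0.9, 4), 1), ncol = 1, dimnames = list(NULL, "A"))
  p <- matrix(0.7, 5, 1, dimnames = list(NULL, "A"))
  design <- simulation_design(
    cal, data.frame(herd = "A", occasion = 1, n = 10000), phi, p)
  sim <- simulate_histories(design, seed = 21)
  st <- cjs_structure(cal, phi = "constant", p = "constant",
                      phi_fix = data.frame(interval = 5, herd = "A",
                                           value = 1))
  # last interval fixed so the constant survival is estimated from
  # identifiable transitions only
  fit <- fit_cjs(sim$histories, st, cjs_options(n_starts = 2))
  expect_lt(abs(fit$phi$estimate[1] - 0.9), 0.01)
  expect_lt(abs(fit$p$estimate[1] - 0.7), 0.01)
  expect_true(all(fit$phi$estimate >= 0 & fit$phi$estimate <= 1))
  ci <- fit$phi[!fit$phi$fixed, ]
  expect_true(all(ci$lcl <= ci$estimate & ci$estimate <= ci$ucl))
})

test_that("three-occasion MLEs match the closed-form m-array estimators", {
  for (seed in c(4, 12)) {
    cal <- toy_calendar(3)
    design <- simulation_design(
      cal, data.frame(herd = "A", occasion = 1, n = 300),
      phi = matrix(c(0.85, 0.8), ncol = 1, dimnames = list(NULL, "A")),
      p = matrix(c(0.55, 0.6), ncol = 1, dimnames = list(NULL, "A")))
    sim <- simulate_histories(design, seed = seed)
    st <- cjs_structure(cal, phi = "time", p = "time",
                        phi_fix = data.frame(interval = 2, herd = "A",
                                             value = 1))
    fit <- fit_cjs(sim$histories, st, cjs_options(n_starts = 3))
    ma <- build_marray(sim$histories)$A
    lam2 <- ma$m[2, 3] / ma$R[2]                    # phi_2 * p_3 product
    phi1 <- ma$m[1, 2] / ma$R[1] + ma$m[1, 3] / (ma$R[1] * lam2)
    p2 <- (ma$m[1, 2] / ma$R[1]) / phi1
    expect_lt(abs(fit$phi$estimate[1] - phi1), 1e-6)
    expect_lt(abs(fit$p$estimate[1] - p2), 1e-6)
    expect_lt(abs(fit$p$estimate[2] - lam2), 1e-6)
  }
})

test_that("the maximized likelihood is at least that of the truth", {
  for (seed in 1:5) {
    ds <- random_dataset(seed, K = 5, n = 60)
    st <- cjs_structure(ds$calendar, phi = "time", p = "time")
    # boundary refitting disabled so the comparison is in the same space
    fit <- fit_cjs(ds$sim$histories, st,
                   cjs_options(n_starts = 2, boundary_threshold = 1))
    theta_true <- stats::qlogis(c(ds$design$phi[, 1], ds$design$p[, 1]))
    ll_true <- cjs_loglik(theta_true, st, ds$sim$histories)
    expect_gte(fit$loglik + 1e-6, ll_true)
  }
})

test_that("saturated data drives survival to the boundary and flags it", {
  cal <- toy_calendar(4)
  h <- toy_histories(rep(list(c(1, 1, 1, 1)), 25), cal)
  st <- cjs_structure(cal, phi = "herd:time", p = "constant")
  fit <- fit_cjs(h, st, cjs_options(n_starts = 1))
  expect_gt(length(fit$boundary_flags), 0)
  expect_true(any(fit$phi$fixed & fit$phi$estimate == 1))
})

test_that("fixing a parameter at its MLE barely moves the likelihood", {
  ds <- random_dataset(7, K = 5, n = 120)
  st <- cjs_structure(ds$calendar, phi = "herd:time", p = "time")
  fit <- fit_cjs(ds$sim$histories, st, cjs_options(n_starts = 2))
  target <- which(!fit$phi$fixed)[1]
  st_fixed <- cjs_structure(
    ds$calendar, phi = "herd:time", p = "time",
    phi_fix = data.frame(interval = fit$phi$interval[target],
                         herd = fit$phi$herd[target],
                         value = fit$phi$estimate[target]))
  fit2 <- fit_cjs(ds$sim$histories, st_fixed, cjs_options(n_starts = 2))
  expect_equal(fit2$K, fit$K - 1)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6)
})

test_that("Wald intervals achieve near-nominal coverage", {
  # 200 moderate-n replicates of a 4-occasion constant model; the logit
  # Wald interval is approximate, so a coarse 90-98% band is asserted
  cal <- toy_calendar(4)
  phi <- matrix(0.85, 3, 1, dimnames = list(NULL, "A"))
  p <- matrix(0.6, 3, 1, dimnames = list(NULL, "A"))
  design <- simulation_design(
    cal, data.frame(herd = "A", occasion = 1, n = 150), phi, p)
  st <- cjs_structure(cal, phi = "constant", p = "constant",
                      phi_fix = data.frame(interval = 3, herd = "A",
                                           value = 1))
  hits <- 0L
  for (r in 1:200) {
    sim <- simulate_histories(design, seed = 3000 + r)
    fit <- fit_cjs(sim$histories, st, cjs_options(n_starts = 1))
    row <- fit$phi[!fit$phi$fixed, ][1, ]
    if (!is.na(row$lcl) && row$lcl <= 0.85 && row$ucl >= 0.85)
      hits <- hits + 1L
  }
  expect_gte(hits, 180)
  expect_lte(hits, 196)
})

test_that("identical structures tie and AICc ranks the candidate set", {
  ds <- random_dataset(2, K = 5, n = 80)
  sa <- cjs_structure(ds$calendar, phi = "time", p = "time",
                      label = "first copy")
  sb <- cjs_structure(ds$calendar, phi = "time", p = "time",
                      label = "second copy")
  cmp <- compare_models(ds$sim$histories, list(a = sa, b = sb),
                        cjs_options(n_starts = 1))
  expect_equal(cmp$dAICc, c(0, 0))
  expect_equal(cmp$AICc[1], cmp$AICc[2])
})

test_that("a true herd-by-time survival effect wins the AICc comparison", {
  cal <- two_herd_calendar(rep(2007:2009, each = 2),
                           rep(c("july", "autumn"), 3))
  # survival diverges between herds in a time-varying way
  phi <- cbind(A = c(0.95, 0.95, 0.95, 0.95, 1),
               B = c(0.95, 0.60, 0.95, 0.55, 1))
  p <- cbind(A = rep(0.7, 5), B = rep(0.6, 5))
  design <- simulation_design(
    cal, data.frame(herd = c("A", "B"), occasion = c(1, 1),
                    n = c(350, 350)), phi, p)
  terminal <- data.frame(interval = c(5, 5), herd = c("A", "B"), value = 1)
  structures <- list(
    "phi(herd:time) p(herd+time)" =
      cjs_structure(cal, "herd:time", "herd+time", phi_fix = terminal),
    "phi(herd+time) p(herd+time)" =
      cjs_structure(cal, "herd+time", "herd+time", phi_fix = terminal),
    "phi(herd:time) p(time)" =
      cjs_structure(cal, "herd:time", "time", phi_fix = terminal),
    "phi(time) p(herd+time)" =
      cjs_structure(cal, "time", "herd+time", phi_fix = terminal))
  wins <- 0L
  for (r in 1:5) {
    sim <- simulate_histories(design, seed = 500 + r)
    cmp <- compare_models(sim$histories, structures,
                          cjs_options(n_starts = 1))
    wins <- wins + (cmp$model[1] == "phi(herd:time) p(herd+time)")
  }
  expect_gte(wins, 3)
})
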