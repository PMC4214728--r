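make_series <- function() {
  herd_series(data.frame(
    herd = "A", year = 2007:2009,
    N_total = c(1000, 900, 800),
    H_total = c(0, 300, 200),
    N_calves = c(300, 270, 240), N_females = c(600, 540, 480),
    N_males = c(100, 90, 80),
    H_calves = c(0, 90, 60), H_females = c(0, 180, 120),
    H_males = c(0, 30, 20)))
}

test_that("growth, recruitment and harvest rates follow their definitions", {
  s <- make_series()
  expect_equal(growth_rate(s, "A", 2008), (900 + 300) / 1000 - 1)  # 0.20
  expect_equal(harvest_rate(s, "A", 2008), 300 / 1200)             # 0.25
  expect_equal(harvest_rate(s, "A", 2008, "calves"), 90 / 360)
  expect_equal(recruitment_rate(s, "A", 2008), (90 + 270) / (180 + 540))
  expect_error(growth_rate(s, "A", 2007), "no record")
  # no change, no harvest -> zero growth
  s0 <- herd_series(data.frame(herd = "B", year = 1:2,
                               N_total = c(500, 500), H_total = c(0, 0)))
  expect_equal(growth_rate(s0, "B", 2), 0)
})

test_that("growth rate is scale invariant and rates stay in range", {
  s <- make_series()
  s2 <- s
  num <- setdiff(names(s2), c("herd", "year"))
  s2[num] <- s2[num] * 3.7
  expect_equal(growth_rate(s2, "A", 2008), growth_rate(s, "A", 2008))
  rates <- herd_rates(s)
  expect_true(all(rates$harvest >= 0 & rates$harvest <= 1))
  expect_true(all(rates$recruitment >= 0))
})

test_that("a constructed recruitment split reproduces 0.50 calves/female", {
  s <- herd_series(data.frame(
    herd = "A", year = 2008,
    N_total = 1350 + 50, H_total = 150 + 50,
    N_calves = 400, N_females = 950, N_males = 50,
    H_calves = 100, H_females = 50, H_males = 50))
  expect_equal(recruitment_rate(s, "A", 2008), 0.50)
})

test_that("series splits must be consistent and years contiguous", {
  bad <- data.frame(herd = "A", year = 2007, N_total = 100, H_total = 10,
                    N_calves = 10, N_females = 10, N_males = 10,
                    H_calves = 5, H_females = 4, H_males = 1)
  expect_error(herd_series(bad), "sum to N_total")
  gap <- data.frame(herd = "A", year = c(2007, 2009),
                    N_total = c(100, 90), H_total = c(0, 0))
  expect_error(herd_series(gap), "contiguous")
})

test_that("annual survival multiplies intervals into autumn-years", {
  sch <- reference_survival()
  a <- annual_survival(sch, "A")
  expect_equal(nrow(a$yearly), 4)
  expect_equal(a$yearly$year_from, 2007:2010)
  # 2008 -> 2009: product of the three intervals ending in 2009
  expect_equal(a$yearly$survival[2], 0.985 * 1.000 * 0.937,
               tolerance = 1e-12)
  expect_equal(round(a$yearly$survival[2], 4), 0.9229)
  # all-ones schedule gives unit yearly products
  ones <- data.frame(herd = "A", year = rep(2008:2010, each = 3),
                     season = rep(c("spring", "july", "autumn"), 3),
                     estimate = 1)
  a1 <- annual_survival(ones, "A", exclude_last_year = FALSE)
  expect_true(all(a1$yearly$survival == 1))
})

test_that("accumulated survival is the running product over the window", {
  sch <- reference_survival()
  a <- annual_survival(sch, "A", exclude_last_year = FALSE)
  acc <- accumulated_survival(sch, "A", 2007, 2011)
  expect_equal(acc, prod(a$yearly$survival[a$yearly$year_from <= 2010]),
               tolerance = 1e-12)
  # empty window is the empty product
  expect_equal(accumulated_survival(sch, "A", 2011, 2011), 1)
})

test_that("expected losses round the mortality x females product", {
  expect_equal(expected_losses(0.10, 500), 50)
  expect_equal(expected_losses(0, 1000), 0)
  expect_equal(expected_losses(0.184, 543), 100)
  expect_error(expected_losses(1.2, 10), "0, 1")
})

test_that("schedules round-trip through CSV", {
  sch <- reference_survival()
  path <- tempfile(fileext = ".csv")
  utils::write.csv(sch, path, row.names = FALSE)
  back <- read_schedule(path)
  expect_equal(back$estimate, sch$estimate)
  expect_equal(annual_survival(back, "B")$mean,
               annual_survival(sch, "B")$mean)
})
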