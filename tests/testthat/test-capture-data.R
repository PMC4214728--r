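test_that("the study calendar encodes the two-herd sampling design", {
  cal <- study_calendar()
  expect_equal(n_occasions(cal), 18)
  expect_identical(herds(cal), c("A", "B"))
  expect_true(all(cal$capturable[, "A"]))
  expect_true(all(!cal$capturable[season_occasions(cal, "spring"), "B"]))
  expect_true(all(cal$capturable[season_occasions(cal, "autumn"), "B"]))
  expect_equal(occasion_label(cal, 1), "spring 2007")
  expect_equal(interval_label(cal, 17), "autumn 2012")
})

test_that("calendars reject disorder and duplicates", {
  expect_error(occasion_calendar(c(2008, 2007), c("july", "july"),
                                 matrix(TRUE, 2, 1,
                                        dimnames = list(NULL, "A"))),
               "ordered")
  expect_error(occasion_calendar(c(2007, 2007), c("july", "july"),
                                 matrix(TRUE, 2, 1,
                                        dimnames = list(NULL, "A"))),
               "duplicated")
})

test_that("INP records decode detections, groups and the removal sign", {
  cal <- two_herd_calendar(rep(2007:2008, each = 3),
                           rep(c("spring", "july", "autumn"), 2))
  txt <- c("/* marked cohort */",
           "110100 1 0;",
           "110100 -1 0;",
           "010010 0 2;")
  h <- read_histories(NULL, cal, format = "inp", text = txt)
  expect_equal(length(h), 4L)
  expect_equal(unname(h$detections[1, ]), c(1, 1, 0, 1, 0, 0))
  expect_false(h$removed[1])
  expect_true(h$removed[2])
  expect_equal(h$herd, c("A", "A", "B", "B"))
  expect_equal(h$detections[3, ], h$detections[4, ])
})

test_that("structurally impossible detections are rejected", {
  cal <- two_herd_calendar(rep(2007:2008, each = 3),
                           rep(c("spring", "july", "autumn"), 2))
  # herd B detected at a spring occasion
  expect_error(
    encounter_histories("b1", "B", matrix(c(1, 0, 0, 1, 0, 0), 1),
                        FALSE, cal),
    "non-capturable")
  expect_error(read_histories(NULL, cal, format = "inp",
                              text = "110100 1;"),
               "frequency per herd")
  expect_error(read_histories(NULL, cal, format = "inp",
                              text = "1101 1 0;"),
               "does not match")
  expect_error(
    encounter_histories("a1", "C", matrix(c(0, 1, 0, 0, 0, 0), 1),
                        FALSE, cal),
    "unknown herd")
  expect_error(
    encounter_histories("a1", "A", matrix(0, 1, 6), FALSE, cal),
    "at least one detection")
})

test_that("CSV and INP round-trips reproduce the dataset", {
  for (seed in 1:3) {
    ds <- random_dataset(seed, K = 6, n = 25)
    h <- ds$sim$histories
    csv <- tempfile(fileext = ".csv")
    inp <- tempfile(fileext = ".inp")
    write_histories(h, csv)
    write_histories(h, inp)
    h_csv <- read_histories(csv, ds$calendar)
    expect_identical(h_csv$detections, h$detections)
    expect_identical(h_csv$herd, h$herd)
    expect_identical(h_csv$removed, h$removed)
    h_inp <- read_histories(inp, ds$calendar)
    # INP drops ids; compare the multiset of (pattern, removed) records
    key <- function(x) sort(paste(apply(x$detections, 1, paste,
                                        collapse = ""), x$removed))
    expect_identical(key(h_inp), key(h))
  }
})

test_that("calendar files round-trip through CSV and YAML", {
  cal <- study_calendar()
  csv <- tempfile(fileext = ".csv")
  write_calendar(cal, csv)
  cal2 <- read_calendar(csv)
  expect_identical(cal2$occasions, cal$occasions)
  expect_identical(cal2$capturable, cal$capturable)
  yml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    occasions = lapply(seq_len(18), function(i)
      list(year = cal$occasions$year[i],
           season = cal$occasions$season[i])),
    herds = list(A = "all", B = list(exclude_seasons = list("spring")))
  )), yml)
  cal3 <- read_calendar(yml)
  expect_identical(cal3$capturable, cal$capturable)
})

test_that("m-array counts transitions, removals and empty input correctly", {
  cal <- toy_calendar(3)
  h <- toy_histories(list(c(1, 1, 1), c(1, 0, 1)), cal)
  ma <- build_marray(h)$A
  expect_equal(ma$R, c(2, 1))
  expect_equal(ma$m[1, 2:3], c(1, 1))
  expect_equal(ma$m[2, 3], 1)
  expect_equal(ma$never, c(0, 0))

  # removal stops the release at the final capture
  hr <- toy_histories(list(c(1, 1, 0)), cal, removed = TRUE)
  mar <- build_marray(hr)$A
  expect_equal(mar$R, c(1, 0))
  expect_equal(mar$m[1, 2], 1)

  # marking at the final occasion opens no release row
  hk <- toy_histories(list(c(0, 0, 1)), cal)
  expect_equal(build_marray(hk)$A$R, c(0, 0))
})

test_that("m-array totals conserve release segments on random data", {
  for (seed in 1:5) {
    ds <- random_dataset(seed, K = 6, n = 30)
    h <- ds$sim$histories
    ma <- build_marray(h)
    expect_equal(total_releases(ma), count_release_segments(h))
    a <- ma$A
    expect_true(all(rowSums(a$m) <= a$R))
    expect_true(all(a$m >= 0) && all(a$never >= 0))
  }
})

test_that("known_alive matches its definition and is non-increasing", {
  cal <- toy_calendar(3)
  h <- toy_histories(list(c(1, 0, 1), c(1, 1, 0)), cal)
  expect_equal(known_alive(h, 2), c(A = 2L))
  expect_equal(known_alive(h, 3), c(A = 1L))
  expect_error(known_alive(h, 4), "1..3")

  ds <- random_dataset(9, K = 6, n = 100)
  h <- ds$sim$histories
  counts <- vapply(1:6, function(t) known_alive(h, t), c(A = 0L))
  oracle <- vapply(1:6, function(t) known_alive_oracle(h, t), c(A = 0L))
  expect_identical(counts, oracle)
  expect_true(all(diff(counts) <= 0))
})
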