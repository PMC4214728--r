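#' Herd count and harvest series
#'
#' Validates a per-herd, per-year table of winter counts and harvest
#' numbers. `N_*` columns are counts *after* harvest (the winter herd);
#' `H_*` columns are harvested animals. Class splits (calves, females over
#' one year, males over one year) are optional but must sum to their totals
#' where both are given. Counts may be non-integer: the deterministic series
#' generator works in expected animals.
#'
#' @param x Data frame with columns `herd`, `year`, `N_total`, `H_total`
#'   and optionally `N_calves`, `N_females`, `N_males`, `H_calves`,
#'   `H_females`, `H_males`.
#' @return The validated data frame, classed `herd_series`.
#' @export
herd_series <- function(x) {
  need <- c("herd", "year", "N_total", "H_total")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  num <- setdiff(names(x), "herd")
  if (any(vapply(x[num], function(v) any(v < 0, na.rm = TRUE), TRUE)))
    stop("counts and harvests must be non-negative")
  for (side in c("N", "H")) {
    parts <- paste0(side, c("_calves", "_females", "_males"))
    if (all(parts %in% names(x))) {
      tot <- rowSums(x[parts])
      ok <- is.na(tot) | abs(tot - x[[paste0(side, "_total")]]) < 1e-6
      if (!all(ok))
        stop(side, " class splits do not sum to ", side, "_total")
    }
  }
  for (h in unique(x$herd)) {
    yrs <- sort(x$year[x$herd == h])
    if (length(yrs) > 1 && any(diff(yrs) != 1))
      stop("years must be contiguous within herd ", h)
  }
  class(x) <- c("herd_series", class(x))
  x
}

series_row <- function(series, herd, year) {
  r <- series[series$herd == herd & series$year == year, , drop = FALSE]
  if (nrow(r) != 1)
    stop("no record for herd ", herd, ", year ", year)
  r
}

#' Annual herd growth rate before harvest
#'
#' `rG_t = (N_t + H_t) / N_{t-1} - 1`: the herd present in year `t` before
#' harvest, relative to the previous year's post-harvest count. The rate is
#' invariant under rescaling all counts by a common factor.
#'
#' @param series A [herd_series()].
#' @param herd Herd label.
#' @param year Year `t`.
#' @return Growth rate (scalar).
#' @export
growth_rate <- function(series, herd, year) {
  now <- series_row(series, herd, year)
  prev <- series_row(series, herd, year - 1)
  if (prev$N_total <= 0) stop("previous year's count must be positive")
  (now$N_total + now$H_total) / prev$N_total - 1
}

#' Autumn recruitment rate
#'
#' Calves per female over one year at the autumn count: (harvested calves +
#' counted calves after harvest) / (harvested females + counted females
#' after harvest).
#'
#' @param series A [herd_series()] with class splits.
#' @param herd Herd label.
#' @param year Year.
#' @return Recruitment rate (calves per female).
#' @export
recruitment_rate <- function(series, herd, year) {
  r <- series_row(series, herd, year)
  den <- r$H_females + r$N_females
  if (!is.finite(den) || den <= 0) stop("no females in the denominator")
  (r$H_calves + r$N_calves) / den
}

#' Harvest rate
#'
#' Harvested animals divided by the sum of harvested and counted (after
#' harvest) animals, for all animals or for calves only.
#'
#' @param series A [herd_series()].
#' @param herd Herd label.
#' @param year Year.
#' @param class `"all"` or `"calves"`.
#' @return Harvest rate in `[0, 1]`.
#' @export
harvest_rate <- function(series, herd, year, class = c("all", "calves")) {
  class <- match.arg(class)
  r <- series_row(series, herd, year)
  H <- if (class == "all") r$H_total else r$H_calves
  N <- if (class == "all") r$N_total else r$N_calves
  if (!is.finite(H + N) || H + N <= 0) stop("empty class")
  H / (H + N)
}

#' All demographic rates of a herd series
#'
#' @param series A [herd_series()].
#' @return Data frame with one row per herd-year (from each herd's second
#'   year on) and columns `herd`, `year`, `growth`, `recruitment`,
#'   `harvest`, `harvest_calves` (the last three `NA` where splits are
#'   absent).
#' @export
herd_rates <- function(series) {
  out <- list()
  for (h in unique(series$herd)) {
    yrs <- sort(series$year[series$herd == h])
    for (y in yrs[-1]) {
      rec <- tryCatch(recruitment_rate(series, h, y),
                      error = function(e) NA_real_)
      hrc <- tryCatch(harvest_rate(series, h, y, "calves"),
                      error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        herd = h, year = y,
        growth = growth_rate(series, h, y),
        recruitment = rec,
        harvest = harvest_rate(series, h, y),
        harvest_calves = hrc)
    }
  }
  do.call(rbind, out)
}

# -- survival schedules ----------------------------------------------------

season_rank <- function(season) match(season, c("spring", "july", "autumn"))

check_schedule <- function(schedule) {
  need <- c("herd", "year", "season", "estimate")
  missing <- setdiff(need, names(schedule))
  if (length(missing))
    stop("schedule is missing columns: ", paste(missing, collapse = ", "))
  if (any(schedule$estimate < 0 | schedule$estimate > 1))
    stop("survival estimates must be in [0, 1]")
  invisible(schedule)
}

# intervals whose end occasion lies in (autumn year_from, autumn year_to]
schedule_window <- function(schedule, herd, year_from, year_to) {
  s <- schedule[schedule$herd == herd, , drop = FALSE]
  t_end <- s$year + season_rank(s$season) / 10
  lo <- year_from + 0.3
  hi <- year_to + 0.3
  s[t_end > lo & t_end <= hi, , drop = FALSE]
}

#' Annual autumn-to-autumn survival
#'
#' Multiplies the interval survival estimates between consecutive autumn
#' occasions into per-year survival products and averages them
#' (arithmetically). Intervals spanning several sampling seasons (e.g. an
#' autumn-to-July estimate for a herd never gathered in spring) enter as the
#' single estimate they are. The last study year is excluded by default:
#' its terminal survival is conventionally fixed at 1 and carries no
#' information.
#'
#' @param schedule Survival schedule: data frame with columns `herd`,
#'   `year`, `season` (end of each interval), `estimate` (see
#'   [fitted_schedule()], [read_schedule()] or [reference_survival()]).
#' @param herd Herd label.
#' @param exclude_last_year Drop the final autumn-to-autumn year.
#' @return A list with `yearly` (data frame `year_from`, `year_to`,
#'   `survival`) and `mean`.
#' @export
annual_survival <- function(schedule, herd, exclude_last_year = TRUE) {
  check_schedule(schedule)
  s <- schedule[schedule$herd == herd, , drop = FALSE]
  if (!nrow(s)) stop("no schedule rows for herd ", herd)
  aut <- sort(unique(s$year[s$season == "autumn"]))
  if (!length(aut)) stop("schedule has no autumn-ending intervals")
  # autumn-to-autumn years start at the first autumn boundary in the
  # schedule; intervals ending before it (the marking year) are not part of
  # any whole year
  years <- min(aut):max(s$year)
  yearly <- do.call(rbind, lapply(years, function(y) {
    w <- schedule_window(s, herd, y, y + 1)
    if (!nrow(w)) return(NULL)
    data.frame(year_from = y, year_to = y + 1,
               survival = prod(w$estimate))
  }))
  if (exclude_last_year) yearly <- yearly[-nrow(yearly), , drop = FALSE]
  list(yearly = yearly, mean = mean(yearly$survival))
}

#' Accumulated survival between two autumns
#'
#' The running product of interval survival estimates from one autumn to a
#' later one; the empty window gives 1.
#'
#' @inheritParams annual_survival
#' @param year_from,year_to Autumn years bounding the window.
#' @return Accumulated survival probability.
#' @export
accumulated_survival <- function(schedule, herd, year_from, year_to) {
  check_schedule(schedule)
  w <- schedule_window(schedule, herd, year_from, year_to)
  prod(w$estimate)
}

#' Expected number of females lost per year
#'
#' @param annual_mortality Annual mortality rate in `[0, 1]`.
#' @param n_females Number of females at risk.
#' @return Rounded expected losses.
#' @export
expected_losses <- function(annual_mortality, n_females) {
  if (annual_mortality < 0 || annual_mortality > 1)
    stop("`annual_mortality` must be in [0, 1]")
  round(annual_mortality * n_females)
}

#' Read a survival schedule from CSV
#'
#' Expects columns `herd`, `year`, `season`, `estimate` (plus anything
#' else, which is kept). `year`/`season` name the occasion at which each
#' survival interval ends.
#'
#' @param path CSV file path.
#' @return A schedule data frame.
#' @export
read_schedule <- function(path) {
  check_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}
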