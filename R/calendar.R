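#' Sampling-occasion calendar
#'
#' An occasion calendar is the ordered list of gathering events at which
#' marked animals can be re-observed, together with a per-herd capturability
#' flag (a herd that is never gathered at a given occasion cannot produce a
#' detection there, and its recapture probability is a structural zero).
#'
#' @param years Integer vector, one entry per occasion.
#' @param seasons Character vector, one of `"spring"`, `"july"`, `"autumn"`
#'   per occasion. Occasions must be strictly ordered in time (by year, then
#'   spring < july < autumn).
#' @param capturable Logical matrix with one row per occasion and one named
#'   column per herd. `TRUE` means the herd is gathered at that occasion.
#' @return An object of class `occasion_calendar`: a list with elements
#'   `occasions` (data frame with columns `occasion`, `year`, `season`) and
#'   `capturable` (logical matrix, occasions x herds).
#' @examples
#' cal <- occasion_calendar(
#'   years = c(2007, 2007, 2008),
#'   seasons = c("july", "autumn", "july"),
#'   capturable = cbind(A = c(TRUE, TRUE, TRUE), B = c(FALSE, TRUE, TRUE))
#' )
#' n_occasions(cal)
#' @export
occasion_calendar <- function(years, seasons, capturable) {
  seasons <- match.arg(seasons, c("spring", "july", "autumn"),
                       several.ok = TRUE)
  if (length(years) != length(seasons))
    stop("`years` and `seasons` must have the same length")
  ord <- order(years, match(seasons, c("spring", "july", "autumn")))
  if (!identical(ord, seq_along(years)))
    stop("occasions must be strictly ordered in time")
  if (anyDuplicated(paste(years, seasons)))
    stop("duplicated occasions")
  capturable <- as.matrix(capturable)
  if (nrow(capturable) != length(years))
    stop("`capturable` needs one row per occasion")
  if (is.null(colnames(capturable)))
    stop("`capturable` needs one named column per herd")
  storage.mode(capturable) <- "logical"
  structure(
    list(
      occasions = data.frame(occasion = seq_along(years),
                             year = as.integer(years),
                             season = seasons),
      capturable = capturable
    ),
    class = "occasion_calendar"
  )
}

#' @export
print.occasion_calendar <- function(x, ...) {
  cat("Occasion calendar:", n_occasions(x), "occasions,",
      paste(herds(x), collapse = "/"), "herds\n")
  occ <- x$occasions
  occ$capturable <- apply(x$capturable, 1, function(z)
    paste(colnames(x$capturable)[z], collapse = ","))
  print(occ, row.names = FALSE)
  invisible(x)
}

#' Number of occasions in a calendar
#' @param calendar An [occasion_calendar()].
#' @return Integer count of occasions.
#' @export
n_occasions <- function(calendar) nrow(calendar$occasions)

#' Herd labels of a calendar
#' @param calendar An [occasion_calendar()].
#' @return Character vector of herd names.
#' @export
herds <- function(calendar) colnames(calendar$capturable)

#' Label for an occasion or an interval
#'
#' Intervals are identified by their 1-based index `i`, running from occasion
#' `i` to occasion `i + 1`; their label names the occasion at which the
#' interval *ends*, matching the convention of survival tables where dates
#' refer to the end of the survival period.
#'
#' @param calendar An [occasion_calendar()].
#' @param i Occasion (or interval) index.
#' @return Character label such as `"july 2008"`.
#' @export
occasion_label <- function(calendar, i) {
  occ <- calendar$occasions
  paste(occ$season[i], occ$year[i])
}

#' @rdname occasion_label
#' @export
interval_label <- function(calendar, i) occasion_label(calendar, i + 1L)

#' Occasion indices of a given season
#' @param calendar An [occasion_calendar()].
#' @param season One of `"spring"`, `"july"`, `"autumn"`.
#' @return Integer vector of occasion indices.
#' @export
season_occasions <- function(calendar, season) {
  which(calendar$occasions$season == season)
}

#' The 18-occasion two-herd study calendar
#'
#' The monitoring design this package was built around: two herds (A and B)
#' observed at up to three occasions per year -- spring (March--April), July
#' (calf marking) and autumn (the main gathering, October--December) -- from
#' spring 2007 through autumn 2012. Herd B was never gathered in spring, so
#' all six spring occasions are non-capturable for it.
#'
#' @return An [occasion_calendar()] with 18 occasions and herds `A` and `B`.
#' @export
study_calendar <- function() {
  years <- rep(2007:2012, each = 3)
  seasons <- rep(c("spring", "july", "autumn"), times = 6)
  cap <- cbind(A = rep(TRUE, 18), B = seasons != "spring")
  occasion_calendar(years, seasons, cap)
}

#' Read an occasion calendar from a YAML or CSV file
#'
#' YAML layout: a top-level `occasions` list of `{year, season}` entries and
#' a `herds` map from herd name to either the string `"all"` or a map with an
#' `exclude_seasons` list. CSV layout: columns `year`, `season`, then one 0/1
#' column per herd.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"yaml"` or `"csv"`.
#' @return An [occasion_calendar()].
#' @export
read_calendar <- function(path, format = c("auto", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml"
              else "csv"
  }
  if (format == "yaml") {
    conf <- yaml::read_yaml(path)
    years <- vapply(conf$occasions, function(o) as.integer(o$year), 1L)
    seasons <- vapply(conf$occasions, function(o) as.character(o$season), "")
    cap <- vapply(conf$herds, function(h) {
      if (identical(h, "all")) rep(TRUE, length(years))
      else !(seasons %in% unlist(h$exclude_seasons))
    }, logical(length(years)))
    occasion_calendar(years, seasons, cap)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    herd_cols <- setdiff(names(tab), c("year", "season"))
    cap <- as.matrix(tab[herd_cols]) > 0
    colnames(cap) <- herd_cols
    occasion_calendar(tab$year, tab$season, cap)
  }
}

#' Write an occasion calendar to CSV
#' @param calendar An [occasion_calendar()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calendar <- function(calendar, path) {
  tab <- cbind(calendar$occasions[c("year", "season")],
               as.data.frame(calendar$capturable) * 1L)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stopifnot_calendar <- function(calendar) {
  if (!inherits(calendar, "occasion_calendar"))
    stop("`calendar` must be an occasion_calendar")
  invisible(calendar)
}
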