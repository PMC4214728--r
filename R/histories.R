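#' Individual encounter histories
#'
#' An encounter history is one marked female's 0/1 detection sequence over
#' the occasion calendar, together with her herd and a removal flag. Removal
#' (`removed = TRUE`) marks an animal deliberately taken out of the herd
#' (harvested/culled) at its last encounter: it contributes no survival
#' information after that occasion.
#'
#' @param id Character vector of individual identifiers.
#' @param herd Character vector of herd labels (must match the calendar's
#'   herds).
#' @param detections 0/1 matrix, one row per individual, one column per
#'   occasion.
#' @param removed Logical vector: was the animal removed (harvested) at its
#'   last encounter?
#' @param calendar An [occasion_calendar()].
#' @return An object of class `encounter_histories`: a list with elements
#'   `calendar`, `id`, `herd`, `removed` and `detections`.
#' @export
encounter_histories <- function(id, herd, detections, removed, calendar) {
  stopifnot_calendar(calendar)
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  dimnames(detections) <- NULL
  n <- length(id)
  if (length(herd) != n || length(removed) != n || nrow(detections) != n)
    stop("id, herd, removed and detections must describe the same animals")
  if (ncol(detections) != n_occasions(calendar))
    stop("detection sequences must have one entry per calendar occasion (",
         n_occasions(calendar), "), got ", ncol(detections))
  if (!all(detections %in% 0:1))
    stop("detections must be 0 or 1")
  bad_herd <- !herd %in% herds(calendar)
  if (any(bad_herd))
    stop("unknown herd label: ", paste(unique(herd[bad_herd]), collapse = ", "))
  if (any(rowSums(detections) == 0))
    stop("every history needs at least one detection (the marking event)")
  # structural zeros: no detection where the herd is not gathered
  for (h in herds(calendar)) {
    idx <- herd == h
    blocked <- !calendar$capturable[, h]
    if (any(idx) && any(blocked) &&
        any(detections[idx, blocked, drop = FALSE] == 1)) {
      stop("detection at a non-capturable occasion for herd ", h)
    }
  }
  structure(
    list(calendar = calendar, id = as.character(id),
         herd = as.character(herd), removed = as.logical(removed),
         detections = detections),
    class = "encounter_histories"
  )
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("Encounter histories:", length(x$id), "individuals over",
      n_occasions(x$calendar), "occasions\n")
  tab <- table(herd = x$herd, removed = x$removed)
  print(tab)
  invisible(x)
}

#' @export
length.encounter_histories <- function(x) length(x$id)

#' Subset encounter histories
#' @param x An [encounter_histories()] object.
#' @param i Index vector of individuals.
#' @param ... Unused.
#' @return An `encounter_histories` object for the selected individuals.
#' @export
`[.encounter_histories` <- function(x, i, ...) {
  encounter_histories(x$id[i], x$herd[i], x$detections[i, , drop = FALSE],
                      x$removed[i], x$calendar)
}

occasion_colnames <- function(calendar) {
  paste(calendar$occasions$year, calendar$occasions$season, sep = "_")
}

#' Read encounter histories from CSV or MARK-style INP text
#'
#' Two dialects are supported. CSV: one row per individual with columns
#' `id`, `herd`, `removed`, then one 0/1 column per occasion named
#' `<year>_<season>`. INP (the de-facto MARK exchange format): one record
#' per line -- a detection string, whitespace, one signed integer frequency
#' per herd (in calendar herd order), and a `;` terminator. A negative
#' frequency encodes loss on capture (removal). `/* ... */` comments are
#' ignored.
#'
#' @param path File path (or, for INP, a character vector of lines via
#'   `text`).
#' @param calendar An [occasion_calendar()].
#' @param format `"auto"` (by extension), `"csv"` or `"inp"`.
#' @param text Optional character vector of raw lines, bypassing `path`.
#' @return An [encounter_histories()] object.
#' @export
read_histories <- function(path, calendar, format = c("auto", "csv", "inp"),
                           text = NULL) {
  stopifnot_calendar(calendar)
  format <- match.arg(format)
  if (format == "auto") {
    if (is.null(path)) stop("`format` must be given when reading from text")
    format <- if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    occ_cols <- occasion_colnames(calendar)
    missing <- setdiff(c("id", "herd", "removed", occ_cols), names(tab))
    if (length(missing))
      stop("CSV is missing columns: ", paste(missing, collapse = ", "))
    det <- as.matrix(tab[occ_cols])
    encounter_histories(tab$id, tab$herd, det,
                        as.logical(tab$removed), calendar)
  } else {
    lines <- if (is.null(text)) readLines(path) else text
    parse_inp(lines, calendar)
  }
}

parse_inp <- function(lines, calendar) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)          # strip comments
  records <- strsplit(txt, ";", fixed = TRUE)[[1]]
  records <- trimws(records)
  records <- records[nzchar(records)]
  K <- n_occasions(calendar)
  hs <- herds(calendar)
  id <- herd <- character(0)
  removed <- logical(0)
  det <- matrix(integer(0), ncol = K)
  counter <- 0L
  for (rec in records) {
    parts <- strsplit(rec, "\\s+")[[1]]
    ch <- parts[1]
    if (nchar(ch) != K)
      stop("INP detection string of length ", nchar(ch),
           " does not match the ", K, "-occasion calendar")
    freqs <- as.integer(parts[-1])
    if (length(freqs) != length(hs))
      stop("expected one frequency per herd (", length(hs),
           "), got ", length(freqs))
    row <- as.integer(strsplit(ch, "")[[1]])
    if (!all(row %in% 0:1)) stop("INP detection string must be 0/1")
    for (g in seq_along(hs)) {
      f <- freqs[g]
      if (f == 0L) next
      for (k in seq_len(abs(f))) {
        counter <- counter + 1L
        id <- c(id, sprintf("%s%04d", hs[g], counter))
        herd <- c(herd, hs[g])
        removed <- c(removed, f < 0L)
        det <- rbind(det, row)
      }
    }
  }
  encounter_histories(id, herd, det, removed, calendar)
}

#' Write encounter histories to CSV or INP
#'
#' @param histories An [encounter_histories()] object.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"inp"`.
#' @return `path`, invisibly.
#' @export
write_histories <- function(histories, path,
                            format = c("auto", "csv", "inp")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  cal <- histories$calendar
  if (format == "csv") {
    det <- as.data.frame(histories$detections)
    names(det) <- occasion_colnames(cal)
    tab <- cbind(data.frame(id = histories$id, herd = histories$herd,
                            removed = histories$removed), det)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    hs <- herds(cal)
    ch <- apply(histories$detections, 1, paste, collapse = "")
    lines <- vapply(seq_along(ch), function(i) {
      freqs <- integer(length(hs))
      freqs[match(histories$herd[i], hs)] <-
        if (histories$removed[i]) -1L else 1L
      paste0(ch[i], " ", paste(freqs, collapse = " "), ";")
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Minimum number known alive at an occasion
#'
#' Counts, per herd, the non-removed individuals detected at the given
#' occasion *or at any later occasion* -- i.e. animals verified as still in
#' the herd at that time. For a fixed, closed set of histories this count is
#' non-increasing in the occasion index.
#'
#' @param histories An [encounter_histories()] object.
#' @param occasion Occasion index (1-based).
#' @return Named integer vector, one count per herd.
#' @export
known_alive <- function(histories, occasion) {
  cal <- histories$calendar
  K <- n_occasions(cal)
  if (length(occasion) != 1 || occasion < 1 || occasion > K)
    stop("`occasion` must be a single index in 1..", K)
  seen_later <- rowSums(
    histories$detections[, occasion:K, drop = FALSE]) > 0
  keep <- seen_later & !histories$removed
  tab <- table(factor(histories$herd[keep], levels = herds(cal)))
  stats::setNames(as.integer(tab), herds(cal))
}
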