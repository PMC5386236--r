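#' File dialects for raw efflux, environment, and flux tables
#'
#' The package reads and writes plain comma-delimited text with a single
#' versioned comment header line (`# chamberflux <kind> v<version>`), a
#' column header row, timestamps in local standard time (UTC+9, no DST)
#' formatted `YYYY-MM-DD HH:MM:SS`, and a configurable missing-value
#' sentinel (default `-9999`).  Files from other loggers can be read by
#' supplying a `columns` map from the dialect's canonical names to the
#' file's column names.
#'
#' Canonical columns: raw efflux files have
#' `timestamp, chamber, co2_ppm, flow_lpm, p_air_kpa, p_cell_kpa, t_air_c,
#' t_soil_c`; environment files have
#' `timestamp, chamber, t_soil_c, vwc, t_air_amb_c, rh`; flux tables have
#' `time, chamber, treatment, flux, model, p_air, t_air, t_air_source, r,
#' n_used, usable, flags` (flags semicolon-joined).
#'
#' @param columns Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @param sentinel Missing-value sentinel written/recognised in numeric
#'   columns.
#' @param tz Timezone of timestamps in the file.
#' @return A list of class `cf_dialect`.
#' @export
raw_dialect <- function(columns = NULL, sentinel = "-9999", tz = CF_TZ) {
  new_dialect("raw", c("timestamp", "chamber", "co2_ppm", "flow_lpm",
                       "p_air_kpa", "p_cell_kpa", "t_air_c", "t_soil_c"),
              columns, sentinel, tz)
}

#' @rdname raw_dialect
#' @export
env_dialect <- function(columns = NULL, sentinel = "-9999", tz = CF_TZ) {
  new_dialect("env", c("timestamp", "chamber", "t_soil_c", "vwc",
                       "t_air_amb_c", "rh"),
              columns, sentinel, tz)
}

new_dialect <- function(kind, canonical, columns, sentinel, tz) {
  if (is.null(columns)) {
    columns <- stats::setNames(canonical, canonical)
  } else {
    missing_cols <- setdiff(canonical, names(columns))
    if (length(missing_cols) > 0)
      stop("dialect column map lacks: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    columns <- columns[canonical]
  }
  structure(list(kind = kind, version = 1L, canonical = canonical,
                 columns = columns, sentinel = sentinel, tz = tz),
            class = "cf_dialect")
}

dialect_header <- function(dialect) {
  sprintf("# chamberflux %s v%d", dialect$kind, dialect$version)
}

## Shared CSV reader: comment header, sentinel -> NA, timestamp parsing.
read_cf_file <- function(path, dialect, time_col = "timestamp") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(
    path, comment = "#", na = c("", "NA", dialect$sentinel),
    col_types = readr::cols(.default = readr::col_guess()),
    locale = readr::locale(tz = dialect$tz),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(df) == 0) {
    warning("empty file: ", path, call. = FALSE)
  }
  unknown <- setdiff(unname(dialect$columns), names(df))
  if (length(unknown) > 0 && nrow(df) > 0)
    stop("file ", path, " lacks mapped column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    df <- df[, unname(dialect$columns), drop = FALSE]
    names(df) <- names(dialect$columns)
    if (is.character(df[[time_col]]))
      df[[time_col]] <- readr::parse_datetime(
        df[[time_col]], locale = readr::locale(tz = dialect$tz))
  } else {
    df <- tibble::as_tibble(
      stats::setNames(rep(list(logical(0)), length(dialect$columns)),
                      names(dialect$columns)))
    df[[time_col]] <- .POSIXct(numeric(0), tz = dialect$tz)
  }
  n_malformed <- nrow(readr::problems(df))
  attr(df, "import_log") <- list(path = path, n_rows = nrow(df),
                                 n_malformed = n_malformed)
  tibble::as_tibble(df)
}

write_cf_file <- function(df, path, dialect, time_cols = "timestamp") {
  out <- df
  for (tc in intersect(time_cols, names(out)))
    out[[tc]] <- format(out[[tc]], "%Y-%m-%d %H:%M:%S", tz = dialect$tz)
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]][!is.finite(out[[j]])] <- NA
  writeLines(dialect_header(dialect), path)
  readr::write_csv(out, path, na = dialect$sentinel, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read and write raw efflux record files
#'
#' Readers return typed tibbles in the canonical column layout; rows whose
#' CO2, pressure, or timestamp fields are missing (sentinel) are flagged
#' `valid = FALSE` but retained, and counts are reported in the
#' `import_log` attribute — nothing is silently dropped.
#'
#' @param path File path.
#' @param dialect A [raw_dialect()] describing the file layout.
#' @param raw A raw record tibble (e.g. from [simulate_campaign()]).
#' @return `read_raw()`: a tibble of records with a `valid` column and an
#'   `import_log` attribute.  `write_raw()`: the path, invisibly.
#' @export
read_raw <- function(path, dialect = raw_dialect()) {
  df <- read_cf_file(path, dialect)
  log <- attr(df, "import_log")
  if (nrow(df) > 0) {
    df$chamber <- as.integer(df$chamber)
    df$valid <- !is.na(df$timestamp) & !is.na(df$chamber) &
      !is.na(df$co2_ppm) & df$co2_ppm > 0
    bad_order <- which(diff(as.numeric(df$timestamp)) < 0)
    log$n_out_of_order <- length(bad_order)
  } else {
    df$valid <- logical(0)
    log$n_out_of_order <- 0L
  }
  log$n_invalid <- sum(!df$valid)
  attr(df, "import_log") <- log
  df
}

#' @rdname read_raw
#' @export
write_raw <- function(raw, path, dialect = raw_dialect()) {
  cols <- c("timestamp", "chamber", "co2_ppm", "flow_lpm", "p_air_kpa",
            "p_cell_kpa", "t_air_c", "t_soil_c")
  write_cf_file(raw[, cols], path, dialect)
}

#' Read and write half-hourly environment files
#'
#' @inheritParams read_raw
#' @param env An environment tibble (see [env_dialect()] for columns).
#' @return `read_env()`: tibble with `import_log` attribute;
#'   `write_env()`: the path, invisibly.
#' @export
read_env <- function(path, dialect = env_dialect()) {
  df <- read_cf_file(path, dialect)
  if (nrow(df) > 0) df$chamber <- as.integer(df$chamber)
  df
}

#' @rdname read_env
#' @export
write_env <- function(env, path, dialect = env_dialect()) {
  write_cf_file(env[, c("timestamp", "chamber", "t_soil_c", "vwc",
                        "t_air_amb_c", "rh")], path, dialect)
}

#' Write and read processed flux tables
#'
#' One row per chamber closure with the efflux estimate, the model used,
#' fit quality, and QC flags (semicolon-joined tokens).  Column order is
#' stable across versions of the dialect.
#'
#' @param fluxes Flux tibble from [compute_fluxes()].
#' @param path File path.
#' @param sentinel,tz As in [raw_dialect()].
#' @return `write_flux_table()`: the path, invisibly; `read_flux_table()`:
#'   the tibble.
#' @export
write_flux_table <- function(fluxes, path, sentinel = "-9999", tz = CF_TZ) {
  cols <- c("time", "chamber", "treatment", "flux", "model", "p_air",
            "t_air", "t_air_source", "r", "n_used", "usable", "flags")
  d <- flux_dialect(sentinel, tz)
  write_cf_file(fluxes[, intersect(cols, names(fluxes))], path, d,
                time_cols = "time")
}

#' @rdname write_flux_table
#' @export
read_flux_table <- function(path, sentinel = "-9999", tz = CF_TZ) {
  d <- flux_dialect(sentinel, tz)
  df <- read_cf_file(path, d, time_col = "time")
  if (nrow(df) > 0) {
    df$chamber <- as.integer(df$chamber)
    df$n_used <- as.integer(df$n_used)
    df$usable <- as.logical(df$usable)
    df$flags <- as.character(df$flags)
    df$flags[is.na(df$flags)] <- ""
  }
  df
}

flux_dialect <- function(sentinel, tz) {
  new_dialect("flux", c("time", "chamber", "treatment", "flux", "model",
                        "p_air", "t_air", "t_air_source", "r", "n_used",
                        "usable", "flags"),
              NULL, sentinel, tz)
}

#' Segment a raw record stream into chamber closures
#'
#' Splits time-sorted raw records into closure segments: each maximal run
#' of consecutive records from the same chamber, within one measurement
#' cycle and without internal gaps longer than `max_gap_s`, becomes one
#' segment.  A record belongs to exactly one segment.  Segments with fewer
#' than `min_records` records are flagged `short`.  Record offsets are
#' seconds since the first record of the segment, so partially missing
#' closures are handled without assuming the schedule.
#'
#' @param raw Raw record tibble (from [read_raw()] or
#'   [simulate_campaign()]).
#' @param meta Chamber metadata ([chamber_layout()]); an error lists any
#'   record chamber ids absent from it.
#' @param cycle_s Measurement cycle length, seconds; a closure never spans
#'   a cycle boundary.
#' @param max_gap_s Records separated by more than this start a new
#'   segment.
#' @param min_records Segments below this record count are flagged short.
#' @return The record tibble with added columns `closure` (integer id),
#'   `offset_s`, `short`, `treatment`, `vs_ratio`, ordered as input.
#'   Invalid records (if a `valid` column exists) keep `closure = NA`.
#' @export
segment_closures <- function(raw, meta = chamber_layout(),
                             cycle_s = 3600, max_gap_s = 30,
                             min_records = 12) {
  missing_ch <- setdiff(unique(raw$chamber), meta$chamber)
  missing_ch <- missing_ch[!is.na(missing_ch)]
  if (length(missing_ch) > 0)
    stop("chamber id(s) absent from meta: ",
         paste(sort(missing_ch), collapse = ", "), call. = FALSE)
  df <- raw
  if (!"valid" %in% names(df)) df$valid <- TRUE
  sec <- as.numeric(df$timestamp)
  if (is.unsorted(sec, na.rm = TRUE)) {
    warning("records were not time-sorted; sorting", call. = FALSE)
    ord <- order(sec)
    df <- df[ord, ]
    sec <- sec[ord]
  }
  ok <- df$valid & !is.na(sec)
  cyc <- floor(sec / cycle_s)
  new_seg <- c(TRUE, diff(sec) > max_gap_s |
                 diff(df$chamber) != 0 |
                 diff(cyc) != 0)
  ## invalid records break and are excluded from segments
  new_seg[!ok] <- TRUE
  new_seg[which(!ok) + 1L] <- TRUE
  new_seg <- new_seg[seq_len(nrow(df))]
  new_seg <- is.na(new_seg) | new_seg
  seg_id <- cumsum(new_seg)
  seg_id[!ok] <- NA_integer_

  df$closure <- seg_id
  ## segments are contiguous runs, so the segment start is the latest
  ## position where a new segment began
  start_pos <- cummax(ifelse(new_seg, seq_along(sec), 0L))
  df$offset_s <- sec - sec[start_pos]
  seg_n <- tabulate(seg_id[ok], nbins = max(seg_id, na.rm = TRUE))
  df$short <- !is.na(seg_id) & seg_n[pmax(1L, seg_id)] < min_records
  df$short[is.na(seg_id)] <- FALSE
  df <- dplyr::left_join(df, meta, by = "chamber")
  tibble::as_tibble(df)
}
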