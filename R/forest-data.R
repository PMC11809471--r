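# Canonical dataset: long-format forest-simulator output.
#
# One row per (stand, regime, year) with a numeric column per indicator.
# Stand-level metadata (area, boolean flags such as PEAT) lives in a
# separate per-stand table.  A (stand, regime) pair that is absent simply
# means the simulator did not run that regime for that stand; present pairs
# must be rectangular over the full year grid.

#' Column schema for simulator CSV files
#'
#' Maps the package's required roles onto the column names used by a
#' particular simulator export.  Any numeric column not named here becomes an
#' indicator; columns whose values are all in \{0, 1, true, false\} (or named
#' in `flags`) are routed to per-stand boolean flags.
#'
#' @param stand,regime,year names of the key columns.
#' @param area optional name of a per-stand area column (hectares); when the
#'   column is absent every stand gets area 1, so per-stand values act as
#'   landscape totals.
#' @param flags character vector of columns to force into stand flags.
#' @param indicators optional character vector restricting which columns are
#'   read as indicators (default: all remaining numeric columns).
#' @return a `forest_schema` list.
#' @export
forest_schema <- function(stand = "standid", regime = "regime", year = "year",
                          area = "area", flags = character(),
                          indicators = NULL) {
  structure(
    list(stand = stand, regime = regime, year = year, area = area,
         flags = flags, indicators = indicators),
    class = "forest_schema"
  )
}

#' Assemble a forest dataset from data frames
#'
#' Validates and indexes a long table of per-(stand, regime, year) indicator
#' values plus optional stand metadata.  This is the constructor used both by
#' [read_forest_data()] and by the synthetic generator.
#'
#' @param data data frame with columns `stand`, `regime`, `year` and one
#'   numeric column per indicator.
#' @param stand_info optional data frame with column `stand`, optional
#'   numeric `area`, and optional logical flag columns.
#' @return a `forest_data` object.
#' @export
forest_data <- function(data, stand_info = NULL) {
  req <- c("stand", "regime", "year")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("schema error: missing key column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$stand <- as.character(data$stand)
  data$regime <- as.character(data$regime)
  data$year <- as.integer(data$year)
  indicators <- setdiff(names(data), req)
  if (!length(indicators)) stop("no indicator columns found")
  for (col in indicators) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))) & !is.na(data[[col]]))
      stop(sprintf(
        "parse error: non-numeric value in indicator '%s' (data row %d)",
        col, if (length(bad)) bad[1] else NA_integer_
      ))
    }
    if (anyNA(data[[col]])) {
      stop(sprintf(
        "parse error: missing/non-numeric value in indicator '%s' (data row %d)",
        col, which(is.na(data[[col]]))[1]
      ))
    }
  }

  key <- paste(data$stand, data$regime, data$year, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup) {
    stop(sprintf(
      "integrity error: duplicate (stand, regime, year) key: (%s, %s, %d)",
      data$stand[dup], data$regime[dup], data$year[dup]
    ))
  }

  years <- sort(unique(data$year))
  pair <- paste(data$stand, data$regime, sep = "\r")
  counts <- table(pair)
  short <- counts != length(years)
  if (any(short)) {
    off <- strsplit(names(counts)[which(short)[1]], "\r", fixed = TRUE)[[1]]
    stop(sprintf(
      "integrity error: (stand %s, regime %s) has %d of %d years",
      off[1], off[2], counts[which(short)[1]], length(years)
    ))
  }

  stands <- sort(unique(data$stand))
  if (is.null(stand_info)) {
    stand_info <- data.frame(stand = stands, stringsAsFactors = FALSE)
  }
  stand_info$stand <- as.character(stand_info$stand)
  unknown <- setdiff(stand_info$stand, stands)
  if (length(unknown)) {
    stop("stand metadata refers to unknown stand(s): ", paste(unknown, collapse = ", "))
  }
  stand_info <- stand_info[match(stands, stand_info$stand), , drop = FALSE]
  stand_info$stand <- stands      # stands absent from metadata get defaults
  rownames(stand_info) <- NULL
  if (is.null(stand_info$area)) stand_info$area <- 1
  stand_info$area[is.na(stand_info$area)] <- 1
  if (any(stand_info$area < 0)) stop("negative stand area")
  flag_cols <- setdiff(names(stand_info), c("stand", "area"))
  for (fc in flag_cols) {
    stand_info[[fc]] <- as.logical(stand_info[[fc]])
    stand_info[[fc]][is.na(stand_info[[fc]])] <- FALSE
  }

  ord <- order(data$stand, data$regime, data$year)
  structure(
    list(
      data = data[ord, c(req, indicators), drop = FALSE],
      indicators = indicators,
      years = years,
      regimes = sort(unique(data$regime)),
      stands = stands,
      stand_info = stand_info,
      flags = flag_cols
    ),
    class = "forest_data"
  )
}

#' @export
print.forest_data <- function(x, ...) {
  cat(sprintf(
    "<forest_data: %d stands x %d regimes x %d years, %d indicators>\n",
    length(x$stands), length(x$regimes), length(x$years), length(x$indicators)
  ))
  cat("  indicators:", paste(x$indicators, collapse = ", "), "\n")
  cat("  years:", x$years[1], "..", x$years[length(x$years)],
      sprintf("(%d rows)", nrow(x$data)), "\n")
  if (length(x$flags)) cat("  stand flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Auto-detected flags must contain a textual boolean; columns coded purely
# as 0/1 (which could be a legitimate indicator) must be named in the
# schema's `flags` to be routed to stand metadata.
.is_boolean_text <- function(v) {
  v <- tolower(trimws(as.character(v)))
  all(v %in% c("0", "1", "true", "false")) && any(v %in% c("true", "false"))
}

#' Read simulator output from CSV
#'
#' Reads a UTF-8, "."-decimal CSV with a header row, one row per
#' (stand, regime, year).  Key columns are located by `schema`; flag columns
#' are collapsed to per-stand booleans; the remaining numeric columns become
#' indicators, in file order.
#'
#' @param path CSV file path.
#' @param schema a [forest_schema()].
#' @return a validated `forest_data` object.
#' @export
read_forest_data <- function(path, schema = forest_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  for (role in c("stand", "regime", "year")) {
    if (!schema[[role]] %in% names(raw)) {
      stop(sprintf("schema error: %s column '%s' not found", role, schema[[role]]))
    }
  }
  key_cols <- c(schema$stand, schema$regime, schema$year)
  other <- setdiff(names(raw), c(key_cols, schema$area))
  flag_cols <- union(intersect(schema$flags, other),
                     other[vapply(raw[other], .is_boolean_text, logical(1))])
  flag_cols <- setdiff(flag_cols, schema$indicators)
  ind_cols <- setdiff(other, flag_cols)
  if (!is.null(schema$indicators)) ind_cols <- intersect(ind_cols, schema$indicators)

  data <- data.frame(
    stand = raw[[schema$stand]], regime = raw[[schema$regime]],
    year = raw[[schema$year]], stringsAsFactors = FALSE
  )
  for (col in ind_cols) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s' at file row %d",
                   raw[[col]][bad[1]], col, bad[1] + 1L))
    }
    data[[col]] <- num
  }

  info <- data.frame(stand = unique(data$stand), stringsAsFactors = FALSE)
  first <- match(info$stand, data$stand)
  if (!is.null(schema$area) && schema$area %in% names(raw)) {
    info$area <- suppressWarnings(as.numeric(raw[[schema$area]]))[first]
  }
  for (fc in flag_cols) {
    info[[fc]] <- tolower(trimws(raw[[fc]][first])) %in% c("1", "true")
  }
  forest_data(data, info)
}

#' Write a forest dataset back to the CSV dialect [read_forest_data()] reads
#'
#' Indicator values are printed with 17 significant digits so a
#' load-write-load round trip reproduces every double bit-for-bit.
#'
#' @param fd a `forest_data`.
#' @param path output file.
#' @param schema column names to write (same defaults as reading).
#' @export
write_forest_data <- function(fd, path, schema = forest_schema()) {
  stopifnot(inherits(fd, "forest_data"))
  out <- fd$data
  names(out)[1:3] <- c(schema$stand, schema$regime, schema$year)
  idx <- match(out[[schema$stand]], fd$stand_info$stand)
  if (!is.null(schema$area)) out[[schema$area]] <- fd$stand_info$area[idx]
  for (fc in fd$flags) out[[fc]] <- tolower(as.character(fd$stand_info[[fc]][idx]))
  for (col in fd$indicators) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive a percent-of-baseline indicator
#'
#' Adds an indicator whose value is the original indicator divided by the
#' same stand's value in `base_year` under a baseline regime, times 100.
#' Simulator exports often ship such "relative" columns precomputed; this
#' derivation is the opt-in equivalent.
#'
#' @param fd a `forest_data`.
#' @param indicator source indicator name.
#' @param base_year the reference year (must be a simulated year).
#' @param baseline_regime regime supplying the per-stand baseline; default is
#'   the alphabetically first regime simulated for each stand.
#' @param name name of the derived column (default `relative_<indicator>`).
#' @return a new `forest_data` with the extra indicator.
#' @export
relative_indicator <- function(fd, indicator, base_year,
                               baseline_regime = NULL, name = NULL) {
  stopifnot(inherits(fd, "forest_data"))
  if (!indicator %in% fd$indicators) stop("unknown indicator: ", indicator)
  if (!base_year %in% fd$years) stop("base year ", base_year, " not simulated")
  if (is.null(name)) name <- paste0("relative_", indicator)

  d <- fd$data
  base <- vapply(fd$stands, function(s) {
    regs <- sort(unique(d$regime[d$stand == s]))
    reg <- if (is.null(baseline_regime)) regs[1] else baseline_regime
    if (!reg %in% regs) {
      stop(sprintf("baseline regime '%s' not simulated for stand %s", reg, s))
    }
    d[[indicator]][d$stand == s & d$regime == reg & d$year == base_year]
  }, numeric(1))
  zero <- fd$stands[base == 0]
  if (length(zero)) {
    stop("zero baseline value for stand(s): ", paste(zero, collapse = ", "))
  }
  d[[name]] <- 100 * d[[indicator]] / base[match(d$stand, fd$stands)]
  forest_data(d, fd$stand_info)
}

#' Regimes simulated for each stand
#' @return named list: stand -> character vector of regimes.
#' @keywords internal
stand_regimes <- function(fd) {
  split(fd$data$regime[fd$data$year == fd$years[1]],
        fd$data$stand[fd$data$year == fd$years[1]])[fd$stands]
}
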