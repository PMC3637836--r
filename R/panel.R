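#' Column-name mapping for long-format panel files
#'
#' Describes which columns of a long-format table hold the region identifier,
#' the outcome, the calendar year and (optionally) a binary region-level
#' covariate.  Defaults follow the naming of regional life-expectancy
#' reporting files (`Region`, `LifeE`, `Year`, `UrbanRural`).
#'
#' @param region,outcome,year Column names (single strings).
#' @param covariate Column name of an optional binary (0/1) region-level
#'   covariate, or `NULL` to ignore any such column.
#' @return A named list of class `"panel_schema"`.
#' @export
panel_schema <- function(region = "Region", outcome = "LifeE",
                         year = "Year", covariate = "UrbanRural") {
  for (nm in c(region, outcome, year)) {
    if (!is.character(nm) || length(nm) != 1L || !nzchar(nm))
      stop("schema column names must be non-empty strings", call. = FALSE)
  }
  structure(list(region = region, outcome = outcome, year = year,
                 covariate = covariate),
            class = "panel_schema")
}

#' Construct a balanced growth panel from a long-format data frame
#'
#' Validates completeness (every region observed in every year exactly once),
#' recodes the sorted distinct years to a time index 1..T, and pivots the
#' outcome into an n x T matrix.  Unbalanced panels are rejected rather than
#' imputed: all closed-form estimation formulas in this package assume
#' balance.
#'
#' @param data A data frame in long format.
#' @param schema A [panel_schema()] naming the relevant columns.
#' @return An object of class `"growth_panel"`: a list with elements
#'   `y` (n x T outcome matrix, rows named by region), `region_ids`
#'   (character), `years` (original calendar years, sorted), `time_index`
#'   (integers `1:T`), and `covariate` (named 0/1 vector or `NULL`).
#' @export
as_panel <- function(data, schema = panel_schema()) {
  data <- as.data.frame(data)
  need <- c(schema$region, schema$outcome, schema$year)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("input is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  region <- as.character(data[[schema$region]])
  year <- data[[schema$year]]
  outcome <- as.numeric(data[[schema$outcome]])
  if (anyNA(outcome))
    stop("outcome column contains missing values", call. = FALSE)
  if (anyNA(year) || anyNA(region))
    stop("region/year columns contain missing values", call. = FALSE)

  key <- paste(region, year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    dup <- sub("\r", ", year ", dup)
    stop("duplicate (region, year) pair(s): ",
         paste(utils::head(dup, 5L), collapse = "; "), call. = FALSE)
  }

  region_ids <- unique(region)            # keep first-appearance order
  years <- sort(unique(year))
  T <- length(years)
  n <- length(region_ids)
  if (T < 3L)
    stop("panel needs at least 3 time points (T >= 3), got T = ", T,
         call. = FALSE)

  # completeness: every region must carry exactly the full year set
  full <- paste(rep(region_ids, each = T), rep(years, times = n), sep = "\r")
  missing_cells <- setdiff(full, key)
  if (length(missing_cells)) {
    lab <- sub("\r", ", year ", missing_cells)
    stop("incomplete panel; missing (region, year) cell(s): ",
         paste(utils::head(lab, 5L), collapse = "; "),
         if (length(lab) > 5L) " ..." else "", call. = FALSE)
  }

  y <- matrix(NA_real_, n, T, dimnames = list(region_ids, years))
  y[cbind(match(region, region_ids), match(year, years))] <- outcome

  covariate <- NULL
  cov_col <- schema$covariate
  if (!is.null(cov_col) && cov_col %in% names(data)) {
    cv <- data[[cov_col]]
    by_region <- split(cv, factor(region, levels = region_ids))
    n_distinct <- vapply(by_region, function(v) length(unique(v)), 1L)
    if (any(n_distinct > 1L))
      stop("covariate '", cov_col, "' varies within region(s): ",
           paste(region_ids[n_distinct > 1L], collapse = ", "), call. = FALSE)
    covariate <- vapply(by_region, function(v) as.numeric(v[1L]), 1)
    if (!all(covariate %in% c(0, 1)))
      stop("covariate '", cov_col, "' must be binary 0/1", call. = FALSE)
    names(covariate) <- region_ids
  }

  structure(list(y = y, region_ids = region_ids, years = years,
                 time_index = seq_len(T), covariate = covariate),
            class = "growth_panel")
}

#' Read a long-format panel file
#'
#' Reads a delimited text file (comma- or tab-separated, auto-detected from
#' the header line unless `sep` is given) and builds a validated
#' [as_panel()] object.
#'
#' @param path Path to a delimited file with a header row.
#' @param schema A [panel_schema()].
#' @param sep Field separator; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return A `"growth_panel"` object.
#' @export
read_panel <- function(path, schema = panel_schema(), sep = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_panel(df, schema)
}

#' Write a panel back to long format
#'
#' Inverse of [read_panel()]: emits one row per (region, year) cell using the
#' schema's column names, so simulated panels can round-trip through the same
#' file interface as observed data.
#'
#' @param panel A `"growth_panel"`.
#' @param path Output file path.
#' @param schema A [panel_schema()] providing the column names.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, schema = panel_schema(), sep = ",") {
  stopifnot(inherits(panel, "growth_panel"))
  df <- as.data.frame(panel)
  # rename to schema
  names(df)[names(df) == "region"] <- schema$region
  names(df)[names(df) == "outcome"] <- schema$outcome
  names(df)[names(df) == "year"] <- schema$year
  if ("covariate" %in% names(df)) {
    if (is.null(schema$covariate)) df$covariate <- NULL
    else names(df)[names(df) == "covariate"] <- schema$covariate
  }
  df$time <- NULL
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.growth_panel <- function(x, ...) {
  n <- length(x$region_ids); T <- length(x$time_index)
  df <- data.frame(
    region = rep(x$region_ids, each = T),
    year = rep(x$years, times = n),
    time = rep(x$time_index, times = n),
    outcome = as.vector(t(x$y)),
    stringsAsFactors = FALSE)
  if (!is.null(x$covariate))
    df$covariate <- rep(unname(x$covariate), each = T)
  df
}

#' @export
print.growth_panel <- function(x, ...) {
  cat(sprintf("Balanced growth panel: %d regions x %d time points\n",
              nrow(x$y), ncol(x$y)))
  cat(sprintf("  years %s-%s (time index 1..%d)\n",
              x$years[1L], x$years[length(x$years)], ncol(x$y)))
  if (!is.null(x$covariate))
    cat(sprintf("  binary covariate present (%d of %d regions = 1)\n",
                sum(x$covariate == 1), length(x$covariate)))
  invisible(x)
}

#' Number of regions / time points of a panel
#' @param panel A `"growth_panel"`.
#' @return Integer count.
#' @export
n_regions <- function(panel) nrow(panel$y)

#' @rdname n_regions
#' @export
n_times <- function(panel) ncol(panel$y)
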