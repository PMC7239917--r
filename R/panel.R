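#' Lake-year panel data
#'
#' A lake panel is a long-format data frame with one row per lake-year and
#' columns `lake_id`, `year` plus the ten model variables: air temperature
#' `AT` (degC), precipitation `PRE` (m), potential evaporation `PE` (m),
#' agricultural land use `LUag` (% of catchment area), water temperature
#' `WT` (degC), water level `WL` (m), chlorophyll-a `CHL` (ug/l), fish catch
#' `CATCH` (kg/ha), stocking `ST` (number/ha) and fishing effort `EFF`
#' (dimensionless). Any model variable may be missing (`NA`); `CHL`, `CATCH`
#' and `EFF` are log-transformed by the model and must be strictly positive
#' when present.
#'
#' @param data data frame with at least `lake_id` and `year` columns; model
#'   variables absent from `data` are created as all-`NA`.
#' @return a `lake_panel` data frame sorted by lake and year.
#' @export
lake_panel <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("lake_id", "year") %in% names(data)))
    stop("panel needs 'lake_id' and 'year' columns")
  for (v in .bnm_variables)
    if (!v %in% names(data)) data[[v]] <- NA_real_
  data <- data[c("lake_id", "year", .bnm_variables)]
  data$lake_id <- as.character(data$lake_id)
  data$year <- as.integer(data$year)
  for (v in .bnm_variables) data[[v]] <- as.numeric(data[[v]])
  key <- paste(data$lake_id, data$year)
  if (anyDuplicated(key))
    stop("duplicate lake-year keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  data <- data[order(data$lake_id, data$year), , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("lake_panel", "data.frame")
  data
}

#' Read / write a panel CSV
#'
#' CSV columns are `lake_id, year, AT, PRE, PE, LUag, WT, WL, CHL, CATCH, ST,
#' EFF`; missing values are empty cells. Values round-trip exactly (written
#' with full precision).
#'
#' @param file path to a CSV file.
#' @return `read_panel` returns a [lake_panel()].
#' @export
read_panel <- function(file) {
  lake_panel(read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_panel
#' @param panel a [lake_panel()].
#' @export
write_panel <- function(panel, file) {
  out <- as.data.frame(panel)
  for (v in .bnm_variables)
    out[[v]] <- ifelse(is.na(out[[v]]), "",
                       formatC(out[[v]], digits = 17, format = "g"))
  write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Annual water-level change
#'
#' First difference of the water-level series: `dWL(t) = WL(t) - WL(t-1)`,
#' defined only when both years are observed and consecutive; the first year
#' is always missing. Gaps propagate as missing rather than being filled.
#'
#' @param wl numeric water levels (m), may contain `NA`.
#' @param years integer years the values belong to (default consecutive).
#' @return numeric vector of the same length as `wl`.
#' @export
delta_wl <- function(wl, years = seq_along(wl)) {
  stopifnot(length(wl) == length(years))
  n <- length(wl)
  out <- rep(NA_real_, n)
  if (n < 2) return(out)
  consec <- diff(years) == 1L
  out[-1][consec] <- (wl[-1] - wl[-n])[consec]
  out
}

#' @rdname delta_wl
#' @param panel a [lake_panel()].
#' @return `add_delta_wl` returns the panel with a derived `dWL` column.
#' @export
add_delta_wl <- function(panel) {
  panel$dWL <- NA_real_
  for (id in unique(panel$lake_id)) {
    i <- which(panel$lake_id == id)
    panel$dWL[i] <- delta_wl(panel$WL[i], panel$year[i])
  }
  panel
}

#' Validate a lake panel
#'
#' Checks the modelling preconditions: every model variable observed in at
#' least `min_years` years per lake (9, the minimum the prior-construction
#' stage tolerates), strictly positive `CHL`/`CATCH`/`EFF` (log domain), and
#' `LUag` within \[0, 100\] percent of catchment area. Duplicate lake-year
#' keys are an error at construction time already.
#'
#' @param panel a [lake_panel()].
#' @param min_years minimum observed years per variable per lake (default 9).
#' @return a `panel_validation` list: `ok` flag, per-lake `counts` matrix and
#'   character vector of `problems`.
#' @export
validate_panel <- function(panel, min_years = 9) {
  panel <- lake_panel(panel)   # re-asserts key uniqueness
  lakes <- unique(panel$lake_id)
  counts <- matrix(0L, length(lakes), length(.bnm_variables),
                   dimnames = list(lakes, .bnm_variables))
  problems <- character()
  for (id in lakes) {
    sub <- panel[panel$lake_id == id, ]
    for (v in .bnm_variables) {
      counts[id, v] <- sum(!is.na(sub[[v]]))
      if (counts[id, v] < min_years)
        problems <- c(problems, sprintf(
          "lake %s: %s observed in %d years (< %d)", id, v, counts[id, v],
          min_years))
    }
    for (v in .bnm_log_vars)
      if (any(sub[[v]] <= 0, na.rm = TRUE))
        problems <- c(problems,
                      sprintf("lake %s: nonpositive %s (log domain)", id, v))
    if (any(sub$LUag < 0 | sub$LUag > 100, na.rm = TRUE))
      problems <- c(problems, sprintf("lake %s: LUag outside [0, 100]", id))
  }
  structure(list(ok = length(problems) == 0L, counts = counts,
                 problems = problems),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(if (x$ok) "panel OK" else "panel INVALID", "\n")
  if (!x$ok) cat(paste0("  - ", x$problems, collapse = "\n"), "\n")
  invisible(x)
}

#' Per-lake medians over the study window
#'
#' Median of the observed values of each model variable (plus derived `dWL`)
#' per lake, over `years` (default: all years present). These are the
#' baseline inputs of the Monte-Carlo driver assessment. Even-count medians
#' are the mean of the two central order statistics.
#'
#' @param panel a [lake_panel()].
#' @param years optional integer vector restricting the window.
#' @return data frame, one row per lake, one column per variable (and `dWL`).
#' @export
compute_medians <- function(panel, years = NULL) {
  panel <- add_delta_wl(lake_panel(panel))
  if (!is.null(years)) panel <- panel[panel$year %in% years, , drop = FALSE]
  vars <- c(.bnm_variables, "dWL")
  lakes <- unique(panel$lake_id)
  out <- data.frame(lake_id = lakes, stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- NA_real_
  for (id in lakes) {
    sub <- panel[panel$lake_id == id, ]
    for (v in vars) {
      x <- sub[[v]][!is.na(sub[[v]])]
      if (length(x) == 0L)
        stop("no observations of ", v, " for lake ", id)
      out[[v]][out$lake_id == id] <- median(x)
    }
  }
  out
}

#' Read a lake-characteristics table
#'
#' Columns: `lake_id`, `access_clean_water` (proportion in \[0,1\]),
#' `shoreline_pop_density` (persons/km2), `avg_depth` (m),
#' `shoreline_length_km`, `lake_area_km2`. A derived `SDI` column
#' (shoreline development index, see [sdi()]) is added.
#'
#' @param file CSV path.
#' @return data frame with a derived `SDI` column.
#' @export
read_characteristics <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("lake_id", "access_clean_water", "shoreline_pop_density",
            "avg_depth", "shoreline_length_km", "lake_area_km2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("characteristics table missing: ",
                         paste(miss, collapse = ", "))
  x$SDI <- sdi(x$shoreline_length_km, x$lake_area_km2)
  x
}
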