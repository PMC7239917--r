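## Vulnerability index, shoreline development index and characteristic
## correlations.

#' Shoreline development index
#'
#' `SDI = 0.5 x SL / sqrt(pi x Alake)`: the ratio of the shoreline length
#' to the circumference of a circle with the lake's area. A circle gives
#' exactly 1; larger values mean a less circular lake with relatively more
#' littoral area.
#'
#' @param shoreline_length shoreline length SL (km), > 0.
#' @param lake_area lake area (km2), > 0.
#' @return dimensionless index (vectorized), >= 1 up to digitization error.
#' @export
sdi <- function(shoreline_length, lake_area) {
  if (any(shoreline_length <= 0) || any(lake_area <= 0))
    stop("shoreline length and lake area must be positive")
  0.5 * shoreline_length / sqrt(pi * lake_area)
}

#' Vulnerability magnitude of a driver assessment
#'
#' The median absolute driver change, over accepted samples, associated
#' with a 25% catch decrease — in the driver's reporting metric. A smaller
#' magnitude means the lake is more vulnerable: a smaller environmental
#' change suffices for the same catch loss.
#'
#' @param assessment a `driver_assessment`.
#' @return nonnegative scalar.
#' @export
magnitude_of_change <- function(assessment) {
  s <- assessment$samples
  if (is.null(s) || nrow(s) == 0) stop("empty assessment")
  median(abs(s$delta_driver))
}

#' Pearson correlation with a t-test
#'
#' Pearson `r` between a lake characteristic and the vulnerability
#' magnitudes, with `t = r sqrt(n-2) / sqrt(1-r^2)` and a two-sided p-value
#' on `n - 2` degrees of freedom. The fitted least-squares line is returned
#' for plotting when the test is significant.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite, with
#'   nonzero variance.
#' @param alpha significance level (default 0.05).
#' @return list `r`, `t`, `df`, `p`, `significant`, `line`
#'   (intercept/slope of y on x).
#' @export
correlation_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  n <- length(x)
  r <- cor(x, y)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df = n - 2)
  list(r = r, t = t, df = n - 2, p = p, significant = p < alpha,
       line = least_squares_line(x, y))
}

# two-parameter OLS line, used for the PE-AT map and correlation plots
least_squares_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(c(intercept = mean(y), slope = 0))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

#' Correlate lake characteristics with vulnerability magnitudes
#'
#' Runs [correlation_test()] for every characteristic x driver
#' combination, within driver (magnitudes are not comparable across
#' drivers: degrees Celsius, percent, percentage points). No
#' multiple-testing correction is applied; each test is reported at its
#' own p-value.
#'
#' @param magnitudes data frame `lake_id, driver, magnitude` (one row per
#'   lake x driver), e.g. built from [magnitude_of_change()].
#' @param characteristics characteristics table (see
#'   [read_characteristics()] or [generate_characteristics()]).
#' @param vars characteristic columns to test.
#' @return data frame: driver, characteristic, n, r, t, p, significant.
#' @export
vulnerability_correlations <- function(magnitudes, characteristics,
                                       vars = c("access_clean_water",
                                                "shoreline_pop_density",
                                                "avg_depth", "SDI")) {
  out <- NULL
  for (dr in unique(magnitudes$driver)) {
    mg <- magnitudes[magnitudes$driver == dr, ]
    j <- match(mg$lake_id, characteristics$lake_id)
    for (v in vars) {
      ct <- correlation_test(characteristics[[v]][j], mg$magnitude)
      out <- rbind(out, data.frame(
        driver = dr, characteristic = v, n = nrow(mg), r = ct$r, t = ct$t,
        p = ct$p, significant = ct$significant, stringsAsFactors = FALSE))
    }
  }
  out
}
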