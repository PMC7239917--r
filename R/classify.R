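## One-tailed credible-interval classification of effects and the 13-pair
## effects table.

#' Classify a coefficient's posterior as positive, negative or mixed
#'
#' Positive if the one-tailed 75% credible interval `[q0.25, Inf)` excludes
#' zero (i.e. the 0.25 quantile is above 0); negative if `(-Inf, q0.75]`
#' excludes zero; mixed otherwise — equivalently, mixed means zero lies
#' inside the central 50% interval.
#'
#' @param x numeric posterior draws (non-empty).
#' @param level one-tailed credibility level (default 0.75).
#' @return `"positive"`, `"negative"` or `"mixed"`.
#' @export
classify_coefficient <- function(x, level = 0.75) {
  if (length(x) == 0) stop("no draws to classify")
  qlo <- quantile(x, 1 - level, names = FALSE)
  qhi <- quantile(x, level, names = FALSE)
  if (qlo > 0) "positive" else if (qhi < 0) "negative" else "mixed"
}

# the 13 predictor-response pairs and the coefficient that carries each
.bnm_pairs <- data.frame(
  predictor = c("AT", "AT", "PRE", "PRE", "LUag", "LUag", "WT", "WT",
                "WL", "WL", "CHL", "ST", "EFF"),
  response = c("WT", "WL", "WL", "CHL", "WL", "CHL", "CHL", "CATCH",
               "CHL", "CATCH", "CATCH", "CATCH", "CATCH"),
  submodel = c("WT", "dWL", "dWL", "CHL", "dWL", "CHL", "CHL", "CATCH",
               "CHL", "CATCH", "CATCH", "CATCH", "CATCH"),
  term = c("AT", "PE", "PRE", "logPRE", "PE.LUag", "logLUag", "muWT",
           "muWT", "muDWL", "muDWL", "muCHL", "logST", "logEFF"),
  stringsAsFactors = FALSE)

#' Effects between variable pairs across lakes
#'
#' Counts, for each of the 13 predictor-response pairs of the network,
#' how many lakes show a positive, negative or mixed effect under
#' [classify_coefficient()]. Air temperature reaches water level through
#' the potential-evaporation term and agricultural land use through the
#' PE x LUag term; every other pair maps to its own coefficient. The
#' stocking row counts only stocking-eligible lakes, so every row sums to
#' the number of lakes carrying that coefficient.
#'
#' @param draws a `bnm_draws`.
#' @param level classification level (default from the run's config).
#' @return data frame: predictor, response, positive, negative, mixed.
#' @export
effects_table <- function(draws, level = draws$config$level) {
  m <- as_draw_matrix(draws)
  reg <- draws$params
  out <- .bnm_pairs[c("predictor", "response")]
  out$positive <- out$negative <- out$mixed <- 0L
  for (i in seq_len(nrow(.bnm_pairs))) {
    sel <- reg$type == "beta" & reg$submodel == .bnm_pairs$submodel[i] &
      reg$term == .bnm_pairs$term[i]
    if (!any(sel) && .bnm_pairs$term[i] != "logST")
      stop("no posterior draws for pair ", .bnm_pairs$predictor[i], "->",
           .bnm_pairs$response[i])
    for (p in reg$param[sel]) {
      cl <- classify_coefficient(m[, p], level)
      out[[cl]][i] <- out[[cl]][i] + 1L
    }
  }
  out[c("predictor", "response", "positive", "negative", "mixed")]
}

#' Stocking eligibility rule
#'
#' A lake's catch submodel carries the log-stocking term only when stocked
#' species contributed more than 20% of catches in more than 10 years.
#' Both bounds are strict.
#'
#' @param contribution yearly fractions (in \[0, 1\]) of catch contributed
#'   by stocked species.
#' @return logical flag.
#' @export
stocking_eligible <- function(contribution) {
  stopifnot(all(contribution >= 0 & contribution <= 1, na.rm = TRUE))
  sum(contribution > 0.20, na.rm = TRUE) > 10
}
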