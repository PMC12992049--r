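# Verbal evidence categories on conventional Bayes factor thresholds.

EVIDENCE_LABELS <- c("support_null", "weak", "moderate", "strong",
                     "very_strong", "extreme")
EVIDENCE_BREAKS <- c(0, 0.33, 3, 10, 30, 100, Inf)

#' Categorize a Bayes factor
#'
#' Maps BF10 values to verbal evidence categories partitioning the positive
#' half-line: (0, 0.33] support for the null, (0.33, 3] weak evidence,
#' (3, 10] moderate, (10, 30] strong, (30, 100] very strong, and above 100
#' extreme evidence against the null. Upper bounds are inclusive for the
#' lower category, so BF = 3 is still "weak" and BF = 0.33 still supports
#' the null.
#'
#' @param bf positive finite Bayes factor(s).
#' @return an ordered factor with levels `support_null < weak < moderate <
#'   strong < very_strong < extreme`.
#' @export
#' @examples
#' categorize_bf(c(0.23, 2.5, 9.0))
categorize_bf <- function(bf) {
  if (any(!is.finite(bf)) || any(bf <= 0))
    stop_config("Bayes factors must be positive and finite")
  cut(bf, breaks = EVIDENCE_BREAKS, labels = EVIDENCE_LABELS,
      right = TRUE, ordered_result = TRUE)
}

#' Evidence category thresholds
#'
#' @return a data.frame of the category labels and their half-open
#'   intervals `(lower, upper]`.
#' @export
bf_categories <- function() {
  data.frame(label = EVIDENCE_LABELS,
             lower = EVIDENCE_BREAKS[-length(EVIDENCE_BREAKS)],
             upper = EVIDENCE_BREAKS[-1],
             stringsAsFactors = FALSE)
}
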