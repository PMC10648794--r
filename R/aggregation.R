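## Slide-level decision from per-tile predictions.
##
## A slide is called OKC when the fraction of OKC-predicted tiles reaches
## the decision threshold (default 20%; the recommended operating band is
## 15-25%). The fraction's denominator defaults to the QC-passing tiles,
## since discarded white tiles carry no signal; a fraction exactly at the
## threshold counts as OKC.

#' Aggregation configuration
#'
#' @param threshold Minimum OKC tile fraction for an OKC call; must lie in
#'   (0, 1), recommended range 0.15-0.25.
#' @param denominator `"KEPT_TILES"` (classified, QC-passing tiles) or
#'   `"ALL_TILES"` (every grid cell, requiring `n_total` in
#'   [decide_slide()]).
#' @return An `aggregation_config` list.
#' @export
aggregation_config <- function(threshold = 0.20,
                               denominator = c("KEPT_TILES", "ALL_TILES")) {
  denominator <- match.arg(denominator)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(threshold = threshold, denominator = denominator),
    class = "aggregation_config"
  )
}

#' Decide a slide's label from its tile predictions
#'
#' @param predictions Tibble of tile predictions with a `label` column
#'   (values OKC/NONKC, as from [predict_tiles()]), or a logical/character
#'   vector of per-tile labels.
#' @param config An [aggregation_config()].
#' @param slide_id Identifier for the report row.
#' @param n_total Total grid-cell count, used only when the configured
#'   denominator is `"ALL_TILES"`.
#' @return One-row tibble: `slide_id, n_tiles, n_okc, n_nonkc,
#'   okc_fraction, threshold, label`.
#' @export
decide_slide <- function(predictions, config = aggregation_config(),
                         slide_id = "slide", n_total = NULL) {
  labels <- if (is.data.frame(predictions)) as.character(predictions$label) else as.character(predictions)
  if (length(labels) < 1L) {
    stop("slide is unclassifiable: no classified tiles", call. = FALSE)
  }
  n_okc <- sum(labels == "OKC")
  n_nonkc <- length(labels) - n_okc
  denom <- if (config$denominator == "ALL_TILES") {
    if (is.null(n_total)) {
      stop("`n_total` is required for denominator = 'ALL_TILES'", call. = FALSE)
    }
    n_total
  } else {
    length(labels)
  }
  frac <- n_okc / denom
  tibble::tibble(
    slide_id = slide_id,
    n_tiles = length(labels),
    n_okc = n_okc,
    n_nonkc = n_nonkc,
    okc_fraction = frac,
    threshold = config$threshold,
    label = ifelse(frac >= config$threshold, "OKC", "NONKC")
  )
}

#' Sweep the slide decision over several thresholds
#'
#' The label is monotone: a slide called OKC at some threshold is OKC at
#' every lower threshold.
#'
#' @param predictions As in [decide_slide()].
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param slide_id,n_total,denominator Passed through to [decide_slide()].
#' @return Tibble with one decision row per threshold.
#' @export
sweep_threshold <- function(predictions, thresholds, slide_id = "slide",
                            n_total = NULL, denominator = "KEPT_TILES") {
  if (length(thresholds) == 0L) {
    return(decide_slide(predictions, slide_id = slide_id)[0, ])
  }
  purrr::map_dfr(thresholds, function(th) {
    decide_slide(predictions, aggregation_config(th, denominator),
      slide_id = slide_id, n_total = n_total
    )
  })
}
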