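#' The six ordinal ripeness stages
#'
#' Strawberry ripeness is graded into six colour-defined stages by the
#' fraction of the fruit surface that has turned red, growing from the fruit
#' tip upward: White (light green, no red), Breaking (one-fifth red),
#' Turning-1 (two-fifths), Turning-2 (three-fifths), Ripe (four-fifths) and
#' Full ripe (entirely dark red).
#'
#' @return A tibble with one row per stage: `stage` (factor, ordered by
#'   ripeness), `code` (integer 0--5) and `red_fraction` (nominal fraction of
#'   the fruit surface that is red at that stage).
#' @examples
#' ripeness_stages()
#' @export
ripeness_stages <- function() {
  tibble(
    stage = factor(stage_levels(), levels = stage_levels()),
    code = 0:5,
    red_fraction = c(0, 0.2, 0.4, 0.6, 0.8, 1)
  )
}

stage_levels <- function() {
  c("White", "Breaking", "Turning-1", "Turning-2", "Ripe", "Full ripe")
}

as_stage <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) x <- stage_levels()[x + 1L]
  bad <- !x %in% stage_levels()
  if (any(bad)) {
    stopf("berry_bad_stage", "unknown ripeness stage(s): %s",
          paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = stage_levels())
}
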