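#' Describe a functional-effect analyzer
#'
#' An analyzer spec records the analyzer's native score range, its
#' deleteriousness cutoff with the direction of the cutoff inequality, and the
#' granularity at which it scores (per variant, or per variant-transcript
#' pair). From these the normalization anchors are derived: after
#' harmonization to a "higher is more deleterious" direction, `x_min` is the
#' harmonized cutoff and `x_max` the harmonized range maximum, so that
#' min-max normalization maps the deleterious part of the scale onto
#' \[0, 1\] with the cutoff at 0.
#'
#' @param name Analyzer name, e.g. `"FATHMM-XF"`.
#' @param score_min,score_max Endpoints of the native score range.
#' @param cutoff Deleteriousness threshold on the native scale.
#' @param direction `"higher"` if larger native scores mean more deleterious
#'   (FATHMM-XF, CADD, PolyPhen), `"lower"` if smaller ones do (SIFT).
#' @param granularity `"variant"` if one score per SNV, `"transcript"` if one
#'   score per (SNV, transcript) pair.
#' @return An object of class `analyzer_spec`.
#' @examples
#' analyzer_spec("SIFT", 0, 1, 0.05, direction = "lower")
#' @export
analyzer_spec <- function(name, score_min, score_max, cutoff,
                          direction = c("higher", "lower"),
                          granularity = c("variant", "transcript")) {
  direction <- match.arg(direction)
  granularity <- match.arg(granularity)
  stopifnot(is.numeric(score_min), is.numeric(score_max),
            length(score_min) == 1, length(score_max) == 1,
            score_min < score_max, is.numeric(cutoff), length(cutoff) == 1)
  if (cutoff < score_min || cutoff > score_max) {
    stop(name, ": cutoff ", cutoff, " outside score range [",
         score_min, ", ", score_max, "]")
  }
  reflect <- function(x) score_min + score_max - x
  x_min <- if (direction == "higher") cutoff else reflect(cutoff)
  x_max <- if (direction == "higher") score_max else reflect(score_min)
  structure(
    list(name = name, score_min = score_min, score_max = score_max,
         cutoff = cutoff, direction = direction, granularity = granularity,
         x_min = x_min, x_max = x_max),
    class = "analyzer_spec"
  )
}

#' @export
print.analyzer_spec <- function(x, ...) {
  op <- if (x$direction == "higher") ">=" else "<="
  cat(sprintf("<analyzer_spec> %s: range [%g, %g], deleterious %s %g, per %s\n",
              x$name, x$score_min, x$score_max, op, x$cutoff, x$granularity))
  invisible(x)
}

#' Default analyzer specifications
#'
#' The four analyzers integrated by default, with their published score
#' ranges and deleteriousness cutoffs: FATHMM-XF (0-1, deleterious >= 0.5,
#' per variant), CADD PHRED (0-99, >= 10, per transcript), SIFT (0-1,
#' <= 0.05, per transcript), PolyPhen (0-1, >= 0.447, per transcript).
#'
#' @return Named list of [analyzer_spec()] objects.
#' @export
default_analyzers <- function() {
  list(
    "FATHMM-XF" = analyzer_spec("FATHMM-XF", 0, 1, 0.5, "higher", "variant"),
    "CADD"      = analyzer_spec("CADD", 0, 99, 10, "higher", "transcript"),
    "SIFT"      = analyzer_spec("SIFT", 0, 1, 0.05, "lower", "transcript"),
    "PolyPhen"  = analyzer_spec("PolyPhen", 0, 1, 0.447, "higher", "transcript")
  )
}

# Lower-case key used for integrated-table column names ("FATHMM-XF" ->
# "fathmm_xf").
analyzer_key <- function(name) gsub("[^a-z0-9]+", "_", tolower(name))

check_score_range <- function(x, spec) {
  bad <- !is.na(x) & (x < spec$score_min | x > spec$score_max)
  if (any(bad)) {
    stop(spec$name, ": score(s) outside [", spec$score_min, ", ",
         spec$score_max, "], e.g. ", x[which(bad)[1]])
  }
  invisible(x)
}

#' Harmonize a raw analyzer score to a common direction
#'
#' Returns the score unchanged for higher-is-deleterious analyzers; for
#' lower-is-deleterious analyzers (SIFT) the score is reflected within its
#' range (on a 0-1 range, `x` becomes `1 - x`), so that after harmonization
#' a larger score always means more deleterious.
#'
#' @param x Numeric vector of raw scores on the analyzer's native scale.
#' @param spec An [analyzer_spec()].
#' @return Harmonized scores; `NA` passes through.
#' @examples
#' harmonize_score(0.05, default_analyzers()$SIFT) # 0.95
#' @export
harmonize_score <- function(x, spec) {
  check_score_range(x, spec)
  if (spec$direction == "lower") spec$score_min + spec$score_max - x else x
}

#' Classify a raw score as deleterious under the analyzer's cutoff
#'
#' Applies the cutoff inequality in the analyzer's native direction:
#' `x >= cutoff` for higher-is-deleterious analyzers, `x <= cutoff` for
#' lower-is-deleterious ones.
#'
#' @inheritParams harmonize_score
#' @return Logical vector (`NA` where the score is missing).
#' @examples
#' classify_deleterious(c(9.99, 10), default_analyzers()$CADD)
#' @export
classify_deleterious <- function(x, spec) {
  check_score_range(x, spec)
  if (spec$direction == "higher") x >= spec$cutoff else x <= spec$cutoff
}

#' Cutoff-anchored min-max normalization of a harmonized score
#'
#' Maps a harmonized score onto \[0, 1\] as `(x - x_min) / (x_max - x_min)`
#' with the anchors taken from the analyzer spec (harmonized cutoff and
#' harmonized range maximum), clamping to \[0, 1\] so that sub-cutoff
#' (benign) scores contribute 0.
#'
#' @param x Numeric vector of harmonized scores (see [harmonize_score()]).
#' @param spec An [analyzer_spec()].
#' @return Normalized scores in \[0, 1\]; `NA` passes through.
#' @examples
#' normalize_score(0.75, default_analyzers()$"FATHMM-XF") # 0.5
#' @export
normalize_score <- function(x, spec) {
  stopifnot(spec$x_min < spec$x_max)
  clamp01((x - spec$x_min) / (spec$x_max - spec$x_min))
}

#' Normalized deleteriousness from a raw analyzer score
#'
#' Convenience composition of [harmonize_score()] and [normalize_score()].
#'
#' @inheritParams harmonize_score
#' @return Normalized scores in \[0, 1\].
#' @export
analyzer_score <- function(x, spec) {
  normalize_score(harmonize_score(x, spec), spec)
}
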