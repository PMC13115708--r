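#' Cumulative per-gene burden scores
#'
#' Aggregates integrated variant scores into one burden score per pathogenic
#' gene. For each transcript \eqn{t_j} of gene \eqn{G} the contributions of
#' its deleterious SNVs are summed as
#' \deqn{\frac{1}{\ln l(t_j)} \sum_{v \in t_j} \mathrm{Score}(v)\,[\mathrm{tumor}_v - \mathrm{normal}_v]}
#' where \eqn{l(t_j)} is the transcript length, \eqn{\mathrm{Score}(v)} the
#' normalized deleteriousness, and \eqn{\mathrm{tumor}_v},
#' \eqn{\mathrm{normal}_v} the numbers of patients carrying \eqn{v} in tumor
#' and normal samples. The gene score is the unweighted average of these
#' transcript sums over all \eqn{N_G} transcripts of the gene observed in
#' the cohort annotations (transcripts without deleterious variants
#' contribute 0 but count in \eqn{N_G}).
#'
#' In `"integrative"` mode a variant is deleterious if any analyzer flags
#' it, and `Score(v)` is `ave_score` (the mean of all available normalized
#' analyzer scores). In single-analyzer mode only that analyzer's flag and
#' normalized score are used; variants it did not score are skipped.
#' A gene is *pathogenic*, and hence scored and ranked, iff it carries at
#' least one deleterious SNV under the mode.
#'
#' @param integrated Integrated score table from [integrate_scores()].
#' @param frequencies Variant frequency table from
#'   [build_frequency_table()].
#' @param mode `"integrative"` or an analyzer name present in the integrated
#'   table (e.g. `"CADD"`, `"FATHMM-XF"`).
#' @param length_penalty Transcript-length penalty: `"ln"` (default,
#'   \eqn{1/\ln l}), `"sqrt"` (\eqn{1/\sqrt l}), or `"linear"` (\eqn{1/l}).
#' @return Ranked tibble (see [rank_genes()]) with columns `gene_symbol`,
#'   `score`, `rank`, `n_transcripts`, `n_variants`; attribute `mode`.
#' @export
score_genes <- function(integrated, frequencies, mode = "integrative",
                        length_penalty = c("ln", "sqrt", "linear")) {
  length_penalty <- match.arg(length_penalty)
  pen <- switch(length_penalty,
                ln = function(l) 1 / log(l),
                sqrt = function(l) 1 / sqrt(l),
                linear = function(l) 1 / l)

  if (identical(mode, "integrative")) {
    sc <- integrated$ave_score
    fl <- integrated$is_deleterious_any
  } else {
    key <- analyzer_key(mode)
    scol <- paste0("score_", key)
    fcol <- paste0("flag_", key)
    if (!all(c(scol, fcol) %in% names(integrated))) {
      stop("no scores for analyzer '", mode, "' in the integrated table")
    }
    sc <- integrated[[scol]]
    fl <- integrated[[fcol]] & !is.na(integrated[[scol]])
  }
  fl[is.na(fl)] <- FALSE
  fl <- fl & !is.na(sc)

  if (any(is.na(integrated$transcript_length) |
          integrated$transcript_length < 2)) {
    stop("transcript lengths must all be >= 2 (ln undefined or zero)")
  }

  df <- integrated %>%
    dplyr::mutate(
      .score = sc, .flag = fl,
      .key = variant_uid(.data$chrom, .data$pos, .data$ref, .data$alt)
    )
  fkey <- variant_uid(frequencies$chrom, frequencies$pos,
                      frequencies$ref, frequencies$alt)
  idx <- match(df$.key, fkey)
  if (any(is.na(idx[df$.flag]))) {
    stop("deleterious variant(s) missing from the frequency table")
  }
  df$.diff <- frequencies$tumor_count[idx] - frequencies$normal_count[idx]

  n_g <- df %>%
    dplyr::distinct(.data$gene_symbol, .data$transcript_id) %>%
    dplyr::count(.data$gene_symbol, name = "n_transcripts")

  contrib <- df %>%
    dplyr::filter(.data$.flag) %>%
    dplyr::group_by(.data$gene_symbol, .data$transcript_id,
                    .data$transcript_length) %>%
    dplyr::summarise(inner = sum(.data$.score * .data$.diff),
                     .groups = "drop") %>%
    dplyr::mutate(tscore = pen(.data$transcript_length) * .data$inner)

  n_var <- df %>%
    dplyr::filter(.data$.flag) %>%
    dplyr::group_by(.data$gene_symbol) %>%
    dplyr::summarise(n_variants = dplyr::n_distinct(.data$.key),
                     .groups = "drop")

  scored <- contrib %>%
    dplyr::group_by(.data$gene_symbol) %>%
    dplyr::summarise(total = sum(.data$tscore), .groups = "drop") %>%
    dplyr::left_join(n_g, by = "gene_symbol") %>%
    dplyr::left_join(n_var, by = "gene_symbol") %>%
    dplyr::transmute(gene_symbol = .data$gene_symbol,
                     score = .data$total / .data$n_transcripts,
                     n_transcripts = .data$n_transcripts,
                     n_variants = .data$n_variants)

  out <- rank_genes(scored)
  attr(out, "mode") <- mode
  attr(out, "length_penalty") <- length_penalty
  out
}

#' Rank pathogenic genes by score
#'
#' Sorts genes by descending score and assigns competition ranks (ties share
#' the minimal rank of their block; the gene after a tied block of size
#' \eqn{m} at rank \eqn{r} gets rank \eqn{r + m}). The highest-scoring gene
#' has rank 1. Output rows are ordered by rank, then gene symbol, for
#' deterministic output.
#'
#' @param scored Tibble with at least `gene_symbol` and `score` columns.
#' @return The input with an integer `rank` column, ordered by rank; the
#'   number of pathogenic genes \eqn{p} is `nrow()` (also attribute `p`).
#' @export
rank_genes <- function(scored) {
  stopifnot(all(c("gene_symbol", "score") %in% names(scored)))
  if (nrow(scored) == 0) {
    out <- dplyr::mutate(scored, rank = integer(0))
    attr(out, "p") <- 0L
    return(out)
  }
  out <- scored %>%
    dplyr::mutate(rank = as.integer(rank(-.data$score, ties.method = "min"))) %>%
    dplyr::arrange(.data$rank, .data$gene_symbol)
  attr(out, "p") <- nrow(out)
  out
}

#' Top-scoring fraction of a gene ranking
#'
#' Returns the gene symbols of the `ceiling(fraction * p)` highest-ranked
#' genes; ties spanning the boundary are all included, so the list may be
#' longer.
#'
#' @param ranked Ranked gene table from [score_genes()]/[rank_genes()].
#' @param fraction Fraction of genes to keep, in (0, 1\].
#' @return Character vector of gene symbols in rank order.
#' @export
top_fraction_genes <- function(ranked, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  p <- nrow(ranked)
  if (p == 0) return(character(0))
  n <- ceiling(fraction * p)
  thr <- sort(ranked$score, decreasing = TRUE)[n]
  ranked$gene_symbol[ranked$score >= thr]
}
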