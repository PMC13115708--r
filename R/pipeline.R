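#' Run the full burden-scoring pipeline on a cohort
#'
#' Convenience wrapper chaining ingestion, the nonsynonymous/protein-coding
#' filter, analyzer score integration, and gene scoring in one or several
#' modes.
#'
#' @param manifest Cohort manifest (path or data frame), see
#'   [ingest_cohort()].
#' @param fathmm,cadd Optional paths to the external per-variant (CSV) and
#'   per-variant-per-transcript (TSV) score tables.
#' @param modes Character vector of scoring modes: `"integrative"` and/or
#'   analyzer names.
#' @param analyzers Named list of [analyzer_spec()]s.
#' @param consequences,biotypes Passed to [filter_nonsynonymous()].
#' @param length_penalty Passed to [score_genes()].
#' @return List with `cohort` (the `snv_cohort`), `filtered` (records),
#'   `integrated` (score table), and `rankings` (named list of ranked gene
#'   tables, one per mode).
#' @export
run_burden_pipeline <- function(manifest, fathmm = NULL, cadd = NULL,
                                modes = "integrative",
                                analyzers = default_analyzers(),
                                consequences = default_nonsynonymous(),
                                biotypes = "protein_coding",
                                length_penalty = "ln") {
  cohort <- ingest_cohort(manifest)
  filtered <- filter_nonsynonymous(cohort$records, consequences, biotypes)
  external <- list()
  if (!is.null(fathmm)) external[["FATHMM-XF"]] <- read_fathmm_scores(fathmm)
  if (!is.null(cadd)) external[["CADD"]] <- read_cadd_scores(cadd)
  integrated <- integrate_scores(filtered, external, analyzers)
  rankings <- lapply(modes, function(m) {
    score_genes(integrated, cohort$frequencies, mode = m,
                length_penalty = length_penalty)
  })
  names(rankings) <- modes
  list(cohort = cohort, filtered = filtered, integrated = integrated,
       rankings = rankings)
}
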