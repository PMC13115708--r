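#' Read a per-variant analyzer score table (FATHMM-XF style)
#'
#' A CSV keyed by chromosome, position, reference and alternate allele with
#' one score per variant.
#'
#' @param path CSV file path.
#' @param cols Named character vector mapping the standard names
#'   (`chrom`, `pos`, `ref`, `alt`, `score`) to the file's column names.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `score`.
#' @export
read_fathmm_scores <- function(path,
                               cols = c(chrom = "chrom", pos = "pos",
                                        ref = "ref", alt = "alt",
                                        score = "score")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  standardize_score_table(df, cols, transcript = FALSE)
}

#' Read a per-variant-per-transcript analyzer score table (CADD style)
#'
#' A TSV keyed by chromosome, position, ref, alt and transcript identifier,
#' with one score per (variant, transcript) pair.
#'
#' @param path TSV file path.
#' @param cols Named character vector mapping the standard names (`chrom`,
#'   `pos`, `ref`, `alt`, `transcript_id`, `score`) to the file's columns.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `transcript_id`, `score`.
#' @export
read_cadd_scores <- function(path,
                             cols = c(chrom = "chrom", pos = "pos",
                                      ref = "ref", alt = "alt",
                                      transcript_id = "transcript_id",
                                      score = "phred")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  standardize_score_table(df, cols, transcript = TRUE)
}

standardize_score_table <- function(df, cols, transcript) {
  wanted <- c("chrom", "pos", "ref", "alt", if (transcript) "transcript_id",
              "score")
  missing <- setdiff(wanted, names(cols))
  if (length(missing)) stop("column mapping lacks: ",
                            paste(missing, collapse = ", "))
  absent <- setdiff(unname(cols[wanted]), names(df))
  if (length(absent)) stop("score table lacks column(s): ",
                           paste(absent, collapse = ", "))
  out <- tibble::tibble(
    chrom = as.character(df[[cols[["chrom"]]]]),
    pos = as.integer(df[[cols[["pos"]]]]),
    ref = as.character(df[[cols[["ref"]]]]),
    alt = as.character(df[[cols[["alt"]]]])
  )
  if (transcript) out$transcript_id <- as.character(df[[cols[["transcript_id"]]]])
  out$score <- as.numeric(df[[cols[["score"]]]])
  out
}

#' Merge analyzer scores into an integrated per-variant score table
#'
#' Joins external score tables and CSQ-embedded SIFT/PolyPhen scores onto
#' the (SNV, transcript) consequence records, then computes for each
#' analyzer the harmonized, cutoff-anchored normalized score and the native
#' deleteriousness flag, the integrative average score `ave_score` (mean of
#' all available normalized scores, deleterious or not), and
#' `is_deleterious_any` (whether at least one analyzer calls the variant
#' deleterious). Per-variant analyzers are broadcast to every transcript of
#' the variant; per-transcript analyzers join on (variant, transcript).
#' Chromosome names are normalized symmetrically (`"chr"` prefix stripped)
#' before joining. External rows matching no cohort variant are counted and
#' ignored; duplicated external keys keep the first score with a warning;
#' out-of-range external scores are rejected (set missing) with a warning.
#'
#' @param records Filtered consequence records ([filter_nonsynonymous()]).
#' @param external Named list of external score tibbles; names must match
#'   analyzer names in `analyzers` (e.g.
#'   `list("FATHMM-XF" = ..., CADD = ...)`).
#' @param analyzers Named list of [analyzer_spec()]s; `SIFT` and `PolyPhen`,
#'   when present, are taken from the records' embedded score columns.
#' @return Tibble with one row per (SNV, transcript): the variant key
#'   columns, `gene_symbol`, `transcript_length`, per-analyzer `raw_*`,
#'   `score_*` (normalized) and `flag_*` columns, `ave_score`, `n_scores`,
#'   and `is_deleterious_any`. Attributes `n_unmatched` and `n_duplicate`
#'   count ignored external rows per analyzer.
#' @export
integrate_scores <- function(records, external = list(),
                             analyzers = default_analyzers()) {
  base <- records %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$transcript_id, .keep_all = TRUE) %>%
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
      transcript_id = .data$transcript_id, gene_symbol = .data$gene_symbol,
      transcript_length = .data$transcript_length,
      .key = variant_uid(.data$chrom, .data$pos, .data$ref, .data$alt),
      .sift = .data$sift_raw, .polyphen = .data$polyphen_raw
    )

  unknown <- setdiff(names(external), names(analyzers))
  if (length(unknown)) stop("external scores for unknown analyzer(s): ",
                            paste(unknown, collapse = ", "))

  n_unmatched <- integer(0)
  n_duplicate <- integer(0)
  score_cols <- character(0)
  flag_cols <- character(0)

  for (nm in names(analyzers)) {
    spec <- analyzers[[nm]]
    key <- analyzer_key(nm)
    raw <- if (nm == "SIFT") {
      base$.sift
    } else if (nm == "PolyPhen") {
      base$.polyphen
    } else if (nm %in% names(external)) {
      ext <- external[[nm]]
      ekey <- variant_uid(ext$chrom, ext$pos, ext$ref, ext$alt)
      if (spec$granularity == "transcript") {
        if (!"transcript_id" %in% names(ext)) {
          stop(nm, ": per-transcript analyzer needs a transcript_id column")
        }
        ekey <- paste(ekey, ext$transcript_id, sep = "@")
        bkey <- paste(base$.key, base$transcript_id, sep = "@")
      } else {
        bkey <- base$.key
      }
      dup <- duplicated(ekey)
      if (any(dup)) {
        warning(nm, ": ", sum(dup),
                " duplicate external score row(s); keeping first",
                call. = FALSE)
        ext <- ext[!dup, , drop = FALSE]
        ekey <- ekey[!dup]
      }
      n_duplicate[nm] <- sum(dup)
      n_unmatched[nm] <- sum(!ekey %in% bkey)
      ext$score[match(bkey, ekey)]
    } else {
      rep(NA_real_, nrow(base))
    }

    out_of_range <- !is.na(raw) & (raw < spec$score_min | raw > spec$score_max)
    if (any(out_of_range)) {
      warning(nm, ": ", sum(out_of_range),
              " score(s) outside [", spec$score_min, ", ", spec$score_max,
              "] rejected, e.g. ", raw[which(out_of_range)[1]],
              call. = FALSE)
      raw[out_of_range] <- NA_real_
    }

    base[[paste0("raw_", key)]] <- raw
    base[[paste0("score_", key)]] <- analyzer_score(raw, spec)
    base[[paste0("flag_", key)]] <- classify_deleterious(raw, spec)
    score_cols <- c(score_cols, paste0("score_", key))
    flag_cols <- c(flag_cols, paste0("flag_", key))
  }

  sc <- as.matrix(base[score_cols])
  fl <- as.matrix(base[flag_cols])
  base$n_scores <- rowSums(!is.na(sc))
  base$ave_score <- ifelse(base$n_scores > 0, rowMeans(sc, na.rm = TRUE),
                           NA_real_)
  base$is_deleterious_any <- rowSums(fl, na.rm = TRUE) > 0

  base <- base %>% dplyr::select(-".sift", -".polyphen", -".key")
  attr(base, "n_unmatched") <- n_unmatched
  attr(base, "n_duplicate") <- n_duplicate
  attr(base, "analyzers") <- analyzers
  base
}
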