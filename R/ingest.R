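#' Default mapping from CSQ field names to record fields
#'
#' CSQ annotation packs per-transcript consequences into pipe-delimited
#' fields whose names are declared in the VCF metadata and vary between
#' projects. This mapping names, for each record field this package needs,
#' the CSQ field it is read from (VEP default names). The transcript length
#' is taken from the denominator of the `cDNA_position` field
#' (`"position/length"`).
#'
#' @return Named list of CSQ field names.
#' @export
default_csq_map <- function() {
  list(
    allele        = "Allele",
    gene          = "SYMBOL",
    transcript    = "Feature",
    consequence   = "Consequence",
    biotype       = "BIOTYPE",
    cdna_position = "cDNA_position",
    sift          = "SIFT",
    polyphen      = "PolyPhen"
  )
}

# "tolerated(0.32)" -> 0.32; bare numerics accepted; anything else -> NA.
parse_prediction_score <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  r <- regexpr("\\(([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\)", x)
  has <- !is.na(x) & r > 0
  if (any(has)) {
    len <- attr(r, "match.length")
    out[has] <- as.numeric(substring(x[has], r[has] + 1, r[has] + len[has] - 2))
  }
  bare <- !has & !is.na(x) & nzchar(x)
  out[bare] <- suppressWarnings(as.numeric(x[bare]))
  out
}

# "123/2034" -> 2034; bare "2034" -> 2034; else NA.
parse_cdna_length <- function(x) {
  out <- rep(NA_integer_, length(x))
  slash <- grepl("/", x, fixed = TRUE)
  out[slash] <- suppressWarnings(as.integer(sub("^.*/", "", x[slash])))
  out[!slash] <- suppressWarnings(as.integer(x[!slash]))
  out
}

empty_records <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gene_symbol = character(), transcript_id = character(),
    consequence = character(), biotype = character(),
    transcript_length = integer(), sift_raw = double(), polyphen_raw = double()
  )
}

empty_carriage <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), patient_id = character(),
    in_tumor = logical(), in_normal = logical()
  )
}

# Does genotype string g (e.g. "0/1", "0|1", "./.") include alt index j?
gt_carries_alt <- function(g, j) {
  if (is.na(g) || g == "" || g == ".") return(FALSE)
  any(strsplit(g, "[/|]")[[1]] == as.character(j))
}

#' Parse one annotated somatic VCF
#'
#' Reads a VCF 4.x file carrying CSQ annotation, expands each comma-separated
#' CSQ entry into one consequence record per (SNV, transcript) pair, and
#' derives per-SNV tumor/normal carriage for the patient from the paired
#' genotype columns (a sample carries the SNV iff its genotype includes the
#' alt allele; unknown genotypes count as not carrying). Multi-allelic lines
#' are split into one SNV per alternate allele; non-SNV alleles (indels,
#' multi-base substitutions) are skipped and counted.
#'
#' @param path Path to a VCF file (plain or bgzipped) whose metadata declare
#'   the CSQ field layout in a `##INFO=<ID=CSQ,... Format: ...>` line.
#' @param patient_id Identifier of the patient the file belongs to.
#' @param csq_map Mapping from record fields to CSQ field names, see
#'   [default_csq_map()].
#' @param tumor_sample,normal_sample Names of the tumor and normal genotype
#'   columns; if a name is absent the second (tumor) and first (normal)
#'   genotype columns are used.
#' @return A list with elements `records` (tibble of consequence records),
#'   `carriage` (tibble with one row per SNV: `patient_id`, `in_tumor`,
#'   `in_normal`), and `skipped` (counts of skipped non-SNV alleles and
#'   malformed CSQ entries).
#' @export
parse_vcf <- function(path, patient_id, csq_map = default_csq_map(),
                      tumor_sample = "TUMOR", normal_sample = "NORMAL") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(csq_line) == 0) {
    stop("no CSQ INFO definition found in ", path)
  }
  fmt <- sub(".*Format:\\s*", "", csq_line[1])
  fmt <- sub("\"?>.*$", "", fmt)
  csq_fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  nf <- length(csq_fields)

  fix <- vcf@fix
  n <- nrow(fix)
  skipped <- c(non_snv = 0L, bad_csq = 0L)
  if (n == 0) {
    return(list(records = empty_records(), carriage = empty_carriage(),
                skipped = skipped))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = n,
                 dimnames = list(NULL, colnames(vcf@gt)[-1]))
  }
  samples <- colnames(gt)
  pick <- function(wanted, fallback) {
    if (!is.null(samples) && wanted %in% samples) wanted
    else samples[min(fallback, length(samples))]
  }
  t_col <- pick(tumor_sample, 2L)
  n_col <- pick(normal_sample, 1L)

  csq_str <- vcfR::extract.info(vcf, element = "CSQ")

  field_or_na <- function(parts, field) {
    if (is.null(field) || !field %in% csq_fields) return(NA_character_)
    parts[[match(field, csq_fields)]]
  }

  recs <- vector("list", n)
  cars <- vector("list", n)
  for (i in seq_len(n)) {
    chrom_i <- unname(fix[i, "CHROM"])
    pos_i <- as.integer(fix[i, "POS"])
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    entries <- if (is.na(csq_str[i])) character() else
      strsplit(csq_str[i], ",", fixed = TRUE)[[1]]
    parsed <- vector("list", length(entries))
    for (e in seq_along(entries)) {
      parts <- strsplit(entries[e], "|", fixed = TRUE)[[1]]
      if (length(parts) > nf) {
        skipped["bad_csq"] <- skipped["bad_csq"] + 1L
        warning("CSQ entry with wrong field count at record ", i,
                " of ", path, call. = FALSE)
        next
      }
      length(parts) <- nf
      parts[is.na(parts)] <- ""
      parsed[[e]] <- parts
    }
    parsed <- parsed[!vapply(parsed, is.null, TRUE)]

    row_recs <- list()
    row_cars <- list()
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES)) {
        skipped["non_snv"] <- skipped["non_snv"] + 1L
        next
      }
      keep <- parsed
      if (length(alts) > 1 && !is.null(csq_map$allele) &&
          csq_map$allele %in% csq_fields) {
        keep <- Filter(function(p) field_or_na(p, csq_map$allele) == alt,
                       parsed)
      }
      if (length(keep) > 0) {
        row_recs[[length(row_recs) + 1L]] <- tibble::tibble(
          chrom = chrom_i, pos = pos_i,
          ref = ref, alt = alt,
          gene_symbol = vapply(keep, field_or_na, "", csq_map$gene),
          transcript_id = vapply(keep, field_or_na, "", csq_map$transcript),
          consequence = vapply(keep, field_or_na, "", csq_map$consequence),
          biotype = vapply(keep, field_or_na, "", csq_map$biotype),
          transcript_length = parse_cdna_length(
            vapply(keep, field_or_na, "", csq_map$cdna_position)),
          sift_raw = parse_prediction_score(
            vapply(keep, field_or_na, "", csq_map$sift)),
          polyphen_raw = parse_prediction_score(
            vapply(keep, field_or_na, "", csq_map$polyphen))
        )
      }
      row_cars[[length(row_cars) + 1L]] <- tibble::tibble(
        chrom = chrom_i, pos = pos_i,
        ref = ref, alt = alt, patient_id = patient_id,
        in_tumor = gt_carries_alt(gt[i, t_col], j),
        in_normal = gt_carries_alt(gt[i, n_col], j)
      )
    }
    recs[[i]] <- dplyr::bind_rows(row_recs)
    cars[[i]] <- dplyr::bind_rows(row_cars)
  }

  records <- dplyr::bind_rows(recs)
  carriage <- dplyr::bind_rows(cars)
  if (nrow(records) == 0) records <- empty_records()
  if (nrow(carriage) == 0) carriage <- empty_carriage()
  list(records = records, carriage = carriage, skipped = skipped)
}

#' Build the unique-variant frequency table
#'
#' Counts, for every SNV, the number of distinct patients carrying it in
#' tumor and in normal samples. Within-patient duplicates (the same SNV seen
#' in several files of one patient) count once; the same SNV in different
#' patients counts once per patient. Each variant is categorized as
#' `tumor_only`, `normal_only`, or `common`.
#'
#' @param carriage Tibble of per-patient carriage rows as produced by
#'   [parse_vcf()] (possibly concatenated across files and patients).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `tumor_count`,
#'   `normal_count`, `category`.
#' @export
build_frequency_table <- function(carriage) {
  if (nrow(carriage) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          tumor_count = integer(), normal_count = integer(),
                          category = character()))
  }
  carriage %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    dplyr::summarise(
      tumor_count = dplyr::n_distinct(.data$patient_id[.data$in_tumor]),
      normal_count = dplyr::n_distinct(.data$patient_id[.data$in_normal]),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$tumor_count + .data$normal_count >= 1) %>%
    dplyr::mutate(category = dplyr::case_when(
      .data$normal_count == 0 ~ "tumor_only",
      .data$tumor_count == 0 ~ "normal_only",
      TRUE ~ "common"
    ))
}

#' Ingest a cohort of annotated somatic VCFs
#'
#' Parses every VCF listed in a cohort manifest, merges per-patient carriage
#' (deduplicating variants repeated across files of the same patient), builds
#' the unique-variant frequency table, and pools the consequence records.
#'
#' @param manifest Either a path to a CSV with columns `patient_id`,
#'   `vcf_path` (relative paths are resolved against the manifest's
#'   directory), or a data frame with those columns.
#' @inheritParams parse_vcf
#' @return An object of class `snv_cohort`: a list with `records` (unique
#'   (SNV, transcript) consequence records), `frequencies` (see
#'   [build_frequency_table()]), `carriage`, `n_files`, `n_patients`,
#'   `patients`, and `skipped` counts.
#' @export
ingest_cohort <- function(manifest, csq_map = default_csq_map(),
                          tumor_sample = "TUMOR", normal_sample = "NORMAL") {
  if (is.character(manifest) && length(manifest) == 1) {
    base_dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
    rel <- !grepl("^(/|[A-Za-z]:)", manifest$vcf_path)
    manifest$vcf_path[rel] <- file.path(base_dir, manifest$vcf_path[rel])
  }
  stopifnot(all(c("patient_id", "vcf_path") %in% names(manifest)))

  parsed <- purrr::map2(manifest$vcf_path, manifest$patient_id, parse_vcf,
                        csq_map = csq_map, tumor_sample = tumor_sample,
                        normal_sample = normal_sample)

  carriage <- purrr::map(parsed, "carriage") %>%
    dplyr::bind_rows() %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$patient_id) %>%
    dplyr::summarise(in_tumor = any(.data$in_tumor),
                     in_normal = any(.data$in_normal), .groups = "drop")

  records <- purrr::map(parsed, "records") %>%
    dplyr::bind_rows() %>%
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$transcript_id, .keep_all = TRUE)

  skipped <- Reduce(`+`, purrr::map(parsed, "skipped"))

  structure(
    list(records = records,
         frequencies = build_frequency_table(carriage),
         carriage = carriage,
         n_files = nrow(manifest),
         n_patients = dplyr::n_distinct(manifest$patient_id),
         patients = sort(unique(manifest$patient_id)),
         skipped = skipped),
    class = "snv_cohort"
  )
}

#' @export
print.snv_cohort <- function(x, ...) {
  cat(sprintf(
    "<snv_cohort> %d patients / %d files; %d unique SNVs; %d (SNV, transcript) records\n",
    x$n_patients, x$n_files, nrow(x$frequencies), nrow(x$records)))
  invisible(x)
}

#' Default nonsynonymous consequence terms
#'
#' Consequence terms treated as nonsynonymous when filtering: missense plus
#' the loss-of-function substitution types expressible as SNVs (nonsense and
#' start/stop disruption).
#'
#' @return Character vector of consequence terms.
#' @export
default_nonsynonymous <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost")
}

#' Filter consequence records to nonsynonymous, protein-coding ones
#'
#' Keeps records whose transcript biotype is in `biotypes` and whose
#' consequence field contains at least one term from `consequences`
#' (compound annotations joined with `&` are split). Records with an empty
#' consequence are dropped and counted in the `n_empty_consequence`
#' attribute of the result.
#'
#' @param records Tibble of consequence records ([parse_vcf()]).
#' @param consequences Character vector of consequence terms to retain.
#' @param biotypes Character vector of transcript biotypes to retain.
#' @return Filtered tibble; filtering is idempotent.
#' @export
filter_nonsynonymous <- function(records,
                                 consequences = default_nonsynonymous(),
                                 biotypes = "protein_coding") {
  empty <- is.na(records$consequence) | !nzchar(records$consequence)
  terms <- strsplit(records$consequence, "&", fixed = TRUE)
  hit <- vapply(terms, function(tt) any(tt %in% consequences), TRUE)
  keep <- !empty & hit & records$biotype %in% biotypes
  out <- records[keep, , drop = FALSE]
  attr(out, "n_empty_consequence") <- sum(empty)
  out
}

#' Tally the 12 single-nucleotide substitution types
#'
#' Counts unique SNVs present in the given sample class by (reference base,
#' alternate base). Returned as a 4x4 integer matrix (rows = ref, columns =
#' alt) whose diagonal is structurally zero, so each row sums to the number
#' of SNVs with that reference base in that sample class.
#'
#' @param frequencies Frequency table from [build_frequency_table()].
#' @param class `"tumor"` or `"normal"`: count variants carried by at least
#'   one patient in that sample class.
#' @return 4x4 integer matrix with dimnames A/C/G/T.
#' @export
change_type_matrix <- function(frequencies, class = c("tumor", "normal")) {
  class <- match.arg(class)
  col <- paste0(class, "_count")
  sub <- frequencies[frequencies[[col]] > 0, , drop = FALSE]
  m <- table(factor(sub$ref, levels = DNA_BASES),
             factor(sub$alt, levels = DNA_BASES))
  m <- matrix(as.integer(m), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m
}

#' Summarize a cohort
#'
#' Collects the headline counts of an ingested cohort: files, patients,
#' unique SNVs (overall and after the nonsynonymous/protein-coding filter),
#' SNV counts by tumor/normal category, unique transcripts and genes, and
#' the 12-way nucleotide-change tallies for tumor and normal samples.
#'
#' @param cohort An `snv_cohort` from [ingest_cohort()].
#' @param filtered Optional pre-filtered record tibble; by default
#'   [filter_nonsynonymous()] with its defaults is applied.
#' @return A list of summary counts and matrices (JSON-serializable).
#' @export
summarize_cohort <- function(cohort, filtered = NULL) {
  if (is.null(filtered)) filtered <- filter_nonsynonymous(cohort$records)
  freq <- cohort$frequencies
  filt_keys <- unique(variant_uid(filtered$chrom, filtered$pos,
                                  filtered$ref, filtered$alt))
  freq_f <- freq[variant_uid(freq$chrom, freq$pos, freq$ref, freq$alt) %in%
                   filt_keys, , drop = FALSE]
  cat_counts <- function(f) {
    as.list(table(factor(f$category,
                         levels = c("normal_only", "tumor_only", "common"))))
  }
  list(
    n_vcf_files = cohort$n_files,
    n_patients = cohort$n_patients,
    n_unique_snvs = list(all = nrow(freq), filtered = nrow(freq_f)),
    categories = list(all = cat_counts(freq), filtered = cat_counts(freq_f)),
    n_transcripts = list(
      all = dplyr::n_distinct(cohort$records$transcript_id),
      filtered = dplyr::n_distinct(filtered$transcript_id)),
    n_genes = list(
      all = dplyr::n_distinct(cohort$records$gene_symbol),
      filtered = dplyr::n_distinct(filtered$gene_symbol)),
    change_type = list(
      tumor = change_type_matrix(freq, "tumor"),
      normal = change_type_matrix(freq, "normal")),
    skipped = as.list(cohort$skipped)
  )
}
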