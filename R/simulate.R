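#' Configuration for a synthetic somatic cohort
#'
#' Defines the generative conditions of a simulated tumor/normal SNV cohort:
#' cohort and gene-model sizes, planted driver genes with elevated
#' deleterious-variant burden, the tumor-only/normal-only/common carriage
#' mix, per-analyzer score noise and missingness, and the latent
#' deleteriousness mixture (Beta distributions for driver and passenger
#' variants). Defaults emulate a paired whole-exome somatic cohort in which
#' about 95% of variants are tumor-only, a small minority normal-only, and
#' 5-10% of analyzer scores are missing.
#'
#' @param n_patients Number of patients (one tumor/normal VCF each).
#' @param n_genes Number of protein-coding genes in the simulated exome.
#' @param n_driver_genes Number of planted driver genes.
#' @param transcripts_per_gene Integer range (min, max) of transcripts per
#'   gene.
#' @param transcript_length Integer range (min, max) of transcript lengths
#'   in nucleotides.
#' @param driver_variant_rate,passenger_variant_rate Expected number of
#'   SNVs per driver / passenger gene in the cohort (Poisson means).
#' @param driver_carrier_rate,passenger_carrier_rate Expected number of
#'   carrier patients beyond the first for driver / passenger variants
#'   (each variant is carried by `1 + Poisson(rate)` patients).
#' @param tumor_only_fraction,normal_only_fraction Probabilities that a
#'   variant is tumor-only / normal-only; the remainder is common to both
#'   sample classes.
#' @param synonymous_fraction Probability a coding variant is synonymous
#'   (filtered out downstream).
#' @param stop_gained_fraction Probability a nonsynonymous variant is
#'   nonsense rather than missense.
#' @param n_noncoding_genes Number of non-protein-coding (lincRNA) genes,
#'   whose variants exercise the biotype filter.
#' @param n_background_extra Number of extra background-only gene symbols
#'   (protein-coding genes never mutated in the cohort).
#' @param analyzer_noise_sd SD of the Gaussian noise each analyzer adds to
#'   the latent deleteriousness (on the latent 0-1 scale).
#' @param missing_score_rate Per-analyzer probability that a score is
#'   missing.
#' @param driver_beta,passenger_beta Beta(shape1, shape2) parameters of the
#'   latent deleteriousness for driver / passenger variants.
#' @param duplicate_vcf_patients Number of patients that get a second,
#'   partially overlapping VCF file (exercises within-patient
#'   deduplication).
#' @param seed Integer seed governing all randomness of the generator.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 50, n_genes = 300, n_driver_genes = 3,
                          transcripts_per_gene = c(1L, 4L),
                          transcript_length = c(500L, 5000L),
                          driver_variant_rate = 12,
                          passenger_variant_rate = 1.5,
                          driver_carrier_rate = 2.5,
                          passenger_carrier_rate = 0.3,
                          tumor_only_fraction = 0.95,
                          normal_only_fraction = 0.005,
                          synonymous_fraction = 0.25,
                          stop_gained_fraction = 0.08,
                          n_noncoding_genes = 10,
                          n_background_extra = 500,
                          analyzer_noise_sd = 0.1,
                          missing_score_rate = 0.075,
                          driver_beta = c(8, 2),
                          passenger_beta = c(1.5, 6),
                          duplicate_vcf_patients = 2,
                          seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(tumor_only_fraction, normal_only_fraction, synonymous_fraction,
             stop_gained_fraction, missing_score_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (tumor_only_fraction + normal_only_fraction > 1) {
    stop("tumor_only_fraction + normal_only_fraction must be <= 1")
  }
  stopifnot(n_patients >= 1, n_genes >= 1, n_driver_genes >= 1,
            n_driver_genes <= n_genes,
            length(transcripts_per_gene) == 2,
            transcripts_per_gene[1] >= 1,
            transcripts_per_gene[1] <= transcripts_per_gene[2],
            length(transcript_length) == 2, transcript_length[1] >= 2,
            transcript_length[1] <= transcript_length[2],
            driver_variant_rate > 0, passenger_variant_rate >= 0,
            analyzer_noise_sd >= 0, n_noncoding_genes >= 0,
            n_background_extra >= 0, duplicate_vcf_patients >= 0,
            length(driver_beta) == 2, length(passenger_beta) == 2,
            all(driver_beta > 0), all(passenger_beta > 0))
  structure(cfg, class = "cohort_config")
}

#' Map a latent deleteriousness onto an analyzer's native scale
#'
#' Adds Gaussian noise to the latent value (clamped back to \[0, 1\]) and
#' maps it linearly onto the analyzer's native score range, respecting the
#' analyzer's direction (a latent of 1 maps to the most deleterious end:
#' the range maximum for higher-is-deleterious analyzers, the range minimum
#' for SIFT).
#'
#' @param latent Numeric vector in \[0, 1\].
#' @param spec An [analyzer_spec()].
#' @param noise_sd SD of the Gaussian perturbation (0 for none).
#' @return Raw scores on the analyzer's native scale, within its range.
#' @export
latent_to_analyzer <- function(latent, spec, noise_sd = 0) {
  stopifnot(all(latent >= 0 & latent <= 1))
  noisy <- latent
  if (noise_sd > 0) {
    noisy <- clamp01(noisy + stats::rnorm(length(latent), 0, noise_sd))
  }
  if (spec$direction == "lower") {
    spec$score_max - noisy * (spec$score_max - spec$score_min)
  } else {
    spec$score_min + noisy * (spec$score_max - spec$score_min)
  }
}

simulated_csq_fields <- function() {
  c("Allele", "Consequence", "SYMBOL", "Gene", "Feature", "BIOTYPE",
    "cDNA_position", "SIFT", "PolyPhen")
}

format_pred_cell <- function(raw, cutoff, lower, del_label, ben_label) {
  ifelse(is.na(raw), "",
         sprintf("%s(%.6f)",
                 ifelse(if (lower) raw <= cutoff else raw >= cutoff,
                        del_label, ben_label),
                 raw))
}

#' Simulate a self-contained somatic SNV cohort
#'
#' Writes a complete synthetic input set to `out_dir`: one annotated VCF per
#' patient (plus optional duplicate files for some patients), a cohort
#' manifest CSV, a per-variant score CSV (FATHMM-XF style), a
#' per-variant-per-transcript score TSV (CADD style), a known-gene list (the
#' planted drivers), a background gene list, and a ground-truth manifest
#' (`truth.json`). Driver genes receive many high-latent, multi-patient,
#' predominantly tumor-only variants; passenger genes sparse low-latent
#' ones. Each analyzer's raw score is the latent deleteriousness mapped to
#' its native scale and direction plus truncated Gaussian noise, dropped at
#' the configured missingness rate. The generated files round-trip through
#' [ingest_cohort()].
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param analyzers Analyzer specs used to scale the simulated scores.
#' @return (Invisibly) the ground-truth list: `config` echo, `drivers`,
#'   `genes`, `transcripts`, `variants` (with latent and per-analyzer raw
#'   scores), `carriage`, `frequencies` (expected frequency table),
#'   `change_type` (expected tumor/normal matrices), `paths` (relative to
#'   `dir`), and `dir`.
#' @export
simulate_cohort <- function(config, out_dir,
                            analyzers = default_analyzers()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE,
             showWarnings = FALSE)

  patients <- sprintf("P%03d", seq_len(config$n_patients))
  n_cod <- config$n_genes
  n_nc <- config$n_noncoding_genes

  genes <- tibble::tibble(
    gene_symbol = c(sprintf("GENE%04d", seq_len(n_cod)),
                    if (n_nc > 0) sprintf("NCRNA%03d", seq_len(n_nc))),
    biotype = rep(c("protein_coding", "lincRNA"), c(n_cod, n_nc)),
    chrom = paste0("chr", sample(1:22, n_cod + n_nc, replace = TRUE)),
    block = seq_len(n_cod + n_nc) * 100000L
  )
  genes$gene_id <- sprintf("ENSG%08d", seq_len(nrow(genes)))
  drivers <- sort(sample(genes$gene_symbol[genes$biotype == "protein_coding"],
                         config$n_driver_genes))
  genes$is_driver <- genes$gene_symbol %in% drivers

  tpg <- config$transcripts_per_gene
  genes$n_tx <- sample(seq(tpg[1], tpg[2]), nrow(genes), replace = TRUE)
  transcripts <- tibble::tibble(
    gene_symbol = rep(genes$gene_symbol, genes$n_tx),
    biotype = rep(genes$biotype, genes$n_tx)
  )
  transcripts$transcript_id <- sprintf("ENST%08d", seq_len(nrow(transcripts)))
  tl <- config$transcript_length
  transcripts$transcript_length <-
    sample(seq(tl[1], tl[2]), nrow(transcripts), replace = TRUE)

  # --- variants ---------------------------------------------------------
  lam <- ifelse(genes$is_driver, config$driver_variant_rate,
                config$passenger_variant_rate)
  nv <- stats::rpois(nrow(genes), lam)
  variants <- genes[rep(seq_len(nrow(genes)), nv),
                    c("gene_symbol", "gene_id", "biotype", "chrom", "block",
                      "is_driver")]
  variants <- variants %>%
    dplyr::group_by(.data$gene_symbol) %>%
    dplyr::mutate(pos = .data$block + sample.int(90000L, dplyr::n())) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"block")
  n <- nrow(variants)
  if (n == 0) stop("configuration produced a cohort with no variants")

  variants$ref <- sample(DNA_BASES, n, replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(DNA_BASES, r), 1), "",
                         USE.NAMES = FALSE)
  db <- config$driver_beta; pb <- config$passenger_beta
  variants$latent <- ifelse(variants$is_driver,
                            stats::rbeta(n, db[1], db[2]),
                            stats::rbeta(n, pb[1], pb[2]))

  cons <- rep("missense_variant", n)
  u_syn <- stats::runif(n); u_stop <- stats::runif(n); u_spl <- stats::runif(n)
  cons[u_stop < config$stop_gained_fraction] <- "stop_gained"
  cons[cons == "missense_variant" & u_spl < 0.05] <-
    "missense_variant&splice_region_variant"
  cons[u_syn < config$synonymous_fraction] <- "synonymous_variant"
  cons[variants$biotype != "protein_coding"] <-
    "non_coding_transcript_exon_variant"
  variants$consequence <- cons

  rest <- 1 - config$tumor_only_fraction - config$normal_only_fraction
  variants$category <- sample(c("tumor_only", "normal_only", "common"), n,
                              replace = TRUE,
                              prob = c(config$tumor_only_fraction,
                                       config$normal_only_fraction, rest))
  clam <- ifelse(variants$is_driver, config$driver_carrier_rate,
                 config$passenger_carrier_rate)
  variants$n_carriers <- pmin(1L + stats::rpois(n, clam), config$n_patients)
  variants$vix <- seq_len(n)

  carriers <- lapply(variants$n_carriers, function(k) sample(patients, k))
  carriage <- tibble::tibble(
    vix = rep(variants$vix, variants$n_carriers),
    patient_id = unlist(carriers)
  ) %>%
    dplyr::left_join(
      variants[, c("vix", "chrom", "pos", "ref", "alt", "category")],
      by = "vix") %>%
    dplyr::mutate(in_tumor = .data$category != "normal_only",
                  in_normal = .data$category != "tumor_only") %>%
    dplyr::select("chrom", "pos", "ref", "alt", "patient_id",
                  "in_tumor", "in_normal", "vix")

  # --- analyzer scores --------------------------------------------------
  miss <- config$missing_score_rate
  nsd <- config$analyzer_noise_sd
  fa <- round(latent_to_analyzer(variants$latent, analyzers[["FATHMM-XF"]],
                                 nsd), 6)
  fa[stats::runif(n) < miss] <- NA
  variants$fathmm_raw <- fa

  vt <- variants[, c("vix", "gene_symbol", "gene_id", "alt", "consequence",
                     "biotype", "pos", "latent")] %>%
    dplyr::inner_join(transcripts[, c("gene_symbol", "transcript_id",
                                      "transcript_length")],
                      by = "gene_symbol", relationship = "many-to-many")
  m <- nrow(vt)
  vt$cadd_raw <- round(latent_to_analyzer(vt$latent, analyzers[["CADD"]],
                                          nsd), 3)
  vt$cadd_raw[stats::runif(m) < miss] <- NA
  vt$sift_raw <- round(latent_to_analyzer(vt$latent, analyzers[["SIFT"]],
                                          nsd), 6)
  vt$sift_raw[stats::runif(m) < miss] <- NA
  vt$polyphen_raw <- round(latent_to_analyzer(vt$latent,
                                              analyzers[["PolyPhen"]], nsd), 6)
  vt$polyphen_raw[stats::runif(m) < miss] <- NA

  # --- CSQ strings ------------------------------------------------------
  vt$cdna_pos <- 1L + vt$pos %% (vt$transcript_length - 1L)
  vt$csq_entry <- sprintf(
    "%s|%s|%s|%s|%s|%s|%d/%d|%s|%s",
    vt$alt, vt$consequence, vt$gene_symbol, vt$gene_id, vt$transcript_id,
    vt$biotype, vt$cdna_pos, vt$transcript_length,
    format_pred_cell(vt$sift_raw, 0.05, TRUE, "deleterious", "tolerated"),
    format_pred_cell(vt$polyphen_raw, 0.447, FALSE, "probably_damaging",
                     "benign"))
  csq_by_variant <- vt %>%
    dplyr::group_by(.data$vix) %>%
    dplyr::summarise(csq = paste(.data$csq_entry, collapse = ","),
                     .groups = "drop")
  variants <- dplyr::left_join(variants, csq_by_variant, by = "vix")

  # --- VCF files --------------------------------------------------------
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snvburden_simulator",
    sprintf(paste0(
      "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
      "annotations from Ensembl VEP. Format: %s\">"),
      paste(simulated_csq_fields(), collapse = "|")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "NORMAL", "TUMOR"), collapse = "\t"))

  patient_rows <- carriage %>%
    dplyr::left_join(variants[, c("vix", "csq")], by = "vix") %>%
    dplyr::arrange(.data$patient_id, .data$chrom, .data$pos)
  patient_rows$line <- paste(
    patient_rows$chrom, patient_rows$pos, ".", patient_rows$ref,
    patient_rows$alt, ".", "PASS", paste0("CSQ=", patient_rows$csq), "GT",
    ifelse(patient_rows$in_normal, "0/1", "0/0"),
    ifelse(patient_rows$in_tumor, "0/1", "0/0"),
    sep = "\t")

  manifest <- tibble::tibble(patient_id = patients,
                             vcf_path = file.path("vcf",
                                                  paste0(patients, ".vcf")))
  for (p in patients) {
    lines <- patient_rows$line[patient_rows$patient_id == p]
    writeLines(c(header, lines), file.path(out_dir, "vcf",
                                           paste0(p, ".vcf")))
  }

  # Duplicate files: first k patients with >= 2 variants get a second file
  # holding roughly half of their variants (must not change any count).
  if (config$duplicate_vcf_patients > 0) {
    counts <- table(patient_rows$patient_id)
    eligible <- patients[patients %in% names(counts)[counts >= 2]]
    dups <- utils::head(eligible, config$duplicate_vcf_patients)
    for (p in dups) {
      lines <- patient_rows$line[patient_rows$patient_id == p]
      half <- lines[seq_len(ceiling(length(lines) / 2))]
      fn <- file.path("vcf", paste0(p, "_b.vcf"))
      writeLines(c(header, half), file.path(out_dir, fn))
      manifest <- dplyr::bind_rows(manifest,
                                   tibble::tibble(patient_id = p,
                                                  vcf_path = fn))
    }
  }
  manifest <- dplyr::arrange(manifest, .data$patient_id, .data$vcf_path)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  # --- external score files (chrom written without the "chr" prefix, as
  # web-service exports typically do; exercises join-time normalization) --
  fathmm_tbl <- variants %>%
    dplyr::filter(!is.na(.data$fathmm_raw)) %>%
    dplyr::transmute(chrom = strip_chr(.data$chrom), pos = .data$pos,
                     ref = .data$ref, alt = .data$alt,
                     score = .data$fathmm_raw)
  readr::write_csv(fathmm_tbl, file.path(out_dir, "fathmm.csv"))

  cadd_tbl <- vt %>%
    dplyr::left_join(variants[, c("vix", "chrom", "pos", "ref", "alt")],
                     by = "vix", suffix = c("", ".v")) %>%
    dplyr::filter(!is.na(.data$cadd_raw)) %>%
    dplyr::transmute(chrom = strip_chr(.data$chrom), pos = .data$pos.v,
                     ref = .data$ref, alt = .data$alt,
                     transcript_id = .data$transcript_id,
                     phred = .data$cadd_raw)
  readr::write_tsv(cadd_tbl, file.path(out_dir, "cadd.tsv"))

  readr::write_csv(tibble::tibble(gene = drivers),
                   file.path(out_dir, "known_genes.csv"))
  background <- c(genes$gene_symbol[genes$biotype == "protein_coding"],
                  if (config$n_background_extra > 0)
                    sprintf("BKG%04d", seq_len(config$n_background_extra)))
  writeLines(background, file.path(out_dir, "background_genes.txt"))

  # --- expected (ground-truth) frequency table and change matrices ------
  expected_freq <- variants %>%
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos, ref = .data$ref,
      alt = .data$alt,
      tumor_count = as.integer(ifelse(.data$category == "normal_only", 0L,
                                      .data$n_carriers)),
      normal_count = as.integer(ifelse(.data$category == "tumor_only", 0L,
                                       .data$n_carriers)),
      category = .data$category) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)

  tally <- function(sub) {
    t0 <- table(factor(sub$ref, levels = DNA_BASES),
                factor(sub$alt, levels = DNA_BASES))
    matrix(as.integer(t0), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  }
  expected_change <- list(
    tumor = tally(expected_freq[expected_freq$tumor_count > 0, ]),
    normal = tally(expected_freq[expected_freq$normal_count > 0, ]))

  truth <- list(
    config = unclass(config),
    drivers = drivers,
    genes = genes,
    transcripts = transcripts,
    variants = variants %>% dplyr::select(-"csq"),
    variant_transcripts = vt %>% dplyr::select(-"csq_entry"),
    carriage = carriage,
    frequencies = expected_freq,
    change_type = expected_change,
    paths = list(manifest = "manifest.csv", fathmm = "fathmm.csv",
                 cadd = "cadd.tsv", known_genes = "known_genes.csv",
                 background = "background_genes.txt", truth = "truth.json")
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  truth$dir <- out_dir
  invisible(truth)
}
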