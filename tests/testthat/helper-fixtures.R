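# Shared fixtures: hand-built VCFs and micro-cohorts constructed in code.

TEST_CSQ_FORMAT <-
  "Allele|Consequence|SYMBOL|Gene|Feature|BIOTYPE|cDNA_position|SIFT|PolyPhen"

write_test_vcf <- function(path, body = character(),
                           samples = c("NORMAL", "TUMOR"),
                           csq_format = TEST_CSQ_FORMAT,
                           with_csq_meta = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (with_csq_meta) {
      sprintf(paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=",
                     "\"Consequence annotations from Ensembl VEP. ",
                     "Format: %s\">"), csq_format)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, csq, ngt = "0/0", tgt = "0/1") {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", paste0("CSQ=", csq),
        "GT", ngt, tgt, sep = "\t")
}

csq_entry <- function(allele, consequence = "missense_variant",
                      symbol = "GENEA", gene = "ENSG1", feature = "TX1",
                      biotype = "protein_coding", cdna = "100/1000",
                      sift = "", polyphen = "") {
  paste(allele, consequence, symbol, gene, feature, biotype, cdna,
        sift, polyphen, sep = "|")
}

# Minimal integrated-score table for direct gene-scoring tests. `rows` is a
# tibble with gene_symbol, transcript_id, transcript_length, chrom, pos,
# ref, alt, ave_score, is_deleterious_any (plus optional analyzer columns).
micro_integrated <- function(rows) {
  defaults <- tibble::tibble(
    chrom = "1", pos = seq_len(nrow(rows)), ref = "A", alt = "C")
  for (nm in names(defaults)) {
    if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
  }
  rows
}

micro_freq <- function(integrated, tumor, normal) {
  u <- !duplicated(paste(integrated$chrom, integrated$pos, integrated$ref,
                         integrated$alt))
  tibble::tibble(
    chrom = integrated$chrom[u], pos = integrated$pos[u],
    ref = integrated$ref[u], alt = integrated$alt[u],
    tumor_count = tumor, normal_count = normal,
    category = dplyr::case_when(normal == 0 ~ "tumor_only",
                                tumor == 0 ~ "normal_only",
                                TRUE ~ "common"))
}

# ---------------------------------------------------------------------------
# Independent oracle: brute-force triple loop over (gene, transcript,
# variant) with analyzer normalization written out by hand. Deliberately
# avoids every package function.

oracle_normalize <- function(raw, analyzer) {
  switch(analyzer,
    fathmm = list(norm = min(1, max(0, (raw - 0.5) / (1 - 0.5))),
                  flag = raw >= 0.5),
    cadd = list(norm = min(1, max(0, (raw - 10) / (99 - 10))),
                flag = raw >= 10),
    sift = list(norm = min(1, max(0, ((1 - raw) - 0.95) / (1 - 0.95))),
                flag = raw <= 0.05),
    polyphen = list(norm = min(1, max(0, (raw - 0.447) / (1 - 0.447))),
                    flag = raw >= 0.447))
}

# case: list with
#   transcripts: data.frame(gene, transcript_id, length)
#   variants: data.frame(vid, gene, tumor, normal, fathmm, cadd, sift,
#             polyphen)  (per-variant raw scores, NA = missing; every
#             variant annotates every transcript of its gene)
# mode: "integrative" or one of "fathmm", "cadd", "sift", "polyphen"
oracle_gene_scores <- function(case, mode) {
  tx <- case$transcripts
  va <- case$variants
  analyzers <- c("fathmm", "cadd", "sift", "polyphen")
  scores <- stats::setNames(numeric(0), character(0))
  for (g in unique(tx$gene)) {
    gtx <- tx[tx$gene == g, , drop = FALSE]
    gva <- va[va$gene == g, , drop = FALSE]
    total <- 0
    pathogenic <- FALSE
    for (j in seq_len(nrow(gtx))) {
      inner <- 0
      for (v in seq_len(nrow(gva))) {
        norms <- c(); flags <- c()
        for (a in analyzers) {
          raw <- gva[[a]][v]
          if (!is.na(raw)) {
            o <- oracle_normalize(raw, a)
            norms[a] <- o$norm
            flags[a] <- o$flag
          }
        }
        if (mode == "integrative") {
          use <- length(flags) > 0 && any(flags)
          sc <- if (length(norms) > 0) mean(norms) else NA
        } else {
          use <- !is.na(gva[[mode]][v]) && oracle_normalize(gva[[mode]][v],
                                                            mode)$flag
          sc <- if (!is.na(gva[[mode]][v]))
            oracle_normalize(gva[[mode]][v], mode)$norm else NA
        }
        if (use) {
          inner <- inner + sc * (gva$tumor[v] - gva$normal[v])
          pathogenic <- TRUE
        }
      }
      total <- total + inner / log(gtx$length[j])
    }
    if (pathogenic) scores[g] <- total / nrow(gtx)
  }
  scores
}

# Random micro-cohort on which both the package pipeline and the oracle run.
random_micro_case <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:5, 1)
  genes <- paste0("G", seq_len(n_genes))
  tx <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- sample(1:3, 1)
    data.frame(gene = genes[i],
               transcript_id = paste0("T", i, "_", seq_len(k)),
               length = sample(50:5000, k))
  }))
  n_var <- sample(5:20, 1)
  va <- data.frame(
    vid = seq_len(n_var),
    gene = sample(genes, n_var, replace = TRUE),
    tumor = sample(0:5, n_var, replace = TRUE),
    normal = sample(0:2, n_var, replace = TRUE),
    fathmm = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var), 4)),
    cadd = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var, 0, 99), 3)),
    sift = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var), 4)),
    polyphen = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var), 4)))
  va <- va[va$tumor + va$normal > 0, , drop = FALSE]
  case <- list(transcripts = tx, variants = va)

  # package-side inputs: consequence records + external score tables
  va$chrom <- "chr1"; va$pos <- 1000L + va$vid
  va$ref <- "G"; va$alt <- "T"
  recs <- merge(va, tx, by = "gene")
  records <- tibble::tibble(
    chrom = recs$chrom, pos = recs$pos, ref = recs$ref, alt = recs$alt,
    gene_symbol = recs$gene, transcript_id = recs$transcript_id,
    consequence = "missense_variant", biotype = "protein_coding",
    transcript_length = recs$length,
    sift_raw = recs$sift, polyphen_raw = recs$polyphen)
  fathmm <- tibble::tibble(chrom = "1", pos = va$pos, ref = va$ref,
                           alt = va$alt, score = va$fathmm)
  fathmm <- fathmm[!is.na(fathmm$score), ]
  cadd <- tibble::tibble(chrom = "1", pos = recs$pos, ref = recs$ref,
                         alt = recs$alt, transcript_id = recs$transcript_id,
                         score = recs$cadd)
  cadd <- cadd[!is.na(cadd$score), ]
  freq <- tibble::tibble(
    chrom = va$chrom, pos = va$pos, ref = va$ref, alt = va$alt,
    tumor_count = va$tumor, normal_count = va$normal,
    category = dplyr::case_when(va$normal == 0 ~ "tumor_only",
                                va$tumor == 0 ~ "normal_only",
                                TRUE ~ "common"))
  case$records <- records
  case$external <- list("FATHMM-XF" = fathmm, "CADD" = cadd)
  case$frequencies <- freq
  case
}

# Map package mode names to oracle mode keys.
MODE_PAIRS <- list(integrative = "integrative", "FATHMM-XF" = "fathmm",
                   CADD = "cadd", SIFT = "sift", PolyPhen = "polyphen")

# SAR of a gene list where an empty ranking counts as worst case (used when
# comparing analyzers, some of which may flag no gene at all).
sar_or_worst <- function(genes, ranked) {
  if (nrow(ranked) == 0) 1 else sar(genes, ranked)
}
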