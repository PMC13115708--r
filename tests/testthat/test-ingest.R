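test_that("one consequence record per CSQ transcript entry, keyed to one SNV", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "p1.vcf"), vcf_line(
    "chr1", 1000, "A", "G",
    paste(csq_entry("G", feature = "TX1", cdna = "10/900"),
          csq_entry("G", feature = "TX2", cdna = "10/1200"),
          sep = ",")))
  out <- parse_vcf(f, "P1")
  expect_equal(nrow(out$records), 2)
  expect_equal(unique(out$records$pos), 1000L)
  expect_equal(out$records$transcript_id, c("TX1", "TX2"))
  expect_equal(out$records$transcript_length, c(900L, 1200L))
  expect_equal(nrow(out$carriage), 1)
  expect_true(out$carriage$in_tumor)
  expect_false(out$carriage$in_normal)
})

test_that("non-SNV alleles are skipped and counted", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "p1.vcf"), c(
    vcf_line("chr1", 1000, "AT", "A", csq_entry("-")),   # 2-bp deletion
    vcf_line("chr1", 2000, "C", "T", csq_entry("T"))))
  out <- parse_vcf(f, "P1")
  expect_equal(out$skipped[["non_snv"]], 1L)
  expect_equal(nrow(out$carriage), 1)
  expect_equal(out$carriage$pos, 2000L)
})

test_that("a VCF without a CSQ definition is a hard error naming the file", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "nocsq.vcf"),
                      vcf_line("chr1", 1000, "A", "G", csq_entry("G")),
                      with_csq_meta = FALSE)
  expect_error(parse_vcf(f, "P1"), "nocsq.vcf")
})

test_that("multi-allelic lines split per alt allele with allele-matched CSQ", {
  dir <- withr::local_tempdir()
  body <- paste("chr2", 500, ".", "A", "C,T", ".", "PASS",
                paste0("CSQ=", csq_entry("C", symbol = "GENEC"), ",",
                       csq_entry("T", symbol = "GENET")),
                "GT", "0/0", "1/2", sep = "\t")
  f <- write_test_vcf(file.path(dir, "p1.vcf"), body)
  out <- parse_vcf(f, "P1")
  expect_equal(nrow(out$carriage), 2)
  expect_setequal(out$carriage$alt, c("C", "T"))
  expect_true(all(out$carriage$in_tumor))
  expect_equal(out$records$gene_symbol[out$records$alt == "C"], "GENEC")
  expect_equal(out$records$gene_symbol[out$records$alt == "T"], "GENET")
})

test_that("unknown genotypes count as not carrying the variant", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "p1.vcf"),
                      vcf_line("chr1", 100, "G", "A", csq_entry("A"),
                               ngt = "./.", tgt = "0/1"))
  out <- parse_vcf(f, "P1")
  expect_true(out$carriage$in_tumor)
  expect_false(out$carriage$in_normal)
})

test_that("embedded prediction cells parse labels with parentheses and bare numbers", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "p1.vcf"), c(
    vcf_line("chr1", 100, "G", "A",
             csq_entry("A", sift = "tolerated(0.32)",
                       polyphen = "probably_damaging(0.981)")),
    vcf_line("chr1", 200, "G", "A", csq_entry("A", sift = "0.01")),
    vcf_line("chr1", 300, "G", "A", csq_entry("A"))))
  out <- parse_vcf(f, "P1")
  expect_equal(out$records$sift_raw, c(0.32, 0.01, NA))
  expect_equal(out$records$polyphen_raw, c(0.981, NA, NA))
})

test_that("patient frequencies deduplicate within patients, count across patients", {
  dir <- withr::local_tempdir()
  v <- function(...) vcf_line("chr3", 700, "C", "A", csq_entry("A"), ...)
  # P1 carries the SNV (tumor) in two separate files; P2 in one; P3 in
  # normal and tumor
  write_test_vcf(file.path(dir, "p1a.vcf"), v())
  write_test_vcf(file.path(dir, "p1b.vcf"), v())
  write_test_vcf(file.path(dir, "p2.vcf"), v())
  write_test_vcf(file.path(dir, "p3.vcf"), v(ngt = "0/1", tgt = "0/1"))
  manifest <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    vcf_path = file.path(dir, c("p1a.vcf", "p1b.vcf", "p2.vcf", "p3.vcf")))
  cohort <- ingest_cohort(manifest)
  expect_equal(nrow(cohort$frequencies), 1)
  expect_equal(cohort$frequencies$tumor_count, 3L)   # P1 once, P2, P3
  expect_equal(cohort$frequencies$normal_count, 1L)  # P3 only
  expect_equal(cohort$frequencies$category, "common")
  # re-ingesting is deterministic
  again <- ingest_cohort(manifest)
  expect_identical(cohort$frequencies, again$frequencies)
  expect_identical(cohort$records, again$records)
})

test_that("frequency categories partition the unique SNVs and respect patient bounds", {
  dir <- withr::local_tempdir()
  truth <- simulate_cohort(
    cohort_config(n_patients = 8, n_genes = 25, n_driver_genes = 2,
                  n_background_extra = 10, seed = 11), dir)
  cohort <- ingest_cohort(file.path(dir, "manifest.csv"))
  freq <- cohort$frequencies
  expect_equal(sum(table(freq$category)), nrow(freq))
  expect_true(all(freq$tumor_count <= cohort$n_patients))
  expect_true(all(freq$normal_count <= cohort$n_patients))
  expect_true(all(freq$tumor_count + freq$normal_count >= 1))
  expect_true(all((freq$category == "tumor_only") ==
                    (freq$normal_count == 0 & freq$tumor_count > 0)))
})

test_that("nonsynonymous/protein-coding filter drops the right records and is idempotent", {
  records <- tibble::tibble(
    chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
    gene_symbol = "GENEA", transcript_id = paste0("TX", 1:5),
    consequence = c("missense_variant", "synonymous_variant", "stop_gained",
                    "missense_variant&splice_region_variant", ""),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA", "protein_coding"),
    transcript_length = 1000L, sift_raw = NA_real_, polyphen_raw = NA_real_)
  out <- filter_nonsynonymous(records)
  expect_equal(out$pos, c(1L, 3L))
  expect_equal(attr(out, "n_empty_consequence"), 1L)
  # missense on a non-coding biotype is dropped; compound terms are split
  records$biotype[4] <- "protein_coding"
  out2 <- filter_nonsynonymous(records)
  expect_equal(out2$pos, c(1L, 3L, 4L))
  expect_equal(filter_nonsynonymous(out2)$pos, out2$pos)
})

test_that("cohort summary tallies substitution types by sample class", {
  freq <- tibble::tibble(
    chrom = "chr1", pos = 1:5, ref = c("C", "C", "C", "T", "A"),
    alt = c("A", "A", "A", "G", "G"),
    tumor_count = c(3L, 1L, 2L, 0L, 1L),
    normal_count = c(0L, 0L, 0L, 1L, 1L),
    category = c("tumor_only", "tumor_only", "tumor_only", "normal_only",
                 "common"))
  m_t <- change_type_matrix(freq, "tumor")
  m_n <- change_type_matrix(freq, "normal")
  expect_equal(m_t["C", "A"], 3L)  # three unique C>A SNVs seen in tumor
  expect_equal(m_t["T", "G"], 0L)
  expect_equal(m_n["T", "G"], 1L)
  expect_equal(m_n["A", "G"], 1L)
  expect_equal(sum(m_t), 4L)
  expect_equal(unname(rowSums(m_t)), c(1L, 3L, 0L, 0L))  # A,C,G,T ref rows
  expect_true(all(diag(m_t) == 0L))
})

test_that("an all-header VCF yields an empty cohort, not an error", {
  dir <- withr::local_tempdir()
  f <- write_test_vcf(file.path(dir, "empty.vcf"))
  out <- parse_vcf(f, "P1")
  expect_equal(nrow(out$records), 0)
  expect_equal(nrow(out$carriage), 0)
  freq <- build_frequency_table(out$carriage)
  expect_equal(nrow(freq), 0)
})
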