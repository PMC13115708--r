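test_that("transcript and gene scores follow the length-penalized weighted sum", {
  # one deleterious variant, score 1, tumor 3 / normal 0, transcript length
  # 100 -> 3 / ln(100)
  rows <- micro_integrated(tibble::tibble(
    gene_symbol = "GENEA", transcript_id = "TX1", transcript_length = 100L,
    ave_score = 1.0, is_deleterious_any = TRUE))
  freq <- micro_freq(rows, tumor = 3L, normal = 0L)
  out <- score_genes(rows, freq)
  expect_equal(out$score, 3 / log(100), tolerance = 1e-12)
  expect_equal(out$rank, 1L)
  expect_equal(out$n_variants, 1L)

  # tumor == normal contributes nothing -> gene not scored at 0? it is
  # pathogenic (flagged) with score 0
  freq0 <- micro_freq(rows, tumor = 2L, normal = 2L)
  expect_equal(score_genes(rows, freq0)$score, 0)

  # two variants (0.5, diff 2) and (1.0, diff 1) on one length-7 transcript
  rows2 <- micro_integrated(tibble::tibble(
    gene_symbol = "GENEB", transcript_id = "TXB", transcript_length = 7L,
    ave_score = c(0.5, 1.0), is_deleterious_any = TRUE,
    pos = c(1L, 2L)))
  freq2 <- micro_freq(rows2, tumor = c(2L, 1L), normal = c(0L, 0L))
  expect_equal(score_genes(rows2, freq2)$score,
               (0.5 * 2 + 1.0 * 1) / log(7), tolerance = 1e-12)
})

test_that("gene score averages over all observed transcripts, empty ones included", {
  rows <- micro_integrated(tibble::tibble(
    gene_symbol = "GENEA",
    transcript_id = c("TX1", "TX2"), transcript_length = c(100L, 100L),
    ave_score = c(1.0, NA), is_deleterious_any = c(TRUE, FALSE),
    pos = c(1L, 2L)))
  freq <- micro_freq(rows, tumor = c(3L, 1L), normal = c(0L, 0L))
  out <- score_genes(rows, freq)
  # second transcript carries no deleterious variant: contributes 0, counts
  # in N_G = 2
  expect_equal(out$score, (3 / log(100)) / 2, tolerance = 1e-12)
  expect_equal(out$n_transcripts, 2L)
})

test_that("gene scores match the brute-force triple loop in every mode", {
  for (seed in c(101, 202, 303, 404)) {
    case <- random_micro_case(seed)
    integrated <- integrate_scores(case$records, case$external)
    for (mode in names(MODE_PAIRS)) {
      expected <- oracle_gene_scores(case, MODE_PAIRS[[mode]])
      got <- score_genes(integrated, case$frequencies, mode = mode)
      expect_setequal(got$gene_symbol, names(expected))
      expect_equal(got$score,
                   unname(expected[got$gene_symbol]),
                   tolerance = 1e-12,
                   label = paste0("seed ", seed, ", mode ", mode))
    }
  }
})

test_that("competition ranking shares the minimal rank across ties", {
  scored <- tibble::tibble(gene_symbol = c("A", "B", "C", "D"),
                           score = c(5, 3, 3, 1))
  out <- rank_genes(scored)
  expect_equal(out$rank, c(1L, 2L, 2L, 4L))
  expect_equal(out$gene_symbol, c("A", "B", "C", "D"))
  one <- rank_genes(tibble::tibble(gene_symbol = "X", score = 0.2))
  expect_equal(one$rank, 1L)
})

test_that("top-fraction selection uses the ceiling and includes boundary ties", {
  ranked <- rank_genes(tibble::tibble(
    gene_symbol = sprintf("G%03d", 1:200), score = 200:1))
  expect_length(top_fraction_genes(ranked, 0.01), 2)
  ranked149 <- rank_genes(tibble::tibble(
    gene_symbol = sprintf("G%03d", 1:149), score = 149:1))
  expect_length(top_fraction_genes(ranked149, 1.0), 149)
  # a tie spanning the cutoff is included wholesale
  tied <- rank_genes(tibble::tibble(
    gene_symbol = sprintf("G%03d", 1:100),
    score = c(100, rep(96, 3), seq(90, by = -1, length.out = 96))))
  expect_equal(top_fraction_genes(tied, 0.01), "G001")
  expect_length(top_fraction_genes(tied, 0.02), 4)  # ceil(2) + tie block
  expect_error(top_fraction_genes(tied, 0), "fraction")
  expect_error(top_fraction_genes(tied, 1.5), "fraction")
})

test_that("scores are linear in the tumor-normal frequency difference", {
  case <- random_micro_case(777)
  integrated <- integrate_scores(case$records, case$external)
  f1 <- case$frequencies
  f2 <- f1
  f2$tumor_count <- f1$tumor_count * 2L
  f2$normal_count <- f1$normal_count * 2L
  s1 <- score_genes(integrated, f1)
  s2 <- score_genes(integrated, f2)
  s2 <- s2[match(s1$gene_symbol, s2$gene_symbol), ]
  expect_equal(s2$score, 2 * s1$score, tolerance = 1e-12)
})

test_that("adding a deleterious tumor-only variant never hurts its gene nor others", {
  rows <- micro_integrated(tibble::tibble(
    gene_symbol = c("GENEA", "GENEB"),
    transcript_id = c("TXA", "TXB"), transcript_length = 1000L,
    ave_score = 0.5, is_deleterious_any = TRUE, pos = c(1L, 2L)))
  freq <- micro_freq(rows, tumor = c(2L, 2L), normal = c(0L, 0L))
  before <- score_genes(rows, freq)
  extra <- micro_integrated(tibble::tibble(
    gene_symbol = "GENEA", transcript_id = "TXA", transcript_length = 1000L,
    ave_score = 0.9, is_deleterious_any = TRUE, pos = 3L))
  rows2 <- dplyr::bind_rows(rows, extra)
  freq2 <- dplyr::bind_rows(freq, micro_freq(extra, 4L, 0L))
  after <- score_genes(rows2, freq2)
  a <- function(d, g) d$score[d$gene_symbol == g]
  expect_gte(a(after, "GENEA"), a(before, "GENEA"))
  expect_equal(a(after, "GENEB"), a(before, "GENEB"))
})

test_that("integrative equals single-analyzer scoring when only one analyzer is configured", {
  case <- random_micro_case(555)
  only_fathmm <- default_analyzers()["FATHMM-XF"]
  integrated <- integrate_scores(case$records,
                                 case$external["FATHMM-XF"],
                                 analyzers = only_fathmm)
  iq <- score_genes(integrated, case$frequencies, mode = "integrative")
  q <- score_genes(integrated, case$frequencies, mode = "FATHMM-XF")
  expect_equal(iq$gene_symbol, q$gene_symbol)
  expect_equal(iq$score, q$score, tolerance = 1e-12)
})

test_that("degenerate transcript lengths are rejected", {
  rows <- micro_integrated(tibble::tibble(
    gene_symbol = "GENEA", transcript_id = "TX1", transcript_length = 1L,
    ave_score = 1, is_deleterious_any = TRUE))
  freq <- micro_freq(rows, 1L, 0L)
  expect_error(score_genes(rows, freq), "transcript length")
})
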