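small_scenario <- function(...) {
  screen_scenario(n_transcripts = 30L, n_suppressors = 3L,
                  length_range = c(800L, 1500L),
                  library_cells = 20000L, reads_per_sample = 20000L,
                  rng_seed = 7L, ...)
}

test_that("transcriptome generation is seed-reproducible with planted folds", {
  sc <- small_scenario()
  tx1 <- generate_transcriptome(sc)
  tx2 <- generate_transcriptome(sc)
  expect_identical(tx1, tx2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(tx1$transcripts, f1)
  write_fasta(tx2$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))  # identical bytes

  cfg <- lego_config()
  sup <- tx1$expression[tx1$expression$planted_suppressor, ]
  expect_equal(nrow(sup), 3L)
  expect_true(all(sup$repression_fold_g1 > cfg$expr_fold_threshold))
  expect_true(all(sup$repression_fold_g2 > cfg$expr_fold_threshold))
  expect_true(all(sup$induction_fold_anchor_loss > cfg$expr_fold_threshold))
})

test_that("AluI site density matches the binomial expectation", {
  sc <- screen_scenario(n_transcripts = 60L, length_range = c(2000L, 2000L),
                        n_suppressors = 1L, rng_seed = 13L)
  tx <- generate_transcriptome(sc)
  sites <- count_alui_sites(tx$transcripts$seq)
  # AGCT at any of L-3 positions with probability (1/4)^4 for uniform bases
  n_pos <- (2000 - 3) * 60
  p <- (1 / 4)^4
  expected <- n_pos * p
  sd2 <- 2 * sqrt(n_pos * p * (1 - p))
  expect_lt(abs(sum(sites) - expected), sd2)
})

test_that("selection with no growth boost leaves compositions equal in expectation", {
  sc <- small_scenario(growth_boost = 1)
  tx <- generate_transcriptome(sc)
  cfg <- lego_config()
  lib <- library_composition(tx$transcripts, tx$expression$expr_tester,
                             tx$expression$expr_driver_g1, config = cfg)
  sel <- simulate_selection(list(lib1 = lib, lib2 = lib), tx$truth, sc, cfg)
  cc <- sel$counts[sel$counts$library == "lib1", ]
  pre <- cc$count[cc$sample == "pre"]
  post <- cc$count[cc$sample == "post2"]
  # null screen: paired multinomial draws from the same weights
  expect_lt(abs(mean(post - pre)), 1e-9)         # same totals
  expect_gt(cor(pre, post), 0.95)
  # and with all efficacies forced to zero no vector is truly transforming
  sc0 <- small_scenario(nonfunctional_fraction = 1)
  sel0 <- simulate_selection(list(lib1 = lib, lib2 = lib), tx$truth, sc0, cfg)
  expect_false(any(sel0$vector_truth$transforming))
})

test_that("planted suppressors accrue >=3 enriched vectors in both libraries", {
  sc <- screen_scenario()  # the default screen conditions
  tx <- generate_transcriptome(sc)
  cfg <- lego_config()
  libs <- list(
    lib1 = library_composition(tx$transcripts, tx$expression$expr_tester,
                               tx$expression$expr_driver_g1, config = cfg),
    lib2 = library_composition(tx$transcripts, tx$expression$expr_tester,
                               tx$expression$expr_driver_g2, config = cfg))
  ok <- replicate(20, {
    sel <- simulate_selection(libs, tx$truth, sc, cfg)
    counts <- sel$counts
    counts$cpm <- NA
    tab <- data.frame(library = counts$library, sample = counts$sample,
                      tag = counts$guide, count = counts$count,
                      stringsAsFactors = FALSE)
    tab <- aggregate(count ~ library + sample + tag, tab, sum)
    calls <- call_transforming(normalize_counts(tab), cfg)
    tr <- calls[calls$is_transforming, ]
    guide_tx <- libs$lib1$catalog[libs$lib1$catalog$realizable,
                                  c("guide", "transcript_id")]
    all(vapply(tx$truth, function(s) {
      g <- guide_tx$guide[guide_tx$transcript_id == s]
      all(vapply(c("lib1", "lib2"), function(l) {
        sum(unique(tr$tag[tr$library == l]) %in% g) >= 3L
      }, logical(1)))
    }, logical(1)))
  })
  expect_gte(mean(ok), 0.95)
})

test_that("emitted reads have the hairpin layout and the configured error rate", {
  sc <- small_scenario(sequencing_error_rate = 0)
  cfg <- lego_config()
  counts <- data.frame(guide = c("CTGACGTAGCATCAGGAACT",
                                 "CTTTACCGGTAAGTCCATGA"),
                       count = c(60L, 40L), stringsAsFactors = FALSE)
  reads <- emit_reads(counts, sc, cfg)
  expect_equal(nrow(reads), sc$reads_per_sample)
  ext <- extract_tags(reads, cfg)
  expect_equal(ext$n_discarded, 0L)  # every error-free read has an exact tag
  expect_setequal(ext$counts$tag, counts$guide)

  # empirical per-base error rate within 3 sigma of the configured rate
  rate <- 0.01
  sc_err <- small_scenario(sequencing_error_rate = rate)
  reads_err <- emit_reads(counts, sc_err, cfg)
  stopifnot(identical(nchar(reads_err$seq[1]), nchar(reads$seq[1])))
  templates <- setNames(
    vapply(counts$guide, perfect_read, character(1), config = cfg),
    NULL)
  # compare each read to the nearer template (guides differ at >2 positions)
  mm <- pmin(
    vapply(seq_len(nrow(reads_err)), function(i)
      sum(strsplit(reads_err$seq[i], "")[[1]] !=
            strsplit(templates[1], "")[[1]]), numeric(1)),
    vapply(seq_len(nrow(reads_err)), function(i)
      sum(strsplit(reads_err$seq[i], "")[[1]] !=
            strsplit(templates[2], "")[[1]]), numeric(1)))
  n_bases <- sum(nchar(reads_err$seq))
  observed <- sum(mm) / n_bases
  sd3 <- 3 * sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(observed - rate), sd3)
})

test_that("generated FASTQ round-trips through the readers", {
  sc <- small_scenario(sequencing_error_rate = 0)
  cfg <- lego_config()
  counts <- data.frame(guide = "CTGACGTAGCATCAGGAACT", count = 10L)
  f <- tempfile(fileext = ".fastq")
  emit_reads(counts, sc, cfg, path = f)
  back <- read_fastq(f)
  expect_equal(nrow(back), sc$reads_per_sample)
  expect_true(all(grepl(cfg$loop_seq, back$seq, fixed = TRUE)))
})
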