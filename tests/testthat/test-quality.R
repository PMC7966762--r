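test_that("quality classification applies strict HIGH and non-strict MEDIUM bounds", {
  expect_equal(classify_quality(95.28, 1.11), "HIGH")
  expect_equal(classify_quality(84.28, 0.66), "MEDIUM")
  expect_equal(classify_quality(90.00, 1.00), "MEDIUM")  # must exceed 90
  expect_equal(classify_quality(95.00, 5.00), "MEDIUM")  # must be under 5
  expect_equal(classify_quality(50.00, 9.99), "MEDIUM")
  expect_equal(classify_quality(49.99, 0.00), "LOW")
  expect_equal(classify_quality(60.00, 10.00), "LOW")
  expect_error(classify_quality(101, 0))
})

test_that("the three classes partition the completeness-contamination plane", {
  grid <- expand.grid(comp = seq(0, 100, by = 2.5),
                      cont = seq(0, 15, by = 0.5))
  cls <- classify_quality(grid$comp, grid$cont)
  expect_true(all(cls %in% c("HIGH", "MEDIUM", "LOW")))
  # each call agrees with a direct restatement of the rules
  direct <- ifelse(grid$comp > 90 & grid$cont < 5, "HIGH",
                   ifelse(grid$comp >= 50 & grid$cont < 10,
                          "MEDIUM", "LOW"))
  expect_identical(cls, direct)
})

test_that("the full MIMAG call needs HIGH class plus an operon and enough tRNAs", {
  expect_true(check_mimag_high(95.28, 1.11, 2, 46))
  expect_true(check_mimag_high(94.64, 0.50, 1, 46))
  expect_false(check_mimag_high(95.28, 1.11, 0, 46))
  expect_false(check_mimag_high(95.28, 1.11, 2, 17))
  expect_false(check_mimag_high(85.00, 0.50, 3, 50))  # MEDIUM genome
  # every genome in the 22-genome table meets the complete criteria
  t1 <- utils::read.delim(fixture_path("table1_transcription.tsv"))
  expect_true(all(check_mimag_high(t1$completeness, t1$contamination,
                                   t1$n_rrna_operons, t1$n_trna)))
})

test_that("the 22-genome table reproduces its printed summary statistics", {
  t1 <- utils::read.delim(fixture_path("table1_transcription.tsv"))
  t1$correction_method <- "megan_lr"
  summ <- summarize_quality_table(t1)
  expect_equal(summ$n_genomes, 22L)
  expect_equal(round(summ$mean_completeness, 2), 95.27)
  expect_equal(summ$min_completeness, 92.57)
  expect_equal(summ$max_completeness, 99.04)
  expect_equal(round(summ$mean_contamination, 2), 0.72)
  expect_equal(summ$min_contamination, 0.00)
  expect_equal(summ$max_contamination, 2.30)
  expect_equal(summ$n_high_quality, 22L)
})

test_that("per-method summaries reproduce the correction-comparison roll-ups", {
  t2 <- read_quality_table(fixture_path("table2_transcription.tsv"))
  summ <- summarize_quality_table(t2, by_method = TRUE)
  get <- function(m, col) summ[summ$correction_method == m, col]
  expect_equal(get("uncorrected", "n_high_quality"), 3L)
  expect_equal(get("medaka", "n_high_quality"), 14L)
  expect_equal(get("racon", "n_high_quality"), 7L)
  expect_equal(get("multiple", "n_high_quality"), 17L)
  expect_equal(get("megan_lr", "n_high_quality"), 22L)
  expect_equal(round(get("uncorrected", "mean_completeness"), 1), 76.8)
  expect_equal(round(get("medaka", "mean_completeness"), 1), 91.8)
  expect_equal(round(get("racon", "mean_completeness"), 1), 86.9)
  expect_equal(round(get("multiple", "mean_completeness"), 1), 92.1)
  expect_equal(round(get("megan_lr", "mean_completeness"), 1), 95.3)
  expect_true(all(summ$max_contamination < 5))
})

test_that("degenerate summaries behave: single record, empty input", {
  one <- data.frame(genome_id = "g", completeness = 80, contamination = 1,
                    correction_method = "none")
  summ <- summarize_quality_table(one)
  expect_equal(summ$mean_completeness, 80)
  expect_equal(summ$min_completeness, summ$max_completeness)
  expect_equal(summ$n_high_quality, 0L)
  expect_error(summarize_quality_table(one[0, ]), "empty")
})

test_that("length ratios use the maximum-bit-score hit per query", {
  hits <- rbind(
    make_aln("g1", "o1", 98, 100, 1, 100, bitscore = 210, qlen = 100,
             slen = 90),
    make_aln("g1", "o2", 98, 100, 1, 100, bitscore = 180, qlen = 100,
             slen = 120),
    make_aln("g2", "o3", 98, 70, 1, 70, bitscore = 140, qlen = 70,
             slen = 100))
  res <- compute_length_ratios(hits, "megan_lr",
                               all_query_ids = c("g1", "g2", "g3"))
  expect_equal(res$ratios$ratio[res$ratios$query_gene_id == "g1"], 100 / 90)
  expect_equal(res$ratios$s_len[res$ratios$query_gene_id == "g1"], 90)
  expect_equal(res$ratios$ratio[res$ratios$query_gene_id == "g2"], 0.7)
  expect_equal(res$unmatched_ids, "g3")
  expect_error(compute_length_ratios(transform(hits, slen = 0)), "zero")
})

test_that("best-hit ratio selection matches a row-scan oracle on generated tables", {
  gen <- simulate_truncated_genes(400, 0.3, 0.7, seed = 6, decoy_rate = 0.5)
  res <- compute_length_ratios(gen$hits, "uncorrected")
  # per-query (not per-pair) brute-force maximum over each query's rows
  want <- do.call(rbind, lapply(split(gen$hits, gen$hits$qseqid),
                                function(sub) {
    sub <- sub[order(-sub$bitscore, -sub$length), , drop = FALSE]
    sub[1, , drop = FALSE]
  }))
  want <- want[order(want$qseqid), ]
  expect_equal(res$ratios$query_gene_id, want$qseqid, ignore_attr = TRUE)
  expect_equal(res$ratios$ratio, want$qlen / want$slen, ignore_attr = TRUE)
  # decoys never win: every retained subject is the true orthologue
  expect_true(all(startsWith(res$ratios$subject_gene_id, "orth_")))
})

test_that("ratio distributions report near-unity fractions and a pooled overflow bin", {
  all_one <- data.frame(query_gene_id = "g", subject_gene_id = "o",
                        q_len = 100, s_len = 100, ratio = 1,
                        correction_method = "none")[rep(1, 4), ]
  summ <- summarize_ratio_distribution(all_one)
  expect_equal(summ$near_unity$fraction_near_unity, 1)

  mixed <- all_one
  mixed$ratio <- c(0.5, 1, 1, 1)
  expect_equal(summarize_ratio_distribution(mixed)$near_unity$
                 fraction_near_unity, 0.75)

  over <- all_one
  over$ratio <- c(0.2, 1.0, 2.3, 3.7)  # 3.7 pools into the overflow bin
  h <- summarize_ratio_distribution(over, n_bins = 25)$histogram
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[nrow(h)], 1)
  expect_equal(h$count[h$bin_start == 2.2], 1)  # 2.3 stays in range
})
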