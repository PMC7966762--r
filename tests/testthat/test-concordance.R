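test_that("best-hit retention keeps the maximum bit-score with documented tie rules", {
  one <- make_aln("c1", "t1", 98, 500, 1, 500, bitscore = 900)
  expect_equal(dedup_best_hits(one), one, ignore_attr = TRUE)

  two <- rbind(make_aln("c1", "t1", 98, 500, 1, 500, bitscore = 500),
               make_aln("c1", "t1", 97, 300, 600, 899, bitscore = 300))
  kept <- dedup_best_hits(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$bitscore, 500)

  tie <- rbind(make_aln("c1", "t1", 98, 700, 1, 700, bitscore = 400),
               make_aln("c1", "t1", 98, 900, 1, 900, bitscore = 400))
  expect_equal(dedup_best_hits(tie)$length, 900)

  # full tie falls back to first occurrence
  full_tie <- rbind(make_aln("c1", "t1", 98, 500, 1, 500, bitscore = 400),
                    make_aln("c1", "t1", 95, 500, 100, 599, bitscore = 400))
  expect_equal(dedup_best_hits(full_tie)$pident, 98)
})

test_that("best-hit retention matches a row-scan oracle on randomized tables", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    tab <- make_aln(sample(paste0("q", 1:8), n, replace = TRUE),
                    sample(paste0("s", 1:4), n, replace = TRUE),
                    pident = round(runif(n, 80, 100), 2),
                    length = sample(100:1000, n, replace = TRUE),
                    sstart = 1, send = 100,
                    bitscore = sample(seq(50, 500, by = 50), n,
                                      replace = TRUE))
    tab$send <- tab$sstart + tab$length - 1
    got <- dedup_best_hits(tab)
    want <- oracle_best_hit(tab)
    expect_equal(got$bitscore, want$bitscore)
    expect_equal(got$length, want$length)
    expect_equal(got$qseqid, want$qseqid)
  }
})

test_that("the hand-computed worked example yields its exact components", {
  ex <- worked_example()
  res <- compute_kappa_matrix(ex$aln, ex$bins)
  expect_equal(res$pid_hat, 0.94)
  expect_equal(res$al2ql_hat, 0.875)
  expect_equal(res$p_srac, 0.5)
  expect_equal(res$p_aln, 0.625)
  expect_equal(res$kappa, 0.735)
  expect_equal(res$n_alignments, 2L)
  expect_equal(res$n_contigs_aligned, 2L)
  expect_equal(res$n_contigs_total, 4L)
})

test_that("perfect tiling gives every component and kappa exactly 1", {
  aln <- rbind(make_aln("c1", "t1", 100, 200, 1, 200, qlen = 200, slen = 400),
               make_aln("c2", "t1", 100, 200, 201, 400, qlen = 200,
                        slen = 400))
  bins <- data.frame(contig_id = c("c1", "c2"), bin_id = "b1")
  res <- compute_kappa_matrix(aln, bins)
  expect_identical(res$kappa, 1)
  expect_identical(res$pid_hat + res$al2ql_hat + res$p_srac + res$p_aln, 4)

  # and from the generator's perfect-tiling limit
  g <- generate_genome(4000, 0.5, seed = 9, id = "gX")
  frag <- fragment_into_bins(g, 8, coverage_fraction = 1,
                             identity_mean = 100, seed = 9)
  res2 <- compute_kappa_matrix(frag$alignments, frag$bins)
  expect_identical(res2$kappa, 1)
})

test_that("overlapping alignments count covered bases once", {
  aln <- rbind(make_aln("c1", "t1", 100, 100, 1, 100, qlen = 100, slen = 200),
               make_aln("c2", "t1", 100, 100, 51, 150, qlen = 100,
                        slen = 200))
  bins <- data.frame(contig_id = c("c1", "c2"), bin_id = "b1")
  res <- compute_kappa_matrix(aln, bins)
  expect_equal(res$p_aln, 0.75)  # union 150 / 200, not 200 / 200
})

test_that("p_aln equals the per-base brute-force oracle on randomized instances", {
  set.seed(33)
  for (rep in 1:100) {
    slen <- sample(1000:100000, 1)
    n <- sample(1:40, 1)
    sstart <- sample(slen, n, replace = TRUE)
    width <- sample(50:5000, n, replace = TRUE)
    send <- pmin(sstart + width - 1, slen)
    aln <- make_aln(sprintf("c%02d", seq_len(n)), "t1",
                    pident = 95, length = send - sstart + 1,
                    sstart = sstart, send = send,
                    qlen = send - sstart + 1, slen = slen)
    bins <- data.frame(contig_id = aln$qseqid, bin_id = "b1")
    res <- compute_kappa_matrix(aln, bins)
    expect_equal(res$p_aln, oracle_p_aln(sstart, send, slen))
  }
})

test_that("near-full-length filtering uses an inclusive 0.95 boundary", {
  tab <- rbind(make_aln("c1", "t1", 99, 95, 1, 95, qlen = 100),
               make_aln("c2", "t1", 99, 94, 200, 293, qlen = 100))
  kept <- filter_near_full_length(tab)
  expect_equal(kept$qseqid, "c1")  # 0.95 kept, 0.94 dropped
})

test_that("the filtered variant recomputes all four components on the filtered set", {
  # a short partial alignment from a third contig inflates nothing after
  # filtering: p_srac and p_aln must drop with it
  aln <- rbind(make_aln("c1", "t1", 100, 200, 1, 200, qlen = 200, slen = 400),
               make_aln("c2", "t1", 100, 200, 201, 400, qlen = 200,
                        slen = 400),
               make_aln("c3", "t1", 100, 50, 120, 169, qlen = 400,
                        slen = 400))
  bins <- data.frame(contig_id = c("c1", "c2", "c3"), bin_id = "b1")
  unfiltered <- compute_kappa_matrix(aln, bins)
  filtered <- compute_kappa_matrix(aln, bins, filtered = TRUE)
  expect_equal(unfiltered$p_srac, 1)
  expect_equal(filtered$p_srac, 2 / 3)
  expect_equal(filtered$p_aln, 1)
  expect_equal(filtered$n_alignments, 2L)
  expect_true(filtered$filtered)
  # dropped alignment had the lowest al2ql, so kappa cannot increase
  # on the al2ql component, and here strictly decreases overall
  expect_lt(filtered$kappa, unfiltered$kappa + 1e-12)
})

test_that("kappa is stored as the exact mean of its four components", {
  s <- build_scenario(seed = 12)
  res <- compute_kappa_matrix(s$alignments, s$bins)
  expect_equal(res$kappa,
               (res$pid_hat + res$al2ql_hat + res$p_srac + res$p_aln) / 4)
  expect_true(all(res$p_srac >= 0 & res$p_srac <= 1))
  expect_true(all(res$p_aln >= 0 & res$p_aln <= 1))
  expect_true(all(res$pid_hat >= 0 & res$pid_hat <= 1))
  expect_true(all(res$n_contigs_aligned <= res$n_contigs_total))
  expect_true(all(res$n_alignments >= 1))
})

test_that("pairs without alignments are omitted and the pair count is bounded", {
  aln <- make_aln("c1", "t1", 98, 100, 1, 100, qlen = 100, slen = 1000)
  bins <- data.frame(contig_id = c("c1", "c2"), bin_id = c("b1", "b2"))
  res <- compute_kappa_matrix(aln, bins)
  expect_equal(nrow(res), 1L)  # only (b1, t1); (b2, t1) absent, not zero
  expect_equal(res$bin_id, "b1")
})

test_that("missing query lengths fail naming the contig", {
  aln <- make_aln("c1", "t1", 98, 100, 1, 100, slen = 1000)
  bins <- data.frame(contig_id = "c1", bin_id = "b1")
  expect_error(compute_kappa_matrix(aln, bins), "c1")
})

test_that("adding an alignment from an unaligned bin contig never lowers p_srac or p_aln", {
  set.seed(77)
  for (rep in 1:25) {
    g <- generate_genome(5000, 0.5, seed = rep, id = "gM")
    frag <- fragment_into_bins(g, 6, coverage_fraction = 0.5,
                               identity_mean = 95, seed = rep,
                               n_extra_contigs = 2)
    base <- compute_kappa_matrix(frag$alignments, frag$bins)
    extra_id <- frag$bins$contig_id[!frag$bins$contig_id %in%
                                      frag$alignments$qseqid][1]
    extra <- make_aln(extra_id, g$id, 90, 80,
                      sstart = sample(4900, 1), send = NA, qlen = 500,
                      slen = 5000)
    extra$send <- extra$sstart + 79
    grown <- compute_kappa_matrix(rbind(frag$alignments, extra), frag$bins)
    expect_gte(grown$p_srac, base$p_srac)
    expect_gte(grown$p_aln, base$p_aln)
  }
})

test_that("cognate ranking orders by kappa with p_aln then bin_id tie-breaks", {
  res <- data.frame(lrac_id = "t1", bin_id = c("b1", "b2"),
                    pid_hat = 1, al2ql_hat = 1, p_srac = 1,
                    p_aln = c(0.9, 0.2), kappa = c(0.97, 0.41),
                    n_alignments = 1L, n_contigs_aligned = 1L,
                    n_contigs_total = 1L, filtered = FALSE)
  expect_equal(rank_cognates(res, "t1")$bin_id, c("b1", "b2"))

  tied <- res
  tied$kappa <- 0.9
  tied$p_aln <- c(0.3, 0.8)
  expect_equal(rank_cognates(tied, "t1")$bin_id, c("b2", "b1"))

  expect_warning(empty <- rank_cognates(res, "absent"), "absent")
  expect_equal(nrow(empty), 0L)
})

test_that("a split bin tiles only its half and scores below an unsplit cognate", {
  g <- generate_genome(20000, 0.5, seed = 4, id = "gS")
  whole <- fragment_into_bins(g, 10, coverage_fraction = 0.9,
                              identity_mean = 99, seed = 4,
                              bin_prefix = "whole")
  split <- fragment_into_bins(g, 10, coverage_fraction = 0.9,
                              identity_mean = 99, seed = 5,
                              split_into = 2, bin_prefix = "half",
                              contig_prefix = "sp")
  aln <- rbind(whole$alignments, split$alignments)
  bins <- rbind(whole$bins, split$bins)
  res <- compute_kappa_matrix(aln, bins)
  ranked <- rank_cognates(res, "gS")
  expect_equal(ranked$bin_id[1], "whole")
  halves <- res[startsWith(res$bin_id, "half"), ]
  expect_equal(nrow(halves), 2L)
  expect_equal(sum(halves$p_aln), 0.9, tolerance = 0.02)
  expect_true(all(halves$kappa < ranked$kappa[1]))
})
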