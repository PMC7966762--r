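# Seeded synthetic-data generator. Builds the fixtures every other module
# consumes — genomes, fragmented binned contigs with matching alignment
# tables, coverage profiles with planted anomalies, best-hit gene tables
# with planted truncations, and replicon feature panels — together with a
# ground-truth record, so the whole pipeline is testable without any
# sequencing data. All randomness is scoped: each operation takes an
# explicit seed and restores the caller's RNG state on exit, so identical
# (parameters, seed) give byte-identical output and nothing leaks into the
# session.

.DNA <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc Target GC proportion, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @param circular Circular flag carried on the record.
#' @return Sequence record (list: `id`, `sequence`, `circular`).
#' @export
generate_genome <- function(length, gc = 0.5, seed, id = "genome",
                            circular = FALSE) {
  stopifnot(length >= 1)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("gc must lie strictly between 0 and 1")
  seq <- withr::with_seed(seed, paste(
    sample(.DNA, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  list(id = id, sequence = seq, circular = circular)
}

.mutate_sequence <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_subs)
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(.DNA, b), 1L), "")
  paste(chars, collapse = "")
}

#' Fragment a genome into binned contigs with a matching alignment table
#'
#' Samples `n_contigs` non-overlapping fragments along the genome, jointly
#' covering approximately `coverage_fraction` of it, applies point
#' substitutions so each emitted contig matches its source span at about
#' `identity_mean` percent identity, and emits the BLAST-style alignment
#' rows those contigs would produce against the genome (correct
#' coordinates, realized identity, bit-score increasing in length x
#' identity). With `split_into > 1` the fragments are partitioned into
#' that many bins over disjoint consecutive stretches of the genome,
#' emulating a genome split across bins by the binning algorithm.
#' `n_extra_contigs` unalignable contigs (random sequence) per bin dilute
#' `p_srac` below 1, as decoy bins show in practice.
#'
#' @param genome Sequence record ([generate_genome()]).
#' @param n_contigs Number of aligned fragments (>= 1).
#' @param coverage_fraction Fraction of the genome covered, in (0, 1].
#' @param identity_mean Target percent identity of the fragments.
#' @param split_into Number of bins the fragments are partitioned into.
#' @param seed Integer seed.
#' @param bin_prefix,contig_prefix Identifier prefixes.
#' @param n_extra_contigs Unaligned contigs added to each bin.
#' @return List: `contigs` (sequence records), `bins` (data.frame),
#'   `alignments` (data.frame in [read_blast_tab()] layout), `truth` (list:
#'   `bin_ids`, per-bin covered fraction `covered_fraction`, planted
#'   subject intervals `intervals`, `identity_mean`).
#' @export
fragment_into_bins <- function(genome, n_contigs, coverage_fraction = 0.9,
                               identity_mean = 99, split_into = 1L,
                               seed = 1L, bin_prefix = "bin",
                               contig_prefix = "contig",
                               n_extra_contigs = 0L) {
  L <- nchar(genome$sequence)
  stopifnot(n_contigs >= 1, coverage_fraction > 0, coverage_fraction <= 1)
  covered <- round(coverage_fraction * L)
  if (covered < n_contigs)
    stop("requested coverage cannot be split across that many contigs")
  withr::with_seed(seed, {
    # fragment lengths: near-equal split of the covered bases, jittered
    base_len <- covered %/% n_contigs
    lens <- rep(base_len, n_contigs)
    lens[seq_len(covered - base_len * n_contigs)] <-
      lens[seq_len(covered - base_len * n_contigs)] + 1L
    if (n_contigs > 1L && base_len > 10L && coverage_fraction < 1) {
      jit <- sample(-(base_len %/% 4):(base_len %/% 4), n_contigs,
                    replace = TRUE)
      jit <- jit - round(mean(jit))
      lens <- pmax(10L, lens + jit)
    }
    # distribute the uncovered bases as gaps around the fragments
    slack <- L - sum(lens)
    if (slack < 0) { lens[which.max(lens)] <- lens[which.max(lens)] + slack
                     slack <- 0L }
    gap_w <- if (slack > 0)
      as.integer(stats::rmultinom(1, size = slack,
                                  prob = rep(1, n_contigs + 1L)))
    else rep(0L, n_contigs + 1L)
    starts <- integer(n_contigs)
    pos <- 1L
    for (i in seq_len(n_contigs)) {
      pos <- pos + gap_w[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    ends <- starts + lens - 1L
    stopifnot(all(ends <= L))
    bin_of <- if (split_into > 1L)
      paste0(bin_prefix, ".", ceiling(seq_len(n_contigs) * split_into /
                                        n_contigs))
    else rep(bin_prefix, n_contigs)
    contigs <- vector("list", n_contigs)
    rows <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      frag <- substr(genome$sequence, starts[i], ends[i])
      n_subs <- round(lens[i] * (100 - identity_mean) / 100)
      mutated <- .mutate_sequence(frag, n_subs)
      cid <- sprintf("%s_%03d", contig_prefix, i)
      contigs[[i]] <- list(id = cid, sequence = mutated, circular = FALSE)
      pident <- round(100 * (1 - n_subs / lens[i]), 3)
      rows[[i]] <- data.frame(
        qseqid = cid, sseqid = genome$id, pident = pident,
        length = lens[i], mismatch = n_subs, gapopen = 0,
        qstart = 1, qend = lens[i], sstart = starts[i], send = ends[i],
        evalue = 0, bitscore = round(2 * lens[i] * pident / 100, 1),
        qlen = lens[i], slen = L, stringsAsFactors = FALSE)
    }
    bins <- data.frame(contig_id = vapply(contigs, `[[`, "", "id"),
                       bin_id = bin_of, stringsAsFactors = FALSE)
    if (n_extra_contigs > 0L) {
      for (b in unique(bin_of)) {
        for (j in seq_len(n_extra_contigs)) {
          cid <- sprintf("%s_x%s_%02d", contig_prefix, b, j)
          extra <- paste(sample(.DNA, 500, replace = TRUE), collapse = "")
          contigs[[length(contigs) + 1L]] <-
            list(id = cid, sequence = extra, circular = FALSE)
          bins <- rbind(bins, data.frame(contig_id = cid, bin_id = b))
        }
      }
    }
    alignments <- normalize_subject_strand(do.call(rbind, rows))
    covered_by_bin <- vapply(unique(bin_of), function(b) {
      idx <- which(bin_of == b)
      sum(lens[idx]) / L
    }, numeric(1))
    list(contigs = contigs, bins = bins, alignments = alignments,
         truth = list(bin_ids = unique(bin_of),
                      covered_fraction = covered_by_bin,
                      intervals = data.frame(contig_id = bins$contig_id[
                        seq_len(n_contigs)], start = starts, end = ends,
                        bin_id = bin_of),
                      identity_mean = identity_mean))
  })
}

#' Generate a coverage profile with planted anomalies
#'
#' Background depth is Poisson around `mean_depth` (the minimal model of
#' sequencing depth); each requested anomaly span is then forced strictly
#' beyond the screening threshold relative to the realized profile median
#' (`factor` times the median, clamped strictly below 0.5x for LOW and
#' strictly above 1.5x for HIGH).
#'
#' @param length Profile length in bp.
#' @param mean_depth Background mean depth.
#' @param anomalies Data.frame with columns `start`, `length`, `kind`
#'   (`"HIGH"`/`"LOW"`), `factor` (target depth as a multiple of the
#'   median; must itself be beyond the corresponding threshold). May be
#'   empty or `NULL`.
#' @param seed Integer seed.
#' @param replicon_id Profile name.
#' @return List: `profile` (named single-element list of depths, the
#'   [read_coverage_tsv()] layout) and `truth` (data.frame `start`, `end`,
#'   `kind`; empty when nothing was planted).
#' @export
plant_coverage_anomaly <- function(length, mean_depth = 50, anomalies = NULL,
                                   seed = 1L, replicon_id = "replicon") {
  stopifnot(length >= 1, mean_depth > 0)
  if (is.null(anomalies) || nrow(anomalies) == 0L)
    anomalies <- data.frame(start = integer(), length = integer(),
                            kind = character(), factor = numeric())
  if (nrow(anomalies) > 0L) {
    stopifnot(all(anomalies$length >= 1),
              all(anomalies$start >= 1),
              all(anomalies$start + anomalies$length - 1 <= length),
              all(anomalies$kind %in% c("HIGH", "LOW")))
    ends <- anomalies$start + anomalies$length - 1
    ord <- order(anomalies$start)
    if (any(anomalies$start[ord][-1] <= ends[ord][-nrow(anomalies)]))
      stop("anomaly spans overlap")
    bad <- (anomalies$kind == "LOW" & anomalies$factor >= 0.5) |
      (anomalies$kind == "HIGH" & anomalies$factor <= 1.5)
    if (any(bad)) stop("anomaly factor does not exceed its threshold")
  }
  depths <- withr::with_seed(seed, stats::rpois(length, mean_depth))
  med <- stats::median(depths)
  if (nrow(anomalies) > 0L) {
    for (i in seq_len(nrow(anomalies))) {
      span <- anomalies$start[i]:(anomalies$start[i] + anomalies$length[i] - 1)
      target <- round(med * anomalies$factor[i])
      if (anomalies$kind[i] == "LOW") {
        thr <- 0.5 * med
        limit <- if (thr %% 1 == 0) thr - 1 else floor(thr)  # strictly below
        depths[span] <- max(0L, min(target, limit))
      } else {
        limit <- floor(1.5 * med) + 1  # strictly above
        depths[span] <- max(target, limit)
      }
    }
    med2 <- stats::median(depths)
    if (med2 != med)
      stop("anomaly spans shifted the profile median; reduce their extent")
  }
  truth <- if (nrow(anomalies) > 0L)
    data.frame(start = anomalies$start,
               end = anomalies$start + anomalies$length - 1,
               kind = anomalies$kind, stringsAsFactors = FALSE)
  else data.frame(start = integer(), end = integer(), kind = character())
  list(profile = stats::setNames(list(as.integer(depths)), replicon_id),
       truth = truth[order(truth$start), , drop = FALSE])
}

#' Simulate a best-hit gene table with planted truncations
#'
#' Emulates a protein best-hit search of predicted genes against an
#' orthologue database: intact genes match their subject full length
#' (ratio 1), truncated genes — the frame-shift signature — match at
#' `q_len = round(s_len * truncation_severity)`. A fraction of queries
#' additionally receives a lower-scoring decoy hit with a different
#' subject length, exercising best-hit selection.
#'
#' @param n_genes Number of query genes.
#' @param truncation_rate Proportion of genes truncated, in `[0, 1]`.
#' @param truncation_severity Length fraction retained by truncated genes
#'   (must be < 0.95 so a truncation leaves the near-unity band).
#' @param seed Integer seed.
#' @param decoy_rate Fraction of queries given a second, lower-bit-score
#'   hit.
#' @return List: `hits` (alignment data.frame with `qlen`/`slen`), `truth`
#'   (data.frame `query_gene_id`, `truncated`).
#' @export
simulate_truncated_genes <- function(n_genes, truncation_rate = 0.3,
                                     truncation_severity = 0.7, seed = 1L,
                                     decoy_rate = 0.1) {
  stopifnot(truncation_rate >= 0, truncation_rate <= 1,
            truncation_severity > 0, truncation_severity < 0.95)
  withr::with_seed(seed, {
    s_len <- sample(100:1500, n_genes, replace = TRUE)
    truncated <- stats::runif(n_genes) < truncation_rate
    q_len <- ifelse(truncated, round(s_len * truncation_severity), s_len)
    qid <- sprintf("gene_%05d", seq_len(n_genes))
    sid <- sprintf("orth_%05d", seq_len(n_genes))
    hits <- data.frame(
      qseqid = qid, sseqid = sid, pident = 98, length = q_len,
      mismatch = 0, gapopen = 0, qstart = 1, qend = q_len, sstart = 1,
      send = q_len, evalue = 0, bitscore = round(2 * q_len, 1),
      qlen = q_len, slen = s_len, stringsAsFactors = FALSE)
    decoy <- which(stats::runif(n_genes) < decoy_rate)
    if (length(decoy)) {
      d <- hits[decoy, , drop = FALSE]
      d$sseqid <- sprintf("decoy_%05d", decoy)
      d$slen <- pmax(50, round(d$slen * stats::runif(length(decoy), 0.4, 2)))
      d$bitscore <- round(d$bitscore * stats::runif(length(decoy), 0.3, 0.8),
                          1)
      hits <- rbind(hits, d)
    }
    hits <- normalize_subject_strand(hits)
    list(hits = hits,
         truth = data.frame(query_gene_id = qid, truncated = truncated,
                            stringsAsFactors = FALSE))
  })
}

#' Build a replicon feature panel with known labels
#'
#' One feature table per requested class, engineered so the triage cascade
#' assigns exactly that class.
#'
#' @param classes Character vector of classes to plant (default: one per
#'   triage class).
#' @param seed Integer seed (controls identifiers/lengths only; the
#'   evidence is deterministic per class).
#' @return List: `features` (feature tables) and `truth` (data.frame
#'   `replicon_id`, `class`).
#' @export
build_replicon_panel <- function(classes = replicon_classes(), seed = 1L) {
  gene <- function(id, product, markers = character())
    data.frame(gene_id = id, product = product,
               markers = I(list(markers)), stringsAsFactors = FALSE)
  make <- function(i, class) {
    id <- sprintf("rep_%02d_%s", i, tolower(class))
    base <- list(replicon_id = id, circular = TRUE, n_rrna_operons = 0L,
                 n_trna = 0L, external_viral_call = "none")
    f <- switch(class,
      PUTATIVE_CHROMOSOME = utils::modifyList(base, list(
        length_bp = 2.5e6, n_rrna_operons = 2L, n_trna = 50L,
        genes = gene("g1", "DNA polymerase III subunit alpha"))),
      SMALL_GENOME = utils::modifyList(base, list(
        length_bp = 848000, n_rrna_operons = 1L, n_trna = 46L,
        genes = gene("g1", "ribosomal protein S12"))),
      CHROMID = utils::modifyList(base, list(
        length_bp = 300000, n_rrna_operons = 1L, n_trna = 3L,
        external_viral_call = "virus",
        genes = gene("g1", "partitioning protein ParA"))),
      VIRUS_PHAGE = utils::modifyList(base, list(
        length_bp = 45000, external_viral_call = "virus",
        genes = rbind(gene("g1", "major capsid protein",
                           "viral_marker"),
                      gene("g2", "terminase large subunit",
                           "viral_marker")))),
      PROPHAGE_HOST = utils::modifyList(base, list(
        length_bp = 120000, external_viral_call = "prophage",
        genes = gene("g1", "integrase", "viral_marker"))),
      CONJUGATIVE_PLASMID = utils::modifyList(base, list(
        length_bp = 90000,
        genes = rbind(gene("g1", "type IV secretion protein VirB4", "T4SS"),
                      gene("g2", "replication initiation protein RepA",
                           "plasmid_replication")))),
      PLASMID = utils::modifyList(base, list(
        length_bp = 60000,
        genes = rbind(gene("g1", "hypothetical protein", "hypothetical"),
                      gene("g2", "toxin-antitoxin system protein")))),
      ARTEFACTUAL_FRAGMENT = utils::modifyList(base, list(
        length_bp = 8000,
        genes = rbind(gene("g1", "hypothetical protein", "hypothetical"),
                      gene("g2", "hypothetical protein", "hypothetical")))),
      stop(sprintf("unknown class '%s'", class)))
    f
  }
  features <- mapply(make, seq_along(classes), classes, SIMPLIFY = FALSE)
  truth <- data.frame(
    replicon_id = vapply(features, `[[`, "", "replicon_id"),
    class = classes, stringsAsFactors = FALSE)
  list(features = features, truth = truth)
}

#' Default scenario configuration
#'
#' The study conditions the generator emulates: one long-read chromosome
#' candidate (50 kb at desk scale), a cognate bin tiling 90% of it at 99%
#' identity, three decoy bins with sparse low-identity alignments (20%
#' coverage at 80% identity, plus unaligned contigs), a coverage profile
#' at mean depth 50 with one planted LOW and one planted HIGH anomaly, a
#' truncated-gene table at rate 0.3, and the eight-class replicon panel.
#'
#' @return Named list of scenario parameters.
#' @export
default_scenario_config <- function() {
  list(genome_length = 50000, genome_gc = 0.55,
       cognate = list(n_contigs = 20, coverage_fraction = 0.9,
                      identity_mean = 99, n_extra_contigs = 1),
       n_decoys = 3,
       decoy = list(n_contigs = 6, coverage_fraction = 0.2,
                    identity_mean = 80, n_extra_contigs = 6),
       coverage = list(length = 20000, mean_depth = 50,
                       anomalies = data.frame(
                         start = c(5001, 12001), length = c(50, 120),
                         kind = c("LOW", "HIGH"), factor = c(0.2, 2.5))),
       genes = list(n_genes = 2000, truncation_rate = 0.3,
                    truncation_severity = 0.7))
}

#' Build a complete synthetic scenario
#'
#' Generates every fixture a full pipeline run needs and, when `out_dir`
#' is given, writes them in the toolkit's external formats: `lrac.fa`,
#' `srac.fa`, `bins.tsv`, `alignments.tsv`, `coverage.tsv`,
#' `replicons.tsv` + `genes.tsv`, `gene_hits.tsv` and `truth.json`.
#' Byte-identical per (config, seed).
#'
#' @param config Scenario parameters ([default_scenario_config()]);
#'   partial lists are completed with the defaults.
#' @param seed Integer seed; sub-seeds for each component are derived from
#'   it deterministically.
#' @param out_dir Optional output directory (created if needed).
#' @return List: `lrac`, `contigs`, `bins`, `alignments`, `coverage`,
#'   `gene_hits`, `replicons`, and `truth` (the ScenarioTruth record).
#' @export
build_scenario <- function(config = default_scenario_config(), seed = 1L,
                           out_dir = NULL) {
  config <- utils::modifyList(default_scenario_config(), config)
  sub_seed <- function(k) (seed * 131L + k) %% 2147483647L
  lrac <- generate_genome(config$genome_length, config$genome_gc,
                          seed = sub_seed(1L), id = "lrac_001",
                          circular = TRUE)
  cog <- fragment_into_bins(
    lrac, config$cognate$n_contigs, config$cognate$coverage_fraction,
    config$cognate$identity_mean, seed = sub_seed(2L),
    bin_prefix = "bin_cognate", contig_prefix = "sr_cog",
    n_extra_contigs = config$cognate$n_extra_contigs)
  contigs <- cog$contigs
  bins <- cog$bins
  alignments <- cog$alignments
  for (d in seq_len(config$n_decoys)) {
    dec <- fragment_into_bins(
      lrac, config$decoy$n_contigs, config$decoy$coverage_fraction,
      config$decoy$identity_mean, seed = sub_seed(10L + d),
      bin_prefix = sprintf("bin_decoy%d", d),
      contig_prefix = sprintf("sr_dec%d", d),
      n_extra_contigs = config$decoy$n_extra_contigs)
    contigs <- c(contigs, dec$contigs)
    bins <- rbind(bins, dec$bins)
    alignments <- rbind(alignments, dec$alignments)
  }
  cov <- plant_coverage_anomaly(
    config$coverage$length, config$coverage$mean_depth,
    config$coverage$anomalies, seed = sub_seed(3L),
    replicon_id = lrac$id)
  genes <- simulate_truncated_genes(
    config$genes$n_genes, config$genes$truncation_rate,
    config$genes$truncation_severity, seed = sub_seed(4L))
  panel <- build_replicon_panel(seed = sub_seed(5L))
  truth <- list(
    seed = seed,
    genomes = data.frame(id = lrac$id, length = config$genome_length,
                         gc = config$genome_gc),
    cognate_map = stats::setNames("bin_cognate", lrac$id),
    cognate_covered_fraction = unname(cog$truth$covered_fraction),
    decoy_bins = sprintf("bin_decoy%d", seq_len(config$n_decoys)),
    planted_anomalies = cov$truth,
    truncation_rate = config$genes$truncation_rate,
    truncated_genes = genes$truth,
    replicon_labels = panel$truth)
  scenario <- list(lrac = lrac, contigs = contigs, bins = bins,
                   alignments = alignments, coverage = cov$profile,
                   gene_hits = genes$hits, replicons = panel$features,
                   truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(list(lrac), p("lrac.fa"))
    write_fasta(contigs, p("srac.fa"))
    write_bins(bins, p("bins.tsv"))
    write_blast_tab(alignments, p("alignments.tsv"), with_lengths = TRUE)
    write_coverage_tsv(cov$profile, p("coverage.tsv"))
    write_feature_table(panel$features, p("replicons.tsv"), p("genes.tsv"))
    write_blast_tab(genes$hits, p("gene_hits.tsv"), with_lengths = TRUE)
    truth_json <- truth
    truth_json$truncated_genes <- NULL  # bulky; derivable from seed
    jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  scenario
}
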