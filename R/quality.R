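# Genome quality classification and summaries, plus the predicted-gene
# length-ratio statistic used to compare sequence-correction procedures.
#
# Quality calls follow the single-copy-marker-gene convention:
#   HIGH    completeness > 90 and contamination < 5   (strict)
#   MEDIUM  not HIGH, completeness >= 50 and contamination < 10
#   LOW     otherwise
# The full MIMAG high-quality call additionally requires at least one
# complete rRNA operon (5S + 16S + 23S) and a minimum tRNA count.

#' Classify genome quality from completeness and contamination
#'
#' Vectorized over its two arguments. The HIGH thresholds are strict
#' (`> 90`, `< 5`): a genome at exactly 90% completeness is MEDIUM.
#'
#' @param completeness Completeness percentage(s) in `[0, 100]`.
#' @param contamination Contamination percentage(s) `>= 0`.
#' @return Character vector over `{"HIGH","MEDIUM","LOW"}`.
#' @export
classify_quality <- function(completeness, contamination) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0))
  ifelse(completeness > 90 & contamination < 5, "HIGH",
         ifelse(completeness >= 50 & contamination < 10, "MEDIUM", "LOW"))
}

#' Full MIMAG high-quality check
#'
#' A genome meets the complete high-quality draft standard when it is HIGH
#' by [classify_quality()] and its annotation shows at least one complete
#' rRNA operon and at least `min_trna` tRNA genes (18 under the MIMAG
#' standard).
#'
#' @param completeness,contamination Percentages as in [classify_quality()].
#' @param n_rrna_operons Count of complete 5S+16S+23S operons.
#' @param n_trna tRNA gene count.
#' @param min_trna Minimum tRNA count required.
#' @return Logical vector.
#' @export
check_mimag_high <- function(completeness, contamination, n_rrna_operons,
                             n_trna, min_trna = 18L) {
  classify_quality(completeness, contamination) == "HIGH" &
    n_rrna_operons >= 1 & n_trna >= min_trna
}

#' Summarise a genome-quality table
#'
#' Per correction method (or overall), reports the number of genomes, the
#' unweighted mean / min / max of completeness and contamination, and the
#' count of HIGH-classified genomes. Values are kept at full precision
#' here; [write_report()] rounds to two decimals at output time.
#'
#' @param records Quality data.frame ([read_quality_table()] layout).
#' @param by_method Group by `correction_method` (default) or summarise all
#'   rows together.
#' @return Data.frame with one row per group.
#' @export
summarize_quality_table <- function(records, by_method = TRUE) {
  if (nrow(records) == 0L) stop("empty quality table")
  groups <- if (by_method)
    split(records, records$correction_method)
  else
    list(all = records)
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    data.frame(correction_method = g, n_genomes = nrow(r),
               mean_completeness = mean(r$completeness),
               min_completeness = min(r$completeness),
               max_completeness = max(r$completeness),
               mean_contamination = mean(r$contamination),
               min_contamination = min(r$contamination),
               max_contamination = max(r$contamination),
               n_high_quality = sum(classify_quality(
                 r$completeness, r$contamination) == "HIGH"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$correction_method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene length ratios against best-hit orthologues
#'
#' For each predicted query gene, takes the single subject hit with the
#' maximum bit-score (ties: larger alignment length, then input order) and
#' computes the ratio of query length to subject length. Truncated genes —
#' the signature of uncorrected frame-shift errors in noisy long-read
#' contigs — show ratios well below 1. Queries with no hit are reported as
#' a count, never as ratio 0.
#'
#' @param hits Alignment data.frame carrying `qlen` and `slen` (e.g.
#'   protein-level best-hit search output read by [read_blast_tab()] with
#'   an extended `column_spec`).
#' @param correction_method Label attached to every ratio.
#' @param all_query_ids Optional character vector of every query searched;
#'   queries absent from `hits` are counted as unmatched.
#' @return List with `ratios` (data.frame `query_gene_id`,
#'   `subject_gene_id`, `q_len`, `s_len`, `ratio`, `correction_method`) and
#'   `unmatched_ids` (character vector).
#' @export
compute_length_ratios <- function(hits, correction_method = "none",
                                  all_query_ids = NULL) {
  if (anyNA(hits$qlen) || anyNA(hits$slen))
    stop("length-ratio computation needs qlen and slen for every hit")
  if (any(hits$slen == 0)) stop("subject length of zero")
  best <- hits
  if (nrow(best) > 0L) {
    ord <- order(best$qseqid, -best$bitscore, -best$length,
                 seq_len(nrow(best)))
    best <- best[ord, , drop = FALSE]
    best <- best[!duplicated(best$qseqid), , drop = FALSE]
  }
  ratios <- data.frame(query_gene_id = best$qseqid,
                       subject_gene_id = best$sseqid,
                       q_len = best$qlen, s_len = best$slen,
                       ratio = best$qlen / best$slen,
                       correction_method = rep(correction_method,
                                               nrow(best)),
                       stringsAsFactors = FALSE)
  rownames(ratios) <- NULL
  unmatched <- if (is.null(all_query_ids)) character() else
    setdiff(all_query_ids, ratios$query_gene_id)
  list(ratios = ratios, unmatched_ids = unmatched)
}

#' Summarise a length-ratio distribution
#'
#' Histogram of ratios over `[0, 2.5]` with deterministic equal-width bin
#' edges (ratios above 2.5 pooled into a final overflow bin), plus the
#' fraction of ratios inside the near-unity band, per correction method.
#' Ratios at exactly 1 mark genes whose predicted length matches the
#' orthologue; the near-unity fraction is the headline number for judging
#' a correction procedure.
#'
#' @param ratios Ratio data.frame ([compute_length_ratios()]`$ratios`).
#' @param near_unity_band Closed interval counted as "near unity".
#' @param n_bins Number of histogram bins across `[0, 2.5]`.
#' @param upper Upper edge of the displayed range.
#' @return List with `histogram` (data.frame `correction_method`,
#'   `bin_start`, `bin_end`, `count`; the last bin of each method pools
#'   overflow) and `near_unity` (data.frame `correction_method`, `n`,
#'   `fraction_near_unity`).
#' @export
summarize_ratio_distribution <- function(ratios,
                                         near_unity_band = c(0.95, 1.05),
                                         n_bins = 50L, upper = 2.5) {
  if (nrow(ratios) == 0L) stop("no ratios to summarise")
  edges <- seq(0, upper, length.out = n_bins + 1L)
  groups <- split(ratios, ratios$correction_method)
  hist_rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]$ratio
    idx <- pmin(findInterval(r, edges, left.open = TRUE,
                             rightmost.closed = FALSE) + (r == 0),
                n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    data.frame(correction_method = g, bin_start = edges[-length(edges)],
               bin_end = edges[-1], count = counts,
               stringsAsFactors = FALSE)
  })
  band_rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]$ratio
    data.frame(correction_method = g, n = length(r),
               fraction_near_unity = mean(r >= near_unity_band[1] &
                                            r <= near_unity_band[2]),
               stringsAsFactors = FALSE)
  })
  list(histogram = do.call(rbind, hist_rows),
       near_unity = do.call(rbind, band_rows))
}
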