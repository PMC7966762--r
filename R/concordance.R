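# The concordance statistic kappa links bins of short-read assembled
# contigs (SRACs) to long-read assembled contigs (LRACs) through BLAST
# tabular alignments. For one (bin, LRAC) pair, kappa is the mean of four
# proportions computed over the retained best-hit alignments of the bin's
# contigs against that LRAC:
#
#   pid_hat   mean percent identity, as a proportion in [0,1]
#   al2ql_hat mean alignment length / query length (can exceed 1)
#   p_srac    aligned contigs in the bin / total contigs in the bin
#   p_aln     fraction of the LRAC covered by >=1 alignment (interval union)
#
# A kappa near 1 means the LRAC is tiled end to end by the bin's contigs
# with near-perfect alignments: the bin is a candidate cognate genome.

#' Retain the best HSP per (query, subject) pair
#'
#' From raw BLAST tabular output, keeps exactly one row per unique
#' combination of query and subject: the one with the highest bit-score.
#' Ties are broken by larger alignment length, then by first occurrence in
#' input order. The result is sorted by `qseqid`, then `sseqid`, so output
#' is deterministic regardless of input order among non-tied rows.
#'
#' @param tab Alignment data.frame ([read_blast_tab()]).
#' @return Data.frame with one row per (query, subject) pair.
#' @export
dedup_best_hits <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  ord <- order(tab$qseqid, tab$sseqid,
               -tab$bitscore, -tab$length, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  keep <- !duplicated(paste(tab$qseqid, tab$sseqid, sep = "\r"))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only near-full-length alignments
#'
#' Filters an alignment table to rows whose alignment length covers at
#' least `min_al2ql` of the query length (default 0.95, boundary
#' inclusive). When the filtered variant of kappa is requested, all four
#' components — including `p_srac` and `p_aln` — are recomputed on the
#' filtered set.
#'
#' @param tab Alignment data.frame.
#' @param query_lengths Optional named vector of query lengths; used for
#'   rows whose `qlen` column is `NA`.
#' @param min_al2ql Minimum alignment-length / query-length ratio.
#' @return The filtered data.frame.
#' @export
filter_near_full_length <- function(tab, query_lengths = NULL,
                                    min_al2ql = 0.95) {
  ql <- .resolve_query_lengths(tab, query_lengths)
  out <- tab[tab$length / ql >= min_al2ql, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.resolve_query_lengths <- function(tab, query_lengths) {
  ql <- tab$qlen
  if (!is.null(query_lengths)) {
    idx <- match(tab$qseqid, names(query_lengths))
    ql <- ifelse(is.na(ql), unname(query_lengths[idx]), ql)
  }
  if (anyNA(ql))
    stop(sprintf("no query length known for contig '%s'",
                 tab$qseqid[which(is.na(ql))[1]]))
  ql
}

#' Concordance components for one (bin, LRAC) pair
#'
#' Computes the four component statistics and their mean (kappa) from the
#' retained best-hit alignments of one bin's contigs against one LRAC.
#' Means are unweighted across alignments; `p_aln` counts each subject base
#' once however many alignments cover it (interval union).
#'
#' @param bin_id,lrac_id Identifiers echoed into the result.
#' @param retained Best-hit alignment data.frame restricted to queries in
#'   the bin and subject `lrac_id`.
#' @param bins Bin membership data.frame (for the `p_srac` denominator).
#' @param query_lengths Named vector of query (contig) lengths; optional if
#'   the table carries `qlen`.
#' @param subject_length Length of the LRAC in bp.
#' @param filtered Flag echoed into the result, marking the
#'   near-full-length variant.
#' @return One-row data.frame: `lrac_id`, `bin_id`, `pid_hat`, `al2ql_hat`,
#'   `p_srac`, `p_aln`, `kappa`, `n_alignments`, `n_contigs_aligned`,
#'   `n_contigs_total`, `filtered`; or `NULL` when `retained` is empty (the
#'   pair is absent, not zero).
#' @export
compute_components <- function(bin_id, lrac_id, retained, bins,
                               query_lengths = NULL, subject_length,
                               filtered = FALSE) {
  if (nrow(retained) == 0L) return(NULL)
  stopifnot(subject_length > 0)
  if (!all(retained$sseqid == lrac_id))
    stop("retained alignments contain subjects other than lrac_id")
  members <- bins$contig_id[bins$bin_id == bin_id]
  if (!all(retained$qseqid %in% members))
    stop("retained alignments contain queries outside the bin")
  ql <- .resolve_query_lengths(retained, query_lengths)
  pid_hat <- mean(retained$pident) / 100
  al2ql_hat <- mean(retained$length / ql)
  p_srac <- length(unique(retained$qseqid)) / length(members)
  covered <- IRanges::reduce(IRanges::IRanges(retained$sstart, retained$send))
  p_aln <- sum(IRanges::width(covered)) / subject_length
  kappa <- (pid_hat + al2ql_hat + p_srac + p_aln) / 4
  data.frame(lrac_id = lrac_id, bin_id = bin_id, pid_hat = pid_hat,
             al2ql_hat = al2ql_hat, p_srac = p_srac, p_aln = p_aln,
             kappa = kappa, n_alignments = nrow(retained),
             n_contigs_aligned = length(unique(retained$qseqid)),
             n_contigs_total = length(members), filtered = filtered,
             stringsAsFactors = FALSE)
}

#' Concordance statistics for all (bin, LRAC) combinations
#'
#' Deduplicates the alignment table to best hits, optionally applies the
#' near-full-length filter, and computes one [compute_components()] row for
#' every (bin, LRAC) pair with at least one retained alignment. Pairs with
#' no alignments are omitted, not reported as zero; in real communities
#' only a subset of bins produces any alignment against a given LRAC.
#' Queries missing from the bin table are ignored (unbinned contigs).
#'
#' @param alignments Raw alignment data.frame ([read_blast_tab()]).
#' @param bins Bin membership data.frame ([read_bins()]).
#' @param query_lengths Named vector of contig lengths (or `NULL` if the
#'   table carries `qlen`).
#' @param subject_lengths Named vector of LRAC lengths (or `NULL` if the
#'   table carries `slen`).
#' @param filtered Apply the near-full-length (al2ql >= `min_al2ql`)
#'   filter before computing all four components.
#' @param min_al2ql Threshold for the filtered variant.
#' @return Data.frame of concordance results, ordered by `lrac_id` then
#'   `bin_id`.
#' @export
compute_kappa_matrix <- function(alignments, bins, query_lengths = NULL,
                                 subject_lengths = NULL, filtered = FALSE,
                                 min_al2ql = 0.95) {
  retained <- dedup_best_hits(alignments)
  retained <- retained[retained$qseqid %in% bins$contig_id, , drop = FALSE]
  if (filtered)
    retained <- filter_near_full_length(retained, query_lengths, min_al2ql)
  if (nrow(retained) == 0L) return(.empty_kappa_matrix())
  slen <- retained$slen
  if (!is.null(subject_lengths)) {
    idx <- match(retained$sseqid, names(subject_lengths))
    slen <- ifelse(is.na(slen), unname(subject_lengths[idx]), slen)
  }
  if (anyNA(slen))
    stop(sprintf("no subject length known for LRAC '%s'",
                 retained$sseqid[which(is.na(slen))[1]]))
  retained$slen <- slen
  retained$.bin <- bins$bin_id[match(retained$qseqid, bins$contig_id)]
  key <- paste(retained$sseqid, retained$.bin, sep = "\r")
  groups <- split(retained, key)
  rows <- lapply(groups, function(g)
    compute_components(g$.bin[1], g$sseqid[1],
                       g[setdiff(names(g), ".bin")], bins,
                       query_lengths, g$slen[1], filtered = filtered))
  out <- do.call(rbind, rows)
  out <- out[order(out$lrac_id, out$bin_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_kappa_matrix <- function() {
  data.frame(lrac_id = character(), bin_id = character(),
             pid_hat = numeric(), al2ql_hat = numeric(),
             p_srac = numeric(), p_aln = numeric(), kappa = numeric(),
             n_alignments = integer(), n_contigs_aligned = integer(),
             n_contigs_total = integer(), filtered = logical(),
             stringsAsFactors = FALSE)
}

#' Rank candidate cognate bins for an LRAC
#'
#' Orders the bins scored against one LRAC by kappa, descending. The
#' top-ranked bin is the cognate candidate: a kappa near unity implies the
#' LRAC is tiled by that bin's contigs. Ties are broken by higher `p_aln`,
#' then lexicographic `bin_id`.
#'
#' @param results Concordance data.frame ([compute_kappa_matrix()]).
#' @param lrac_id LRAC to rank bins for.
#' @param top_n Maximum number of rows to return (default all).
#' @return The ranked subset of `results`; empty (with a warning) when
#'   `lrac_id` has no scored bins.
#' @export
rank_cognates <- function(results, lrac_id, top_n = Inf) {
  sub <- results[results$lrac_id == lrac_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("no concordance results for LRAC '%s'", lrac_id))
    return(sub)
  }
  sub <- sub[order(-sub$kappa, -sub$p_aln, sub$bin_id), , drop = FALSE]
  if (is.finite(top_n)) sub <- utils::head(sub, top_n)
  rownames(sub) <- NULL
  sub
}
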