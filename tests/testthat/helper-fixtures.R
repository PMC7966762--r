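# Shared fixtures and independent oracles. The oracles deliberately use
# the dumbest correct algorithm available (per-base marking, row-wise
# scans) so they stay independent of the implementation they check.

# Minimal well-formed alignment row(s) in the parsed layout.
make_aln <- function(qseqid, sseqid, pident, length, sstart, send,
                     bitscore = 2 * length, qlen = NA_real_,
                     slen = NA_real_) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0, gapopen = 0, qstart = 1,
             qend = length, sstart = sstart, send = send, evalue = 0,
             bitscore = bitscore, qlen = qlen, slen = slen,
             strand = "+", stringsAsFactors = FALSE)
}

# The hand-computed two-alignment example: bin of 4 contigs, subject 400 bp.
worked_example <- function() {
  aln <- rbind(
    make_aln("ctgA", "lrac1", 98, 100, 1, 100, bitscore = 180, qlen = 100,
             slen = 400),
    make_aln("ctgB", "lrac1", 90, 150, 151, 300, bitscore = 250, qlen = 200,
             slen = 400))
  bins <- data.frame(contig_id = c("ctgA", "ctgB", "ctgC", "ctgD"),
                     bin_id = "bin1", stringsAsFactors = FALSE)
  list(aln = aln, bins = bins)
}

# Per-base brute-force oracle for p_aln: mark every covered subject base.
oracle_p_aln <- function(sstart, send, subject_length) {
  covered <- logical(subject_length)
  for (i in seq_along(sstart)) covered[sstart[i]:send[i]] <- TRUE
  sum(covered) / subject_length
}

# Row-scan oracle for best-hit retention over one (query, subject) pair.
oracle_best_hit <- function(tab) {
  keys <- unique(tab[, c("qseqid", "sseqid")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$qseqid == keys$qseqid[i] & tab$sseqid == keys$sseqid[i],
               , drop = FALSE]
    sub <- sub[sub$bitscore == max(sub$bitscore), , drop = FALSE]
    sub <- sub[sub$length == max(sub$length), , drop = FALSE]
    sub[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out[order(out$qseqid, out$sseqid), , drop = FALSE]
}

# Per-base oracle for anomalous-interval screening.
oracle_intervals <- function(depths, high = 1.5, low = 0.5, min_len = 10) {
  med <- stats::median(depths)
  kind <- character(length(depths))
  kind[depths > high * med] <- "HIGH"
  kind[depths < low * med] <- "LOW"
  out <- data.frame(start = integer(), end = integer(), kind = character())
  i <- 1L
  while (i <= length(depths)) {
    if (kind[i] != "") {
      j <- i
      while (j < length(depths) && kind[j + 1L] == kind[i]) j <- j + 1L
      if (j - i + 1L >= min_len)
        out <- rbind(out, data.frame(start = i, end = j, kind = kind[i]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Simple GC oracle on a character string (N-exclusive).
oracle_gc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  informative <- chars != "N"
  sum(chars %in% c("G", "C")) / sum(informative)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "magconcord", mustWork = TRUE)
}
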