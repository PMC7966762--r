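# Readers and writers for the external formats the toolkit consumes:
# BLAST tabular (outfmt 6, optionally extended with qlen/slen), two-column
# bin membership TSVs, per-base coverage TSVs (bedtools genomecov -d
# dialect), FASTA, genome-quality tables and replicon feature tables.
# All readers validate strictly and fail with the offending line so that
# downstream modules only ever see well-formed records.

#' Standard BLAST outfmt-6 column names
#'
#' The twelve columns of BLAST tabular output in their conventional order.
#' Extended tables append `qlen` and/or `slen`.
#'
#' @return Character vector of column names.
#' @export
blast6_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

.blast6_numeric <- c("pident", "length", "mismatch", "gapopen", "qstart",
                     "qend", "sstart", "send", "evalue", "bitscore",
                     "qlen", "slen")

#' Read a BLAST tabular alignment file
#'
#' Parses tab-separated BLAST output (`-outfmt 6`): the standard twelve
#' columns, optionally extended with query/subject lengths. Subject
#' coordinates written in descending order (reverse-strand alignments) are
#' normalized to `sstart <= send` and flagged in a `strand` column; all the
#' concordance components are strand-agnostic, so only the normalized
#' interval is used downstream.
#'
#' @param path Path to the tab-separated alignment file.
#' @param column_spec Character vector of column names, in file order.
#'   Defaults to the standard twelve ([blast6_columns()]); append `"qlen"`
#'   and/or `"slen"` for extended tables.
#' @return A data.frame with one row per alignment, columns as in
#'   `column_spec` plus `strand` (`"+"`/`"-"`), with `qlen`/`slen` columns
#'   of `NA` when not supplied. An empty file yields a zero-row data.frame.
#' @export
read_blast_tab <- function(path, column_spec = blast6_columns()) {
  if (!all(blast6_columns() %in% column_spec))
    stop("column_spec must contain the 12 standard outfmt-6 columns")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_blast_tab())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col != length(column_spec))
  if (length(bad))
    stop(sprintf("line %d of '%s': expected %d columns, found %d",
                 bad[1], path, length(column_spec), n_col[bad[1]]))
  mat <- matrix(unlist(fields), ncol = length(column_spec), byrow = TRUE)
  colnames(mat) <- column_spec
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (col in intersect(column_spec, .blast6_numeric)) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("line %d of '%s': non-numeric value '%s' in column %s",
                   bad[1], path, tab[[col]][bad[1]], col))
    tab[[col]] <- val
  }
  for (col in c("qlen", "slen"))
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  validate_blast_tab(tab, path)
  normalize_subject_strand(tab)
}

.empty_blast_tab <- function() {
  tab <- as.data.frame(stats::setNames(
    c(rep(list(character()), 2), rep(list(numeric()), 12)),
    c(blast6_columns(), "qlen", "slen")))
  tab$qseqid <- character()
  tab$sseqid <- character()
  tab$strand <- character()
  tab
}

validate_blast_tab <- function(tab, path = "<alignments>") {
  chk <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad)) stop(sprintf("line %d of '%s': %s", bad[1], path, msg))
  }
  chk(tab$pident >= 0 & tab$pident <= 100, "percent identity outside [0,100]")
  chk(tab$length >= 1, "alignment length < 1")
  chk(tab$bitscore >= 0, "negative bit-score")
  chk(tab$evalue >= 0, "negative e-value")
  chk(tab$mismatch >= 0 & tab$gapopen >= 0, "negative mismatch/gapopen count")
  ok_q <- is.na(tab$qlen) |
    (tab$qstart >= 1 & tab$qend >= 1 &
       tab$qstart <= tab$qlen & tab$qend <= tab$qlen)
  chk(ok_q, "query coordinates outside [1, qlen]")
  invisible(tab)
}

normalize_subject_strand <- function(tab) {
  if (!"strand" %in% names(tab)) {
    rev <- tab$sstart > tab$send
    tab$strand <- ifelse(rev, "-", "+")
    if (any(rev)) {
      tmp <- tab$sstart[rev]
      tab$sstart[rev] <- tab$send[rev]
      tab$send[rev] <- tmp
    }
  }
  tab
}

#' Write a BLAST tabular alignment file
#'
#' Inverse of [read_blast_tab()]. Reverse-strand rows (`strand == "-"`) are
#' written with descending subject coordinates, so a read/write cycle is
#' lossless.
#'
#' @param tab Alignment data.frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @param with_lengths Write the `qlen`/`slen` columns (14-column table).
#' @return Invisibly, `path`.
#' @export
write_blast_tab <- function(tab, path, with_lengths = !all(is.na(tab$qlen))) {
  out <- tab
  if ("strand" %in% names(out)) {
    rev <- out$strand == "-"
    if (any(rev)) {
      tmp <- out$sstart[rev]
      out$sstart[rev] <- out$send[rev]
      out$send[rev] <- tmp
    }
  }
  cols <- blast6_columns()
  if (with_lengths) cols <- c(cols, "qlen", "slen")
  utils::write.table(format(out[, cols], trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contig-to-bin membership table
#'
#' Two-column TSV (`contig_id`, `bin_id`), no header. A contig may appear
#' more than once only with an identical bin assignment; conflicting
#' duplicates are an error.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `contig_id` and `bin_id`, one row per
#'   contig, input order preserved (first occurrence).
#' @export
read_bins <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("contig_id", "bin_id"))
  if (nrow(tab) == 0L) stop(sprintf("empty bin table '%s'", path))
  conflict <- stats::aggregate(bin_id ~ contig_id, tab,
                               function(b) length(unique(b)))
  bad <- conflict$contig_id[conflict$bin_id > 1]
  if (length(bad))
    stop(sprintf("contig '%s' assigned to more than one bin in '%s'",
                 bad[1], path))
  tab[!duplicated(tab$contig_id), , drop = FALSE]
}

#' Write a contig-to-bin membership table
#' @param bins data.frame with `contig_id`, `bin_id`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(bins[, c("contig_id", "bin_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-bin contig counts
#' @param bins Bin membership data.frame ([read_bins()]).
#' @return Named integer vector: contigs per bin.
#' @export
bin_sizes <- function(bins) {
  tab <- table(bins$bin_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read per-base coverage profiles
#'
#' Three-column TSV in the `bedtools genomecov -d` dialect: replicon id,
#' 1-based position, integer depth. Positions must be contiguous `1..length`
#' within each replicon; depths must be non-negative integers (real-valued
#' depths are rejected — the format is a per-base count).
#'
#' @param path Path to the TSV.
#' @return Named list of integer depth vectors, one per replicon, names in
#'   order of first appearance.
#' @export
read_coverage_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric"),
                           col.names = c("replicon", "pos", "depth"))
  if (any(tab$depth %% 1 != 0 | tab$depth < 0))
    stop(sprintf("non-integer or negative depth in '%s'", path))
  profiles <- lapply(split(tab, factor(tab$replicon, unique(tab$replicon))),
                     function(d) {
    bad <- which(d$pos != seq_len(nrow(d)))
    if (length(bad))
      stop(sprintf(
        "replicon '%s' in '%s': position %g at row %d (expected %d); %s",
        d$replicon[1], path, d$pos[bad[1]], bad[1], bad[1],
        "positions must be contiguous from 1"))
    as.integer(d$depth)
  })
  profiles
}

#' Write per-base coverage profiles
#' @param profiles Named list of integer depth vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_tsv <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(profiles)) {
    d <- profiles[[id]]
    writeLines(paste(id, seq_along(d), d, sep = "\t"), con)
  }
  invisible(path)
}

#' Read FASTA sequences
#'
#' Sequences are upper-cased and restricted to the `{A,C,G,T,N}` alphabet.
#' A `suggestCircular=yes` token in the header (the long-read assembler's
#' convention for closed replicons) sets the record's `circular` flag.
#'
#' @param path Path to a FASTA file.
#' @return List of records, each a list with `id` (first header word),
#'   `sequence` (upper-case character string) and `circular` (logical).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf(
                    "failed to read FASTA '%s': %s", path, conditionMessage(e))))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("record '%s' in '%s' contains characters outside {A,C,G,T,N}",
                 ids[which(bad)[1]], path))
  if (any(nchar(seqs) == 0L))
    stop(sprintf("record '%s' in '%s' has an empty sequence",
                 ids[which(nchar(seqs) == 0L)[1]], path))
  circ <- grepl("suggestCircular=yes", headers, fixed = TRUE)
  mapply(function(i, s, cc) list(id = i, sequence = s, circular = cc),
         ids, seqs, circ, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write FASTA sequences
#'
#' Circular records are written with a `suggestCircular=yes` header token so
#' the flag round-trips through [read_fasta()].
#'
#' @param records List of sequence records (`id`, `sequence`, `circular`).
#' @param path Output path.
#' @param line_width Characters per sequence line.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  ids <- vapply(records, `[[`, "", "id")
  circ <- vapply(records, function(r) isTRUE(r$circular), logical(1))
  names(seqs) <- ifelse(circ, paste(ids, "suggestCircular=yes"), ids)
  Biostrings::writeXStringSet(seqs, path, width = line_width)
  invisible(path)
}

#' Named sequence lengths
#' @param records List of sequence records from [read_fasta()].
#' @return Named integer vector of sequence lengths.
#' @export
sequence_lengths <- function(records) {
  stats::setNames(vapply(records, function(r) nchar(r$sequence), integer(1)),
                  vapply(records, `[[`, "", "id"))
}

.correction_methods <- c("uncorrected", "megan_lr", "medaka", "racon",
                         "multiple", "none")

#' Read a genome-quality table
#'
#' TSV with header `genome_id`, `completeness`, `contamination`,
#' `correction_method` (extra columns are preserved). Completeness is a
#' percentage in `[0,100]`; contamination a percentage `>= 0`.
#'
#' @param path Path to the TSV.
#' @return Validated data.frame.
#' @export
read_quality_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "completeness", "contamination", "correction_method")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("'%s' lacks column(s): %s", path, paste(miss, collapse = ", ")))
  bad <- which(tab$completeness < 0 | tab$completeness > 100 |
                 is.na(tab$completeness))
  if (length(bad))
    stop(sprintf("row %d of '%s': completeness %s outside [0,100]",
                 bad[1], path, tab$completeness[bad[1]]))
  bad <- which(tab$contamination < 0 | is.na(tab$contamination))
  if (length(bad))
    stop(sprintf("row %d of '%s': negative contamination", bad[1], path))
  bad <- which(!tab$correction_method %in% .correction_methods)
  if (length(bad))
    stop(sprintf("row %d of '%s': unknown correction method '%s'",
                 bad[1], path, tab$correction_method[bad[1]]))
  tab
}

#' Write a tabular report
#'
#' All report writers share one dialect: TSV with a header line, fixed
#' column order as given, and numeric columns formatted to two decimals so
#' that reruns are diffable byte for byte.
#'
#' @param rows data.frame to write.
#' @param path Output path.
#' @param digits Decimal places for numeric (non-integer) columns.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, digits = 2L) {
  out <- rows
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- sprintf(paste0("%.", digits, "f"), out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.marker_flags <- c("T4SS", "plasmid_replication", "viral_marker",
                   "hypothetical")
.viral_calls <- c("none", "virus", "prophage")

#' Read replicon feature tables
#'
#' Annotation evidence for circular replicon triage comes as two TSVs: a
#' replicon-level table (`replicon_id`, `length_bp`, `circular`,
#' `n_rrna_operons`, `n_trna`, `external_viral_call`) and a per-gene table
#' (`replicon_id`, `gene_id`, `product`, `markers` — comma-separated subset
#' of `T4SS`, `plasmid_replication`, `viral_marker`, `hypothetical`, or
#' empty).
#'
#' @param replicon_path Path to the replicon-level TSV.
#' @param genes_path Path to the per-gene TSV.
#' @return List of feature tables, one per replicon, each a list with the
#'   replicon-level fields plus `genes` (data.frame `gene_id`, `product`,
#'   `markers` list-column).
#' @export
read_feature_table <- function(replicon_path, genes_path) {
  rep_tab <- utils::read.delim(replicon_path, stringsAsFactors = FALSE)
  need <- c("replicon_id", "length_bp", "circular", "n_rrna_operons",
            "n_trna", "external_viral_call")
  miss <- setdiff(need, names(rep_tab))
  if (length(miss))
    stop(sprintf("'%s' lacks column(s): %s", replicon_path,
                 paste(miss, collapse = ", ")))
  if (any(rep_tab$n_rrna_operons < 0 | rep_tab$n_trna < 0))
    stop("negative rRNA/tRNA counts")
  bad <- which(!rep_tab$external_viral_call %in% .viral_calls)
  if (length(bad))
    stop(sprintf("row %d of '%s': unknown viral call '%s'", bad[1],
                 replicon_path, rep_tab$external_viral_call[bad[1]]))
  gene_tab <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  gneed <- c("replicon_id", "gene_id", "product", "markers")
  miss <- setdiff(gneed, names(gene_tab))
  if (length(miss))
    stop(sprintf("'%s' lacks column(s): %s", genes_path,
                 paste(miss, collapse = ", ")))
  gene_tab$markers <- lapply(strsplit(gene_tab$markers, ",", fixed = TRUE),
                             function(m) m[nzchar(m)])
  bad_flag <- setdiff(unlist(gene_tab$markers), .marker_flags)
  if (length(bad_flag))
    stop(sprintf("unknown marker flag '%s' in '%s'", bad_flag[1], genes_path))
  lapply(seq_len(nrow(rep_tab)), function(i) {
    genes <- gene_tab[gene_tab$replicon_id == rep_tab$replicon_id[i],
                      c("gene_id", "product", "markers")]
    rownames(genes) <- NULL
    list(replicon_id = rep_tab$replicon_id[i],
         length_bp = rep_tab$length_bp[i],
         circular = as.logical(rep_tab$circular[i]),
         n_rrna_operons = rep_tab$n_rrna_operons[i],
         n_trna = rep_tab$n_trna[i],
         external_viral_call = rep_tab$external_viral_call[i],
         genes = genes)
  })
}

#' Write replicon feature tables
#' @param tables List of feature tables ([read_feature_table()] layout).
#' @param replicon_path,genes_path Output paths for the two TSVs.
#' @return Invisibly, `replicon_path`.
#' @export
write_feature_table <- function(tables, replicon_path, genes_path) {
  rep_tab <- do.call(rbind, lapply(tables, function(f)
    data.frame(replicon_id = f$replicon_id, length_bp = f$length_bp,
               circular = f$circular, n_rrna_operons = f$n_rrna_operons,
               n_trna = f$n_trna,
               external_viral_call = f$external_viral_call)))
  utils::write.table(rep_tab, replicon_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  gene_rows <- lapply(tables, function(f) {
    if (nrow(f$genes) == 0L) return(NULL)
    data.frame(replicon_id = f$replicon_id, gene_id = f$genes$gene_id,
               product = f$genes$product,
               markers = vapply(f$genes$markers, paste, "", collapse = ","))
  })
  gene_tab <- do.call(rbind, gene_rows)
  if (is.null(gene_tab))
    gene_tab <- data.frame(replicon_id = character(), gene_id = character(),
                           product = character(), markers = character())
  utils::write.table(gene_tab, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(replicon_path)
}
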