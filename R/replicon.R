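# Rule-based triage of circular contigs shorter than 1 Mbp. A circular
# replicon recovered from a metagenome assembly may be a small microbial
# genome (e.g. Patescibacteria at ~850 kb), a chromid, a virus or phage, a
# conjugative or ordinary plasmid, or an artefactually circularised
# fragment. The classifier applies an ordered evidence cascade:
#
#   R1 length >= 1 Mbp                                -> PUTATIVE_CHROMOSOME
#   R2 rRNA operon present, tRNAs >= threshold        -> SMALL_GENOME
#   R3 rRNA operon present, tRNAs <  threshold        -> CHROMID
#   R4 short, all genes hypothetical, no viral call   -> ARTEFACTUAL_FRAGMENT
#   R5 external viral classifier: virus / prophage    -> VIRUS_PHAGE /
#                                                        PROPHAGE_HOST
#   R6 T4SS + plasmid-replication markers             -> CONJUGATIVE_PLASMID
#   R7 otherwise                                      -> PLASMID
#
# An rRNA operon deliberately outranks a viral verdict (R3 before R5): a
# replicon carrying core translation machinery alongside viral signal is
# better read as a chromid hosting a prophage than as a free virus.

.replicon_classes <- c("PUTATIVE_CHROMOSOME", "SMALL_GENOME", "CHROMID",
                       "VIRUS_PHAGE", "PROPHAGE_HOST", "CONJUGATIVE_PLASMID",
                       "PLASMID", "ARTEFACTUAL_FRAGMENT")

#' Replicon class levels
#' @return Character vector of the eight possible triage classes.
#' @export
replicon_classes <- function() .replicon_classes

#' Screen a gene list against marker sets
#'
#' Exact string membership of annotation identifiers in named marker sets
#' (e.g. T4SS components, plasmid replication genes, viral hallmark genes).
#'
#' @param genes Character vector of gene annotation identifiers.
#' @param marker_sets Named list of character vectors; each must be
#'   non-empty.
#' @return Named logical vector: does any gene hit each set?
#' @export
marker_gene_screen <- function(genes, marker_sets) {
  if (length(marker_sets) == 0L || any(lengths(marker_sets) == 0L))
    stop("every marker set must contain at least one identifier")
  vapply(marker_sets, function(set) any(genes %in% set), logical(1))
}

.gene_is_hypothetical <- function(genes) {
  flag <- vapply(genes$markers, function(m) "hypothetical" %in% m, logical(1))
  flag | grepl("hypothetical", genes$product, ignore.case = TRUE)
}

.gene_has_flag <- function(genes, flag) {
  any(vapply(genes$markers, function(m) flag %in% m, logical(1)))
}

#' Classify one circular replicon
#'
#' Applies the ordered rule cascade (see the class-level comments) to a
#' feature table. Non-circular inputs are not triage candidates and are
#' rejected with a warning (`NULL` return).
#'
#' @param feature Feature table for one replicon
#'   ([read_feature_table()] element).
#' @param trna_small_genome_min tRNA count at or above which an
#'   rRNA-operon-bearing replicon is called a small genome rather than a
#'   chromid. Default 20: observed exemplars carry 46 (small genome)
#'   versus 8 and 3 (chromids).
#' @param artefact_max_length Maximum length of an "extremely short"
#'   fragment eligible for the artefact rule (default 20,000 bp).
#' @return List with `replicon_id`, `class`, `rule_fired` (`"R1"`–`"R7"`)
#'   and `evidence` (the counts/flags the decision used), or `NULL` for a
#'   rejected non-circular input.
#' @export
classify_replicon <- function(feature, trna_small_genome_min = 20L,
                              artefact_max_length = 20000L) {
  if (!isTRUE(feature$circular)) {
    warning(sprintf("replicon '%s' is not circular: not a triage candidate",
                    feature$replicon_id))
    return(NULL)
  }
  genes <- feature$genes
  evidence <- list(length_bp = feature$length_bp,
                   n_rrna_operons = feature$n_rrna_operons,
                   n_trna = feature$n_trna,
                   external_viral_call = feature$external_viral_call,
                   n_genes = nrow(genes),
                   all_hypothetical = nrow(genes) > 0L &&
                     all(.gene_is_hypothetical(genes)),
                   has_t4ss = .gene_has_flag(genes, "T4SS"),
                   has_plasmid_replication =
                     .gene_has_flag(genes, "plasmid_replication"))
  pick <- function(class, rule)
    list(replicon_id = feature$replicon_id, class = class,
         rule_fired = rule, evidence = evidence)
  if (feature$length_bp >= 1e6)
    return(pick("PUTATIVE_CHROMOSOME", "R1"))
  if (feature$n_rrna_operons >= 1) {
    if (feature$n_trna >= trna_small_genome_min)
      return(pick("SMALL_GENOME", "R2"))
    return(pick("CHROMID", "R3"))
  }
  if (feature$length_bp <= artefact_max_length &&
      evidence$all_hypothetical &&
      feature$external_viral_call == "none")
    return(pick("ARTEFACTUAL_FRAGMENT", "R4"))
  if (feature$external_viral_call == "virus")
    return(pick("VIRUS_PHAGE", "R5"))
  if (feature$external_viral_call == "prophage")
    return(pick("PROPHAGE_HOST", "R5"))
  if (evidence$has_t4ss && evidence$has_plasmid_replication)
    return(pick("CONJUGATIVE_PLASMID", "R6"))
  pick("PLASMID", "R7")
}

#' Classify a panel of replicons
#'
#' Runs [classify_replicon()] over every feature table and tallies the
#' classes. Non-circular entries are skipped (with their warnings).
#'
#' @param features List of feature tables.
#' @param trna_small_genome_min,artefact_max_length Passed through.
#' @return List with `calls` (data.frame `replicon_id`, `length_bp`,
#'   `class`, `rule_fired`, ordered by `replicon_id`) and `tally` (named
#'   integer vector over [replicon_classes()]).
#' @export
classify_all <- function(features, trna_small_genome_min = 20L,
                         artefact_max_length = 20000L) {
  if (length(features) == 0L) stop("no feature tables supplied")
  calls <- lapply(features, classify_replicon,
                  trna_small_genome_min = trna_small_genome_min,
                  artefact_max_length = artefact_max_length)
  calls <- calls[!vapply(calls, is.null, logical(1))]
  tab <- do.call(rbind, lapply(calls, function(cl)
    data.frame(replicon_id = cl$replicon_id,
               length_bp = cl$evidence$length_bp, class = cl$class,
               rule_fired = cl$rule_fired, stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(replicon_id = character(), length_bp = numeric(),
                      class = character(), rule_fired = character())
  tab <- tab[order(tab$replicon_id), , drop = FALSE]
  rownames(tab) <- NULL
  tally <- table(factor(tab$class, levels = .replicon_classes))
  list(calls = tab, tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Read marker sets from a directory
#'
#' Each `<name>.txt` file holds one annotation identifier per line (blank
#' lines and `#` comments ignored); the file stem names the set. Marker
#' sets ship as editable text so the screen can track whatever annotation
#' vocabulary is in use.
#'
#' @param dir Directory of marker files.
#' @return Named list of character vectors.
#' @export
read_marker_sets <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop(sprintf("no marker files in '%s'", dir))
  sets <- lapply(files, function(f) {
    x <- trimws(readLines(f))
    x[nzchar(x) & !startsWith(x, "#")]
  })
  names(sets) <- tools::file_path_sans_ext(basename(files))
  sets
}
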