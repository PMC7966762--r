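# Coverage-based mis-assembly screening. Chimeric joins and collapsed
# repeats leave footprints in the per-base depth profile: runs where depth
# drops below half, or rises above one and a half times, the replicon
# median. Windowed GC content supports the same visual inspection of
# composition shifts along a replicon.

#' Flag anomalous-coverage intervals
#'
#' Screens one per-base depth profile for genomic intervals of at least
#' `min_length` bp whose depth is abnormally high (`> high_factor` times
#' the median, strict) or abnormally low (`< low_factor` times the median,
#' strict). The median is taken over all positions, zeros included. Maximal
#' runs of consecutive same-kind positions are merged; a HIGH position
#' adjacent to a LOW position terminates both runs. Runs shorter than
#' `min_length` are discarded.
#'
#' @param depths Integer vector of per-base depths (one replicon), or a
#'   single-element named list as returned by [read_coverage_tsv()].
#' @param replicon_id Identifier echoed into the output (defaults to the
#'   list name when `depths` is a list).
#' @param high_factor,low_factor Multiples of the median defining
#'   abnormally high / low depth.
#' @param min_length Minimum interval length in bp.
#' @return Data.frame `replicon_id`, `start`, `end` (1-based inclusive),
#'   `kind` (`"HIGH"`/`"LOW"`), `median_depth`, `extreme_depth` (max depth
#'   inside a HIGH interval, min inside a LOW), sorted by `start`.
#' @export
flag_anomalous_intervals <- function(depths, replicon_id = "replicon",
                                     high_factor = 1.5, low_factor = 0.5,
                                     min_length = 10L) {
  if (is.list(depths)) {
    if (length(depths) != 1L)
      stop("pass one profile at a time (got a list of ", length(depths), ")")
    replicon_id <- names(depths)
    depths <- depths[[1]]
  }
  if (length(depths) == 0L) stop("empty coverage profile")
  med <- stats::median(depths)
  if (med == 0)
    stop(sprintf("profile '%s' has median depth 0: unusable for screening",
                 replicon_id))
  kind <- character(length(depths))
  kind[depths > high_factor * med] <- "HIGH"
  kind[depths < low_factor * med] <- "LOW"
  runs <- rle(kind)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != "" & runs$lengths >= min_length
  if (!any(keep)) return(.empty_intervals())
  out <- data.frame(replicon_id = replicon_id, start = starts[keep],
                    end = ends[keep], kind = runs$values[keep],
                    median_depth = med, stringsAsFactors = FALSE)
  out$extreme_depth <- mapply(function(s, e, k) {
    if (k == "HIGH") max(depths[s:e]) else min(depths[s:e])
  }, out$start, out$end, out$kind)
  out[order(out$start), , drop = FALSE]
}

.empty_intervals <- function() {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             kind = character(), median_depth = numeric(),
             extreme_depth = numeric(), stringsAsFactors = FALSE)
}

#' Windowed GC content along a sequence
#'
#' GC content in adjacent, non-overlapping windows. The final partial
#' window is retained with its true (shorter) length. `N` bases are
#' excluded from both numerator and denominator; a window consisting
#' entirely of `N` has undefined GC and is omitted with a warning.
#'
#' @param record Sequence record (list with `id`, `sequence`) or a plain
#'   character string.
#' @param window_length Window size in bp (>= 1).
#' @return Data.frame `replicon_id`, `start`, `end` (1-based inclusive),
#'   `window_length` (actual bases in the window), `gc` (proportion).
#' @export
compute_gc_windows <- function(record, window_length) {
  stopifnot(window_length >= 1)
  if (is.character(record)) record <- list(id = "seq", sequence = record)
  seq <- Biostrings::DNAString(record$sequence)
  n <- length(seq)
  starts <- seq.int(1L, n, by = window_length)
  ends <- pmin(starts + window_length - 1L, n)
  views <- Biostrings::Views(seq, start = starts, end = ends)
  freq <- Biostrings::letterFrequency(views, c("G", "C", "N"))
  informative <- (ends - starts + 1L) - freq[, "N"]
  gc <- ifelse(informative > 0, (freq[, "G"] + freq[, "C"]) / informative,
               NA_real_)
  out <- data.frame(replicon_id = record$id, start = starts, end = ends,
                    window_length = ends - starts + 1L, gc = gc,
                    stringsAsFactors = FALSE)
  if (anyNA(out$gc)) {
    warning(sprintf("%d all-N window(s) omitted for '%s'",
                    sum(is.na(out$gc)), record$id))
    out <- out[!is.na(out$gc), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Mean depth in contiguous bins
#'
#' Reduces a per-base profile to `n_bins` contiguous bins of near-equal
#' width (bin `i` spans positions `floor((i-1)*L/n)+1 .. floor(i*L/n)`),
#' reporting the mean depth per bin. Used to draw coverage tracks at
#' plottable resolution.
#'
#' @param depths Integer vector of per-base depths.
#' @param n_bins Number of bins, between 1 and `length(depths)`.
#' @return Data.frame `start`, `end`, `mean_depth`.
#' @export
binned_coverage <- function(depths, n_bins) {
  L <- length(depths)
  stopifnot(n_bins >= 1, n_bins <= L)
  bounds <- floor(seq_len(n_bins) * L / n_bins)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  means <- vapply(seq_len(n_bins), function(i)
    mean(depths[starts[i]:bounds[i]]), numeric(1))
  data.frame(start = starts, end = as.integer(bounds), mean_depth = means)
}
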