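#' Strand call from an alignment flag word
#'
#' Implements the flag-filter convention used for strand-specific paired-end
#' libraries: a fragment is called *reverse* when its flag contains bitmask
#' 80 or 160, and *forward* when it contains 96 or 144. Matching is bitmask
#' containment (`bitwAnd(flag, mask) == mask`), mirroring samtools
#' `-f`-style flag filters; reverse masks take precedence. Flags matching
#' neither family return `"unassigned"`.
#'
#' @param flag Integer vector of SAM-style flag words (>= 0).
#' @return Character vector in `{"forward", "reverse", "unassigned"}`.
#' @examples
#' fragment_strand_from_flag(c(80, 96, 99, 16))
#' @export
fragment_strand_from_flag <- function(flag) {
  if (any(flag < 0)) stop("flags must be non-negative")
  flag <- as.integer(flag)
  rev_hit <- bitwAnd(flag, 80L) == 80L | bitwAnd(flag, 160L) == 160L
  fwd_hit <- bitwAnd(flag, 96L) == 96L | bitwAnd(flag, 144L) == 144L
  out <- rep("unassigned", length(flag))
  out[fwd_hit] <- "forward"
  out[rev_hit] <- "reverse"  # reverse masks take precedence
  out
}

#' Bin fragments into a stranded coverage track
#'
#' Each fragment adds its per-bin overlap length (in bases) to the track of
#' its strand, so total binned signal per strand equals total covered bases.
#' Strand is taken from the `strand` column if present (values `"forward"`/
#' `"reverse"`), otherwise derived from the `flag` column via
#' [fragment_strand_from_flag()]. Unassigned fragments are skipped.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (half-open, 0-based) and either `strand` or `flag`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param strand_invert If `TRUE`, route forward fragments to Crick and
#'   reverse to Watson (library-chemistry switch). Default `FALSE`:
#'   forward -> Watson, reverse -> Crick.
#' @return A [stranded_track()].
#' @export
bin_fragments <- function(fragments, chrom_sizes, bin_size,
                          strand_invert = FALSE) {
  stopifnot(is.data.frame(fragments))
  if (nrow(fragments) > 0 && any(fragments$start >= fragments$end)) {
    stop("fragments must satisfy start < end")
  }
  if (!"strand" %in% names(fragments)) {
    if (!"flag" %in% names(fragments)) {
      stop("fragments need a 'strand' or 'flag' column")
    }
    fragments$strand <- fragment_strand_from_flag(fragments$flag)
  }
  track <- stranded_track(chrom_sizes, bin_size)
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    if (fr$strand == "unassigned") next
    check_chrom(track, fr$chrom)
    if (fr$start < 0 || fr$end > chrom_sizes[[fr$chrom]]) {
      stop("fragment [", fr$start, ",", fr$end, ") beyond ", fr$chrom,
           " bounds")
    }
    first <- floor(fr$start / bin_size) + 1L
    last <- floor((fr$end - 1) / bin_size) + 1L
    idx <- first:last
    ov <- pmin(idx * bin_size, fr$end) - pmax((idx - 1L) * bin_size, fr$start)
    dest <- if (xor(fr$strand == "forward", strand_invert)) "watson" else "crick"
    track[[dest]][[fr$chrom]][idx] <- track[[dest]][[fr$chrom]][idx] + ov
  }
  track
}

#' Spike-in scale factor
#'
#' Returns `1e6 / n_spike_reads`, the scaling applied to coverage tracks
#' from libraries carrying an exogenous spike-in genome (e.g. Drosophila
#' dm6 for qDRIP-seq, S. cerevisiae for TT-seq): doubling the spike read
#' count halves the factor.
#'
#' @param n_spike_reads Number of reads mapped to the spike-in genome (> 0).
#' @return Positive scale factor.
#' @examples
#' spike_in_factor(1e6)  # 1
#' spike_in_factor(2e6)  # 0.5
#' @export
spike_in_factor <- function(n_spike_reads) {
  if (length(n_spike_reads) != 1L || !is.finite(n_spike_reads) ||
      n_spike_reads <= 0) {
    stop("n_spike_reads must be a single positive number")
  }
  1e6 / n_spike_reads
}

track_granges <- function(track, strand) {
  grl <- list()
  for (chr in names(track$chrom_sizes)) {
    v <- track[[strand]][[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    gstart <- (starts[keep] - 1L) * track$bin_size
    gend <- pmin(ends[keep] * track$bin_size, track$chrom_sizes[[chr]])
    grl[[chr]] <- GenomicRanges::GRanges(
      seqnames = chr,
      ranges = IRanges::IRanges(start = gstart + 1L, end = gend),
      score = r$values[keep]
    )
  }
  if (length(grl) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  do.call(c, unname(grl))
}

#' Write a stranded track as a bedGraph pair
#'
#' Emits `<prefix>_watson.bedGraph` and `<prefix>_crick.bedGraph`; runs of
#' equal-value bins are merged into single bedGraph lines and zero runs are
#' omitted, so a write/load round trip is lossless at bin resolution.
#'
#' @param track A [stranded_track()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_stranded_track <- function(track, prefix) {
  stopifnot(is_stranded_track(track))
  paths <- c(watson = paste0(prefix, "_watson.bedGraph"),
             crick = paste0(prefix, "_crick.bedGraph"))
  for (s in c("watson", "crick")) {
    gr <- track_granges(track, s)
    rtracklayer::export(gr, paths[[s]], format = "bedGraph")
  }
  invisible(paths)
}

bedgraph_to_bins <- function(path, chrom_sizes, bin_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 1) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0) stop("overlapping bedGraph intervals in ", path)
  }
  nbins <- ceiling(chrom_sizes / bin_size)
  out <- lapply(nbins, function(n) numeric(n))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
  ends <- GenomicRanges::end(gr)
  scores <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) {
    chr <- chroms[i]
    if (!chr %in% names(chrom_sizes)) {
      stop("bedGraph chromosome ", chr, " not in chrom_sizes")
    }
    if (ends[i] > chrom_sizes[[chr]]) {
      stop("bedGraph interval beyond ", chr, " bounds in ", path)
    }
    first <- floor(starts[i] / bin_size) + 1L
    last <- floor((ends[i] - 1) / bin_size) + 1L
    idx <- first:last
    ov <- pmin(idx * bin_size, ends[i]) - pmax((idx - 1L) * bin_size, starts[i])
    out[[chr]][idx] <- out[[chr]][idx] + scores[i] * ov / bin_size
  }
  out
}

#' Load a stranded track from a bedGraph pair
#'
#' Bin values are reconstructed as the overlap-weighted mean of interval
#' scores per bin (uncovered regions count as zero), so bin-aligned
#' bedGraphs — in particular anything produced by
#' [write_stranded_track()] — round-trip exactly.
#'
#' @param watson_path,crick_path bedGraph files for the two strands.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param norm Normalization tag to attach (see [stranded_track()]).
#' @return A [stranded_track()].
#' @export
load_stranded_track <- function(watson_path, crick_path, chrom_sizes,
                                bin_size,
                                norm = list(kind = "raw", factor = 1)) {
  track <- stranded_track(chrom_sizes, bin_size, norm = norm)
  track$watson <- bedgraph_to_bins(watson_path, chrom_sizes, bin_size)
  track$crick <- bedgraph_to_bins(crick_path, chrom_sizes, bin_size)
  track
}
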