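#' TSS-anchored metagene matrix
#'
#' Builds the 180-column metagene layout used for damage-aware scale
#' factors: 40 upstream flank bins of 50 bp (-2 kb to the TSS), 100
#' length-proportional gene-body bins, and 40 downstream flank bins of
#' 50 bp past the TES. Cells hold the mean per-bin track signal over each
#' region; rows of `-` genes are flipped so column 1 is always the most
#' upstream. Genes shorter than `min_length` are skipped with a warning.
#'
#' @param track A [stranded_track()].
#' @param genes A [gene_table()].
#' @param strands Which strand signal to use (summed for `"both"`).
#' @param flank Flank width in bp (default 2000).
#' @param flank_bins,body_bins Bin counts (defaults 40 and 100).
#' @param min_length Minimum gene length in bp (default 100).
#' @return genes x `(2 * flank_bins + body_bins)` matrix, rownames
#'   `gene_id`.
#' @export
metagene_matrix <- function(track, genes,
                            strands = c("both", "watson", "crick"),
                            flank = 2000, flank_bins = 40, body_bins = 100,
                            min_length = 100) {
  strands <- match.arg(strands)
  short <- (genes$end - genes$start) < min_length
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", min_length, " bp skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  ncols <- 2L * flank_bins + body_bins
  out <- matrix(NA_real_, nrow(genes), ncols,
                dimnames = list(genes$gene_id, NULL))
  fw <- flank / flank_bins
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    check_chrom(track, g$chrom)
    vecs <- strand_vectors(track, g$chrom, strands)
    vec <- Reduce(`+`, vecs)
    size <- track$chrom_sizes[[g$chrom]]
    if (g$start - flank < 0 || g$end + flank > size) {
      stop("gene ", g$gene_id, " metagene layout exceeds ", g$chrom,
           " bounds")
    }
    # region boundaries in transcription order
    if (g$strand == "+") {
      up <- seq(g$start - flank, g$start, by = fw)
      body <- seq(g$start, g$end, length.out = body_bins + 1)
      down <- seq(g$end, g$end + flank, by = fw)
      bounds <- c(up, body[-1], down[-1])
      vals <- vapply(seq_len(ncols), function(j) {
        region_signal(vec, track$bin_size, bounds[j], bounds[j + 1], "mean")
      }, numeric(1))
    } else {
      up <- seq(g$end + flank, g$end, by = -fw)
      body <- seq(g$end, g$start, length.out = body_bins + 1)
      down <- seq(g$start, g$start - flank, by = -fw)
      bounds <- c(up, body[-1], down[-1])
      vals <- vapply(seq_len(ncols), function(j) {
        region_signal(vec, track$bin_size, bounds[j + 1], bounds[j], "mean")
      }, numeric(1))
    }
    out[i, ] <- vals
  }
  structure(out, flank_bins = flank_bins, body_bins = body_bins,
            flank = flank)
}

#' Scale-factor object
#'
#' @param value Positive scale factor.
#' @param kind One of `"tss_metagene"`, `"spike_in"`, `"total_count"`.
#' @param provenance Free-text provenance note.
#' @return List of class `scale_factor`.
#' @export
scale_factor <- function(value, kind = c("tss_metagene", "spike_in",
                                         "total_count"),
                         provenance = "") {
  kind <- match.arg(kind)
  if (!is.finite(value) || value <= 0) stop("scale factor must be > 0")
  structure(list(value = value, kind = kind, provenance = provenance),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  cat("scale_factor(", x$kind, ") = ", signif(x$value, 6), "\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' TSS-metagene scale factor for damage-aware normalization
#'
#' Global transcriptional repression after damage lowers polymerase
#' occupancy genome-wide; dividing the damaged-condition track by this
#' factor equalizes average TSS occupancy so that DSB-local changes stand
#' out. The factor is the mean signal over metagene columns `tss_bins`
#' (1-based; default 30-50, i.e. -550 bp to +10% of the gene body around
#' the TSS) in the `+`DSB matrix divided by the same mean in the `-`DSB
#' matrix.
#'
#' @param matrix_plus,matrix_minus Metagene matrices from
#'   [metagene_matrix()] over the same genes and layout.
#' @param tss_bins Column indices to average (default `30:50`).
#' @return A [scale_factor()] of kind `"tss_metagene"`.
#' @export
tss_scale_factor <- function(matrix_plus, matrix_minus, tss_bins = 30:50) {
  if (!identical(dim(matrix_plus), dim(matrix_minus))) {
    stop("metagene matrices must share gene set and layout")
  }
  num <- mean(matrix_plus[, tss_bins])
  den <- mean(matrix_minus[, tss_bins])
  if (!is.finite(den) || den == 0) stop("-DSB TSS mean is zero")
  scale_factor(num / den, "tss_metagene",
               provenance = sprintf(
                 "mean(+DSB)/mean(-DSB) over metagene bins %d-%d; applied by dividing the +DSB track",
                 min(tss_bins), max(tss_bins)))
}

#' Apply a scale factor to a track
#'
#' Every bin value is divided by the factor (the damaged/numerator
#' condition is the one that gets divided); the track's normalization
#' provenance is updated.
#'
#' @param track A [stranded_track()].
#' @param factor A [scale_factor()] or a single positive number.
#' @return The rescaled track.
#' @export
apply_scale <- function(track, factor) {
  if (inherits(factor, "scale_factor")) {
    kind <- factor$kind
    value <- factor$value
  } else {
    kind <- "total_count"
    value <- as.numeric(factor)
  }
  if (!is.finite(value) || value <= 0) stop("scale factor must be > 0")
  track <- track_map(track, function(v) v / value)
  track$norm <- list(kind = if (kind == "tss_metagene") "tss_scaled" else kind,
                     factor = value)
  track
}

#' Log2 fold-change ratio track
#'
#' Per bin and strand, `log2((a + pseudocount) / (b + pseudocount))`; the
#' pseudocount bounds the ratio at zero-coverage bins. Inputs must be
#' non-negative and share the binning.
#'
#' @param track_a,track_b [stranded_track()]s (numerator, denominator).
#' @param pseudocount Positive pseudocount (default 1).
#' @return Signed [stranded_track()] with norm kind `"log2_ratio"`.
#' @export
log2_ratio <- function(track_a, track_b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  neg <- function(tr) any(vapply(c(tr$watson, tr$crick),
                                 function(v) any(v < 0), logical(1)))
  if (neg(track_a) || neg(track_b)) {
    stop("log2_ratio requires non-negative input tracks")
  }
  out <- track_map2(track_a, track_b, function(a, b) {
    log2((a + pseudocount) / (b + pseudocount))
  })
  out$norm <- list(kind = "log2_ratio", factor = pseudocount)
  out
}
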