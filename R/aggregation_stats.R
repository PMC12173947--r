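#' Anchor-centred profile matrix
#'
#' One row per anchor (DSB cut or TSS), columns covering
#' `[anchor - halfwidth, anchor + halfwidth)` in fixed-width bins; cells
#' are the mean per-bin track signal over each output bin. Anchors whose
#' window runs off a chromosome are dropped with a warning.
#'
#' @param track A [stranded_track()].
#' @param anchors data.frame with `chrom` and an anchor coordinate column
#'   (`cut` or `pos`), optionally an id column (`dsb_id` or `id`).
#' @param halfwidth Window half-width in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size Output bin width; multiple of the track bin size
#'   (default: the track's).
#' @param strands `"both"` (summed), `"watson"` or `"crick"`.
#' @param condition Optional condition label stored as an attribute.
#' @return Matrix with attributes `bin_size`, `halfwidth`, `strands`,
#'   `condition`, `anchor_col` (the central bin index).
#' @export
profile_matrix <- function(track, anchors, halfwidth,
                           bin_size = track$bin_size,
                           strands = c("both", "watson", "crick"),
                           condition = NULL) {
  strands <- match.arg(strands)
  if (halfwidth %% bin_size != 0) {
    stop("halfwidth must be a multiple of bin_size")
  }
  if (bin_size %% track$bin_size != 0) {
    stop("bin_size must be a multiple of the track bin size")
  }
  pos <- if ("cut" %in% names(anchors)) anchors$cut else anchors$pos
  ids <- if ("dsb_id" %in% names(anchors)) anchors$dsb_id
         else if ("id" %in% names(anchors)) anchors$id
         else as.character(seq_along(pos))
  keep <- vapply(seq_len(nrow(anchors)), function(i) {
    check_chrom(track, anchors$chrom[i])
    pos[i] - halfwidth >= 0 &&
      pos[i] + halfwidth <= track$chrom_sizes[[anchors$chrom[i]]]
  }, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " anchor(s) too close to a chromosome edge dropped")
  }
  anchors <- anchors[keep, , drop = FALSE]
  pos <- pos[keep]
  ids <- ids[keep]
  nb <- as.integer(2 * halfwidth / bin_size)
  out <- matrix(NA_real_, length(pos), nb, dimnames = list(ids, NULL))
  for (i in seq_along(pos)) {
    vecs <- strand_vectors(track, anchors$chrom[i], strands)
    vec <- Reduce(`+`, vecs)
    starts <- pos[i] - halfwidth + (seq_len(nb) - 1L) * bin_size
    out[i, ] <- vapply(seq_len(nb), function(j) {
      region_signal(vec, track$bin_size, starts[j], starts[j] + bin_size,
                    "mean")
    }, numeric(1))
  }
  structure(out, bin_size = bin_size, halfwidth = halfwidth,
            strands = strands, condition = condition,
            anchor_col = as.integer(halfwidth / bin_size))
}

#' Column-wise (trimmed) mean profile
#'
#' @param matrix Profile or metagene matrix.
#' @param trim_fraction Fraction trimmed from each tail per column
#'   (default 0 = plain mean; the DRB/TT-seq metagene convention is 0.01).
#' @return Numeric vector, one value per column.
#' @export
average_profile <- function(matrix, trim_fraction = 0) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0) {
    stop("average_profile needs a non-empty matrix")
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  apply(matrix, 2, mean, trim = trim_fraction)
}

#' Windowed signal per anchor
#'
#' Summed track signal over `[anchor - halfwidth, anchor + halfwidth)` on
#' the selected strands (partial track bins prorated by overlap). Sums
#' rather than means are reported; the two differ only by the constant
#' window size.
#'
#' @inheritParams profile_matrix
#' @return Named numeric vector, one value per retained anchor.
#' @export
window_signal <- function(track, anchors, halfwidth,
                          strands = c("both", "watson", "crick")) {
  strands <- match.arg(strands)
  pos <- if ("cut" %in% names(anchors)) anchors$cut else anchors$pos
  ids <- if ("dsb_id" %in% names(anchors)) anchors$dsb_id
         else if ("id" %in% names(anchors)) anchors$id
         else as.character(seq_along(pos))
  out <- vapply(seq_len(nrow(anchors)), function(i) {
    chr <- anchors$chrom[i]
    check_chrom(track, chr)
    if (pos[i] - halfwidth < 0 ||
        pos[i] + halfwidth > track$chrom_sizes[[chr]]) {
      stop("window around anchor ", pos[i], " exceeds ", chr)
    }
    vecs <- strand_vectors(track, chr, strands)
    sum(vapply(vecs, function(v) {
      region_signal(v, track$bin_size, pos[i] - halfwidth,
                    pos[i] + halfwidth, "sum")
    }, numeric(1)))
  }, numeric(1))
  names(out) <- ids
  out
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' The statistical convention for per-site quantification comparisons:
#' zero differences are dropped, the exact null distribution is used for
#' n <= 25 without ties in the absolute differences, and the normal
#' approximation with tie and continuity correction otherwise. All-zero
#' differences return p = 1 with a warning.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Two-sided p value.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 1) stop("need at least one pair")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value
}

#' Boxplot summary with the 1.5 x IQR outlier rule
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers extend to
#' the most extreme data points within
#' `[q1 - 1.5 * IQR, q3 + 1.5 * IQR]`; values strictly outside are
#' outliers.
#'
#' @param values Numeric vector (n >= 1).
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(values) {
  if (length(values) < 1) stop("box_stats needs at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo | values > hi]))
}
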