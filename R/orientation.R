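#' Template strand of a gene
#'
#' The template strand is the DNA strand complementary to the transcript:
#' the Crick strand for a gene transcribed in the forward (`+`)
#' orientation and the Watson strand for a `-` gene. RNA:DNA hybrids
#' formed by nascent or retained transcripts therefore accumulate on the
#' Crick strand over `+` genes.
#'
#' @param gene_strand Character vector of `"+"`/`"-"`.
#' @return Character vector of `"crick"`/`"watson"`.
#' @export
template_strand <- function(gene_strand) {
  if (!all(gene_strand %in% c("+", "-"))) {
    stop("gene_strand must be '+' or '-'")
  }
  ifelse(gene_strand == "+", "crick", "watson")
}

#' Split signal around a cut into 3'-overhang and resected strands
#'
#' 5' to 3' resection degrades the 5'-terminated strand on each side of a
#' break, leaving a 3' single-stranded overhang. Reading Watson 5'->3'
#' left to right: on the right-hand fragment the Watson strand is
#' 5'-terminated at the break (resected) and Crick is the 3' overhang;
#' mirrored on the left. This function folds the two sides of the break
#' together by distance from the cut:
#' `resected(d) = combine(crick_left(d), watson_right(d))` and
#' `overhang(d) = combine(watson_left(d), crick_right(d))`.
#'
#' The cut bin itself belongs to the right-hand side (half-open
#' convention); `d = 0` abuts the cut on both sides and increases away
#' from it.
#'
#' @param watson,crick Full-chromosome bin vectors (same length).
#' @param cut Cut coordinate in bp.
#' @param halfwidth Window half-width in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size Bin width in bp.
#' @param combine `"sum"` (default) or `"mean"` of the two sides.
#' @return List with `overhang` and `resected` vectors (length
#'   `halfwidth / bin_size`) and `distance`, the bin-start distance from
#'   the cut.
#' @export
split_by_resection <- function(watson, crick, cut, halfwidth, bin_size,
                               combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  stopifnot(length(watson) == length(crick))
  b <- halfwidth / bin_size
  if (b != round(b)) stop("halfwidth must be a multiple of bin_size")
  b <- as.integer(b)
  cb <- floor(cut / bin_size) + 1L  # bin containing the cut: right side
  if (cb - b < 1L || cb + b - 1L > length(watson)) {
    stop("window of ", halfwidth, " bp around cut ", cut,
         " exceeds chromosome")
  }
  left_idx <- cb - seq_len(b)        # mirrored: d increases away from cut
  right_idx <- cb + seq_len(b) - 1L
  comb <- if (combine == "sum") `+` else function(x, y) (x + y) / 2
  list(
    overhang = comb(watson[left_idx], crick[right_idx]),
    resected = comb(crick[left_idx], watson[right_idx]),
    distance = (seq_len(b) - 1L) * bin_size,
    combine = combine
  )
}

#' Per-site overhang/resected split over a whole DSB table
#'
#' @param track A [stranded_track()].
#' @param sites data.frame with `dsb_id`, `chrom`, `cut`.
#' @inheritParams split_by_resection
#' @return List of matrices `overhang` and `resected` (sites x distance
#'   bins, rownames = `dsb_id`).
#' @export
split_by_resection_sites <- function(track, sites, halfwidth,
                                     combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  b <- as.integer(halfwidth / track$bin_size)
  ov <- rs <- matrix(NA_real_, nrow(sites), b,
                     dimnames = list(sites$dsb_id, NULL))
  for (i in seq_len(nrow(sites))) {
    chr <- sites$chrom[i]
    check_chrom(track, chr)
    sp <- split_by_resection(track$watson[[chr]], track$crick[[chr]],
                             sites$cut[i], halfwidth, track$bin_size,
                             combine)
    ov[i, ] <- sp$overhang
    rs[i, ] <- sp$resected
  }
  list(overhang = ov, resected = rs)
}

flip_strand_rows <- function(mat_watson, mat_crick, flip) {
  stopifnot(nrow(mat_watson) == nrow(mat_crick),
            length(flip) == nrow(mat_watson))
  w <- mat_watson
  k <- mat_crick
  for (i in which(flip)) {
    w[i, ] <- rev(mat_crick[i, ])
    k[i, ] <- rev(mat_watson[i, ])
  }
  list(watson = w, crick = k)
}

#' Orient stranded profile matrices by gene direction
#'
#' Rows of `-` genes are reversed in bin order with Watson/Crick labels
#' swapped, so the returned `template` matrix holds each gene's
#' template-strand signal reading 5'->3' along the gene, and
#' `nontemplate` the coding-strand signal. The transform is involutive:
#' re-applying the underlying row flip restores the input.
#'
#' @param matrix_watson,matrix_crick Numeric matrices, one row per gene,
#'   columns in genomic (Watson) orientation.
#' @param gene_strands Character vector of `"+"`/`"-"`, one per row.
#' @return List with `template`, `nontemplate` matrices, logical
#'   `flipped`, and `rule = "gene_direction"`.
#' @export
orient_by_gene <- function(matrix_watson, matrix_crick, gene_strands) {
  if (length(gene_strands) != nrow(matrix_watson)) {
    stop("one gene strand per matrix row required")
  }
  if (!all(gene_strands %in% c("+", "-"))) {
    stop("gene_strands must be '+' or '-'")
  }
  flip <- gene_strands == "-"
  fl <- flip_strand_rows(matrix_watson, matrix_crick, flip)
  # in the oriented frame, crick carries the template strand of '+' genes
  list(template = fl$crick, nontemplate = fl$watson, flipped = flip,
       rule = "gene_direction")
}

#' Orient per-DSB windows by hybrid (dominant-side) directionality
#'
#' For each site the summed signal on both strands over
#' `(cut, cut + halfwidth]` is compared with `[cut - halfwidth, cut)`;
#' windows whose left side dominates are flipped (bin order reversed,
#' strand labels swapped) so the stronger side always reads to the right.
#' Ties are not flipped.
#'
#' @param track A [stranded_track()].
#' @param sites data.frame with `dsb_id`, `chrom`, `cut`.
#' @param halfwidth Window half-width in bp (default 2000).
#' @return List with oriented `watson`/`crick` matrices (sites x window
#'   bins), logical `flipped` and `rule = "hybrid_direction"`.
#' @export
orient_by_dominant_side <- function(track, sites, halfwidth = 2000) {
  bs <- track$bin_size
  b <- as.integer(halfwidth / bs)
  n <- nrow(sites)
  w <- k <- matrix(NA_real_, n, 2L * b, dimnames = list(sites$dsb_id, NULL))
  flip <- logical(n)
  for (i in seq_len(n)) {
    chr <- sites$chrom[i]
    check_chrom(track, chr)
    cb <- floor(sites$cut[i] / bs) + 1L
    idx <- (cb - b):(cb + b - 1L)
    if (idx[1] < 1L || idx[length(idx)] > length(track$watson[[chr]])) {
      stop("window around cut ", sites$cut[i], " exceeds chromosome")
    }
    wv <- track$watson[[chr]][idx]
    kv <- track$crick[[chr]][idx]
    left <- sum(wv[seq_len(b)]) + sum(kv[seq_len(b)])
    right <- sum(wv[b + seq_len(b)]) + sum(kv[b + seq_len(b)])
    flip[i] <- left > right
    w[i, ] <- wv
    k[i, ] <- kv
  }
  fl <- flip_strand_rows(w, k, flip)
  list(watson = fl$watson, crick = fl$crick, flipped = flip,
       rule = "hybrid_direction")
}

#' Rank DSB sites by damage-induced signal gain
#'
#' Scores each site as the windowed signal (both strands, `+`DSB minus
#' `-`DSB) over `[cut - halfwidth, cut + halfwidth)` and returns the top
#' `k`, ties broken by `dsb_id`.
#'
#' @param track_plus,track_minus [stranded_track()]s on the same binning.
#' @param sites data.frame with `dsb_id`, `chrom`, `cut`.
#' @param halfwidth Window half-width in bp.
#' @param k Number of sites to return.
#' @return `sites` rows for the top `k`, with a `score` column, in
#'   descending score order.
#' @export
rank_hybrid_sites <- function(track_plus, track_minus, sites, halfwidth, k) {
  if (k > nrow(sites)) stop("k exceeds number of sites")
  stopifnot(track_plus$bin_size == track_minus$bin_size)
  score <- vapply(seq_len(nrow(sites)), function(i) {
    p <- window_signal(track_plus, sites[i, , drop = FALSE], halfwidth,
                       strands = "both")
    m <- window_signal(track_minus, sites[i, , drop = FALSE], halfwidth,
                       strands = "both")
    p - m
  }, numeric(1))
  ord <- order(-score, sites$dsb_id)
  out <- sites[ord[seq_len(k)], , drop = FALSE]
  out$score <- score[ord[seq_len(k)]]
  rownames(out) <- NULL
  out
}
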