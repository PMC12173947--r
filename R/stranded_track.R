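#' Stranded binned coverage track
#'
#' A `stranded_track` holds per-chromosome binned coverage with separate
#' Watson (reference/plus) and Crick (reverse-complement) vectors, plus a
#' normalization provenance tag. Bin `i` (1-based) covers the half-open
#' interval `[(i-1) * bin_size, i * bin_size)`. Bin values are signal mass
#' per bin (for fragment-derived tracks, the number of covered bases), so
#' summing bins conserves total coverage exactly.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (> 0).
#' @param norm Normalization tag: a list with elements `kind` (one of
#'   `"raw"`, `"total_count"`, `"spike_in"`, `"tss_scaled"`,
#'   `"log2_ratio"`) and `factor` (numeric).
#'
#' @return An object of class `stranded_track`: a list with elements
#'   `bin_size`, `chrom_sizes`, `watson` and `crick` (named lists of
#'   per-chromosome numeric vectors) and `norm`.
#' @export
stranded_track <- function(chrom_sizes, bin_size,
                           norm = list(kind = "raw", factor = 1)) {
  if (length(chrom_sizes) < 1L || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a single positive number")
  }
  nbins <- ceiling(chrom_sizes / bin_size)
  zero <- lapply(nbins, function(n) numeric(n))
  structure(
    list(bin_size = bin_size, chrom_sizes = chrom_sizes,
         watson = zero, crick = zero, norm = norm),
    class = "stranded_track"
  )
}

#' @export
print.stranded_track <- function(x, ...) {
  cat("stranded_track: ", length(x$chrom_sizes), " chromosome(s), bin ",
      x$bin_size, " bp, norm=", x$norm$kind, "\n", sep = "")
  for (chr in names(x$chrom_sizes)) {
    cat("  ", chr, ": ", x$chrom_sizes[[chr]], " bp, total watson=",
        signif(sum(x$watson[[chr]]), 4), ", crick=",
        signif(sum(x$crick[[chr]]), 4), "\n", sep = "")
  }
  invisible(x)
}

is_stranded_track <- function(x) inherits(x, "stranded_track")

#' Apply a function to every strand vector of a track
#' @noRd
track_map <- function(track, f) {
  track$watson <- lapply(track$watson, f)
  track$crick <- lapply(track$crick, f)
  track
}

#' Binary operation over two tracks with identical layout
#' @noRd
track_map2 <- function(a, b, f) {
  stopifnot(identical(names(a$chrom_sizes), names(b$chrom_sizes)),
            a$bin_size == b$bin_size)
  for (chr in names(a$chrom_sizes)) {
    a$watson[[chr]] <- f(a$watson[[chr]], b$watson[[chr]])
    a$crick[[chr]] <- f(a$crick[[chr]], b$crick[[chr]])
  }
  a
}

check_chrom <- function(track, chrom) {
  if (!chrom %in% names(track$chrom_sizes)) {
    stop("unknown chromosome: ", chrom)
  }
  invisible(TRUE)
}

#' Signal over a genomic range from a binned vector
#'
#' Bin mass is prorated by overlap fraction, so a range covering half a bin
#' receives half that bin's value; `how = "mean"` divides by the range
#' length in bins, giving the mean per-bin value over the range.
#' @noRd
region_signal <- function(vec, bin_size, start, end, how = c("sum", "mean")) {
  how <- match.arg(how)
  if (end <= start) return(0)
  first <- floor(start / bin_size) + 1L
  last <- floor((end - 1) / bin_size) + 1L
  if (first < 1L || last > length(vec)) {
    stop("range [", start, ",", end, ") outside binned vector bounds")
  }
  idx <- first:last
  bs <- (idx - 1L) * bin_size
  be <- idx * bin_size
  ov <- pmin(be, end) - pmax(bs, start)
  total <- sum(vec[idx] * ov / bin_size)
  if (how == "mean") total / ((end - start) / bin_size) else total
}

#' Extract the strand vectors selected by a strand label
#' @noRd
strand_vectors <- function(track, chrom, strands = c("both", "watson", "crick")) {
  strands <- match.arg(strands)
  check_chrom(track, chrom)
  switch(strands,
    both = list(track$watson[[chrom]], track$crick[[chrom]]),
    watson = list(track$watson[[chrom]]),
    crick = list(track$crick[[chrom]])
  )
}
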