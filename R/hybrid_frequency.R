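#' Per-damaged-copy hybrid frequency estimate
#'
#' Back-of-the-envelope estimate of how often an RNA:DNA hybrid forms on a
#' cleaved DNA copy. If break-site hybrid levels are comparable to R-loops
#' that form on `hybrid_freq_pct` percent of all copies of a benchmark
#' locus, while the site is cleaved in only `cleavage_pct` percent of
#' cells, then the fraction of *damaged* copies carrying a hybrid is the
#' ratio of the two. With the literature ranges (R-loop frequency 5-10%
#' from single-molecule footprinting of highly R-loop-prone genes,
#' cleavage 10-20% from droplet digital PCR) the point estimate is 50%
#' and the cross-bound range 25-100%: hybrids form on at least half of
#' the damaged copies.
#'
#' @param hybrid_freq_pct Length-2 range (percent of all copies with a
#'   hybrid). Default `c(5, 10)`.
#' @param cleavage_pct Length-2 range (percent of copies cleaved).
#'   Default `c(10, 20)`.
#' @return List with `estimate` (percent, ratio of range midpoints),
#'   `lower` and `upper` (cross-bound percent range, capped at 100).
#' @export
hybrid_frequency_per_damaged_copy <- function(hybrid_freq_pct = c(5, 10),
                                              cleavage_pct = c(10, 20)) {
  h <- sort(as.numeric(hybrid_freq_pct))
  cl <- sort(as.numeric(cleavage_pct))
  if (length(h) != 2 || length(cl) != 2 || any(h <= 0) || any(cl <= 0)) {
    stop("both ranges must be two positive percentages")
  }
  list(
    estimate = 100 * mean(h) / mean(cl),
    lower = min(100, 100 * h[1] / cl[2]),
    upper = min(100, 100 * h[2] / cl[1])
  )
}
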