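# Shared fixture builders and independent oracles used across test files.

# A small track with signal placed by hand.
toy_track <- function(size = 1e5, bin = 50) {
  stranded_track(c(chrT = size), bin)
}

# Independent brute-force classification oracle: re-states the annotation
# rule as plain interval arithmetic over every (cut, gene) pair, without
# touching the package's classifier internals.
oracle_classify <- function(cut, genes, exons, window = 1000) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$expression <= 0) next
    if (g$strand == "+") {
      tss <- g$start
      promoter <- cut > tss - window && cut <= tss
      in_body <- cut >= g$start && cut <= g$end
      five <- !promoter && in_body && cut <= tss + window
      body <- in_body && !promoter && !five
      dist <- abs(cut - tss)
    } else {
      tss <- g$end
      promoter <- cut >= tss && cut < tss + window
      in_body <- cut >= g$start && cut <= g$end
      five <- !promoter && in_body && cut >= tss - window
      body <- in_body && !promoter && !five
      dist <- abs(tss - cut)
    }
    if (!(promoter || five || body)) next
    pos <- if (promoter) "promoter" else if (five) "five_prime" else "gene_body"
    exon_class <- "not_applicable"
    if (pos != "promoter") {
      ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      inside <- if (g$strand == "+") {
        any(ex$start <= cut & cut < ex$end)
      } else {
        any(ex$start < cut & cut <= ex$end)
      }
      exon_class <- if (nrow(ex) > 0 && inside) "exonic" else "intronic"
    }
    hits[[length(hits) + 1L]] <- data.frame(
      gene_id = g$gene_id, position_class = pos, exon_class = exon_class,
      dist = dist, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h$dist, h$gene_id), , drop = FALSE]
  h[seq_len(min(2, nrow(h))), c("gene_id", "position_class", "exon_class")]
}

# Base-level binning oracle: accumulate fragment coverage one base at a
# time, then sum per bin.
oracle_bin <- function(fragments, size, bin) {
  per_base <- list(watson = numeric(size), crick = numeric(size))
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    dest <- if (fr$strand == "forward") "watson" else "crick"
    idx <- (fr$start + 1):fr$end
    per_base[[dest]][idx] <- per_base[[dest]][idx] + 1
  }
  nb <- ceiling(size / bin)
  grp <- rep(seq_len(nb), each = bin, length.out = size)
  lapply(per_base, function(v) as.numeric(tapply(v, grp, sum)))
}
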