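#' Build a validated gene table
#'
#' Coordinates are 0-based half-open throughout the package: a gene
#' occupies `[start, end)`; its TSS is `start` for `+` genes and `end` for
#' `-` genes. Expression is in arbitrary units with 0 meaning silent.
#'
#' @param gene_id,chrom Character vectors.
#' @param start,end Numeric gene bounds, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param expression Non-negative expression level.
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand, expression) {
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  strand = as.character(strand),
                  expression = as.numeric(expression),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id")
  if (any(g$start >= g$end)) stop("genes must satisfy start < end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(g$expression < 0)) stop("expression must be >= 0")
  class(g) <- c("gene_table", "data.frame")
  g
}

gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' Signed distance from TSS in the direction of transcription
#' @noRd
tss_distance <- function(cut, tss, strand) {
  ifelse(strand == "+", cut - tss, tss - cut)
}

exon_hit <- function(cut, strand, exon_start, exon_end) {
  # mirror-symmetric bond membership: the bond at an exon's 5' boundary
  # belongs to the exon, at its 3' boundary to the following intron
  if (strand == "+") any(exon_start <= cut & cut < exon_end)
  else any(exon_start < cut & cut <= exon_end)
}

classify_one_gene <- function(cut, gene, exons, window) {
  tss <- if (gene$strand == "+") gene$start else gene$end
  d <- tss_distance(cut, tss, gene$strand)
  len <- gene$end - gene$start
  in_body <- d >= 0 && d <= len
  if (d > -window && d <= 0) {
    pos <- "promoter"
  } else if (in_body && d <= window) {
    pos <- "five_prime"
  } else if (in_body) {
    pos <- "gene_body"
  } else {
    return(NULL)
  }
  exon_class <- "not_applicable"
  if (pos %in% c("five_prime", "gene_body")) {
    ex <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
    exon_class <- if (nrow(ex) > 0 &&
                      exon_hit(cut, gene$strand, ex$start, ex$end)) {
      "exonic"
    } else {
      "intronic"
    }
  }
  list(gene_id = gene$gene_id, position_class = pos,
       exon_class = exon_class, dist_tss = abs(d))
}

#' Classify one DSB site by transcriptional context and position
#'
#' A break is transcription-coupled (TC) when it lies within the body of an
#' expressed gene or within `window` bp upstream of its TSS. TC annotations
#' are subdivided into `promoter` (within `window` upstream of the TSS,
#' including the TSS bond itself), `five_prime` (within `window` downstream
#' of the TSS inside the body) and `gene_body` (further inside), with
#' exonic/intronic labels for the intragenic classes. At most two
#' annotations are retained per site (the two qualifying genes nearest by
#' TSS distance). When no expressed gene qualifies, a silent gene
#' containing the cut (expression at or below `expression_threshold`) is
#' reported with `tc = FALSE`; failing that, a single intergenic
#' annotation is emitted.
#'
#' The `cut` coordinate denotes the bond between positions `cut - 1` and
#' `cut` (0-based).
#'
#' @param dsb One-row data.frame or list with `dsb_id`, `chrom`, `cut`.
#' @param genes A [gene_table()] (or equivalent data.frame).
#' @param exons data.frame with `gene_id`, `start`, `end` exon intervals.
#' @param window Promoter/5' window in bp (default 1000).
#' @param expression_threshold Genes with expression strictly above this
#'   count as expressed (default 0).
#' @param chrom_sizes Optional named vector; when given, cuts outside the
#'   declared chromosome bounds raise an error.
#' @return data.frame with columns `dsb_id`, `gene_id` (NA for
#'   intergenic), `tc`, `position_class`, `exon_class`.
#' @export
classify_dsb <- function(dsb, genes, exons = NULL, window = 1000,
                         expression_threshold = 0, chrom_sizes = NULL) {
  if (window <= 0) stop("window must be > 0")
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(0), start = numeric(0),
                        end = numeric(0))
  }
  cut <- as.numeric(dsb$cut)
  chrom <- as.character(dsb$chrom)
  if (!is.null(chrom_sizes)) {
    if (!chrom %in% names(chrom_sizes)) {
      stop("DSB chromosome ", chrom, " not declared")
    }
    if (cut < 0 || cut > chrom_sizes[[chrom]]) {
      stop("cut ", cut, " outside ", chrom, " bounds")
    }
  }
  cand <- genes[genes$chrom == chrom, , drop = FALSE]
  expressed <- cand[cand$expression > expression_threshold, , drop = FALSE]
  silent <- cand[cand$expression <= expression_threshold, , drop = FALSE]

  hits <- list()
  for (i in seq_len(nrow(expressed))) {
    h <- classify_one_gene(cut, expressed[i, ], exons, window)
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) > 0) {
    ord <- order(vapply(hits, `[[`, 0, "dist_tss"),
                 vapply(hits, `[[`, "", "gene_id"))
    hits <- hits[ord[seq_len(min(2L, length(hits)))]]
    return(data.frame(
      dsb_id = as.character(dsb$dsb_id),
      gene_id = vapply(hits, `[[`, "", "gene_id"),
      tc = TRUE,
      position_class = vapply(hits, `[[`, "", "position_class"),
      exon_class = vapply(hits, `[[`, "", "exon_class"),
      stringsAsFactors = FALSE
    ))
  }
  # no expressed gene qualifies: try silent genes, then intergenic
  shits <- list()
  for (i in seq_len(nrow(silent))) {
    h <- classify_one_gene(cut, silent[i, ], exons, window)
    if (!is.null(h)) shits[[length(shits) + 1L]] <- h
  }
  if (length(shits) > 0) {
    ord <- order(vapply(shits, `[[`, 0, "dist_tss"),
                 vapply(shits, `[[`, "", "gene_id"))
    h <- shits[[ord[1L]]]
    return(data.frame(dsb_id = as.character(dsb$dsb_id),
                      gene_id = h$gene_id, tc = FALSE,
                      position_class = h$position_class,
                      exon_class = h$exon_class, stringsAsFactors = FALSE))
  }
  data.frame(dsb_id = as.character(dsb$dsb_id), gene_id = NA_character_,
             tc = FALSE, position_class = "intergenic",
             exon_class = "not_applicable", stringsAsFactors = FALSE)
}

#' Classify a table of DSB sites
#'
#' @param dsbs data.frame with `dsb_id`, `chrom`, `cut`.
#' @inheritParams classify_dsb
#' @return Row-bound annotation data.frame (see [classify_dsb()]).
#' @export
classify_dsbs <- function(dsbs, genes, exons = NULL, window = 1000,
                          expression_threshold = 0, chrom_sizes = NULL) {
  out <- lapply(seq_len(nrow(dsbs)), function(i) {
    classify_dsb(dsbs[i, ], genes, exons, window,
                 expression_threshold, chrom_sizes)
  })
  do.call(rbind, out)
}

#' Summarize DSB annotation categories
#'
#' Site-level counts (`n_total`, `n_tc`, `n_silent`, `n_dual`) count
#' distinct `dsb_id`s; position and exon counts count TC annotations.
#' `pct_within_1kb_tss` is the percentage of TC annotations lying within
#' the promoter window or the 5' region, rounded to an integer.
#'
#' @param annotations Annotation data.frame as from [classify_dsbs()] or
#'   [load_dsb_annotation_fixture()].
#' @return Named list of category counts.
#' @export
summarize_categories <- function(annotations) {
  a <- annotations
  key <- paste(a$dsb_id, a$gene_id, sep = "\r")
  if (anyDuplicated(key[!is.na(a$gene_id)])) {
    stop("duplicate (dsb_id, gene_id) annotation pairs")
  }
  n_total <- length(unique(a$dsb_id))
  tc_sites <- unique(a$dsb_id[a$tc])
  n_tc <- length(tc_sites)
  tca <- a[a$tc, , drop = FALSE]
  n_promoter <- sum(tca$position_class == "promoter")
  n_five_prime <- sum(tca$position_class == "five_prime")
  n_gene_body <- sum(tca$position_class == "gene_body")
  n_exonic <- sum(tca$exon_class == "exonic")
  n_intronic <- sum(tca$exon_class == "intronic")
  ann_per_site <- table(a$dsb_id[a$tc])
  n_dual <- sum(ann_per_site >= 2)
  n_within <- n_exonic + n_intronic
  denom <- n_promoter + n_five_prime + n_gene_body
  pct <- if (denom > 0) {
    round(100 * (n_promoter + n_five_prime) / denom)
  } else {
    0
  }
  list(n_total = n_total, n_tc = n_tc, n_silent = n_total - n_tc,
       n_promoter = n_promoter, n_five_prime = n_five_prime,
       n_gene_body = n_gene_body, n_exonic = n_exonic,
       n_intronic = n_intronic, n_dual = n_dual,
       n_within_gene = n_within, pct_within_1kb_tss = pct)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Select expression-matched control genes
#'
#' Damaged genes are split into `n_bins` expression bins at their own
#' empirical quantiles; the same number of control genes per bin is then
#' sampled without replacement from the pool, after excluding genes within
#' `exclusion_radius` of any cut site, genes in `excluded_ids` (e.g. an
#' external differential-expression list) and the damaged genes
#' themselves. Deterministic for a fixed seed.
#'
#' @param damaged [gene_table()] of damaged genes.
#' @param pool [gene_table()] of candidate control genes.
#' @param cut_sites data.frame with `chrom`, `cut`.
#' @param excluded_ids Character vector of gene ids to exclude.
#' @param exclusion_radius Exclusion distance in bp around cuts
#'   (default 1e6).
#' @param n_bins Number of expression bins (default 5, i.e. quintiles).
#' @param seed Integer RNG seed.
#' @return Character vector of control gene ids, one per damaged gene.
#' @export
select_control_genes <- function(damaged, pool, cut_sites,
                                 excluded_ids = character(0),
                                 exclusion_radius = 1e6, n_bins = 5,
                                 seed = 1L) {
  if (nrow(damaged) == 0) return(character(0))
  edges <- stats::quantile(damaged$expression,
                           probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7, names = FALSE)
  edges[1] <- -Inf
  edges[n_bins + 1] <- Inf
  bin_of <- function(x) pmin(findInterval(x, edges, left.open = FALSE),
                             n_bins)
  damaged_bins <- bin_of(damaged$expression)
  demand <- tabulate(damaged_bins, nbins = n_bins)

  near_cut <- function(g) {
    on_chr <- cut_sites$chrom == g$chrom
    if (!any(on_chr)) return(FALSE)
    cuts <- cut_sites$cut[on_chr]
    any(cuts >= g$start - exclusion_radius & cuts <= g$end + exclusion_radius)
  }
  eligible <- vapply(seq_len(nrow(pool)), function(i) {
    g <- pool[i, ]
    !(g$gene_id %in% excluded_ids) &&
      !(g$gene_id %in% damaged$gene_id) &&
      !near_cut(g)
  }, logical(1))
  pool <- pool[eligible, , drop = FALSE]
  pool <- pool[order(pool$gene_id), , drop = FALSE]  # tie-stable
  pool_bins <- bin_of(pool$expression)

  with_seed(seed, {
    picked <- character(0)
    for (b in seq_len(n_bins)) {
      avail <- pool$gene_id[pool_bins == b]
      if (length(avail) < demand[b]) {
        stop("expression bin ", b, " exhausted: need ", demand[b],
             " control genes, only ", length(avail), " eligible")
      }
      picked <- c(picked,
                  avail[sample.int(length(avail), demand[b])])
    }
    picked
  })
}
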