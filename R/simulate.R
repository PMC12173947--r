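#' Simulation configuration
#'
#' Builds the full parameterization of the synthetic-data generator. All
#' randomness flows from the single `seed`: every track and stage derives
#' its own RNG stream from `seed` plus a stage name, so adding a track
#' never perturbs the others. Amplitudes are in arbitrary signal units per
#' bin before Poisson sampling at `noise$depth`.
#'
#' Signal geometry encoded by the defaults: hybrids form only at
#' transcription-coupled DSBs, on the template strand, on the side of the
#' break where the template strand is the 3' overhang (the gene-downstream
#' side), decaying exponentially with length `hybrid_lambda`; resection is
#' bidirectional with exponential length law growing from `L_4h` to
#' `L_24h`; RNAPII occupancy is globally repressed by factor `g` after
#' damage with additional local eviction `eviction` at damaged genes.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of top-level entries or nested lists
#'   (merged with `modifyList`); unknown keys raise an error.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chrS = 3e6),
    bin_size = 50,
    n_genes = 60,
    gene_length = c(5000, 40000),
    intergenic_gap = c(4000, 15000),
    fraction_silent = 0.2,
    expression_meanlog = 1.5,
    expression_sdlog = 0.8,
    dsb_contexts = c(promoter = 4, five_prime_exon = 4,
                     five_prime_intron = 4, gene_body_exon = 2,
                     gene_body_intron = 2, intergenic = 3,
                     silent_gene = 3),
    cleavage_range = c(0.3, 0.9),
    qdrip = list(baseline_amp = 0.6, baseline_span = 1500,
                 hybrid_amp = 6, hybrid_lambda = 800,
                 repression_strength = 1, background = 0.2),
    resection = list(L_4h = 1000, L_24h = 3000, amp = 4),
    rpa = list(amp = 3, beta = 1, boost_span = 500),
    rnapii = list(tss_amp = 8, tss_sigma = 200, body_amp = 1,
                  g = 0.7, eviction = 0.5, background = 0.1),
    ttseq = list(body_amp = 1, attenuation = 0.4, background = 0.1),
    drb = list(times = c(5, 10, 20, 30, 40), rate = 2,
               plateau_amp = 2, crest_amp = 4, crest_sigma = 1500,
               bin_size = 100, upstream = 2000, downstream = 120000,
               n_genes = 55, gene_length = c(85000, 118000),
               background = 0.1),
    noise = list(enabled = TRUE, depth = 10),
    spike = list(mean_reads = 1e6)
  )
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) > 0 || is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    }
    for (k in names(dots)) {
      if (is.list(cfg[[k]]) && is.list(dots[[k]])) {
        bad2 <- setdiff(names(dots[[k]]), names(cfg[[k]]))
        if (length(bad2) > 0) {
          stop("unknown config keys: ", paste0(k, "$", bad2, collapse = ", "))
        }
        cfg[[k]] <- utils::modifyList(cfg[[k]], dots[[k]])
      } else {
        cfg[[k]] <- dots[[k]]
      }
    }
  }
  class(cfg) <- c("simulation_config", "list")
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file of config overrides (same keys as
#'   [simulation_config()]).
#' @param seed Optional seed overriding the file's.
#' @return A [simulation_config()].
#' @export
config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$seed)) y$seed <- 1L
  sd <- y$seed
  y$seed <- NULL
  # yaml reads numeric vectors as lists; flatten the plain-vector fields
  flat <- function(x) if (is.list(x) && all(lengths(x) == 1L) &&
                          is.null(names(x))) unlist(x) else x
  y <- lapply(y, function(el) {
    if (is.list(el) && !is.null(names(el))) lapply(el, flat) else flat(el)
  })
  if (!is.null(y$chrom_sizes)) y$chrom_sizes <- unlist(y$chrom_sizes)
  if (!is.null(y$dsb_contexts)) y$dsb_contexts <- unlist(y$dsb_contexts)
  do.call(simulation_config, c(list(seed = sd), y))
}

#' Deterministic per-stage RNG stream seed
#' @noRd
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with random strands, exon chains and
#' log-normal expression (a `fraction_silent` share set to 0) on the
#' configured chromosome, left to right with random intergenic gaps.
#' Genes keep a 2.1-kb margin from chromosome ends so metagene flanks
#' stay in bounds.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (a [gene_table()]) and `exons` (data.frame
#'   `gene_id`, `start`, `end` in genomic coordinates).
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(stream_seed(cfg$seed, "genome"))
  chrom <- names(cfg$chrom_sizes)[1]
  size <- cfg$chrom_sizes[[1]]
  pad <- 2100
  cursor <- pad
  rows <- list()
  exon_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    gap <- stats::runif(1, cfg$intergenic_gap[1], cfg$intergenic_gap[2])
    len <- round(stats::runif(1, cfg$gene_length[1], cfg$gene_length[2]))
    start <- round(cursor + gap)
    end <- start + len
    if (end > size - pad) {
      stop("genome too small: placed ", i - 1L, " of ", cfg$n_genes,
           " genes")
    }
    strand <- sample(c("+", "-"), 1)
    silent <- stats::runif(1) < cfg$fraction_silent
    expr <- if (silent) 0 else stats::rlnorm(1, cfg$expression_meanlog,
                                             cfg$expression_sdlog)
    gene_id <- sprintf("G%04d", i)
    # exon chain in transcription coordinates, first exon at the TSS
    t0 <- 0
    ex <- list()
    ex_len <- round(stats::runif(1, 150, 1400))
    repeat {
      t1 <- min(t0 + ex_len, len)
      ex[[length(ex) + 1L]] <- c(t0, t1)
      if (t1 >= len) break
      t0 <- t1 + round(stats::runif(1, 500, 4000))
      if (t0 >= len) break
      ex_len <- round(stats::runif(1, 150, 1000))
    }
    exm <- do.call(rbind, ex)
    gstart <- if (strand == "+") start + exm[, 1] else end - exm[, 2]
    gend <- if (strand == "+") start + exm[, 2] else end - exm[, 1]
    exon_rows[[i]] <- data.frame(gene_id = gene_id, start = gstart,
                                 end = gend, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(gene_id = gene_id, chrom = chrom,
                            start = start, end = end, strand = strand,
                            expression = expr, stringsAsFactors = FALSE)
    cursor <- end
  }
  genes <- do.call(rbind, rows)
  list(
    genes = gene_table(genes$gene_id, genes$chrom, genes$start, genes$end,
                       genes$strand, genes$expression),
    exons = do.call(rbind, exon_rows)
  )
}

first_exon_len <- function(gene, exons) {
  ex <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
  if (gene$strand == "+") {
    min_ex <- ex[which.min(ex$start), ]
    min_ex$end - min_ex$start
  } else {
    max_ex <- ex[which.max(ex$end), ]
    max_ex$end - max_ex$start
  }
}

#' Simulate DSB sites in requested genomic contexts
#'
#' Places each break in its requested context (promoter, 5' exon,
#' 5' intron, gene-body exon/intron, intergenic, silent gene) relative to
#' the simulated genes, drawing at most one break per gene, and records
#' the ground-truth context labels that [classify_dsb()] should
#' reproduce.
#'
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @return data.frame with `dsb_id`, `chrom`, `cut`, `cleavage`,
#'   `context`, `gene_id`, `gene_strand`, `tc`, `position_class`,
#'   `exon_class`, `hybrid_side`.
#' @export
simulate_dsbs <- function(config, genome) {
  cfg <- config
  genes <- genome$genes
  exons <- genome$exons
  set.seed(stream_seed(cfg$seed, "dsbs"))
  contexts <- cfg$dsb_contexts
  if (sum(contexts) == 0) {
    return(data.frame(dsb_id = character(0), chrom = character(0),
                      cut = numeric(0), cleavage = numeric(0),
                      context = character(0), gene_id = character(0),
                      gene_strand = character(0), tc = logical(0),
                      position_class = character(0),
                      exon_class = character(0),
                      hybrid_side = character(0),
                      stringsAsFactors = FALSE))
  }
  expressed <- genes$gene_id[genes$expression > 0]
  silent <- genes$gene_id[genes$expression == 0]
  ex1 <- vapply(seq_len(nrow(genes)), function(i) {
    first_exon_len(genes[i, ], exons)
  }, numeric(1))
  names(ex1) <- genes$gene_id
  used <- character(0)
  rows <- list()
  take_gene <- function(pool, context) {
    pool <- setdiff(pool, used)
    if (length(pool) == 0) {
      stop("context '", context, "' unrealizable: no suitable gene left")
    }
    g <- pool[sample.int(length(pool), 1)]
    used <<- c(used, g)
    g
  }
  tss_of <- function(g) if (g$strand == "+") g$start else g$end
  t2g <- function(g, d) if (g$strand == "+") tss_of(g) + d else tss_of(g) - d
  mid_feature <- function(g, want_exon, min_d) {
    # transcription-coordinate midpoints of exons (or introns) beyond min_d
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (g$strand == "+") {
      ts <- ex$start - g$start; te <- ex$end - g$start
    } else {
      ts <- g$end - ex$end; te <- g$end - ex$start
    }
    o <- order(ts); ts <- ts[o]; te <- te[o]
    if (want_exon) {
      mids <- (ts + te) / 2
    } else {
      if (length(ts) < 2) return(numeric(0))
      mids <- (te[-length(te)] + ts[-1]) / 2
    }
    mids[mids > min_d]
  }
  place <- function(context) {
    switch(context,
      promoter = {
        g <- genes[genes$gene_id ==
                     take_gene(expressed, context), ][1, ]
        d <- -sample(100:900, 1)
        list(g = g, d = d, pos = "promoter", ex = "not_applicable")
      },
      five_prime_exon = {
        pool <- expressed[ex1[expressed] >= 200]
        g <- genes[genes$gene_id == take_gene(pool, context), ][1, ]
        hi <- min(950, ex1[[g$gene_id]] - 50)
        d <- sample(50:hi, 1)
        list(g = g, d = d, pos = "five_prime", ex = "exonic")
      },
      five_prime_intron = {
        # cut inside the first intron, within 1 kb of the TSS: needs a
        # first exon ending well before the 1-kb mark
        ok <- vapply(expressed, function(id) {
          e1 <- ex1[[id]]
          g <- genes[genes$gene_id == id, ][1, ]
          nex <- sum(exons$gene_id == id)
          e1 <= 800 && nex >= 2
        }, logical(1))
        g <- genes[genes$gene_id ==
                     take_gene(expressed[ok], context), ][1, ]
        e1 <- ex1[[g$gene_id]]
        # introns are >= 500 bp, so anything within 450 bp of the first
        # exon's end is intronic
        d <- sample((e1 + 50):min(949, e1 + 450), 1)
        list(g = g, d = d, pos = "five_prime", ex = "intronic")
      },
      gene_body_exon = {
        ok <- vapply(expressed, function(id) {
          g <- genes[genes$gene_id == id, ][1, ]
          length(mid_feature(g, TRUE, 1100)) > 0
        }, logical(1))
        g <- genes[genes$gene_id ==
                     take_gene(expressed[ok], context), ][1, ]
        mids <- mid_feature(g, TRUE, 1100)
        d <- round(mids[sample.int(length(mids), 1)])
        list(g = g, d = d, pos = "gene_body", ex = "exonic")
      },
      gene_body_intron = {
        ok <- vapply(expressed, function(id) {
          g <- genes[genes$gene_id == id, ][1, ]
          length(mid_feature(g, FALSE, 1100)) > 0
        }, logical(1))
        g <- genes[genes$gene_id ==
                     take_gene(expressed[ok], context), ][1, ]
        mids <- mid_feature(g, FALSE, 1100)
        d <- round(mids[sample.int(length(mids), 1)])
        list(g = g, d = d, pos = "gene_body", ex = "intronic")
      },
      silent_gene = {
        ok <- vapply(silent, function(id) {
          g <- genes[genes$gene_id == id, ][1, ]
          length(mid_feature(g, FALSE, 1100)) > 0
        }, logical(1))
        g <- genes[genes$gene_id ==
                     take_gene(silent[ok], context), ][1, ]
        mids <- mid_feature(g, FALSE, 1100)
        d <- round(mids[sample.int(length(mids), 1)])
        list(g = g, d = d, pos = "gene_body", ex = "intronic")
      },
      stop("unknown context: ", context)
    )
  }
  k <- 0L
  for (context in names(contexts)) {
    for (j in seq_len(contexts[[context]])) {
      k <- k + 1L
      if (context == "intergenic") {
        # midpoint of a wide gap between consecutive genes
        gaps_start <- genes$end[-nrow(genes)]
        gaps_end <- genes$start[-1]
        wide <- which(gaps_end - gaps_start >= 4000)
        wide <- wide[!paste0("gap", wide) %in% used]
        if (length(wide) == 0) stop("context 'intergenic' unrealizable")
        gi <- wide[sample.int(length(wide), 1)]
        used <- c(used, paste0("gap", gi))
        cut <- round((gaps_start[gi] + gaps_end[gi]) / 2)
        rows[[k]] <- data.frame(
          dsb_id = sprintf("DSB%03d", k), chrom = genes$chrom[1],
          cut = cut, cleavage = stats::runif(1, cfg$cleavage_range[1],
                                             cfg$cleavage_range[2]),
          context = context, gene_id = NA_character_,
          gene_strand = NA_character_, tc = FALSE,
          position_class = "intergenic", exon_class = "not_applicable",
          hybrid_side = NA_character_, stringsAsFactors = FALSE)
      } else {
        p <- place(context)
        tc <- context != "silent_gene"
        rows[[k]] <- data.frame(
          dsb_id = sprintf("DSB%03d", k), chrom = p$g$chrom,
          cut = t2g(p$g, p$d),
          cleavage = stats::runif(1, cfg$cleavage_range[1],
                                  cfg$cleavage_range[2]),
          context = context, gene_id = p$g$gene_id,
          gene_strand = p$g$strand, tc = tc,
          position_class = p$pos, exon_class = p$ex,
          hybrid_side = if (tc) {
            if (p$g$strand == "+") "right" else "left"
          } else {
            NA_character_
          },
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

add_region <- function(vec, bs, start, end, amp) {
  if (end <= start) return(vec)
  first <- max(1L, floor(start / bs) + 1L)
  last <- min(length(vec), floor((end - 1) / bs) + 1L)
  if (first > last) return(vec)
  idx <- first:last
  ov <- pmin(idx * bs, end) - pmax((idx - 1L) * bs, start)
  vec[idx] <- vec[idx] + amp * ov / bs
  vec
}

add_exp_decay <- function(vec, bs, cut, side, amp, lambda) {
  span <- 8 * lambda
  if (side == "right") {
    first <- max(1L, floor(cut / bs) + 1L)
    last <- min(length(vec), floor((cut + span) / bs) + 1L)
    if (first > last) return(vec)
    idx <- first:last
    d <- pmax((idx - 0.5) * bs - cut, 0)
  } else {
    first <- max(1L, floor((cut - span) / bs) + 1L)
    last <- min(length(vec), ceiling(cut / bs))
    if (first > last) return(vec)
    idx <- first:last
    d <- pmax(cut - (idx - 0.5) * bs, 0)
  }
  vec[idx] <- vec[idx] + amp * exp(-d / lambda)
  vec
}

add_gaussian <- function(vec, bs, center, amp, sigma) {
  span <- 4 * sigma
  first <- max(1L, floor((center - span) / bs) + 1L)
  last <- min(length(vec), floor((center + span) / bs) + 1L)
  idx <- first:last
  x <- (idx - 0.5) * bs
  vec[idx] <- vec[idx] + amp * exp(-(x - center)^2 / (2 * sigma^2))
  vec
}

poissonize <- function(track, cfg, stream) {
  depth <- cfg$noise$depth
  if (!isTRUE(cfg$noise$enabled)) {
    return(track_map(track, function(v) v * depth))
  }
  set.seed(stream_seed(cfg$seed, stream))
  track_map(track, function(v) {
    as.numeric(stats::rpois(length(v), pmax(v, 0) * depth))
  })
}

#' Simulate the full stranded-track bundle
#'
#' Generates qDRIP-seq (-/+DSB), END-seq and RPA ChIP-seq (4 h/24 h),
#' RNAPII ChIP-seq (-/+DSB) and TT-seq (-/+DSB) tracks over the simulated
#' genes and breaks, Poisson-sampled at the configured depth, plus spike
#' read counts per library and ground-truth tables.
#'
#' Signal rules: (i) baseline R-loops on the template strand over each
#' expressed gene's first 1.5 kb, amplitude proportional to expression;
#' (ii) +DSB adds, at TC-DSBs only, an exponential-decay hybrid on the
#' template strand on the side where the template strand is the 3'
#' overhang, amplitude proportional to expression x cleavage x
#' repression strength; (iii) END-seq places the survival function of the
#' exponential resection-length law on each side's overhang strand;
#' (iv) RPA follows the resected span on the overhang strand with a
#' (1 + beta) boost within 500 bp on the hybrid side of TC-DSBs;
#' (v) RNAPII has Gaussian TSS peaks plus body plateaus scaled by
#' expression, globally repressed by `g` after damage and additionally by
#' `eviction` at damaged genes; (vi) TT-seq covers gene bodies on the
#' sense strand, attenuated downstream of the cut at damaged genes after
#' damage.
#'
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @param dsbs Output of [simulate_dsbs()].
#' @return List of class `track_bundle`: `tracks` (named
#'   [stranded_track()]s), `spike_reads`, `truth` (per-DSB hybrid
#'   amplitude/side, damaged-gene flags, `g`), `config`.
#' @export
simulate_tracks <- function(config, genome, dsbs) {
  cfg <- config
  genes <- genome$genes
  bs <- cfg$bin_size
  blank <- function() stranded_track(cfg$chrom_sizes, bs)
  strand_of <- function(gstrand) template_strand(gstrand)
  chrom <- names(cfg$chrom_sizes)[1]

  damaged_ids <- unique(dsbs$gene_id[dsbs$tc & !is.na(dsbs$gene_id)])

  ## qDRIP baseline (-DSB)
  qd_minus <- blank()
  qd_minus <- track_map(qd_minus, function(v) v + cfg$qdrip$background)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$expression <= 0) next
    s <- strand_of(g$strand)
    span <- cfg$qdrip$baseline_span
    reg <- if (g$strand == "+") c(g$start, g$start + span)
           else c(g$end - span, g$end)
    qd_minus[[s]][[chrom]] <- add_region(qd_minus[[s]][[chrom]], bs,
                                         reg[1], reg[2],
                                         cfg$qdrip$baseline_amp * g$expression)
  }

  ## qDRIP +DSB = baseline + hybrids at TC-DSBs
  qd_plus <- qd_minus
  hyb_amp <- rep(NA_real_, nrow(dsbs))
  for (i in seq_len(nrow(dsbs))) {
    d <- dsbs[i, ]
    if (!d$tc) next
    g <- genes[genes$gene_id == d$gene_id, ][1, ]
    amp <- cfg$qdrip$hybrid_amp * g$expression * d$cleavage *
      cfg$qdrip$repression_strength
    hyb_amp[i] <- amp
    s <- strand_of(g$strand)
    qd_plus[[s]][[chrom]] <- add_exp_decay(qd_plus[[s]][[chrom]], bs,
                                           d$cut, d$hybrid_side, amp,
                                           cfg$qdrip$hybrid_lambda)
  }

  ## END-seq and RPA at 4 h and 24 h
  make_resection <- function(L, rpa = FALSE) {
    tr <- blank()
    for (i in seq_len(nrow(dsbs))) {
      d <- dsbs[i, ]
      amp <- (if (rpa) cfg$rpa$amp else cfg$resection$amp) * d$cleavage
      # right-side 3' overhang is Crick, left-side is Watson
      tr$crick[[chrom]] <- add_exp_decay(tr$crick[[chrom]], bs, d$cut,
                                         "right", amp, L)
      tr$watson[[chrom]] <- add_exp_decay(tr$watson[[chrom]], bs, d$cut,
                                          "left", amp, L)
      if (rpa && d$tc && !is.na(d$hybrid_side)) {
        # (1 + beta) boost within boost_span of the cut on the hybrid side
        s <- if (d$hybrid_side == "right") "crick" else "watson"
        v <- tr[[s]][[chrom]]
        if (d$hybrid_side == "right") {
          idx <- (floor(d$cut / bs) + 1L):
            min(length(v), floor((d$cut + cfg$rpa$boost_span - 1) / bs) + 1L)
          dist <- pmax((idx - 0.5) * bs - d$cut, 0)
        } else {
          idx <- max(1L, floor((d$cut - cfg$rpa$boost_span) / bs) + 1L):
            ceiling(d$cut / bs)
          dist <- pmax(d$cut - (idx - 0.5) * bs, 0)
        }
        v[idx] <- v[idx] + cfg$rpa$beta * amp * exp(-dist / L)
        tr[[s]][[chrom]] <- v
      }
    }
    tr
  }
  end_4h <- make_resection(cfg$resection$L_4h)
  end_24h <- make_resection(cfg$resection$L_24h)
  rpa_4h <- make_resection(cfg$resection$L_4h, rpa = TRUE)
  rpa_24h <- make_resection(cfg$resection$L_24h, rpa = TRUE)

  ## RNAPII
  rnap_minus <- blank()
  rnap_minus <- track_map(rnap_minus,
                          function(v) v + cfg$rnapii$background)
  rnap_plus <- rnap_minus
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$expression <= 0) next
    tss <- if (g$strand == "+") g$start else g$end
    scale_plus <- cfg$rnapii$g *
      (if (g$gene_id %in% damaged_ids) cfg$rnapii$eviction else 1)
    for (s in c("watson", "crick")) {  # ChIP signal is unstranded: half each
      rnap_minus[[s]][[chrom]] <- add_gaussian(
        rnap_minus[[s]][[chrom]], bs, tss,
        cfg$rnapii$tss_amp * g$expression / 2, cfg$rnapii$tss_sigma)
      rnap_minus[[s]][[chrom]] <- add_region(
        rnap_minus[[s]][[chrom]], bs, g$start, g$end,
        cfg$rnapii$body_amp * g$expression / 2)
      rnap_plus[[s]][[chrom]] <- add_gaussian(
        rnap_plus[[s]][[chrom]], bs, tss,
        scale_plus * cfg$rnapii$tss_amp * g$expression / 2,
        cfg$rnapii$tss_sigma)
      rnap_plus[[s]][[chrom]] <- add_region(
        rnap_plus[[s]][[chrom]], bs, g$start, g$end,
        scale_plus * cfg$rnapii$body_amp * g$expression / 2)
    }
  }

  ## TT-seq (sense strand: Watson for '+' genes)
  tt_minus <- blank()
  tt_minus <- track_map(tt_minus, function(v) v + cfg$ttseq$background)
  tt_plus <- tt_minus
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$expression <= 0) next
    s <- if (g$strand == "+") "watson" else "crick"
    amp <- cfg$ttseq$body_amp * g$expression
    tt_minus[[s]][[chrom]] <- add_region(tt_minus[[s]][[chrom]], bs,
                                         g$start, g$end, amp)
    if (g$gene_id %in% damaged_ids) {
      cut <- dsbs$cut[match(g$gene_id, dsbs$gene_id)]
      if (g$strand == "+") {
        tt_plus[[s]][[chrom]] <- add_region(tt_plus[[s]][[chrom]], bs,
                                            g$start, max(g$start, cut), amp)
        tt_plus[[s]][[chrom]] <- add_region(
          tt_plus[[s]][[chrom]], bs, max(g$start, cut), g$end,
          amp * cfg$ttseq$attenuation)
      } else {
        tt_plus[[s]][[chrom]] <- add_region(tt_plus[[s]][[chrom]], bs,
                                            min(g$end, cut), g$end, amp)
        tt_plus[[s]][[chrom]] <- add_region(
          tt_plus[[s]][[chrom]], bs, g$start, min(g$end, cut),
          amp * cfg$ttseq$attenuation)
      }
    } else {
      tt_plus[[s]][[chrom]] <- add_region(tt_plus[[s]][[chrom]], bs,
                                          g$start, g$end, amp)
    }
  }

  signal <- list(
    qdrip_minus = qd_minus, qdrip_plus = qd_plus,
    endseq_4h = end_4h, endseq_24h = end_24h,
    rpa_4h = rpa_4h, rpa_24h = rpa_24h,
    rnapii_minus = rnap_minus, rnapii_plus = rnap_plus,
    ttseq_minus = tt_minus, ttseq_plus = tt_plus
  )
  tracks <- lapply(names(signal), function(nm) {
    poissonize(signal[[nm]], cfg, paste0("noise_", nm))
  })
  names(tracks) <- names(signal)

  set.seed(stream_seed(cfg$seed, "spike"))
  spike_reads <- stats::rpois(length(tracks), cfg$spike$mean_reads)
  names(spike_reads) <- names(tracks)

  truth_dsbs <- dsbs
  truth_dsbs$hybrid_amp <- hyb_amp
  truth_genes <- genome$genes
  truth_genes$damaged <- truth_genes$gene_id %in% damaged_ids

  structure(list(tracks = tracks, spike_reads = spike_reads,
                 truth = list(dsbs = truth_dsbs, genes = truth_genes,
                              g = cfg$rnapii$g),
                 config = cfg),
            class = "track_bundle")
}

#' Simulate a DRB/TT-seq transcription-wave time course
#'
#' For each long gene, per-time-point coverage over -2 kb..+120 kb around
#' the TSS (100-bp bins, oriented 5'->3') consists of a plateau from the
#' TSS to the advancing front at `rate x t` kb, a Gaussian crest centred
#' at the front, and background, Poisson-sampled at the configured depth.
#' A front beyond the gene end triggers a truncation warning for that
#' gene (the crest is dropped there and the plateau clipped at the gene
#' end).
#'
#' @param config A [simulation_config()]; the `drb` block holds the true
#'   rate (kb/min), time points, amplitudes and cohort size.
#' @param genes Optional data.frame with `gene_id` and `length` in bp
#'   (all > 60 kb); by default a cohort of `drb$n_genes` genes with
#'   lengths drawn from `drb$gene_length` is generated.
#' @return List with `timecourses` (see [cohort_rate()]), `truth`
#'   (data.frame `gene_id`, `rate`), `positions`, `config`.
#' @export
simulate_drb_timecourse <- function(config, genes = NULL) {
  cfg <- config
  drb <- cfg$drb
  if (any(diff(drb$times) <= 0)) stop("time points must be increasing")
  set.seed(stream_seed(cfg$seed, "drb_genes"))
  if (is.null(genes)) {
    genes <- data.frame(
      gene_id = sprintf("LG%04d", seq_len(drb$n_genes)),
      length = round(stats::runif(drb$n_genes, drb$gene_length[1],
                                  drb$gene_length[2])),
      stringsAsFactors = FALSE)
  }
  if (any(genes$length <= 60000)) {
    stop("DRB cohort genes must be longer than 60 kb")
  }
  positions <- drb_bin_positions(drb$upstream, drb$downstream,
                                 drb$bin_size)
  depth <- cfg$noise$depth
  set.seed(stream_seed(cfg$seed, "drb_noise"))
  timecourses <- lapply(seq_len(nrow(genes)), function(i) {
    len <- genes$length[i]
    cov <- matrix(0, length(drb$times), length(positions))
    for (j in seq_along(drb$times)) {
      front <- drb$rate * 1000 * drb$times[j]
      sig <- rep(drb$background, length(positions))
      if (front > len) {
        warning("gene ", genes$gene_id[i],
                ": wave front beyond gene end at t=", drb$times[j],
                " min; truncated")
        body <- positions > 0 & positions <= len
        sig[body] <- sig[body] + drb$plateau_amp
      } else {
        body <- positions > 0 & positions <= front
        sig[body] <- sig[body] + drb$plateau_amp
        sig <- sig + drb$crest_amp *
          exp(-(positions - front)^2 / (2 * drb$crest_sigma^2)) *
          (positions > 0 & positions <= len)
      }
      cov[j, ] <- if (isTRUE(cfg$noise$enabled)) {
        as.numeric(stats::rpois(length(sig), sig * depth))
      } else {
        sig * depth
      }
    }
    list(gene_id = genes$gene_id[i], times = drb$times,
         positions = positions, coverage = cov)
  })
  list(timecourses = timecourses,
       truth = data.frame(gene_id = genes$gene_id, rate = drb$rate,
                          stringsAsFactors = FALSE),
       positions = positions, config = cfg)
}
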