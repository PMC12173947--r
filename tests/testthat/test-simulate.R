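test_that("config validates keys and merges nested overrides", {
  cfg <- simulation_config(seed = 5, rnapii = list(g = 0.5))
  expect_equal(cfg$rnapii$g, 0.5)
  expect_equal(cfg$rnapii$tss_sigma, 200)  # untouched sibling default
  expect_error(simulation_config(bogus = 1), "unknown config keys")
  expect_error(simulation_config(rnapii = list(gg = 1)), "unknown config")
})

test_that("YAML config round-trips through the constructor", {
  td <- withr::local_tempdir()
  f <- file.path(td, "c.yaml")
  writeLines(c("drb:", "  rate: 1.5", "noise:", "  enabled: false"), f)
  cfg <- config_from_yaml(f, seed = 3)
  expect_equal(cfg$seed, 3)
  expect_equal(cfg$drb$rate, 1.5)
  expect_false(cfg$noise$enabled)
  expect_equal(cfg$drb$times, c(5, 10, 20, 30, 40))
})

test_that("genome simulation is deterministic and geometrically valid", {
  cfg <- simulation_config(seed = 12)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  genes <- g1$genes
  # non-overlap, brute force over every pair
  o <- order(genes$start)
  s <- genes[o, ]
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  # exons inside their gene
  for (i in seq_len(nrow(genes))) {
    ex <- g1$exons[g1$exons$gene_id == genes$gene_id[i], ]
    expect_true(all(ex$start >= genes$start[i] & ex$end <= genes$end[i]))
    expect_true(all(ex$start < ex$end))
  }
  expect_true(all(genes$expression >= 0))

  all_silent <- simulate_genome(simulation_config(seed = 12,
                                                  fraction_silent = 1))
  expect_true(all(all_silent$genes$expression == 0))

  expect_error(
    simulate_genome(simulation_config(seed = 1,
                                      chrom_sizes = c(chrS = 1e5))),
    "too small"
  )
})

test_that("DSB placement reproduces requested contexts through classify", {
  for (seed in c(2, 19)) {
    cfg <- simulation_config(seed = seed)
    gn <- simulate_genome(cfg)
    dsbs <- simulate_dsbs(cfg, gn)
    expect_equal(as.vector(table(dsbs$context)[names(cfg$dsb_contexts)]),
                 unname(cfg$dsb_contexts))
    ann <- classify_dsbs(dsbs, gn$genes, gn$exons)
    m <- merge(dsbs, ann, by = "dsb_id", suffixes = c(".t", ".a"))
    expect_equal(nrow(m), nrow(dsbs))  # single annotation per site
    same_gene <- (is.na(m$gene_id.t) & is.na(m$gene_id.a)) |
      (!is.na(m$gene_id.t) & !is.na(m$gene_id.a) &
         m$gene_id.t == m$gene_id.a)
    expect_true(all(same_gene))
    expect_equal(m$tc.a, m$tc.t)
    expect_equal(m$position_class.a, m$position_class.t)
    expect_equal(m$exon_class.a, m$exon_class.t)
  }
})

test_that("zero requested DSBs yield an empty table", {
  cfg <- simulation_config(seed = 1, dsb_contexts = c(promoter = 0))
  gn <- simulate_genome(cfg)
  expect_equal(nrow(simulate_dsbs(cfg, gn)), 0)
})

test_that("unrealizable contexts raise a capacity error", {
  cfg <- simulation_config(seed = 1, fraction_silent = 0,
                           dsb_contexts = c(silent_gene = 1))
  gn <- simulate_genome(cfg)
  expect_error(simulate_dsbs(cfg, gn), "unrealizable")
})

test_that("silent DSBs add no qDRIP signal beyond noise", {
  cfg <- simulation_config(seed = 8, noise = list(enabled = FALSE),
                           dsb_contexts = c(silent_gene = 2,
                                            intergenic = 2))
  gn <- simulate_genome(cfg)
  dsbs <- simulate_dsbs(cfg, gn)
  tb <- simulate_tracks(cfg, gn, dsbs)
  diff_w <- mapply(function(p, m) sum(abs(p - m)),
                   tb$tracks$qdrip_plus$watson, tb$tracks$qdrip_minus$watson)
  diff_k <- mapply(function(p, m) sum(abs(p - m)),
                   tb$tracks$qdrip_plus$crick, tb$tracks$qdrip_minus$crick)
  expect_equal(sum(diff_w) + sum(diff_k), 0)
})

test_that("noiseless TC-DSB places the hybrid on template strand, overhang side", {
  cfg <- simulation_config(seed = 5, noise = list(enabled = FALSE),
                           dsb_contexts = c(five_prime_exon = 1),
                           qdrip = list(background = 0))
  gn <- simulate_genome(cfg)
  dsbs <- simulate_dsbs(cfg, gn)
  tb <- simulate_tracks(cfg, gn, dsbs)
  g <- gn$genes[gn$genes$gene_id == dsbs$gene_id[1], ]
  ts <- template_strand(g$strand)
  induced <- track_map2(tb$tracks$qdrip_plus, tb$tracks$qdrip_minus, `-`)
  other <- setdiff(c("watson", "crick"), ts)
  expect_gt(sum(induced[[ts]][[1]]), 0)
  expect_equal(sum(abs(induced[[other]][[1]])), 0)
  # split_by_resection: all induced signal on the overhang strand class
  sp <- split_by_resection_sites(induced, dsbs, halfwidth = 2000)
  expect_gt(sum(sp$overhang), 0)
  expect_equal(sum(sp$resected), 0)
  # and on the programmed side of the cut
  chrom <- dsbs$chrom[1]
  vec <- induced[[ts]][[chrom]]
  cutbin <- floor(dsbs$cut[1] / cfg$bin_size) + 1
  left <- sum(vec[seq_len(cutbin - 1)])
  right <- sum(vec[cutbin:length(vec)])
  if (dsbs$hybrid_side[1] == "right") {
    expect_equal(left, 0)
    expect_gt(right, 0)
  } else {
    expect_equal(right, 0)
    expect_gt(left, 0)
  }
})

resection_extent <- function(track, dsbs, side, chrom, threshold = 0.1) {
  vapply(seq_len(nrow(dsbs)), function(i) {
    cutbin <- floor(dsbs$cut[i] / track$bin_size) + 1
    nmax <- length(track$crick[[chrom]])
    v <- if (side == "right") {
      track$crick[[chrom]][cutbin:min(nmax, cutbin + 300)]
    } else {
      rev(track$watson[[chrom]][max(1, cutbin - 300):(cutbin - 1)])
    }
    sm <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    max(which(sm >= threshold * max(sm)), 1) * track$bin_size
  }, numeric(1))
}

test_that("END-seq extent grows from 4 h to 24 h at every break", {
  cfg <- simulation_config(seed = 14)
  gn <- simulate_genome(cfg)
  dsbs <- simulate_dsbs(cfg, gn)
  tb <- simulate_tracks(cfg, gn, dsbs)
  chrom <- names(cfg$chrom_sizes)[1]
  for (side in c("left", "right")) {
    e4 <- resection_extent(tb$tracks$endseq_4h, dsbs, side, chrom)
    e24 <- resection_extent(tb$tracks$endseq_24h, dsbs, side, chrom)
    expect_true(all(e24 > e4))
  }
})

test_that("RPA proximal boost appears only with beta > 0", {
  base <- list(seed = 9, noise = list(enabled = FALSE),
               dsb_contexts = c(five_prime_exon = 1))
  cfg0 <- do.call(simulation_config, c(base, list(rpa = list(beta = 0))))
  cfg1 <- do.call(simulation_config, c(base, list(rpa = list(beta = 1))))
  gn <- simulate_genome(cfg0)
  dsbs <- simulate_dsbs(cfg0, gn)
  t0 <- simulate_tracks(cfg0, gn, dsbs)
  t1 <- simulate_tracks(cfg1, gn, dsbs)
  chrom <- dsbs$chrom[1]
  side <- dsbs$hybrid_side[1]
  strand <- if (side == "right") "crick" else "watson"
  cutbin <- floor(dsbs$cut[1] / cfg0$bin_size) + 1
  prox <- if (side == "right") cutbin:(cutbin + 9) else (cutbin - 10):(cutbin - 1)
  # beta = 0: RPA equals the pure resection decay (END-seq shape x amp ratio)
  ratio <- t0$tracks$rpa_4h[[strand]][[chrom]][prox] /
    t0$tracks$endseq_4h[[strand]][[chrom]][prox]
  expect_true(all(abs(ratio - 3 / 4) < 1e-9))
  # beta = 1 doubles the proximal span
  expect_equal(t1$tracks$rpa_4h[[strand]][[chrom]][prox],
               2 * t0$tracks$rpa_4h[[strand]][[chrom]][prox])
})

test_that("per-track RNG streams are independent of bundle composition", {
  cfg <- simulation_config(seed = 77)
  gn <- simulate_genome(cfg)
  dsbs <- simulate_dsbs(cfg, gn)
  tb1 <- simulate_tracks(cfg, gn, dsbs)
  tb2 <- simulate_tracks(cfg, gn, dsbs)
  expect_identical(tb1$tracks, tb2$tracks)
  expect_identical(tb1$spike_reads, tb2$spike_reads)
})

test_that("DRB time course is deterministic with truth rates recorded", {
  cfg <- simulation_config(seed = 6)
  d1 <- simulate_drb_timecourse(cfg)
  d2 <- simulate_drb_timecourse(cfg)
  expect_identical(d1$timecourses, d2$timecourses)
  expect_equal(nrow(d1$truth), cfg$drb$n_genes)
  expect_true(all(d1$truth$rate == cfg$drb$rate))
  bad <- simulation_config(seed = 6, drb = list(times = c(10, 5)))
  expect_error(simulate_drb_timecourse(bad), "increasing")
})

test_that("noiseless DRB crest sits at the front position", {
  cfg <- simulation_config(seed = 4, noise = list(enabled = FALSE),
                           drb = list(n_genes = 3))
  drb <- simulate_drb_timecourse(cfg)
  tc <- drb$timecourses[[1]]
  j <- which(tc$times == 10)
  peak_pos <- tc$positions[which.max(tc$coverage[j, ])]
  expect_lt(abs(peak_pos - 2 * 1000 * 10), 100)
})
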