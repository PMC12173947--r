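test_that("template strand maps '+' to Crick and '-' to Watson", {
  expect_equal(template_strand("+"), "crick")
  expect_equal(template_strand("-"), "watson")
  expect_equal(template_strand(c("+", "-", "+")),
               c("crick", "watson", "crick"))
  expect_error(template_strand("."), "'\\+' or '-'")
})

test_that("resection split routes impulses to the correct strand class", {
  n <- 200
  bin <- 10
  cut <- 1000  # bin-aligned
  # impulse on Watson at cut + 5 bins -> right-side Watson is resected
  w <- numeric(n); k <- numeric(n)
  w[cut / bin + 1 + 5] <- 1
  sp <- split_by_resection(w, k, cut, 500, bin)
  expect_equal(sp$resected[6], 1)   # d = 5 bins, 0-based
  expect_equal(sum(sp$overhang), 0)
  expect_equal(sum(sp$resected), 1)

  # impulse on Crick at cut + 5 bins -> right-side Crick is the overhang
  w2 <- numeric(n); k2 <- numeric(n)
  k2[cut / bin + 1 + 5] <- 1
  sp2 <- split_by_resection(w2, k2, cut, 500, bin)
  expect_equal(sp2$overhang[6], 1)
  expect_equal(sum(sp2$resected), 0)

  # impulse on Watson on the LEFT side at distance 5 bins -> overhang
  w3 <- numeric(n); k3 <- numeric(n)
  w3[cut / bin - 5] <- 1  # bin covering [cut - 6*bin, cut - 5*bin)
  sp3 <- split_by_resection(w3, k3, cut, 500, bin)
  expect_equal(sp3$overhang[6], 1)
  expect_equal(sum(sp3$resected), 0)

  expect_error(split_by_resection(w, k, 20, 500, bin), "exceeds")
  expect_error(split_by_resection(w, k, cut, 505, bin), "multiple")
})

test_that("overhang + resected conserves the two-strand total", {
  set.seed(11)
  n <- 400; bin <- 25; cut <- 5000
  w <- rpois(n, 3); k <- rpois(n, 3)
  sp <- split_by_resection(w, k, cut, 2000, bin, combine = "sum")
  b <- 2000 / bin
  cb <- cut / bin + 1
  for (d in seq_len(b)) {
    total <- w[cb - d] + k[cb - d] + w[cb + d - 1] + k[cb + d - 1]
    expect_equal(sp$overhang[d] + sp$resected[d], total)
  }
  # mean combine halves the sum combine
  spm <- split_by_resection(w, k, cut, 2000, bin, combine = "mean")
  expect_equal(spm$overhang * 2, sp$overhang)
})

test_that("gene-direction orientation flips '-' rows and is involutive", {
  w <- rbind(1:6, 1:6)
  k <- rbind(11:16, 11:16)
  out <- orient_by_gene(w, k, c("+", "-"))
  # '+' row: template is Crick, untouched
  expect_equal(out$template[1, ], 11:16)
  expect_equal(out$nontemplate[1, ], 1:6)
  # '-' row: reversed and swapped -> template holds reversed Watson
  expect_equal(out$template[2, ], rev(1:6))
  expect_equal(out$nontemplate[2, ], rev(11:16))
  expect_equal(out$flipped, c(FALSE, TRUE))

  # involution: flipping the oriented pair again restores the input
  back <- orient_by_gene(out$nontemplate, out$template, c("+", "-"))
  expect_equal(back$template, k)
  expect_equal(back$nontemplate, w)

  expect_error(orient_by_gene(w, k, "+"), "one gene strand per")
})

test_that("orientation transforms conserve signal", {
  set.seed(5)
  w <- matrix(rpois(60, 4), 5)
  k <- matrix(rpois(60, 4), 5)
  strands <- c("+", "-", "-", "+", "-")
  out <- orient_by_gene(w, k, strands)
  expect_equal(sum(out$template) + sum(out$nontemplate), sum(w) + sum(k))
  expect_equal(sort(as.numeric(cbind(out$template, out$nontemplate))),
               sort(as.numeric(cbind(w, k))))
})

test_that("dominant-side orientation flips left-heavy windows only", {
  tr <- toy_track(size = 20000, bin = 100)
  # site A: all signal left of the cut; site B: right; site C: symmetric
  tr$watson$chrT[31:40] <- 5    # [3000,4000) left of cut at 4000
  tr$crick$chrT[121:130] <- 5   # [12000,13000) right of cut at 12000
  tr$watson$chrT[171:190] <- 2  # symmetric around cut at 18000
  sites <- data.frame(dsb_id = c("A", "B", "C"), chrom = "chrT",
                      cut = c(4000, 12000, 18000))
  out <- orient_by_dominant_side(tr, sites, halfwidth = 1000)
  expect_equal(unname(out$flipped), c(TRUE, FALSE, FALSE))
  # flipped row A: its Watson signal now appears right, on Crick
  expect_true(sum(out$crick["A", 11:20]) > 0)
  expect_equal(sum(out$watson["A", ]), 0)
})

test_that("hybrid-site ranking orders by induced gain with id tie-break", {
  minus <- toy_track(size = 20000, bin = 100)
  plus <- minus
  sites <- data.frame(dsb_id = c("s1", "s2", "s3"), chrom = "chrT",
                      cut = c(4000, 8000, 12000))
  plus$watson$chrT[41:45] <- 2   # s1 gains 10
  plus$crick$chrT[81:85] <- 1    # s2 gains 5
  top <- rank_hybrid_sites(plus, minus, sites, halfwidth = 1000, k = 2)
  expect_equal(top$dsb_id, c("s1", "s2"))
  expect_equal(top$score, c(10, 5))
  # all-zero gain: ordering falls back to dsb_id
  top0 <- rank_hybrid_sites(minus, minus, sites, halfwidth = 1000, k = 3)
  expect_equal(top0$dsb_id, c("s1", "s2", "s3"))
  expect_error(rank_hybrid_sites(plus, minus, sites, 1000, k = 5),
               "exceeds")
})

test_that("ranking recovers programmed hybrid amplitude order", {
  cfg <- simulation_config(
    seed = 31, noise = list(enabled = FALSE),
    dsb_contexts = c(five_prime_exon = 3, intergenic = 1)
  )
  gn <- simulate_genome(cfg)
  dsbs <- simulate_dsbs(cfg, gn)
  tb <- simulate_tracks(cfg, gn, dsbs)
  top <- rank_hybrid_sites(tb$tracks$qdrip_plus, tb$tracks$qdrip_minus,
                           dsbs, halfwidth = 2000, k = nrow(dsbs))
  amp <- tb$truth$dsbs$hybrid_amp
  amp[is.na(amp)] <- 0
  want <- dsbs$dsb_id[order(-amp, dsbs$dsb_id)]
  expect_equal(top$dsb_id, want)
})
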