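test_that("a near-degenerate matrix scans like a substring search", {
  m <- matrix(1e-6, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["T", c(1, 3, 4)] <- 1
  m["C", 2] <- 1
  motif <- motifMatrix(m, pseudocount = 1e-6)
  s <- "GGTCTTAAATCTTCTT"
  occ <- pwmScan(c(x = s), motif, p_threshold = 1e-2)
  lit <- gregexpr("(?=TCTT)", s, perl = TRUE)[[1]]
  expect_identical(occ$start, as.integer(lit) - 1L)

  expect_identical(nrow(pwmScan(c(e = ""), motif)), 0L)
  expect_identical(nrow(pwmScan(c(e = "TC"), motif)), 0L)
})

test_that("scan p-values equal exhaustive enumeration for small widths", {
  set.seed(33)
  for (w in 3:5) {
    probs <- matrix(rexp(4 * w), 4, w,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
    bg <- c(0.3, 0.2, 0.2, 0.3)
    motif <- motifMatrix(probs, background = bg)
    oracle <- pwm_tail_oracle(motif)
    seqs <- c(s = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                               prob = bg), collapse = ""))
    occ <- pwmScan(seqs, motif, p_threshold = 1)
    expect_identical(nrow(occ), 200L - w + 1L)
    p_oracle <- vapply(occ$score, oracle, numeric(1))
    expect_lt(max(abs(occ$p - p_oracle)), 1e-6)
    # monotone: higher score, smaller or equal p
    o <- order(occ$score)
    expect_true(all(diff(occ$p[o]) <= 1e-12))
  }
})

test_that("positions containing N are skipped, not scored", {
  motif <- readMotifMatrix(system.file("extdata",
                                       "cu_rich_motif_synthetic.tsv",
                                       package = "sasptools"))
  occ <- pwmScan(c(x = "TCTTNTCTTC"), motif, p_threshold = 1)
  expect_true(all(occ$start >= 5L))  # every window before 5 covers the N
})

test_that("anchoring converts genomic hits to strand-aware offsets", {
  ev <- data.frame(event_id = c("p", "m"), event_type = "SE",
                   chrom = "c1", strand = c("+", "-"),
                   gene_id = c("g1", "g2"),
                   up_start = c(500, 1500), up_end = c(600, 1600),
                   alt_start = c(1000, 1000), alt_end = c(1100, 1000 + 100),
                   down_start = c(1500, 500), down_end = c(1600, 600),
                   score = 0)
  # plus strand: occurrence [960, 966) upstream of the acceptor at 1000
  occ_p <- data.frame(event_id = "p", start = 960, end = 966)
  a_p <- anchorOccurrences(ev[1, ], occ_p)
  expect_equal(a_p$off_start, -40)
  expect_equal(a_p$off_end, -34)
  # minus strand mirror: acceptor at alt_end = 1100, occurrence
  # [1134, 1140) genomically downstream = 40 nt upstream in transcript
  occ_m <- data.frame(event_id = "m", start = 1134, end = 1140)
  a_m <- anchorOccurrences(ev[2, ], occ_m)
  expect_equal(a_m$off_start, -40)
  expect_equal(a_m$off_end, -34)

  far <- data.frame(event_id = "p", start = 400, end = 406)
  a_far <- anchorOccurrences(ev[1, ], far)
  expect_identical(nrow(a_far), 0L)
  expect_identical(attr(a_far, "n_dropped"), 1L)
})

test_that("simulated occurrences lift to genomic coordinates coherently", {
  # plant the literal consensus word so every instance is recoverable
  # at a stringent scan threshold
  sim <- simulateSplicing(40, motif = "TCTTC", seed = 17)
  motif <- readMotifMatrix(system.file("extdata",
                                       "cu_rich_motif_synthetic.tsv",
                                       package = "sasptools"))
  up <- sim$sequences[grepl("upstream_intron", names(sim$sequences))]
  occ <- pwmScan(up, motif, p_threshold = 1e-3)
  g <- occurrencesToGenomic(occ, sim$regions)
  anch <- anchorOccurrences(sim$events, g)
  rep_ev <- names(sim$truth$class)[sim$truth$class == "repressed"]
  # every repressed event's planted instance is recovered in-window
  for (e in rep_ev) {
    offs <- anch$off_start[anch$event_id == e]
    expect_true(any(offs == sim$truth$motif_placements[[e]]["offset"]))
  }
})

test_that("RNA-map windows reproduce the hypergeometric table worked example", {
  groups <- setNames(rep(c("repressed", "unchanged"), each = 10),
                     paste0("e", 1:20))
  # 8/10 repressed and 2/10 unchanged events carry a motif at -40
  carriers <- c(paste0("e", 1:8), paste0("e", 11:12))
  anch <- data.frame(event_id = carriers, off_start = -40, off_end = -35)
  attr(anch, "n_dropped") <- 0L
  map <- buildRnaMap(groups, anch, axis_range = c(-100L, 20L))
  win <- mapWindows(map)
  p_at <- win$p_repressed[win$center == -40]
  expect_equal(p_at, 2126 / 184756, tolerance = 1e-12)
  expect_equal(p_at, fisher_oracle(8, 2, 2, 8, "greater"),
               tolerance = 1e-12)
  expect_equal(p_at,
               fisher.test(matrix(c(8, 2, 2, 8), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  # densities are exon fractions
  d <- mapDensity(map)
  expect_equal(unname(d["repressed", map@axis %in% -40:-36]),
               rep(0.8, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("map construction is order-invariant and needs a reference group", {
  groups <- setNames(rep(c("repressed", "unchanged"), each = 5),
                     paste0("e", 1:10))
  anch <- data.frame(event_id = c("e1", "e2", "e6"),
                     off_start = c(-30, -50, -30),
                     off_end = c(-25, -45, -25))
  attr(anch, "n_dropped") <- 0L
  m1 <- buildRnaMap(groups, anch, axis_range = c(-80L, 10L))
  m2 <- buildRnaMap(groups[sample(10)], anch[3:1, ],
                    axis_range = c(-80L, 10L))
  expect_equal(mapWindows(m1), mapWindows(m2))
  expect_equal(mapDensity(m1), mapDensity(m2))

  expect_error(buildRnaMap(setNames(rep("repressed", 5), paste0("e", 1:5)),
                           anch), "reference-group error")

  # no occurrences anywhere: all windows p = 1
  empty <- data.frame(event_id = character(0), off_start = integer(0),
                      off_end = integer(0))
  attr(empty, "n_dropped") <- 0L
  m3 <- buildRnaMap(groups, empty, axis_range = c(-80L, 10L))
  expect_true(all(mapWindows(m3)$p_repressed == 1))
})

test_that("window significance reports raw p and optional BH adjustment", {
  groups <- setNames(rep(c("repressed", "unchanged"), each = 10),
                     paste0("e", 1:20))
  anch <- data.frame(event_id = paste0("e", 1:6), off_start = -40,
                     off_end = -35)
  attr(anch, "n_dropped") <- 0L
  map <- buildRnaMap(groups, anch, axis_range = c(-60L, 0L))
  raw <- windowSignificance(map)
  expect_false("p_adj_repressed" %in% names(raw))
  adj <- windowSignificance(map, adjust = TRUE)
  o <- order(adj$p_repressed)
  expect_true(all(diff(adj$p_adj_repressed[o]) >= -1e-12))
  expect_true(all(adj$p_adj_repressed >= adj$p_repressed - 1e-12))
})
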