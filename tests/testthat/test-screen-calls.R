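make_b_table <- function(il8, il6, sirna = "si_a", gene = "gA") {
  rbind(
    data.frame(sirna_id = sirna, gene_id = gene, replicate = 1:3,
               readout = "IL8", b = il8),
    data.frame(sirna_id = sirna, gene_id = gene, replicate = 1:3,
               readout = "IL6", b = il6))
}

test_that("primary hit rule enforces replicate consensus on both readouts", {
  hit <- callPrimaryHits(make_b_table(c(-2.5, -2.1, -0.5),
                                      c(-3.0, -2.2, -2.4)))
  expect_identical(hit$direction, "down")
  expect_identical(hit$n_down_IL8, 2L)
  expect_identical(hit$n_down_IL6, 3L)

  none <- callPrimaryHits(make_b_table(c(-2.5, -2.1, -0.5),
                                       c(-2.5, -1.0, -1.1)))
  expect_identical(none$direction, "none")

  up <- callPrimaryHits(make_b_table(c(2.5, 2.1, 0.5), c(2.5, 3.0, 2.2)))
  expect_identical(up$direction, "up")

  # as-printed reading: down < -2 strictly, up > 3
  border <- callPrimaryHits(make_b_table(c(-2, -2, -2), c(-2, -2, -2)),
                            as_printed = TRUE)
  expect_identical(border$direction, "none")
  expect_identical(
    callPrimaryHits(make_b_table(c(-2, -2, -2), c(-2, -2, -2)))$direction,
    "down")

  two <- rbind(make_b_table(c(-3, -3, -3), c(-3, -3, -3), "si_a", "gA"),
               make_b_table(c(0, 0, 0), c(0, 0, 0), "si_b", "gB"))
  expect_identical(callPrimaryHits(two),
                   callPrimaryHits(two[sample(nrow(two)), ]))

  expect_error(
    callPrimaryHits(make_b_table(c(-3, -3, -3), c(-3, -3, -3))[1:4, ]),
    "coverage error")
})

test_that("secondary validation reproduces the pooled t and gene rule", {
  scr <- list(IL8 = c(0.95, 1.05, 1.0, 0.98, 1.02, 1.01, 0.99, 1.0,
                      1.03, 0.97),
              IL6 = c(0.95, 1.05, 1.0, 0.98, 1.02, 1.01, 0.99, 1.0,
                      1.03, 0.97))
  tab <- expand.grid(sirna_id = paste0("si_", 1:4), readout = c("IL8", "IL6"),
                     replicate = 1:3, stringsAsFactors = FALSE)
  tab$gene_id <- "gA"
  # siRNAs 1 and 2 strongly inhibitory on both readouts; 3 and 4 null
  base <- c(si_1 = 0.5, si_2 = 0.55, si_3 = 1.0, si_4 = 1.0)
  set.seed(5)
  tab$npi <- base[tab$sirna_id] + c(-0.05, 0, 0.05)[tab$replicate]
  res <- secondaryValidation(tab, scr)

  t_pkg <- res$sirna$t[res$sirna$sirna_id == "si_1" &
                         res$sirna$readout == "IL8"]
  x <- tab$npi[tab$sirna_id == "si_1" & tab$readout == "IL8"]
  expect_equal(t_pkg, pooled_t_oracle(x, scr$IL8), tolerance = 1e-9)
  expect_equal(t_pkg, unname(t.test(x, scr$IL8, var.equal = TRUE)$statistic),
               tolerance = 1e-9)

  # null siRNAs match the scramble distribution: no qualification
  expect_false(any(res$sirna$qualify[res$sirna$sirna_id %in%
                                       c("si_3", "si_4")]))
  # exactly 2 of 4 siblings qualify on both readouts -> gene passes
  expect_identical(res$gene$n_qualifying, 2L)
  expect_true(res$gene$gene_pass)
})

test_that("k-means recovers separated blobs and the trivial k = 1 case", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20))
  x <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(30 * 2, sd = 1), 30, 2), 2, centers[i, ], "+")))
  truth <- rep(1:4, each = 30)
  fit <- kmeansCluster(x, k = 4, n_init = 10, seed = 3)
  expect_equal(adjusted_rand_index(fit$cluster, truth), 1)
  expect_identical(kmeansCluster(x, k = 4, n_init = 10, seed = 3)$cluster,
                   fit$cluster)

  one <- kmeansCluster(x, k = 1, n_init = 2, seed = 1)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(x)),
               tolerance = 1e-9)
  expect_error(kmeansCluster(x[1:3, ], k = 4), "parameter error")
})

test_that("k-means++ restarts match a 1000-restart random oracle", {
  set.seed(19)
  x <- matrix(rnorm(100), 50, 2)
  fit <- kmeansCluster(x, k = 4, n_init = 100, seed = 6)
  best <- Inf
  for (i in 1:1000) {
    o <- suppressWarnings(kmeans(x, centers = 4, algorithm = "Lloyd",
                                 iter.max = 100))
    if (o$tot.withinss < best) best <- o$tot.withinss
  }
  expect_lte(fit$tot_withinss, best + 1e-6)
})

test_that("cluster roles follow the reversion-margin rules", {
  centers <- rbind(c(BrdU_r1 = 6, p16_r1 = -4, p21_r1 = 0),
                   c(BrdU_r1 = 0, p16_r1 = 0, p21_r1 = 5),
                   c(BrdU_r1 = 0.1, p16_r1 = -0.2, p21_r1 = 0.3),
                   c(BrdU_r1 = 5, p16_r1 = 0, p21_r1 = 0))
  roles <- labelClusters(centers)
  expect_identical(roles$cluster_role,
                   c("arrest_reverted", "arrest_exacerbated",
                     "sasp_only", "other"))
  # precedence: a centroid that both reverts and exacerbates is reverted
  both <- labelClusters(rbind(c(BrdU_r1 = 6, p16_r1 = -4, p21_r1 = 6)))
  expect_identical(both$cluster_role, "arrest_reverted")
})
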