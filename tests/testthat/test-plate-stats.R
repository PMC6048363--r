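test_that("median polish handles degenerate and exactly additive inputs", {
  m <- matrix(7, 8, 12)
  fit <- medianPolish(m)
  expect_equal(max(abs(fit$residuals)), 0)
  expect_equal(fit$overall, 7)

  a <- rnorm(8); b <- rnorm(12)
  fit2 <- medianPolish(outer(a, b, "+"))
  expect_lt(max(abs(fit2$residuals)), 1e-9)
  # decomposition is exact and effect medians vanish at convergence
  rec <- fit2$overall + outer(fit2$row_effects, fit2$col_effects, "+")
  expect_equal(rec, outer(a, b, "+"), tolerance = 1e-9)
  expect_lt(abs(median(fit2$row_effects)), 1e-9)
  expect_lt(abs(median(fit2$col_effects)), 1e-9)

  bad <- matrix(rnorm(96), 8, 12)
  bad[1, 2:12] <- NA
  expect_error(medianPolish(bad), "fewer than 2 non-missing")
})

test_that("median polish matches the explicit-sweep oracle", {
  set.seed(101)
  for (i in 1:20) {
    m <- matrix(rnorm(96), 8, 12)
    m[sample(96, 1)] <- m[sample(96, 1)] + 10  # spiked cell
    if (i %% 4 == 0) m[sample(96, 5)] <- NA    # masked wells
    if (any(rowSums(!is.na(m)) < 2) || any(colSums(!is.na(m)) < 2)) next
    fit <- medianPolish(m, max_iter = 200L, tol = 1e-9)
    ora <- median_polish_oracle(m, max_iter = 200L, tol = 1e-9)
    expect_equal(fit$residuals, ora$residuals, tolerance = 1e-8)
    expect_equal(fit$overall, ora$overall, tolerance = 1e-8)
  }
})

test_that("median polish agrees with medpolish on complete matrices", {
  set.seed(7)
  m <- matrix(rnorm(96), 8, 12)
  fit <- medianPolish(m, max_iter = 500L, tol = 1e-12)
  ref <- stats::medpolish(m, maxiter = 500L, eps = 1e-12,
                          trace.iter = FALSE)
  expect_equal(unname(fit$residuals), unname(ref$residuals),
               tolerance = 1e-6)
})

test_that("B-scores absorb additive row/column shifts and flag spikes", {
  sim <- simulateScreen(88, replicate_count = 1L, seed = 21)
  b1 <- bScore(sim$plates, "IL8")

  w <- wells(sim$plates)
  w$IL8[w$row == 3L] <- w$IL8[w$row == 3L] + 100
  b2 <- bScore(PlateSet(w), "IL8")
  expect_lt(max(abs(b1$b - b2$b)), 1e-9)

  # an additive plate with one well spiked at +5 noise SD: the spike
  # dominates every other well's B-score
  set.seed(3)
  w3 <- w
  w3$IL8 <- 100 + rnorm(8)[w3$row] + rnorm(12)[w3$col] + rnorm(96)
  spike <- which(w3$well_role == "sample")[40]
  w3$IL8[spike] <- w3$IL8[spike] + 5
  b3 <- bScore(PlateSet(w3), "IL8")
  b3s <- b3[b3$well_role == "sample", ]
  top <- b3s[which.max(abs(b3s$b)), ]
  expect_identical(paste(top$row, top$col),
                   paste(w3$row[spike], w3$col[spike]))
  expect_gt(abs(top$b), 3)

  # flat plate: zero MAD is a degenerate-plate error
  w4 <- w; w4$IL8 <- 5
  expect_error(bScore(PlateSet(w4), "IL8"), "degenerate plate.*MAD")
})

test_that("NPI is the affine rescaling between control means", {
  w <- wells(simulateScreen(88, replicate_count = 1L, seed = 4)$plates)
  w$IL8[w$well_role == "negative_control"] <- 100
  w$IL8[w$well_role == "positive_control"] <- 10
  w$IL8[w$well_role == "sample"][1:3] <- c(100, 10, 55)
  res <- npi(PlateSet(w), "IL8")
  s <- res[res$well_role == "sample", ]
  m <- merge(w[w$well_role == "sample", c("row", "col", "IL8")],
             s[, c("row", "col", "npi")], by = c("row", "col"))
  expect_equal(m$npi, (m$IL8 - 10) / 90, tolerance = 1e-12)
  expect_equal(mean(res$npi[res$well_role == "negative_control"]), 1)
  expect_equal(mean(res$npi[res$well_role == "positive_control"]), 0)

  w$IL8[w$well_role == "positive_control"] <- 100
  expect_error(npi(PlateSet(w), "IL8"), "degenerate controls")
})

test_that("scramble SD cutoffs follow mean +/- k SD", {
  expect_equal(unname(scrambleSdCutoffs(c(-1, 0, 1), k = 2)), c(-2, 2))
  expect_equal(unname(scrambleSdCutoffs(c(3, 3, 3))), c(3, 3))
  expect_error(scrambleSdCutoffs(c(1, 2)), "sample-size error")
  set.seed(12)
  cuts <- scrambleSdCutoffs(rnorm(1e4), k = 2)
  expect_lt(max(abs(unname(cuts) - c(-2, 2))), 0.05)
})
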