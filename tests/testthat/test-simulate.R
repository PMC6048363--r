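test_that("screen simulator is deterministic and capacity-checked", {
  a <- simulateScreen(60, seed = 42)
  b <- simulateScreen(60, seed = 42)
  expect_identical(wells(a$plates), wells(b$plates))
  expect_identical(a$truth$effects, b$truth$effects)
  c <- simulateScreen(60, seed = 43)
  expect_false(identical(wells(a$plates)$IL8, wells(c$plates)$IL8))

  expect_error(simulateScreen(100, n_plates = 1L), "capacity error")
})

test_that("pure-noise plates have sample SD near the stated noise SD", {
  # zero effects, zero artifacts: the only variation is N(0, noise_sd)
  sim <- simulateScreen(88 * 20, replicate_count = 1L,
                        artifact_spec = list(row_sd = 0, col_sd = 0),
                        noise_sd = 1, seed = 9)
  w <- wells(sim$plates)
  s <- sd(w$IL8[w$well_role == "sample"])
  expect_lt(abs(s - 1), 0.1)
  # well noise matches its stated family
  ks <- ks.test(w$IL8[w$well_role == "sample"] - sim$truth$baseline,
                "pnorm", 0, 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("a strongly inhibited gene sits at the plate minimum", {
  # oracle: P(the planted well is the strict minimum of an 88-well
  # plate) = E[(1 - Phi(x))^87], x ~ N(effect, 1)
  effect <- -4
  p_true <- integrate(function(x)
    dnorm(x, effect, 1) * (1 - pnorm(x))^87, -Inf, Inf)$value
  expect_gte(p_true, 0.9)

  n_rep <- 300L
  eff <- data.frame(gene_id = "gene00001", IL8 = effect)
  sim <- simulateScreen(88, replicate_count = n_rep, effect_table = eff,
                        artifact_spec = list(row_sd = 0, col_sd = 0),
                        seed = 31)
  w <- wells(sim$plates)
  w <- w[w$well_role == "sample", ]
  hit_min <- vapply(split(w, w$replicate), function(pw)
    pw$gene_id[which.min(pw$IL8)] == "gene00001", logical(1))
  expect_gt(mean(hit_min),
            p_true - 3 * sqrt(p_true * (1 - p_true) / n_rep))
})

test_that("splicing simulator honors classes, placement and determinism", {
  a <- simulateSplicing(30, seed = 7)
  b <- simulateSplicing(30, seed = 7)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$junction_counts, b$junction_counts)

  u <- simulateSplicing(30, class_proportions = c(unchanged = 1),
                        seed = 7)
  expect_identical(sum(u$truth$class == "repressed"), 0L)
  expect_length(u$truth$motif_placements, 0L)

  # repressed events gain inclusion upon knockdown; placements lie in
  # the declared window
  rep_ev <- names(a$truth$class)[a$truth$class == "repressed"]
  expect_true(all(a$truth$psi_knockdown[rep_ev] >
                    a$truth$psi_control[rep_ev]))
  offs <- vapply(a$truth$motif_placements, `[[`, numeric(1), "offset")
  expect_true(all(offs >= -60 & offs <= -20 - 5))

  expect_error(simulateSplicing(10, placement_window = c(-4L, 0L)),
               "motif longer than the placement window")
})

test_that("high-coverage junction counts concentrate on the true PSI", {
  sim <- simulateSplicing(50, coverage = 1e6, seed = 13)
  jc <- sim$junction_counts
  ctrl <- jc[jc$condition == "control" & jc$replicate == 1L, ]
  est <- psiFromJunctions(ctrl$inc1, ctrl$inc2, ctrl$skip)
  expect_lt(max(abs(est$psi - sim$truth$psi_control[ctrl$event_id])),
            0.01)
  kd <- jc[jc$condition == "knockdown" & jc$replicate == 1L, ]
  est_kd <- psiFromJunctions(kd$inc1, kd$inc2, kd$skip)
  d <- est_kd$psi - est$psi
  d_true <- sim$truth$psi_knockdown - sim$truth$psi_control
  expect_lt(max(abs(d - d_true[kd$event_id])), 0.01)
})

test_that("tissue simulator plants an anti-correlated bimodal structure", {
  sim <- simulateTissueMatrix(n_genes = 300, n_samples = 250, seed = 5)
  reg <- log2(sim$counts[sim$truth$regulator, ] + 1)
  expect_lt(cor(reg, sim$psi), 0)
  expect_identical(sim$counts,
                   simulateTissueMatrix(n_genes = 300, n_samples = 250,
                                        seed = 5)$counts)
  empty <- simulateTissueMatrix(n_genes = 100, n_samples = 50,
                                enriched_set_size = 0, seed = 5)
  expect_length(empty$truth$enriched_set, 0L)
  expect_error(simulateTissueMatrix(n_genes = 50, n_samples = 20,
                                    lib_size = 0),
               "library size")
})
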