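test_that("PSI estimators follow their defining arithmetic", {
  expect_equal(psiFromJunctions(10, 10, 10)$psi, 0.5)
  expect_equal(psiFromJunctions(30, 10, 20)$psi, 0.5)  # I = 20
  expect_equal(psiFromJunctions(30, 10, 20)$effective_coverage, 40)
  expect_equal(psiFromJunctions(5, 5, 0)$psi, 1)
  expect_equal(psiFromJunctions(0, 0, 7)$psi, 0)
  expect_error(psiFromJunctions(0, 0, 0, event_id = "evX"),
               "undefined PSI.*evX")

  expect_equal(psiFromConcentrations(2, 2), 0.5)
  expect_equal(psiFromConcentrations(0, 3), 0)
  expect_equal(psiFromConcentrations(9, 1), 0.9)
  expect_error(psiFromConcentrations(0, 0), "undefined PSI")
})

test_that("delta-PSI test matches the Fisher oracle and is symmetric", {
  a <- data.frame(event_id = "e1", inc1 = 10, inc2 = 10, skip = 10)
  b <- data.frame(event_id = "e1", inc1 = 18, inc2 = 18, skip = 2)
  r <- deltaPsiTest(a, b)
  # 2x2 table [I, skip] x [A, B] with I rounded half-up
  expect_equal(r$p, fisher_oracle(10, 18, 10, 2, "two.sided"),
               tolerance = 1e-12)
  expect_equal(r$delta_psi, 0.9 - 0.5, tolerance = 1e-12)

  r_swap <- deltaPsiTest(b, a)
  expect_equal(r_swap$delta_psi, -r$delta_psi, tolerance = 1e-12)
  expect_equal(r_swap$p, r$p, tolerance = 1e-12)

  same <- deltaPsiTest(a, a)
  expect_equal(same$delta_psi, 0)
  expect_equal(same$p, 1)

  # replicate rows pool by summation before testing
  a2 <- data.frame(event_id = c("e1", "e1"), inc1 = c(4, 6),
                   inc2 = c(5, 5), skip = c(3, 7))
  expect_equal(deltaPsiTest(a2, b)$p,
               deltaPsiTest(data.frame(event_id = "e1", inc1 = 10,
                                       inc2 = 10, skip = 10), b)$p)

  degen <- deltaPsiTest(data.frame(event_id = "e1", inc1 = 2, inc2 = 2,
                                   skip = 0),
                        data.frame(event_id = "e1", inc1 = 4, inc2 = 4,
                                   skip = 0))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)

  expect_error(deltaPsiTest(a, data.frame(event_id = "e9", inc1 = 1,
                                          inc2 = 1, skip = 1)),
               "coverage error")
})

test_that("regulation classes follow the delta/FDR rule", {
  rec <- data.frame(event_id = c("a", "b", "c", "d"),
                    delta_psi = c(0.25, 0.25, -0.5, 0.1),
                    fdr = c(0.01, 0.2, 1e-6, 1e-6))
  out <- classifyRegulation(rec)
  expect_identical(out$regulation_class,
                   c("repressed", "unchanged", "enhanced", "unchanged"))
  expect_error(classifyRegulation(rec[, -3]), "fdr")
})

test_that("two-tier shortlisting applies the stricter senescence-naive cutoff", {
  reg <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                    delta_psi = c(0.25, 0.25, 0.35, 0.1),
                    fdr = c(0.01, 0.01, 0.01, 0.01))
  sen <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                    delta_psi = c(0.30, 0.01, 0.01, 0.5),
                    fdr = c(0.01, 0.9, 0.9, 0.01))
  out <- shortlistEvents(reg, sen)
  expect_identical(out$event_id, c("e3", "e1"))
  expect_identical(out$tier, c(2L, 1L))  # e2 excluded: 0.25 < strict 0.3
  # order-invariant
  out2 <- shortlistEvents(reg[4:1, ], sen[c(2, 4, 1, 3), ])
  expect_identical(out, out2)
  expect_error(shortlistEvents(reg, sen[1:3, ]), "coverage error")
})

test_that("inclusion proportion test matches the analytic chi-square tail", {
  even <- inclusionProportionTest(50, 100)
  expect_equal(even$chi2, 0)
  expect_equal(even$p_one_sided, 0.5)

  r <- inclusionProportionTest(70, 100)
  expect_equal(r$chi2, 16)
  # chi-square(1) tail halved = upper normal tail at z = 4
  expect_equal(r$p_one_sided, pnorm(-4), tolerance = 1e-8)

  opp <- inclusionProportionTest(0, 10)
  expect_gt(opp$p_one_sided, 0.99)
  expect_error(inclusionProportionTest(5, 0), "sample-size error")
})

test_that("event-type summaries count the five AS classes", {
  ev <- data.frame(event_type = c("SE", "SE", "SE", "RI"))
  s <- summarizeEventTypes(ev)
  expect_identical(s$n, c(3L, 1L, 0L, 0L, 0L))
  expect_equal(sum(s$fraction), 1)
  empty <- summarizeEventTypes(data.frame(event_type = character(0)))
  expect_identical(empty$n, rep(0L, 5))
  expect_error(summarizeEventTypes(data.frame(event_type = "EX")),
               "unknown event type")
})
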