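test_that("noiseless 3PL data is recovered essentially exactly", {
  d <- make_dr(bottom = 0, top = 1, logec50 = -6)
  f <- fit_3pl(d)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients["bottom"]), 0, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["top"]), 1, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["logec50"]), -6, tolerance = 1e-6)
  expect_lt(f$ss, 1e-10)
  expect_equal(f$df, nrow(d) - 3)
})

test_that("flat data yields a flagged degenerate fit, not an error", {
  d <- tibble::tibble(log10_conc_M = rep(seq(-8, -2), each = 3),
                      response = 0.25)
  f <- fit_3pl(d)
  expect_true(f$degenerate)
  expect_lt(abs(f$span), 1e-6)
})

test_that("too few concentrations is an error", {
  d <- make_dr(0, 1, -6, x = c(-8, -6, -4))
  expect_error(fit_3pl(d), class = "orevo_dose_error")
})

test_that("fit is equivariant to response scaling and dose shifts", {
  d <- make_dr(0.1, 1.1, -5.5, sd = 0.03, seed = 4)
  f <- fit_3pl(d)
  c_scale <- 7
  f2 <- fit_3pl(dplyr::mutate(d, response = response * c_scale))
  expect_equal(unname(f2$coefficients["bottom"]),
               c_scale * unname(f$coefficients["bottom"]), tolerance = 1e-4)
  expect_equal(f2$span, c_scale * f$span, tolerance = 1e-4)
  expect_equal(unname(f2$coefficients["logec50"]),
               unname(f$coefficients["logec50"]), tolerance = 1e-5)
  expect_equal(f2$ss, c_scale^2 * f$ss, tolerance = 1e-4)
  f3 <- fit_3pl(dplyr::mutate(d, log10_conc_M = log10_conc_M + 1))
  expect_equal(unname(f3$coefficients["logec50"]),
               unname(f$coefficients["logec50"]) + 1, tolerance = 1e-5)
})

test_that("logEC50 confidence intervals achieve near-nominal coverage", {
  # sigma = 5% of span, triplicates, 8 doses
  n_rep <- 100
  hits <- 0
  for (i in seq_len(n_rep)) {
    d <- make_dr(0, 1, -5, x = seq(-8, -1, by = 1), sd = 0.05, seed = 2000 + i)
    f <- fit_3pl(d)
    if (f$ci_lower["logec50"] <= -5 && -5 <= f$ci_upper["logec50"]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("extra-SS test treats an exact copy as one shared curve", {
  d <- make_dr(0, 1, -6, sd = 0.05, seed = 9)
  r <- extra_ss_compare(d, d)
  expect_lt(r$F, 1e-6)
  expect_equal(r$p, 1, tolerance = 1e-6)
  # 2 curves x 7 concentrations x 3 replicates -> denominator df = 36
  expect_equal(r$df_den, 36)
  expect_equal(r$df_num, 3)
})

test_that("extra-SS test is symmetric in its arguments", {
  a <- make_dr(0, 1, -6, sd = 0.05, seed = 21)
  b <- make_dr(0, 0.6, -5, sd = 0.05, seed = 22)
  r1 <- extra_ss_compare(a, b)
  r2 <- extra_ss_compare(b, a)
  expect_equal(r1$F, r2$F, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("agonist gate applies all three criteria by name", {
  ctrl <- make_dr(0, 0, -6, sd = 0.02, seed = 31)
  # strong sigmoid over flat control passes
  d <- make_dr(0, 1, -5, sd = 0.02, seed = 32)
  f <- fit_3pl(d)
  g <- agonist_gate(f, d, ctrl)
  expect_true(g$agonist)
  expect_length(g$reasons, 0)
  # flat receptor data fails the CI-separation criterion
  flat <- make_dr(0, 0, -6, sd = 0.02, seed = 33)
  ff <- fit_3pl(flat)
  gf <- agonist_gate(ff, flat, ctrl)
  expect_false(gf$agonist)
  expect_true("top_bottom_ci_overlap" %in% gf$reasons)
  # an imprecise logEC50 (SE >= 1 log unit) fails criterion 2
  f2 <- f
  f2$se["logec50"] <- 1.5
  g2 <- agonist_gate(f2, d, ctrl)
  expect_true("logec50_sd_too_large" %in% g2$reasons)
  expect_false(g2$agonist)
  expect_error(agonist_gate(f, d, NULL), class = "orevo_control_error")
})

test_that("pair classification follows the concordance rule", {
  # identical data: indistinguishable
  d <- make_dr(0, 1, -6, sd = 0.05, seed = 41)
  expect_equal(classify_pair(d, d)$label, "indistinguishable")
  # A 10x more potent and twice the span: hyperfunctional
  a <- make_dr(0, 2, -6, sd = 0.02, seed = 42)
  b <- make_dr(0, 1, -5, sd = 0.02, seed = 43)
  cls <- classify_pair(a, b)
  expect_equal(cls$label, "a_hyperfunctional")
  expect_lt(cls$d_logec50, 0)
  expect_gt(cls$d_span, 0)
  expect_equal(classify_pair(b, a)$label, "a_hypofunctional")
  # discordant: lower EC50 but smaller span
  a2 <- make_dr(0, 0.5, -6.5, sd = 0.02, seed = 44)
  b2 <- make_dr(0, 1, -4.5, sd = 0.02, seed = 45)
  expect_equal(classify_pair(a2, b2)$label, "undefined")
})

test_that("pairs failing the agonist gate are not comparable", {
  ctrl <- make_dr(0, 0, -6, sd = 0.02, seed = 51)
  a <- make_dr(0, 1, -5.5, sd = 0.02, seed = 52)
  flat <- make_dr(0, 0, -6, sd = 0.02, seed = 53)
  cls <- classify_pair(a, flat, control_a = ctrl, control_b = ctrl)
  expect_equal(cls$label, "not_comparable")
})

test_that("display normalization scales a curve set as documented", {
  a <- make_dr(0.2, 1.2, -6)  # span 1.0
  b <- make_dr(0.2, 0.7, -6)  # span 0.5
  out <- normalize_curve_set(list(A = a, B = b), mode = "max_of_set")
  expect_equal(max(out$scaled_response[out$receptor == "A"]), 1,
               tolerance = 1e-3)
  expect_equal(max(out$scaled_response[out$receptor == "B"]), 0.5,
               tolerance = 1e-3)
  # reference mode: divide by the reference fitted top, no baselining
  ref <- normalize_curve_set(list(A = a, B = b), mode = "reference",
                             reference = "A")
  expect_equal(ref$scaled_response, c(a$response, b$response) / 1.2,
               tolerance = 1e-3)
  flat <- make_dr(0, 0, -6)
  expect_error(normalize_curve_set(list(A = flat)),
               class = "orevo_degenerate_scope_error")
})
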