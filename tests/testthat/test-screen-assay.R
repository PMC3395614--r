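toy_plate <- function() {
  # 3 odor wells with hand-set readings plus duplicate no-odor controls
  tibble::tibble(
    receptor = "R",
    odor = c("a", "b", "c", "no_odor", "no_odor"),
    replicate = c(1, 1, 1, 1, 2),
    firefly = c(200, 400, 100, 110, 90),
    renilla = c(100, 100, 100, 100, 100),
    plate_id = "p1")
}

test_that("plate normalization anchors the scope extremes at 0 and 1", {
  sc <- normalize_plate(toy_plate())
  w <- sc$wells
  # ratios: 2, 4, 1, 1.1, 0.9 -> L_min 0.9, L_max 4
  expect_equal(w$normalized[w$odor == "c"], (1 - 0.9) / (4 - 0.9))
  expect_equal(min(w$normalized), 0)
  expect_equal(max(w$normalized), 1)
  expect_equal(sc$anchors$l_min, 0.9)
  expect_equal(sc$anchors$l_max, 4)
  expect_true(all(w$normalized >= 0 & w$normalized <= 1))
})

test_that("normalization is invariant to rescaling the raw luminescence", {
  p <- toy_plate()
  sc1 <- normalize_plate(p)
  p2 <- dplyr::mutate(p, firefly = firefly * 37.5)
  sc2 <- normalize_plate(p2)
  expect_equal(sc2$wells$normalized, sc1$wells$normalized)
  p3 <- dplyr::mutate(p, firefly = firefly * 2.5, renilla = renilla * 2.5)
  sc3 <- normalize_plate(p3)
  expect_equal(sc3$wells$normalized, sc1$wells$normalized)
})

test_that("degenerate and invalid plates are rejected", {
  flat <- dplyr::mutate(toy_plate(), firefly = 100)
  expect_error(normalize_plate(flat), class = "orevo_degenerate_scope_error")
  bad <- dplyr::mutate(toy_plate(), renilla = c(100, 100, 0, 100, 100))
  expect_error(normalize_plate(bad), class = "orevo_plate_error")
})

test_that("per-plate scope normalizes within each plate separately", {
  p <- dplyr::bind_rows(
    toy_plate(),
    dplyr::mutate(toy_plate(), plate_id = "p2", firefly = firefly * 10))
  sc <- normalize_plate(p, scope = "plate")
  w <- sc$wells
  for (pid in c("p1", "p2")) {
    expect_equal(min(w$normalized[w$plate_id == pid]), 0)
    expect_equal(max(w$normalized[w$plate_id == pid]), 1)
  }
  expect_equal(nrow(sc$anchors), 2)
})

test_that("agonist calls agree with the t-test oracle and keep signs", {
  plate <- withr::with_seed(11, {
    n_odors <- 10
    eff <- tibble::tibble(
      receptor = "R",
      odor = c("odor01", "odor02"),
      effect = c(0.5, -0.4))  # one agonist, one inhibitor
    simulate_screen("R", n_odors = n_odors, effects = eff, noise_sd = 0.02,
                    seed = 11)
  })
  sc <- normalize_plate(plate)
  calls <- call_agonists(sc, n_odors = 10)
  r <- calls[calls$receptor == "R", ]
  expect_true(r$significant[r$odor == "odor01"])
  expect_true(r$significant[r$odor == "odor02"])
  expect_lt(r$mean_response[r$odor == "odor02"], 0)
  # oracle: pooled-variance two-sample t test per cell
  w <- sc$wells
  ctrl <- w$normalized[w$receptor == "R" & w$odor == "no_odor"]
  for (od in c("odor01", "odor05")) {
    x <- w$normalized[w$receptor == "R" & w$odor == od]
    expect_equal(r$p_value[r$odor == od],
                 stats::t.test(x, ctrl, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("odor cells identical to the control are never significant", {
  p <- tibble::tibble(
    receptor = "R",
    odor = rep(c("a", "no_odor", "spread"), each = 3),
    replicate = rep(1:3, 3),
    firefly = c(100, 110, 90, 100, 110, 90, 50, 300, 150),
    renilla = 100, plate_id = "p1")
  calls <- call_agonists(normalize_plate(p), n_odors = 2)
  expect_false(calls$significant[calls$odor == "a"])
  expect_equal(calls$mean_response[calls$odor == "a"], 0)
})

test_that("missing or undersized controls are reported", {
  p <- dplyr::filter(toy_plate(), odor != "no_odor")
  expect_error(call_agonists(normalize_plate(p)),
               class = "orevo_control_error")
  p2 <- toy_plate()[-5, ]  # single control replicate
  expect_error(call_agonists(normalize_plate(p2)),
               class = "orevo_plate_error")
})

test_that("non-significant responses are zeroed only in the tuning copy", {
  calls <- tibble::tibble(
    receptor = "R", odor = c("a", "b"),
    n = 3, mean_response = c(0.5, 0.2), se = 0.1,
    p_value = c(1e-6, 0.5), significant = c(TRUE, FALSE))
  tr <- tuning_responses(calls)
  expect_equal(tr$response, c(0.5, 0))
  expect_equal(calls$mean_response, c(0.5, 0.2))  # source untouched
  raw <- tuning_responses(calls, zero_nonsignificant = FALSE)
  expect_equal(raw$response, c(0.5, 0.2))
})

test_that("center-out ordering places ranks alternately around the center", {
  resp <- tibble::tibble(
    receptor = rep(c("ref", "var"), each = 3),
    odor = rep(c("x", "y", "z"), 2),
    response = c(5, 3, 1, 0.1, 0.2, 0.3))
  tc <- order_tuning_curve(resp, reference = "ref")
  ref <- tc[tc$receptor == "ref", ]
  # rank 1 (x) center, rank 2 (y) right, rank 3 (z) left
  expect_equal(ref$odor[order(ref$position)], c("z", "x", "y"))
  # variant reuses the reference ordering
  var <- tc[tc$receptor == "var", ]
  expect_equal(var$position[match(ref$odor, var$odor)], ref$position)
})

test_that("tied responses fall back to lexicographic center-out order", {
  resp <- tibble::tibble(receptor = "r", odor = c("b", "a", "c"),
                         response = c(1, 1, 1))
  tc <- order_tuning_curve(resp, reference = "r")
  expect_equal(tc$odor[order(tc$rank)], c("a", "b", "c"))
  expect_equal(sort(tc$position), 1:3)
})

test_that("tuning ordering is a permutation for any panel size", {
  for (n in c(2, 5, 42)) {
    resp <- withr::with_seed(n, tibble::tibble(
      receptor = "r", odor = sprintf("o%02d", 1:n),
      response = stats::rnorm(n)))
    tc <- order_tuning_curve(resp, reference = "r")
    expect_setequal(tc$position, seq_len(n))
    expect_setequal(tc$odor, resp$odor)
  }
  expect_error(order_tuning_curve(
    tibble::tibble(receptor = "r", odor = "a", response = 1), "nope"),
    class = "orevo_reference_error")
})
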