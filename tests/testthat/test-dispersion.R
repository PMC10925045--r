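test_that("vertical reflection factor matches its frozen direct evaluation", {
  # independent term-by-term value at the coastal defaults
  expect_equal(oracle_vertical(2, 1, 900, 2), 0.2706705664732254, tolerance = 1e-15)
  expect_equal(vertical_term(plume_params(l = 900)), 0.2706705664732254,
    tolerance = 1e-12
  )
  # reflections are invisible at these scales: l = 900 vs 1100 identical
  expect_equal(vertical_term(plume_params(l = 1100)), vertical_term(plume_params(l = 900)))
  # and increasing the reflection bound changes nothing
  expect_equal(
    vertical_term(plume_params(l = 900, n_reflections = 10)),
    vertical_term(plume_params(l = 900, n_reflections = 2)),
    tolerance = 1e-15
  )
})

test_that("vertical factor reaches its analytic limits", {
  # ground-level source under an infinitely deep mixing layer
  expect_equal(vertical_term(plume_params(h = 0, l = 1e9)), 2.0)
  # delta_z -> infinity: every exponent -> 0, P -> 2 + 2N
  expect_equal(vertical_term(plume_params(delta_z = 1e6, l = 900)), 6, tolerance = 1e-6)
  expect_equal(
    vertical_term(plume_params(delta_z = 1e6, l = 900, n_reflections = 5)),
    12,
    tolerance = 1e-5
  )
})

test_that("single-receptor concentration follows the plume formula", {
  p <- plume_params(l = 900)
  # source strength chosen to cancel the prefactor: C(y = 0) = P
  E0 <- 2 * pi * 3.7 * 1.33 * 1
  expect_equal(concentration_at(E0, 0, p), vertical_term(p), tolerance = 1e-12)
  expect_equal(concentration_at(0, 1, p), 0)
  expect_equal(
    concentration_at(1, 1, p),
    oracle_concentration(1, 1, 3.7, 1.33, 1, 2, 900, 2),
    tolerance = 1e-14
  )
  expect_error(concentration_at(-1, 0, p), "non-negative")
})

test_that("plume output matches the independent oracle over random draws", {
  set.seed(1234)
  for (i in 1:200) {
    mu <- runif(1, 0.5, 10)
    dy <- runif(1, 0.5, 5)
    dz <- runif(1, 0.5, 5)
    h <- runif(1, 0, 50)
    l <- runif(1, 100, 2000)
    nref <- sample(0:5, 1)
    E <- runif(1, 0, 100)
    y <- runif(1, -10, 10)
    p <- plume_params(
      mu = mu, delta_y = dy, delta_z = dz, h = h, l = l,
      n_reflections = nref
    )
    got <- concentration_at(E, y, p)
    want <- oracle_concentration(E, y, mu, dy, dz, h, l, nref)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("averaged concentration is the mean over receptor offsets", {
  p <- plume_params(l = 900)
  expect_equal(
    average_concentration(1, p),
    oracle_average(1, 3.7, 1.33, 1, 2, 900, 2),
    tolerance = 1e-14
  )
  expect_equal(average_concentration(0, p), 0)
  # linearity
  expect_equal(average_concentration(2 * 7.3, p), 2 * average_concentration(7.3, p))
  a <- runif(1, 0, 10)
  expect_equal(average_concentration(a * 5, p), a * average_concentration(5, p))
  # degenerate offset list is refused
  expect_error(plume_params(receptor_offsets = numeric(0)))
  broken <- p
  broken$receptor_offsets <- numeric(0)
  expect_error(average_concentration(1, broken), "non-empty")
})

test_that("concentration decreases in |y|, wind speed, and source height", {
  p <- plume_params(l = 900)
  ys <- seq(0, 5, by = 0.5)
  cs <- vapply(ys, function(y) concentration_at(1, y, p), numeric(1))
  expect_true(all(diff(cs) < 0))

  mus <- c(1, 2, 4, 8)
  cmu <- vapply(mus, function(m) {
    concentration_at(1, 1, plume_params(mu = m, l = 900))
  }, numeric(1))
  expect_true(all(diff(cmu) < 0))

  hs <- c(0, 1, 2, 3, 5)
  ch <- vapply(hs, function(h) {
    concentration_at(1, 1, plume_params(h = h, l = 900))
  }, numeric(1))
  expect_true(all(diff(ch) < 0))

  # upper bound from P <= 2 + 2N and the lateral factor <= 1
  set.seed(99)
  for (i in 1:20) {
    E <- runif(1, 0, 50)
    p2 <- plume_params(
      mu = runif(1, 0.5, 5), delta_y = runif(1, 0.5, 3),
      delta_z = runif(1, 0.5, 3), h = runif(1, 0, 10), l = runif(1, 200, 2000)
    )
    bound <- E * (2 + 2 * p2$n_reflections) /
      (2 * pi * p2$mu * p2$delta_y * p2$delta_z)
    expect_lte(concentration_at(E, runif(1, -5, 5), p2), bound)
  }
})

test_that("literal exp-of-sum reading is available and differs when reflections matter", {
  std <- plume_params(l = 5, delta_z = 4, h = 2)
  lit <- plume_params(l = 5, delta_z = 4, h = 2, literal_exp_of_sum = TRUE)
  expect_false(isTRUE(all.equal(vertical_term(std), vertical_term(lit))))
  # at default geometry the reflection terms underflow and the readings agree
  expect_equal(
    vertical_term(plume_params(l = 900, literal_exp_of_sum = TRUE)),
    vertical_term(plume_params(l = 900))
  )
})

test_that("mixing-layer height resolves from the coastal flag with override", {
  expect_equal(select_mixing_layer(TRUE), 900)
  expect_equal(select_mixing_layer(FALSE), 1100)
  expect_equal(select_mixing_layer(c(TRUE, FALSE), c(NA, NA)), c(900, 1100))
  expect_equal(select_mixing_layer(TRUE, 1000), 1000)
  expect_error(select_mixing_layer(TRUE, -5), "positive")
})

test_that("concentration table applies each airport's mixing layer", {
  reg <- tibble::tibble(airport = c("AAA", "BBB"), coastal = c(TRUE, FALSE))
  em <- tibble::tibble(
    year = 2020, month = 6, airport = c("AAA", "BBB"),
    flow_g_per_s = c(1, 1)
  )
  ct <- run_concentration_table(em, reg)
  expect_identical(nrow(ct), 2L)
  expect_true(all(ct$conc_ugm3 > 0 & is.finite(ct$conc_ugm3)))
  expect_equal(ct$conc_ugm3[1], oracle_average(1, 3.7, 1.33, 1, 2, 900, 2),
    tolerance = 1e-12
  )
  expect_equal(ct$conc_ugm3[2], oracle_average(1, 3.7, 1.33, 1, 2, 1100, 2),
    tolerance = 1e-12
  )

  empty <- em[0, ]
  expect_identical(nrow(run_concentration_table(empty, reg)), 0L)

  em_bad <- dplyr::mutate(em, airport = c("AAA", "ZZZ"))
  expect_error(run_concentration_table(em_bad, reg), "ZZZ")

  # a per-airport override replaces the coastal default
  reg2 <- dplyr::mutate(reg, mixing_layer_override = c(NA, 500))
  ct2 <- run_concentration_table(em, reg2, plume_params(delta_z = 100))
  expect_equal(ct2$conc_ugm3[2],
    oracle_average(1, 3.7, 1.33, 100, 2, 500, 2),
    tolerance = 1e-12
  )
})
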