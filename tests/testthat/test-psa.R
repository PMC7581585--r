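test_that("beta moment matching reproduces the target moments or refuses", {
  ab <- beta_from_moments(0.67, (0.2 * 0.67)^2)
  expect_equal(ab$alpha, 7.580, tolerance = 1e-3)
  expect_equal(ab$beta, 3.733, tolerance = 1e-3)

  # the literal variance-fraction rule is infeasible for the 0.82 utility
  expect_error(beta_from_moments(0.82, 0.2 * 0.82), "not below")
  expect_error(beta_from_moments(1.2, 0.01), "mean")

  # property: mean and variance recovered exactly for valid inputs
  set.seed(11)
  for (i in 1:20) {
    m <- runif(1, 0.01, 0.99)
    v <- runif(1, 1e-6, 0.9) * m * (1 - m)
    ab <- beta_from_moments(m, v)
    expect_equal(ab$alpha / (ab$alpha + ab$beta), m)
    s <- ab$alpha + ab$beta
    expect_equal(ab$alpha * ab$beta / (s^2 * (s + 1)), v)
  }
})

test_that("log-normal moment matching preserves the arithmetic mean", {
  lp <- lognormal_from_moments(45307, (0.2 * 45307)^2)
  expect_equal(lp$sigma2, log(1.04))
  expect_equal(lp$mu, log(45307) - log(1.04) / 2)
  expect_equal(exp(lp$mu + lp$sigma2 / 2), 45307)

  expect_equal(lognormal_from_moments(2223, 0)$sigma2, 0)
  expect_error(lognormal_from_moments(-5, 1), "positive")

  set.seed(12)
  for (i in 1:20) {
    m <- runif(1, 1, 1e5)
    v <- (runif(1, 0, 1) * m)^2
    lp <- lognormal_from_moments(m, v)
    expect_equal(exp(lp$mu + lp$sigma2 / 2), m)
    expect_equal((exp(lp$sigma2) - 1) * exp(2 * lp$mu + lp$sigma2), v, tolerance = 1e-9)
  }
})

test_that("the distribution table covers the sampled rows and validates eagerly", {
  p <- default_parameters()
  specs <- psa_distributions(p)
  expect_equal(nrow(specs), 30)
  expect_true(all(specs$family[grepl("costs", specs$address)] == "lognormal"))
  expect_true(all(specs$family[grepl("risks|utilities", specs$address)] == "beta"))
  # shared rows: mortality, second-period risks, utilities; arm-specific: the rest
  expect_equal(sum(specs$shared), 5 + 7 + 2)
  expect_equal(sum(!specs$shared), 4 + 12)
  expect_true(all(specs$mean > 0))

  # the literal variance rule must fail on the utility rows, loudly
  expect_error(
    psa_distributions(p, rule = "variance_fraction_of_mean"),
    "utilities"
  )
})

test_that("replicate draws are seeded, shared where stated, and mean-centred", {
  p <- default_parameters()
  specs <- psa_distributions(p)

  expect_identical(draw_replicate(p, specs[0, ]), p)

  one <- withr::with_seed(99, draw_replicate(p, specs))
  two <- withr::with_seed(99, draw_replicate(p, specs))
  expect_identical(one, two)
  # shared rows landed identically in both arms; arm-specific rows did not
  expect_identical(one$usual_care$utilities, one$pcc$utilities)
  expect_identical(one$usual_care$risks_5y, one$pcc$risks_5y)
  expect_identical(
    one$usual_care$risks_2y$death_after_remission1,
    one$pcc$risks_2y$death_after_remission1
  )
  expect_false(one$usual_care$risks_2y$relapse1 == one$pcc$risks_2y$relapse1)

  # law of large numbers: drawn means approach the base values
  n <- 4000
  draws <- withr::with_seed(123, vapply(seq_len(n), function(i) {
    d <- draw_replicate(p, specs)
    c(d$pcc$risks_2y$relapse1, d$usual_care$costs$relapse1_cost, d$pcc$utilities$remission)
  }, numeric(3)))
  means <- c(0.0093, 45307, 0.82)
  for (j in 1:3) {
    se <- sd(draws[j, ]) / sqrt(n)
    expect_lt(abs(mean(draws[j, ]) - means[j]), 3.5 * se)
  }
})

test_that("run_psa is reproducible and degenerates to the base case", {
  p <- default_parameters()
  a <- run_psa(p, n_draws = 25, seed = 5)
  b <- run_psa(p, n_draws = 25, seed = 5)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 25)

  # zero-variance specs reproduce the deterministic increments exactly
  specs0 <- psa_distributions(p)
  specs0$variance <- 0
  d0 <- run_psa(p, specs = specs0, n_draws = 1, seed = 1)$draws
  base <- compare_arms(p)
  expect_equal(d0$delta_qalys, base$increments$delta_qalys)
  expect_equal(d0$delta_cost_societal, base$increments$delta_cost_total)
  expect_equal(d0$delta_cost_direct_only, base$increments$delta_cost_direct)
})

test_that("acceptability curves agree with a per-replicate classification oracle", {
  p <- default_parameters()
  psa <- run_psa(p, n_draws = 200, seed = 31)
  grid <- c(0, 2e5, 5e5, 1e6)
  curve <- ceac(psa, grid)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))

  # brute-force recount straight from the draw table
  d <- psa$draws
  for (i in seq_along(grid)) {
    manual <- mean(grid[i] * d$delta_qalys - d$delta_cost_societal > 0)
    expect_equal(curve$probability[i], manual)
  }
  # probability at wtp 0 is the fraction of cost-saving replicates
  expect_equal(curve$probability[1], mean(d$delta_cost_societal < 0))
  expect_equal(
    prob_cost_effective(psa, wtp = 5e5),
    curve$probability[curve$wtp == 5e5]
  )

  # the ratio-ordering construction also counts dominated replicates
  # (their ratios are negative, hence below any positive threshold)
  manual_io <- mean(ifelse(
    d$delta_qalys == 0,
    d$delta_cost_societal < 0,
    d$delta_cost_societal / d$delta_qalys < 5e5
  ))
  expect_equal(prob_cost_effective(psa, wtp = 5e5, method = "icer_ordering"), manual_io)
  expect_gte(
    prob_cost_effective(psa, wtp = 5e5, method = "icer_ordering"),
    prob_cost_effective(psa, wtp = 5e5)
  )

  # a wholly dominant sample is cost-effective at every non-negative wtp
  dom <- psa
  dom$draws <- dplyr::filter(d, delta_qalys > 0, delta_cost_societal < 0)
  expect_true(all(ceac(dom, grid)$probability == 1))

  expect_error(ceac(psa, numeric(0)), "non-empty")

  # with all effects positive the curve is non-decreasing in wtp
  fine <- ceac(dom, seq(0, 1e6, length.out = 21))
  expect_true(all(diff(fine$probability) >= 0))
})
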