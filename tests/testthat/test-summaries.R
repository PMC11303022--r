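# A tiny fitted object whose draws we can manipulate directly.
toy_fit <- function(seed = 100) {
  set.seed(seed)
  n <- 80
  d <- data.frame(ff = rbinom(n, 1, 0.5),
                  species_on_scene = rep(species_levels(), n / 2),
                  emotion_category = rep(emotion_levels(), length.out = n),
                  emotional_side = rep(c("left", "right"), each = n / 2),
                  stringsAsFactors = FALSE)
  suppressWarnings(
    fit_logistic(d, response = "ff",
                 fixed = ~ emotional_side + species_on_scene * emotion_category,
                 random = list(), iter = 260, warmup = 60, chains = 2,
                 seed = seed))
}

test_that("the 89% HDI of a uniform sample has width about 0.89", {
  set.seed(2)
  h <- hdi(runif(200000), level = 0.89)
  expect_lt(abs((h[["hi"]] - h[["lo"]]) - 0.89), 0.01)
  # and for a normal sample it is narrower than the quantile interval
  x <- rnorm(50000)
  h2 <- hdi(x, 0.89)
  q <- quantile(x, c(0.055, 0.945), names = FALSE)
  expect_lte(h2[["hi"]] - h2[["lo"]], q[2] - q[1] + 1e-3)
})

test_that("probability of direction behaves at the extremes and at the null", {
  expect_equal(prob_direction(abs(rnorm(1000)) + 0.01), 1)
  set.seed(3)
  x <- rnorm(100000)
  expect_lt(abs(prob_direction(x) - 0.5), 0.01)
  expect_equal(prob_direction(rep(0, 100)), 0.5)
})

test_that("the Gelman-Rubin diagnostic flags separated chains", {
  set.seed(4)
  same <- replicate(4, rnorm(1000), simplify = FALSE)
  expect_lt(gb_rhat(same), 1.02)
  apart <- list(rnorm(1000, 0), rnorm(1000, 3))
  expect_gt(gb_rhat(apart), 1.5)
  expect_equal(gb_rhat(list(rep(1, 100), rep(1, 100))), 1)
})

test_that("summarize_draws warns when rhat exceeds 1.05", {
  fit <- toy_fit()
  bad <- fit
  bad$draws[[2]][, "b_(Intercept)"] <- bad$draws[[2]][, "b_(Intercept)"] + 5
  expect_warning(summarize_draws(bad, pars = "b_\\(Intercept\\)"), "rhat")
})

test_that("null coefficients give response-scale estimates of exactly 0.5", {
  fit <- toy_fit()
  for (ch in seq_along(fit$draws)) {
    fit$draws[[ch]][, grep("^b_", colnames(fit$draws[[ch]]))] <- 0
  }
  ce <- condition_estimates(fit, data.frame(species_on_scene = species_levels()))
  expect_equal(ce$median, c(0.5, 0.5))
  expect_equal(ce$pd, c(0.5, 0.5))
  # two cells with identical coefficients give identical summaries
  expect_equal(ce$hdi_lo[1], ce$hdi_lo[2])
})

test_that("contrasts are antisymmetric and vanish on identical cells", {
  fit <- toy_fit()
  a <- data.frame(species_on_scene = "bonobo")
  b <- data.frame(species_on_scene = "human")
  ab <- contrast(fit, a, b)
  ba <- contrast(fit, b, a)
  expect_equal(ab$median, -ba$median)
  expect_equal(ab$hdi_lo, -ba$hdi_hi)
  aa <- contrast(fit, a, a)
  expect_equal(aa$median, 0)
  expect_equal(aa$hdi_lo, 0)
  expect_equal(aa$hdi_hi, 0)
})

test_that("cells marginalize over omitted factors", {
  fit <- toy_fit()
  full <- condition_estimates(fit,
                              expand.grid(species_on_scene = "bonobo",
                                          emotion_category = emotion_levels(),
                                          stringsAsFactors = FALSE))
  marg <- condition_estimates(fit, data.frame(species_on_scene = "bonobo"))
  # the marginal cell uses the averaged design row, so its median must lie
  # within the span of the per-emotion cells
  expect_gte(marg$median, min(full$median) - 0.02)
  expect_lte(marg$median, max(full$median) + 0.02)
  expect_error(condition_estimates(fit, data.frame(species_on_scene = "orang")),
               "orang")
})
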