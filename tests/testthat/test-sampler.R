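# Model fits here use deliberately short chains; the convergence-sensitive
# checks live in the acceptance suite with longer runs.

test_that("integer weights equal row duplication exactly in log posterior", {
  set.seed(8)
  n <- 60
  d <- data.frame(pld = rzoib(n, 0.55, 8, 0.15, 0.5),
                  subject = rep(c("A", "B", "C"), length.out = n),
                  stringsAsFactors = FALSE)
  w <- sample(1:3, n, replace = TRUE)
  drep <- d[rep(seq_len(n), w), , drop = FALSE]
  des_w <- gazebias:::build_design(d, ~1, list(re_term("subject")))
  des_d <- gazebias:::build_design(drep, ~1, list(re_term("subject")))
  mw <- list(y = d$pld, X = des_w$X, w = w, re = des_w$re, family = "zoib",
             aux_names = c("log_phi", "logit_zoi", "logit_coi"))
  md <- list(y = drep$pld, X = des_d$X, w = rep(1, nrow(drep)),
             re = des_d$re, family = "zoib",
             aux_names = c("log_phi", "logit_zoi", "logit_coi"))
  for (s in 1:5) {
    set.seed(s)
    st <- gazebias:::gb_init_state(mw, 0.6)
    # mathematically identical; summation order differs at double precision
    expect_equal(gazebias:::gb_log_posterior(mw, st),
                 gazebias:::gb_log_posterior(md, st), tolerance = 1e-12)
  }
})

test_that("uniform weight rescaling preserves location estimates", {
  set.seed(14)
  n <- 300
  d <- data.frame(pld = rzoib(n, 0.6, 12, 0.1, 0.5), stringsAsFactors = FALSE)
  f1 <- fit_zoib(d, response = "pld", fixed = ~1, random = list(),
                 weights = rep(1, n), iter = 1500, warmup = 500,
                 chains = 2, seed = 4)
  f2 <- fit_zoib(d, response = "pld", fixed = ~1, random = list(),
                 weights = rep(2, n), iter = 1500, warmup = 500,
                 chains = 2, seed = 4)
  m1 <- summarize_draws(f1, pars = "b_")$median
  m2 <- summarize_draws(f2, pars = "b_")$median
  expect_lt(abs(m1 - m2), 0.1)
})

test_that("the logistic intercept-only posterior matches a quadrature oracle", {
  set.seed(4)
  y <- rbinom(400, 1, 0.62)
  fit <- fit_logistic(data.frame(ff = y), response = "ff", fixed = ~1,
                      random = list(), iter = 3000, warmup = 1000,
                      chains = 2, seed = 5)
  th <- seq(-3, 3, length.out = 4001)
  lp <- vapply(th, function(t) {
    sum(y * plogis(t, log.p = TRUE) + (1 - y) * plogis(-t, log.p = TRUE)) +
      dnorm(t, log = TRUE)
  }, numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_mean <- sum(th * w)
  oracle_sd <- sqrt(sum(th^2 * w) - oracle_mean^2)
  dr <- unlist(lapply(fit$draws, function(m) m[, "b_(Intercept)"]))
  mc_se <- oracle_sd / sqrt(200)  # generous effective-size assumption
  expect_lt(abs(mean(dr) - oracle_mean), 3 * mc_se)
})

test_that("a null logistic model recovers chance level", {
  set.seed(6)
  y <- rbinom(2000, 1, 0.5)
  fit <- fit_logistic(data.frame(ff = y), response = "ff", fixed = ~1,
                      random = list(), iter = 2000, warmup = 700,
                      chains = 2, seed = 7)
  expect_lt(abs(summarize_draws(fit, pars = "b_")$median), 0.1)
})

test_that("complete separation stays finite under the prior", {
  fit <- suppressWarnings(
    fit_logistic(data.frame(ff = rep(1, 50)), response = "ff", fixed = ~1,
                 random = list(), iter = 2000, warmup = 700, chains = 2,
                 seed = 8))
  s <- summarize_draws(fit, pars = "b_")
  expect_true(is.finite(s$median))
  p <- plogis(s$median)
  expect_gt(p, 0.9)
})

test_that("all-boundary responses push the inflation probability toward 1", {
  set.seed(9)
  d <- data.frame(pld = rep(c(0, 1), 40))
  fit <- suppressWarnings(
    fit_zoib(d, response = "pld", fixed = ~1, random = list(), weights = NULL,
             iter = 1500, warmup = 500, chains = 2, seed = 9))
  expect_gt(summarize_draws(fit, pars = "^zoi$")$median, 0.9)
})

test_that("responses outside the unit interval or with NA are rejected", {
  expect_error(fit_zoib(data.frame(pld = c(0.5, 1.2)), response = "pld",
                        fixed = ~1, random = list(), weights = NULL),
               "\\[0, 1\\]")
  expect_error(fit_logistic(data.frame(ff = c(0, NA)), response = "ff",
                            fixed = ~1, random = list()), "NA")
  expect_error(fit_zoib(data.frame(pld = 0.5), response = "pld", fixed = ~1,
                        random = list(), weights = -1), "positive")
})
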