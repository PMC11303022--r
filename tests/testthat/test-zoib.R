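test_that("boundary masses and the uniform case are exact", {
  expect_equal(zoib_logdensity(0, 0.5, 2, 0.3, 0.4), log(0.3 * 0.6))
  expect_equal(zoib_logdensity(1, 0.5, 2, 0.3, 0.4), log(0.3 * 0.4))
  # mu = 0.5, phi = 2 is Beta(1, 1): uniform on (0, 1)
  expect_equal(zoib_logdensity(0.5, 0.5, 2, 0, 0.5), 0)
  expect_error(zoib_logdensity(1.2, 0.5, 2, 0, 0.5), "\\[0, 1\\]")
  expect_error(zoib_logdensity(0.5, 0.5, -1, 0, 0.5), "phi")
})

test_that("the continuous component matches a log-gamma beta oracle", {
  beta_oracle <- function(y, mu, phi) {
    a <- mu * phi; b <- (1 - mu) * phi
    lgamma(a + b) - lgamma(a) - lgamma(b) + (a - 1) * log(y) +
      (b - 1) * log(1 - y)
  }
  for (p in list(c(0.7, 0.6, 10, 0.2, 0.5), c(0.15, 0.3, 4, 0, 0.5),
                 c(0.99, 0.8, 25, 0.6, 0.1))) {
    expect_equal(zoib_logdensity(p[1], p[2], p[3], p[4], p[5]),
                 log1p(-p[4]) + beta_oracle(p[1], p[2], p[3]),
                 tolerance = 1e-10)
  }
})

test_that("the mixture normalizes over a parameter grid", {
  gr <- expand.grid(mu = c(0.25, 0.5, 0.8), phi = c(5, 12, 30),
                    zoi = c(0, 0.3, 0.7), coi = c(0.2, 0.8))
  for (i in seq_len(nrow(gr))) {
    p <- gr[i, ]
    cont <- integrate(function(y) exp(zoib_logdensity(y, p$mu, p$phi,
                                                      p$zoi, p$coi)),
                      1e-12, 1 - 1e-12, rel.tol = 1e-9)$value
    expect_lt(abs(p$zoi + cont - 1), 1e-6)
  }
})

test_that("rzoib produces the configured boundary mass and beta mean", {
  set.seed(3)
  y <- rzoib(40000, 0.6, 10, 0.2, 0.75)
  expect_lt(abs(mean(y %in% c(0, 1)) - 0.2), 0.01)
  expect_lt(abs(mean(y == 1) - 0.15), 0.01)
  expect_lt(abs(mean(y[!y %in% c(0, 1)]) - 0.6), 0.01)
})

test_that("sum coding builds the expected design columns", {
  d <- data.frame(species_on_scene = rep(species_levels(), 5),
                  emotion_category = rep(emotion_levels(), each = 2),
                  emotional_side = rep(c("left", "right"), 5),
                  stringsAsFactors = FALSE)
  des <- gazebias:::build_design(d, ~ emotional_side +
                                   species_on_scene * emotion_category,
                                 list())
  X <- des$X
  # 2-level factor -> one column in {-1, 1}
  expect_equal(sort(unique(X[, "species_on_scene1"])), c(-1, 1))
  expect_equal(unname(X[d$species_on_scene == "bonobo",
                        "species_on_scene1"][1]), 1)
  # 5-level factor -> 4 columns, each summing to zero over one level cycle
  emo_cols <- grep("^emotion_category", colnames(X), value = TRUE)
  emo_cols <- setdiff(emo_cols, grep(":", emo_cols, value = TRUE))
  expect_length(emo_cols, 4)
  expect_equal(unname(colSums(X[1:10, emo_cols])), rep(0, 4))
  # interaction -> 4 product columns
  int_cols <- grep("^species_on_scene1:", colnames(X), value = TRUE)
  expect_length(int_cols, 4)
  expect_equal(X[, int_cols[1]],
               X[, "species_on_scene1"] * X[, sub("^species_on_scene1:", "",
                                                  int_cols[1])])
  expect_equal(ncol(X), 1 + 1 + 1 + 4 + 4)
})

test_that("unseen factor levels are rejected", {
  d <- data.frame(species_on_scene = c("bonobo", "gorilla"),
                  emotion_category = "play", emotional_side = "left",
                  stringsAsFactors = FALSE)
  expect_error(gazebias:::build_design(d, ~ species_on_scene, list()),
               "gorilla")
})

test_that("nested grouping yields one index per subject-session combination", {
  ds <- quick_dataset(61)
  des <- gazebias:::build_design(ds$manifest, ~ species_on_scene,
                                 list(re_term("subject"),
                                      re_term(c("subject", "session"))))
  expect_equal(des$re[[1]]$G, 2)
  expect_equal(des$re[[2]]$G, 4)
  expect_equal(des$re[[2]]$q, 1)
})
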