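#' Fit a weighted zero-one-inflated beta mixed regression
#'
#' Bayesian estimation of the sustained-attention model: the dwell
#' proportion response follows a [zoib_logdensity()] mixture whose beta
#' mean `mu` gets a logit-linear predictor with sum-coded fixed effects
#' and random intercepts (precision `phi`, inflation `zoi` and
#' conditional-one `coi` are intercept-only). Trial weights enter the
#' likelihood as `sum(w_i * log f(y_i))`. Priors: Normal(0, 1) on every
#' location coefficient (and on the log/logit-scale intercepts of `phi`,
#' `zoi`, `coi`); half-Student-t(3, 0, 2.5) on random-effect standard
#' deviations. Sampling is adaptive Metropolis-within-Gibbs (see the
#' methods vignette); step sizes adapt only during warmup. Multiple chains
#' start from dispersed random initializations, and all randomness derives
#' from `seed`.
#'
#' @param data data.frame of scored trials (e.g. `filter_tfd()$scored`
#'   restricted to included rows).
#' @param response Name of the response column (proportions in `[0, 1]`).
#' @param fixed One-sided formula of sum-coded fixed effects.
#' @param random List of [re_term()]s; `NULL` or `list()` for none.
#' @param weights Optional name of a positive weight column (or a numeric
#'   vector); default all-1.
#' @param iter,warmup Total and warmup iterations per chain.
#' @param chains Number of chains.
#' @param seed Integer seed.
#' @return An object of class `"gb_fit"`: draws (list of per-chain
#'   matrices of post-warmup draws, named columns), the design bookkeeping
#'   needed by [condition_estimates()], and sampler metadata.
#' @examples
#' \donttest{
#' ds <- simulate_gaze(gen_config(seed = 1))
#' fx <- detect_fixations(ds$gaze)
#' mt <- compute_metrics(fx, ds$geometry, trial_ids = ds$manifest$trial_id)
#' sc <- filter_tfd(mt, ds$manifest)$scored
#' fit <- fit_zoib(sc[!sc$excluded, ], iter = 1500, warmup = 500,
#'                 chains = 2, seed = 1)
#' summarize_draws(fit, pars = "^b_")
#' }
#' @export
fit_zoib <- function(data, response = "pld_emotion",
                     fixed = ~ emotional_side +
                       species_on_scene * emotion_category,
                     random = list(re_term("subject"),
                                   re_term(c("subject", "session"))),
                     weights = "weight",
                     iter = 10000, warmup = 2000, chains = 4, seed = 1) {
  gb_fit_family(data, response, fixed, random, weights, iter, warmup,
                chains, seed, family = "zoib")
}

#' Fit a Bayesian logistic mixed regression
#'
#' Immediate-attention counterpart of [fit_zoib()]: Bernoulli-logit
#' likelihood for the binary first-fixation outcome with the same priors,
#' sum coding, random-effect structure (including random slopes via
#' `re_term(group, form)`) and sampler. Complete separation is handled by
#' the Normal(0, 1) prior, which keeps the posterior proper.
#'
#' @inheritParams fit_zoib
#' @export
fit_logistic <- function(data, response = "first_fix_emotional",
                         fixed = ~ emotional_side +
                           species_on_scene * emotion_category,
                         random = list(re_term("subject")),
                         weights = NULL,
                         iter = 10000, warmup = 2000, chains = 4, seed = 1) {
  gb_fit_family(data, response, fixed, random, weights, iter, warmup,
                chains, seed, family = "bernoulli")
}

gb_fit_family <- function(data, response, fixed, random, weights,
                          iter, warmup, chains, seed, family) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            iter > warmup, warmup >= 0, chains >= 1)
  if (!response %in% names(data)) stop_gb("response column '%s' absent", response)
  y <- data[[response]]
  if (anyNA(y)) stop_gb("response contains NA; filter excluded trials first")
  if (family == "zoib" && any(y < 0 | y > 1)) stop_gb("response must lie in [0, 1]")
  if (family == "bernoulli" && !all(y %in% c(0, 1))) {
    stop_gb("response must be binary 0/1")
  }
  w <- if (is.null(weights)) rep(1, length(y))
       else if (is.character(weights)) data[[weights]]
       else weights
  if (is.null(w)) w <- rep(1, length(y))
  if (any(!is.finite(w) | w <= 0)) stop_gb("weights must be positive")

  des <- build_design(data, fixed, random %||% list())
  model <- list(y = y, X = des$X, w = w, re = des$re, family = family,
                aux_names = if (family == "zoib")
                  c("log_phi", "logit_zoi", "logit_coi") else character(0))

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- gb_run_chain(model, iter, warmup, child_seed(seed, ch))
  }

  fit <- structure(list(
    family = family,
    draws = lapply(res, `[[`, "draws"),
    accept_rate = vapply(res, `[[`, numeric(1), "accept_rate"),
    model = model,
    terms_obj = des$terms_obj, xlev = des$xlev, contrasts = des$contrasts,
    sampler = list(iter = iter, warmup = warmup, chains = chains,
                   seed = seed),
    n_obs = length(y)
  ), class = "gb_fit")
  check_convergence(fit)
  fit
}

check_convergence <- function(fit, threshold = 1.05) {
  core <- grep("^(b_|phi$|zoi$|coi$|sd_)", colnames(fit$draws[[1]]), value = TRUE)
  rh <- vapply(core, function(p) gb_rhat(lapply(fit$draws, function(d) d[, p])),
               numeric(1))
  bad <- names(rh)[is.finite(rh) & rh > threshold]
  if (length(bad)) {
    warn_gb("Gelman-Rubin diagnostic above %.2f for: %s", threshold,
            paste(sprintf("%s (%.3f)", bad, rh[bad]), collapse = ", "))
  }
  invisible(rh)
}

#' @export
print.gb_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d obs, %d chains x %d iterations (%d warmup), seed %d\n",
              if (x$family == "zoib") "Zero-one-inflated beta" else "Logistic",
              x$n_obs, x$sampler$chains, x$sampler$iter, x$sampler$warmup,
              x$sampler$seed))
  cat(sprintf("  mean acceptance probability: %.2f\n", mean(x$accept_rate)))
  print(summarize_draws(x, pars = "^(b_|phi$|zoi$|coi$|sd_)"), digits = 3)
  invisible(x)
}

#' Persist posterior draws as a flat CSV
#'
#' Long format: `chain, iteration, parameter, value`.
#'
#' @param fit A `"gb_fit"`.
#' @param path File path.
#' @param pars Regular expression selecting parameters (default: fixed
#'   effects, family parameters and SDs; use `"."` for everything).
#' @export
write_draws <- function(fit, path, pars = "^(b_|phi$|zoi$|coi$|sd_)") {
  sel <- grep(pars, colnames(fit$draws[[1]]), value = TRUE)
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]][, sel, drop = FALSE]
    data.frame(chain = ch, iteration = seq_len(nrow(d)),
               parameter = rep(sel, each = nrow(d)),
               value = as.vector(d), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
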