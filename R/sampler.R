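# Adaptive Metropolis-within-Gibbs engine shared by the ZOIB and logistic
# mixed models. Blocks: fixed-effect coefficients (componentwise), auxiliary
# scalars (log phi, logit zoi, logit coi), random effects (all groups of a
# term column proposed jointly and accepted per group, valid because rows
# partition across groups), and random-effect log-SDs (prior-only blocks).
# Step sizes adapt toward a 0.44 acceptance probability during warmup via
# Robbins-Monro on the log scale, and are frozen afterwards so the
# post-warmup chain is Markovian.

GB_TARGET_ACC <- 0.44

# Per-row log likelihood. aux is a named numeric vector on the sampling
# scale (log_phi, logit_zoi, logit_coi) for the ZOIB family; empty for
# bernoulli.
gb_loglik_rows <- function(family, y, eta, aux) {
  if (family == "zoib") {
    zoib_ll_core(y, stats::plogis(eta), exp(aux[["log_phi"]]),
                 stats::plogis(aux[["logit_zoi"]]),
                 stats::plogis(aux[["logit_coi"]]))
  } else {
    y * stats::plogis(eta, log.p = TRUE) +
      (1 - y) * stats::plogis(-eta, log.p = TRUE)
  }
}

# log prior of the half-Student-t(3, 0, 2.5) on an SD, evaluated at
# log_sd with the change-of-variables Jacobian.
gb_lp_logsd <- function(log_sd) {
  sd <- exp(log_sd)
  stats::dt(sd / 2.5, df = 3, log = TRUE) - log(2.5) + log(2) + log_sd
}

# Joint log posterior of a full state; the reference implementation the
# sampler's incremental bookkeeping must agree with (and the quantity the
# weighted-likelihood == row-duplication property is asserted on).
gb_log_posterior <- function(model, state) {
  eta <- gb_eta(model, state)
  ll <- sum(model$w * gb_loglik_rows(model$family, model$y, eta, state$aux))
  lp <- sum(stats::dnorm(state$beta, 0, 1, log = TRUE)) +
    sum(stats::dnorm(state$aux, 0, 1, log = TRUE))
  for (t in seq_along(model$re)) {
    sd_t <- exp(state$log_sd[[t]])
    lp <- lp + sum(gb_lp_logsd(state$log_sd[[t]]))
    lp <- lp + sum(stats::dnorm(state$b[[t]], 0,
                                rep(sd_t, each = nrow(state$b[[t]])),
                                log = TRUE))
  }
  ll + lp
}

gb_eta <- function(model, state) {
  eta <- drop(model$X %*% state$beta)
  for (t in seq_along(model$re)) {
    re <- model$re[[t]]
    eta <- eta + rowSums(re$Z * state$b[[t]][re$gi, , drop = FALSE])
  }
  eta
}

gb_init_state <- function(model, scale) {
  list(
    beta = stats::rnorm(ncol(model$X), 0, scale),
    aux = stats::setNames(stats::rnorm(length(model$aux_names), 0, scale),
                          model$aux_names),
    log_sd = lapply(model$re, function(re) stats::rnorm(re$q, -1, 0.3)),
    b = lapply(model$re, function(re)
      matrix(stats::rnorm(re$G * re$q, 0, 0.1), re$G, re$q))
  )
}

# One chain. Returns list(draws = matrix, accept = named rates).
gb_run_chain <- function(model, iter, warmup, chain_seed) {
  with_seed(chain_seed, {
    n <- length(model$y)
    p <- ncol(model$X)
    n_aux <- length(model$aux_names)

    state <- gb_init_state(model, 0.5)
    eta <- gb_eta(model, state)
    rowll <- gb_loglik_rows(model$family, model$y, eta, state$aux)
    tries <- 0
    while (!all(is.finite(rowll)) && tries < 20) {
      tries <- tries + 1
      state <- gb_init_state(model, 0.5 / (1 + tries))
      eta <- gb_eta(model, state)
      rowll <- gb_loglik_rows(model$family, model$y, eta, state$aux)
    }
    if (!all(is.finite(rowll))) {
      stop_gb("could not find a finite-posterior initialization")
    }

    ls_beta <- rep(log(0.2), p)
    ls_aux <- rep(log(0.2), n_aux)
    ls_b <- lapply(model$re, function(re) matrix(log(0.4), re$G, re$q))
    ls_sd <- lapply(model$re, function(re) rep(log(0.4), re$q))
    ls_swap <- rep(log(0.2), length(model$re))
    ls_resc <- lapply(model$re, function(re) rep(log(0.5), re$q))
    # location-swap moves resolve the ridge between the fixed intercept and
    # the mean of a term's random intercepts: shift beta0 by delta and every
    # group effect by -delta, leaving the likelihood untouched
    j0 <- match("(Intercept)", colnames(model$X))
    swap_ok <- vapply(model$re, function(re)
      !is.na(j0) && re$q == 1L && all(re$Z[, 1] == 1), logical(1))

    par_names <- gb_par_names(model)
    keep <- iter - warmup
    draws <- matrix(NA_real_, keep, length(par_names),
                    dimnames = list(NULL, par_names))
    acc_n <- acc_d <- 0

    for (it in seq_len(iter)) {
      adapting <- it <= warmup
      gam <- if (adapting) (it + 10)^-0.6 else 0

      ## -- fixed effects, componentwise
      for (j in seq_len(p)) {
        prop <- stats::rnorm(1, 0, exp(ls_beta[j]))
        eta2 <- eta + model$X[, j] * prop
        rowll2 <- gb_loglik_rows(model$family, model$y, eta2, state$aux)
        d <- sum(model$w * (rowll2 - rowll)) +
          stats::dnorm(state$beta[j] + prop, 0, 1, log = TRUE) -
          stats::dnorm(state$beta[j], 0, 1, log = TRUE)
        a <- min(1, exp(d))
        if (is.finite(d) && stats::runif(1) < a) {
          state$beta[j] <- state$beta[j] + prop
          eta <- eta2; rowll <- rowll2
        }
        if (adapting) ls_beta[j] <- ls_beta[j] + gam * (a - GB_TARGET_ACC)
        acc_n <- acc_n + a; acc_d <- acc_d + 1
      }

      ## -- auxiliary scalars (likelihood depends on them, eta unchanged)
      for (a_i in seq_len(n_aux)) {
        prop <- stats::rnorm(1, 0, exp(ls_aux[a_i]))
        aux2 <- state$aux
        aux2[a_i] <- aux2[a_i] + prop
        rowll2 <- gb_loglik_rows(model$family, model$y, eta, aux2)
        d <- sum(model$w * (rowll2 - rowll)) +
          stats::dnorm(aux2[a_i], 0, 1, log = TRUE) -
          stats::dnorm(state$aux[a_i], 0, 1, log = TRUE)
        a <- min(1, exp(d))
        if (is.finite(d) && stats::runif(1) < a) {
          state$aux <- aux2; rowll <- rowll2
        }
        if (adapting) ls_aux[a_i] <- ls_aux[a_i] + gam * (a - GB_TARGET_ACC)
        acc_n <- acc_n + a; acc_d <- acc_d + 1
      }

      ## -- random effects: per-term, per-column, all groups at once
      for (t in seq_along(model$re)) {
        re <- model$re[[t]]
        for (cc in seq_len(re$q)) {
          sd_c <- exp(state$log_sd[[t]][cc])
          eps <- stats::rnorm(re$G, 0, exp(ls_b[[t]][, cc]))
          bc <- state$b[[t]][, cc]
          eta2 <- eta + re$Z[, cc] * eps[re$gi]
          rowll2 <- gb_loglik_rows(model$family, model$y, eta2, state$aux)
          # gi covers 1..G (labels come from the data), so the sorted
          # rowsum aligns with group index
          dg <- rowsum(model$w * (rowll2 - rowll), re$gi, reorder = TRUE)[, 1]
          dg <- dg + stats::dnorm(bc + eps, 0, sd_c, log = TRUE) -
            stats::dnorm(bc, 0, sd_c, log = TRUE)
          aprob <- pmin(1, exp(dg))
          aprob[!is.finite(dg)] <- 0
          acc <- stats::runif(re$G) < aprob
          if (any(acc)) {
            state$b[[t]][acc, cc] <- bc[acc] + eps[acc]
            accrow <- acc[re$gi]
            eta[accrow] <- eta2[accrow]
            rowll[accrow] <- rowll2[accrow]
          }
          if (adapting) {
            ls_b[[t]][, cc] <- ls_b[[t]][, cc] + gam * (aprob - GB_TARGET_ACC)
          }
          acc_n <- acc_n + mean(aprob); acc_d <- acc_d + 1
        }
      }

      ## -- intercept/random-effect location swaps (prior-only ratio)
      for (t in which(swap_ok)) {
        delta <- stats::rnorm(1, 0, exp(ls_swap[t]))
        bt <- state$b[[t]][, 1]
        sd_t <- exp(state$log_sd[[t]][1])
        d <- stats::dnorm(state$beta[j0] + delta, 0, 1, log = TRUE) -
          stats::dnorm(state$beta[j0], 0, 1, log = TRUE) +
          sum(stats::dnorm(bt - delta, 0, sd_t, log = TRUE) -
                stats::dnorm(bt, 0, sd_t, log = TRUE))
        a <- min(1, exp(d))
        if (is.finite(d) && stats::runif(1) < a) {
          state$beta[j0] <- state$beta[j0] + delta
          state$b[[t]][, 1] <- bt - delta
        }
        if (adapting) ls_swap[t] <- ls_swap[t] + gam * (a - GB_TARGET_ACC)
        acc_n <- acc_n + a; acc_d <- acc_d + 1
      }

      ## -- random-effect scales (log scale, prior-only block)
      for (t in seq_along(model$re)) {
        for (cc in seq_len(model$re[[t]]$q)) {
          cur <- state$log_sd[[t]][cc]
          prop <- cur + stats::rnorm(1, 0, exp(ls_sd[[t]][cc]))
          bc <- state$b[[t]][, cc]
          d <- sum(stats::dnorm(bc, 0, exp(prop), log = TRUE)) -
            sum(stats::dnorm(bc, 0, exp(cur), log = TRUE)) +
            gb_lp_logsd(prop) - gb_lp_logsd(cur)
          a <- min(1, exp(d))
          if (is.finite(d) && stats::runif(1) < a) state$log_sd[[t]][cc] <- prop
          if (adapting) ls_sd[[t]][cc] <- ls_sd[[t]][cc] + gam * (a - GB_TARGET_ACC)
          acc_n <- acc_n + a; acc_d <- acc_d + 1
        }
      }

      ## -- joint rescale of (scale, effects): log_sd += delta, b *= e^delta.
      ## The Jacobian cancels the Gaussian-prior scale term, leaving the
      ## hyperprior and likelihood ratios; this escapes the funnel when the
      ## scale sits near zero.
      for (t in seq_along(model$re)) {
        re <- model$re[[t]]
        for (cc in seq_len(re$q)) {
          delta <- stats::rnorm(1, 0, exp(ls_resc[[t]][cc]))
          cur <- state$log_sd[[t]][cc]
          bc <- state$b[[t]][, cc]
          bc2 <- bc * exp(delta)
          eta2 <- eta + re$Z[, cc] * (bc2 - bc)[re$gi]
          rowll2 <- gb_loglik_rows(model$family, model$y, eta2, state$aux)
          d <- sum(model$w * (rowll2 - rowll)) +
            gb_lp_logsd(cur + delta) - gb_lp_logsd(cur)
          a <- min(1, exp(d))
          if (is.finite(d) && stats::runif(1) < a) {
            state$log_sd[[t]][cc] <- cur + delta
            state$b[[t]][, cc] <- bc2
            eta <- eta2; rowll <- rowll2
          }
          if (adapting) ls_resc[[t]][cc] <- ls_resc[[t]][cc] +
            gam * (a - GB_TARGET_ACC)
          acc_n <- acc_n + a; acc_d <- acc_d + 1
        }
      }

      if (it > warmup) draws[it - warmup, ] <- gb_flatten_state(model, state)
    }
    list(draws = draws, accept_rate = acc_n / acc_d)
  })
}

gb_par_names <- function(model) {
  nm <- c(paste0("b_", colnames(model$X)),
          if (model$family == "zoib") c("phi", "zoi", "coi"))
  for (re in model$re) {
    nm <- c(nm, paste0("sd_", re$name, ":", re$colnames))
    nm <- c(nm, as.vector(outer(re$labels, re$colnames,
                                function(g, cc)
                                  sprintf("r_%s[%s,%s]", re$name, g, cc))))
  }
  nm
}

gb_flatten_state <- function(model, state) {
  out <- c(state$beta,
           if (model$family == "zoib")
             c(exp(state$aux[["log_phi"]]),
               stats::plogis(state$aux[["logit_zoi"]]),
               stats::plogis(state$aux[["logit_coi"]])))
  for (t in seq_along(model$re)) {
    out <- c(out, exp(state$log_sd[[t]]), as.vector(state$b[[t]]))
  }
  out
}
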