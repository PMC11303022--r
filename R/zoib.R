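#' Zero-one-inflated beta log density
#'
#' Mixture distribution for proportions with point masses at the
#' boundaries: mass `zoi * (1 - coi)` at `y = 0`, mass `zoi * coi` at
#' `y = 1`, and density `(1 - zoi) * Beta(y; mu * phi, (1 - mu) * phi)` on
#' `(0, 1)` (mean/precision parameterization: `mu` is the beta mean, `phi`
#' the precision). `zoi` is the zero-or-one inflation probability, `coi`
#' the conditional-one probability.
#'
#' @param y Proportions in `[0, 1]` (vectorized, recycled with parameters).
#' @param mu Beta mean in (0, 1).
#' @param phi Beta precision (> 0).
#' @param zoi Probability of a boundary value, in \[0, 1\].
#' @param coi Conditional probability that a boundary value is 1.
#' @return Log density/mass at `y`.
#' @examples
#' zoib_logdensity(0, mu = 0.5, phi = 2, zoi = 0.3, coi = 0.4)  # log(0.18)
#' @export
zoib_logdensity <- function(y, mu, phi, zoi, coi) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop_gb("y must lie in [0, 1]")
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0) ||
      any(zoi < 0 | zoi > 1) || any(coi < 0 | coi > 1)) {
    stop_gb("require mu in (0,1), phi > 0, zoi and coi in [0,1]")
  }
  n <- max(length(y), length(mu), length(phi), length(zoi), length(coi))
  zoib_ll_core(rep_len(y, n), rep_len(mu, n), rep_len(phi, n),
               rep_len(zoi, n), rep_len(coi, n))
}

# Non-validating likelihood core used by the sampler: parameter values that
# escape their domain (e.g. an inverse link saturating at exactly 0 or 1
# under an extreme proposal) yield -Inf, so such proposals are rejected
# rather than raising an error.
zoib_ll_core <- function(y, mu, phi, zoi, coi) {
  out <- numeric(length(y))
  at0 <- y == 0; at1 <- y == 1; mid <- !(at0 | at1)
  if (length(zoi) == 1) zoi <- rep_len(zoi, length(y))
  if (length(coi) == 1) coi <- rep_len(coi, length(y))
  out[at0] <- log(zoi[at0]) + log1p(-coi[at0])
  out[at1] <- log(zoi[at1]) + log(coi[at1])
  if (any(mid)) {
    mu_m <- if (length(mu) > 1) mu[mid] else mu
    phi_m <- if (length(phi) > 1) phi[mid] else phi
    out[mid] <- suppressWarnings(
      log1p(-zoi[mid]) + stats::dbeta(y[mid], mu_m * phi_m,
                                      (1 - mu_m) * phi_m, log = TRUE))
  }
  out[is.nan(out)] <- -Inf
  out
}

#' @rdname zoib_logdensity
#' @param n Number of draws.
#' @export
rzoib <- function(n, mu, phi, zoi, coi) {
  infl <- stats::runif(n) < zoi
  one <- stats::runif(n) < coi
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  ifelse(infl, as.numeric(one), y)
}

# --- design construction -------------------------------------------------

canonical_levels <- list(
  emotional_side = c("left", "right"),
  species_on_scene = c("bonobo", "human"),
  emotion_category = c("distress", "groom_embrace", "play", "sex_erotic",
                       "yawn")
)

gb_factorize <- function(data, cols = names(canonical_levels)) {
  for (cl in intersect(cols, names(data))) {
    vals <- as.character(data[[cl]])
    bad <- setdiff(unique(vals), canonical_levels[[cl]])
    if (length(bad)) {
      stop_gb("unseen %s level(s): %s", cl, paste(bad, collapse = ", "))
    }
    lev <- canonical_levels[[cl]][canonical_levels[[cl]] %in% vals]
    data[[cl]] <- factor(vals, levels = lev)
  }
  data
}

#' Declare a random-effect term
#'
#' @param group Character vector of grouping columns; more than one column
#'   denotes the nested key (e.g. `c("subject", "session")` for session
#'   nested within subject).
#' @param form One-sided formula for the effect design within each group;
#'   the default `~ 1` is a random intercept. Factor terms are sum coded;
#'   each resulting column gets its own standard deviation (no
#'   correlations are modelled).
#' @return A `"re_term"` specification used by [fit_zoib()]/[fit_logistic()].
#' @export
re_term <- function(group, form = ~1) {
  stopifnot(is.character(group), length(group) >= 1, inherits(form, "formula"))
  structure(list(group = group, form = form), class = "re_term")
}

sum_contrasts <- function(formula, data) {
  vars <- all.vars(formula)
  fac <- vars[vapply(vars, function(v) is.factor(data[[v]]), logical(1))]
  stats::setNames(as.list(rep("contr.sum", length(fac))), fac)
}

# Build fixed-effect matrix (sum coded) and realized random-effect terms.
# Returns list(X, terms_obj, xlev, contrasts, re) where re[[t]] has
# gi (group index per row), G, Z, labels, name.
build_design <- function(data, fixed, random) {
  data <- gb_factorize(data)
  ctr <- sum_contrasts(fixed, data)
  mf <- stats::model.frame(fixed, data)
  terms_obj <- attr(mf, "terms")
  X <- stats::model.matrix(terms_obj, mf,
                           contrasts.arg = if (length(ctr)) ctr else NULL)
  xlev <- stats::.getXlevels(terms_obj, mf)
  re <- lapply(random, function(rt) {
    stopifnot(inherits(rt, "re_term"))
    miss <- setdiff(rt$group, names(data))
    if (length(miss)) stop_gb("grouping column(s) absent: %s",
                              paste(miss, collapse = ", "))
    key <- do.call(paste, c(data[rt$group], sep = ":"))
    labels <- unique(key)
    gi <- match(key, labels)
    ctr_z <- sum_contrasts(rt$form, data)
    Z <- stats::model.matrix(rt$form, data,
                             contrasts.arg = if (length(ctr_z)) ctr_z else NULL)
    list(name = paste(rt$group, collapse = ":"), gi = gi,
         G = length(labels), Z = Z, labels = labels,
         q = ncol(Z), colnames = colnames(Z))
  })
  nm <- vapply(re, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    nm <- make.unique(nm)
    for (i in seq_along(re)) re[[i]]$name <- nm[i]
  }
  list(X = X, terms_obj = terms_obj, xlev = xlev,
       contrasts = attr(X, "contrasts"), re = re, data = data)
}
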