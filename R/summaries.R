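#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing `level` of the draws. When
#' the draws are multimodal a contiguous interval can misrepresent the
#' density; the interval is still returned and a flag is attached
#' (attribute `"multimodal_flag"`) when the shortest window is far from
#' unique.
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Probability mass the interval must contain.
#' @return Numeric `c(lo, hi)`.
#' @export
hdi <- function(draws, level = 0.89) {
  stopifnot(level > 0, level < 1)
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2) return(c(lo = x[1] %||% NA_real_, hi = x[1] %||% NA_real_))
  m <- ceiling(level * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  out <- c(lo = x[i], hi = x[i + m])
  near <- sum(widths <= widths[i] * 1.001)
  if (near > max(3, 0.05 * length(widths))) {
    attr(out, "multimodal_flag") <- TRUE
  }
  out
}

#' Probability of direction
#'
#' The posterior certainty that an effect is strictly on one side of
#' `ref`: the larger of `P(draws > ref)` and `P(draws < ref)`, floored at
#' 0.5 for degenerate samples.
#'
#' @param draws Numeric vector of posterior draws.
#' @param ref Reference value (0 for coefficients and contrasts, 0.5 for
#'   response-scale proportions).
#' @return Value in `[0.5, 1]`.
#' @export
prob_direction <- function(draws, ref = 0) {
  max(mean(draws > ref), mean(draws < ref), 0.5)
}

#' Gelman-Rubin convergence diagnostic (split chains)
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half; values close to 1 indicate convergence.
#'
#' @param chains List of numeric vectors (one per chain, equal length).
#' @return Scalar rhat (1 when the draws are constant).
#' @export
gb_rhat <- function(chains) {
  half <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }), recursive = FALSE)
  mat <- do.call(cbind, half)
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4 || m < 2) return(NA_real_)
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(colMeans(mat))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

summ_one <- function(draw_list, level, ref) {
  all_d <- unlist(draw_list, use.names = FALSE)
  h <- hdi(all_d, level)
  q <- stats::quantile(all_d, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  data.frame(median = stats::median(all_d),
             hdi_lo = h[["lo"]], hdi_hi = h[["hi"]],
             ci_lo = q[1], ci_hi = q[2],
             pd = prob_direction(all_d, ref),
             rhat = gb_rhat(draw_list),
             n_draws = length(all_d))
}

#' Summarize posterior draws
#'
#' Per estimand: posterior median (Mdn), the 89% highest-density interval
#' (primary, following the narrowest-interval definition), the equal-tailed
#' quantile interval alongside it, the probability of direction, the
#' split-chain Gelman-Rubin diagnostic and the number of draws. A warning
#' is raised when any rhat exceeds 1.05.
#'
#' @param fit A `"gb_fit"` (or a list of per-chain draw matrices).
#' @param pars Regular expression selecting parameters; default reports
#'   fixed effects, family parameters and random-effect SDs.
#' @param level Credible mass (default 0.89).
#' @param ref Reference value for the probability of direction.
#' @return data.frame with one row per estimand.
#' @export
summarize_draws <- function(fit, pars = "^(b_|phi$|zoi$|coi$|sd_)",
                            level = 0.89, ref = 0) {
  draws <- if (inherits(fit, "gb_fit")) fit$draws else fit
  stopifnot(is.list(draws), is.matrix(draws[[1]]))
  sel <- grep(pars, colnames(draws[[1]]), value = TRUE)
  if (!length(sel)) stop_gb("no parameters match '%s'", pars)
  out <- do.call(rbind, lapply(sel, function(p) {
    cbind(data.frame(estimand = p, stringsAsFactors = FALSE),
          summ_one(lapply(draws, function(d) d[, p]), level, ref))
  }))
  bad <- out$estimand[is.finite(out$rhat) & out$rhat > 1.05]
  if (length(bad)) {
    warn_gb("rhat > 1.05 for: %s", paste(bad, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

# Per-draw response-scale estimate for one design cell: inverse-link
# expected response with random effects at 0; for the ZOIB family the
# mixture mean zoi*coi + (1-zoi)*mu. Factors omitted from `cell` are
# marginalized by averaging the design row over their levels (e.g. a cell
# naming only the species averages over emotion categories and sides).
cell_draws <- function(fit, cell) {
  stopifnot(inherits(fit, "gb_fit"))
  cell <- as.data.frame(cell, stringsAsFactors = FALSE)
  if (nrow(cell) != 1) stop_gb("one cell at a time")
  miss <- setdiff(names(fit$xlev), names(cell))
  grid <- expand.grid(c(lapply(fit$xlev[miss], identity),
                        as.list(cell[intersect(names(cell),
                                               names(fit$xlev))])),
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) grid <- data.frame(.dummy = 1)  # intercept-only model
  for (v in names(fit$xlev)) {
    bad <- setdiff(unique(as.character(grid[[v]])), fit$xlev[[v]])
    if (length(bad)) stop_gb("unknown level '%s' for %s", bad[1], v)
    grid[[v]] <- factor(grid[[v]], levels = fit$xlev[[v]])
  }
  tt <- stats::delete.response(fit$terms_obj)
  Xc <- stats::model.matrix(tt, grid, contrasts.arg = fit$contrasts)
  xrow <- colMeans(Xc)
  bcols <- paste0("b_", colnames(fit$model$X))
  unlist(lapply(fit$draws, function(d) {
    eta <- as.vector(d[, bcols, drop = FALSE] %*% xrow)
    mu <- stats::plogis(eta)
    if (fit$family == "zoib") {
      d[, "zoi"] * d[, "coi"] + (1 - d[, "zoi"]) * mu
    } else mu
  }), use.names = FALSE)
}

#' Posterior condition estimates on the response scale
#'
#' For each condition cell, evaluates per draw the expected response of
#' the cell (inverse link, random effects at zero; for the ZOIB family the
#' full mixture mean `zoi * coi + (1 - zoi) * mu`) and summarizes it.
#' Factors omitted from `cells` are marginalized by averaging over their
#' levels. The probability of direction is assessed against `ref = 0.5`,
#' the chance level of a two-scene proportion.
#'
#' @param fit A `"gb_fit"`.
#' @param cells data.frame of condition cells (columns a subset of the
#'   model's factors), one row per estimand.
#' @param level Credible mass.
#' @param ref Reference for the probability of direction.
#' @return data.frame with one row per cell.
#' @examples
#' \donttest{
#' # condition_estimates(fit, data.frame(species_on_scene = c("bonobo", "human")))
#' }
#' @export
condition_estimates <- function(fit, cells, level = 0.89, ref = 0.5) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    dr <- cell_draws(fit, cells[i, , drop = FALSE])
    per_chain <- split(dr, rep(seq_along(fit$draws),
                               each = nrow(fit$draws[[1]])))
    cbind(data.frame(estimand = paste(unlist(lapply(cells[i, , drop = FALSE],
                                                    as.character)),
                                      collapse = ":"),
                     stringsAsFactors = FALSE),
          summ_one(per_chain, level, ref))
  }))
  rownames(out) <- NULL
  out
}

#' Posterior contrast between two condition cells
#'
#' Per-draw difference of the response-scale estimates of `cellA` and
#' `cellB` (A minus B), summarized with median, HDI and probability of
#' direction against 0.
#'
#' @param fit A `"gb_fit"`.
#' @param cellA,cellB One-row data.frames (or named lists) identifying the
#'   cells.
#' @param level Credible mass.
#' @return One-row data.frame.
#' @export
contrast <- function(fit, cellA, cellB, level = 0.89) {
  dr <- cell_draws(fit, cellA) - cell_draws(fit, cellB)
  per_chain <- split(dr, rep(seq_along(fit$draws),
                             each = nrow(fit$draws[[1]])))
  lab <- function(cl) paste(unlist(lapply(as.data.frame(cl), as.character)),
                            collapse = ":")
  out <- cbind(data.frame(estimand = sprintf("%s - %s", lab(cellA), lab(cellB)),
                          stringsAsFactors = FALSE),
               summ_one(per_chain, level, ref = 0))
  rownames(out) <- NULL
  out
}
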