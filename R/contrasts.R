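#' Per-draw marginal means for the six modules in one stratum
#'
#' For the drinking model at risk level `stratum` ("low" or "high"), the
#' module marginal mean on the log-odds scale is the module effect plus
#' the module-by-risk cell effect; fixed-effect terms are shared by all
#' modules and cancel in one-vs-rest contrasts, so they are omitted. For
#' the feedback model, `stratum` names an item and the marginal mean on
#' the rating scale is the module effect plus the module-by-item cell.
#'
#' @param pd A `posterior_draws` from [fit_alcohol_model()] or
#'   [fit_feedback_model()].
#' @param stratum `"low"`/`"high"` (alcohol) or an item name (feedback).
#' @return Matrix of pooled draws x 6 modules (columns named by topic).
#' @export
module_marginal_means <- function(pd, stratum) {
  topics <- module_topics()
  if (pd$model == "alcohol") {
    if (!stratum %in% c("low", "high")) {
      stop("unknown stratum for the alcohol model: ", stratum, call. = FALSE)
    }
    mu <- draws_matrix(pd, paste0("mod_", topics)) +
      draws_matrix(pd, paste0("modrisk_", topics, "_", stratum))
  } else {
    if (!stratum %in% feedback_items()) {
      stop("unknown item for the feedback model: ", stratum, call. = FALSE)
    }
    mu <- draws_matrix(pd, paste0("mod_", topics)) +
      draws_matrix(pd, paste0("moditem_", topics, "_", stratum))
  }
  colnames(mu) <- topics
  mu
}

#' Empirical equal-tailed quantiles of a draw vector
#'
#' Linear-interpolation (type 7) quantiles, the convention used for all
#' credible intervals in the package.
#'
#' @param x Non-empty numeric vector of draws.
#' @param probs Probabilities; default the 95% equal-tailed pair.
#' @return Named numeric vector of quantiles.
#' @export
summarize_quantiles <- function(x, probs = c(0.025, 0.975)) {
  if (length(x) == 0) stop("empty draw vector", call. = FALSE)
  quantile(x, probs = probs, type = 7, names = TRUE)
}

#' One-vs-rest module contrasts with posterior superiority probabilities
#'
#' Per draw, each module's contrast is its marginal mean minus the
#' average of the other five modules' marginal means (the rest-average is
#' taken on the linear-predictor scale, so the six contrasts sum to zero
#' in every draw). For `direction = "less"` the effect is reported as an
#' odds ratio `exp(contrast)` and the posterior probability is the
#' fraction of draws with a strictly negative contrast (less drinking);
#' for `direction = "greater"` the effect is the raw mean difference and
#' the probability uses strictly positive contrasts (better ratings).
#' Exact ties count against the hypothesis. Point summary is the
#' posterior median by default.
#'
#' @param mu_draws Draws x 6 matrix from [module_marginal_means()].
#' @param direction `"less"` or `"greater"`.
#' @param point `"median"` or `"mean"` point summary.
#' @return Tibble with one row per module: `module_topic`, `effect`,
#'   `ci_low`, `ci_high`, `posterior_prob`.
#' @export
one_vs_rest <- function(mu_draws, direction = c("less", "greater"),
                        point = c("median", "mean")) {
  direction <- match.arg(direction)
  point <- match.arg(point)
  stopifnot(ncol(mu_draws) == 6)
  if (nrow(mu_draws) < 100) {
    warning("fewer than 100 draws: interval estimates are unstable",
            call. = FALSE)
  }
  delta <- vapply(seq_len(6), function(m) {
    mu_draws[, m] - rowMeans(mu_draws[, -m, drop = FALSE])
  }, numeric(nrow(mu_draws)))
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  eff <- if (direction == "less") exp(delta) else delta
  pt <- if (point == "median") apply(eff, 2, median) else colMeans(eff)
  ci <- apply(eff, 2, summarize_quantiles)
  prob <- if (direction == "less") colMeans(delta < 0) else colMeans(delta > 0)
  tibble::tibble(
    module_topic = colnames(mu_draws),
    effect = pt, ci_low = ci[1, ], ci_high = ci[2, ],
    posterior_prob = prob)
}

#' Full contrast table for a fitted model
#'
#' One-vs-rest contrasts for every stratum: both risk levels for the
#' drinking model (odds ratios, probability of less drinking), or every
#' feedback item (mean differences, probability of better ratings).
#'
#' @param pd A `posterior_draws` object.
#' @param point Point summary passed to [one_vs_rest()].
#' @return Tibble: `module_topic`, `stratum`, `effect`, `ci_low`,
#'   `ci_high`, `posterior_prob`.
#' @export
contrast_table <- function(pd, point = "median") {
  if (pd$model == "alcohol") {
    strata <- c("low", "high")
    direction <- "less"
  } else {
    strata <- feedback_items()
    direction <- "greater"
  }
  out <- lapply(strata, function(s) {
    res <- one_vs_rest(module_marginal_means(pd, s), direction, point)
    res$stratum <- s
    res
  })
  dplyr::bind_rows(out)[, c("module_topic", "stratum", "effect", "ci_low",
                            "ci_high", "posterior_prob")]
}
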