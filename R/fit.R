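#' Rescale model covariates
#'
#' Age is centered at 21 years with 1 unit = 10 years; days since
#' randomization are scaled so 1 unit = 28 days. Missing inputs propagate
#' as missing. These rescalings keep the posterior geometry well
#' conditioned for sampling.
#'
#' @param age_years Numeric vector of ages (years), may contain `NA`.
#' @param days_since_randomization Numeric vector of day counts, may
#'   contain `NA`.
#' @return List with `age_scaled` and `time_scaled`.
#' @export
rescale_covariates <- function(age_years, days_since_randomization) {
  list(age_scaled = (age_years - 21) / 10,
       time_scaled = days_since_randomization / 28)
}

#' Prior specification for the mixed models
#'
#' Defaults follow the analysis plan: noninformative normal(0, 1e6) priors
#' on fixed effects, inverse-gamma(0.01, 0.01) on the residual variance of
#' the linear model, and half-t(0, 10, 3) shrinkage priors on every
#' random-effect standard deviation (one scale per grouping factor), which
#' pool level estimates toward zero and temper multiplicity across the
#' module hypotheses.
#'
#' @param fixed_mean,fixed_var Mean and variance of the normal prior on
#'   each fixed effect.
#' @param re_scale,re_df Scale and degrees of freedom of the half-t prior
#'   on random-effect standard deviations.
#' @param resid_shape,resid_scale Shape and scale of the inverse-gamma
#'   prior on the residual variance (feedback model only).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(fixed_mean = 0, fixed_var = 1e6,
                       re_scale = 10, re_df = 3,
                       resid_shape = 0.01, resid_scale = 0.01) {
  structure(list(fixed_mean = fixed_mean, fixed_var = fixed_var,
                 re_scale = re_scale, re_df = re_df,
                 resid_shape = resid_shape, resid_scale = resid_scale),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' Defaults: 4 chains with different initial values, 1000 warmup
#' iterations (half adaptation, half burn-in) and 2000 retained draws per
#' chain at a thinning interval of 3 (thinning decorrelates the slowest
#' parameter, the module-by-risk scale, enough to clear the ESS gate).
#' Per-chain RNG seeds are derived deterministically from `seed`.
#'
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup iterations per chain.
#' @param thin Thinning interval.
#' @param seed Master integer seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iter = 2000, warmup = 1000, thin = 3,
                        seed = 1) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 2)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Missing-data model switches
#'
#' When enabled (the default), missing values are modelled jointly inside
#' the sampler: missing outcomes from their likelihood, missing ASI
#' scores from a zero-or-one inflated beta, missing scaled times from a
#' half-normal whose scale is the empirical SD of the observed scaled
#' times, missing prior-week indicators from a Bernoulli, and missing
#' age/sex from normal/Bernoulli baseline models. With `enabled = FALSE`
#' all covariates must be fully observed (missing outcomes are always
#' allowed and imputed).
#'
#' @param enabled Logical.
#' @return A `missing_spec` list.
#' @export
missing_spec <- function(enabled = TRUE) {
  structure(list(enabled = enabled), class = "missing_spec")
}

chain_seeds <- function(seed, chains) {
  (as.numeric(seed) * 1009 + 7919 * seq_len(chains)) %% 2147483629 + 1
}

covariate_block <- function(ms) {
  if (!ms$enabled) return("")
  paste(
    "  for (j in 1:P) {",
    "    zcat[j] ~ dcat(theta[1:3])",
    "    asi_raw[j] ~ dbeta(alpha_a, beta_a)",
    "    asi_use[j] <- equals(zcat[j], 2) + equals(zcat[j], 3) * asi_raw[j]",
    "    age_s[j] ~ dnorm(mu_age, tau_age)",
    "    sex[j] ~ dbern(p_male)",
    "  }",
    "  theta[1:3] ~ ddirch(dir_ones[1:3])",
    "  alpha_a <- exp(log_alpha_a)",
    "  beta_a <- exp(log_beta_a)",
    "  log_alpha_a ~ dnorm(0, 0.16)",
    "  log_beta_a ~ dnorm(0, 0.16)",
    "  mu_age ~ dnorm(0, 1.0E-4)",
    "  tau_age ~ dgamma(0.01, 0.01)",
    "  p_male ~ dbeta(1, 1)",
    "  for (i in 1:N) { time_s[i] ~ dnorm(0, tau_time) T(0,) }",
    sep = "\n")
}

# Half-t(0, scale, df) prior on a random-effect SD via the exactly
# equivalent gamma-gamma scale mixture (sigma^2 | a ~ IG(df/2, df/a),
# 1/a ~ Gamma(1/2, scale^-2)), which gives the precision a conjugate
# full conditional and avoids the funnel that direct sampling of the
# half-t scale produces.
re_sd_prior <- function(name, pr) {
  suf <- sub("sd_", "", name)
  sprintf(paste0("  ainv_%s ~ dgamma(0.5, %.10g)\n",
                 "  tau_%s ~ dgamma(%.10g, %d * ainv_%s)\n",
                 "  %s <- pow(tau_%s, -0.5)"),
          suf, 1 / pr$re_scale^2,
          suf, pr$re_df / 2, as.integer(pr$re_df), suf,
          name, suf)
}

fixed_prior <- function(names, pr) {
  paste(sprintf("  %s ~ dnorm(%.10g, %.10g)", names, pr$fixed_mean,
                1 / pr$fixed_var), collapse = "\n")
}

alcohol_model_string <- function(pr, ms, sample_prior = FALSE) {
  lik <- paste(
    "  for (i in 1:N) {",
    "    y[i] ~ dbern(p[i])",
    "    logit(p[i]) <- b0 + b_age * age_s[pid[i]] + b_sex * sex[pid[i]] +",
    "      b_asi * asi_use[pid[i]] + b_trial * trial2[pid[i]] +",
    "      b_time * time_s[i] + b_risk * risk[i] + b_pw * pw[i] +",
    "      u[pid[i]] + a[mod[i]] + v[mod[i], risk[i] + 1]",
    "  }",
    if (ms$enabled) "  for (i in 1:N) { pw[i] ~ dbern(p_pw) }\n  p_pw ~ dbeta(1, 1)" else NULL,
    if (ms$enabled) covariate_block(ms) else NULL,
    sep = "\n")
  paste(
    "model {",
    if (!sample_prior) lik else NULL,
    "  for (j in 1:P) { u[j] ~ dnorm(0, tau_u) }",
    "  for (m in 1:6) { a[m] ~ dnorm(0, tau_a) }",
    "  for (m in 1:6) { for (r in 1:2) { v[m, r] ~ dnorm(0, tau_v) } }",
    re_sd_prior("sd_u", pr), re_sd_prior("sd_a", pr), re_sd_prior("sd_v", pr),
    fixed_prior(c("b0", "b_age", "b_sex", "b_asi", "b_trial", "b_time",
                  "b_risk", "b_pw"), pr),
    "}", sep = "\n")
}

feedback_model_string <- function(pr, ms, sample_prior = FALSE) {
  lik <- paste(
    "  for (i in 1:N) {",
    "    y[i] ~ dnorm(mu[i], tau_resid)",
    "    mu[i] <- b0 + b_age * age_s[pid[i]] + b_sex * sex[pid[i]] +",
    "      b_asi * asi_use[pid[i]] + b_trial * trial2[pid[i]] +",
    "      b_time * time_s[i] +",
    "      u[pid[i]] + a[mod[i]] + q[item[i]] + w[mod[i], item[i]]",
    "  }",
    if (ms$enabled) covariate_block(ms) else NULL,
    sep = "\n")
  paste(
    "model {",
    if (!sample_prior) lik else NULL,
    "  for (j in 1:P) { u[j] ~ dnorm(0, tau_u) }",
    "  for (m in 1:6) { a[m] ~ dnorm(0, tau_a) }",
    "  for (k in 1:6) { q[k] ~ dnorm(0, tau_q) }",
    "  for (m in 1:6) { for (k in 1:6) { w[m, k] ~ dnorm(0, tau_w) } }",
    re_sd_prior("sd_u", pr), re_sd_prior("sd_a", pr), re_sd_prior("sd_q", pr),
    re_sd_prior("sd_w", pr),
    sprintf("  tau_resid ~ dgamma(%.10g, %.10g)", pr$resid_shape, pr$resid_scale),
    "  sigma_resid <- pow(tau_resid, -0.5)",
    fixed_prior(c("b0", "b_age", "b_sex", "b_asi", "b_trial", "b_time"), pr),
    "}", sep = "\n")
}

# Shared participant-level data preparation. Returns indices and
# participant-level covariate vectors in participant order.
participant_data <- function(rows, ms) {
  pids <- sort(unique(rows$participant_id))
  per <- rows[!duplicated(rows$participant_id), ]
  per <- per[match(pids, per$participant_id), ]
  dat <- list(P = length(pids),
              pid = match(rows$participant_id, pids),
              trial2 = per$trial2)
  if (ms$enabled) {
    asi <- per$asi_alcohol
    zcat <- ifelse(is.na(asi), NA_integer_,
                   ifelse(asi == 0, 1L, ifelse(asi == 1, 2L, 3L)))
    asi_raw <- ifelse(!is.na(asi) & asi > 0 & asi < 1, asi, NA_real_)
    dat <- c(dat, list(zcat = zcat, asi_raw = asi_raw, dir_ones = rep(1, 3),
                       age_s = per$age_scaled, sex = per$sex_male))
  } else {
    if (anyNA(per$asi_alcohol) || anyNA(per$age_scaled) || anyNA(per$sex_male)) {
      stop("missing covariates present but missing-data models disabled",
           call. = FALSE)
    }
    dat <- c(dat, list(asi_use = per$asi_alcohol, age_s = per$age_scaled,
                       sex = per$sex_male))
  }
  list(data = dat, pids = pids)
}

run_jags <- function(model_string, data, monitors, config, model_label,
                     sample_prior = FALSE) {
  seeds <- chain_seeds(config$seed, config$chains)
  inits <- lapply(seq_len(config$chains), function(ch) {
    set.seed(seeds[ch])
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seeds[ch]),
                b0 = rnorm(1, 0, 0.5))
    ini
  })
  rjags::load.module("glm", quiet = TRUE)
  adapt <- max(2L, config$warmup %/% 2L)
  burn <- max(0L, config$warmup - adapt)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = config$chains,
                          n.adapt = adapt, quiet = TRUE)
  if (burn > 0) stats::update(jm, n.iter = burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = config$iter * config$thin,
                              thin = config$thin, progress.bar = "none")
  mats <- lapply(samp, as.matrix)
  draws <- array(NA_real_, dim = c(nrow(mats[[1]]), length(mats), ncol(mats[[1]])),
                 dimnames = list(NULL, NULL, colnames(mats[[1]])))
  for (ch in seq_along(mats)) draws[, ch, ] <- mats[[ch]]
  structure(list(draws = draws,
                 model = model_label,
                 config = config,
                 chain_seeds = seeds,
                 sample_prior = sample_prior),
            class = "posterior_draws")
}

rename_params <- function(pd, pids) {
  nm <- dimnames(pd$draws)[[3]]
  topics <- module_topics()
  items <- feedback_items()
  idx1 <- function(s) as.integer(sub("^[a-z]+\\[(\\d+)[],].*$", "\\1", s))
  idx2 <- function(s) as.integer(sub("^[a-z]+\\[\\d+,(\\d+)\\]$", "\\1", s))
  out <- nm
  is_a <- grepl("^a\\[", nm)
  out[is_a] <- paste0("mod_", topics[idx1(nm[is_a])])
  is_v <- grepl("^v\\[", nm)
  out[is_v] <- paste0("modrisk_", topics[idx1(nm[is_v])], "_",
                      c("low", "high")[idx2(nm[is_v])])
  is_q <- grepl("^q\\[", nm)
  out[is_q] <- paste0("item_", items[idx1(nm[is_q])])
  is_w <- grepl("^w\\[", nm)
  out[is_w] <- paste0("moditem_", topics[idx1(nm[is_w])], "_",
                      items[idx2(nm[is_w])])
  is_u <- grepl("^u\\[", nm)
  out[is_u] <- paste0("u_", pids[idx1(nm[is_u])])
  dimnames(pd$draws)[[3]] <- out
  pd
}

#' Fit the Bayesian logistic mixed model of daily drinking
#'
#' Bernoulli-logit regression on the day-level analysis table from
#' [assemble_alcohol_rows()]. Fixed effects: intercept, scaled age, male
#' sex, ASI alcohol composite, second-trial indicator, scaled days since
#' randomization, high-risk-day indicator and prior-week-use indicator.
#' Random effects (each with its own half-t shrinkage scale): participant
#' intercepts, the 6 module topics, and the 12 module-by-risk cells.
#' Missing outcomes and covariates are sampled jointly each iteration.
#'
#' @param rows Day-level analysis table.
#' @param priors A [prior_spec()].
#' @param missing A [missing_spec()].
#' @param config An [mcmc_config()].
#' @param sample_prior If `TRUE`, drop the likelihood and sample the prior
#'   (for prior-predictive checks).
#' @return A `posterior_draws` object: array `draws` indexed
#'   (iteration, chain, parameter) with descriptive parameter names.
#' @export
fit_alcohol_model <- function(rows, priors = prior_spec(),
                              missing = missing_spec(),
                              config = mcmc_config(), sample_prior = FALSE) {
  if (sample_prior) {
    dat <- list(P = 2)
    monitors <- c("b0", "b_risk", "a", "v", "sd_u", "sd_a", "sd_v")
    pd <- run_jags(alcohol_model_string(priors, missing, TRUE), dat,
                   monitors, config, "alcohol", TRUE)
    return(rename_params(pd, c("p1", "p2")))
  }
  if (nrow(rows) == 0 || all(is.na(rows$drank))) {
    stop("all outcomes missing: nothing to fit", call. = FALSE)
  }
  if (length(unique(rows$participant_id)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  pdat <- participant_data(rows, missing)
  dat <- c(pdat$data, list(
    N = nrow(rows), y = rows$drank,
    mod = match(rows$module_topic, module_topics()),
    risk = rows$high_risk, time_s = rows$time_scaled,
    pw = rows$prior_week_use))
  if (missing$enabled) {
    sd_time <- sd(rows$time_scaled, na.rm = TRUE)
    dat$tau_time <- 1 / max(sd_time, 1e-3)^2
  } else if (anyNA(rows$prior_week_use) || anyNA(rows$time_scaled)) {
    stop("missing covariates present but missing-data models disabled",
         call. = FALSE)
  }
  monitors <- c("b0", "b_age", "b_sex", "b_asi", "b_trial", "b_time",
                "b_risk", "b_pw", "a", "v", "sd_u", "sd_a", "sd_v")
  pd <- run_jags(alcohol_model_string(priors, missing, FALSE), dat,
                 monitors, config, "alcohol", FALSE)
  rename_params(pd, pdat$pids)
}

#' Fit the Bayesian linear mixed model of feedback ratings
#'
#' Normal regression on the item-level analysis table from
#' [assemble_feedback_rows()] (the full participant x module x item grid;
#' absent ratings are missing and imputed). Fixed effects: intercept,
#' scaled age, male sex, ASI composite, second-trial indicator and scaled
#' time. Random effects: participant intercepts, 6 module topics, 6
#' feedback items and the 36 module-by-item cells, each with a half-t
#' shrinkage scale; residual variance has an inverse-gamma prior.
#'
#' @inheritParams fit_alcohol_model
#' @param rows Item-level analysis table.
#' @return A `posterior_draws` object.
#' @export
fit_feedback_model <- function(rows, priors = prior_spec(),
                               missing = missing_spec(),
                               config = mcmc_config(), sample_prior = FALSE) {
  if (sample_prior) {
    dat <- list(P = 2)
    monitors <- c("b0", "a", "q", "w", "sd_u", "sd_a", "sd_q", "sd_w",
                  "sigma_resid")
    pd <- run_jags(feedback_model_string(priors, missing, TRUE), dat,
                   monitors, config, "feedback", TRUE)
    return(rename_params(pd, c("p1", "p2")))
  }
  if (nrow(rows) == 0 || all(is.na(rows$rating))) {
    stop("all outcomes missing: nothing to fit", call. = FALSE)
  }
  if (length(unique(rows$participant_id)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  pdat <- participant_data(rows, missing)
  dat <- c(pdat$data, list(
    N = nrow(rows), y = rows$rating,
    mod = match(rows$module_topic, module_topics()),
    item = match(rows$item, feedback_items()),
    time_s = rows$time_scaled))
  if (missing$enabled) {
    sd_time <- sd(rows$time_scaled, na.rm = TRUE)
    dat$tau_time <- 1 / max(sd_time, 1e-3)^2
  } else if (anyNA(rows$time_scaled)) {
    stop("missing covariates present but missing-data models disabled",
         call. = FALSE)
  }
  monitors <- c("b0", "b_age", "b_sex", "b_asi", "b_trial", "b_time",
                "a", "q", "w", "sd_u", "sd_a", "sd_q", "sd_w", "sigma_resid")
  pd <- run_jags(feedback_model_string(priors, missing, FALSE), dat,
                 monitors, config, "feedback", FALSE)
  rename_params(pd, pdat$pids)
}

#' Extract pooled draws as a matrix
#'
#' @param pd A `posterior_draws` object.
#' @param params Optional character vector of parameter names.
#' @return Matrix with one row per pooled draw (all chains concatenated)
#'   and one column per parameter.
#' @export
draws_matrix <- function(pd, params = NULL) {
  d <- pd$draws
  if (!is.null(params)) {
    missing_p <- setdiff(params, dimnames(d)[[3]])
    if (length(missing_p) > 0) {
      stop("unknown parameter(s): ", paste(missing_p, collapse = ", "),
           call. = FALSE)
    }
    d <- d[, , params, drop = FALSE]
  }
  out <- matrix(d, nrow = prod(dim(d)[1:2]), ncol = dim(d)[3])
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' Extract one parameter as an iterations x chains matrix
#'
#' @param pd A `posterior_draws` object.
#' @param param Parameter name.
#' @return Numeric matrix, rows = iterations, columns = chains.
#' @export
chains_matrix <- function(pd, param) {
  if (!param %in% dimnames(pd$draws)[[3]]) {
    stop("unknown parameter: ", param, call. = FALSE)
  }
  pd$draws[, , param]
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_draws> %s model: %d iterations x %d chains x %d parameters\n",
              x$model, d[1], d[2], d[3]))
  invisible(x)
}
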