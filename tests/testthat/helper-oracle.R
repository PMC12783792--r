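# Independent route to the drinking-model posterior: the joint density is
# re-derived from scratch here (logistic likelihood, exchangeable normal
# random effects, half-t scale priors, normal fixed-effect priors) and
# sampled with a component-wise adaptive random-walk Metropolis sampler.
# Nothing below touches the package's model-string builder or JAGS.

# Parameter vector layout for the micro dataset (complete data, no
# missing-data machinery): 8 fixed effects, P participant intercepts,
# 6 module effects, 12 module-by-risk effects, 3 log-scales.
oracle_log_posterior <- function(theta, rows, pids, fixed_var, re_scale, re_df) {
  P <- length(pids)
  b <- theta[1:8]                    # b0, age, sex, asi, trial, time, risk, pw
  u <- theta[8 + seq_len(P)]
  a <- theta[8 + P + 1:6]
  v <- matrix(theta[8 + P + 6 + 1:12], nrow = 6)   # [module, risk + 1]
  log_sd <- theta[8 + P + 18 + 1:3]
  sds <- exp(log_sd)
  pid <- match(rows$participant_id, pids)
  mod <- match(rows$module_topic, module_topics())
  eta <- b[1] + b[2] * rows$age_scaled + b[3] * rows$sex_male +
    b[4] * rows$asi_alcohol + b[5] * rows$trial2 + b[6] * rows$time_scaled +
    b[7] * rows$high_risk + b[8] * rows$prior_week_use +
    u[pid] + a[mod] + v[cbind(mod, rows$high_risk + 1)]
  loglik <- sum(rows$drank * eta - log1p(exp(eta)))
  half_t <- function(s) log(2) + dt(s / re_scale, re_df, log = TRUE) -
    log(re_scale)
  loglik +
    sum(dnorm(b, 0, sqrt(fixed_var), log = TRUE)) +
    sum(dnorm(u, 0, sds[1], log = TRUE)) +
    sum(dnorm(a, 0, sds[2], log = TRUE)) +
    sum(dnorm(v, 0, sds[3], log = TRUE)) +
    sum(vapply(sds, half_t, numeric(1))) +
    sum(log_sd)                      # Jacobian of the log transform
}

oracle_rwmh <- function(rows, fixed_var, re_scale, re_df,
                        n_burn = 4000, n_keep = 8000, thin = 2, seed = 1) {
  set.seed(seed)
  pids <- sort(unique(rows$participant_id))
  P <- length(pids)
  d <- 8 + P + 18 + 3
  theta <- c(rep(0, 8 + P + 18), rep(log(0.5), 3))
  scales <- rep(0.4, d)
  lp <- oracle_log_posterior(theta, rows, pids, fixed_var, re_scale, re_df)
  acc <- integer(d)
  out <- matrix(NA_real_, n_keep %/% thin, d)
  for (it in seq_len(n_burn + n_keep)) {
    for (k in seq_len(d)) {
      prop <- theta
      prop[k] <- theta[k] + rnorm(1, 0, scales[k])
      lp_prop <- oracle_log_posterior(prop, rows, pids, fixed_var, re_scale,
                                      re_df)
      if (log(runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc[k] <- acc[k] + 1L
      }
    }
    if (it <= n_burn && it %% 200 == 0) {      # adapt toward ~44% acceptance
      rate <- acc / 200
      scales <- scales * exp(pmin(pmax(rate - 0.44, -0.25), 0.25))
      acc <- integer(d)
    }
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      out[(it - n_burn) %/% thin, ] <- theta
    }
  }
  colnames(out) <- c(
    c("b0", "b_age", "b_sex", "b_asi", "b_trial", "b_time", "b_risk", "b_pw"),
    paste0("u_", pids), paste0("mod_", module_topics()),
    paste0("modrisk_", rep(module_topics(), 2), "_",
           rep(c("low", "high"), each = 6)),
    c("log_sd_u", "log_sd_a", "log_sd_v"))
  out
}
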