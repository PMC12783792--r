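# Rank-normalized split-chain convergence diagnostics.
#
# The formulas follow the rank-normalization standard: draws are pooled,
# converted to fractional ranks with the Blom offset (r - 3/8)/(S + 1/4)
# and mapped through the normal quantile function; chains are split in
# half (first and last halves, middle draw dropped when odd); R-hat takes
# the maximum of the bulk statistic and the folded (median-absolute-
# deviation) statistic; autocorrelation sums use Geyer's initial positive
# and monotone sequence rules on FFT autocovariances. All draw matrices
# are iterations x chains.

z_scale <- function(m) {
  r <- rank(m, ties.method = "average")
  matrix(qnorm((r - 0.375) / (length(m) + 0.25)), nrow = nrow(m))
}

split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  cbind(m[seq_len(half), , drop = FALSE],
        m[seq.int(n - half + 1L, n), , drop = FALSE])
}

rhat_base <- function(m) {
  n <- nrow(m)
  chain_mean <- colMeans(m)
  w <- mean(apply(m, 2, var))
  b <- n * var(chain_mean)
  sqrt((b / w + n - 1) / n)
}

is_constant <- function(m) {
  (max(m) - min(m)) < .Machine$double.eps^0.5 * (1 + abs(max(m)))
}

autocov_fft <- function(x) {
  n <- length(x)
  m <- nextn(2L * n, factors = c(2, 3, 5))
  a <- c(x - mean(x), rep(0, m - n))
  f <- fft(a)
  Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

ess_base <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (is_constant(m)) return(length(m))
  acov <- apply(m, 2, autocov_fft)            # n x k
  chain_mean <- colMeans(m)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (k > 1) var_plus <- var_plus + var(chain_mean)
  rho <- numeric(n)
  rho_even <- 1
  rho[1] <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  rho[2] <- rho_odd
  t <- 1L
  while (t < (n - 3L) && (rho_even + rho_odd) > 0) {
    rho_even <- 1 - (mean_var - mean(acov[t + 2L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 3L, ])) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 2L] <- rho_even
      rho[t + 3L] <- rho_odd
    }
    t <- t + 2L
  }
  max_t <- t - 2L
  if (rho_even > 0) rho[max_t + 2L] <- rho_even
  t <- 1L
  while (t <= max_t - 2L) {
    if ((rho[t + 2L] + rho[t + 3L]) > (rho[t] + rho[t + 1L])) {
      rho[t + 2L] <- (rho[t] + rho[t + 1L]) / 2
      rho[t + 3L] <- rho[t + 2L]
    }
    t <- t + 2L
  }
  nominal <- n * k
  tau <- -1 + 2 * sum(rho[seq_len(max_t + 1L)]) +
    (if (max_t + 2L <= n) rho[max_t + 2L] else 0)
  tau <- max(tau, 1 / log10(nominal))
  nominal / tau
}

#' Rank-normalized split R-hat
#'
#' Potential-scale-reduction diagnostic on rank-normalized draws: chains
#' are split in half, pooled draws are mapped to normal scores through
#' their fractional ranks, and the statistic is the maximum of the bulk
#' value and the value on draws folded about the pooled median (which is
#' sensitive to scale differences between chains). Constant input is
#' defined as 1 by convention.
#'
#' @param m Numeric matrix of draws, iterations x chains (>= 2 chains,
#'   >= 4 iterations).
#' @return Scalar R-hat.
#' @export
rhat_rank <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 2, nrow(m) >= 4)
  if (is_constant(m)) return(1)
  s <- split_chains(m)
  bulk <- rhat_base(z_scale(s))
  folded <- abs(s - median(s))
  tail <- if (is_constant(folded)) 1 else rhat_base(z_scale(folded))
  max(bulk, tail)
}

#' Bulk and tail effective sample sizes
#'
#' Bulk ESS from the autocorrelation sum of rank-normalized split chains;
#' tail ESS for the 5% and 95% quantiles from indicator-transformed
#' draws (`x <= q`), each on split chains. Constant input returns the
#' nominal draw count.
#'
#' @param m Numeric matrix of draws, iterations x chains.
#' @return List with `ess_bulk`, `ess_tail_05`, `ess_tail_95`.
#' @export
ess_bulk_tail <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 1, nrow(m) >= 4)
  if (is_constant(m)) {
    return(list(ess_bulk = length(m), ess_tail_05 = length(m),
                ess_tail_95 = length(m)))
  }
  ess_q <- function(prob) {
    q <- quantile(m, prob, type = 7, names = FALSE)
    ess_base(split_chains(matrix(as.numeric(m <= q), nrow = nrow(m))))
  }
  list(ess_bulk = ess_base(z_scale(split_chains(m))),
       ess_tail_05 = ess_q(0.05),
       ess_tail_95 = ess_q(0.95))
}

#' Convergence report for a set of posterior draws
#'
#' Computes rank-normalized split R-hat and bulk/tail ESS for every
#' monitored parameter and gates the run: `pass` requires every R-hat
#' below `rhat_max` and every ESS (bulk, 5% tail, 95% tail) above
#' `ess_min`.
#'
#' @param pd A `posterior_draws` object.
#' @param rhat_max,ess_min Gate thresholds.
#' @return A `convergence_report`: list with `parameters` (tibble of
#'   per-parameter diagnostics), `pass`, and `thresholds`.
#' @export
check_convergence <- function(pd, rhat_max = 1.01, ess_min = 400) {
  params <- dimnames(pd$draws)[[3]]
  rows <- lapply(params, function(p) {
    m <- chains_matrix(pd, p)
    e <- ess_bulk_tail(m)
    tibble::tibble(parameter = p, rhat = rhat_rank(m),
                   ess_bulk = e$ess_bulk, ess_tail_05 = e$ess_tail_05,
                   ess_tail_95 = e$ess_tail_95)
  })
  tab <- dplyr::bind_rows(rows)
  pass <- all(tab$rhat < rhat_max) &&
    all(tab$ess_bulk > ess_min) && all(tab$ess_tail_05 > ess_min) &&
    all(tab$ess_tail_95 > ess_min)
  structure(list(parameters = tab, pass = pass,
                 thresholds = list(rhat_max = rhat_max, ess_min = ess_min)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s (max R-hat %.4f, min ESS %.0f; gates: R-hat < %s, ESS > %s)\n",
              if (x$pass) "PASS" else "FAIL",
              max(x$parameters$rhat),
              min(x$parameters$ess_bulk, x$parameters$ess_tail_05,
                  x$parameters$ess_tail_95),
              x$thresholds$rhat_max, x$thresholds$ess_min))
  invisible(x)
}
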