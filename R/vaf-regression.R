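#' Clamped logit transform of a VAF
#'
#' `log(v' / (1 - v'))` with `v' = clamp(v, eps, 1 - eps)`, so that VAFs
#' of exactly 0 or 1 remain finite.
#'
#' @param v VAF value(s) in `[0, 1]`.
#' @param eps Clamping margin (default 1e-4).
#' @return Numeric vector of logits.
#' @examples
#' logit_clamped(0.5) # 0
#' logit_clamped(0)   # about -9.21
#' @export
logit_clamped <- function(v, eps = 1e-4) {
  v <- pmin(pmax(v, eps), 1 - eps)
  log(v / (1 - v))
}

.vaf_regression_jags <- "
model {
  for (i in 1:n) {
    y[i] ~ dnorm(beta * x[i], tau)
  }
  beta ~ dnorm(1, slope_prec)
  v ~ dexp(1)
  tau <- 1 / v
}
"

#' Bayesian no-intercept regression on logit VAFs
#'
#' Tests whether VAFs measured by two assays follow the expected 1:1
#' relationship by regressing `logit(vaf_b)` on `logit(vaf_a)` without
#' an intercept: `logit(vaf_b) = beta * logit(vaf_a) + e`, with
#' `e ~ Normal(0, sigma^2)`. Since the two assays are expected to be
#' positively correlated and almost equal, the slope prior is
#' Normal(1, 0.5) — read as standard deviation 0.5 by default; set
#' `slope_prior = "var"` to read it as a variance — and the error
#' variance prior is Exponential with mean 1. The posterior is sampled
#' by MCMC (Gibbs/Metropolis via JAGS) with seeded chains; the Gelman-
#' Rubin statistic is reported and the result flagged when it exceeds
#' the convergence threshold.
#'
#' With zero pairs the posterior equals the prior, which is sampled
#' directly.
#'
#' @param vaf_a Reference-assay VAFs (fractions).
#' @param vaf_b Test-assay VAFs, same length.
#' @param draws Post-warmup draws per chain (default 2000).
#' @param chains Number of chains (default 4).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param slope_prior Whether 0.5 in the Normal(1, 0.5) slope prior is a
#'   standard deviation (`"sd"`, default) or a variance (`"var"`).
#' @param rhat_threshold Convergence threshold for the Gelman-Rubin
#'   statistic (default 1.01).
#' @param eps Logit clamping margin.
#' @return Object of class `vaf_regression`: `beta` and `sigma2`
#'   posterior draws (pooled across chains), `rhat`, `converged`, `n`,
#'   `chains`, `draws`.
#' @export
fit_vaf_regression <- function(vaf_a, vaf_b, draws = 2000, chains = 4,
                               warmup = 1000, seed = 1,
                               slope_prior = c("sd", "var"),
                               rhat_threshold = 1.01, eps = 1e-4) {
  slope_prior <- match.arg(slope_prior)
  slope_prec <- if (slope_prior == "sd") 1 / 0.5^2 else 1 / 0.5
  n <- length(vaf_a)
  stopifnot(length(vaf_b) == n)

  if (n == 0) {
    # Bayesian limit: no data, posterior = prior
    set.seed(seed)
    total <- draws * chains
    sd_slope <- sqrt(1 / slope_prec)
    return(structure(list(beta = stats::rnorm(total, 1, sd_slope),
                          sigma2 = stats::rexp(total, 1),
                          rhat = c(beta = 1, sigma2 = 1), converged = TRUE,
                          n = 0L, chains = chains, draws = draws,
                          prior_only = TRUE),
                     class = "vaf_regression"))
  }
  if (n < 3) stop("fit_vaf_regression: need at least 3 VAF pairs (or 0 for prior sampling)")

  x <- logit_clamped(vaf_a, eps)
  y <- logit_clamped(vaf_b, eps)
  data <- list(n = n, x = x, y = y, slope_prec = slope_prec)
  inits <- lapply(seq_len(chains), function(c)
    list(beta = 1, v = 1,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + c)))
  jm <- rjags::jags.model(textConnection(.vaf_regression_jags), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = warmup, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("beta", "v"), n.iter = draws,
                              progress.bar = "none")
  gd <- try(coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE),
            silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) c(beta = NA_real_, sigma2 = NA_real_)
          else stats::setNames(gd$psrf[, 1], c("beta", "sigma2"))
  converged <- all(is.finite(rhat)) && all(rhat < rhat_threshold)
  if (!converged)
    warning(sprintf("fit_vaf_regression: convergence diagnostic above %.3f (Rhat: %s)",
                    rhat_threshold, paste(round(rhat, 4), collapse = ", ")))
  mat <- do.call(rbind, lapply(samp, as.matrix))
  structure(list(beta = mat[, "beta"], sigma2 = mat[, "v"],
                 rhat = rhat, converged = converged,
                 n = n, chains = chains, draws = draws,
                 prior_only = FALSE),
            class = "vaf_regression")
}

#' @export
print.vaf_regression <- function(x, ...) {
  cat(sprintf("<vaf_regression: n=%d pairs, %d chains x %d draws%s>\n",
              x$n, x$chains, x$draws,
              if (isTRUE(x$prior_only)) " (prior only)" else ""))
  cat(sprintf("  slope beta: mean %.3f, 95%% CrI [%.3f, %.3f], Rhat %.4f\n",
              mean(x$beta), stats::quantile(x$beta, 0.025),
              stats::quantile(x$beta, 0.975), x$rhat["beta"]))
  cat(sprintf("  error sd:   mean %.3f\n", mean(sqrt(x$sigma2))))
  invisible(x)
}

#' Posterior-predictive VAF interval
#'
#' For a reference-assay VAF, the interval in which the test-assay VAF
#' is expected to fall: computed on the logit scale from the posterior
#' draws — per draw, a predictive value `beta * logit(vaf_a) + e` with
#' `e ~ Normal(0, sigma)` — then back-transformed, so the interval
#' always lies in (0, 1). A measured VAF is "within the expected range"
#' when it falls inside this interval.
#'
#' @param posterior A `vaf_regression` fit.
#' @param vaf_a Reference-assay VAF(s).
#' @param level Interval mass (default 0.95).
#' @param seed Seed for the predictive noise draws.
#' @return Matrix with columns `low`, `high`, one row per `vaf_a`.
#' @export
predictive_interval <- function(posterior, vaf_a, level = 0.95, seed = 1) {
  stopifnot(inherits(posterior, "vaf_regression"), level > 0, level < 1)
  set.seed(seed)
  nd <- length(posterior$beta)
  e <- stats::rnorm(nd, 0, sqrt(posterior$sigma2))
  a <- (1 - level) / 2
  out <- t(vapply(vaf_a, function(v) {
    yrep <- posterior$beta * logit_clamped(v) + e
    q <- stats::quantile(yrep, c(a, 1 - a), names = FALSE)
    stats::plogis(q)
  }, numeric(2)))
  colnames(out) <- c("low", "high")
  out
}
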