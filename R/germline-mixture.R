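#' Fit a four-component beta mixture to variant allele frequencies
#'
#' VAFs of calls surviving the model filter mix four populations:
#' sequencing errors (VAF near 0), true somatic variants (low VAF),
#' germline heterozygous variants (VAF near 0.5) and germline homozygous
#' variants (VAF near 1). The mixture is fitted by expectation-
#' maximization with each component initialized to bias it towards one of
#' these categories; component roles are assigned by sorted means after
#' fitting.
#'
#' The E-step computes posterior responsibilities; the M-step updates the
#' weights in closed form and each component's (alpha, beta) by
#' Nelder-Mead maximization of the responsibility-weighted beta
#' log-likelihood starting from the current values, so the observed-data
#' log-likelihood never decreases. VAFs are clamped to
#' `[eps, 1 - eps]` before fitting because the beta support is open.
#'
#' @param vafs Numeric vector of VAFs in `[0, 1]`; at least 40 values and
#'   not all identical.
#' @param k Number of components (4: error / somatic / germline-het /
#'   germline-hom).
#' @param init_means Initial component means (role-biased defaults
#'   0.005, 0.10, 0.50, 0.95).
#' @param init_concentration Initial alpha + beta of each component.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param eps Clamping margin.
#' @return Object of class `beta_mixture`: `alpha`, `beta`, `weight`
#'   (length-k vectors), `roles`, `means`, `loglik` (per-iteration
#'   trace), `iterations`, `converged`, `n`.
#' @export
fit_beta_mixture <- function(vafs, k = 4,
                             init_means = c(0.005, 0.10, 0.50, 0.95),
                             init_concentration = 20,
                             tol = 1e-6, max_iter = 500, eps = 1e-4) {
  stopifnot(k == length(init_means))
  x <- pmin(pmax(as.numeric(vafs), eps), 1 - eps)
  if (length(x) < 40)
    stop("fit_beta_mixture: need at least 40 observations")
  if (stats::sd(x) == 0)
    stop("fit_beta_mixture: degenerate data (all values identical)")

  alpha <- init_means * init_concentration
  beta <- (1 - init_means) * init_concentration
  weight <- rep(1 / k, k)
  n <- length(x)

  comp_loglik <- function(a, b) {
    vapply(seq_len(k), function(j) stats::dbeta(x, a[j], b[j], log = TRUE),
           numeric(n))
  }
  obs_ll <- function(a, b, w) {
    ll <- comp_loglik(a, b)
    lw <- sweep(ll, 2, log(w), "+")
    m <- apply(lw, 1, max)
    sum(m + log(rowSums(exp(lw - m))))
  }

  loglik <- obs_ll(alpha, beta, weight)
  trace <- loglik
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(max_iter)) {
    # E-step
    lw <- sweep(comp_loglik(alpha, beta), 2, log(weight), "+")
    m <- apply(lw, 1, max)
    r <- exp(lw - m)
    r <- r / rowSums(r)
    # M-step
    weight <- colMeans(r)
    weight <- weight / sum(weight)
    for (j in seq_len(k)) {
      if (weight[j] < 1e-10) next
      rj <- r[, j]
      nll <- function(par) {
        a <- exp(par[1]); b <- exp(par[2])
        -sum(rj * stats::dbeta(x, a, b, log = TRUE))
      }
      opt <- stats::optim(log(c(alpha[j], beta[j])), nll,
                          method = "Nelder-Mead",
                          control = list(maxit = 200))
      alpha[j] <- exp(opt$par[1])
      beta[j] <- exp(opt$par[2])
    }
    new_ll <- obs_ll(alpha, beta, weight)
    trace <- c(trace, new_ll)
    if (is.finite(loglik) &&
        abs(new_ll - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- new_ll
      converged <- TRUE
      break
    }
    loglik <- new_ll
  }

  means <- alpha / (alpha + beta)
  role_names <- c("error", "somatic", "germline_het", "germline_hom")
  ord <- order(means)
  roles <- character(k)
  roles[ord] <- role_names[seq_len(k)]
  structure(list(alpha = alpha, beta = beta, weight = weight,
                 roles = roles, means = means,
                 loglik = trace, iterations = iter,
                 converged = converged, n = n),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("<beta_mixture: %d components, n=%d, %d EM iterations%s>\n",
              length(x$alpha), x$n, x$iterations,
              if (x$converged) ", converged" else ""))
  df <- data.frame(role = x$roles, alpha = round(x$alpha, 3),
                   beta = round(x$beta, 3), weight = round(x$weight, 4),
                   mean = round(x$means, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior component responsibilities at given VAFs
#'
#' @param model A fitted `beta_mixture`.
#' @param v VAF values in `(0, 1)`.
#' @return Matrix (length(v) x k) of posterior probabilities, columns
#'   named by component role.
#' @export
posterior_responsibilities <- function(model, v) {
  k <- length(model$alpha)
  lw <- vapply(seq_len(k), function(j)
    stats::dbeta(v, model$alpha[j], model$beta[j], log = TRUE) +
      log(model$weight[j]), numeric(length(v)))
  lw <- matrix(lw, ncol = k)
  m <- apply(lw, 1, max)
  r <- exp(lw - m)
  r <- r / rowSums(r)
  colnames(r) <- model$roles
  r
}

#' The default germline VAF intervals
#'
#' The intervals derived from the full-cohort mixture fit reported for
#' this pipeline: a VAF in `[0.36, 0.67)` is indicative of a germline
#' heterozygous variant and `[0.67, 1.0]` of a germline homozygous
#' variant. Used when no mixture is fitted (small panels, few variants).
#'
#' @return Object of class `germline_intervals` with elements `het` and
#'   `hom`, each `c(low, high)`.
#' @export
default_germline_intervals <- function() {
  structure(list(het = c(0.36, 0.67), hom = c(0.67, 1.0)),
            class = "germline_intervals")
}

#' @export
print.germline_intervals <- function(x, ...) {
  cat(sprintf("<germline_intervals: het [%.4f, %.4f), hom [%.4f, %.4f]>\n",
              x$het[1], x$het[2], x$hom[1], x$hom[2]))
  invisible(x)
}

.refine_boundary <- function(model, j1, j2, lo, hi) {
  # crossover where posterior of components j1 and j2 are equal
  d <- function(v) {
    stats::dbeta(v, model$alpha[j1], model$beta[j1], log = TRUE) +
      log(model$weight[j1]) -
      stats::dbeta(v, model$alpha[j2], model$beta[j2], log = TRUE) -
      log(model$weight[j2])
  }
  if (sign(d(lo)) == sign(d(hi))) return((lo + hi) / 2)
  stats::uniroot(d, c(lo, hi), tol = 1e-7)$root
}

#' Derive germline VAF intervals from a fitted mixture
#'
#' The heterozygous interval is the VAF range over which the
#' germline-het component has the highest posterior probability, and
#' likewise for the homozygous interval. Found by a dense scan over
#' `(0, 1)` at step 1e-3, with boundaries refined to the exact posterior
#' crossover points between adjacent winning components.
#'
#' @param model A fitted `beta_mixture`.
#' @param step Scan resolution.
#' @return A `germline_intervals` object; `het` is half-open at the top
#'   where it abuts `hom`.
#' @export
derive_intervals <- function(model, step = 1e-3) {
  grid <- seq(step / 2, 1 - step / 2, by = step)
  winner <- model$roles[max.col(
    matrix(vapply(seq_along(model$alpha), function(j)
      stats::dbeta(grid, model$alpha[j], model$beta[j], log = TRUE) +
        log(model$weight[j]), numeric(length(grid))), ncol = length(model$alpha)),
    ties.method = "first")]

  interval_of <- function(role) {
    idx <- which(winner == role)
    if (length(idx) == 0)
      stop(sprintf("derive_intervals: component '%s' is never the most likely one (means: %s; weights: %s)",
                   role, paste(round(model$means, 3), collapse = ", "),
                   paste(round(model$weight, 3), collapse = ", ")))
    c(first = idx[1], last = idx[length(idx)])
  }
  het_idx <- interval_of("germline_het")
  hom_idx <- interval_of("germline_hom")
  j <- function(role) which(model$roles == role)

  refine_low <- function(idx_first, role) {
    if (idx_first == 1) return(0)
    prev_role <- winner[idx_first - 1]
    .refine_boundary(model, j(prev_role), j(role),
                     grid[idx_first - 1], grid[idx_first])
  }
  refine_high <- function(idx_last, role) {
    if (idx_last == length(grid)) return(1)
    next_role <- winner[idx_last + 1]
    .refine_boundary(model, j(role), j(next_role),
                     grid[idx_last], grid[idx_last + 1])
  }

  het <- c(refine_low(het_idx["first"], "germline_het"),
           refine_high(het_idx["last"], "germline_het"))
  hom <- c(refine_low(hom_idx["first"], "germline_hom"),
           refine_high(hom_idx["last"], "germline_hom"))
  structure(list(het = unname(het), hom = unname(hom)),
            class = "germline_intervals")
}

#' Flag likely germline variants
#'
#' A call is flagged as germline (to be removed) when its VAF falls in
#' the heterozygous interval `[het_low, het_high)` or the homozygous
#' interval `[hom_low, hom_high]` AND its key is present in dbSNP. Both
#' conditions are required: a VAF near 50% alone is not evidence of
#' germline origin, nor is dbSNP membership at somatic-range VAFs.
#'
#' @param calls A calls data frame.
#' @param intervals A `germline_intervals` object (fitted via
#'   [derive_intervals()] or the defaults).
#' @param dbsnp A dbSNP [membership_set()].
#' @return Logical vector: `TRUE` where the call is flagged germline.
#' @export
flag_germline <- function(calls, intervals = default_germline_intervals(),
                          dbsnp) {
  stopifnot(inherits(intervals, "germline_intervals"))
  vaf <- call_vaf(calls)
  in_het <- !is.na(vaf) & vaf >= intervals$het[1] & vaf < intervals$het[2]
  in_hom <- !is.na(vaf) & vaf >= intervals$hom[1] & vaf <= intervals$hom[2]
  (in_het | in_hom) & has_key(dbsnp, call_keys(calls))
}
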