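## Recursive Bayesian decoder over position bins.
##
## Each update step k covers the half-open window (t_curr - dt_delay - dt,
## t_curr - dt_delay]; dt_delay shifts the spike-collection window behind the
## current time so spikes have time to be turned into JMI estimates. The
## clusterless likelihood multiplies, over electrode groups, each spike's
## JMI * dt and the no-spike factor exp(-ground * dt); the posterior is the
## one-step prediction through the transition model times that likelihood,
## renormalised.

#' Decoder configuration
#'
#' @param n_bins Number of position bins.
#' @param dt_ms Time-bin size in ms (default 6).
#' @param dt_delay_ms Non-negative window delay in ms (default 30). The spike
#'   incorporation latency is `dt_delay_ms + dt_ms`.
#' @param transition A [transition_model()]; default uniform (non-informative).
#' @return A `decoder_config`.
#' @export
decoder_config <- function(n_bins, dt_ms = 6, dt_delay_ms = 30,
                           transition = transition_model("uniform", n_bins)) {
  stopifnot(dt_ms > 0, dt_delay_ms >= 0, n_bins >= 1)
  structure(list(n_bins = as.integer(n_bins), dt_ms = dt_ms,
                 dt_delay_ms = dt_delay_ms, transition = transition),
            class = "decoder_config")
}

#' Movement (state-transition) model between position bins
#'
#' @param kind `"uniform"` (non-informative), `"identity"`, or
#'   `"random_walk"` (discretised Gaussian step).
#' @param n_bins Number of position bins.
#' @param sd_bins Random-walk step standard deviation in bins (default 1).
#' @return A `transition_model` with a row-stochastic `matrix` (rows:
#'   previous bin, columns: next bin).
#' @export
transition_model <- function(kind = c("uniform", "identity", "random_walk"),
                             n_bins, sd_bins = 1) {
  kind <- match.arg(kind)
  M <- switch(kind,
    uniform = matrix(1 / n_bins, n_bins, n_bins),
    identity = diag(n_bins),
    random_walk = {
      d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
      K <- dnorm(d, sd = sd_bins)
      K / rowSums(K)
    })
  structure(list(kind = kind, matrix = M, n_bins = as.integer(n_bins)),
            class = "transition_model")
}

#' Spike-collection window for an update at t_curr
#'
#' @param t_curr Time of the posterior update (same unit as the config's
#'   `dt_ms`/`dt_delay_ms`, i.e. ms).
#' @param config A [decoder_config()].
#' @return `c(lower, upper)`: the half-open window `(lower, upper]`; a spike
#'   is usable iff its timestamp falls in it.
#' @export
bin_window <- function(t_curr, config) {
  stopifnot(t_curr >= config$dt_delay_ms + config$dt_ms)
  upper <- t_curr - config$dt_delay_ms
  c(lower = upper - config$dt_ms, upper = upper)
}

#' Clusterless likelihood over position bins for one time bin
#'
#' For each electrode group with spikes, the factor is
#' `prod_j [jmi_j(x) * delta] * exp(-ground(x) * delta)`; a group with no
#' spikes contributes `exp(-ground(x) * delta)` only. The product over groups
#' is accumulated in log space and exponentiated after subtracting the
#' maximum, so the returned vector is the likelihood up to a positive scale.
#'
#' @param group_results List, one element per active electrode group, each a
#'   list with `ground` (vector over bins, spikes/s) and `jmi` (list of JMI
#'   vectors, one per spike in the bin; may be empty).
#' @param delta_s Time-bin size in seconds.
#' @return List with `likelihood` (max 1) and `log_likelihood` (unshifted).
#' @export
likelihood_clusterless <- function(group_results, delta_s) {
  n_bins <- length(group_results[[1]]$ground)
  loglik <- numeric(n_bins)
  for (g in group_results) {
    if (any(g$ground < 0)) stop("negative ground intensity")
    loglik <- loglik - g$ground * delta_s
    for (jmi in g$jmi) {
      if (any(jmi < 0)) stop("negative joint mark intensity")
      loglik <- loglik + log(jmi * delta_s)
    }
  }
  list(likelihood = exp(loglik - max(loglik)), log_likelihood = loglik)
}

#' One-step prediction through the transition model
#'
#' @param posterior Normalised distribution over bins at step k-1.
#' @param transition A [transition_model()] (or a row-stochastic matrix).
#' @return Normalised one-step prior over bins.
#' @export
predict_prior <- function(posterior, transition) {
  M <- if (inherits(transition, "transition_model")) transition$matrix
       else transition
  if (any(abs(rowSums(M) - 1) > 1e-9)) stop("transition rows must sum to 1")
  prior <- as.numeric(crossprod(M, posterior))
  prior / sum(prior)
}

#' Posterior update for one time bin
#'
#' `posterior` is proportional to `prior * likelihood`, renormalised to sum to
#' one. If the product is identically zero (degenerate evidence) the prior is
#' returned with a warning.
#'
#' @param prior Normalised one-step prior from [predict_prior()].
#' @param likelihood Non-negative likelihood vector (any positive scale).
#' @param bin_timestamps Optional `(left, right]` tick bounds of the bin.
#' @param spike_count Optional number of spikes incorporated.
#' @return A `posterior_state` with `posterior`, `likelihood`,
#'   `bin_timestamps`, `spike_count`.
#' @export
posterior_update <- function(prior, likelihood,
                             bin_timestamps = c(NA_real_, NA_real_),
                             spike_count = NA_integer_) {
  if (any(likelihood < 0)) stop("likelihood must be non-negative")
  p <- prior * likelihood
  s <- sum(p)
  if (s == 0 || !is.finite(s)) {
    warning("degenerate evidence (all-zero posterior product); keeping prior")
    p <- prior
  } else p <- p / s
  structure(list(posterior = p, likelihood = likelihood,
                 bin_timestamps = bin_timestamps,
                 spike_count = spike_count),
            class = "posterior_state")
}

#' Run the forward filter over a sequence of likelihoods
#'
#' @param likelihoods Matrix, one row per time bin, columns = position bins.
#' @param transition A [transition_model()].
#' @param prior0 Initial distribution (default uniform).
#' @return Matrix of posteriors, same shape as `likelihoods`.
#' @export
forward_filter <- function(likelihoods, transition, prior0 = NULL) {
  n_bins <- ncol(likelihoods)
  p <- if (is.null(prior0)) rep(1 / n_bins, n_bins) else prior0
  out <- matrix(NA_real_, nrow(likelihoods), n_bins)
  for (k in seq_len(nrow(likelihoods))) {
    prior <- predict_prior(p, transition)
    p <- posterior_update(prior, likelihoods[k, ])$posterior
    out[k, ] <- p
  }
  out
}
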