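#' Gaussian Fay-Herriot baseline
#'
#' The classical area-level model with Gaussian random effects
#' `v_i ~ N(0, sigma_v^2)` and common variance, fitted by Gibbs sampling.
#' The `beta` and `v` updates are the same compiled conditional draws used
#' by [fit_fhas()], with the area-specific variance `lambda_i * gamma`
#' replaced by the common `sigma_v^2` (i.e. all mixing variables pinned at
#' one); `sigma_v^2` gets an inverse-Gamma(`a`, `b`) prior, so
#' `sigma_v^-2 | v ~ Gamma(m/2 + a, sum(v^2)/2 + b)`.
#'
#' @inheritParams fit_fhas
#' @return An `"sae_fit"` object; `draws$sigma2_v` holds the variance chain.
#' @examples
#' set.seed(1)
#' sim <- generate_scenario(scenario_config(1, m = 20, seed = 42), rep = 1)
#' fit <- fit_fh_normal(sim$data,
#'                      control = mcmc_control(iterations = 600,
#'                                             burn_in = 300, seed = 1))
#' fit
#' @export
fit_fh_normal <- function(data, prior = NULL, control = mcmc_control()) {
  stopifnot(inherits(data, "area_data"), inherits(control, "mcmc_control"))
  if (is.null(prior)) prior <- prior_spec(p = data$p)
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(control$seed)) set.seed(control$seed)

  m <- data$m
  ones <- rep(1, m)
  beta <- gls_init(data)
  v <- rep(0, m)
  sigma2 <- 1
  n_keep <- (control$iterations - control$burn_in) %/% control$thin
  beta_s <- matrix(NA_real_, n_keep, data$p)
  v_s <- theta_s <- matrix(NA_real_, n_keep, m)
  sig_s <- numeric(n_keep)
  k <- 0L
  for (it in seq_len(control$iterations)) {
    beta <- as.numeric(cpp_update_beta(data$y, data$X, data$psi, v,
                                       prior$mu_beta, prior$Sigma_beta_inv))
    xb <- as.numeric(data$X %*% beta)
    v <- as.numeric(cpp_update_v(data$y - xb, data$psi, ones, sigma2))
    sigma2 <- cpp_update_gamma(v, ones, prior$a, prior$b)
    if (it > control$burn_in && k < n_keep &&
        (it - control$burn_in - 1L) %% control$thin == 0L) {
      k <- k + 1L
      beta_s[k, ] <- beta
      v_s[k, ] <- v
      theta_s[k, ] <- xb + v
      sig_s[k] <- sigma2
    }
  }
  draws <- list(beta = beta_s, v = v_s, theta = theta_s, sigma2_v = sig_s)
  colnames(draws$beta) <- colnames(data$X)
  colnames(draws$v) <- colnames(draws$theta) <- data$area_id
  new_sae_fit(model = "fh", draws = draws, data = data, prior = prior,
              control = control)
}

#' Student-t random-effects baseline
#'
#' Area-level model with `v_i ~ t_k` scaled by `sigma`, fitted through the
#' inverse-gamma scale-mixture representation
#' `v_i | w_i ~ N(0, sigma^2 w_i)`, `w_i ~ IG(k/2, k/2)`. The degrees of
#' freedom `k` carry a discrete uniform prior on `k_grid` and are drawn from
#' their full conditional given the mixing weights. The `beta`/`v`/variance
#' updates reuse the same compiled conditionals as [fit_fhas()], with
#' `lambda_i * gamma` replaced by `w_i * sigma^2`.
#'
#' @inheritParams fit_fhas
#' @param k_grid support of the degrees-of-freedom prior; defaults to
#'   `1:50` (a t law needs at least 1 df).
#' @return An `"sae_fit"` object; `draws$sigma2` and `draws$k` hold the
#'   scale and degrees-of-freedom chains.
#' @examples
#' set.seed(1)
#' sim <- generate_scenario(scenario_config(2, m = 20, seed = 42), rep = 1)
#' fit <- fit_t(sim$data, control = mcmc_control(iterations = 600,
#'                                               burn_in = 300, seed = 1))
#' median(fit$draws$k)
#' @export
fit_t <- function(data, prior = NULL, control = mcmc_control(),
                  k_grid = 1:50) {
  stopifnot(inherits(data, "area_data"), inherits(control, "mcmc_control"),
            all(k_grid >= 1))
  if (is.null(prior)) prior <- prior_spec(p = data$p)
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.null(control$seed)) set.seed(control$seed)

  m <- data$m
  beta <- gls_init(data)
  v <- rep(0, m)
  sigma2 <- 1
  w <- rep(1, m)
  k_df <- k_grid[ceiling(length(k_grid) / 2)]
  keep_n <- (control$iterations - control$burn_in) %/% control$thin
  beta_s <- matrix(NA_real_, keep_n, data$p)
  v_s <- theta_s <- matrix(NA_real_, keep_n, m)
  sig_s <- k_s <- numeric(keep_n)
  kk <- 0L
  # log full conditional of k on the grid, given mixing weights w:
  # prod_i IG(w_i; k/2, k/2)
  log_k_cond <- function(w) {
    s_logw <- sum(log(w)); s_invw <- sum(1 / w)
    vapply(k_grid, function(k) {
      hk <- k / 2
      m * (hk * log(hk) - lgamma(hk)) - (hk + 1) * s_logw - hk * s_invw
    }, numeric(1))
  }
  for (it in seq_len(control$iterations)) {
    beta <- as.numeric(cpp_update_beta(data$y, data$X, data$psi, v,
                                       prior$mu_beta, prior$Sigma_beta_inv))
    xb <- as.numeric(data$X %*% beta)
    v <- as.numeric(cpp_update_v(data$y - xb, data$psi, w, sigma2))
    sigma2 <- cpp_update_gamma(v, w, prior$a, prior$b)
    w <- 1 / rgamma(m, shape = (k_df + 1) / 2,
                    rate = (k_df + v^2 / sigma2) / 2)
    lp <- log_k_cond(w)
    pk <- exp(lp - max(lp))
    k_df <- k_grid[sample.int(length(k_grid), 1L, prob = pk)]
    if (it > control$burn_in && kk < keep_n &&
        (it - control$burn_in - 1L) %% control$thin == 0L) {
      kk <- kk + 1L
      beta_s[kk, ] <- beta
      v_s[kk, ] <- v
      theta_s[kk, ] <- xb + v
      sig_s[kk] <- sigma2
      k_s[kk] <- k_df
    }
  }
  draws <- list(beta = beta_s, v = v_s, theta = theta_s, sigma2 = sig_s,
                k = k_s)
  colnames(draws$beta) <- colnames(data$X)
  colnames(draws$v) <- colnames(draws$theta) <- data$area_id
  new_sae_fit(model = "t", draws = draws, data = data, prior = prior,
              control = control, k_grid = k_grid)
}
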