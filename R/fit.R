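#' Fit the stable-random-effects area-level model
#'
#' Fully Bayesian fit of the area-level model
#' `y_i = x_i' beta + v_i + e_i`, `e_i ~ N(0, psi_i)` with known `psi_i` and
#' symmetric alpha-stable random effects `v_i ~ S(alpha, 0, gamma1, 0)`.
#' Using the scale-mixture representation `v_i | lambda_i ~ N(0, lambda_i
#' gamma)` with `gamma = 2 gamma1^2` and positive-stable mixing variables
#' `lambda_i`, the sampler combines Gibbs updates for `beta`, `v` and
#' `gamma`, exact rejection sampling for each `lambda_i`, and a uniform
#' random-walk Metropolis-Hastings step for the tail index `alpha` (skipped
#' when `prior$alpha_fixed` is set). Sweep order:
#' `beta -> v -> gamma -> lambda -> alpha`.
#'
#' Initialization: `beta` at its GLS estimate, `v = 0`, `gamma = 1`,
#' `lambda = 1`, `alpha = 1.5` (or `alpha_fixed`). Inside the sampler the
#' tail index is clamped at `2 - 1e-6` when evaluating the mixing density,
#' since the mixing law degenerates at the Gaussian boundary; the exact
#' Gaussian model is available as [fit_fh_normal()].
#'
#' @param data an [area_level_data()] object.
#' @param prior a [prior_spec()]; default `prior_spec(p = data$p)`.
#' @param control an [mcmc_control()].
#' @return An object of class `"sae_fit"` holding the kept draws
#'   (`beta`, `v`, `theta` with `theta_i = x_i' beta + v_i`, `gamma`,
#'   `alpha`), the tail-index acceptance rate, rejection-attempt statistics
#'   for the mixing variables, and the data/prior/control used.
#' @examples
#' set.seed(1)
#' sim <- generate_scenario(scenario_config(1, m = 20, seed = 42), rep = 1)
#' fit <- fit_fhas(sim$data,
#'                 control = mcmc_control(iterations = 600, burn_in = 300,
#'                                        seed = 1))
#' head(posterior_means(fit))
#' @export
fit_fhas <- function(data, prior = NULL, control = mcmc_control()) {
  stopifnot(inherits(data, "area_data"), inherits(control, "mcmc_control"))
  if (is.null(prior)) prior <- prior_spec(p = data$p)
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$p != data$p)
    stop("prior dimension does not match the design matrix", call. = FALSE)
  if (!is.null(control$seed)) set.seed(control$seed)

  alpha0 <- if (!is.null(prior$alpha_fixed)) prior$alpha_fixed else 1.5
  res <- cpp_fhas_mcmc(
    data$y, data$X, data$psi, prior$mu_beta, prior$Sigma_beta_inv,
    prior$a, prior$b,
    beta = gls_init(data), v = rep(0, data$m), gam = 1, alpha = alpha0,
    lam = rep(1, data$m),
    alpha_is_fixed = !is.null(prior$alpha_fixed),
    halfwidth = control$proposal_halfwidth,
    iterations = control$iterations, burn_in = control$burn_in,
    thin = control$thin, max_attempts = control$max_attempts,
    n_quad = 96L, store_lambda = control$store_lambda)

  draws <- list(beta = res$beta, v = res$v, theta = res$theta,
                gamma = as.numeric(res$gamma), alpha = as.numeric(res$alpha))
  colnames(draws$beta) <- colnames(data$X)
  colnames(draws$v) <- colnames(draws$theta) <- data$area_id
  if (control$store_lambda) {
    draws$lambda <- res$lambda
    colnames(draws$lambda) <- data$area_id
  }
  if (res$lambda_fallbacks > 0)
    warning(sprintf(
      "rejection sampler hit the attempt cap %d time(s); grid inverse-CDF fallback used",
      res$lambda_fallbacks))
  new_sae_fit(model = "fhas", draws = draws, data = data, prior = prior,
              control = control,
              alpha_accept_rate = if (res$alpha_proposals > 0)
                res$alpha_accepts / res$alpha_proposals else NA_real_,
              lambda_attempts = list(mean = res$lambda_attempts_mean,
                                     max = res$lambda_attempts_max,
                                     fallbacks = res$lambda_fallbacks))
}

gls_init <- function(data) {
  w <- 1 / data$psi
  Xw <- data$X * w
  as.numeric(solve(crossprod(data$X, Xw), crossprod(Xw, data$y)))
}

new_sae_fit <- function(model, draws, data, prior, control, ...) {
  structure(c(list(model = model, draws = draws, data = data, prior = prior,
                   control = control), list(...)),
            class = "sae_fit")
}

#' @export
print.sae_fit <- function(x, ...) {
  labs <- c(fhas = "stable random effects",
            fh = "Gaussian random effects",
            t = "Student-t random effects")
  cat(sprintf("Area-level model fit (%s), %d areas\n",
              labs[[x$model]], x$data$m))
  cat(sprintf("  kept draws: %d (of %d sweeps, burn-in %d, thin %d)\n",
              nrow(x$draws$theta), x$control$iterations, x$control$burn_in,
              x$control$thin))
  bm <- colMeans(x$draws$beta)
  cat("  posterior mean beta:", paste(sprintf("%.3f", bm), collapse = ", "), "\n")
  if (x$model == "fhas") {
    if (is.finite(x$alpha_accept_rate))
      cat(sprintf("  tail index alpha: mean %.3f (MH acceptance %.2f)\n",
                  mean(x$draws$alpha), x$alpha_accept_rate))
    else
      cat(sprintf("  tail index alpha fixed at %.3f\n", x$draws$alpha[1]))
  }
  invisible(x)
}

#' Posterior means of the small-area parameters
#'
#' @param fit an `"sae_fit"` object.
#' @return Named numeric vector of posterior means of
#'   `theta_i = x_i' beta + v_i`.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "sae_fit"))
  colMeans(fit$draws$theta)
}

#' Equal-tailed posterior credible intervals for the small-area parameters
#'
#' @param fit an `"sae_fit"` object.
#' @param level interval level, default 0.95.
#' @return `m x 2` matrix of lower/upper interval endpoints.
#' @export
posterior_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sae_fit"), level > 0, level < 1)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  t(apply(fit$draws$theta, 2, quantile, probs = pr, names = FALSE))
}
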