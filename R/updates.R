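#' Single conditional updates of the Gibbs sweep
#'
#' These functions expose, one draw at a time, the exact conditional updates
#' used inside [fit_fhas()] (the full chain calls the same compiled
#' routines). They are the building blocks for the baselines and for
#' distributional checks of each block.
#'
#' The conditionals, with `Sigma = diag(psi)` and shrinkage weight
#' `delta_i = lambda_i gamma / (lambda_i gamma + psi_i)`:
#' * `beta | ...  ~ N((X' Sigma^-1 X + Sigma_beta^-1)^-1 X' Sigma^-1 (y - v),
#'    (X' Sigma^-1 X + Sigma_beta^-1)^-1)` (plus the prior-mean term when
#'    `mu_beta != 0`),
#' * `v_i | ... ~ N(delta_i (y_i - x_i' beta), delta_i psi_i)`,
#' * `gamma^-1 | ... ~ Gamma(m/2 + a, rate = sum_i v_i^2 / (2 lambda_i) + b)`,
#' * `lambda_i | ... ~ N(v_i | 0, lambda_i gamma) f_{alpha/2}(lambda_i)`
#'    drawn exactly by rejection with the positive-stable prior as proposal
#'    and bound `N(v | 0, s) <= (2 pi v^2)^{-1/2} e^{-1/2}`,
#' * `alpha`: uniform random-walk Metropolis-Hastings on (0, 2] with
#'    acceptance ratio `prod_i f_{alpha_new/2}(lambda_i) /
#'    f_{alpha_cur/2}(lambda_i)`.
#'
#' @param state an [mcmc_state()].
#' @param data an [area_level_data()] object.
#' @param prior a [prior_spec()].
#' @name gibbs_updates
NULL

#' @rdname gibbs_updates
#' @return `update_beta()`: a new draw of the coefficient vector.
#' @export
update_beta <- function(state, data, prior) {
  as.numeric(cpp_update_beta(data$y, data$X, data$psi, state$v,
                             prior$mu_beta, prior$Sigma_beta_inv))
}

#' @rdname gibbs_updates
#' @return `update_v()`: a new draw of the `m` random effects.
#' @export
update_v <- function(state, data) {
  as.numeric(cpp_update_v(data$y - as.numeric(data$X %*% state$beta),
                          data$psi, state$lambda, state$gamma))
}

#' @rdname gibbs_updates
#' @return `update_gamma()`: a new draw of the global variance `gamma`.
#' @export
update_gamma <- function(state, prior) {
  cpp_update_gamma(state$v, state$lambda, prior$a, prior$b)
}

#' @rdname gibbs_updates
#' @param max_attempts rejection-attempt cap per area before the grid
#'   inverse-CDF fallback.
#' @param n_quad quadrature order for the positive-stable density.
#' @return `update_lambda()`: list with `lambda` (new draws), `attempts`
#'   (per-area rejection attempts) and `fallbacks` (count of capped areas).
#' @export
update_lambda <- function(state, max_attempts = 1e5, n_quad = 96) {
  out <- cpp_update_lambda(state$v, state$gamma, state$alpha,
                           as.integer(max_attempts), as.integer(n_quad))
  out$lambda <- as.numeric(out$lambda)
  out
}

#' @rdname gibbs_updates
#' @param halfwidth half-width of the uniform proposal for the tail index.
#' @param cur_loglik optional current value of
#'   `sum_i log f_{alpha/2}(lambda_i)` to avoid recomputation; `NA` (default)
#'   recomputes it.
#' @return `update_alpha()`: list with `alpha` (new value), `accepted`
#'   (logical) and `loglik` (the mixing log-likelihood at the new value).
#' @export
update_alpha <- function(state, halfwidth = 0.15, n_quad = 96,
                         cur_loglik = NA_real_) {
  cpp_update_alpha(state$lambda, state$alpha, halfwidth,
                   as.integer(n_quad), cur_loglik)
}
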