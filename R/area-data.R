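#' Area-level survey data
#'
#' The observed layer of an area-level small area model: one direct estimate
#' `y[i]` per area with its known design-based sampling variance `psi[i]`
#' and a design matrix of area-level covariates (intercept column first).
#'
#' @param y numeric vector of direct estimates, one per area.
#' @param X design matrix (`m x p`); if it lacks a leading column of ones one
#'   is prepended. A plain numeric vector is taken as a single covariate.
#' @param psi known sampling variances, strictly positive.
#' @param area_id optional area labels; defaults to `"area_1"`, ...
#' @return An object of class `"area_data"` with elements `y`, `X`, `psi`,
#'   `area_id`, `m`, `p`.
#' @examples
#' d <- area_level_data(y = c(10, 12, 9), X = c(1.2, 0.7, 1.0),
#'                      psi = c(1, 0.5, 2))
#' d$m; d$p
#' @export
area_level_data <- function(y, X = NULL, psi, area_id = NULL) {
  y <- as.numeric(y)
  m <- length(y)
  if (is.null(X)) X <- matrix(1, m, 1)
  if (is.vector(X) && is.numeric(X)) X <- cbind(X)
  X <- as.matrix(X)
  if (nrow(X) != m) stop("'X' must have one row per area", call. = FALSE)
  if (!all(X[, 1] == 1)) X <- cbind(1, X)
  psi <- as.numeric(psi)
  if (length(psi) != m) stop("'psi' must have one value per area", call. = FALSE)
  if (anyNA(y) || anyNA(X) || anyNA(psi))
    stop("area-level data must not contain missing values", call. = FALSE)
  if (any(psi <= 0))
    stop("all sampling variances 'psi' must be strictly positive", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix 'X' does not have full column rank", call. = FALSE)
  if (is.null(area_id)) area_id <- paste0("area_", seq_len(m))
  if (anyDuplicated(area_id)) stop("duplicated 'area_id'", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", if (ncol(X) > 1)
      paste0("x", seq_len(ncol(X) - 1)))
  structure(list(y = y, X = X, psi = psi,
                 area_id = as.character(area_id), m = m, p = ncol(X)),
            class = "area_data")
}

#' @export
print.area_data <- function(x, ...) {
  cat(sprintf("Area-level data: %d areas, %d regression column(s)\n", x$m, x$p))
  cat(sprintf("  y:   [%.4g, %.4g]   psi: [%.4g, %.4g]\n",
              min(x$y), max(x$y), min(x$psi), max(x$psi)))
  invisible(x)
}

# drop one area, used by leave-one-out cross-validation
drop_area <- function(data, i) {
  area_level_data(y = data$y[-i], X = data$X[-i, , drop = FALSE],
                  psi = data$psi[-i], area_id = data$area_id[-i])
}

#' Prior specification for the area-level samplers
#'
#' Defaults follow the weakly-informative choices used throughout:
#' flat-ish Gaussian prior on the regression coefficients
#' (`mu_beta = 0`, `Sigma_beta = diag(1e5)`), inverse-Gamma(`a`, `b`) on the
#' global random-effect variance with `a = b = 0.01`, and a Uniform(0, 2]
#' prior on the tail index. Setting `alpha_fixed` pins the tail index and
#' skips its Metropolis-Hastings step (e.g. `alpha_fixed = 1.1` gives the
#' known-tail-index variant of the stable model).
#'
#' @param p number of regression coefficients (intercept included).
#' @param mu_beta prior mean of the coefficients.
#' @param Sigma_beta prior covariance of the coefficients (symmetric
#'   positive definite).
#' @param a,b inverse-Gamma shape and scale for the global variance, both
#'   positive.
#' @param alpha_fixed optional fixed tail index in (0, 2]; `NULL` (default)
#'   estimates it.
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec(p = 2)
#' prior_spec(p = 2, alpha_fixed = 1.1)
#' @export
prior_spec <- function(p, mu_beta = rep(0, p), Sigma_beta = diag(1e5, p),
                       a = 0.01, b = 0.01, alpha_fixed = NULL) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
  mu_beta <- as.numeric(mu_beta)
  Sigma_beta <- as.matrix(Sigma_beta)
  if (length(mu_beta) != p || !all(dim(Sigma_beta) == p))
    stop("'mu_beta' and 'Sigma_beta' must match 'p'", call. = FALSE)
  if (!isSymmetric(unname(Sigma_beta)) ||
      inherits(try(chol(Sigma_beta), silent = TRUE), "try-error"))
    stop("'Sigma_beta' must be symmetric positive definite", call. = FALSE)
  if (!(a > 0 && b > 0))
    stop("'a' and 'b' must be positive", call. = FALSE)
  if (!is.null(alpha_fixed)) {
    stopifnot(is.numeric(alpha_fixed), length(alpha_fixed) == 1L)
    if (!(alpha_fixed > 0 && alpha_fixed <= 2))
      stop("'alpha_fixed' must lie in (0, 2]", call. = FALSE)
  }
  structure(list(p = as.integer(p), mu_beta = mu_beta, Sigma_beta = Sigma_beta,
                 Sigma_beta_inv = solve(Sigma_beta), a = a, b = b,
                 alpha_fixed = alpha_fixed),
            class = "prior_spec")
}

#' Chain configuration for the MCMC samplers
#'
#' @param iterations total sweeps.
#' @param burn_in sweeps discarded, `0 <= burn_in < iterations`.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed optional integer seed; when set the chain is bit-reproducible.
#' @param proposal_halfwidth half-width of the uniform random-walk proposal
#'   for the tail index.
#' @param max_attempts cap on rejection-sampling attempts per area and sweep
#'   for the local mixing variables; beyond it a grid inverse-CDF draw is
#'   used (and counted).
#' @param store_lambda keep the per-sweep local mixing variables in the
#'   output (needed only for diagnostics on lambda itself).
#' @return An object of class `"mcmc_control"`.
#' @examples
#' mcmc_control(iterations = 2000, burn_in = 1000, seed = 7)
#' @export
mcmc_control <- function(iterations = 20000, burn_in = 10000, thin = 1,
                         seed = NULL, proposal_halfwidth = 0.15,
                         max_attempts = 1e5, store_lambda = FALSE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1,
            proposal_halfwidth > 0, max_attempts >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = if (!is.null(seed)) as.integer(seed),
                 proposal_halfwidth = proposal_halfwidth,
                 max_attempts = as.integer(max_attempts),
                 store_lambda = isTRUE(store_lambda)),
            class = "mcmc_control")
}

#' One sweep's parameter state
#'
#' Bundles the blocks updated by the Gibbs sweep: regression coefficients
#' `beta`, random effects `v`, global variance `gamma` (the variance of the
#' conditionally Gaussian random effect is `lambda[i] * gamma`; in terms of
#' the stable scale, `gamma = 2 * gamma1^2`), tail index `alpha`, and the
#' positive local mixing variables `lambda`.
#'
#' @param beta,v,gamma,alpha,lambda current values of each block.
#' @return An object of class `"mcmc_state"`.
#' @export
mcmc_state <- function(beta, v, gamma, alpha, lambda) {
  stopifnot(gamma > 0, all(lambda > 0), alpha > 0, alpha <= 2,
            length(v) == length(lambda))
  structure(list(beta = as.numeric(beta), v = as.numeric(v),
                 gamma = gamma, alpha = alpha, lambda = as.numeric(lambda)),
            class = "mcmc_state")
}
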