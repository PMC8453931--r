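#' Read area-level data from CSV
#'
#' Expects one row per area with columns `area_id`, `y` (direct estimate)
#' and `psi` (its known sampling variance), plus any number of covariate
#' columns. An intercept column is prepended automatically. Schema
#' violations (missing column, nonpositive `psi`, missing values,
#' duplicated ids) are reported with the offending column and rows.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param covariates character vector of covariate column names to use;
#'   `NULL` selects every numeric column other than
#'   `area_id`/`y`/`psi`/`true_v`/`true_theta`.
#' @param standardize center and scale the covariates (common for real
#'   survey runs where covariates live on very different scales);
#'   coefficients then refer to the standardized scale.
#' @param y_col,psi_col,area_col column names for the direct estimates,
#'   variances and labels.
#' @return An [area_level_data()] object; if the file carries `true_v` /
#'   `true_theta` columns (simulator output) they are attached as
#'   attributes `"true_v"` / `"true_theta"`.
#' @export
load_area_csv <- function(path, covariates = NULL, standardize = FALSE,
                          y_col = "y", psi_col = "psi",
                          area_col = "area_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c(area_col, y_col, psi_col))
    if (!col %in% names(df))
      stop(sprintf("required column '%s' missing from %s", col, path),
           call. = FALSE)
  if (is.null(covariates)) {
    reserved <- c(area_col, y_col, psi_col, "true_v", "true_theta")
    covariates <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          reserved)
  } else {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov))
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  check_col <- function(x, name, positive = FALSE) {
    if (!is.numeric(x))
      stop(sprintf("column '%s' must be numeric", name), call. = FALSE)
    if (anyNA(x))
      stop(sprintf("column '%s' has missing values in row(s) %s", name,
                   paste(which(is.na(x)), collapse = ", ")), call. = FALSE)
    if (positive && any(x <= 0))
      stop(sprintf("column '%s' must be strictly positive; offending row(s): %s",
                   name, paste(which(x <= 0), collapse = ", ")),
           call. = FALSE)
  }
  check_col(df[[y_col]], y_col)
  check_col(df[[psi_col]], psi_col, positive = TRUE)
  for (cv in covariates) check_col(df[[cv]], cv)
  X <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  if (!is.null(X) && standardize) X <- scale(X)
  out <- area_level_data(y = df[[y_col]], X = X, psi = df[[psi_col]],
                         area_id = df[[area_col]])
  if ("true_v" %in% names(df)) attr(out, "true_v") <- df$true_v
  if ("true_theta" %in% names(df)) attr(out, "true_theta") <- df$true_theta
  out
}

#' Posterior summary tables for a fitted area-level model
#'
#' @param fit an `"sae_fit"` object.
#' @return List with `theta`: one row per area (posterior mean, sd,
#'   quantiles 2.5/50/97.5), and `params`: the same summaries for the model
#'   parameters (`beta`, plus `gamma` and `alpha` for the stable model,
#'   `sigma2_v` for the Gaussian baseline, `sigma2` and `k` for the
#'   Student-t baseline), with the tail-index acceptance rate attached as
#'   attribute `"alpha_accept_rate"` where applicable.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "sae_fit"))
  if (nrow(fit$draws$theta) < 1) stop("empty chain", call. = FALSE)
  smry <- function(x) c(mean = mean(x), sd = sd(x),
                        quantile(x, c(0.025, 0.5, 0.975), names = FALSE))
  tab <- function(mat) {
    out <- t(apply(mat, 2, smry))
    colnames(out) <- c("mean", "sd", "q2.5", "q50", "q97.5")
    as.data.frame(out)
  }
  theta <- cbind(area_id = fit$data$area_id, tab(fit$draws$theta))
  rownames(theta) <- NULL
  pars <- fit$draws$beta
  extra <- switch(fit$model,
                  fhas = cbind(gamma = fit$draws$gamma,
                               alpha = fit$draws$alpha),
                  fh = cbind(sigma2_v = fit$draws$sigma2_v),
                  t = cbind(sigma2 = fit$draws$sigma2, k = fit$draws$k))
  params <- tab(cbind(pars, extra))
  if (fit$model == "fhas")
    attr(params, "alpha_accept_rate") <- fit$alpha_accept_rate
  list(theta = theta, params = params)
}

#' Synthetic stand-in for the California county fitness survey
#'
#' Generates a synthetic area-level data set emulating the structure of the
#' 2015-2016 California county survey of student physical-fitness test
#' passing proportions: 57 areas, direct estimates on the percent scale
#' roughly in (18, 58) with two strongly outlying counties, design-based
#' standard errors between about 2.2 and 9.6, and seven standardized
#' socio-economic covariates. This is simulated data for examples and
#' stress tests only -- it is not the survey data, and numbers computed
#' from it do not reproduce results obtained on the real survey.
#'
#' @param seed integer seed.
#' @param m number of counties.
#' @return An [area_level_data()] object with attribute `"outliers"` giving
#'   the indices of the two planted outlying areas.
#' @export
synthetic_pft_data <- function(seed = 2016, m = 57) {
  set.seed(seed)
  p_cov <- 7
  Z <- matrix(rnorm(m * p_cov), m, p_cov)
  colnames(Z) <- c("pct_under18", "pct_hispanic", "pct_white", "pct_black",
                   "pct_bachelor", "median_income", "pct_poverty")
  beta <- c(31, 0, -2.0, 2.2, 0, 2.6, 0.8, -2.2)  # intercept + 7 effects
  v <- rnorm(m, 0, 2)
  out_idx <- c(11L, 43L)
  v[out_idx] <- c(18, 14)                          # two gross outliers
  se <- runif(m, 2.3, 9.5)
  psi <- se^2
  theta <- as.numeric(cbind(1, Z) %*% beta) + v
  y <- pmin(pmax(theta + rnorm(m, 0, se), 12), 75)
  out <- area_level_data(y = y, X = Z, psi = psi,
                         area_id = sprintf("county_%02d", seq_len(m)))
  attr(out, "outliers") <- out_idx
  out
}
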