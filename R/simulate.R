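#' Simulation-study scenario configuration
#'
#' Encodes the four data-generating designs of the comparison study. All
#' scenarios share the mean structure: design matrix with an intercept and
#' one covariate drawn from N(10, sd 2), true coefficients `beta = (20, 1)`,
#' and sampling errors `e_i ~ N(0, psi_i)` with the variances allocated
#' equally over `psi_grid`. The scenarios differ in the random-effect law:
#'
#' * Scenario 1: `v_i ~ N(0, 1)` (the Gaussian model holds);
#' * Scenario 2: `v_i ~ t_3` (mild outliers);
#' * Scenario 3: `v_i ~ S(1.1, 0, 1/2, 0)` symmetric stable (gross outliers);
#' * Scenario 4: `v_i ~ Pareto(scale 5, shape 2)` (skewed, occasional very
#'   large effects).
#'
#' The default variance grid is the ten-value set `{0.5, 1, ..., 5}`; an
#' equal allocation requires `m` divisible by the grid length. (A grid
#' including 0 would make those areas' direct estimates exact and is
#' inconsistent with the direct-estimator error levels the design targets,
#' but can be supplied explicitly via `psi_grid`.)
#'
#' @param scenario integer 1-4.
#' @param m number of areas (20, 50, 100 canonical), divisible by
#'   `length(psi_grid)`.
#' @param replicates number of replicate data sets (50 canonical).
#' @param beta_true true coefficient vector (intercept, slope).
#' @param x_mean,x_sd covariate distribution parameters.
#' @param psi_grid sampling-variance grid, equal allocation.
#' @param alpha,gamma1 stable tail index and scale for Scenario 3.
#' @param t_df degrees of freedom for Scenario 2.
#' @param pareto_scale,pareto_shape Pareto parameters for Scenario 4.
#' @param seed master seed; per-replicate seeds are derived from it so each
#'   `(seed, rep)` pair maps to one fixed data set.
#' @return An object of class `"scenario_config"`.
#' @examples
#' scenario_config(3, m = 20, seed = 1)
#' @export
scenario_config <- function(scenario, m = 20, replicates = 50,
                            beta_true = c(20, 1), x_mean = 10, x_sd = 2,
                            psi_grid = seq(0.5, 5, by = 0.5),
                            alpha = 1.1, gamma1 = 0.5, t_df = 3,
                            pareto_scale = 5, pareto_shape = 2, seed = 1) {
  stopifnot(scenario %in% 1:4, m >= 1, replicates >= 1,
            length(beta_true) == 2, x_sd > 0, all(psi_grid > 0),
            alpha > 0, alpha <= 2, gamma1 > 0, t_df >= 1,
            pareto_scale > 0, pareto_shape > 0)
  if (m %% length(psi_grid) != 0)
    stop(sprintf("'m' (%d) must be divisible by the psi grid length (%d) for equal allocation",
                 m, length(psi_grid)), call. = FALSE)
  structure(list(scenario = as.integer(scenario), m = as.integer(m),
                 replicates = as.integer(replicates),
                 beta_true = as.numeric(beta_true),
                 x_mean = x_mean, x_sd = x_sd, psi_grid = as.numeric(psi_grid),
                 alpha = alpha, gamma1 = gamma1, t_df = t_df,
                 pareto_scale = pareto_scale, pareto_shape = pareto_shape,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  law <- switch(x$scenario,
                "v ~ N(0, 1)",
                sprintf("v ~ t_%g", x$t_df),
                sprintf("v ~ S(%g, 0, %g, 0)", x$alpha, x$gamma1),
                sprintf("v ~ Pareto(%g, %g)", x$pareto_scale, x$pareto_shape))
  cat(sprintf("Scenario %d: %s; m = %d, %d replicate(s), seed %d\n",
              x$scenario, law, x$m, x$replicates, x$seed))
  invisible(x)
}

#' Equal allocation of sampling variances over areas
#'
#' Assigns each value of the variance grid to the same number of areas, in
#' deterministic order (grid value 1 to areas 1..m/k, and so on).
#'
#' @param m number of areas, divisible by `length(grid)`.
#' @param grid variance values, nonnegative. (Allocation itself permits a
#'   zero entry; generating or fitting data requires every `psi > 0`, so
#'   zero-variance areas are rejected downstream.)
#' @return Numeric vector of `m` sampling variances.
#' @examples
#' allocate_psi(20, seq(0.5, 5, by = 0.5))
#' @export
allocate_psi <- function(m, grid = seq(0.5, 5, by = 0.5)) {
  stopifnot(m >= 1, all(grid >= 0))
  if (m %% length(grid) != 0)
    stop(sprintf("'m' (%d) is not divisible by the grid length (%d)",
                 m, length(grid)), call. = FALSE)
  rep(as.numeric(grid), each = m / length(grid))
}

replicate_seeds <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  sample.int(.Machine$integer.max, cfg$replicates)
}

#' Generate one replicate data set from a simulation scenario
#'
#' Draws the covariate, random effects and sampling errors for replicate
#' `rep` of the configured design. The replicate seed is derived
#' deterministically from `(cfg$seed, rep)`, so the same pair always yields
#' the same data set; the covariate is drawn afresh for each replicate.
#'
#' @param cfg a [scenario_config()].
#' @param rep replicate index in `1:cfg$replicates`.
#' @return An object of class `"simulated_dataset"`: list with `data` (an
#'   [area_level_data()]), the truths `true_v` and
#'   `true_theta = X beta_true + true_v`, the replicate index and seed.
#' @examples
#' sim <- generate_scenario(scenario_config(1, m = 20, seed = 9), rep = 2)
#' sim$data
#' @export
generate_scenario <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!(rep >= 1 && rep <= cfg$replicates))
    stop("'rep' must lie in 1..replicates", call. = FALSE)
  seed_r <- replicate_seeds(cfg)[rep]
  set.seed(seed_r)
  m <- cfg$m
  x1 <- rnorm(m, cfg$x_mean, cfg$x_sd)
  X <- cbind(1, x1)
  v <- switch(cfg$scenario,
              rnorm(m),
              rt(m, df = cfg$t_df),
              sample_sas(m, alpha = cfg$alpha, gamma1 = cfg$gamma1),
              cfg$pareto_scale * runif(m)^(-1 / cfg$pareto_shape))
  psi <- allocate_psi(m, cfg$psi_grid)
  e <- rnorm(m, 0, sqrt(psi))
  theta <- as.numeric(X %*% cfg$beta_true) + v
  y <- theta + e
  structure(list(data = area_level_data(y = y, X = X, psi = psi),
                 true_v = v, true_theta = theta, rep = as.integer(rep),
                 seed = seed_r),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated data set (replicate %d, seed %d)\n", x$rep, x$seed))
  print(x$data)
  invisible(x)
}

#' Write scenario replicates to CSV files with a manifest
#'
#' Writes one CSV per replicate (columns `area_id, y, psi, x1, true_v,
#' true_theta`) and a JSON manifest carrying the full configuration and the
#' derived per-replicate seeds, sufficient to regenerate the files
#' byte-for-byte.
#'
#' @param cfg a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_scenario_csvs <- function(cfg, dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing the manifest requires the 'jsonlite' package", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    sim <- generate_scenario(cfg, r)
    df <- data.frame(area_id = sim$data$area_id, y = sim$data$y,
                     psi = sim$data$psi, x1 = sim$data$X[, 2],
                     true_v = sim$true_v, true_theta = sim$true_theta)
    files[r] <- file.path(dir, sprintf("scenario%d_m%d_rep%03d.csv",
                                       cfg$scenario, cfg$m, r))
    write.csv(df, files[r], row.names = FALSE)
  }
  manifest <- file.path(dir, sprintf("scenario%d_m%d_manifest.json",
                                     cfg$scenario, cfg$m))
  jsonlite::write_json(
    list(config = unclass(cfg), replicate_seeds = replicate_seeds(cfg),
         files = basename(files),
         package_version = as.character(utils::packageVersion("fhstable"))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
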