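# Shared fixtures, all generated in code.

toy_data_m3 <- function() {
  area_level_data(y = c(2.3, -1.1, 0.7),
                  X = c(0.5, -0.2, 1.4),
                  psi = c(1.0, 0.5, 2.0))
}

# empirical characteristic function at frequencies w
ecf <- function(x, w) vapply(w, function(wi) mean(cos(wi * x)), numeric(1))

# two-sided KS distance of draws against a cdf given on a grid
ks_grid <- function(draws, grid, cdf) {
  cdf_at <- approx(grid, cdf, xout = sort(draws), yleft = 0, yright = 1)$y
  n <- length(draws)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(abs(emp_hi - cdf_at), abs(emp_lo - cdf_at))
}

# KS critical value at level 0.01
ks_crit01 <- function(n) 1.628 / sqrt(n)

# total-variation distance between a sample and a density known on a grid,
# computed on the grid's bin partition
tv_sample_vs_grid <- function(draws, grid, dens) {
  breaks <- c(grid[1] - diff(grid[1:2]) / 2,
              grid[-length(grid)] + diff(grid) / 2,
              grid[length(grid)] + diff(grid)[length(grid) - 1] / 2)
  p_grid <- dens * diff(breaks)
  p_grid <- p_grid / sum(p_grid)
  h <- hist(pmin(pmax(draws, breaks[1]), breaks[length(breaks)]),
            breaks = breaks, plot = FALSE)
  p_emp <- h$counts / sum(h$counts)
  0.5 * sum(abs(p_emp - p_grid))
}

levy_logpdf <- function(x) log(1 / (2 * sqrt(pi))) - 1.5 * log(x) - 1 / (4 * x)
levy_cdf <- function(x) 2 * pnorm(1 / sqrt(2 * x), lower.tail = FALSE)
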