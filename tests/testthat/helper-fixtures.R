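# shared fixtures, all generated in code

toy_climate <- function(rows = 20, cols = 20, vars = c("env1", "env2"),
                        seed = 1, autocorr = 50) {
  generate_climate(c(rows, cols), vars, autocorr_length_km = autocorr,
                   cell_size_km = 10, seed = seed)
}

# climate stack with hand-chosen layer values (bypasses the generator)
manual_climate <- function(layers, cell_size_km = 10) {
  climate_stack(layers, cell_size_km = cell_size_km)
}

# linearly separable presence/background cloud in two covariates
separable_cloud <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  x <- data.frame(env1 = c(rnorm(n, gap), rnorm(n, -gap)),
                  env2 = rnorm(2 * n))
  list(x = x, y = c(rep(1L, n), rep(0L, n)))
}

# occurrence-like data frame on a grid
occ_df <- function(rows, cols) data.frame(row = rows, col = cols,
                                          x_km = (cols - 0.5) * 10,
                                          y_km = (rows - 0.5) * 10)

# random presence-absence matrix without empty rows
random_pa <- function(n, p, prob = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    pa <- matrix(stats::rbinom(n * p, 1, prob), n, p)
    if (all(rowSums(pa) > 0) && sum(pa) < n * p) return(pa)
  }
}

# brute-force AUC: concordant pairs + half ties
auc_brute <- function(pres, bg) {
  s <- 0
  for (p in pres) for (b in bg) s <- s + (p > b) + 0.5 * (p == b)
  s / (length(pres) * length(bg))
}

# independent VIF oracle via per-column OLS R^2
vif_oracle <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

# brute-force iterative VIF filter, independent of the package's loop
vif_filter_oracle <- function(x, threshold = 10) {
  x <- as.matrix(x)
  repeat {
    if (ncol(x) == 1) break
    v <- vif_oracle(x)
    if (all(v < threshold)) break
    x <- x[, -which.max(v), drop = FALSE]
  }
  colnames(x)
}
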