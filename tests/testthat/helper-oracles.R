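# Independent oracles used by module and acceptance tests.

# Median oracle: evaluate the polyline on a fine grid and invert the first
# 0.5 crossing with a local linear solve inside the bracketing grid cell.
grid_median <- function(cum, age_ma, root_age, n_grid = 1e6) {
  t_pts <- c(root_age, age_ma)
  c_pts <- c(0, cum)
  # include the breakpoints so no grid cell spans a polyline kink
  grid <- sort(unique(c(seq(root_age, age_ma[length(age_ma)],
                            length.out = n_grid), t_pts)),
               decreasing = TRUE)
  vals <- stats::approx(t_pts, c_pts, xout = grid)$y
  i <- which(vals >= 0.5)[1]
  if (vals[i] == 0.5) return(grid[i])
  g0 <- grid[i - 1]; g1 <- grid[i]
  v0 <- vals[i - 1]; v1 <- vals[i]
  g0 + (0.5 - v0) / (v1 - v0) * (g1 - g0)
}

# Fisher oracle: full hypergeometric enumeration of the 2x2 family with
# the observed margins; two-sided by the point-probability rule.
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}
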