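# independent oracle: vectorized grid search of the AE likelihood with a
# closed-form GLS intercept at each (a, e) grid point
ae_grid_m2ll <- function(pairs, a_grid, e_grid) {
  y <- c(pairs$y1, pairs$y2)
  mu <- mean(y); sdv <- sd(y)
  y1 <- (pairs$y1 - mu) / sdv; y2 <- (pairs$y2 - mu) / sdv
  mz <- pairs$zygosity == "MZ"
  stats_z <- function(idx) {
    c(n = sum(idx), s1 = sum(y1[idx] + y2[idx]),
      ss = sum(y1[idx]^2 + y2[idx]^2), cp = sum(y1[idx] * y2[idx]))
  }
  S <- list(MZ = stats_z(mz), DZ = stats_z(!mz))
  g <- expand.grid(a = a_grid, e = e_grid)
  V <- g$a^2 + g$e^2
  cv <- list(MZ = g$a^2, DZ = 0.5 * g$a^2)
  # GLS intercept: b0 = sum_z s1_z/(V+c_z) / sum_z 2 n_z/(V+c_z)
  num <- den <- 0
  for (z in c("MZ", "DZ")) {
    num <- num + S[[z]]["s1"] / (V + cv[[z]])
    den <- den + 2 * S[[z]]["n"] / (V + cv[[z]])
  }
  b0 <- num / den
  m2 <- 0
  for (z in c("MZ", "DZ")) {
    n <- S[[z]]["n"]; s1 <- S[[z]]["s1"]; ss <- S[[z]]["ss"]; cp <- S[[z]]["cp"]
    ssb <- ss - 2 * b0 * s1 + 2 * n * b0^2
    cpb <- cp - b0 * s1 + n * b0^2
    det <- V^2 - cv[[z]]^2
    m2 <- m2 + (V * ssb - 2 * cv[[z]] * cpb) / det +
      n * (2 * log(2 * pi) + log(det))
  }
  min(m2[is.finite(m2)])
}
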