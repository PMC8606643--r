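# Independent oracles and small builders shared across tests.

# -2 log likelihood of independent normals, coded independently of the
# package's objective (via dnorm)
wls_m2ll <- function(y, mu, v) {
  -2 * sum(stats::dnorm(y, mu, sqrt(v), log = TRUE))
}

# -2 log density of a multivariate normal, via Cholesky
mvn_m2ll <- function(y, mu, V) {
  U <- chol(V)
  z <- forwardsolve(t(U), y - mu)
  length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2)
}

# small effect series used in several objective tests
tiny_series <- function() {
  effect_series(
    study_id = rep(c("a", "b"), c(3, 2)),
    time_weeks = c(2, 8, 26, 12, 52),
    effect_pct = c(-0.8, -1.2, -1.4, -0.9, -1.6),
    n_eff = c(40, 40, 40, 100, 100))
}

# write a study table data.frame to a temp csv and return the path
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
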