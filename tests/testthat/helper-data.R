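# Shared fixtures, all generated in code.

# Standard regression dataset with a known active set.
make_regression <- function(n = 300, p = 50, k = 5, r_star2 = 0.75,
                            seed = 11, ...) {
  spec <- synthetic_spec(n = n, p = p, k_informative = k, beta = 1,
                         r_star2 = r_star2, seed = seed, ...)
  fm <- gen_features(spec)
  resp <- gen_response(fm, spec)
  list(X = fm$values, y = resp$y, truth = resp$truth,
       r_star2 = resp$r_star2, fm = fm, spec = spec)
}

# Write a tiny activity CSV and return its path.
write_activity_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Brute-force Tanimoto over two 0/1 vectors (independent of the package's
# bit-algebra implementation).
tanimoto_oracle <- function(a, b) {
  c11 <- sum(a == 1 & b == 1)
  n_on <- sum(a == 1) + sum(b == 1) - c11
  if (n_on == 0) 0 else c11 / n_on
}
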