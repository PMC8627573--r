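# Independent oracles, written from the definitions, never from the package
# code paths they check.

# Step-down Holm from its definition: sort ascending, multiply the i-th
# smallest by (m - i + 1), enforce a running maximum, cap at 1, restore order.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dense-inverse GLS: explicit solve() of the correlation matrix.
gls_oracle <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  se <- sqrt(diag(rss / (n - p) * solve(t(X) %*% Vi %*% X)))
  loglik <- -0.5 * (n * log(2 * pi * rss / n) +
                      as.numeric(determinant(V)$modulus) + n)
  list(beta = as.vector(beta), se = se, loglik = loglik)
}

# Brute-force check of the quantitation-ion rule over every target ion.
quant_ion_ok <- function(mz, target, coeluters, rule = "tenfold",
                         thres = 0.9) {
  tg <- target / max(target)
  ti <- tg[[as.character(mz)]]
  all(vapply(coeluters, function(cs) {
    cs <- cs / max(cs)
    ci <- if (as.character(mz) %in% names(cs)) cs[[as.character(mz)]] else 0
    if (rule == "tenfold") ti >= 10 * ci else ti / (ti + ci) >= thres
  }, TRUE))
}

# Small deterministic composition profile used across metric tests.
demo_profile <- function() {
  c("C14:0" = 0.10, "C16:0" = 0.30, "C18:0" = 0.10, "C18:1" = 0.15,
    "C20:5" = 0.12, "C22:6" = 0.13, "C15:0" = 0.04, "C17:1" = 0.02,
    "C22:1(n-9) alcohol" = 0.04)
}
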