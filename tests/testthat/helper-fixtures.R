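# shared fixture builders and independent oracles

make_fixture <- function(n, p, sigma_b2 = 0.02, sigma_e2 = 0.5, seed = 1,
                         mu = 0, ld_model = "independent", rho = 0,
                         maf = c(0.1, 0.5)) {
  X <- simulate_genotypes(n, p, maf, ld_model, rho, seed = seed)
  ds <- simulate_phenotypes(X, sigma_b2, sigma_e2, mu, seed = seed + 1000L)
  grm <- build_grm(X)
  list(X = X, ds = ds, grm = grm, y = ds$phenotypes)
}

# restricted log-likelihood by explicit dense V inversion -- the brute-force
# oracle, written independently of the eigenbasis implementation
dense_restricted_ll <- function(y, G, sigma_g2, sigma_e2) {
  n <- length(y)
  V <- sigma_g2 * G + sigma_e2 * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  s <- drop(crossprod(one, Vi %*% one))
  mu <- drop(crossprod(one, Vi %*% y)) / s
  r <- y - mu
  -0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus[1] + log(s) +
            drop(crossprod(r, Vi %*% r)))
}

# profile the dense restricted likelihood over sigma_e2 at fixed ratio lambda
dense_profile_ll <- function(y, G, lambda) {
  n <- length(y)
  H <- lambda * G + diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  s <- drop(crossprod(one, Hi %*% one))
  mu <- drop(crossprod(one, Hi %*% y)) / s
  r <- y - mu
  s2e <- drop(crossprod(r, Hi %*% r)) / (n - 1)
  dense_restricted_ll(y, G, lambda * s2e, s2e)
}
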