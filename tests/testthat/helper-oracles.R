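# Brute-force zygote-class oracle: enumerate the 3 configurations x 4
# equiprobable gametes, weight by the mixture and viability, renormalize.
# Independent of the vectorized implementation in the package.
brute_force_zygote <- function(mixture, viability = rep(1, 6)) {
  gametes <- list(
    L = c("X", "12", "X2", "1"),   # X pairs Y1; Y2 free
    M = c("X1", "2", "X", "12"),   # X pairs Y2; Y1 free
    N = c("X1", "2", "X2", "1")    # Y1 pairs Y2; X free
  )
  classes <- c("X", "12", "X1", "2", "X2", "1")
  v <- setNames(viability, classes)
  raw <- setNames(numeric(6), classes)
  for (k in 1:3) {
    for (g in gametes[[k]]) raw[g] <- raw[g] + mixture[k] * 0.25
  }
  w <- raw * v
  w / sum(w)
}

random_mixture <- function() {
  p <- rexp(3)
  p / sum(p)
}

# per-vial mixture variation: draw a mixture per vial from a Dirichlet
# around `mixture` with concentration kappa, then multinomial counts
simulate_mixture_varying_vials <- function(mixture, kappa, n_vials, vial_size) {
  counts <- t(vapply(seq_len(n_vials), function(i) {
    g <- rgamma(3, shape = kappa * mixture)
    m <- pairing_mixture(g / sum(g))
    as.integer(rmultinom(1, vial_size, zygote_distribution(m)))
  }, integer(6)))
  colnames(counts) <- gamete_classes
  data.frame(counts, check.names = FALSE)
}
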