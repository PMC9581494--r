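# Independent brute-force oracles shared by unit and acceptance tests.

# BH step-up by definition: largest k with p_(k) <= k * alpha / m,
# rejecting all smaller order statistics.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * alpha / m)
  disc <- logical(m)
  if (length(ks)) disc[o[seq_len(max(ks))]] <- TRUE
  disc
}

# Exact hypergeometric upper tail by enumerating every attainable
# overlap value from binomial coefficients.
hyper_oracle <- function(k, N, K, n) {
  vals <- max(0, n - (N - K)):min(K, n)
  pm <- choose(K, vals) * choose(N - K, n - vals) / choose(N, n)
  sum(pm[vals >= k])
}

# Exact HWE by combinatorial enumeration: count allele-to-individual
# arrangements for each heterozygote configuration compatible with the
# observed allele counts; p = mass of configurations no more likely
# than the observed one.
hwe_oracle <- function(a, b, c) {
  n <- a + b + c
  n_minor <- min(2 * a + b, 2 * c + b)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  w <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    choose(n, hom_maj) * choose(n - hom_maj, h) * 2^h
  }, numeric(1))
  stopifnot(isTRUE(all.equal(sum(w), choose(2 * n, n_minor))))
  obs <- w[hets == b]
  sum(w[w <= obs * (1 + 1e-12)]) / sum(w)
}
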