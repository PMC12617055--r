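# Independent oracles, written from first principles (log-binomial
# coefficients only), deliberately separate from the package's code paths.

lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

# P(X = k) for X ~ Hypergeometric(white = K, black = n - K, drawn = t)
oracle_hyper_pmf <- function(k, K, n, t) {
  lo <- max(0, t - (n - K)); hi <- min(K, t)
  if (k < lo || k > hi) return(0)
  exp(lchoose2(K, k) + lchoose2(n - K, t - k) - lchoose2(n, t))
}

# one-sided tails by explicit summation over the support
oracle_hyper_upper <- function(k, K, n, t) {
  hi <- min(K, t)
  if (k > hi) return(0)
  sum(vapply(k:hi, oracle_hyper_pmf, 1.0, K = K, n = n, t = t))
}
oracle_hyper_lower <- function(k, K, n, t) {
  lo <- max(0, t - (n - K))
  if (k < lo) return(0)
  sum(vapply(lo:k, oracle_hyper_pmf, 1.0, K = K, n = n, t = t))
}

# Two-sided Fisher exact p for table rbind(c(a, b), c(c, d)): the sum of
# probabilities of all tables with the same margins whose probability does
# not exceed the observed one (with the standard relative tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + b; t <- a + c; n <- a + b + c + d
  lo <- max(0, t - (n - K)); hi <- min(K, t)
  probs <- vapply(lo:hi, oracle_hyper_pmf, 1.0, K = K, n = n, t = t)
  obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# the delta-x chain in one line, independent of the package implementation
oracle_delta_x <- function(focal, related, m = length(focal), N = 3) {
  ((mean(focal) - mean(related)) / mean(focal)) /
    (sqrt((m * N - 1) / (m * N - m)) *
       ((max(focal) - min(focal)) / mean(focal)))
}

# small default simulation shared by several tests
tiny_sim <- function(seed = 7, n_genes = 300, tissues = c("gonad", "brain"),
                     ...) {
  simulate_dataset(sim_config(n_genes = n_genes, tissues = tissues,
                              seed = seed, ...))
}
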