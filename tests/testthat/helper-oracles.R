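# Independent literal-formula oracles, kept deliberately naive: they follow
# the published formulas term by term and never share code with the package.

oracle_h_mle <- function(x) {
  n <- sum(x)
  p <- x / n
  -sum(p * log(p))
}

# literal n-fold leave-one-out jackknife: delete each gene copy in turn
oracle_h_zahl <- function(x) {
  n <- sum(x)
  copies <- rep(seq_along(x), x)
  loo <- vapply(seq_len(n), function(i) {
    tb <- as.numeric(table(copies[-i]))
    oracle_h_mle(tb)
  }, 0.0)
  n * oracle_h_mle(x) - (n - 1) * mean(loo)
}

oracle_h_cs <- function(x) {
  n <- sum(x)
  f1 <- sum(x == 1)
  C <- 1 - f1 / n
  if (C == 0) return(NA_real_)
  pt <- C * x / n
  sum(-pt * log(pt) / (1 - (1 - pt)^n))
}

oracle_h_chao <- function(x) {
  n <- sum(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  t1 <- sum(vapply(x, function(xi)
    if (xi <= n - 1) (xi / n) * sum(1 / (xi:(n - 1))) else 0, 0.0))
  if (f1 == 0) return(t1)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else 2 / ((n - 1) * (f1 - 1) + 2)
  if (A == 1) return(t1)
  r <- seq_len(n - 1)
  t1 + (f1 / n) * (1 - A)^(1 - n) * (-log(A) - sum((1 - A)^r / r))
}

oracle_gene_div <- function(x) {
  1 - sum((x / sum(x))^2)
}

# all integer partitions of n (every possible allele-count multiset with n
# gene copies)
partitions <- function(n, max = n) {
  if (n == 0) return(list(numeric(0)))
  out <- list()
  for (k in seq_len(min(n, max)))
    for (p in partitions(n - k, k))
      out[[length(out) + 1L]] <- c(k, p)
  out
}

# small deterministic diploid sample: locus A counts (1,2,1), locus B
# monomorphic, locus C all singletons (the H_CS failure case)
toy_pop <- function() {
  pop_sample("toy",
             a1 = cbind(A = c(0L, 1L), B = c(7L, 7L), C = c(0L, 2L)),
             a2 = cbind(A = c(1L, 2L), B = c(7L, 7L), C = c(1L, 3L)))
}

tiny_config <- function(...) {
  defaults <- list(
    preset = "scaled",
    loci = rbind(locus_spec("hi1", 0.02, 12), locus_spec("hi2", 0.05, 20)),
    scenarios = default_scenarios(n = 60, bottleneck = 5, recovery = 5),
    pop_size = 60, sample_sizes = c(5L, 10L), n_resamples = 3L,
    sd_comparison_pairs = 1000L, master_seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
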