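#' @name shannon-estimators
#' @title Shannon diversity estimators and Nei's gene diversity
#'
#' @description
#' All estimators consume an allele-count vector (see [allele_counts()]) and
#' return a value in nats (natural logarithm). Writing `x_i` for the count of
#' allele `i`, `n = sum(x_i)`, `p_i = x_i / n`, `f1` / `f2` for the numbers
#' of singleton / doubleton alleles:
#'
#' * `h_mle()` — the plug-in (maximum-likelihood) estimate
#'   `-sum(p_i * log(p_i))`. Negatively biased at small `n`.
#' * `h_zahl()` — the Zahl (1977) jackknife,
#'   `n * H_hat - (n - 1) * mean(leave-one-out H_hat)`, where the mean runs
#'   over the `n` single-copy deletions (grouped by allele for speed, but
#'   exactly equal to the literal leave-one-out average).
#' * `h_chao_shen()` — the Chao & Shen (2003) coverage-adjusted
#'   Horvitz-Thompson estimator with Good-Turing coverage
#'   `C = 1 - f1 / n` and `p~_i = C * p_i`:
#'   `sum(-p~_i log(p~_i) / (1 - (1 - p~_i)^n))`. When every allele is a
#'   singleton (`f1 == n`, coverage 0) the estimator is undefined; this is a
#'   first-class failure mode reported as `NA` so that batch estimation can
#'   record it and continue.
#' * `h_chao2013()` — the Chao et al. (2013) estimator combining harmonic
#'   sums `sum_i (x_i/n) * sum(1/k, k = x_i .. n-1)` with a singleton tail
#'   correction parameterised by
#'   `A = 2 f2 / ((n-1) f1 + 2 f2)` (or `2 / ((n-1)(f1-1) + 2)` if `f2 = 0`;
#'   no correction if `f1 = 0`).
#' * `gene_diversity()` — Nei's gene diversity (expected heterozygosity)
#'   `1 - sum(p_i^2)`.
#'
#' Every estimator is invariant to the order (and labels) of the counts and
#' returns exactly 0 for a monomorphic sample.
#'
#' @param x An `allele_counts` object or a numeric vector of allele counts
#'   (zeros dropped).
#' @return A single numeric value; `h_chao_shen()` returns `NA` on its
#'   defined failure mode (`f1 == n`).
#' @references Zahl S (1977) Ecology 58:907-913. Chao A, Shen TJ (2003)
#'   Environ Ecol Stat 10:429-443. Chao A, Wang YT, Jost L (2013) Methods
#'   Ecol Evol 4:1091-1100. Nei M (1973) PNAS 70:3321-3323.
#' @examples
#' h_mle(c(1, 1, 2))
#' h_zahl(c(1, 1, 2))
#' h_chao_shen(c(1, 1, 1)) # all singletons: NA (coverage 0)
NULL

#' @rdname shannon-estimators
#' @export
h_mle <- function(x) {
  c <- allele_counts(x)
  .h_mle(c$counts, c$n)
}

#' @rdname shannon-estimators
#' @export
h_zahl <- function(x) {
  c <- allele_counts(x)
  if (c$n < 2) stop("h_zahl requires at least 2 gene copies", call. = FALSE)
  .h_zahl(c$counts, c$n)
}

#' @rdname shannon-estimators
#' @export
h_chao_shen <- function(x) {
  c <- allele_counts(x)
  .h_cs(c$counts, c$n)
}

#' @rdname shannon-estimators
#' @export
h_chao2013 <- function(x) {
  c <- allele_counts(x)
  if (c$n < 2) stop("h_chao2013 requires at least 2 gene copies", call. = FALSE)
  .h_chao(c$counts, c$n)
}

#' @rdname shannon-estimators
#' @export
gene_diversity <- function(x) {
  c <- allele_counts(x)
  .gene_div(c$counts, c$n)
}

# ---- internal fast paths (positive counts, n = sum(x)) ---------------------

.h_mle <- function(x, n = sum(x)) {
  p <- x / n
  -sum(p * log(p))
}

# Grouped leave-one-out: removing one copy of allele i changes only the i-th
# term of the entropy sum, so H(-i) = S - g(x_i) + g(x_i - 1) with
# g(v) = -(v/(n-1)) log(v/(n-1)) and g(0) = 0.
.h_zahl <- function(x, n = sum(x)) {
  n1 <- n - 1
  g <- function(v) {
    r <- numeric(length(v))
    pos <- v > 0
    q <- v[pos] / n1
    r[pos] <- -q * log(q)
    r
  }
  loo <- sum(g(x)) - g(x) + g(x - 1)
  n * .h_mle(x, n) - (n1 / n) * sum(x * loo)
}

.h_cs <- function(x, n = sum(x)) {
  f1 <- sum(x == 1)
  if (f1 == n) return(NA_real_) # coverage 0: defined failure mode
  C <- 1 - f1 / n
  pt <- C * x / n
  h <- -pt * log(pt)
  h[pt == 1] <- 0 # 0*log(0) convention is moot here, but 1*log(1) term is 0
  sum(h / (1 - (1 - pt)^n))
}

.h_chao <- function(x, n = sum(x)) {
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  # first term via cumulative harmonic numbers: Hh[m + 1] = sum(1/1..1/m)
  Hh <- c(0, cumsum(1 / seq_len(n - 1)))
  t1 <- sum(x / n * (Hh[n] - Hh[x]))
  if (f1 == 0) return(t1) # A = 1: the tail correction vanishes
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2) else 2 / ((n - 1) * (f1 - 1) + 2)
  lq <- log1p(-A) # log(1 - A) < 0
  if ((n - 1) * (-lq) < 30) {
    # (1-A)^(n-1) is not small: the printed form is overflow- and
    # cancellation-safe here
    r <- seq_len(n - 1)
    tail <- (1 - A)^(1 - n) * (-log(A) - sum(exp(r * lq) / r))
  } else {
    # (1-A)^(n-1) tiny: -log(A) - sum_{r<n} (1-A)^r/r cancels
    # catastrophically, so evaluate the equivalent convergent series
    # sum_{s>=1} (1-A)^s / (s + n - 1) directly
    smax <- ceiling(41 / (-lq))
    s <- seq_len(smax)
    tail <- sum(exp(s * lq) / (s + n - 1))
  }
  t1 + max(f1 / n * tail, 0)
}

.gene_div <- function(x, n = sum(x)) {
  1 - sum((x / n)^2)
}

#' Metric labels known to the package
#'
#' @return `c("H_MLE", "H_Z", "H_CS", "H_Chao", "Hs")`: the four Shannon
#'   estimators and Nei's gene diversity.
#' @export
shannon_metrics <- function() c("H_MLE", "H_Z", "H_CS", "H_Chao", "Hs")

.metrics_on_counts <- function(cnt, metrics, n = sum(cnt)) {
  vapply(metrics, function(m) switch(m,
    H_MLE  = .h_mle(cnt, n),
    H_Z    = .h_zahl(cnt, n),
    H_CS   = .h_cs(cnt, n),
    H_Chao = .h_chao(cnt, n),
    Hs     = .gene_div(cnt, n)
  ), 0.0)
}

#' Evaluate several diversity metrics on one allele-count vector
#'
#' A Chao-Shen failure (all alleles singletons) is recorded as a missing
#' value without aborting the remaining metrics.
#'
#' @param x An `allele_counts` object or numeric count vector.
#' @param metrics Subset of [shannon_metrics()].
#' @return A data frame with columns `metric`, `locus`, `value` (one row per
#'   requested metric; `value` is `NA` only for a failed `H_CS`).
#' @export
#' @examples
#' estimate_all(c(1, 1, 2))
estimate_all <- function(x, metrics = shannon_metrics()) {
  c <- allele_counts(x)
  if (length(metrics) == 0L) stop("`metrics` must be nonempty", call. = FALSE)
  bad <- setdiff(metrics, shannon_metrics())
  if (length(bad))
    stop(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  data.frame(metric = metrics, locus = c$locus,
             value = unname(.metrics_on_counts(c$counts, metrics, c$n)),
             stringsAsFactors = FALSE)
}
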