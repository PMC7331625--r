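#' Piecewise-constant demographic history
#'
#' Epochs are ordered backward in time from the sampling point; the final
#' epoch must have infinite duration.
#'
#' @param duration Epoch durations in generations (last must be `Inf`, all
#'   others finite and > 0).
#' @param N Diploid population size in each epoch (>= 1).
#' @return An object of class `demography`.
#' @export
#' @examples
#' # 20 generations at 10,000, a 20-generation bottleneck of 20, then 10,000
#' demography(c(20, 20, Inf), c(10000, 20, 10000))
demography <- function(duration, N) {
  stopifnot(is.numeric(duration), is.numeric(N),
            length(duration) == length(N), length(N) >= 1L)
  k <- length(duration)
  if (!is.infinite(duration[k]))
    stop("the final epoch must have infinite duration", call. = FALSE)
  if (k > 1L && any(!is.finite(duration[-k]) | duration[-k] <= 0))
    stop("all non-final epoch durations must be finite and > 0", call. = FALSE)
  if (any(!is.finite(N) | N < 1))
    stop("all population sizes must be >= 1", call. = FALSE)
  structure(list(duration = as.numeric(duration), N = as.numeric(N)),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("demography (backward from sampling):\n")
  for (i in seq_along(x$N))
    cat(sprintf("  %s generations at N = %g\n",
                format(x$duration[i]), x$N[i]))
  invisible(x)
}

#' The four demographic scenarios of the bottleneck study
#'
#' A constant-size control `P_C` and three scenarios `P_500`, `P_50`, `P_20`
#' that, looking backward from sampling, spend `recovery` generations at the
#' full size, `bottleneck` generations at 500 / 50 / 20 diploids, and are at
#' the full size before that.
#'
#' @param n Diploid size outside the bottleneck (default 10,000).
#' @param bottleneck,recovery Durations in generations (default 20 each).
#' @return Named list of [demography()] objects
#'   (`P_C`, `P_500`, `P_50`, `P_20`).
#' @export
default_scenarios <- function(n = 10000, bottleneck = 20, recovery = 20) {
  btl <- function(nb) demography(c(recovery, bottleneck, Inf), c(n, nb, n))
  list(P_C = demography(Inf, n),
       P_500 = btl(500), P_50 = btl(50), P_20 = btl(20))
}

#' The 24-locus simulation design
#'
#' Loci `L01`..`L24` cross four mutation rates (rows: 0.0001, 0.0002, 0.0005,
#' 0.001 per gene copy per generation) with six allele-count caps (columns:
#' 3, 6, 9, 12, 15, 20 states).
#'
#' @return A 24-row data frame with columns `name`, `mu`, `k_max`.
#' @export
default_loci <- function() {
  mu <- c(0.0001, 0.0002, 0.0005, 0.001)
  k <- c(3L, 6L, 9L, 12L, 15L, 20L)
  data.frame(name = sprintf("L%02d", 1:24),
             mu = rep(mu, each = length(k)),
             k_max = rep(k, times = length(mu)),
             stringsAsFactors = FALSE)
}

#' Simulate one locus under the bounded stepwise-mutation coalescent
#'
#' Runs a Kingman coalescent on `n_copies` gene copies through the epochs of
#' `dem` (pairwise coalescence rate `1/(2N)` per generation, exponential
#' waiting times bounded at epoch boundaries), drops mutations on branches as
#' a Poisson process at rate `mu` per generation, and walks allele states
#' `+/-1` per mutation from the root state `floor(k_max / 2)`. A step that
#' would leave `[0, k_max - 1]` is discarded (state unchanged) by default,
#' or bounced back with `boundary = "reflect"`.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param dem A [demography()].
#' @param locus A one-row data frame (or list) with `mu` and `k_max`, e.g.
#'   from [locus_spec()] or a row of [default_loci()].
#' @param n_copies Number of gene copies to sample (>= 2).
#' @param boundary Allele-range constraint handling: `"discard"` or
#'   `"reflect"`.
#' @return Integer vector of `n_copies` tip allele states in
#'   `[0, k_max - 1]`, with the tree height in generations attached as
#'   attribute `"tmrca"`.
#' @export
simulate_locus <- function(dem, locus, n_copies,
                           boundary = c("discard", "reflect")) {
  stopifnot(inherits(dem, "demography"))
  boundary <- match.arg(boundary)
  mu <- locus$mu
  k_max <- locus$k_max
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(k_max), length(k_max) == 1L, k_max >= 2)
  if (!is.numeric(n_copies) || length(n_copies) != 1L || n_copies < 2)
    stop("`n_copies` must be a single integer >= 2", call. = FALSE)
  res <- sim_bounded_smm_cpp(as.integer(n_copies), dem$duration, dem$N,
                             mu, as.integer(k_max),
                             as.integer(floor(k_max / 2)),
                             boundary == "reflect")
  structure(res$states, tmrca = res$tmrca)
}

#' Simulate a whole diploid population sample
#'
#' Simulates each locus independently (unlinked) with
#' `n_copies = 2 * n_individuals` and forms diploid genotypes by pairing
#' consecutive gene copies (coalescent tip labels are exchangeable, so this
#' is a random union of gametes).
#'
#' @param dem A [demography()].
#' @param loci Data frame of loci (columns `name`, `mu`, `k_max`).
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param population Population label.
#' @param boundary See [simulate_locus()].
#' @param seeds Optional integer vector (one per locus): when given,
#'   `set.seed(seeds[l])` is called before simulating locus `l`, giving each
#'   locus its own reproducible stream.
#' @return A [pop_sample()].
#' @export
simulate_population <- function(dem, loci, n_individuals,
                                population = "pop",
                                boundary = c("discard", "reflect"),
                                seeds = NULL) {
  stopifnot(is.data.frame(loci), nrow(loci) >= 1L,
            n_individuals >= 1L)
  boundary <- match.arg(boundary)
  if (!is.null(seeds)) stopifnot(length(seeds) == nrow(loci))
  L <- nrow(loci)
  n2 <- 2L * as.integer(n_individuals)
  a1 <- matrix(NA_integer_, n_individuals, L)
  a2 <- matrix(NA_integer_, n_individuals, L)
  odd <- seq(1L, n2, by = 2L)
  for (l in seq_len(L)) {
    if (!is.null(seeds)) set.seed(seeds[l])
    st <- simulate_locus(dem, loci[l, ], n2, boundary)
    a1[, l] <- st[odd]
    a2[, l] <- st[odd + 1L]
  }
  pop_sample(population, a1, a2, loci$name)
}

# Deterministic child seed from a master seed and arbitrary keys: a simple
# polynomial string hash mod a prime < 2^31, so replicate/scenario/locus
# streams are reproducible independently of execution order.
child_seed <- function(master, ...) {
  keys <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (b in utf8ToInt(keys)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}
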