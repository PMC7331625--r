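#' Locus specification
#'
#' A microsatellite locus is described by its per-gene-copy mutation rate and
#' the maximum number of allelic states the bounded stepwise mutation model
#' allows (the "allele cap").
#'
#' @param name Character label, e.g. `"L01"`.
#' @param mu Mutation rate per gene copy per generation (> 0).
#' @param k_max Maximum number of allelic states (integer >= 2).
#' @return A one-row data frame with columns `name`, `mu`, `k_max`.
#' @seealso [default_loci()] for the 24-locus design used by the simulation
#'   experiment.
#' @export
#' @examples
#' locus_spec("L01", mu = 1e-4, k_max = 3)
locus_spec <- function(name, mu, k_max) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("`mu` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max != floor(k_max) || k_max < 2)
    stop("`k_max` must be a single integer >= 2", call. = FALSE)
  data.frame(name = name, mu = mu, k_max = as.integer(k_max),
             stringsAsFactors = FALSE)
}

#' Observed allele counts at one locus
#'
#' The universal estimator input: the vector of positive counts of each
#' observed allele in a sample, together with the derived quantities used by
#' the estimators (total gene copies `n`, number of singletons `f1`, number
#' of doubletons `f2`, number of observed alleles `k_obs`). Allele identity
#' labels are discarded; only counts matter.
#'
#' @param x A `pop_sample` (counts are tallied at `locus`), or a numeric
#'   vector of non-negative allele counts (zeros are dropped).
#' @param locus Locus label (required for a `pop_sample`; optional otherwise).
#' @param ... Unused.
#' @return An object of class `allele_counts`: a list with elements `locus`,
#'   `counts`, `n`, `k_obs`, `f1`, `f2`.
#' @export
#' @examples
#' allele_counts(c(1, 1, 2))
allele_counts <- function(x, locus = "", ...) UseMethod("allele_counts")

#' @export
allele_counts.default <- function(x, locus = "", ...) {
  if (!is.numeric(x))
    stop("`x` must be a pop_sample or a numeric vector of allele counts",
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop("allele counts must be non-negative integers", call. = FALSE)
  x <- as.numeric(x[x > 0])
  if (length(x) == 0L)
    stop("no positive allele counts", call. = FALSE)
  new_allele_counts(x, locus)
}

#' @export
allele_counts.allele_counts <- function(x, locus = "", ...) x

#' @export
allele_counts.pop_sample <- function(x, locus = "", ...) {
  l <- match(locus, x$loci)
  if (is.na(l))
    stop(sprintf("unknown locus '%s' in population '%s'", locus, x$population),
         call. = FALSE)
  if (nrow(x$a1) == 0L)
    stop("population sample contains zero individuals", call. = FALSE)
  cnt <- .locus_counts(x$a1[, l], x$a2[, l])
  if (length(cnt) == 0L)
    stop(sprintf("locus '%s' has no non-missing gene copies", locus),
         call. = FALSE)
  new_allele_counts(cnt, locus)
}

new_allele_counts <- function(counts, locus = "") {
  structure(list(locus = locus, counts = counts, n = sum(counts),
                 k_obs = length(counts), f1 = sum(counts == 1),
                 f2 = sum(counts == 2)),
            class = "allele_counts")
}

# Tally both gene copies of every individual; missing copies (NA) are
# excluded, so n = 2 * individuals only when no copy is missing.
.locus_counts <- function(a1, a2) {
  s <- c(a1, a2)
  s <- s[!is.na(s)]
  if (length(s) == 0L) return(numeric(0))
  cnt <- tabulate(s + 1L)
  as.numeric(cnt[cnt > 0L])
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele counts%s: n = %d gene copies, k = %d alleles (f1 = %d, f2 = %d)\n",
              if (nzchar(x$locus)) paste0(" [", x$locus, "]") else "",
              as.integer(x$n), x$k_obs, as.integer(x$f1), as.integer(x$f2)))
  cat(" counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Diploid multilocus population sample
#'
#' Genotypes of one population at a set of loci. Genotypes are unordered
#' pairs of integer allele states (no phase); states are arbitrary
#' non-negative integer labels, `NA` marks a missing gene copy. The simulator
#' produces states in `[0, k_max - 1]`; GENEPOP input stores allele code `c`
#' as state `c - 1`.
#'
#' @param population Population label.
#' @param a1,a2 Integer matrices (individuals x loci) holding the two gene
#'   copies of each genotype.
#' @param loci Character vector of locus names (defaults to `colnames(a1)`).
#' @return An object of class `pop_sample`.
#' @export
pop_sample <- function(population, a1, a2, loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(is.character(population), length(population) == 1L,
            identical(dim(a1), dim(a2)))
  if (is.null(loci) || length(loci) != ncol(a1) || anyDuplicated(loci))
    stop("`loci` must name each column uniquely", call. = FALSE)
  if (any(a1 < 0, na.rm = TRUE) || any(a2 < 0, na.rm = TRUE))
    stop("allele states must be non-negative integers", call. = FALSE)
  colnames(a1) <- colnames(a2) <- loci
  structure(list(population = population, a1 = a1, a2 = a2,
                 loci = as.character(loci)),
            class = "pop_sample")
}

#' @export
print.pop_sample <- function(x, ...) {
  cat(sprintf("pop_sample '%s': %d individuals x %d loci\n",
              x$population, nrow(x$a1), length(x$loci)))
  invisible(x)
}

#' Number of individuals in a population sample
#' @param x A `pop_sample`.
#' @return Integer count of individuals (rows).
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "pop_sample"))
  nrow(x$a1)
}

#' Draw a subsample of whole individuals without replacement
#'
#' Selects `ns` individuals uniformly without replacement, keeping both gene
#' copies of each genotype together. Uses the current RNG state, so results
#' are reproducible under [set.seed()].
#'
#' @param x A `pop_sample`.
#' @param ns Number of individuals to draw (1 <= ns <= individuals).
#' @return A `pop_sample` with `ns` rows; the input is unmodified.
#' @export
subsample <- function(x, ns) {
  stopifnot(inherits(x, "pop_sample"))
  n <- nrow(x$a1)
  if (!is.numeric(ns) || length(ns) != 1L || ns != floor(ns) || ns < 1)
    stop("`ns` must be a single positive integer", call. = FALSE)
  if (ns > n)
    stop(sprintf("cannot draw %d individuals from a sample of %d", ns, n),
         call. = FALSE)
  idx <- sample.int(n, ns)
  pop_sample(x$population, x$a1[idx, , drop = FALSE],
             x$a2[idx, , drop = FALSE], x$loci)
}

#' Bundle population samples sharing one locus set
#'
#' @param samples List of `pop_sample` objects with identical loci and unique
#'   population labels.
#' @return An object of class `multilocus_dataset`: list with elements
#'   `samples` (named by population) and `loci`.
#' @export
multilocus_dataset <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (!all(vapply(samples, inherits, TRUE, "pop_sample")))
    stop("all elements must be pop_sample objects", call. = FALSE)
  loci <- samples[[1L]]$loci
  if (!all(vapply(samples, function(s) identical(s$loci, loci), TRUE)))
    stop("all populations must share the same loci", call. = FALSE)
  labels <- vapply(samples, `[[`, "", "population")
  if (anyDuplicated(labels))
    stop("population labels must be unique", call. = FALSE)
  names(samples) <- labels
  structure(list(samples = samples, loci = loci),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat(sprintf("multilocus_dataset: %d population(s), %d loci\n",
              length(x$samples), length(x$loci)))
  for (s in x$samples)
    cat(sprintf("  %s: %d individuals\n", s$population, nrow(s$a1)))
  invisible(x)
}

#' Write records to a CSV file
#'
#' Plain UTF-8 comma-separated output with a header row. Column order is the
#' column order of `records`; doubles are rendered with 17 significant digits
#' (binary round-trip safe, so summaries recomputed from stored records are
#' bit-identical); missing values become empty fields.
#'
#' @param records A data frame (possibly with zero rows, which yields a
#'   header-only file).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v) # binary round-trip safe
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    suppressWarnings(write.csv(out, path, row.names = FALSE, na = "",
                               quote = FALSE, fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write records to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}
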