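#' Relative bias of an estimate
#'
#' `rB = (estimate - reference) / reference`, the signed deviation of a
#' sample estimate from the parametric (whole-population) value.
#'
#' @param estimate,reference Numeric (vectorised); `reference` must be > 0.
#' @return `(estimate - reference) / reference`.
#' @export
#' @examples
#' relative_bias(0.9, 1.0)
relative_bias <- function(estimate, reference) {
  if (any(!is.na(reference) & reference <= 0))
    stop("`reference` must be > 0", call. = FALSE)
  (estimate - reference) / reference
}

#' Mean relative squared error over resamples
#'
#' `MRSE = mean((H_i - H)^2 / H)` over the non-missing estimates `H_i`
#' (squared deviations divided by `H`, not `H^2`).
#'
#' @param estimates Numeric vector of resample estimates; `NA`s (e.g. failed
#'   `H_CS` attempts) are excluded.
#' @param reference Parametric value `H` (> 0).
#' @return List with `mrse` and `m`, the number of contributing estimates.
#' @export
#' @examples
#' mrse(c(1.1, 0.9), 1.0)
mrse <- function(estimates, reference) {
  if (length(reference) != 1L || is.na(reference) || reference <= 0)
    stop("`reference` must be a single value > 0", call. = FALSE)
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L)
    stop("all estimates are missing", call. = FALSE)
  list(mrse = mean((est - reference)^2) / reference, m = length(est))
}

#' Whole-population parametric reference values
#'
#' Evaluates each metric per locus on all individuals of a population, plus
#' the arithmetic mean over loci (a missing per-locus value, i.e. a failed
#' `H_CS`, propagates to a missing mean).
#'
#' @param pop A [pop_sample()].
#' @param metrics Metrics to evaluate.
#' @param replicate Replicate id recorded in the output.
#' @return Data frame with columns `population`, `replicate`, `locus`
#'   (locus names plus `"mean"`), `metric`, `value`, `sample_size`
#'   (`"parametric"`).
#' @export
parametric_reference <- function(pop, metrics = shannon_metrics(),
                                 replicate = 1L) {
  stopifnot(inherits(pop, "pop_sample"))
  if (nrow(pop$a1) == 0L) stop("empty population sample", call. = FALSE)
  L <- length(pop$loci)
  refmat <- matrix(NA_real_, L, length(metrics),
                   dimnames = list(pop$loci, metrics))
  for (l in seq_len(L)) {
    cnt <- .locus_counts(pop$a1[, l], pop$a2[, l])
    refmat[l, ] <- .metrics_on_counts(cnt, metrics)
  }
  ref_mean <- colMeans(refmat) # NA propagates by design
  data.frame(population = pop$population, replicate = replicate,
             locus = rep(c(pop$loci, "mean"), times = length(metrics)),
             metric = rep(metrics, each = L + 1L),
             value = as.vector(rbind(refmat, ref_mean)),
             sample_size = "parametric",
             stringsAsFactors = FALSE)
}

#' Run one replicate of the full resampling experiment
#'
#' For each demographic scenario: simulate the whole population (one
#' independent locus stream per (replicate, scenario, locus), derived from
#' the master seed), compute the parametric references, and for each sample
#' size draw `n_resamples` independent without-replacement subsamples of
#' whole genotypes. Per subsample, every metric is evaluated per locus and as
#' the mean over loci (a failed `H_CS` at any locus makes the mean missing).
#'
#' The relative bias `rB` is computed once per (metric, population, sample
#' size) from the first resample; MRSE is averaged over all resamples (per
#' locus and for the mean over loci); SD is the standard deviation of the
#' mean-over-loci estimates across resamples.
#'
#' @param replicate_id Integer replicate id (keys the RNG streams).
#' @param config A [sim_config()].
#' @param keep_estimates Also return every per-resample estimate (memory
#'   heavy; meant for small runs).
#' @return List of data frames: `references`, `bias`, `mrse`, `sd`,
#'   `failures` (per-locus counts of failed `H_CS` attempts), and
#'   `estimates` when requested.
#' @export
run_replicate <- function(replicate_id, config, keep_estimates = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  loci <- config$loci
  L <- nrow(loci)
  lnames <- loci$name
  metrics <- config$metrics
  M <- length(metrics)
  npop <- config$pop_size
  nres <- config$n_resamples
  ics <- match("H_CS", metrics)

  refs_l <- list(); bias_l <- list(); mrse_l <- list()
  sd_l <- list(); fail_l <- list(); est_l <- list()

  for (sc in names(config$scenarios)) {
    dem <- config$scenarios[[sc]]
    seeds <- vapply(lnames, function(ln)
      child_seed(config$master_seed, "sim", replicate_id, sc, ln), 0L)
    pop <- simulate_population(dem, loci, npop, population = sc,
                               boundary = config$boundary, seeds = seeds)
    a1 <- pop$a1; a2 <- pop$a2

    refmat <- matrix(NA_real_, L, M, dimnames = list(lnames, metrics))
    he_loc <- numeric(L)
    for (l in seq_len(L)) {
      cnt <- .locus_counts(a1[, l], a2[, l])
      refmat[l, ] <- .metrics_on_counts(cnt, metrics)
      he_loc[l] <- .gene_div(cnt)
    }
    ref_mean <- colMeans(refmat)
    he_mean <- mean(he_loc)
    refs_l[[sc]] <- data.frame(
      population = sc, replicate = replicate_id,
      locus = rep(c(lnames, "mean"), times = M),
      metric = rep(metrics, each = L + 1L),
      value = as.vector(rbind(refmat, ref_mean)),
      sample_size = "parametric", stringsAsFactors = FALSE)

    denom <- refmat
    denom[!is.na(denom) & denom <= 0] <- NA # rB/MRSE undefined at H <= 0
    ref_mean_d <- ifelse(!is.na(ref_mean) & ref_mean > 0, ref_mean, NA_real_)

    for (ns in config$sample_sizes) {
      set.seed(child_seed(config$master_seed, "samp", replicate_id, sc, ns))
      meanvals <- matrix(NA_real_, nres, M, dimnames = list(NULL, metrics))
      sumsq <- matrix(0, L, M)
      mcnt <- matrix(0L, L, M)
      failcnt <- integer(L)
      locv <- matrix(NA_real_, L, M)
      if (keep_estimates)
        est_arr <- array(NA_real_, c(nres, L + 1L, M))
      for (r in seq_len(nres)) {
        idx <- sample.int(npop, ns)
        for (l in seq_len(L)) {
          cnt <- .locus_counts(a1[idx, l], a2[idx, l])
          locv[l, ] <- .metrics_on_counts(cnt, metrics)
        }
        meanvals[r, ] <- colMeans(locv)
        d2 <- (locv - refmat)^2 / denom
        ok <- !is.na(d2)
        sumsq[ok] <- sumsq[ok] + d2[ok]
        mcnt <- mcnt + ok
        if (!is.na(ics)) failcnt <- failcnt + is.na(locv[, ics])
        if (keep_estimates) est_arr[r, , ] <- rbind(locv, meanvals[r, ])
      }

      rb <- (meanvals[1L, ] - ref_mean_d) / ref_mean_d
      bias_l[[paste(sc, ns)]] <- data.frame(
        metric = metrics, population = sc, sample_size = ns,
        replicate = replicate_id, rB = unname(rb), stringsAsFactors = FALSE)

      mm <- colSums(!is.na(meanvals))
      dev2 <- sweep(meanvals, 2L, ref_mean_d)^2
      mrse_mean <- suppressWarnings(colMeans(dev2, na.rm = TRUE)) / ref_mean_d
      mrse_mean[mm == 0L] <- NA_real_
      mrse_loc <- sumsq / mcnt # 0/0 -> NaN where nothing contributed
      mrse_loc[mcnt == 0L] <- NA_real_
      mrse_l[[paste(sc, ns)]] <- data.frame(
        metric = rep(metrics, each = L + 1L),
        population = sc, sample_size = ns, replicate = replicate_id,
        locus = rep(c(lnames, "mean"), times = M),
        He_locus = rep(c(he_loc, he_mean), times = M),
        mrse = as.vector(rbind(mrse_loc, mrse_mean)),
        m = as.vector(rbind(mcnt, mm)), stringsAsFactors = FALSE)

      sdv <- apply(meanvals, 2L, stats::sd, na.rm = TRUE)
      sdv[mm < 2L] <- NA_real_
      sd_l[[paste(sc, ns)]] <- data.frame(
        metric = metrics, population = sc, sample_size = ns,
        replicate = replicate_id, sd = unname(sdv), m = unname(mm),
        stringsAsFactors = FALSE)

      if (any(failcnt > 0L)) {
        w <- which(failcnt > 0L)
        fail_l[[paste(sc, ns)]] <- data.frame(
          population = sc, sample_size = ns, replicate = replicate_id,
          locus = lnames[w], n_failed = failcnt[w], stringsAsFactors = FALSE)
      }

      if (keep_estimates)
        est_l[[paste(sc, ns)]] <- data.frame(
          metric = rep(metrics, each = nres * (L + 1L)),
          population = sc, sample_size = ns, replicate = replicate_id,
          resample = rep(seq_len(nres), times = M * (L + 1L)),
          locus = rep(rep(c(lnames, "mean"), each = nres), times = M),
          value = as.vector(est_arr), stringsAsFactors = FALSE)
    }
  }

  out <- list(references = do.call(rbind, unname(refs_l)),
              bias = .rbind_or_empty(bias_l, .bias_proto()),
              mrse = .rbind_or_empty(mrse_l, .mrse_proto()),
              sd = .rbind_or_empty(sd_l, .sd_proto()),
              failures = .rbind_or_empty(fail_l, .fail_proto()))
  if (keep_estimates) out$estimates <- .rbind_or_empty(est_l, NULL)
  out
}

.rbind_or_empty <- function(lst, proto) {
  if (length(lst)) do.call(rbind, unname(lst)) else proto
}
.bias_proto <- function() data.frame(
  metric = character(), population = character(), sample_size = integer(),
  replicate = integer(), rB = numeric(), stringsAsFactors = FALSE)
.mrse_proto <- function() data.frame(
  metric = character(), population = character(), sample_size = integer(),
  replicate = integer(), locus = character(), He_locus = numeric(),
  mrse = numeric(), m = integer(), stringsAsFactors = FALSE)
.sd_proto <- function() data.frame(
  metric = character(), population = character(), sample_size = integer(),
  replicate = integer(), sd = numeric(), m = integer(),
  stringsAsFactors = FALSE)
.fail_proto <- function() data.frame(
  population = character(), sample_size = integer(), replicate = integer(),
  locus = character(), n_failed = integer(), stringsAsFactors = FALSE)

#' Run the full experiment over many replicates
#'
#' Replicates are independent, replicate-keyed RNG jobs: results do not
#' depend on execution order, and the same `master_seed` reproduces the
#' output tables bit for bit.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicates (default `config$n_replicates`).
#' @param out_dir If non-`NULL`, write `references.csv`, `bias.csv`,
#'   `mrse.csv`, `sd.csv`, `failures.csv`, the summary tables and a JSON run
#'   manifest there.
#' @param keep_estimates Keep per-resample estimates (small runs only; also
#'   written as `estimates.csv`).
#' @param summaries Also compute the Table 2/3/4 analogues via
#'   [summarize_records()].
#' @param progress Emit a progress message every 10 replicates with the
#'   cumulative count of failed `H_CS` attempts.
#' @return An object of class `shannon_experiment`: list of record data
#'   frames plus `tables` and `config`.
#' @export
run_experiment <- function(config, replicates = config$n_replicates,
                           out_dir = NULL, keep_estimates = FALSE,
                           summaries = TRUE, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- proc.time()[["elapsed"]]
  res <- vector("list", replicates)
  fail_total <- 0L
  for (i in seq_len(replicates)) {
    res[[i]] <- run_replicate(i, config, keep_estimates = keep_estimates)
    fail_total <- fail_total + sum(res[[i]]$failures$n_failed)
    if (progress && (i %% 10L == 0L || i == replicates))
      message(sprintf("replicate %d/%d (cumulative H_CS failures: %d)",
                      i, replicates, fail_total))
  }
  sim_elapsed <- proc.time()[["elapsed"]] - t0
  out <- list(references = do.call(rbind, lapply(res, `[[`, "references")),
              bias = do.call(rbind, lapply(res, `[[`, "bias")),
              mrse = do.call(rbind, lapply(res, `[[`, "mrse")),
              sd = do.call(rbind, lapply(res, `[[`, "sd")),
              failures = do.call(rbind, lapply(res, `[[`, "failures")),
              config = config, replicates = replicates)
  if (keep_estimates)
    out$estimates <- do.call(rbind, lapply(res, `[[`, "estimates"))
  if (summaries)
    out$tables <- summarize_records(out, n_pairs = config$sd_comparison_pairs)
  out$elapsed <- c(simulation = sim_elapsed,
                   total = proc.time()[["elapsed"]] - t0)
  class(out) <- "shannon_experiment"
  if (!is.null(out_dir)) .write_experiment(out, out_dir)
  out
}

#' @export
print.shannon_experiment <- function(x, ...) {
  cat(sprintf("shannon_experiment: %d replicate(s), %d bias records, %d H_CS failures\n",
              x$replicates, nrow(x$bias), sum(x$failures$n_failed)))
  invisible(x)
}

.write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("references", "bias", "mrse", "sd", "failures")
  if (!is.null(x$estimates)) files <- c(files, "estimates")
  rows <- integer(0)
  for (f in files) {
    p <- file.path(out_dir, paste0(f, ".csv"))
    write_records(x[[f]], p)
    rows[paste0(f, ".csv")] <- nrow(x[[f]])
  }
  if (!is.null(x$tables)) {
    for (f in names(x$tables)) {
      if (is.null(x$tables[[f]])) next
      p <- file.path(out_dir, paste0(f, ".csv"))
      write_records(x$tables[[f]], p)
      rows[paste0(f, ".csv")] <- nrow(x$tables[[f]])
    }
  }
  manifest <- list(
    package = "shannonpop",
    version = as.character(packageVersion("shannonpop")),
    master_seed = x$config$master_seed,
    replicates = x$replicates,
    config = .config_snapshot(x$config),
    elapsed_seconds = as.list(x$elapsed),
    hcs_failures = sum(x$failures$n_failed),
    outputs = as.list(rows))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

.config_snapshot <- function(cfg) {
  list(preset = cfg$preset,
       loci = cfg$loci,
       scenarios = lapply(cfg$scenarios, function(d)
         list(durations = d$duration, sizes = d$N)),
       pop_size = cfg$pop_size,
       sample_sizes = cfg$sample_sizes,
       n_resamples = cfg$n_resamples,
       n_replicates = cfg$n_replicates,
       sd_comparison_pairs = cfg$sd_comparison_pairs,
       metrics = cfg$metrics,
       master_seed = cfg$master_seed,
       boundary = cfg$boundary)
}

#' Compare two SD distributions by random pairing
#'
#' Draws `n_pairs` independent pairs (one value from each distribution,
#' uniformly with replacement) and reports the fraction of pairs ordered
#' against the observed difference of means, floored at `1 / n_pairs`. Ties
#' count against rejection (so two identical constant distributions give
#' p = 1). One-sided by the observed mean order.
#'
#' @param a,b Numeric vectors (nonempty).
#' @param n_pairs Number of random pairs.
#' @param metric_a,metric_b,population,sample_size Labels recorded in the
#'   output row.
#' @return One-row data frame: `metric_a`, `metric_b`, `population`,
#'   `sample_size`, `p`.
#' @export
compare_sd_distributions <- function(a, b, n_pairs = 100000L,
                                     metric_a = "a", metric_b = "b",
                                     population = "", sample_size = NA_integer_) {
  if (length(a) == 0L || length(b) == 0L)
    stop("`a` and `b` must be nonempty", call. = FALSE)
  if (n_pairs < 1) stop("`n_pairs` must be >= 1", call. = FALSE)
  pa <- a[sample.int(length(a), n_pairs, replace = TRUE)]
  pb <- b[sample.int(length(b), n_pairs, replace = TRUE)]
  against <- if (mean(a) <= mean(b)) pa >= pb else pa <= pb
  p <- max(mean(against), 1 / n_pairs)
  data.frame(metric_a = metric_a, metric_b = metric_b,
             population = population, sample_size = sample_size, p = p,
             stringsAsFactors = FALSE)
}
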