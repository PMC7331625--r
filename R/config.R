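#' Simulation experiment configuration
#'
#' Bundles every knob of the resampling experiment. The `"paper"` preset is
#' the full study design (1000 replicates); the `"scaled"` preset keeps the
#' identical populations, loci and sampling scheme but runs 100 replicates,
#' which stabilises medians and means at desk scale.
#'
#' @param preset `"paper"` or `"scaled"`; only sets `n_replicates` when that
#'   argument is `NULL`.
#' @param loci Data frame of loci (columns `name`, `mu`, `k_max`).
#' @param scenarios Named list of [demography()] objects.
#' @param pop_size Diploid individuals per simulated population.
#' @param sample_sizes Genotype counts drawn without replacement (may be
#'   empty, in which case only parametric values are computed).
#' @param n_resamples Independent subsamples per sample size (>= 2).
#' @param n_replicates Simulation replicates.
#' @param sd_comparison_pairs Random pairs drawn when comparing SD
#'   distributions.
#' @param metrics Metrics to evaluate, a subset of [shannon_metrics()].
#' @param master_seed Master seed; all child streams derive from it.
#' @param boundary Allele-range constraint handling (see [simulate_locus()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(preset = c("paper", "scaled"),
                       loci = default_loci(),
                       scenarios = default_scenarios(),
                       pop_size = 10000,
                       sample_sizes = c(5L, 20L, 80L, 200L),
                       n_resamples = 500L,
                       n_replicates = NULL,
                       sd_comparison_pairs = 100000L,
                       metrics = shannon_metrics(),
                       master_seed = 1L,
                       boundary = c("discard", "reflect")) {
  preset <- match.arg(preset)
  boundary <- match.arg(boundary)
  if (is.null(n_replicates))
    n_replicates <- if (preset == "paper") 1000L else 100L
  stopifnot(is.data.frame(loci),
            all(c("name", "mu", "k_max") %in% names(loci)),
            nrow(loci) >= 1L, !anyDuplicated(loci$name),
            all(loci$mu >= 0), all(loci$k_max >= 2))
  if (!is.list(scenarios) || length(scenarios) == 0L ||
      is.null(names(scenarios)) || anyDuplicated(names(scenarios)) ||
      !all(vapply(scenarios, inherits, TRUE, "demography")))
    stop("`scenarios` must be a uniquely named list of demography objects",
         call. = FALSE)
  stopifnot(pop_size >= 1, n_resamples >= 2, n_replicates >= 1,
            sd_comparison_pairs >= 1)
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) &&
      (any(sample_sizes < 1) || any(sample_sizes > pop_size)))
    stop("sample sizes must lie in [1, pop_size]", call. = FALSE)
  bad <- setdiff(metrics, shannon_metrics())
  if (length(bad))
    stop(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      abs(master_seed) >= 2^31)
    stop("`master_seed` must be a single 32-bit integer", call. = FALSE)
  structure(list(preset = preset, loci = loci, scenarios = scenarios,
                 pop_size = as.integer(pop_size),
                 sample_sizes = sample_sizes,
                 n_resamples = as.integer(n_resamples),
                 n_replicates = as.integer(n_replicates),
                 sd_comparison_pairs = as.integer(sd_comparison_pairs),
                 metrics = metrics,
                 master_seed = as.integer(master_seed),
                 boundary = boundary),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config (%s preset): %d loci, %d scenarios, N = %d diploids\n",
              x$preset, nrow(x$loci), length(x$scenarios), x$pop_size))
  cat(sprintf("  sample sizes {%s}, %d resamples, %d replicates, seed %d\n",
              paste(x$sample_sizes, collapse = ", "), x$n_resamples,
              x$n_replicates, x$master_seed))
  cat(sprintf("  metrics: %s; boundary: %s\n",
              paste(x$metrics, collapse = ", "), x$boundary))
  invisible(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Recognised keys: `preset`, `pop_size`, `sample_sizes`, `n_resamples`,
#' `n_replicates`, `sd_comparison_pairs`, `metrics`, `master_seed`,
#' `boundary`, `loci` (the string `"default"` or a list of
#' `{name, mu, k_max}` entries) and `scenarios` (the string `"default"` or a
#' map of name to `{durations, sizes}`). Unknown keys abort before any
#' computation.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  allowed <- c("preset", "loci", "scenarios", "pop_size", "sample_sizes",
               "n_resamples", "n_replicates", "sd_comparison_pairs",
               "metrics", "master_seed", "boundary")
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  args <- y
  if (!is.null(y$loci)) {
    args$loci <- if (identical(y$loci, "default")) default_loci()
    else do.call(rbind, lapply(y$loci, function(l)
      locus_spec(l$name, l$mu, l$k_max)))
  }
  if (!is.null(y$scenarios)) {
    args$scenarios <- if (identical(y$scenarios, "default")) default_scenarios()
    else lapply(y$scenarios, function(s) {
      d <- as.numeric(s$durations)
      d[is.na(d) | d < 0] <- Inf # YAML ".inf" or negative sentinel
      demography(d, as.numeric(s$sizes))
    })
  }
  do.call(sim_config, args)
}

#' Planned number of estimation events per metric
#'
#' The design bookkeeping of the experiment: each metric is evaluated
#' `loci * scenarios * (|sample sizes| * n_resamples + 1)` times per
#' replicate (the `+ 1` is the whole-population parametric value). With the
#' paper preset this is `24 * 4 * (4 * 500 + 1) * 1000 = 192,096,000`.
#'
#' @param config A [sim_config()].
#' @param per_replicate Return the per-replicate count instead of the total.
#' @return A single number.
#' @export
count_estimation_events <- function(config, per_replicate = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  per <- nrow(config$loci) * length(config$scenarios) *
    (length(config$sample_sizes) * config$n_resamples + 1)
  if (per_replicate) per else per * config$n_replicates
}
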