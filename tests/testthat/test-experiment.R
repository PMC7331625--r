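test_that("relative_bias and mrse follow their definitions", {
  expect_equal(relative_bias(0.9, 1.0), -0.1)
  expect_equal(relative_bias(1.0, 1.0), 0)
  expect_equal(relative_bias(1.2, 0.8), 0.5)
  expect_error(relative_bias(1, 0), "> 0")

  expect_equal(mrse(c(1, 1, 1), 1)$mrse, 0)
  r <- mrse(c(1.1, 0.9), 1.0)
  expect_equal(r$mrse, 0.01)
  expect_equal(r$m, 2L)
  r <- mrse(c(1.1, NA), 1.0)
  expect_equal(r$mrse, 0.01)
  expect_equal(r$m, 1L)
  # denominator is H, not H^2
  expect_equal(mrse(c(3), 2)$mrse, (3 - 2)^2 / 2)
  expect_error(mrse(c(NA_real_, NA_real_), 1), "all estimates are missing")
  expect_error(mrse(c(1), -1), "> 0")
})

test_that("parametric_reference composes hand-checked per-locus values", {
  refs <- parametric_reference(toy_pop())
  val <- function(m, l) refs$value[refs$metric == m & refs$locus == l]
  expect_equal(val("H_MLE", "A"), 1.0397207708, tolerance = 1e-9)
  expect_equal(val("H_MLE", "B"), 0)
  expect_equal(val("H_MLE", "C"), log(4), tolerance = 1e-12)
  expect_equal(val("H_MLE", "mean"), mean(c(1.0397207708, 0, log(4))),
               tolerance = 1e-9)
  expect_equal(val("Hs", "A"), 0.625)
  # the all-singleton locus fails H_CS and poisons the H_CS mean only
  expect_true(is.na(val("H_CS", "C")))
  expect_true(is.na(val("H_CS", "mean")))
  expect_false(is.na(val("H_Chao", "mean")))
  expect_true(all(refs$sample_size == "parametric"))
})

test_that("estimating on the whole population gives exactly zero bias", {
  set.seed(3)
  pop <- simulate_population(demography(Inf, 400), default_loci()[23:24, ], 30)
  ref <- h_mle(allele_counts(pop, "L24"))
  set.seed(4)
  est <- h_mle(allele_counts(subsample(pop, n_individuals(pop)), "L24"))
  expect_equal(relative_bias(est, ref), 0)
})

test_that("run_replicate produces the full record set deterministically", {
  cfg <- tiny_config()
  r1 <- run_replicate(1L, cfg)
  r2 <- run_replicate(1L, cfg)
  expect_identical(r1, r2)
  r3 <- run_replicate(2L, cfg)
  expect_false(identical(r1$references$value, r3$references$value))

  # exactly one bias record per metric/population/size
  expect_equal(nrow(r1$bias),
               length(cfg$metrics) * length(cfg$scenarios) * length(cfg$sample_sizes))
  expect_false(anyDuplicated(r1$bias[c("metric", "population", "sample_size")]) > 0)

  # references: (loci + mean) x metrics x scenarios
  expect_equal(nrow(r1$references), 3L * length(cfg$metrics) * length(cfg$scenarios))

  # sd and mrse bookkeeping
  expect_true(all(r1$sd$m <= cfg$n_resamples))
  expect_true(all(r1$sd$sd >= 0, na.rm = TRUE))
  expect_true(all(r1$mrse$mrse >= 0, na.rm = TRUE))
  expect_true(all(c("He_locus", "mrse", "m") %in% names(r1$mrse)))

  # degenerate config: no sample sizes -> parametric references only
  cfg0 <- tiny_config(sample_sizes = integer(0))
  r0 <- run_replicate(1L, cfg0)
  expect_equal(nrow(r0$bias), 0L)
  expect_equal(nrow(r0$sd), 0L)
  expect_gt(nrow(r0$references), 0L)
})

test_that("estimation-event bookkeeping matches the design formula", {
  expect_equal(count_estimation_events(sim_config(preset = "paper")),
               24 * 4 * (4 * 500 + 1) * 1000)
  cfg1 <- sim_config(loci = locus_spec("L01", 1e-4, 3), sample_sizes = 5L,
                     n_replicates = 1L)
  expect_equal(count_estimation_events(cfg1), 1 * 4 * (1 * 500 + 1))
  expect_equal(count_estimation_events(tiny_config(), per_replicate = TRUE),
               2 * 4 * (2 * 3 + 1))
})

test_that("random-pair SD comparison implements the documented tie and floor rules", {
  set.seed(8)
  # identical constant distributions: every pair ties, ties count against
  expect_equal(compare_sd_distributions(rep(2, 5), rep(2, 5), 1000)$p, 1)
  # complete separation: the floor 1/n_pairs applies
  expect_equal(compare_sd_distributions(1:5, 101:105, 1000)$p, 1 / 1000)
  # Monte-Carlo agreement with the normal overlap integral:
  # shift of 3 SD between unit-variance samples -> P(X >= Y) = 1 - pnorm(3/sqrt(2))
  set.seed(9)
  b <- stats::rnorm(1000)
  p3 <- compare_sd_distributions(b + 3, b, 100000L)$p
  expect_equal(p3, 1 - stats::pnorm(3 / sqrt(2)), tolerance = 0.2)
  # a shift of 3 SDs of the pairwise difference is clearly significant
  p3d <- compare_sd_distributions(b + 3 * sqrt(2), b, 100000L)$p
  expect_lt(p3d, 0.01)
  expect_error(compare_sd_distributions(numeric(0), 1:3), "nonempty")
})

test_that("summary tables aggregate replicates correctly", {
  cfg <- tiny_config()
  res <- run_experiment(cfg, replicates = 1L, summaries = TRUE)
  t2 <- res$tables$table2
  # single replicate: min = median = max in every cell
  expect_true(all(t2$min == t2$median & t2$median == t2$max, na.rm = TRUE))

  # hand-set two-replicate medians
  refs <- data.frame(population = "P", replicate = c(1L, 2L), locus = "mean",
                     metric = "H_MLE", value = c(1.0, 3.0),
                     sample_size = "parametric")
  bias <- data.frame(metric = "H_MLE", population = "P",
                     sample_size = c(5L, 5L), replicate = c(1L, 2L),
                     rB = c(-0.2, -0.1))
  sdr <- data.frame(metric = rep(c("H_MLE", "H_CS"), each = 2),
                    population = "P", sample_size = 5L,
                    replicate = c(1L, 2L, 1L, 2L),
                    sd = c(0.1, 0.3, 0.2, 0.4), m = c(10L, 10L, 10L, 9L))
  tabs <- summarize_records(list(references = refs, bias = bias, sd = sdr),
                            n_pairs = 100)
  expect_equal(tabs$table2$median, 2.0)
  expect_equal(tabs$table2[, c("min", "max")], data.frame(min = 1, max = 3))
  expect_equal(tabs$table4$median, -0.15)
  # the H_CS cell with incomplete resampling is excluded from mean SD
  expect_equal(tabs$table3$mean_sd[tabs$table3$metric == "H_MLE"], 0.2)
  expect_true(is.na(tabs$table3$mean_sd[tabs$table3$metric == "H_CS"]))
  expect_true(tabs$table3$excluded[tabs$table3$metric == "H_CS"])
})

test_that("experiment output tables are identical when rerun with the same seed", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_experiment(cfg, replicates = 2L, out_dir = d1)
  run_experiment(cfg, replicates = 2L, out_dir = d2)
  for (f in c("references.csv", "bias.csv", "mrse.csv", "sd.csv", "table2.csv",
              "table4.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$master_seed, cfg$master_seed)
  expect_equal(man$config$pop_size, cfg$pop_size)
})
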