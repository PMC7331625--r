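.range_summary <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(c(min = NA_real_, median = NA_real_, max = NA_real_, n = 0))
  c(min = min(v), median = median(v), max = max(v), n = length(v))
}

.group_summary <- function(df, by, value) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  parts <- split(df, key)
  do.call(rbind, lapply(parts, function(d) {
    s <- .range_summary(d[[value]])
    cbind(d[1L, by, drop = FALSE],
          data.frame(min = s[["min"]], median = s[["median"]],
                     max = s[["max"]], n = as.integer(s[["n"]]),
                     row.names = NULL))
  }))
}

#' Summary tables of a resampling experiment
#'
#' Builds the three summary tables of the study from the record data frames:
#'
#' * `table2` — min / median / max over replicates of the mean-over-loci
#'   parametric value, per scenario and metric.
#' * `table3` — mean SD per scenario and metric at the smallest sample size
#'   (5 genotypes in the default design). An `H_CS` cell in which any
#'   replicate had failed resampling attempts (incomplete `m`) is excluded
#'   (reported `NA`), mirroring the exclusion of the failure-ridden cells
#'   from the sampling-variance comparison.
#' * `table3_comparisons` — one-sided random-pair p-values
#'   ([compare_sd_distributions()]) for every metric pair within each
#'   scenario, excluded cells skipped.
#' * `table4` — min / median / max relative bias per sample size and metric,
#'   pooled over scenarios and replicates.
#'
#' @param x A `shannon_experiment`, or any list with data frames
#'   `references`, `bias` and `sd` in the schemas written by
#'   [run_experiment()].
#' @param n_pairs Random pairs per SD comparison.
#' @param comparison_seed Seed for the pair draws.
#' @param table3_ns Sample size summarised in `table3` (default: 5 when
#'   present, otherwise the smallest available).
#' @return Named list of data frames `table2`, `table3`,
#'   `table3_comparisons`, `table4`.
#' @export
summarize_records <- function(x, n_pairs = 100000L, comparison_seed = 1L,
                              table3_ns = NULL) {
  stopifnot(is.list(x), all(c("references", "bias", "sd") %in% names(x)))
  refs <- x$references; bias <- x$bias; sdr <- x$sd
  pops <- unique(refs$population)
  mets <- unique(refs$metric)

  rm <- refs[refs$locus == "mean", ]
  rm$population <- factor(rm$population, levels = pops)
  rm$metric <- factor(rm$metric, levels = mets)
  t2 <- .group_summary(rm, c("population", "metric"), "value")
  t2$population <- as.character(t2$population)
  t2$metric <- as.character(t2$metric)
  rownames(t2) <- NULL

  t3 <- t3cmp <- NULL
  if (nrow(sdr)) {
    ns3 <- table3_ns %||%
      (if (5L %in% sdr$sample_size) 5L else min(sdr$sample_size))
    s5 <- sdr[sdr$sample_size == ns3, ]
    max_m <- max(s5$m)
    pops3 <- unique(c(intersect(pops, s5$population), s5$population))
    mets3 <- unique(c(intersect(mets, s5$metric), s5$metric))
    cells <- expand.grid(population = pops3, metric = mets3,
                         stringsAsFactors = FALSE)
    cells <- cells[order(match(cells$population, pops3),
                         match(cells$metric, mets3)), ]
    t3 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      d <- s5[s5$population == cells$population[i] &
                s5$metric == cells$metric[i], ]
      excluded <- any(d$m < max_m)
      data.frame(population = cells$population[i], metric = cells$metric[i],
                 sample_size = ns3,
                 mean_sd = if (excluded || !nrow(d)) NA_real_
                           else mean(d$sd, na.rm = TRUE),
                 excluded = excluded, n = sum(!is.na(d$sd)),
                 stringsAsFactors = FALSE)
    }))
    rownames(t3) <- NULL
    set.seed(comparison_seed)
    cmp <- list()
    for (p in unique(t3$population)) {
      ok <- t3$metric[t3$population == p & !t3$excluded & !is.na(t3$mean_sd)]
      if (length(ok) < 2L) next
      for (pair in combn(ok, 2L, simplify = FALSE)) {
        da <- s5$sd[s5$population == p & s5$metric == pair[1L] & !is.na(s5$sd)]
        db <- s5$sd[s5$population == p & s5$metric == pair[2L] & !is.na(s5$sd)]
        cmp[[paste(p, pair[1L], pair[2L])]] <- compare_sd_distributions(
          da, db, n_pairs = n_pairs, metric_a = pair[1L], metric_b = pair[2L],
          population = p, sample_size = ns3)
      }
    }
    t3cmp <- .rbind_or_empty(cmp, data.frame(
      metric_a = character(), metric_b = character(),
      population = character(), sample_size = integer(), p = numeric(),
      stringsAsFactors = FALSE))
  }

  t4 <- NULL
  if (nrow(bias)) {
    b <- bias
    b$sample_size <- factor(b$sample_size, levels = sort(unique(b$sample_size)))
    b$metric <- factor(b$metric, levels = mets)
    t4 <- .group_summary(b, c("sample_size", "metric"), "rB")
    t4$sample_size <- as.integer(as.character(t4$sample_size))
    t4$metric <- as.character(t4$metric)
    rownames(t4) <- NULL
  }

  list(table2 = t2, table3 = t3, table3_comparisons = t3cmp, table4 = t4)
}
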