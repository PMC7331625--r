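test_that("default_loci matches the 24-locus design", {
  loci <- default_loci()
  expect_equal(nrow(loci), 24L)
  expect_equal(loci$name[1], "L01")
  expect_equal(loci$mu[1], 0.0001)
  expect_equal(loci$k_max[1], 3L)
  expect_equal(loci[7, ]$mu, 0.0002) # rates vary over rows of the design
  expect_equal(loci[7, ]$k_max, 3L)
  expect_equal(loci[24, ]$mu, 0.001)
  expect_equal(loci[24, ]$k_max, 20L)
  expect_equal(unique(loci$mu), c(1e-4, 2e-4, 5e-4, 1e-3))
  expect_equal(unique(loci$k_max), c(3L, 6L, 9L, 12L, 15L, 20L))
})

test_that("demography validates epoch structure", {
  expect_error(demography(c(20, 20), c(100, 100)), "infinite duration")
  expect_error(demography(c(-1, Inf), c(100, 100)), "finite and > 0")
  expect_error(demography(Inf, 0.5), ">= 1")
  sc <- default_scenarios()
  expect_equal(names(sc), c("P_C", "P_500", "P_50", "P_20"))
  expect_equal(sc$P_20$N, c(10000, 20, 10000))
  expect_equal(sc$P_20$duration, c(20, 20, Inf))
})

test_that("simulated tip states respect the mutation model structure", {
  dem <- demography(Inf, 100)
  # no mutation: every tip carries the root state floor(k_max / 2)
  set.seed(1)
  st <- simulate_locus(dem, list(mu = 0, k_max = 9), 50)
  expect_true(all(st == 4L))
  expect_equal(length(st), 50L)

  # states always stay inside [0, k_max - 1], for both boundary rules
  for (bd in c("discard", "reflect")) {
    set.seed(2)
    st <- simulate_locus(dem, list(mu = 0.05, k_max = 3), 200, boundary = bd)
    expect_true(all(st >= 0L & st <= 2L))
  }

  expect_error(simulate_locus(dem, list(mu = 0.01, k_max = 5), 1), ">= 2")
})

test_that("simulation is reproducible under a fixed seed", {
  dem <- default_scenarios()$P_50
  loc <- list(mu = 5e-4, k_max = 12)
  set.seed(77); a <- simulate_locus(dem, loc, 400)
  set.seed(77); b <- simulate_locus(dem, loc, 400)
  expect_identical(a, b)
  set.seed(78); c <- simulate_locus(dem, loc, 400)
  expect_false(identical(as.integer(a), as.integer(c)))

  seeds <- c(11L, 12L)
  p1 <- simulate_population(dem, default_loci()[1:2, ], 30, seeds = seeds)
  p2 <- simulate_population(dem, default_loci()[1:2, ], 30, seeds = seeds)
  expect_identical(p1, p2)
})

test_that("pairwise coalescence times match the closed-form expectation", {
  # constant N: E[TMRCA of a pair] = 2N generations
  set.seed(31)
  N <- 500
  tm <- replicate(5000, attr(simulate_locus(demography(Inf, N),
                                            list(mu = 0, k_max = 3), 2), "tmrca"))
  expect_equal(mean(tm), 2 * N, tolerance = 0.05)

  # epoch boundaries: no coalescence in a huge first epoch, then E = d + 2N2
  set.seed(32)
  tm <- replicate(4000, attr(simulate_locus(demography(c(100, Inf), c(1e8, 50)),
                                            list(mu = 0, k_max = 3), 2), "tmrca"))
  expect_true(all(tm > 100))
  expect_equal(mean(tm), 100 + 2 * 50, tolerance = 0.05)
})

test_that("mean gene diversity increases strictly with mutation rate", {
  dem <- demography(Inf, 10000)
  mus <- c(1e-4, 2e-4, 5e-4, 1e-3)
  means <- vapply(mus, function(mu) {
    v <- vapply(1:60, function(r) {
      set.seed(1000 * r + round(mu * 1e5))
      st <- simulate_locus(dem, list(mu = mu, k_max = 20), 200)
      gene_diversity(allele_counts(tabulate(st + 1L)))
    }, 0.0)
    mean(v)
  }, 0.0)
  expect_true(all(diff(means) > 0))
})

test_that("the allele-count cap binds at high mutation rates", {
  dem <- demography(Inf, 10000)
  k <- vapply(1:60, function(r) {
    set.seed(r)
    st <- simulate_locus(dem, list(mu = 1e-3, k_max = 3), 500)
    length(unique(st))
  }, 0L)
  expect_true(all(k <= 3L))
  expect_gt(mean(k), 2.7) # approaches the cap
})

test_that("a bottleneck reduces diversity in paired replicates", {
  scen <- default_scenarios()
  loci <- default_loci()[c(16, 17, 18, 22, 23, 24), ]
  lower <- vapply(1:50, function(r) {
    hs <- vapply(c("P_C", "P_20"), function(sc) {
      v <- vapply(seq_len(nrow(loci)), function(l) {
        set.seed(shannonpop:::child_seed(3L, "pair", r, sc, loci$name[l]))
        st <- simulate_locus(scen[[sc]], loci[l, ], 300)
        gene_diversity(allele_counts(tabulate(st + 1L)))
      }, 0.0)
      mean(v)
    }, 0.0)
    hs["P_20"] < hs["P_C"]
  }, TRUE)
  expect_gte(mean(lower), 0.95)
})

test_that("scenario diversity is ordered P_20 < P_50 < P_500 < P_C", {
  scen <- default_scenarios()
  loci <- default_loci()
  means <- vapply(c("P_20", "P_50", "P_500", "P_C"), function(sc) {
    v <- vapply(1:80, function(r) {
      hs <- vapply(seq_len(nrow(loci)), function(l) {
        set.seed(shannonpop:::child_seed(4L, "ord", r, sc, loci$name[l]))
        st <- simulate_locus(scen[[sc]], loci[l, ], 400)
        gene_diversity(allele_counts(tabulate(st + 1L)))
      }, 0.0)
      mean(hs)
    }, 0.0)
    mean(v)
  }, 0.0)
  expect_true(all(diff(means) > 0))
})

test_that("simulate_population assembles diploid genotypes at every locus", {
  set.seed(9)
  pop <- simulate_population(demography(Inf, 300), default_loci()[1:3, ], 25)
  expect_s3_class(pop, "pop_sample")
  expect_equal(dim(pop$a1), c(25L, 3L))
  expect_equal(pop$loci, c("L01", "L02", "L03"))
  expect_false(anyNA(pop$a1))

  # zero mutation rate everywhere -> every estimator is exactly 0
  loci0 <- data.frame(name = c("z1", "z2"), mu = 0, k_max = 5L)
  pop0 <- simulate_population(demography(Inf, 300), loci0, 20)
  for (l in pop0$loci)
    expect_true(all(estimate_all(allele_counts(pop0, l))$value == 0))
})
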