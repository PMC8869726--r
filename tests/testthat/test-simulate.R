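test_that("category fraction draws sit at the centroid in the tight limit", {
  expect_equal(unname(simulate_category_fractions("Balance", Inf)[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(simulate_category_fractions("A dominant", Inf)[1, ]),
               c(1, 0, 0))
  expect_error(simulate_category_fractions("Low", 10), "unknown")
  expect_error(simulate_category_fractions("Balance", 0), "positive")
  # finite kappa: rows on the simplex
  set.seed(19)
  f <- simulate_category_fractions("B suppressed", 50, n = 100)
  expect_equal(rowSums(f), rep(1, 100))
  expect_true(all(f > 0))
})

test_that("moderate-concentration draws classify back to their category", {
  set.seed(20)
  f <- simulate_category_fractions("D suppressed", 50, n = 10000)
  cls <- classify_triad(f)
  expect_gte(mean(cls$category == "D suppressed"), 0.95)
})

test_that("count draws follow the FPKM-inverted negative binomial", {
  set.seed(21)
  expect_equal(simulate_counts(0, 1000, 1e7, 0.1), 0)
  # mu = 1 * 1000 * 1e7 / 1e9 = 10; near-Poisson limit
  x <- simulate_counts(rep(1, 10000), 1000, 1e7, 1e-13)
  expect_lt(abs(mean(x) - 10), 3 * sd(x) / sqrt(length(x)))
  # NB variance identity: mu = 10, alpha = 2 -> var = 10 + 2 * 100 = 210
  y <- simulate_counts(rep(1, 20000), 1000, 1e7, 2)
  expect_lt(abs(mean(y) - 10), 3 * sd(y) / sqrt(length(y)))
  se_var <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(var(y) - 210), 4 * se_var)
  expect_error(simulate_counts(-1, 1000, 1e7, 0.1), "nonnegative")
  expect_error(simulate_counts(1, 0, 1e7, 0.1), "positive")
  expect_error(simulate_counts(1, 1000, 1e7, -2), "nonnegative")
})

test_that("dataset generation is deterministic and seed-sensitive", {
  cfg <- simulation_config(n_triads = 50, seed = 22)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(simulation_config(n_triads = 50, seed = 23))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("empty configuration yields empty, well-formed outputs", {
  ds <- simulate_dataset(simulation_config(n_triads = 0))
  expect_equal(nrow(ds$counts), 0)
  expect_equal(ncol(ds$counts), 18)
  expect_equal(nrow(ds$triads), 0)
  expect_equal(nrow(ds$truth$category), 0)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(category_mix = setNames(rep(0.2, 8),
                                                         bias_categories())),
               "sum to 1")
  expect_error(simulation_config(nb_dispersion = -1))
  expect_error(simulation_config(library_size_range = c(100, 10)))
  expect_error(simulation_config(de_fraction = 1))
})

test_that("planted truth is internally consistent", {
  cfg <- simulation_config(n_triads = 200, seed = 24)
  ds <- simulate_dataset(cfg)
  # exactly one category per triad x time point
  expect_equal(nrow(ds$truth$category), 200 * 6)
  expect_false(anyNA(ds$truth$category$category))
  # Low triad-time-points carry planted total FPKM below the threshold,
  # expressed ones above it
  tot <- rowsum(ds$planted_fpkm,
                rep(ds$triads$triad_id, each = 3))
  tru <- ds$truth$category
  planted_tot <- tot[cbind(match(tru$triad_id, rownames(tot)),
                           match(tru$timepoint, colnames(tot)))]
  expect_true(all(planted_tot[tru$category == "Low"] < 1))
  expect_true(all(planted_tot[tru$category != "Low"] > 1))
  # planted transcriptome mass is on the FPKM scale (Low triads add a
  # negligible unscaled remainder)
  mass <- colSums(ds$planted_fpkm * ds$lengths[rownames(ds$planted_fpkm)])
  expect_equal(unname(mass / 1e9), rep(1, 6), tolerance = 1e-3)
})

test_that("all-balanced zero-noise data classifies 100% balanced", {
  mix <- setNames(c(1, rep(0, 7)), bias_categories())
  cfg <- simulation_config(n_triads = 100, category_mix = mix,
                           category_stay = 1, bias_concentration = Inf,
                           nb_dispersion = 0, seed = 25)
  ds <- simulate_dataset(cfg)
  fk <- fpkm(ds$counts, ds$lengths)
  asn <- classify_all(fk, ds$triads, ds$samples)
  expect_true(all(asn$category == "Balance"))
})

test_that("realized FPKM converges to planted values as noise vanishes", {
  mix <- setNames(c(0.8, rep(0.2 / 6, 6), 0), bias_categories())
  cfg <- simulation_config(n_triads = 100, category_mix = mix,
                           category_stay = 1, nb_dispersion = 0,
                           library_size_range = c(5e8, 5e8), seed = 26)
  ds <- simulate_dataset(cfg)
  fk <- fpkm(ds$counts, ds$lengths)
  tp_mean <- sapply(unique(ds$samples$timepoint), function(tp) {
    rowMeans(fk[, ds$samples$sample_id[ds$samples$timepoint == tp]])
  })
  rel_err <- abs(tp_mean - ds$planted_fpkm) / (ds$planted_fpkm + 1)
  expect_lt(median(rel_err), 0.05)
  expect_lt(max(rel_err), 0.5)
})

test_that("transition truth follows the configured retention probabilities", {
  mix <- setNames(rep(1 / 8, 8), bias_categories())
  cfg <- simulation_config(n_triads = 4000, category_mix = mix,
                           category_stay = 0.9, seed = 27)
  ds <- simulate_dataset(cfg)
  tru <- ds$truth$category
  wide <- matrix(tru$category, nrow = 4000)
  stays <- wide[, -1] == wide[, -6]
  expect_equal(mean(stays), 0.9, tolerance = 0.02)
  # stationarity: last time point's mix matches the first's
  p1 <- table(factor(wide[, 1], bias_categories())) / 4000
  p6 <- table(factor(wide[, 6], bias_categories())) / 4000
  expect_lt(max(abs(as.vector(p6) - as.vector(p1))), 0.03)
})

test_that("round-trip through TSV files preserves the dataset", {
  cfg <- simulation_config(n_triads = 30, seed = 28)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$lengths, ds$lengths)
  expect_equal(back$samples, ds$samples)
  expect_equal(back$triads, ds$triads)
  expect_equal(back$truth$category, ds$truth$category)
  expect_equal(back$truth$de, ds$truth$de)
})
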