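test_that("profiles are replicate means z-scored per gene", {
  samples <- make_samples(c(0, 2, 4), 2)
  fk <- rbind(
    up = c(1, 1, 4, 4, 10, 10),
    flat = rep(3, 6)
  )
  colnames(fk) <- samples$sample_id
  expect_message(prof <- temporal_profiles(fk, samples), "constant")
  expect_equal(rownames(prof), "up")
  expect_equal(attr(prof, "dropped"), "flat")
  expect_equal(unname(rowMeans(prof)), 0)
  expect_equal(unname(apply(prof, 1, sd)), 1)
  # replicate averaging happens before scaling
  raw <- c(1, 4, 10)
  expect_equal(unname(prof[1, ]), (raw - mean(raw)) / sd(raw))
})

test_that("duplicate template profiles cluster exactly with zero scatter", {
  templ <- cluster_templates(6, 4)
  x <- templ[rep(1:4, each = 2), ]
  rownames(x) <- paste0("g", 1:8)
  fit <- kmeans_correlation(x, k = 4, seed = 1, n_init = 5)
  expect_equal(fit$tot_withinss, 0, tolerance = 1e-12)
  expect_equal(length(unique(fit$labels)), 4)
  # each duplicate pair shares a label
  expect_equal(fit$labels[c(1, 3, 5, 7)], fit$labels[c(2, 4, 6, 8)],
               ignore_attr = TRUE)
})

test_that("anticorrelated profiles split into different clusters at k = 2", {
  t <- 1:6
  x <- rbind(a = t, b = -t)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  fit <- kmeans_correlation(x, k = 2, seed = 1, n_init = 5)
  expect_false(fit$labels["a"] == fit$labels["b"])
})

test_that("clustering errors on too few or constant profiles", {
  templ <- cluster_templates(6, 3)
  expect_error(kmeans_correlation(templ, k = 4), "fewer profiles")
  bad <- rbind(templ, flat = rep(1, 6))
  expect_error(kmeans_correlation(bad, k = 2), "constant profile")
})

test_that("silhouette handles exact, degenerate and general cases", {
  templ <- cluster_templates(6, 2)
  x <- templ[rep(1:2, each = 3), ]
  expect_equal(silhouette_overall(x, rep(1:2, each = 3))$overall, 1)
  # identical profiles split arbitrarily: a = b = 0 convention gives 0
  y <- templ[rep(1, 4), ]
  expect_equal(silhouette_overall(y, c(1, 1, 2, 2))$overall, 0)
  expect_error(silhouette_overall(x, rep(1, 6)), "at least 2")
  # 20-gene toy set equals the brute-force a/b definition
  gen <- make_template_profiles(20, 3, 6, noise_sd = 0.5, seed = 9)
  got <- silhouette_overall(gen$profiles, gen$labels)
  expect_equal(got$overall, oracle_silhouette(gen$profiles, gen$labels))
  expect_true(got$overall >= -1 && got$overall <= 1)
  # label permutation invariance
  relab <- c(3, 1, 2)[gen$labels]
  expect_equal(silhouette_overall(gen$profiles, relab)$overall, got$overall)
})

test_that("silhouette-based selection recovers four planted templates", {
  gen <- make_template_profiles(300, 4, 6, noise_sd = 0.4, seed = 10)
  sel <- select_k(gen$profiles, k_range = 2:8, seed = 11, n_init = 10)
  expect_equal(sel$best_k, 4)
  expect_gte(adjusted_rand_index(sel$assignment$labels, gen$labels), 0.9)
  expect_equal(sel$table$k, 2:8)
  # deterministic under the same seed
  sel2 <- select_k(gen$profiles, k_range = 2:8, seed = 11, n_init = 10)
  expect_identical(sel$table, sel2$table)
  expect_identical(sel$assignment$labels, sel2$assignment$labels)
  expect_error(select_k(gen$profiles, k_range = integer(0)), "empty")
})

test_that("k_range of a single value returns it with its assignment", {
  gen <- make_template_profiles(30, 3, 6, noise_sd = 0.3, seed = 12)
  sel <- select_k(gen$profiles, k_range = 2, seed = 1, n_init = 5)
  expect_equal(sel$best_k, 2)
  expect_equal(sel$assignment$k, 2)
})

test_that("row-affine transforms of raw profiles do not change clusters", {
  # correlation distance ignores per-gene location/scale: feeding FPKM
  # scaled per gene through z-scoring yields identical partitions
  samples <- make_samples(c(0, 2, 4, 6, 8, 10), 3)
  gen <- make_template_profiles(60, 3, 6, noise_sd = 0.3, seed = 13)
  raw <- 2^(3 + gen$profiles) # positive "FPKM-like" values
  fk <- raw[, rep(1:6, each = 3)]
  colnames(fk) <- samples$sample_id
  scaled <- fk * rexp(60)     # per-gene scale factors
  p1 <- temporal_profiles(fk, samples)
  p2 <- temporal_profiles(scaled, samples)
  f1 <- kmeans_correlation(p1, 3, seed = 2, n_init = 10)
  f2 <- kmeans_correlation(p2, 3, seed = 2, n_init = 10)
  expect_equal(adjusted_rand_index(f1$labels, f2$labels), 1)
})

test_that("noise degrades planted-structure recovery monotonically", {
  ari <- vapply(c(0.2, 0.8, 2.0), function(sd) {
    gen <- make_template_profiles(200, 4, 6, noise_sd = sd, seed = 14)
    fit <- kmeans_correlation(gen$profiles, 4, seed = 15, n_init = 10)
    adjusted_rand_index(fit$labels, gen$labels)
  }, numeric(1))
  expect_true(all(diff(ari) <= 0))
  expect_gte(ari[1], 0.9)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(16)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})
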