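test_that("relative contributions are simple ratios on the simplex", {
  expect_equal(unname(relative_contributions(5, 5, 5)[1, ]), rep(1 / 3, 3))
  expect_equal(unname(relative_contributions(2, 0, 0)[1, ]), c(1, 0, 0))
  expect_equal(unname(relative_contributions(6, 2, 2)[1, ]), c(0.6, 0.2, 0.2))
  expect_error(relative_contributions(0, 0, 0), "zero total")
  expect_error(relative_contributions(-1, 1, 1), "nonnegative")
})

test_that("centroid classification matches hand-worked cases", {
  expect_equal(classify_triad(c(1, 1, 1) / 3),
               data.frame(category = "Balance", distance = 0))
  expect_equal(classify_triad(c(0.5, 0.5, 0)),
               data.frame(category = "D suppressed", distance = 0))
  # (0.6, 0.2, 0.2): distance to the balanced centroid
  # sqrt(0.2667^2 + 2 * 0.1333^2) ~ 0.327 beats all others
  res <- classify_triad(c(0.6, 0.2, 0.2))
  expect_equal(res$category, "Balance")
  expect_equal(res$distance, sqrt(sum((c(0.6, 0.2, 0.2) - 1 / 3)^2)))
  expect_equal(round(res$distance, 3), 0.327)
  expect_error(classify_triad(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("classification agrees with the brute-force nearest-centroid oracle", {
  set.seed(42)
  f <- runif_simplex(2000)
  got <- classify_triad(f)
  want <- apply(f, 1, oracle_nearest_centroid)
  expect_identical(got$category, vapply(want, `[[`, character(1), "category"))
  expect_equal(got$distance, vapply(want, `[[`, numeric(1), "distance"))
})

test_that("ternary coordinates map vertices and centroid correctly", {
  expect_equal(unname(ternary_coordinates(c(1, 0, 0))[1, ]), c(0, 0))
  expect_equal(unname(ternary_coordinates(c(0, 1, 0))[1, ]), c(1, 0))
  expect_equal(unname(ternary_coordinates(c(0, 0, 1))[1, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(ternary_coordinates(c(1, 1, 1) / 3)[1, ]),
               c(0.5, sqrt(3) / 6))
  expect_error(ternary_coordinates(c(0.7, 0.2, 0.2)), "simplex")
})

make_triad_fpkm <- function(abd, timepoints = "0", n_replicates = 2) {
  # abd: n x 3 matrix of per-homoeolog replicate-mean FPKM (same all tps)
  n <- nrow(abd)
  triads <- data.frame(
    triad_id = paste0("tr", seq_len(n)),
    gene_A = paste0("tr", seq_len(n), ".A"),
    gene_B = paste0("tr", seq_len(n), ".B"),
    gene_D = paste0("tr", seq_len(n), ".D"),
    stringsAsFactors = FALSE
  )
  samples <- make_samples(timepoints, n_replicates)
  vals <- as.vector(t(abd))
  fk <- matrix(rep(vals, nrow(samples)), length(vals), nrow(samples),
               dimnames = list(
                 as.vector(t(as.matrix(triads[, 2:4]))), samples$sample_id))
  list(fpkm = fk, triads = triads, samples = samples)
}

test_that("classify_all gates by the Low rule and classifies the rest", {
  d <- make_triad_fpkm(rbind(c(0.2, 0.3, 0.4), c(10, 10, 10), c(8, 1, 1)))
  asn <- classify_all(d$fpkm, d$triads, d$samples, threshold = 1.0)
  expect_equal(asn$category, c("Low", "Balance", "A dominant"))
  expect_true(is.na(asn$fA[1]) && is.na(asn$distance[1]))
  expect_equal(asn$total_fpkm, c(0.9, 30, 10))
  # the boundary value (sum exactly at the threshold) belongs to Low
  d2 <- make_triad_fpkm(rbind(c(0.5, 0.3, 0.2)))
  expect_equal(classify_all(d2$fpkm, d2$triads, d2$samples)$category, "Low")
  # a missing homoeolog is reported with its triad
  d$triads$gene_B[2] <- "absent"
  expect_error(classify_all(d$fpkm, d$triads, d$samples), "tr2")
})

test_that("subgenome permutation of the input permutes the calls", {
  set.seed(7)
  f <- runif_simplex(500)
  base <- make_triad_fpkm(f * 50)
  ref <- classify_all(base$fpkm, base$triads, base$samples)$category
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  subg <- c("A", "B", "D")
  for (pm in perms) {
    # homoeolog columns permuted: position i now holds subgenome subg[pm[i]]
    d2 <- make_triad_fpkm(f[, pm] * 50)
    got <- classify_all(d2$fpkm, d2$triads, d2$samples)$category
    relabel <- ref
    for (i in 1:3) {
      from <- subg[pm[i]]
      to <- subg[i]
      relabel[ref == paste(from, "dominant")] <- paste(to, "dominant")
      relabel[ref == paste(from, "suppressed")] <- paste(to, "suppressed")
    }
    expect_identical(got, relabel)
  }
})

test_that("transition tables conserve marginals and detect planted switches", {
  # 10 triads, 2 time points: 3 planted switches, rest stay
  cat_t1 <- c(rep("Balance", 6), "A dominant", "A dominant",
              "D suppressed", "Low")
  cat_t2 <- cat_t1
  cat_t2[c(1, 7, 9)] <- c("B suppressed", "Balance", "Low")
  asn <- data.frame(
    triad_id = rep(paste0("tr", 1:10), 2),
    timepoint = rep(c("0", "2"), each = 10),
    category = c(cat_t1, cat_t2),
    stringsAsFactors = FALSE
  )
  tr <- transitions(asn)
  tab <- tr$tables[["0_to_2"]]
  expect_equal(rowSums(tab), table(factor(cat_t1, bias_categories()))[bias_categories()],
               ignore_attr = TRUE)
  expect_equal(colSums(tab), table(factor(cat_t2, bias_categories()))[bias_categories()],
               ignore_attr = TRUE)
  expect_equal(sum(tab) - sum(diag(tab)), 3)
  expect_equal(sum(tab), 10)
  # all triads in one category: a single nonzero diagonal cell
  asn2 <- asn
  asn2$category <- "Balance"
  tab2 <- transitions(asn2)$tables[["0_to_2"]]
  expect_equal(tab2["Balance", "Balance"], 10)
  expect_equal(sum(tab2), 10)
  # inconsistent triad sets are rejected
  expect_error(transitions(asn[-1, ]), "identical triad sets")
})

test_that("category proportions sum to one per time point", {
  d <- make_triad_fpkm(rbind(c(0.2, 0.3, 0.4), c(10, 10, 10), c(8, 1, 1),
                             c(1, 9, 10)))
  asn <- classify_all(d$fpkm, d$triads, d$samples)
  pr <- category_proportions(asn, include_low = TRUE)
  expect_equal(sum(pr$proportion), 1)
  expect_equal(sum(pr$n), 4)
  pr2 <- category_proportions(asn, include_low = FALSE)
  expect_equal(sum(pr2$proportion), 1)
  expect_equal(sum(pr2$n), 3)
  expect_false("Low" %in% pr2$category)
})
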