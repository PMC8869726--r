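# Independent brute-force oracles used to verify the implementation.
# These deliberately re-derive each quantity from its definition and share
# no code with the package internals.

# nearest-centroid classification by explicit loop over the seven ideal
# compositions, in the documented tie-break order
oracle_nearest_centroid <- function(f) {
  cen <- list(
    "Balance" = c(1, 1, 1) / 3,
    "A suppressed" = c(0, 0.5, 0.5),
    "B suppressed" = c(0.5, 0, 0.5),
    "D suppressed" = c(0.5, 0.5, 0),
    "A dominant" = c(1, 0, 0),
    "B dominant" = c(0, 1, 0),
    "D dominant" = c(0, 0, 1)
  )
  best <- names(cen)[1]
  best_d <- Inf
  for (nm in names(cen)) {
    d <- sqrt(sum((f - cen[[nm]])^2))
    if (d < best_d) { # strict <: first name wins ties
      best <- nm
      best_d <- d
    }
  }
  list(category = best, distance = best_d)
}

# one-sided hypergeometric upper tail by explicit binomial-coefficient sums
oracle_hyper_tail <- function(k, n, K, N) {
  j <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# silhouette from its a/b definition with correlation distance, double loop
oracle_silhouette <- function(profiles, labels) {
  n <- nrow(profiles)
  d <- function(i, j) 1 - cor(profiles[i, ], profiles[j, ])
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Spearman correlation as Pearson on hand-computed average ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# median-of-ratios size factors evaluated directly from the definition
oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  gm <- apply(counts[keep, , drop = FALSE], 1, function(x) exp(mean(log(x))))
  apply(counts[keep, , drop = FALSE], 2, function(col) median(col / gm))
}

# uniform draws on the 2-simplex (Dirichlet(1,1,1))
runif_simplex <- function(n) {
  g <- matrix(-log(runif(n * 3)), n, 3)
  g / rowSums(g)
}

# sample metadata for a toy design
make_samples <- function(timepoints, n_replicates = 3) {
  data.frame(
    sample_id = paste0("T", rep(timepoints, each = n_replicates),
                       "_R", rep(seq_len(n_replicates), length(timepoints))),
    timepoint = as.character(rep(timepoints, each = n_replicates)),
    replicate = rep(seq_len(n_replicates), length(timepoints)),
    stringsAsFactors = FALSE
  )
}

# genes x samples matrix of planted template profiles plus gaussian noise,
# replicated per sample; used as known-structure clustering input
make_template_profiles <- function(n_genes, n_templates, n_timepoints,
                                   noise_sd, seed) {
  set.seed(seed)
  templ <- cluster_templates(n_timepoints, n_templates)
  lab <- rep_len(seq_len(n_templates), n_genes)
  x <- templ[lab, , drop = FALSE] +
    matrix(rnorm(n_genes * n_timepoints, sd = noise_sd), n_genes)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  rownames(x) <- paste0("g", seq_len(n_genes))
  list(profiles = x, labels = lab)
}
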