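#' Replicate-mean, z-scored temporal expression profiles
#'
#' Averages FPKM over replicates within each time point and z-scores each
#' gene's profile across time points (mean 0, unit variance). Genes with a
#' constant raw profile cannot be z-scored and are dropped with a message;
#' their ids are attached as attribute `"dropped"`.
#'
#' On z-scored rows of length T, squared Euclidean distance equals
#' `2 * T * (1 - Pearson r)`, so k-means on these profiles is k-means
#' under Pearson-correlation distance.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param samples Sample metadata (`sample_id`, `timepoint`, `replicate`).
#' @param genes Optional gene-id subset (e.g. the DEG union).
#' @return Matrix of z-scored profiles, genes x time points.
#' @export
temporal_profiles <- function(fpkm, samples, genes = NULL) {
  check_samples(samples)
  if (!is.null(genes)) fpkm <- fpkm[intersect(genes, rownames(fpkm)), ,
                                    drop = FALSE]
  tps <- timepoint_levels(samples$timepoint)
  prof <- sapply(tps, function(tp) {
    cols <- samples$sample_id[as.character(samples$timepoint) == tp]
    rowMeans(fpkm[, cols, drop = FALSE])
  })
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = nrow(fpkm),
                                         dimnames = list(rownames(fpkm), tps))
  mu <- rowMeans(prof)
  s <- apply(prof, 1, sd)
  constant <- s == 0 | !is.finite(s)
  if (any(constant)) {
    message("dropping ", sum(constant), " gene(s) with constant profiles")
  }
  z <- (prof[!constant, , drop = FALSE] - mu[!constant]) / s[!constant]
  attr(z, "dropped") <- rownames(prof)[constant]
  z
}

#' Library of planted temporal template shapes
#'
#' Fixed set of unimodal / monotone profile shapes over the time course
#' (early-high, late-high, mid-peak, mid-valley, second-point peak,
#' penultimate peak, ...), z-scored per row. Used by the synthetic-data
#' generator to plant recoverable co-expression structure and by tests as
#' known cluster prototypes.
#'
#' @param n_timepoints Number of time points T (>= 3).
#' @param n_templates How many templates to return (1 to 8).
#' @return Matrix, `n_templates` x T, rows z-scored.
#' @export
cluster_templates <- function(n_timepoints, n_templates = 4) {
  if (n_timepoints < 3) stop("templates need at least 3 time points")
  if (n_templates < 1 || n_templates > 8) stop("n_templates must be in 1..8")
  t <- seq(0, 1, length.out = n_timepoints)
  shapes <- rbind(
    early_high = 1 - t,
    late_high = t,
    mid_peak = exp(-((t - 0.5) / 0.25)^2),
    mid_valley = -exp(-((t - 0.5) / 0.25)^2),
    second_peak = exp(-((t - 1 / (n_timepoints - 1)) / 0.2)^2),
    penultimate_peak = exp(-((t - (n_timepoints - 2) / (n_timepoints - 1)) / 0.2)^2),
    early_shoulder = 1 / (1 + exp(15 * (t - 0.33))),
    late_shoulder = 1 / (1 + exp(-15 * (t - 0.67)))
  )
  shapes <- shapes[seq_len(n_templates), , drop = FALSE]
  mu <- rowMeans(shapes)
  s <- apply(shapes, 1, sd)
  z <- (shapes - mu) / s
  colnames(z) <- NULL
  z
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to the squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      stop("fewer distinct profiles than clusters requested")
    }
    centers[j] <- sample.int(n, 1, prob = d2)
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering under Pearson-correlation distance
#'
#' Clusters z-scored temporal profiles. Because rows are z-scored, squared
#' Euclidean distance is an affine function of 1 - Pearson r, so standard
#' Euclidean k-means minimizes the correlation-distance objective.
#' Initialization is k-means++ with `n_init` restarts; the restart with
#' the lowest within-cluster sum of squares wins. Deterministic given
#' `seed`.
#'
#' @param profiles Matrix of z-scored profiles (genes x time points), e.g.
#'   from [temporal_profiles()].
#' @param k Number of clusters (>= 2, <= number of profiles).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @return A list with `labels` (named integer vector, values 1..k),
#'   `centers` (k x T matrix), `tot_withinss`, and `k`.
#' @export
kmeans_correlation <- function(profiles, k, seed = 1, n_init = 25) {
  x <- as.matrix(profiles)
  if (k < 2) stop("k must be at least 2")
  if (nrow(x) < k) stop("fewer profiles (", nrow(x), ") than clusters (", k, ")")
  s <- apply(x, 1, sd)
  if (any(s == 0 | !is.finite(s))) {
    stop("constant profile passed to clustering; z-score and filter first")
  }
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      cen <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        kmeans(x, centers = cen, iter.max = 100, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(
      labels = setNames(best$cluster, rownames(x)),
      centers = best$centers,
      tot_withinss = best$tot.withinss,
      k = k
    )
  })
}

#' Overall silhouette coefficient under correlation distance
#'
#' Standard silhouette: for gene i with within-cluster mean distance a(i)
#' and smallest mean distance to another cluster b(i),
#' `s(i) = (b - a) / max(a, b)`; genes in singleton clusters get s = 0, as
#' do degenerate genes with a = b = 0. Distances are Pearson-correlation
#' distances (1 - r) between profiles. The overall coefficient is the mean
#' over genes.
#'
#' @param profiles Matrix of profiles, genes x time points.
#' @param labels Cluster labels, one per profile row (>= 2 nonempty
#'   clusters).
#' @param dist_matrix Optional precomputed correlation-distance matrix
#'   (1 - cor of profiles), to amortize over repeated calls.
#' @return A list with `overall` (mean silhouette) and `per_gene` (named
#'   numeric vector).
#' @export
silhouette_overall <- function(profiles, labels, dist_matrix = NULL) {
  labels <- as.vector(labels)
  n <- if (is.null(dist_matrix)) nrow(profiles) else nrow(dist_matrix)
  if (length(labels) != n) stop("one label per profile required")
  ulab <- unique(labels)
  if (length(ulab) < 2) stop("silhouette requires at least 2 clusters")
  D <- if (is.null(dist_matrix)) 1 - cor(t(profiles)) else dist_matrix
  sizes <- table(labels)
  # mean distance from each gene to each cluster: n x n_clusters
  member <- outer(labels, ulab, "==") + 0
  sums <- D %*% member
  sil <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], ulab)
    ni <- sizes[[as.character(labels[i])]]
    if (ni <= 1) { sil[i] <- 0; next }
    a <- sums[i, ci] / (ni - 1) # exclude self (D[i,i] = 0)
    others <- setdiff(seq_along(ulab), ci)
    b <- min(sums[i, others] / as.numeric(sizes[as.character(ulab[others])]))
    m <- max(a, b)
    sil[i] <- if (m == 0) 0 else (b - a) / m
  }
  names(sil) <- if (is.null(dist_matrix)) rownames(profiles) else rownames(D)
  list(overall = mean(sil), per_gene = sil)
}

#' Select the number of clusters by the overall silhouette
#'
#' Runs [kmeans_correlation()] for every k in `k_range`, scores each
#' partition with [silhouette_overall()], and returns the k with the
#' highest overall silhouette (ties broken toward smaller k).
#'
#' @inheritParams kmeans_correlation
#' @param k_range Integer vector of candidate k values, each within
#'   `[2, nrow(profiles) - 1]`.
#' @return A list with `best_k`, `table` (data.frame `k`,
#'   `silhouette`), and `assignment` (the [kmeans_correlation()] result at
#'   `best_k`).
#' @export
select_k <- function(profiles, k_range = 2:15, seed = 1, n_init = 25) {
  if (!length(k_range)) stop("k_range must not be empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(profiles) - 1) {
    stop("k_range must lie within [2, n_profiles - 1]")
  }
  D <- 1 - cor(t(profiles))
  fits <- vector("list", length(k_range))
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- kmeans_correlation(profiles, k_range[i],
                                    seed = derive_seed(seed, paste0("k", k_range[i])),
                                    n_init = n_init)
    sil[i] <- silhouette_overall(profiles, fits[[i]]$labels,
                                 dist_matrix = D)$overall
  }
  best <- which.max(sil) # first maximum == smallest k on ties
  list(
    best_k = k_range[best],
    table = data.frame(k = k_range, silhouette = sil),
    assignment = fits[[best]]
  )
}
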