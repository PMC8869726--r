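#' Homoeolog expression-bias categories and their ideal centroids
#'
#' An expressed wheat triad (one homoeolog from each of the A, B, and D
#' subgenomes) is classified by comparing its relative expression fractions
#' (fA, fB, fD) against seven ideal compositions: balanced expression,
#' single-homoeolog dominance (one homoeolog carries all expression), and
#' single-homoeolog suppression (one homoeolog silent, the other two equal).
#' A triad is assigned to the category whose centroid is nearest in
#' Euclidean distance.
#'
#' The row order of the centroid matrix is the deterministic tie-break
#' order used by [classify_triad()]: Balance first, then the suppressed
#' categories (A, B, D), then the dominant categories (A, B, D). Ties can
#' only occur on a measure-zero set of compositions; breaking toward
#' Balance is conservative against over-calling bias.
#'
#' @return A 7 x 3 numeric matrix; rows are categories (in tie-break
#'   order), columns are the A, B, D fractions. Each row sums to 1.
#' @examples
#' bias_centroids()
#' @export
bias_centroids <- function() {
  m <- rbind(
    "Balance"      = c(1 / 3, 1 / 3, 1 / 3),
    "A suppressed" = c(0, 1 / 2, 1 / 2),
    "B suppressed" = c(1 / 2, 0, 1 / 2),
    "D suppressed" = c(1 / 2, 1 / 2, 0),
    "A dominant"   = c(1, 0, 0),
    "B dominant"   = c(0, 1, 0),
    "D dominant"   = c(0, 0, 1)
  )
  colnames(m) <- c("A", "B", "D")
  m
}

#' All bias category labels, including the low-expression state
#'
#' Categories in canonical reporting order: Balance, the three dominant,
#' the three suppressed, and "Low" for triads whose summed FPKM does not
#' exceed the expressed threshold.
#'
#' @return Character vector of length 8.
#' @export
bias_categories <- function() {
  c("Balance", "A dominant", "B dominant", "D dominant",
    "A suppressed", "B suppressed", "D suppressed", "Low")
}

#' Relative contribution of each homoeolog to triad expression
#'
#' @param fpkm_a,fpkm_b,fpkm_d Nonnegative FPKM values (vectors of equal
#'   length) for the A, B, and D homoeologs.
#' @return A matrix with columns fA, fB, fD summing to 1 per row.
#' @examples
#' relative_contributions(6, 2, 2)
#' @export
relative_contributions <- function(fpkm_a, fpkm_b, fpkm_d) {
  x <- cbind(fA = fpkm_a, fB = fpkm_b, fD = fpkm_d)
  if (any(x < 0)) stop("FPKM values must be nonnegative")
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    stop("triad with zero total expression; gate by the Low rule first")
  }
  x / tot
}

#' Classify triad compositions by nearest bias centroid
#'
#' Assigns each composition on the 2-simplex to the bias category whose
#' ideal centroid (see [bias_centroids()]) is nearest in Euclidean
#' distance. Ties are broken deterministically in centroid row order.
#'
#' @param fractions Numeric vector of length 3 (fA, fB, fD) or a matrix
#'   with 3 columns; each row must sum to 1 within `tol`.
#' @param centroids Centroid matrix as returned by [bias_centroids()].
#' @param tol Tolerance on the simplex constraint.
#' @return A data.frame with columns `category` and `distance` (one row
#'   per input composition).
#' @examples
#' classify_triad(c(0.6, 0.2, 0.2))
#' @export
classify_triad <- function(fractions, centroids = bias_centroids(),
                           tol = 1e-6) {
  f <- if (is.null(dim(fractions))) matrix(fractions, nrow = 1)
       else as.matrix(fractions)
  if (ncol(f) != 3) stop("fractions must have three components (fA, fB, fD)")
  if (any(abs(rowSums(f) - 1) > tol)) {
    stop("fractions must sum to 1 within tolerance ", tol)
  }
  # squared distances to each centroid: n x 7
  d2 <- outer(rowSums(f^2), rep(1, nrow(centroids))) -
    2 * f %*% t(centroids) +
    outer(rep(1, nrow(f)), rowSums(centroids^2))
  idx <- apply(d2, 1, which.min) # which.min takes the first == tie-break order
  data.frame(
    category = rownames(centroids)[idx],
    distance = sqrt(pmax(d2[cbind(seq_len(nrow(f)), idx)], 0)),
    stringsAsFactors = FALSE
  )
}

#' Map simplex compositions to ternary plot coordinates
#'
#' Standard barycentric-to-Cartesian map with the A vertex at the origin,
#' B at (1, 0), and D at (1/2, sqrt(3)/2): `x = fB + fD/2`,
#' `y = sqrt(3)/2 * fD`. Invertible on the simplex.
#'
#' @inheritParams classify_triad
#' @return A matrix with columns `x` and `y`.
#' @examples
#' ternary_coordinates(c(1 / 3, 1 / 3, 1 / 3))
#' @export
ternary_coordinates <- function(fractions, tol = 1e-6) {
  f <- if (is.null(dim(fractions))) matrix(fractions, nrow = 1)
       else as.matrix(fractions)
  if (ncol(f) != 3) stop("fractions must have three components")
  if (any(f < -tol) || any(abs(rowSums(f) - 1) > tol)) {
    stop("fractions must lie on the simplex")
  }
  cbind(x = f[, 2] + f[, 3] / 2, y = sqrt(3) / 2 * f[, 3])
}

#' Classify every triad at every time point
#'
#' Computes replicate-mean FPKM per homoeolog per time point, gates triads
#' by the expressed rule (summed FPKM of the three homoeologs must exceed
#' `threshold`, otherwise the triad is in the "Low" state at that time
#' point), and classifies expressed triads by nearest bias centroid.
#'
#' @param fpkm FPKM matrix, genes x samples (rownames are gene ids).
#' @param triads data.frame with columns `triad_id`, `gene_A`, `gene_B`,
#'   `gene_D`.
#' @param samples Sample metadata with columns `sample_id`, `timepoint`,
#'   `replicate`.
#' @param threshold Low-expression gate on the summed FPKM; the boundary
#'   value itself (sum equal to `threshold`) is assigned to Low, the
#'   complement of the strict "expressed when sum > threshold" rule.
#' @return A data.frame with one row per triad x time point: `triad_id`,
#'   `timepoint`, `total_fpkm`, `fA`, `fB`, `fD` (NA for Low),
#'   `category`, `distance` (NA for Low).
#' @seealso [category_proportions()], [transitions()]
#' @export
classify_all <- function(fpkm, triads, samples, threshold = 1.0) {
  check_samples(samples)
  req <- c("triad_id", "gene_A", "gene_B", "gene_D")
  if (!all(req %in% names(triads))) {
    stop("triads must have columns ", paste(req, collapse = ", "))
  }
  genes <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  missing <- setdiff(genes, rownames(fpkm))
  if (length(missing)) {
    bad <- triads$triad_id[triads$gene_A %in% missing |
                           triads$gene_B %in% missing |
                           triads$gene_D %in% missing]
    stop("triad(s) with members missing from the FPKM matrix: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tps <- timepoint_levels(samples$timepoint)
  # replicate-mean FPKM per gene per time point
  tp_mean <- sapply(tps, function(tp) {
    cols <- samples$sample_id[as.character(samples$timepoint) == tp]
    rowMeans(fpkm[, cols, drop = FALSE])
  })
  if (is.null(dim(tp_mean))) tp_mean <- matrix(tp_mean, nrow = nrow(fpkm),
                                               dimnames = list(rownames(fpkm), tps))
  out <- vector("list", length(tps))
  for (j in seq_along(tps)) {
    a <- tp_mean[triads$gene_A, j]
    b <- tp_mean[triads$gene_B, j]
    d <- tp_mean[triads$gene_D, j]
    total <- a + b + d
    expressed <- total > threshold
    res <- data.frame(
      triad_id = triads$triad_id, timepoint = tps[j],
      total_fpkm = total,
      fA = NA_real_, fB = NA_real_, fD = NA_real_,
      category = "Low", distance = NA_real_,
      stringsAsFactors = FALSE
    )
    if (any(expressed)) {
      fr <- relative_contributions(a[expressed], b[expressed], d[expressed])
      cls <- classify_triad(fr)
      res$fA[expressed] <- fr[, "fA"]
      res$fB[expressed] <- fr[, "fB"]
      res$fD[expressed] <- fr[, "fD"]
      res$category[expressed] <- cls$category
      res$distance[expressed] <- cls$distance
    }
    out[[j]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-time-point bias category proportions
#'
#' @param assignments Output of [classify_all()].
#' @param include_low Include the Low state in the denominator (`TRUE`) or
#'   report proportions among expressed triads only (`FALSE`).
#' @return A data.frame `timepoint` x `category` long table with columns
#'   `timepoint`, `category`, `n`, `proportion`. Proportions sum to 1 per
#'   time point.
#' @export
category_proportions <- function(assignments, include_low = TRUE) {
  a <- assignments
  if (!include_low) a <- a[a$category != "Low", , drop = FALSE]
  cats <- bias_categories()
  if (!include_low) cats <- setdiff(cats, "Low")
  tps <- timepoint_levels(a$timepoint)
  grid <- expand.grid(timepoint = tps, category = cats,
                      stringsAsFactors = FALSE)
  tab <- table(factor(a$timepoint, tps), factor(a$category, cats))
  grid$n <- as.vector(tab)
  tot <- rowSums(tab)
  grid$proportion <- as.vector(tab / ifelse(tot == 0, 1, tot))
  grid[order(match(grid$timepoint, tps), match(grid$category, cats)), ,
       drop = FALSE]
}

#' Category transitions between adjacent time points
#'
#' Builds, for every adjacent time-point pair, the 8 x 8 table counting
#' triads that move from category i to category j (the Low state is a
#' first-class category here), plus a stability summary: per category, the
#' fraction of triads in that category at a time point that remain in it
#' at the next one, and aggregate retention for the Balance, any-dominant,
#' and any-suppressed groups across the whole series.
#'
#' @param assignments Output of [classify_all()]; every time point must
#'   cover the identical triad set.
#' @return A list with `tables` (named list of 8 x 8 matrices, one per
#'   adjacent pair, named "<t1>_to_<t2>"), `stability` (data.frame with
#'   per-category retention per adjacent pair), and `group_stability`
#'   (data.frame with aggregate retention for Balance / dominant /
#'   suppressed / Low over all adjacent pairs; `retained_group` is the
#'   fraction staying within the group, `retained_category` the fraction
#'   staying in exactly the same category).
#' @export
transitions <- function(assignments) {
  cats <- bias_categories()
  tps <- timepoint_levels(assignments$timepoint)
  if (length(tps) < 2) stop("need at least two time points")
  by_tp <- split(assignments, factor(assignments$timepoint, tps))
  ids <- sort(by_tp[[1]]$triad_id)
  for (x in by_tp) {
    if (!identical(sort(x$triad_id), ids)) {
      stop("assignments must cover identical triad sets at all time points")
    }
  }
  cat_mat <- sapply(by_tp, function(x) x$category[match(ids, x$triad_id)])
  tables <- list()
  stab <- list()
  for (j in seq_len(length(tps) - 1)) {
    tab <- table(factor(cat_mat[, j], cats), factor(cat_mat[, j + 1], cats))
    nm <- paste0(tps[j], "_to_", tps[j + 1])
    tables[[nm]] <- unclass(as.matrix(tab))
    rs <- rowSums(tab)
    stab[[nm]] <- data.frame(
      from = tps[j], to = tps[j + 1], category = cats,
      n = as.vector(rs),
      retained = ifelse(rs > 0, diag(as.matrix(tab)) / rs, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  stability <- do.call(rbind, stab)
  rownames(stability) <- NULL

  groups <- list(
    Balance = "Balance",
    dominant = c("A dominant", "B dominant", "D dominant"),
    suppressed = c("A suppressed", "B suppressed", "D suppressed"),
    Low = "Low"
  )
  group_stability <- do.call(rbind, lapply(names(groups), function(g) {
    members <- groups[[g]]
    n_from <- 0; n_group <- 0; n_same <- 0
    for (tab in tables) {
      n_from <- n_from + sum(tab[members, , drop = FALSE])
      n_group <- n_group + sum(tab[members, members, drop = FALSE])
      n_same <- n_same + sum(diag(tab)[members])
    }
    data.frame(group = g, n = n_from,
               retained_group = if (n_from > 0) n_group / n_from else NA_real_,
               retained_category = if (n_from > 0) n_same / n_from else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(tables = tables, stability = stability,
       group_stability = group_stability)
}
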