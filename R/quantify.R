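#' Normalize read counts to FPKM
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length_bp[g] * total[s])` where
#' `total[s]` is the summed counts of sample s.
#'
#' @param counts Integer count matrix, genes x samples, rownames gene ids.
#' @param lengths Named numeric vector of transcript lengths in bp; must
#'   cover every gene in `counts` with positive values.
#' @return FPKM matrix with the same dimensions and dimnames.
#' @examples
#' cnt <- matrix(c(10, 90), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' fpkm(cnt * 1e5, c(g1 = 1000, g2 = 1000))
#' @export
fpkm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("missing gene length for: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0 | !is.finite(len))) {
    bad <- rownames(counts)[len <= 0 | !is.finite(len)]
    stop("non-positive gene length for: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  sweep(counts / len, 2, totals, "/") * 1e9
}

#' Expressed-gene sets per time point and overall
#'
#' A gene is expressed at a time point when its mean FPKM across that time
#' point's replicates strictly exceeds `threshold`, and expressed overall
#' when expressed at one or more time points.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param samples Sample metadata (`sample_id`, `timepoint`, `replicate`).
#' @param threshold Expression threshold on the replicate-mean FPKM
#'   (strict `>`).
#' @return A list with `per_timepoint` (named list of gene-id vectors),
#'   `overall` (gene-id vector), and `counts` (data.frame of set sizes).
#' @export
expressed_genes <- function(fpkm, samples, threshold = 1.0) {
  check_samples(samples)
  if (!all(samples$sample_id %in% colnames(fpkm))) {
    stop("sample metadata names samples absent from the FPKM matrix")
  }
  tps <- timepoint_levels(samples$timepoint)
  per_tp <- lapply(tps, function(tp) {
    cols <- samples$sample_id[as.character(samples$timepoint) == tp]
    m <- rowMeans(fpkm[, cols, drop = FALSE])
    rownames(fpkm)[m > threshold]
  })
  names(per_tp) <- tps
  overall <- unique(unlist(per_tp, use.names = FALSE))
  list(
    per_timepoint = per_tp,
    overall = overall,
    counts = data.frame(
      timepoint = c(tps, "overall"),
      n_expressed = c(vapply(per_tp, length, integer(1)), length(overall)),
      stringsAsFactors = FALSE
    )
  )
}

#' Sample-level quality control
#'
#' Spearman correlation between all sample pairs, average-linkage
#' hierarchical clustering on the correlation distance (1 - SCC), and a
#' PCA of samples on log2(FPKM + 1) with genes as features.
#'
#' @param fpkm FPKM matrix, genes x samples (at least 2 samples).
#' @return A list with `scc` (symmetric correlation matrix, unit
#'   diagonal), `hclust` (an `stats::hclust` object; `$merge` is the merge
#'   list), `pca` (data.frame `sample_id`, `PC1`, `PC2`), and
#'   `var_explained` (fractions of variance for PC1 and PC2).
#' @export
sample_qc <- function(fpkm) {
  if (ncol(fpkm) < 2) stop("sample QC requires at least 2 samples")
  scc <- cor(fpkm, method = "spearman")
  hc <- hclust(as.dist(1 - scc), method = "average")
  pc <- prcomp(t(log2(fpkm + 1)), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(2, ncol(pc$x))
  coords <- pc$x[, seq_len(n_pc), drop = FALSE]
  pca <- data.frame(sample_id = colnames(fpkm), coords,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(pca) <- NULL
  list(scc = scc, hclust = hc, pca = pca,
       var_explained = ve[seq_len(n_pc)])
}
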