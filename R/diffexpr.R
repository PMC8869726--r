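#' Median-of-ratios size factors
#'
#' Classic median-of-ratios library-size normalization: per gene, the
#' geometric mean of its counts over all samples (genes with any zero
#' count are excluded); per sample, the size factor is the median over
#' genes of `count / geometric mean`.
#'
#' @param counts Count matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in all samples; cannot estimate size factors")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geomean <- exp(rowMeans(lg))
  sf <- apply(counts[pos, , drop = FALSE] / geomean, 2, median)
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  sf
}

#' Negative-binomial Wald test between two time points
#'
#' Self-contained two-group test on size-factor-normalized counts. Per
#' gene, the log2 fold change is `log2((m2 + c) / (m1 + c))` for group
#' means m1 (earlier time point) and m2 (later), with pseudocount c.
#' Within-group variances are pooled across the two groups per gene and a
#' single common dispersion is estimated by averaging the per-gene
#' method-of-moments values `(s^2 - mean) / mean^2` over well-expressed
#' genes (pooled normalized mean > 1), floored at `alpha_min`. The Wald
#' statistic is `(log(m2 + c) - log(m1 + c)) / SE` with the delta-method
#' standard error from the NB variance `mu + alpha * mu^2`, referred to
#' the standard normal. Genes with all-zero counts in both groups get
#' `log2fc = 0, p = 1`.
#'
#' Pooling the dispersion across genes (rather than using each gene's own
#' 4-df moment estimate) is what keeps the test calibrated and powered at
#' 3 replicates per group; the per-gene estimate is far too noisy there.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample metadata (`sample_id`, `timepoint`, `replicate`).
#' @param contrast Character vector of length 2: (earlier, later) time
#'   point labels; each group needs at least 2 replicates.
#' @param sf Optional named size factors; estimated by [size_factors()]
#'   from the full matrix when `NULL`.
#' @param genes Optional gene-id subset to test (e.g. expressed genes).
#' @param pseudocount Pseudocount c on normalized group means.
#' @param alpha_min Floor on the common dispersion.
#' @return data.frame `gene_id`, `contrast` ("<later>_vs_<earlier>"),
#'   `base_mean`, `log2fc`, `p_raw`; the estimated common dispersion is
#'   attached as attribute `"dispersion"`.
#' @export
nb_wald_test <- function(counts, samples, contrast, sf = NULL, genes = NULL,
                         pseudocount = 0.5, alpha_min = 1e-4) {
  check_samples(samples)
  stopifnot(length(contrast) == 2)
  t1 <- as.character(contrast[1]); t2 <- as.character(contrast[2])
  s1 <- samples$sample_id[as.character(samples$timepoint) == t1]
  s2 <- samples$sample_id[as.character(samples$timepoint) == t2]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each group needs at least 2 replicates (", t1, ": ", length(s1),
         ", ", t2, ": ", length(s2), ")")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(genes)) genes <- rownames(counts)
  y <- sweep(counts[genes, c(s1, s2), drop = FALSE], 2,
             sf[c(s1, s2)], "/")
  i1 <- seq_along(s1); i2 <- length(s1) + seq_along(s2)
  n1 <- length(s1); n2 <- length(s2)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- apply(y[, i1, drop = FALSE], 1, var)
  v2 <- apply(y[, i2, drop = FALSE], 1, var)
  s2pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mbar <- (m1 + m2) / 2
  mom <- (s2pool - mbar) / mbar^2
  keep <- is.finite(mom) & mbar > 1
  alpha <- if (any(keep)) max(mean(mom[keep]), alpha_min) else alpha_min
  c0 <- pseudocount
  se <- sqrt((m1 + alpha * m1^2) / n1 / (m1 + c0)^2 +
             (m2 + alpha * m2^2) / n2 / (m2 + c0)^2)
  z <- (log(m2 + c0) - log(m1 + c0)) / se
  allzero <- m1 == 0 & m2 == 0
  z[allzero] <- 0
  p <- 2 * pnorm(-abs(z))
  p[allzero] <- 1
  res <- data.frame(
    gene_id = genes,
    contrast = paste0(t2, "_vs_", t1),
    base_mean = mbar,
    log2fc = ifelse(allzero, 0, log2((m2 + c0) / (m1 + c0))),
    p_raw = p,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "dispersion") <- alpha
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' and capping at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_raw, method = "BH")
}

#' Differential expression across all adjacent time-point contrasts
#'
#' Runs [nb_wald_test()] for every adjacent pair of time points (earlier
#' time point as control), adjusts p-values by Benjamini-Hochberg within
#' each contrast, and flags DEGs at the stated thresholds. When an FPKM
#' matrix is supplied, a gene is only tested for a contrast if it is
#' expressed (replicate-mean FPKM > `expressed_threshold`) at one or both
#' of the contrast's time points; untested genes do not enter the BH
#' denominator.
#'
#' @inheritParams nb_wald_test
#' @param fpkm Optional FPKM matrix used for the expressed-gene filter;
#'   `NULL` tests every gene.
#' @param expressed_threshold Replicate-mean FPKM threshold for the filter.
#' @param p_threshold Adjusted-p threshold (strict `<`).
#' @param lfc_threshold Absolute log2 fold-change threshold (`>=`).
#' @return data.frame `gene_id`, `contrast`, `base_mean`, `log2fc`,
#'   `p_raw`, `p_adj`, `is_deg` covering all tested gene x contrast pairs.
#' @export
run_de <- function(counts, samples, fpkm = NULL, expressed_threshold = 1.0,
                   p_threshold = 0.05, lfc_threshold = 1.0,
                   pseudocount = 0.5, alpha_min = 1e-4) {
  check_samples(samples)
  tps <- timepoint_levels(samples$timepoint)
  if (length(tps) < 2) stop("need at least two time points")
  sf <- size_factors(counts)
  expr <- if (!is.null(fpkm)) {
    expressed_genes(fpkm, samples, expressed_threshold)$per_timepoint
  }
  out <- vector("list", length(tps) - 1)
  for (j in seq_len(length(tps) - 1)) {
    genes <- if (is.null(expr)) rownames(counts) else {
      g <- union(expr[[tps[j]]], expr[[tps[j + 1]]])
      intersect(rownames(counts), g)
    }
    if (!length(genes)) next
    res <- nb_wald_test(counts, samples, c(tps[j], tps[j + 1]), sf = sf,
                        genes = genes, pseudocount = pseudocount,
                        alpha_min = alpha_min)
    res$p_adj <- bh_adjust(res$p_raw)
    res$is_deg <- res$p_adj < p_threshold & abs(res$log2fc) >= lfc_threshold
    out[[j]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' DEG sets per contrast and their union
#'
#' Applies the DEG rule (adjusted p strictly below `p_threshold` and
#' absolute log2 fold change at least `lfc_threshold`) to a table of test
#' results and summarizes per-contrast and union counts.
#'
#' @param results data.frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `p_adj` (e.g. from [run_de()]).
#' @inheritParams run_de
#' @return A list with `per_contrast` (named list of DEG gene-id vectors),
#'   `union` (gene-id vector), and `counts` (data.frame of set sizes).
#' @export
call_degs <- function(results, p_threshold = 0.05, lfc_threshold = 1.0) {
  req <- c("gene_id", "contrast", "log2fc", "p_adj")
  if (!all(req %in% names(results))) {
    stop("results must have columns ", paste(req, collapse = ", "))
  }
  hit <- results$p_adj < p_threshold & abs(results$log2fc) >= lfc_threshold
  contrasts <- unique(results$contrast)
  per <- lapply(contrasts, function(cn) {
    results$gene_id[hit & results$contrast == cn]
  })
  names(per) <- contrasts
  uni <- unique(unlist(per, use.names = FALSE))
  list(
    per_contrast = per,
    union = uni,
    counts = data.frame(
      contrast = c(contrasts, "union"),
      n_deg = c(vapply(per, length, integer(1)), length(uni)),
      stringsAsFactors = FALSE
    )
  )
}
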