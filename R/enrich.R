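#' Fisher's exact test term over-representation
#'
#' For every (member set, term) pair, tests whether genes carrying the
#' term are over-represented in the set relative to the background, with a
#' one-sided (greater) Fisher's exact test on the 2 x 2 table
#' `[[k, n - k], [K - k, N - n - K + k]]` where k = set members with the
#' term, n = set size, K = background genes with the term, N = background
#' size. The reported odds ratio is the sample odds ratio with a Haldane
#' 0.5 correction applied when any cell is zero. No multiple-testing
#' correction is applied by default, matching the raw-p thresholds used
#' for TF-family (0.01) and pathway (0.05) enrichment; set `adjust = TRUE`
#' for Benjamini-Hochberg adjustment across all tests.
#'
#' @param member_sets Named list of gene-id vectors (e.g. co-expression
#'   clusters or bias categories); every member must be in `background`.
#' @param annotation data.frame with columns `gene_id`, `term_id`; rows
#'   for genes outside the background are ignored.
#' @param background Character vector of background gene ids.
#' @param alpha Significance threshold on the (possibly adjusted) p-value.
#' @param adjust Apply BH adjustment across all (set, term) tests.
#' @return data.frame with one row per (set, term): `set`, `term_id`, `k`,
#'   `n`, `K`, `N`, `odds_ratio`, `p`, (`p_adj` when `adjust`), and
#'   `significant`.
#' @export
fisher_enrichment <- function(member_sets, annotation, background,
                              alpha = 0.05, adjust = FALSE) {
  background <- unique(background)
  N <- length(background)
  if (N == 0) stop("background is empty")
  if (is.null(names(member_sets)) || any(names(member_sets) == "")) {
    stop("member_sets must be a named list")
  }
  outside <- setdiff(unique(unlist(member_sets, use.names = FALSE)), background)
  if (length(outside)) {
    stop("member gene(s) outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(ann$term_id))
  term_genes <- split(ann$gene_id, ann$term_id)
  rows <- list()
  for (set_name in names(member_sets)) {
    members <- unique(member_sets[[set_name]])
    n <- length(members)
    for (tm in terms) {
      tg <- unique(term_genes[[tm]])
      K <- length(tg)
      k <- length(intersect(members, tg))
      tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2, 2)
      p <- fisher.test(tab, alternative = "greater")$p.value
      ct <- if (any(tab == 0)) tab + 0.5 else tab
      or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
      rows[[length(rows) + 1]] <- data.frame(
        set = set_name, term_id = tm, k = k, n = n, K = K, N = N,
        odds_ratio = or, p = p, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (adjust) {
    res$p_adj <- bh_adjust(res$p)
    res$significant <- res$p_adj < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res
}

#' Set-by-term matrix of -log10 enrichment p-values
#'
#' Rectangular, plot-ready export of [fisher_enrichment()] results:
#' `-log10(p)` per (set, term) cell with insignificant cells masked
#' (`NA`).
#'
#' @param results Output of [fisher_enrichment()].
#' @return Numeric matrix, sets x terms; masked cells are `NA`.
#' @export
enrichment_matrix <- function(results) {
  req <- c("set", "term_id", "p", "significant")
  if (!all(req %in% names(results))) {
    stop("results must have columns ", paste(req, collapse = ", "))
  }
  sets <- unique(results$set)
  terms <- unique(results$term_id)
  m <- matrix(NA_real_, length(sets), length(terms),
              dimnames = list(sets, terms))
  sig <- results[results$significant, , drop = FALSE]
  m[cbind(match(sig$set, sets), match(sig$term_id, terms))] <- -log10(sig$p)
  m
}
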