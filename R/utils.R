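#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own random substream
#' so that re-running one stage does not perturb the others. Substream seeds
#' are derived from the master seed and a purpose label by a Lehmer-style
#' multiplicative hash, and always fall in `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param purpose Character label naming the consumer of the substream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(purpose))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(seed) %% m
  for (code in utf8ToInt(purpose)) {
    h <- (h * 31 + code) %% m
  }
  # Lehmer step keeps nearby (seed, purpose) pairs well separated
  h <- (h * 48271) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted cluster or category structure. 1 means
#' identical partitions (up to label permutation), 0 is the expected value
#' for independent partitions.
#'
#' @param a,b Vectors of labels of equal length; `NA` pairs are dropped.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need at least two jointly labeled items")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# ---- TSV plumbing ---------------------------------------------------------
# All pipeline artifacts are plain TSV: header row, tab separator, UTF-8,
# '.' decimal, no quoting, no row names.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Matrix <-> TSV with an id column first.
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

# Order time point labels numerically when they all parse as numbers,
# otherwise by first appearance in the metadata.
timepoint_levels <- function(timepoints) {
  u <- unique(as.character(timepoints))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else u
}

check_samples <- function(samples) {
  req <- c("sample_id", "timepoint", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("sample metadata must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id values")
  invisible(samples)
}
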