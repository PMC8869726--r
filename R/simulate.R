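#' Configuration for the synthetic triad time-series generator
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults emulate a 6-time-point (0-10 days after pollination, step 2),
#' 3-replicate grain development design: the bias-category mix follows the
#' average expressed-triad shares reported for developing wheat grain
#' (72.13% balanced, 20.97% suppressed, 6.90% dominant) scaled by an 80%
#' expressed fraction (Low = 0.2), and per-category retention between
#' adjacent time points defaults to the reported values (balanced 0.7182,
#' dominant 0.2883, suppressed 0.2225; Low retention 0.8).
#'
#' @param n_triads Number of triads (3 genes each).
#' @param n_timepoints Number of time points (labels 0, 2, 4, ...).
#' @param n_replicates Replicates per time point.
#' @param category_mix Named proportions over the 8 categories of
#'   [bias_categories()] (7 expression categories plus "Low"); must sum
#'   to 1.
#' @param category_stay Per-category probability of keeping the same
#'   category at the next time point; scalar or named vector over the 8
#'   categories. 1 disables transitions. The pair (mix, stay) must be
#'   jointly feasible: no category may shed more probability per step than
#'   the others collectively absorb, i.e.
#'   `mix[i] * (1 - stay[i]) <= sum(mix[-i] * (1 - stay[-i]))`; otherwise
#'   no kernel with the requested stationary mix exists and the generator
#'   stops with an error.
#' @param bias_concentration Dirichlet concentration kappa around the
#'   category centroid; `Inf` plants exact centroids.
#' @param nb_dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param base_expression_log_mean,base_expression_log_sd Log-normal
#'   parameters (natural log) of the baseline triad total FPKM. Expressed
#'   triads are floored at 2 FPKM and Low triads drawn U(0.05, 0.8) so the
#'   planted Low/expressed truth keeps a guard band around the threshold.
#'   Expressed values are then rescaled per time point so the planted
#'   transcriptome mass `sum(FPKM * length)` is exactly 1e9, as the
#'   compositional FPKM definition requires of a complete gene set; the
#'   log-normal therefore sets relative, not absolute, expression.
#' @param library_size_range Per-sample library sizes, drawn log-uniformly
#'   within this (low, high) pair.
#' @param gene_length_range Per-gene transcript lengths (bp), uniform
#'   within this pair.
#' @param n_clusters_planted Number of temporal templates (see
#'   [cluster_templates()]) modulating triad totals; 0 plants flat
#'   profiles.
#' @param cluster_amplitude Amplitude (log2 fold units) of the template
#'   modulation.
#' @param de_fraction Fraction of triads planted differentially expressed
#'   at each adjacent boundary (all three homoeologs scaled together).
#' @param de_log2fc Planted absolute log2 fold change.
#' @param n_terms Number of annotation terms per annotation map.
#' @param enrichment_fold Fold over the base annotation rate at which
#'   planted terms occur in their target set.
#' @param term_base_rate Background probability that a gene carries a
#'   term.
#' @param seed Master seed; all stages draw from substreams derived from
#'   it.
#' @return A validated list of class `triadyn_config`.
#' @export
simulation_config <- function(n_triads = 2000,
                              n_timepoints = 6,
                              n_replicates = 3,
                              category_mix = NULL,
                              category_stay = NULL,
                              bias_concentration = 200,
                              nb_dispersion = 0.05,
                              base_expression_log_mean = 3,
                              base_expression_log_sd = 1,
                              library_size_range = c(2e7, 5e7),
                              gene_length_range = c(500, 3000),
                              n_clusters_planted = 4,
                              cluster_amplitude = 1,
                              de_fraction = 0.1,
                              de_log2fc = 2,
                              n_terms = 20,
                              enrichment_fold = 4,
                              term_base_rate = 0.02,
                              seed = 1) {
  cats <- bias_categories()
  if (is.null(category_mix)) {
    category_mix <- c(
      "Balance" = 0.7213 * 0.8,
      "A dominant" = 0.0690 / 3 * 0.8, "B dominant" = 0.0690 / 3 * 0.8,
      "D dominant" = 0.0690 / 3 * 0.8,
      "A suppressed" = 0.2097 / 3 * 0.8, "B suppressed" = 0.2097 / 3 * 0.8,
      "D suppressed" = 0.2097 / 3 * 0.8,
      "Low" = 0.2
    )
  }
  if (is.null(category_stay)) {
    category_stay <- c(
      "Balance" = 0.7182,
      "A dominant" = 0.2883, "B dominant" = 0.2883, "D dominant" = 0.2883,
      "A suppressed" = 0.2225, "B suppressed" = 0.2225, "D suppressed" = 0.2225,
      "Low" = 0.8
    )
  }
  if (length(category_stay) == 1) {
    category_stay <- setNames(rep(as.numeric(category_stay), 8), cats)
  }
  cfg <- list(
    n_triads = n_triads, n_timepoints = n_timepoints,
    n_replicates = n_replicates,
    category_mix = category_mix[cats], category_stay = category_stay[cats],
    bias_concentration = bias_concentration, nb_dispersion = nb_dispersion,
    base_expression_log_mean = base_expression_log_mean,
    base_expression_log_sd = base_expression_log_sd,
    library_size_range = library_size_range,
    gene_length_range = gene_length_range,
    n_clusters_planted = n_clusters_planted,
    cluster_amplitude = cluster_amplitude,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    n_terms = n_terms, enrichment_fold = enrichment_fold,
    term_base_rate = term_base_rate, seed = seed
  )
  names(cfg$category_mix) <- cats
  names(cfg$category_stay) <- cats
  validate_config(cfg)
  class(cfg) <- "triadyn_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_triads >= 0, n_timepoints >= 1, n_replicates >= 1,
      length(category_mix) == 8, !anyNA(category_mix),
      all(category_mix >= 0 & category_mix <= 1),
      length(category_stay) == 8, !anyNA(category_stay),
      all(category_stay >= 0 & category_stay <= 1),
      bias_concentration > 0,
      nb_dispersion >= 0,
      base_expression_log_sd >= 0,
      length(library_size_range) == 2,
      library_size_range[1] > 0, library_size_range[1] <= library_size_range[2],
      length(gene_length_range) == 2,
      gene_length_range[1] > 0, gene_length_range[1] <= gene_length_range[2],
      n_clusters_planted >= 0, n_clusters_planted <= 8,
      cluster_amplitude >= 0,
      de_fraction >= 0, de_fraction < 1, de_log2fc > 0,
      n_terms >= 1, enrichment_fold >= 1,
      term_base_rate > 0, term_base_rate <= 1
    )
    if (abs(sum(category_mix) - 1) > 1e-9) {
      stop("category_mix must sum to 1 (within 1e-9)")
    }
  })
  invisible(cfg)
}

#' Draw homoeolog fractions around a bias-category centroid
#'
#' Samples compositions from a Dirichlet distribution whose mean is the
#' category's ideal centroid, with concentration `kappa` controlling the
#' spread (larger = tighter). Centroid components that are exactly zero
#' are replaced by epsilon = 1e-3 (then renormalized) so every Dirichlet
#' parameter is strictly positive; `kappa = Inf` returns the (epsilon-free)
#' centroid exactly.
#'
#' @param category One of the seven expression categories (not "Low").
#' @param kappa Positive concentration; may be `Inf`.
#' @param n Number of draws.
#' @return An `n` x 3 matrix of (fA, fB, fD) rows summing to 1.
#' @export
simulate_category_fractions <- function(category, kappa, n = 1) {
  cen <- bias_centroids()
  if (length(category) != 1 || !category %in% rownames(cen)) {
    stop("unknown bias category: ", paste(category, collapse = ", "))
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa <= 0) {
    stop("kappa must be a positive real")
  }
  target <- cen[category, ]
  if (is.infinite(kappa)) {
    out <- matrix(target, n, 3, byrow = TRUE)
    colnames(out) <- c("fA", "fB", "fD")
    return(out)
  }
  eps <- 1e-3
  mean_dir <- pmax(target, eps)
  mean_dir <- mean_dir / sum(mean_dir)
  a <- kappa * mean_dir
  g <- matrix(rgamma(n * 3, shape = rep(a, each = n)), n, 3)
  out <- g / rowSums(g)
  colnames(out) <- c("fA", "fB", "fD")
  out
}

#' Draw a negative-binomial read count from an FPKM mean
#'
#' Inverts the FPKM definition to a count mean
#' `mu = mean_fpkm * length_bp * library_size / 1e9` and draws
#' NB(mu, variance `mu + dispersion * mu^2`); dispersion below 1e-12 is
#' treated as the Poisson limit. Vectorized over all arguments.
#'
#' @param mean_fpkm Nonnegative expected FPKM.
#' @param length_bp Positive transcript length (bp).
#' @param library_size Positive mapped-fragment total of the sample.
#' @param dispersion Nonnegative NB dispersion alpha.
#' @return Integer-valued counts, same length as the recycled inputs.
#' @export
simulate_counts <- function(mean_fpkm, length_bp, library_size, dispersion) {
  if (any(mean_fpkm < 0)) stop("mean_fpkm must be nonnegative")
  if (any(length_bp <= 0) || any(library_size <= 0)) {
    stop("length_bp and library_size must be positive")
  }
  if (any(dispersion < 0)) stop("dispersion must be nonnegative")
  mu <- mean_fpkm * length_bp * library_size / 1e9
  if (any(!is.finite(mu))) stop("count mean overflow")
  n <- length(mu)
  disp <- rep_len(dispersion, n)
  out <- numeric(n)
  pois <- disp < 1e-12
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / disp[!pois])
  }
  out
}

# Markov kernel over the 8 categories with prescribed stationary mix and
# per-category retention. Off-diagonal flows are found by Sinkhorn scaling
# so that the flow matrix has row sums mix_i * (1 - stay_i), column sums
# mix_j * (1 - stay_j), and zero diagonal; dividing rows by mix_i yields a
# stochastic kernel with stationary distribution `mix` and diagonal `stay`.
transition_kernel <- function(mix, stay, tol = 1e-12, max_iter = 10000) {
  k <- length(mix)
  u <- mix * (1 - stay) # off-diagonal row margins
  M <- diag(stay)
  active <- u > 0
  if (any(active)) {
    # feasibility: leavers from category i must be absorbable by the others
    infeasible <- u > sum(u) - u + 1e-12
    if (any(infeasible)) {
      stop("category_mix and category_stay are jointly infeasible: ",
           paste(names(mix)[infeasible], collapse = ", "),
           " sheds more probability than the other categories can absorb; ",
           "raise its retention or lower its mix share")
    }
    F_off <- outer(u, u)
    diag(F_off) <- 0
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      rs <- rowSums(F_off)
      F_off[active, ] <- F_off[active, , drop = FALSE] * (u[active] / rs[active])
      cs <- colSums(F_off)
      F_off[, active] <- sweep(F_off[, active, drop = FALSE], 2,
                               u[active] / cs[active], "*")
      if (max(abs(rowSums(F_off) - u)) < tol &&
          max(abs(colSums(F_off) - u)) < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) stop("transition kernel construction did not converge")
    pos <- mix > 0
    M[pos, ] <- M[pos, , drop = FALSE] + F_off[pos, , drop = FALSE] / mix[pos]
  }
  rownames(M) <- colnames(M) <- names(mix)
  # rows for zero-probability categories never arise; make them absorbing
  zero <- rowSums(M) == 0
  diag(M)[zero] <- 1
  M / rowSums(M)
}

#' Simulate a triad time-series RNA-seq dataset with planted truth
#'
#' Generates a gene-level count matrix (3 genes per triad), gene lengths,
#' sample metadata, the triad table, two annotation maps, and the full
#' ground truth needed to validate the analysis pipeline:
#'
#' * per triad x time point, a bias category evolving by a Markov kernel
#'   with the configured mix as stationary distribution and the configured
#'   per-category retention;
#' * a baseline log-normal triad total FPKM, modulated over time by one of
#'   the planted temporal templates (co-expression truth) and, for planted
#'   DE triads, stepped by `2^(+/- de_log2fc)` from a random adjacent
#'   boundary onward (differential-expression truth);
#' * homoeolog fractions drawn around the category centroid at
#'   concentration `bias_concentration` (Low triads get uniform
#'   fractions);
#' * counts realized per gene x sample as NB with mean
#'   `fpkm * length * library_size / 1e9`;
#' * annotation terms planted at `enrichment_fold` times the base rate in
#'   their target cluster (TF-family map) or initial bias category
#'   (pathway map).
#'
#' Deterministic given the config (including its seed); stages use
#' independent derived substreams.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `counts` (genes x samples), `lengths`
#'   (named vector), `samples`, `triads`, `annotations` (list
#'   `tf_families`, `pathways`), `planted_fpkm` (genes x time points) and
#'   `truth` (list `category`, `cluster`, `de`, `enriched`).
#' @export
simulate_dataset <- function(config) {
  validate_config(config)
  cfg <- config
  cats <- bias_categories()
  tps <- as.character(seq(0, by = 2, length.out = cfg$n_timepoints))
  samples <- data.frame(
    sample_id = paste0("DAP", rep(sprintf("%02d", as.integer(tps)),
                                  each = cfg$n_replicates),
                       "_R", rep(seq_len(cfg$n_replicates), cfg$n_timepoints)),
    timepoint = rep(tps, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), cfg$n_timepoints),
    stringsAsFactors = FALSE
  )
  nt <- cfg$n_triads
  if (nt == 0) {
    empty <- matrix(numeric(0), 0, nrow(samples),
                    dimnames = list(character(0), samples$sample_id))
    return(list(
      counts = empty, lengths = setNames(numeric(0), character(0)),
      samples = samples,
      triads = data.frame(triad_id = character(0), gene_A = character(0),
                          gene_B = character(0), gene_D = character(0),
                          stringsAsFactors = FALSE),
      annotations = list(
        tf_families = data.frame(gene_id = character(0), term_id = character(0)),
        pathways = data.frame(gene_id = character(0), term_id = character(0))
      ),
      planted_fpkm = empty[, 0, drop = FALSE],
      truth = list(
        category = data.frame(triad_id = character(0), timepoint = character(0),
                              category = character(0)),
        cluster = data.frame(gene_id = character(0), cluster = integer(0)),
        de = data.frame(gene_id = character(0), contrast = character(0),
                        true_de = logical(0)),
        enriched = data.frame(annotation = character(0), set = character(0),
                              term_id = character(0))
      )
    ))
  }
  triad_id <- sprintf("TRIAD%05d", seq_len(nt))
  triads <- data.frame(
    triad_id = triad_id,
    gene_A = paste0(triad_id, ".A"),
    gene_B = paste0(triad_id, ".B"),
    gene_D = paste0(triad_id, ".D"),
    stringsAsFactors = FALSE
  )
  genes <- as.vector(t(as.matrix(triads[, c("gene_A", "gene_B", "gene_D")])))
  ngene <- length(genes)
  T_ <- cfg$n_timepoints

  # --- category paths ------------------------------------------------------
  kern <- transition_kernel(cfg$category_mix, cfg$category_stay)
  cat_path <- with_seed(derive_seed(cfg$seed, "categories"), {
    m <- matrix("", nt, T_)
    m[, 1] <- sample(cats, nt, replace = TRUE, prob = cfg$category_mix)
    if (T_ > 1) {
      for (j in 2:T_) {
        for (cc in unique(m[, j - 1])) {
          idx <- which(m[, j - 1] == cc)
          m[idx, j] <- sample(cats, length(idx), replace = TRUE,
                              prob = kern[cc, ])
        }
      }
    }
    m
  })

  # --- totals: baseline x template modulation x planted DE steps ----------
  totals <- with_seed(derive_seed(cfg$seed, "totals"), {
    base <- pmax(2, rlnorm(nt, cfg$base_expression_log_mean,
                           cfg$base_expression_log_sd))
    tot <- matrix(base, nt, T_)
    if (cfg$n_clusters_planted > 0 && T_ >= 3) {
      templ <- cluster_templates(T_, cfg$n_clusters_planted)
      cl <- sample.int(cfg$n_clusters_planted, nt, replace = TRUE)
      tot <- tot * 2^(cfg$cluster_amplitude * templ[cl, , drop = FALSE])
      attr(tot, "cluster") <- cl
    }
    tot
  })
  planted_cluster <- attr(totals, "cluster")

  de_truth <- with_seed(derive_seed(cfg$seed, "de"), {
    de <- matrix(FALSE, nt, max(T_ - 1, 0))
    if (cfg$de_fraction > 0 && T_ >= 2) {
      ever_low <- apply(cat_path == "Low", 1, any)
      eligible <- which(!ever_low)
      n_de <- round(cfg$de_fraction * nt)
      for (b in seq_len(T_ - 1)) {
        pick <- sample(eligible, min(n_de, length(eligible)))
        sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
        fold <- 2^(sgn * cfg$de_log2fc)
        totals[pick, (b + 1):T_] <-
          totals[pick, (b + 1):T_, drop = FALSE] * fold
        de[pick, b] <- TRUE
      }
    }
    attr(de, "totals") <- totals
    de
  })
  totals <- attr(de_truth, "totals")
  attr(de_truth, "totals") <- NULL

  # Low time points override the baseline total
  low_draw <- with_seed(derive_seed(cfg$seed, "low_totals"),
                        matrix(runif(nt * T_, 0.05, 0.8), nt, T_))
  is_low <- cat_path == "Low"
  totals[is_low] <- low_draw[is_low]

  # --- homoeolog fractions -------------------------------------------------
  # A triad's composition is a persistent property: fractions are drawn when
  # a category run starts and reused while the category is unchanged, so
  # genes of category-stable triads carry no spurious between-time-point
  # fold changes.
  fractions <- with_seed(derive_seed(cfg$seed, "fractions"), {
    fr <- array(NA_real_, c(nt, T_, 3))
    for (j in seq_len(T_)) {
      redraw <- if (j == 1) rep(TRUE, nt) else cat_path[, j] != cat_path[, j - 1]
      for (cc in setdiff(unique(cat_path[redraw, j]), "Low")) {
        idx <- which(redraw & cat_path[, j] == cc)
        fr[idx, j, ] <- simulate_category_fractions(cc, cfg$bias_concentration,
                                                    n = length(idx))
      }
      lowj <- which(redraw & is_low[, j])
      if (length(lowj)) {
        g <- matrix(rgamma(length(lowj) * 3, shape = 1), length(lowj), 3)
        fr[lowj, j, ] <- g / rowSums(g)
      }
      if (j > 1 && any(!redraw)) {
        fr[!redraw, j, ] <- fr[!redraw, j - 1, ]
      }
    }
    fr
  })

  # planted per-gene FPKM, genes x time points (A, B, D interleaved per triad)
  planted_fpkm <- matrix(0, ngene, T_, dimnames = list(genes, tps))
  for (j in seq_len(T_)) {
    gm <- totals[, j] * fractions[, j, ]
    planted_fpkm[, j] <- as.vector(t(gm))
  }

  lengths <- with_seed(derive_seed(cfg$seed, "lengths"), {
    setNames(sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                    ngene, replace = TRUE), genes)
  })

  # FPKM is compositional: the planted values must carry a transcriptome
  # mass of sum(FPKM * length) ~ 1e9 per time point, or the FPKM recomputed
  # from realized counts lands on a different scale than planted and the
  # Low/expressed truth breaks. Rescale expressed triad-time-points by a
  # single global factor (Low totals stay on the absolute < 1 scale).
  gene_low <- is_low[rep(seq_len(nt), each = 3), , drop = FALSE]
  mass <- colSums(planted_fpkm * ifelse(gene_low, 0, 1) * lengths)
  for (j in seq_len(T_)) {
    if (mass[j] > 0) {
      keep <- !gene_low[, j]
      planted_fpkm[keep, j] <- planted_fpkm[keep, j] * (1e9 / mass[j])
    }
  }

  # Template modulation and planted DE steps can drag an expressed triad's
  # total toward the Low threshold; clamp such cells to a total of 2
  # (keeping fractions) so the planted expressed/Low truth stays valid, and
  # void the profile/DE truth of the affected triads, whose planted shapes
  # are no longer exact.
  tri_idx <- rep(seq_len(nt), each = 3)
  tri_tot <- rowsum(planted_fpkm, tri_idx)
  clamped <- !is_low & tri_tot < 2
  if (any(clamped)) {
    fac <- ifelse(clamped, 2 / tri_tot, 1)
    planted_fpkm <- planted_fpkm * fac[tri_idx, , drop = FALSE]
    if (ncol(de_truth) > 0) {
      for (b in seq_len(T_ - 1)) {
        de_truth[, b] <- de_truth[, b] & !clamped[, b] & !clamped[, b + 1]
      }
    }
  }
  ever_clamped <- apply(clamped, 1, any)

  # --- library sizes, counts -----------------------------------------------
  lib_sizes <- with_seed(derive_seed(cfg$seed, "libsizes"), {
    r <- log(cfg$library_size_range)
    setNames(round(exp(runif(nrow(samples), r[1], r[2]))), samples$sample_id)
  })
  counts <- with_seed(derive_seed(cfg$seed, "counts"), {
    m <- matrix(0, ngene, nrow(samples),
                dimnames = list(genes, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      j <- match(samples$timepoint[s], tps)
      m[, s] <- simulate_counts(planted_fpkm[, j], lengths,
                                lib_sizes[s], cfg$nb_dispersion)
    }
    m
  })

  # --- annotation maps with planted enrichment -----------------------------
  ever_low <- apply(is_low, 1, any)
  gene_cluster <- if (is.null(planted_cluster)) rep(NA_integer_, ngene) else {
    cl <- ifelse(ever_low | ever_clamped, NA_integer_, planted_cluster)
    rep(cl, each = 3)
  }
  gene_cat0 <- rep(cat_path[, 1], each = 3)
  ann <- with_seed(derive_seed(cfg$seed, "annotation"), {
    make_map <- function(prefix, target_of_term) {
      rows <- list()
      for (i in seq_len(cfg$n_terms)) {
        tm <- sprintf("%s%02d", prefix, i)
        p <- rep(cfg$term_base_rate, ngene)
        tgt <- target_of_term(i)
        if (!is.null(tgt)) {
          p[tgt] <- min(1, cfg$enrichment_fold * cfg$term_base_rate)
        }
        hit <- runif(ngene) < p
        if (any(hit)) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = genes[hit], term_id = tm, stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(0), term_id = character(0))
    }
    n_cl <- cfg$n_clusters_planted
    tf <- make_map("TF", function(i) {
      if (n_cl > 0 && i <= n_cl) which(gene_cluster == i) else NULL
    })
    expr_cats <- setdiff(cats, "Low")
    pw <- make_map("PW", function(i) {
      if (i <= length(expr_cats)) which(gene_cat0 == expr_cats[i]) else NULL
    })
    list(tf_families = tf, pathways = pw)
  })
  enriched <- rbind(
    if (cfg$n_clusters_planted > 0) data.frame(
      annotation = "tf_families",
      set = paste0("C", seq_len(cfg$n_clusters_planted)),
      term_id = sprintf("TF%02d", seq_len(cfg$n_clusters_planted)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      annotation = "pathways",
      set = setdiff(cats, "Low"),
      term_id = sprintf("PW%02d", seq_along(setdiff(cats, "Low"))),
      stringsAsFactors = FALSE
    )
  )

  truth <- list(
    category = data.frame(
      triad_id = rep(triad_id, T_),
      timepoint = rep(tps, each = nt),
      category = as.vector(cat_path),
      stringsAsFactors = FALSE
    ),
    cluster = data.frame(gene_id = genes, cluster = gene_cluster,
                         stringsAsFactors = FALSE),
    de = if (T_ >= 2) data.frame(
      gene_id = rep(genes, T_ - 1),
      contrast = rep(paste0(tps[-1], "_vs_", tps[-T_]), each = ngene),
      true_de = as.vector(de_truth[rep(seq_len(nt), each = 3), , drop = FALSE]),
      stringsAsFactors = FALSE
    ) else data.frame(gene_id = character(0), contrast = character(0),
                      true_de = logical(0)),
    enriched = enriched
  )
  list(counts = counts, lengths = lengths, samples = samples, triads = triads,
       annotations = ann, planted_fpkm = planted_fpkm, truth = truth)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `counts.tsv`, `lengths.tsv`, `samples.tsv`, `triads.tsv`,
#' `tf_families.tsv`, `pathways.tsv`, and the truth tables
#' (`truth_category.tsv`, `truth_cluster.tsv`, `truth_de.tsv`,
#' `truth_enriched.tsv`). All files are TSV with a header row, UTF-8, '.'
#' decimal separator.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_matrix_tsv(dataset$counts, p("counts.tsv"))
  write_tsv(data.frame(gene_id = names(dataset$lengths),
                       length_bp = as.integer(dataset$lengths)),
            p("lengths.tsv"))
  write_tsv(dataset$samples, p("samples.tsv"))
  write_tsv(dataset$triads, p("triads.tsv"))
  write_tsv(dataset$annotations$tf_families, p("tf_families.tsv"))
  write_tsv(dataset$annotations$pathways, p("pathways.tsv"))
  write_tsv(dataset$truth$category, p("truth_category.tsv"))
  write_tsv(dataset$truth$cluster, p("truth_cluster.tsv"))
  write_tsv(dataset$truth$de, p("truth_de.tsv"))
  write_tsv(dataset$truth$enriched, p("truth_enriched.tsv"))
  invisible(vapply(c("counts.tsv", "lengths.tsv", "samples.tsv", "triads.tsv",
                     "tf_families.tsv", "pathways.tsv", "truth_category.tsv",
                     "truth_cluster.tsv", "truth_de.tsv", "truth_enriched.tsv"),
                   p, character(1)))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the TSV files.
#' @return A list shaped like the output of [simulate_dataset()] (without
#'   `planted_fpkm`); truth tables are included when present.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  lengths_df <- read_tsv(p("lengths.tsv"))
  out <- list(
    counts = read_matrix_tsv(p("counts.tsv")),
    lengths = setNames(lengths_df$length_bp, lengths_df$gene_id),
    samples = read_tsv(p("samples.tsv"), colClasses = c(timepoint = "character")),
    triads = read_tsv(p("triads.tsv")),
    annotations = list(
      tf_families = read_tsv(p("tf_families.tsv")),
      pathways = read_tsv(p("pathways.tsv"))
    )
  )
  truth_files <- c(category = "truth_category.tsv", cluster = "truth_cluster.tsv",
                   de = "truth_de.tsv", enriched = "truth_enriched.tsv")
  if (all(file.exists(vapply(truth_files, p, character(1))))) {
    out$truth <- list(
      category = read_tsv(p("truth_category.tsv"),
                          colClasses = c(timepoint = "character")),
      cluster = read_tsv(p("truth_cluster.tsv")),
      de = read_tsv(p("truth_de.tsv")),
      enriched = read_tsv(p("truth_enriched.tsv"))
    )
  }
  out
}
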