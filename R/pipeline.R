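#' Pipeline configuration
#'
#' Assembles, or loads from YAML, the configuration for [run_pipeline()]:
#' the output directory, stage toggles, every analysis threshold, and the
#' synthetic-data generator settings. All thresholds are surfaced here so
#' a run is fully auditable from its manifest.
#'
#' @param outdir Directory for all pipeline artifacts.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "qc", "de", "cluster", "bias", "enrich")` in that
#'   dependency order. When "simulate" is omitted, `counts.tsv`,
#'   `lengths.tsv`, `samples.tsv`, `triads.tsv` and annotation TSVs must
#'   already exist in `outdir`.
#' @param sim A [simulation_config()] (or list of its arguments) for the
#'   simulate stage.
#' @param expressed_threshold Replicate-mean FPKM above which a gene (or,
#'   summed over homoeologs, a triad) counts as expressed.
#' @param de_p,de_lfc DEG thresholds: adjusted p (strict `<`) and absolute
#'   log2 fold change (`>=`).
#' @param k_range Candidate cluster numbers for [select_k()].
#' @param n_init K-means restarts.
#' @param cluster_max_genes Cap on the number of DEG profiles clustered;
#'   when exceeded, the most variable profiles are kept (distance matrices
#'   are quadratic in this number).
#' @param tf_alpha,pathway_alpha Enrichment significance thresholds (raw
#'   one-sided Fisher p) for TF families in clusters and pathway terms in
#'   bias categories.
#' @param seed Master seed for all stochastic stages.
#' @param yaml Optional path to a YAML file; values in the file override
#'   the defaults, and explicit arguments override the file.
#' @return A list of class `triadyn_pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            stages = c("simulate", "qc", "de", "cluster",
                                       "bias", "enrich"),
                            sim = simulation_config(),
                            expressed_threshold = 1.0,
                            de_p = 0.05, de_lfc = 1.0,
                            k_range = 2:15, n_init = 25,
                            cluster_max_genes = 3000,
                            tf_alpha = 0.01, pathway_alpha = 0.05,
                            seed = 1, yaml = NULL) {
  cfg <- list(
    outdir = outdir, stages = stages, sim = sim,
    expressed_threshold = expressed_threshold,
    de_p = de_p, de_lfc = de_lfc,
    k_range = k_range, n_init = n_init,
    cluster_max_genes = cluster_max_genes,
    tf_alpha = tf_alpha, pathway_alpha = pathway_alpha,
    seed = seed
  )
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    passed <- names(as.list(match.call())[-1])
    for (nm in setdiff(intersect(names(y), names(cfg)), passed)) {
      cfg[[nm]] <- if (nm == "sim") do.call(simulation_config, y$sim) else y[[nm]]
    }
  }
  if (is.list(cfg$sim) && !inherits(cfg$sim, "triadyn_config")) {
    cfg$sim <- do.call(simulation_config, cfg$sim)
  }
  bad <- setdiff(cfg$stages, c("simulate", "qc", "de", "cluster", "bias",
                               "enrich"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(cfg$expressed_threshold >= 0, cfg$de_p > 0, cfg$de_p <= 1,
            cfg$de_lfc >= 0, all(cfg$k_range >= 2), cfg$n_init >= 1,
            cfg$cluster_max_genes >= 10,
            cfg$tf_alpha > 0, cfg$tf_alpha <= 1,
            cfg$pathway_alpha > 0, cfg$pathway_alpha <= 1)
  class(cfg) <- "triadyn_pipeline_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

require_files <- function(outdir, files, stage) {
  paths <- file.path(outdir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("stage '", stage, "' is missing upstream input(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate -> qc -> de -> cluster -> bias -> enrich). Each stage reads
#' only TSV artifacts in `config$outdir` and writes only its declared
#' outputs there, so a single stage can be re-run in isolation and
#' reproduces its outputs byte-identically given the same config. A
#' manifest (`manifest.json`) recording the effective config and the MD5
#' checksum of every artifact is written at the end.
#'
#' Stage outputs: simulate - the [write_dataset()] files; qc - `fpkm.tsv`,
#' `expressed_sets.tsv`, `qc_scc.tsv`, `qc_pca.tsv`; de -
#' `de_results.tsv`; cluster - `clusters.tsv`, `silhouette_by_k.tsv`,
#' `cluster_means.tsv`; bias - `bias_assignments.tsv`,
#' `category_proportions.tsv`, `ternary_coords.tsv`,
#' `transitions_<t1>_<t2>.tsv`, `stability.tsv`; enrich -
#' `enrichment_tf.tsv`, `enrichment_pathway.tsv`.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, the manifest as a list (`config`, `files` with
#'   checksums).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "triadyn_pipeline_config")) {
    stop("config must come from pipeline_config()")
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  produced <- character(0)
  note <- function(paths) produced <<- union(produced, basename(paths))

  if ("simulate" %in% config$stages) {
    ds <- simulate_dataset(config$sim)
    note(write_dataset(ds, outdir))
    stage_log("simulate", nrow(ds$triads), " triads, ",
              nrow(ds$counts), " genes, ", nrow(ds$samples), " samples")
  }

  p <- function(f) file.path(outdir, f)

  if ("qc" %in% config$stages) {
    require_files(outdir, c("counts.tsv", "lengths.tsv", "samples.tsv"), "qc")
    ds <- read_dataset_core(outdir)
    fk <- fpkm(ds$counts, ds$lengths)
    write_matrix_tsv(fk, p("fpkm.tsv"))
    expr <- expressed_genes(fk, ds$samples, config$expressed_threshold)
    sets <- do.call(rbind, lapply(names(expr$per_timepoint), function(tp) {
      if (!length(expr$per_timepoint[[tp]])) return(NULL)
      data.frame(gene_id = expr$per_timepoint[[tp]], timepoint = tp,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sets)) sets <- data.frame(gene_id = character(0),
                                          timepoint = character(0))
    write_tsv(sets, p("expressed_sets.tsv"))
    qc <- sample_qc(fk)
    write_matrix_tsv(round(qc$scc, 10), p("qc_scc.tsv"), id_col = "sample_id")
    pca <- qc$pca
    pca[-1] <- round(pca[-1], 10)
    write_tsv(pca, p("qc_pca.tsv"))
    note(c("fpkm.tsv", "expressed_sets.tsv", "qc_scc.tsv", "qc_pca.tsv"))
    stage_log("qc", length(expr$overall), " expressed genes overall")
  }

  if ("de" %in% config$stages) {
    require_files(outdir, c("counts.tsv", "samples.tsv", "fpkm.tsv"), "de")
    ds <- read_dataset_core(outdir)
    fk <- read_matrix_tsv(p("fpkm.tsv"))
    res <- run_de(ds$counts, ds$samples, fpkm = fk,
                  expressed_threshold = config$expressed_threshold,
                  p_threshold = config$de_p, lfc_threshold = config$de_lfc)
    out <- res
    out$base_mean <- round(out$base_mean, 6)
    out$log2fc <- round(out$log2fc, 10)
    out$p_raw <- signif(out$p_raw, 10)
    out$p_adj <- signif(out$p_adj, 10)
    write_tsv(out, p("de_results.tsv"))
    note("de_results.tsv")
    degs <- call_degs(res, config$de_p, config$de_lfc)
    stage_log("de", nrow(res), " tests, ", length(degs$union), " DEGs (union)")
  }

  if ("cluster" %in% config$stages) {
    require_files(outdir, c("fpkm.tsv", "samples.tsv", "de_results.tsv"),
                  "cluster")
    ds <- read_dataset_core(outdir, counts = FALSE)
    fk <- read_matrix_tsv(p("fpkm.tsv"))
    de <- read_tsv(p("de_results.tsv"))
    degs <- call_degs(de, config$de_p, config$de_lfc)$union
    prof <- temporal_profiles(fk, ds$samples, genes = degs)
    if (nrow(prof) > config$cluster_max_genes) {
      tp_means <- fk[rownames(prof), , drop = FALSE]
      v <- apply(log2(tp_means + 1), 1, var)
      keep <- names(sort(v, decreasing = TRUE))[seq_len(config$cluster_max_genes)]
      prof <- prof[rownames(prof) %in% keep, , drop = FALSE]
      stage_log("cluster", "capped to ", nrow(prof), " most variable profiles")
    }
    sel <- select_k(prof, k_range = config$k_range,
                    seed = derive_seed(config$seed, "cluster"),
                    n_init = config$n_init)
    labels <- sel$assignment$labels
    write_tsv(data.frame(gene_id = names(labels),
                         cluster = paste0("C", labels),
                         stringsAsFactors = FALSE),
              p("clusters.tsv"))
    tab <- sel$table
    tab$silhouette <- round(tab$silhouette, 10)
    write_tsv(tab, p("silhouette_by_k.tsv"))
    centers <- round(sel$assignment$centers, 10)
    rownames(centers) <- paste0("C", seq_len(nrow(centers)))
    write_matrix_tsv(centers, p("cluster_means.tsv"), id_col = "cluster")
    note(c("clusters.tsv", "silhouette_by_k.tsv", "cluster_means.tsv"))
    stage_log("cluster", "k = ", sel$best_k, ", ", length(labels),
              " genes clustered")
  }

  if ("bias" %in% config$stages) {
    require_files(outdir, c("fpkm.tsv", "samples.tsv", "triads.tsv"), "bias")
    ds <- read_dataset_core(outdir, counts = FALSE)
    fk <- read_matrix_tsv(p("fpkm.tsv"))
    triads <- read_tsv(p("triads.tsv"))
    asn <- classify_all(fk, triads, ds$samples,
                        threshold = config$expressed_threshold)
    out <- asn
    for (cl in c("total_fpkm", "fA", "fB", "fD", "distance")) {
      out[[cl]] <- round(out[[cl]], 10)
    }
    write_tsv(out, p("bias_assignments.tsv"))
    prop <- rbind(
      cbind(category_proportions(asn, include_low = TRUE), low_included = TRUE),
      cbind(category_proportions(asn, include_low = FALSE), low_included = FALSE)
    )
    prop$proportion <- round(prop$proportion, 10)
    write_tsv(prop, p("category_proportions.tsv"))
    expressed <- !is.na(asn$fA)
    tern <- data.frame(
      triad_id = asn$triad_id[expressed], timepoint = asn$timepoint[expressed],
      round(ternary_coordinates(as.matrix(asn[expressed, c("fA", "fB", "fD")])), 10),
      stringsAsFactors = FALSE
    )
    write_tsv(tern, p("ternary_coords.tsv"))
    tr <- transitions(asn)
    tr_files <- character(0)
    for (nm in names(tr$tables)) {
      f <- paste0("transitions_", nm, ".tsv")
      write_matrix_tsv(tr$tables[[nm]], p(f), id_col = "from_category")
      tr_files <- c(tr_files, f)
    }
    stab <- tr$stability
    stab$retained <- round(stab$retained, 10)
    gs <- tr$group_stability
    gs$retained_group <- round(gs$retained_group, 10)
    gs$retained_category <- round(gs$retained_category, 10)
    write_tsv(stab, p("stability.tsv"))
    write_tsv(gs, p("group_stability.tsv"))
    note(c("bias_assignments.tsv", "category_proportions.tsv",
           "ternary_coords.tsv", tr_files, "stability.tsv",
           "group_stability.tsv"))
    stage_log("bias", sum(expressed), " expressed triad-timepoints, ",
              sum(!expressed), " Low")
  }

  if ("enrich" %in% config$stages) {
    require_files(outdir, c("clusters.tsv", "expressed_sets.tsv",
                            "bias_assignments.tsv", "tf_families.tsv",
                            "pathways.tsv"), "enrich")
    clusters <- read_tsv(p("clusters.tsv"))
    expr_sets <- read_tsv(p("expressed_sets.tsv"))
    asn <- read_tsv(p("bias_assignments.tsv"),
                    colClasses = c(timepoint = "character"))
    tf_ann <- read_tsv(p("tf_families.tsv"))
    pw_ann <- read_tsv(p("pathways.tsv"))
    # TF families in co-expression clusters; background = expressed genes
    bg_genes <- unique(expr_sets$gene_id)
    cl_sets <- split(clusters$gene_id, clusters$cluster)
    tf_res <- fisher_enrichment(cl_sets, tf_ann, bg_genes,
                                alpha = config$tf_alpha)
    write_enrichment(tf_res, p("enrichment_tf.tsv"))
    # pathway terms in bias categories; sets and background are homoeologs
    # of triads, grouped by the triad's category at each time point
    triads <- read_tsv(p("triads.tsv"))
    gene_by_triad <- triads[, c("gene_A", "gene_B", "gene_D")]
    rownames(gene_by_triad) <- triads$triad_id
    expressed_asn <- asn[asn$category != "Low", , drop = FALSE]
    bg_triads <- unique(expressed_asn$triad_id)
    bg_hom <- unique(unlist(gene_by_triad[bg_triads, ], use.names = FALSE))
    cat_sets <- lapply(split(expressed_asn$triad_id, expressed_asn$category),
                       function(ids) {
                         unique(unlist(gene_by_triad[unique(ids), ],
                                       use.names = FALSE))
                       })
    pw_res <- fisher_enrichment(cat_sets, pw_ann, bg_hom,
                                alpha = config$pathway_alpha)
    write_enrichment(pw_res, p("enrichment_pathway.tsv"))
    note(c("enrichment_tf.tsv", "enrichment_pathway.tsv"))
    stage_log("enrich", sum(tf_res$significant), " significant TF-family and ",
              sum(pw_res$significant), " pathway enrichments")
  }

  manifest <- list(
    config = config_to_list(config),
    files = lapply(sort(produced), function(f) {
      list(name = f, md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log("manifest", length(produced), " artifacts recorded")
  invisible(manifest)
}

write_enrichment <- function(res, path) {
  out <- res
  out$odds_ratio <- round(out$odds_ratio, 10)
  out$p <- signif(out$p, 10)
  write_tsv(out, path)
}

read_dataset_core <- function(outdir, counts = TRUE) {
  p <- function(f) file.path(outdir, f)
  out <- list(
    samples = read_tsv(p("samples.tsv"), colClasses = c(timepoint = "character"))
  )
  if (counts) {
    out$counts <- read_matrix_tsv(p("counts.tsv"))
    lengths_df <- read_tsv(p("lengths.tsv"))
    out$lengths <- setNames(lengths_df$length_bp, lengths_df$gene_id)
  }
  out
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$sim <- unclass(out$sim)
  out
}
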