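#' Build a workflow configuration
#'
#' Collects everything the end-to-end workflow needs: input data (PED/MAP
#' paths or a simulation config), QC thresholds, the approach registry
#' subset to run, the Canberra location parameters, the clustering-agreement
#' threshold used to pick which of them feed the consensus, the cluster
#' count, the union cutoff, and the haplotype-block source.
#'
#' @param input Either `list(ped =, map =, covar = NULL)` or a
#'   [sim_config()] object (the dataset is then simulated).
#' @param approaches Character vector of registry names to run (defaults to
#'   a fast all-internal subset), or a named list of `approach_spec`s.
#' @param external_paths Named paths to externally computed ranked lists,
#'   passed to [default_approach_registry()].
#' @param qc Thresholds from [qc_thresholds()], or `NULL` to skip QC.
#' @param n_pcs Number of PCA covariates to compute (on the LD-pruned
#'   marker set) and attach; 0 for none.
#' @param k_values Ascending Canberra location parameters.
#' @param agreement_threshold Minimum pairwise cophenetic correlation for a
#'   prefix of `k_values` to enter the consensus (default 0.97).
#' @param n_clusters Clusters to cut the consensus into.
#' @param representative_overrides Optional approach names forced as
#'   cluster representatives.
#' @param union_k Top-list cutoff for the union stage.
#' @param block_source `"infer"` or a path to a .blocks.det-style file.
#' @param out_dir Output directory.
#' @param seed Global seed; per-approach seeds derive from it.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(input,
                            approaches = c("plink.add", "plink.dom",
                                           "plink.rec", "plink.model.trend",
                                           "mdr.ba", "entropy"),
                            external_paths = NULL,
                            qc = qc_thresholds(), n_pcs = 0L,
                            k_values = c(50L, 100L, 200L, 500L),
                            agreement_threshold = 0.97,
                            n_clusters = 4L,
                            representative_overrides = NULL,
                            union_k = 100L,
                            block_source = "infer",
                            out_dir = "gwasrank_out", seed = 1L) {
  if (is.unsorted(k_values)) stop("k_values must be ascending")
  cfg <- list(input = input, approaches = approaches,
              external_paths = external_paths, qc = qc,
              n_pcs = as.integer(n_pcs), k_values = as.integer(k_values),
              agreement_threshold = agreement_threshold,
              n_clusters = as.integer(n_clusters),
              representative_overrides = representative_overrides,
              union_k = as.integer(union_k), block_source = block_source,
              out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' Top-level keys mirror the arguments of [workflow_config()]; `input` is
#' either a mapping with `ped`/`map` (and optional `covar`) paths or a
#' mapping `simulate:` with [sim_config()] fields (where `planted_effects`
#' is a list of `{marker, model, odds_ratio}` mappings).
#'
#' @param path YAML file path.
#' @return A `workflow_config`.
#' @export
load_workflow_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input$simulate)) {
    s <- y$input$simulate
    if (!is.null(s$planted_effects))
      s$planted_effects <- do.call(rbind, lapply(s$planted_effects,
                                                 as.data.frame))
    y$input <- do.call(sim_config, s)
  }
  if (!is.null(y$qc)) y$qc <- do.call(qc_thresholds, y$qc)
  args <- y[intersect(names(y), names(formals(workflow_config)))]
  do.call(workflow_config, args)
}

#' Select the location parameters entering the consensus
#'
#' Takes the largest prefix of the ascending `k_values` whose clusterings
#' all agree pairwise at or above the threshold (cophenetic correlation).
#' Falls back to the smallest k, with a warning, when no prefix of two or
#' more qualifies.
#'
#' @param agreements Symmetric matrix of pairwise cophenetic correlations
#'   between the per-k clusterings, dimnames `"k<value>"`.
#' @param k_values Ascending integer location parameters.
#' @param threshold Minimum agreement.
#' @return Integer vector: the selected k values.
#' @export
select_k_for_consensus <- function(agreements, k_values, threshold = 0.97) {
  labels <- paste0("k", k_values)
  stopifnot(all(labels %in% rownames(agreements)))
  best <- integer(0)
  for (p in seq.int(2L, length(k_values))) {
    if (p > length(k_values)) break
    sub <- agreements[labels[1:p], labels[1:p]]
    if (all(sub[lower.tri(sub)] >= threshold)) best <- k_values[1:p]
  }
  if (!length(best)) {
    warning("no prefix of k values meets the agreement threshold ",
            threshold, "; falling back to k = ", k_values[1])
    return(k_values[1])
  }
  best
}

resolve_approaches <- function(cfg) {
  if (is.list(cfg$approaches) &&
      all(vapply(cfg$approaches, inherits, logical(1), "approach_spec")))
    return(cfg$approaches)
  reg <- default_approach_registry(external_paths = cfg$external_paths)
  unknown <- setdiff(cfg$approaches, names(reg))
  if (length(unknown))
    stop("unknown approach name(s): ", paste(unknown, collapse = ", "))
  reg[cfg$approaches]
}

wf_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the multi-approach workflow end to end
#'
#' QC -> per-approach ranked lists -> Canberra distance matrices per k ->
#' per-k clusterings and pairwise cophenetic agreements -> selection of the
#' k values entering the consensus -> consensus clustering -> cut ->
#' cluster representatives -> top-k union -> haplotype-block pruning ->
#' reports. Every stage's tabular output is written under
#' `config$out_dir` as it completes, so a failed run preserves the outputs
#' of the stages before the failure; a stage failure stops with the stage
#' name and cause. The whole run is a pure function of (inputs, config,
#' seed).
#'
#' @param config A `workflow_config`.
#' @return Invisible list with every intermediate product: the QC'd
#'   `genotypes`, `ranked_lists`, `distance_matrices`, `clusterings`,
#'   `agreements`, `selected_k`, `consensus`, `cluster_labels`,
#'   `representatives`, `union` and `pruned_union` tables, and `blocks`.
#' @export
run_workflow <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "workflow.log"), "w")
  on.exit(close(logcon))
  stage <- function(name, expr) {
    wf_log(logcon, name, "start")
    tryCatch(expr, error = function(e)
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res <- list(config = config)

  res$genotypes <- stage("input", {
    if (inherits(config$input, "sim_config")) {
      sim <- simulate_gwas(config$input)
      res$truth <- sim$truth
      write.table(sim$truth, file.path(config$out_dir, "truth.tsv"),
                  quote = FALSE, sep = "\t", row.names = FALSE)
      sim$genotypes
    } else {
      gm <- read_ped_map(config$input$ped, config$input$map)
      if (!is.null(config$input$covar))
        gm <- attach_covariates(gm, config$input$covar)
      gm
    }
  })

  if (!is.null(config$qc)) {
    res$genotypes <- stage("qc", {
      q <- apply_qc(res$genotypes, config$qc)
      write_qc_report(q$report, file.path(config$out_dir, "qc_report.tsv"))
      res$qc_report <- q$report
      q$genotypes
    })
  }

  if (config$n_pcs > 0L) {
    res$genotypes <- stage("pca", {
      pruned <- ld_prune(res$genotypes)
      pcs <- pca_covariates(subset_genotypes(res$genotypes, markers = pruned),
                            config$n_pcs)
      gm <- res$genotypes
      for (j in seq_len(config$n_pcs))
        gm$samples[[paste0("PC", j)]] <- pcs$scores[, j]
      gm
    })
  }

  specs <- resolve_approaches(config)
  res$ranked_lists <- stage("approaches", {
    rls <- list()
    for (nm in names(specs)) {
      wf_log(logcon, "approaches", nm)
      rls[[nm]] <- run_approach(res$genotypes, specs[[nm]],
                                seed = config$seed)
      write_ranked_list(rls[[nm]],
                        file.path(config$out_dir,
                                  paste0("ranked_", nm, ".tsv")))
    }
    rls
  })

  res$distance_matrices <- stage("distances", {
    dm <- pairwise_distance_matrices(res$ranked_lists, config$k_values)
    for (nm in names(dm))
      write_distance_matrix(dm[[nm]],
                            file.path(config$out_dir,
                                      paste0("distance_", nm, ".tsv")))
    dm
  })

  res$clusterings <- stage("clusterings", {
    lapply(res$distance_matrices, hclust_average)
  })

  res$agreements <- stage("agreements", {
    nms <- names(res$clusterings)
    A <- matrix(1, length(nms), length(nms), dimnames = list(nms, nms))
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (j > i)
        A[i, j] <- A[j, i] <- cophenetic_correlation(
          res$clusterings[[i]], res$clusterings[[j]])
    }
    write_distance_matrix(A, file.path(config$out_dir,
                                       "clustering_agreements.tsv"))
    A
  })

  res$selected_k <- stage("k_selection", {
    ks <- select_k_for_consensus(res$agreements, config$k_values,
                                 config$agreement_threshold)
    wf_log(logcon, "k_selection",
           paste("selected k:", paste(ks, collapse = ", ")))
    ks
  })

  res$consensus <- stage("consensus", {
    sel <- paste0("k", res$selected_k)
    dends <- res$clusterings[sel]
    cons <- if (length(dends) >= 2L) consensus_clustering(dends)
            else dends[[1]]
    write_dendrogram_newick(cons, file.path(config$out_dir,
                                            "consensus.nwk"))
    cons
  })

  res$cluster_labels <- stage("cut", {
    cut_tree(res$consensus, min(config$n_clusters,
                                length(res$ranked_lists)))
  })

  res$representatives <- stage("representatives", {
    reps <- select_representatives(res$cluster_labels,
                                   ultrametric_matrix(res$consensus),
                                   override = config$representative_overrides)
    writeLines(paste(names(reps), reps, sep = "\t"),
               file.path(config$out_dir, "representatives.tsv"))
    reps
  })

  res$union <- stage("union", {
    k <- min(config$union_k, nrow(res$ranked_lists[[1]]))
    ut <- union_table(res$ranked_lists[res$representatives], k)
    write_union_table(ut, file.path(config$out_dir, "union_table.tsv"))
    ut
  })

  res$blocks <- stage("blocks", {
    if (identical(config$block_source, "infer"))
      infer_blocks(res$genotypes)
    else load_blocks(config$block_source, res$genotypes)
  })

  res$pruned_union <- stage("prune", {
    pu <- prune_union(res$union, res$blocks)
    write_union_table(pu, file.path(config$out_dir,
                                    "pruned_union_table.tsv"))
    bp <- extraction_boxplot_data(pu)
    write_boxplot_data(bp, file.path(config$out_dir,
                                     "extraction_boxplots.tsv"))
    m <- length(res$representatives)
    stab <- data.frame(
      k = attr(res$union, "k"), m = m,
      union_number = nrow(res$union),
      pruned_union_number = nrow(pu),
      pct_of_complete_instability = stability_fraction(
        nrow(res$union), attr(res$union, "k"), m))
    write.table(stab, file.path(config$out_dir, "union_stats.tsv"),
                quote = FALSE, sep = "\t", row.names = FALSE)
    res$union_stats <- stab
    pu
  })

  wf_log(logcon, "done", paste("outputs in", config$out_dir))
  invisible(res)
}
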