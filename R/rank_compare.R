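#' Canberra distance between two rankings
#'
#' Sum over SNPs of `|tau(SNP) - sigma(SNP)| / (tau(SNP) + sigma(SNP))`.
#' Disagreements near the top of the lists (small ranks) weigh more than
#' equal-sized disagreements further down.
#'
#' @param sigma,tau Named integer vectors mapping marker id to rank 1..N
#'   (as from [ranking_of()]); must cover the same marker universe.
#' @return Non-negative Canberra distance.
#' @export
canberra <- function(sigma, tau) {
  tau <- align_rankings(sigma, tau)
  sum(abs(tau - sigma) / (tau + sigma))
}

#' Top-k Canberra distance (location parameter k + 1)
#'
#' Ranks beyond `k` are truncated at `k + 1` before the Canberra sum, so
#' the distance reflects only disagreement involving the top-k portions of
#' the lists. At `k = N` this reduces to the plain Canberra distance.
#'
#' @param sigma,tau As in [canberra()].
#' @param k Location parameter, `1 <= k <= N`.
#' @return Non-negative truncated Canberra distance.
#' @export
canberra_topk <- function(sigma, tau, k) {
  if (k < 1 || k > length(sigma))
    stop("k must be in 1..N (N = ", length(sigma), ")")
  tau <- align_rankings(sigma, tau)
  s <- pmin(sigma, k + 1)
  t <- pmin(tau, k + 1)
  sum(abs(t - s) / (t + s))
}

align_rankings <- function(sigma, tau) {
  if (length(sigma) != length(tau) ||
      !setequal(names(sigma), names(tau))) {
    diff <- union(setdiff(names(sigma), names(tau)),
                  setdiff(names(tau), names(sigma)))
    stop("rankings cover different marker universes; symmetric difference: ",
         paste(head(diff, 5), collapse = ", "))
  }
  # marker-sorted summation order for determinism
  tau[names(sigma)]
}

#' Pairwise Canberra distance matrices across approaches
#'
#' One symmetric matrix per requested `k`, plus one for the full (untruncated)
#' Canberra distance. `k` values exceeding the number of ranked SNPs are
#' clamped to the full distance with a warning.
#'
#' @param rankings Named list of rankings (named rank vectors or
#'   `ranked_list` objects).
#' @param k_values Integer vector of location parameters.
#' @return Named list of distance matrices; element `"full"` holds the
#'   untruncated distance, elements `"k<value>"` the truncated ones.
#' @export
pairwise_distance_matrices <- function(rankings, k_values) {
  rankings <- lapply(rankings, function(r)
    if (inherits(r, "ranked_list")) ranking_of(r) else r)
  if (length(rankings) < 2L) stop("need at least two rankings")
  N <- length(rankings[[1]])
  k_use <- k_values
  over <- k_use >= N
  if (any(over)) {
    warning("k value(s) ", paste(k_values[over], collapse = ", "),
            " >= N = ", N, "; clamped to the full Canberra distance")
  }
  out <- list()
  for (k in unique(k_use[!over]))
    out[[paste0("k", k)]] <- distance_matrix(rankings, function(a, b)
      canberra_topk(a, b, k))
  out[["full"]] <- distance_matrix(rankings, canberra)
  for (k in k_values[over]) out[[paste0("k", k)]] <- out[["full"]]
  out
}

distance_matrix <- function(rankings, fn) {
  m <- length(rankings)
  D <- matrix(0, m, m, dimnames = list(names(rankings), names(rankings)))
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    D[i, j] <- D[j, i] <- fn(rankings[[i]], rankings[[j]])
  }
  D
}

#' Average-linkage hierarchical clustering of approaches
#'
#' UPGMA agglomeration of a distance matrix via [stats::hclust()].
#'
#' @param dist_matrix Symmetric distance matrix with named rows/columns.
#' @return An `hclust` object.
#' @export
hclust_average <- function(dist_matrix) {
  if (any(is.na(dist_matrix))) stop("distance matrix contains NA/NaN")
  if (nrow(dist_matrix) < 2L) stop("need at least two items")
  hclust(as.dist(dist_matrix), method = "average")
}

#' Ultrametric (cophenetic) distances of a dendrogram
#' @param dend An `hclust` object.
#' @return Symmetric matrix of merge-height distances between leaves.
#' @export
ultrametric_matrix <- function(dend) {
  as.matrix(cophenetic(dend))
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation, over all unordered leaf pairs, of the two
#' ultrametric (merge-height) distances; the standard agreement measure
#' between hierarchical clusterings of the same items.
#'
#' @param dend_a,dend_b `hclust` objects on the same leaf set.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when either
#'   ultrametric is constant.
#' @export
cophenetic_correlation <- function(dend_a, dend_b) {
  if (!setequal(dend_a$labels, dend_b$labels))
    stop("dendrograms have different leaf sets")
  da <- cophenetic(dend_a)
  db <- cophenetic(dend_b)
  # align leaf-pair order
  ma <- as.matrix(da); mb <- as.matrix(db)[rownames(as.matrix(da)),
                                           colnames(as.matrix(da))]
  va <- ma[lower.tri(ma)]; vb <- mb[lower.tri(mb)]
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("constant ultrametric: cophenetic correlation undefined")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Consensus clustering of several dendrograms
#'
#' Least-squares (Euclidean) consensus approximated by the standard
#' closed-form surrogate: the input ultrametric matrices are averaged
#' elementwise and the average is re-clustered with average linkage. The
#' result is the UPGMA tree closest to the least-squares consensus within
#' the UPGMA-reachable family, and is deterministic and invariant to input
#' order.
#'
#' @param dendrograms List of `hclust` objects on the same leaves.
#' @return An `hclust` consensus dendrogram.
#' @export
consensus_clustering <- function(dendrograms) {
  if (length(dendrograms) < 2L) stop("need at least two dendrograms")
  leaves <- sort(dendrograms[[1]]$labels)
  mats <- lapply(dendrograms, function(d) {
    if (!setequal(d$labels, leaves))
      stop("dendrograms have different leaf sets")
    as.matrix(cophenetic(d))[leaves, leaves]
  })
  avg <- Reduce(`+`, mats) / length(mats)
  hclust_average(avg)
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' @param dend An `hclust` object.
#' @param n_clusters Desired number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(dend, n_clusters) {
  n_leaves <- length(dend$labels)
  if (n_clusters < 1L || n_clusters > n_leaves)
    stop("n_clusters must be in 1..", n_leaves)
  cutree(dend, k = n_clusters)
}

#' Select one representative approach per cluster
#'
#' Default rule: the cluster medoid (member with minimum summed
#' within-cluster distance), ties broken by approach name. Explicit
#' overrides (e.g. an analyst's manual pick) take precedence for their
#' clusters.
#'
#' @param labels Named cluster labels from [cut_tree()].
#' @param dist_matrix Distance matrix over the same approaches.
#' @param override Optional character vector of approach names to force as
#'   representatives of their clusters.
#' @return Named character vector: cluster id -> representative approach.
#' @export
select_representatives <- function(labels, dist_matrix, override = NULL) {
  reps <- character(0)
  for (cl in sort(unique(labels))) {
    members <- sort(names(labels)[labels == cl])
    forced <- intersect(override, members)
    if (length(forced)) {
      reps[as.character(cl)] <- forced[1]
      next
    }
    if (length(members) == 1L) {
      reps[as.character(cl)] <- members
      next
    }
    sums <- vapply(members, function(m)
      sum(dist_matrix[m, setdiff(members, m)]), numeric(1))
    reps[as.character(cl)] <- members[which.min(sums)]  # tie: first by name
  }
  reps
}

#' Normalize a distance matrix for heatmap display
#'
#' Elementwise division by the maximum off-diagonal entry, mapping
#' dissimilarities to `[0, 1]`.
#'
#' @param dist_matrix Symmetric distance matrix.
#' @return Normalized matrix with unchanged zero diagonal.
#' @export
normalize_for_heatmap <- function(dist_matrix) {
  off <- dist_matrix[row(dist_matrix) != col(dist_matrix)]
  mx <- max(off)
  if (mx <= 0) stop("all off-diagonal distances are zero; cannot normalize")
  dist_matrix / mx
}

#' Write / read a distance matrix as TSV
#'
#' Square layout with approach names as header row and first column. A
#' distance matrix carries no per-SNP genotype information, so this file is
#' shareable across studies (e.g. within a consortium).
#'
#' @param dist_matrix Symmetric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dist_matrix, path) {
  out <- cbind(approach = rownames(dist_matrix), as.data.frame(dist_matrix))
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return `read_distance_matrix`: the matrix.
#' @export
read_distance_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Serialize a dendrogram as Newick with merge-height branch lengths
#'
#' @param dend An `hclust` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
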