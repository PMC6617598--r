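#' Pairwise linkage disequilibrium as squared Pearson correlation
#'
#' r-squared of the two 0/1/2 call vectors over pairwise-complete samples.
#'
#' @param calls_a,calls_b Call vectors for two markers over the same samples.
#' @return r^2 in `[0, 1]`, or `NA` when fewer than two complete pairs remain
#'   or either marker is monomorphic on the complete subset (the pair is
#'   skipped in pruning).
#' @export
ld_r2 <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- calls_a[ok]; b <- calls_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Sliding-window LD pruning
#'
#' Mirrors PLINK's `--indep-pairwise` scheme: within each window of
#' `window_snps` consecutive retained markers (per chromosome), while any
#' retained pair has r^2 above the threshold, the member of the offending
#' pair with the lower MAF is removed (tie broken by removing the marker at
#' the later genomic coordinate); the window then advances by `step_snps`.
#'
#' @param gm A `genotype_matrix` (markers coordinate-sorted).
#' @param window_snps,step_snps,r2_threshold Pruning parameters; defaults
#'   50, 5, 0.2.
#' @return Character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_threshold = 0.2) {
  ids <- gm$markers$marker_id
  keep <- rep(TRUE, length(ids))
  maf <- apply(gm$calls, 1, function(x)
    if (all(is.na(x))) NA_real_ else compute_maf(x))
  for (chr in unique(gm$markers$chromosome)) {
    idx <- which(gm$markers$chromosome == chr)
    s <- 1L
    while (s <= length(idx)) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      repeat {
        live <- win[keep[win]]
        if (length(live) < 2L) break
        offender <- find_offending_pair(gm$calls, live, r2_threshold)
        if (is.null(offender)) break
        i <- offender[1]; j <- offender[2]
        drop <- if (is.na(maf[i]) || is.na(maf[j])) j
                else if (maf[i] < maf[j]) i
                else if (maf[j] < maf[i]) j
                else j   # equal MAF: later coordinate
        keep[drop] <- FALSE
      }
      s <- s + step_snps
    }
  }
  ids[keep]
}

find_offending_pair <- function(calls, live, thr) {
  for (ai in seq_len(length(live) - 1L)) {
    for (bi in seq(ai + 1L, length(live))) {
      r2 <- ld_r2(calls[live[ai], ], calls[live[bi], ])
      if (!is.na(r2) && r2 > thr) return(c(live[ai], live[bi]))
    }
  }
  NULL
}

#' Principal-component covariates from standardized genotypes
#'
#' Each marker is centered by twice its alternate-allele frequency and scaled
#' by `sqrt(2 p (1 - p))`; missing calls become 0 after centering
#' (mean imputation). Returns the leading eigenvectors of the sample-sample
#' covariance, scaled by the square roots of their eigenvalues, as PC
#' coordinates suitable for covariate adjustment. Intended to be run on the
#' LD-pruned marker set.
#'
#' @param gm A `genotype_matrix`.
#' @param n_components Number of components (<= number of samples).
#' @return List with `scores` (samples x n_components matrix, columns
#'   `PC1..PCn`) and `eigenvalues` (all, non-increasing).
#' @export
pca_covariates <- function(gm, n_components) {
  n <- ncol(gm$calls)
  if (n_components > n) stop("n_components exceeds number of samples")
  X <- standardize_genotypes(gm$calls)
  G <- crossprod(X)                     # samples x samples
  eig <- eigen(G, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- gm$samples$sample_id
  list(scores = scores, eigenvalues = ev)
}

standardize_genotypes <- function(calls) {
  p <- rowSums(calls, na.rm = TRUE) / (2 * rowSums(!is.na(calls)))
  use <- is.finite(p) & p > 0 & p < 1    # polymorphic, defined MAF
  calls <- calls[use, , drop = FALSE]; p <- p[use]
  X <- (calls - 2 * p) / sqrt(2 * p * (1 - p))
  X[is.na(X)] <- 0
  X
}
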