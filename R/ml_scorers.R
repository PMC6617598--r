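#' MDR one-locus risk model
#'
#' Labels each genotype (0/1/2) high risk when its case:control ratio
#' strictly exceeds the overall case:control ratio of the training data
#' (comparison done on cross-products, so zero-control cells are handled
#' without division). A tie is labeled low risk; genotypes unseen in
#' training default to low risk.
#'
#' @param calls 0/1/2 calls (no NA).
#' @param phenotype 0/1 phenotype.
#' @return Named logical vector over genotypes "0","1","2": `TRUE` = high
#'   risk.
#' @export
mdr_risk_model <- function(calls, phenotype) {
  n_case <- sum(phenotype == 1L); n_ctrl <- sum(phenotype == 0L)
  high <- setNames(logical(3), c("0", "1", "2"))
  for (g in 0:2) {
    cg <- sum(calls == g & phenotype == 1L)
    tg <- sum(calls == g & phenotype == 0L)
    if (cg + tg == 0L) next                      # unseen: stays low risk
    high[g + 1L] <- cg * n_ctrl > tg * n_case    # ratio strictly exceeds
  }
  high
}

#' One-locus MDR balanced accuracy
#'
#' Cross-validated multifactor dimensionality reduction restricted to
#' single-SNP (1-way) models: per fold, the risk model built on the training
#' part classifies test samples (high risk -> case), and the balanced
#' accuracy (sensitivity + specificity) / 2 is averaged over folds. Folds
#' are stratified by phenotype; assignment is a seeded shuffle followed by
#' round-robin. `folds = 1` trains and tests on the full data.
#'
#' @param calls 0/1/2/NA calls for one marker.
#' @param phenotype 0/1 phenotype.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return Mean balanced accuracy over evaluable folds.
#' @export
mdr_1way <- function(calls, phenotype, folds = 10L, seed = 1L) {
  ok <- !is.na(calls) & !is.na(phenotype)
  calls <- calls[ok]; phenotype <- phenotype[ok]
  if (!any(phenotype == 1L) || !any(phenotype == 0L))
    stop("both phenotype classes required")
  if (folds < 1L || folds > length(calls)) stop("invalid fold count")
  if (folds == 1L) return(mdr_fold_ba(calls, phenotype, calls, phenotype))
  fold_id <- stratified_folds(phenotype, folds, seed)
  bas <- numeric(0)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    if (length(unique(phenotype[te])) < 2L ||
        length(unique(phenotype[!te])) < 2L) {
      warning("fold ", f, " lacks a phenotype class; skipped")
      next
    }
    bas <- c(bas, mdr_fold_ba(calls[!te], phenotype[!te],
                              calls[te], phenotype[te]))
  }
  if (!length(bas)) stop("no evaluable folds")
  mean(bas)
}

mdr_fold_ba <- function(tr_calls, tr_ph, te_calls, te_ph) {
  high <- mdr_risk_model(tr_calls, tr_ph)
  pred <- as.integer(high[as.character(te_calls)])
  pred[is.na(pred)] <- 0L                         # unseen genotype -> low risk
  sens <- mean(pred[te_ph == 1L] == 1L)
  spec <- mean(pred[te_ph == 0L] == 0L)
  (sens + spec) / 2
}

stratified_folds <- function(phenotype, folds, seed) {
  rng <- local_rng(seed)
  fold_id <- integer(length(phenotype))
  for (cls in c(1L, 0L)) {
    idx <- which(phenotype == cls)
    idx <- idx[rng$sample(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Entropy-based information gain of a SNP
#'
#' Reduction in phenotype uncertainty given the genotype:
#' `H(Y) - H(Y|G)` in bits, with plug-in empirical probabilities and the
#' `0 log 0 = 0` convention. Equals the mutual information I(G; Y).
#'
#' @param calls 0/1/2/NA calls.
#' @param phenotype 0/1 phenotype.
#' @return Information gain in bits, in `[0, 1]` for a binary phenotype.
#' @export
entropy_gain <- function(calls, phenotype) {
  ok <- !is.na(calls) & !is.na(phenotype)
  calls <- calls[ok]; phenotype <- phenotype[ok]
  if (length(unique(phenotype)) < 2L)
    stop("both phenotype classes required")
  n <- length(calls)
  hy <- entropy_bits(table(phenotype) / n)
  hyg <- 0
  for (g in unique(calls)) {
    sel <- calls == g
    hyg <- hyg + mean(sel) * entropy_bits(table(phenotype[sel]) / sum(sel))
  }
  hy - hyg
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-SNP decision-tree score
#'
#' Fits a single-feature classification tree on the 0/1/2 genotype (at most
#' two internal splits, at 0.5 and 1.5). The data are split 75/25
#' (stratified, seeded); hyperparameters are chosen on the training part by
#' stratified 5-fold cross-validation over the grid
#' criterion in {gini, entropy} x min impurity decrease in
#' {0, 0.1, 0.2, 0.3, 0.4, 0.5}, scored by the coefficient of determination
#' (r^2) of the 0/1 label predictions; the selected model's r^2 on the 25%
#' held-out part is returned.
#'
#' @param calls 0/1/2/NA calls.
#' @param phenotype 0/1 phenotype.
#' @param seed Integer seed for the split and folds. If a split lacks a
#'   phenotype class it is redrawn with an incremented seed, at most 5
#'   times.
#' @return Held-out r^2 score (1 = perfect prediction; <= 0 for a
#'   constant-prediction model).
#' @export
decision_tree_score <- function(calls, phenotype, seed = 1L) {
  ok <- !is.na(calls) & !is.na(phenotype)
  calls <- calls[ok]; phenotype <- phenotype[ok]
  if (length(unique(phenotype)) < 2L) stop("both phenotype classes required")
  grid <- expand.grid(mid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                      criterion = c("gini", "entropy"),
                      stringsAsFactors = FALSE)
  for (attempt in 0:5) {
    sp <- train_test_split(phenotype, 0.75, seed + attempt)
    tr_g <- calls[sp]; tr_y <- phenotype[sp]
    te_g <- calls[!sp]; te_y <- phenotype[!sp]
    if (length(unique(tr_y)) == 2L && length(unique(te_y)) == 2L) {
      cv_scores <- vapply(seq_len(nrow(grid)), function(i)
        tree_cv_r2(tr_g, tr_y, grid$criterion[i], grid$mid[i],
                   folds = 5L, seed = seed + attempt), numeric(1))
      best <- which.max(cv_scores)            # tie: first in grid order
      tree <- fit_genotype_tree(tr_g, tr_y, grid$criterion[best],
                                grid$mid[best])
      return(r2_score(te_y, predict_genotype_tree(tree, te_g)))
    }
    if (attempt == 5) stop("could not draw a split with both classes")
  }
}

train_test_split <- function(phenotype, frac, seed) {
  rng <- local_rng(seed)
  in_train <- logical(length(phenotype))
  for (cls in c(1L, 0L)) {
    idx <- which(phenotype == cls)
    idx <- idx[rng$sample(length(idx))]
    in_train[idx[seq_len(round(frac * length(idx)))]] <- TRUE
  }
  in_train
}

tree_cv_r2 <- function(g, y, criterion, mid, folds, seed) {
  fold_id <- stratified_folds(y, folds, seed)
  r2 <- numeric(0)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    if (length(unique(y[!te])) < 2L || var(y[te]) == 0) next
    tree <- fit_genotype_tree(g[!te], y[!te], criterion, mid)
    r2 <- c(r2, r2_score(y[te], predict_genotype_tree(tree, g[te])))
  }
  if (!length(r2)) return(-Inf)
  mean(r2)
}

r2_score <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(if (all(pred == y)) 1 else -Inf)
  1 - sum((y - pred)^2) / sst
}

impurity <- function(y, criterion) {
  if (!length(y)) return(0)
  p <- table(factor(y, levels = c(0L, 1L))) / length(y)
  if (criterion == "gini") 1 - sum(p^2) else entropy_bits(p)
}

# recursive greedy tree on a ternary feature; splits at 0.5 / 1.5 only.
# A split is accepted when its weighted impurity decrease
# (n_node/n_total) * (imp - wL*impL - wR*impR) reaches min_impurity_decrease.
fit_genotype_tree <- function(g, y, criterion, mid) {
  n_total <- length(g)
  grow <- function(idx) {
    yg <- y[idx]; gg <- g[idx]
    node <- list(pred = majority_class(yg))
    best <- NULL; best_dec <- -Inf
    for (thr in c(0.5, 1.5)) {
      left <- gg <= thr
      if (!any(left) || all(left)) next
      dec <- (length(idx) / n_total) *
        (impurity(yg, criterion) -
           mean(left) * impurity(yg[left], criterion) -
           mean(!left) * impurity(yg[!left], criterion))
      if (dec > best_dec + 1e-12) { best_dec <- dec; best <- thr }
    }
    if (!is.null(best) && best_dec >= mid - 1e-12 && best_dec > 1e-12) {
      node$split <- best
      node$left <- grow(idx[g[idx] <= best])
      node$right <- grow(idx[g[idx] > best])
    }
    node
  }
  grow(seq_along(g))
}

majority_class <- function(y) {
  if (sum(y == 1L) > sum(y == 0L)) 1L else 0L   # tie -> class 0
}

predict_genotype_tree <- function(tree, g) {
  vapply(g, function(x) {
    node <- tree
    while (!is.null(node$split))
      node <- if (x <= node$split) node$left else node$right
    node$pred
  }, integer(1))
}
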