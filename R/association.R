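#' Encode genotype calls for association modeling
#'
#' Additive keeps the 0/1/2 allele count; dominant codes carriers of the
#' alternate allele as 1; recessive codes only homozygous-alternate as 1;
#' codominant produces two dummy columns, `Het` (1 iff heterozygous) and
#' `Hom` (1 iff homozygous alternate). Missing calls propagate as `NA`.
#'
#' @param calls Integer vector of 0/1/2/NA calls.
#' @param scheme One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"codominant"`.
#' @return Numeric matrix with one column (or two for codominant), plus a
#'   `"scheme"` attribute.
#' @export
encode_genotype <- function(calls, scheme) {
  enc <- switch(scheme,
    additive  = matrix(as.numeric(calls), ncol = 1,
                       dimnames = list(NULL, "Add")),
    dominant  = matrix(as.numeric(calls >= 1L), ncol = 1,
                       dimnames = list(NULL, "Dom")),
    recessive = matrix(as.numeric(calls == 2L), ncol = 1,
                       dimnames = list(NULL, "Rec")),
    codominant = cbind(Het = as.numeric(calls == 1L),
                       Hom = as.numeric(calls == 2L)),
    stop("unknown encoding scheme: ", scheme))
  attr(enc, "scheme") <- scheme
  enc
}

#' Per-SNP logistic regression test
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares) of
#' case status on the encoded genotype plus optional covariates. For
#' one-column encodings the p-value is the Wald test on the genotype
#' coefficient; for the codominant encoding it is the 2-df likelihood-ratio
#' test against the covariate-only model.
#'
#' @param phenotype 0/1 vector (NA allowed, removed with complete cases).
#' @param encoded Matrix from [encode_genotype()].
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param max_iter,tol IRLS controls. Fits with any `|beta| > 15` on a
#'   genotype column are flagged as separated.
#' @return List: `beta`, `se`, `p_value`, `df`, `flagged` (TRUE on
#'   non-convergence, separation, rank deficiency, or a missing class).
#' @export
logistic_test <- function(phenotype, encoded, covariates = NULL,
                          max_iter = 25L, tol = 1e-12) {
  X <- cbind(`(Intercept)` = 1, encoded)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  cc <- complete.cases(X) & !is.na(phenotype)
  X <- X[cc, , drop = FALSE]; y <- phenotype[cc]
  n_enc <- ncol(encoded)
  failed <- list(beta = rep(NA_real_, n_enc), se = rep(NA_real_, n_enc),
                 p_value = NA_real_, df = n_enc, flagged = TRUE)
  if (length(unique(y)) < 2L) return(failed)
  if (qr(X)$rank < ncol(X)) return(failed)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial(),
                             control = list(epsilon = tol, maxit = max_iter))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(failed)
  enc_idx <- seq_len(n_enc) + 1L
  beta <- fit$coefficients[enc_idx]
  if (anyNA(beta) || any(abs(beta) > 15)) return(failed)
  cov_unscaled <- tryCatch(chol2inv(fit$qr$qr[seq_len(ncol(X)),
                                              seq_len(ncol(X)), drop = FALSE]),
                           error = function(e) NULL)
  if (is.null(cov_unscaled)) return(failed)
  se_all <- numeric(ncol(X))
  se_all[fit$qr$pivot] <- sqrt(diag(cov_unscaled))  # undo any QR pivoting
  se <- se_all[enc_idx]
  if (n_enc == 1L) {
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
  } else {
    null_fit <- suppressWarnings(glm.fit(
      X[, -enc_idx, drop = FALSE], y, family = binomial(),
      control = list(epsilon = tol, maxit = max_iter)))
    lr <- null_fit$deviance - fit$deviance
    p <- pchisq(max(lr, 0), df = n_enc, lower.tail = FALSE)
  }
  list(beta = unname(beta), se = unname(se), p_value = unname(p),
       df = n_enc, flagged = FALSE)
}

#' Allelic association test on a 2x2 allele-count table
#'
#' @param case_allele_counts,control_allele_counts Length-2 vectors
#'   `(ref, alt)` allele counts.
#' @param exact If `TRUE`, two-sided Fisher exact test; otherwise 1-df
#'   Pearson chi-square without continuity correction.
#' @return List: `statistic` (chi-square, NA for exact), `p_value`,
#'   `flagged` (TRUE when a table margin is zero).
#' @export
allelic_test <- function(case_allele_counts, control_allele_counts,
                         exact = FALSE) {
  tab <- rbind(case = case_allele_counts, control = control_allele_counts)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  if (exact) {
    list(statistic = NA_real_, p_value = fisher.test(tab)$p.value,
         flagged = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
         flagged = FALSE)
  }
}

#' Cochran-Armitage trend test on a 2x3 genotype table
#'
#' Trend weights (0, 1, 2) over genotype classes; 1-df chi-square p-value.
#'
#' @param genotype_counts_cases,genotype_counts_controls Length-3 counts for
#'   genotypes 0/1/2.
#' @return List: `statistic`, `p_value`, `flagged`.
#' @export
trend_test <- function(genotype_counts_cases, genotype_counts_controls) {
  r <- genotype_counts_cases; s <- genotype_counts_controls
  n_col <- r + s
  if (sum(n_col > 0) < 2L || sum(r) == 0 || sum(s) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  w <- c(0, 1, 2)
  N <- sum(n_col); R <- sum(r)
  num <- sum(w * (r - n_col * R / N))
  pbar <- R / N
  varT <- pbar * (1 - pbar) *
    (sum(w^2 * n_col) - sum(w * n_col)^2 / N)
  if (varT <= 0)
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  stat <- num^2 / varT
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
       flagged = FALSE)
}

#' Genotypic (2-df) chi-square test on a 2x3 genotype table
#'
#' Following the genotype-model convention of the mirrored tools, the test
#' is skipped (flagged) when any observed cell of the tested table falls
#' below `min_cell` (default 5), where the asymptotic chi-square reference
#' is unreliable; set `min_cell = 0` to test regardless (a zero column or
#' row still flags).
#'
#' @param table_2x3 Matrix with rows (cases, controls) and columns for
#'   genotypes 0/1/2.
#' @param min_cell Minimum observed count per cell (default 5).
#' @return List: `statistic`, `p_value`, `flagged`.
#' @export
genotypic_test <- function(table_2x3, min_cell = 5) {
  tab <- as.matrix(table_2x3)
  if (any(tab < min_cell))
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       flagged = ncol(tab) < 3L)
}

#' Collapsed dominant/recessive model test on a 2x3 genotype table
#'
#' Collapses the genotype table per the encoding (dominant: genotype 0 vs
#' 1+2; recessive: 0+1 vs 2) and applies the 1-df chi-square test. As in
#' [genotypic_test()], the test is flagged when any cell of the collapsed
#' 2x2 table is below `min_cell`.
#'
#' @param table_2x3 As in [genotypic_test()].
#' @param mode `"dom"` or `"rec"`.
#' @param min_cell Minimum observed count per collapsed cell (default 5).
#' @return List: `statistic`, `p_value`, `flagged`.
#' @export
model_collapsed_test <- function(table_2x3, mode = c("dom", "rec"),
                                 min_cell = 5) {
  mode <- match.arg(mode)
  tab <- as.matrix(table_2x3)
  col2 <- if (mode == "dom") cbind(tab[, 1], tab[, 2] + tab[, 3])
          else cbind(tab[, 1] + tab[, 2], tab[, 3])
  if (any(col2 < min_cell) ||
      any(colSums(col2) == 0) || any(rowSums(col2) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  ct <- suppressWarnings(chisq.test(col2, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       flagged = FALSE)
}

genotype_table <- function(calls, phenotype) {
  ok <- !is.na(calls) & !is.na(phenotype)
  # single tabulate pass: cases in bins 1..3, controls in bins 4..6
  idx <- calls[ok] + 1L + 3L * (phenotype[ok] == 0L)
  cnt <- tabulate(idx, nbins = 6L)
  matrix(cnt, 2, 3, byrow = TRUE,
         dimnames = list(c("case", "control"), c("0", "1", "2")))
}

table_to_alleles <- function(tab) {
  # rows case/control, cols genotype 0/1/2 -> (ref, alt) allele counts
  list(case = c(2 * tab[1, 1] + tab[1, 2], tab[1, 2] + 2 * tab[1, 3]),
       control = c(2 * tab[2, 1] + tab[2, 2], tab[2, 2] + 2 * tab[2, 3]))
}

min_model_p <- function(tab) {
  al <- table_to_alleles(tab)
  ps <- c(allelic = allelic_test(al$case, al$control)$p_value,
          trend = trend_test(tab[1, ], tab[2, ])$p_value,
          geno = genotypic_test(tab)$p_value,
          dom = model_collapsed_test(tab, "dom")$p_value,
          rec = model_collapsed_test(tab, "rec")$p_value)
  if (all(is.na(ps))) return(list(p = NA_real_, label = NA_character_))
  i <- which.min(ps)
  list(p = ps[[i]], label = names(ps)[i])
}

#' Best-model test with permutation p-value
#'
#' The observed statistic is the minimum p-value over the allelic, trend,
#' genotypic, dominant and recessive tests on the marker's 2x3 genotype
#' table. Its significance is calibrated empirically: phenotype labels are
#' permuted `permutations` times (seeded) and the empirical p-value is
#' `(1 + b) / (1 + m)` where `b` counts permutations whose min-p is at most
#' the observed one.
#'
#' @param calls 0/1/2/NA calls for one marker.
#' @param phenotype 0/1 phenotype vector.
#' @param permutations Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return List: `best_label`, `observed_min_p`, `empirical_p`, `flagged`.
#' @export
model_best_perm <- function(calls, phenotype, permutations = 1000L, seed = 1L) {
  if (permutations < 1L) stop("permutations must be >= 1")
  ok <- !is.na(calls) & !is.na(phenotype)
  calls <- calls[ok]; phenotype <- phenotype[ok]
  obs <- min_model_p(genotype_table(calls, phenotype))
  if (is.na(obs$p))
    return(list(best_label = NA_character_, observed_min_p = NA_real_,
                empirical_p = NA_real_, flagged = TRUE))
  rng <- local_rng(seed)
  b <- 0L
  for (i in seq_len(permutations)) {
    perm <- min_model_p(genotype_table(calls, rng$sample(phenotype)))
    if (!is.na(perm$p) && perm$p <= obs$p) b <- b + 1L
  }
  list(best_label = obs$label, observed_min_p = obs$p,
       empirical_p = (1 + b) / (1 + permutations), flagged = FALSE)
}

# private RNG stream that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    st <- .Random.seed
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    st
  }
  with_state <- function(expr) {
    old <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- .Random.seed
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(x, ...) with_state(sample(x, ...)),
    runif = function(n) with_state(runif(n)),
    rnorm = function(n, ...) with_state(rnorm(n, ...)),
    integers = function(n, max) with_state(sample.int(max, n, replace = TRUE))
  )
}
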