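# Independent oracles: every function here recomputes an expected value by
# direct enumeration or a closed formula, without touching the package's
# implementation path.

# HWE exact test by exhaustive enumeration: probability of each feasible
# heterozygote count from the direct log-factorial expression
# P(h) = n! / (n_AA! h! n_aa!) * 2^h * n_A! * n_a! / (2n)!
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_ref + n_het
  na <- 2 * n_hom_alt + n_het
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_common) - lfactorial(h) -
      lfactorial(hom_rare) + h * log(2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-10)])
}

# two-sided Fisher p on a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square by the direct sum(O - E)^2 / E computation
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Canberra distances by plain loops over the SNP universe
canberra_oracle <- function(sigma, tau, k = NULL) {
  total <- 0
  for (snp in names(sigma)) {
    s <- sigma[[snp]]; t <- tau[[snp]]
    if (!is.null(k)) { s <- min(s, k + 1); t <- min(t, k + 1) }
    total <- total + abs(t - s) / (t + s)
  }
  total
}

# mutual information I(G;Y) in bits by the direct double sum over the joint
mutual_info_oracle <- function(g, y) {
  n <- length(g)
  mi <- 0
  for (gv in unique(g)) for (yv in unique(y)) {
    pxy <- sum(g == gv & y == yv) / n
    if (pxy > 0)
      mi <- mi + pxy * log2(pxy / (sum(g == gv) / n * sum(y == yv) / n))
  }
  mi
}

# saturated binomial log-likelihood of a 2x3 genotype table (rows
# case/control), and the genotype-blind null log-likelihood
loglik_2x3_saturated <- function(tab) {
  ll <- 0
  for (j in seq_len(ncol(tab))) {
    nj <- sum(tab[, j]); cj <- tab[1, j]
    if (nj == 0) next
    for (cnt in c(cj, nj - cj)) if (cnt > 0) ll <- ll + cnt * log(cnt / nj)
  }
  ll
}
loglik_2x3_null <- function(tab) {
  n <- sum(tab); ca <- sum(tab[1, ])
  ca * log(ca / n) + (n - ca) * log((n - ca) / n)
}

# closed-form MDR balanced accuracy of a 2x3 table at train = test
mdr_ba_oracle <- function(tab) {
  ratio_all <- sum(tab[1, ]) / sum(tab[2, ])
  high <- vapply(1:3, function(j) {
    if (sum(tab[, j]) == 0) return(FALSE)
    tab[2, j] == 0 && tab[1, j] > 0 || tab[1, j] / tab[2, j] > ratio_all
  }, logical(1))
  tp <- sum(tab[1, high]); fn <- sum(tab[1, !high])
  tn <- sum(tab[2, !high]); fp <- sum(tab[2, high])
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# expand a 2x3 genotype table (rows case/control) into call/phenotype vectors
table_to_vectors <- function(tab) {
  g <- ph <- integer(0)
  for (j in 1:3) {
    g <- c(g, rep(j - 1L, tab[1, j] + tab[2, j]))
    ph <- c(ph, rep(1L, tab[1, j]), rep(0L, tab[2, j]))
  }
  list(calls = g, phenotype = ph)
}

# random full ranking over n markers
random_ranking <- function(n, ids = sprintf("m%04d", seq_len(n))) {
  setNames(sample(n), ids)
}

# small genotype_matrix from a calls matrix
make_gm <- function(calls, chromosome = NULL, position = NULL,
                    phenotype = NULL) {
  m <- nrow(calls); n <- ncol(calls)
  markers <- data.frame(
    marker_id = sprintf("m%03d", seq_len(m)),
    chromosome = chromosome %||% rep("1", m),
    position_bp = position %||% (1000L * seq_len(m)),
    allele_ref = "A", allele_alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        phenotype = phenotype %||% rep(NA_integer_, n),
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
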