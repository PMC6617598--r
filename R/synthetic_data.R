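#' Simulation configuration for synthetic case-control GWAS data
#'
#' Describes a dataset of biallelic autosomal SNPs in Hardy-Weinberg
#' equilibrium with block-wise linkage disequilibrium, a binary phenotype
#' generated by a logistic liability model with planted per-SNP effects and
#' an age-like covariate, and optional two-subpopulation structure.
#'
#' @param n_cases,n_controls Target sample counts (sampled exactly).
#' @param n_markers Number of markers.
#' @param maf_range Range the per-marker minor allele frequencies are drawn
#'   from, within `(0, 0.5]`; the default floor 0.05 matches the QC MAF
#'   filter so null markers survive QC.
#' @param ld_block_size Markers per LD block; each block lives on one
#'   chromosome.
#' @param ld_rho AR(1) correlation of the latent haplotype field within a
#'   block, in `[0, 1)`; 0 gives independent markers.
#' @param planted_effects Data frame with columns `marker` (index), `model`
#'   (`"additive"`, `"dominant"`, `"recessive"`, `"heterozygote"`,
#'   `"genotypic"`) and `odds_ratio` (> 0); optional `odds_ratio_hom` for
#'   the genotypic model (default `odds_ratio^2`).
#' @param covariate List `age_mean`, `age_sd`, `age_coef` (log-odds per
#'   year); set `age_coef = 0` for no covariate effect.
#' @param structure Optional list `fraction` (share of samples in
#'   subpopulation 2) and `divergence` (absolute allele-frequency offset
#'   between subpopulations).
#' @param missing_rate Probability a call is masked missing.
#' @param seed Integer seed; every random draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 300L, n_controls = 300L, n_markers = 1000L,
                       maf_range = c(0.05, 0.5), ld_block_size = 10L,
                       ld_rho = 0.5, planted_effects = NULL,
                       covariate = list(age_mean = 55, age_sd = 10,
                                        age_coef = 0.02),
                       structure = NULL, missing_rate = 0.002, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_markers >= 1L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1L, ld_rho >= 0, ld_rho < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    stopifnot(all(planted_effects$marker >= 1L),
              all(planted_effects$marker <= n_markers),
              !anyDuplicated(planted_effects$marker),
              all(planted_effects$odds_ratio > 0),
              all(planted_effects$model %in%
                    c("additive", "dominant", "recessive",
                      "heterozygote", "genotypic")))
  }
  if (!is.null(structure))
    stopifnot(structure$fraction > 0, structure$fraction < 1,
              structure$divergence >= 0)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_markers = as.integer(n_markers), maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 planted_effects = planted_effects, covariate = covariate,
                 structure = structure, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate genotypes under blockwise LD and HWE
#'
#' Haplotypes are drawn from a Gaussian copula: per LD block, a latent
#' standard-normal AR(1) vector (correlation `ld_rho` between adjacent
#' markers) is thresholded per marker at the quantile implied by its
#' alternate-allele frequency; two haplotypes per individual are summed to
#' a 0/1/2 call. Marker MAFs are uniform in `maf_range`. Under population
#' structure, subpopulation allele frequencies are offset by
#' `+/- divergence / 2` (sign per marker random). Missing calls are masked
#' uniformly at random. Blocks are laid out on chromosomes 1..22 with 2 kb
#' spacing within a block and 500 kb between blocks.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of individuals to generate (defaults to
#'   `n_cases + n_controls`; the phenotype step may need a larger pool).
#' @return A `genotype_matrix` with phenotypes all `NA`.
#' @export
simulate_genotypes <- function(config, n_samples = NULL) {
  n <- n_samples %||% (config$n_cases + config$n_controls)
  with_seed(config$seed, {
    m <- config$n_markers
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    n_blocks <- ceiling(m / config$ld_block_size)
    block_of <- rep(seq_len(n_blocks), each = config$ld_block_size)[seq_len(m)]
    chrom <- as.character((block_of - 1L) %% 22L + 1L)
    pos <- integer(m)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      chunk <- (b - 1L) %/% 22L            # how many blocks precede on this chr
      pos[idx] <- 1e6 + chunk * 5e5 + 2000L * seq_along(idx)
    }

    freq <- matrix(maf, m, 2)              # alt-allele freq per subpop
    pop <- rep(1L, n)
    if (!is.null(config$structure)) {
      d <- config$structure$divergence
      sgn <- sample(c(-1, 1), m, replace = TRUE)
      freq[, 1] <- pmin(pmax(maf + sgn * d / 2, 0.01), 0.99)
      freq[, 2] <- pmin(pmax(maf - sgn * d / 2, 0.01), 0.99)
      pop <- ifelse(seq_len(n) <= round(n * (1 - config$structure$fraction)),
                    1L, 2L)
    }

    calls <- matrix(0L, m, n)
    rho <- config$ld_rho
    for (hap in 1:2) {
      z <- matrix(rnorm(m * n), m, n)
      if (rho > 0) {
        for (b in seq_len(n_blocks)) {
          idx <- which(block_of == b)
          if (length(idx) > 1L) {
            for (r in seq(2L, length(idx)))
              z[idx[r], ] <- rho * z[idx[r - 1L], ] +
                sqrt(1 - rho^2) * z[idx[r], ]
          }
        }
      }
      thr <- qnorm(freq[, pop, drop = FALSE])  # m x n thresholds
      calls <- calls + (z < thr)
    }
    if (config$missing_rate > 0)
      calls[runif(m * n) < config$missing_rate] <- NA_integer_

    markers <- data.frame(
      marker_id = sprintf("snp%05d", seq_len(m)),
      chromosome = chrom, position_bp = pos,
      allele_ref = "A", allele_alt = "G", stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sprintf("ind%05d", seq_len(n)),
                          phenotype = NA_integer_, stringsAsFactors = FALSE)
    if (!is.null(config$structure)) samples$subpop <- pop
    genotype_matrix(calls, markers, samples)
  })
}

planted_predictor <- function(calls, model) {
  switch(model,
    additive = as.numeric(calls),
    dominant = as.numeric(calls >= 1L),
    recessive = as.numeric(calls == 2L),
    heterozygote = as.numeric(calls == 1L),
    genotypic = as.numeric(calls == 1L),   # het part; hom handled separately
    stop("unknown planted model: ", model))
}

#' Simulate a binary phenotype with planted genetic effects
#'
#' Logistic liability: `logit P(case) = alpha + sum_j beta_j x_j + gamma
#' age`, with `beta_j = log(odds_ratio_j)` on the model-specific encoding
#' of each planted marker and age drawn from the configured normal
#' distribution. The intercept `alpha` is tuned by bisection so the
#' expected case fraction over the supplied individuals matches
#' `n_cases / (n_cases + n_controls)`; case status is then drawn per
#' individual.
#'
#' @param gm A `genotype_matrix` (genotypes only; missing calls count as 0
#'   in planted predictors).
#' @param config The [sim_config()] used to generate it.
#' @return List: `phenotype` (0/1 per individual), `age`, `alpha`.
#' @export
simulate_phenotype <- function(gm, config) {
  n <- ncol(gm$calls)
  with_seed(config$seed + 1L, {
    age <- rnorm(n, config$covariate$age_mean, config$covariate$age_sd)
    eta <- config$covariate$age_coef * (age - config$covariate$age_mean)
    pe <- config$planted_effects
    if (!is.null(pe)) {
      for (r in seq_len(nrow(pe))) {
        # markers are stored coordinate-sorted: resolve the planted index
        # (generation order) through its id
        row <- match(sprintf("snp%05d", pe$marker[r]), gm$markers$marker_id)
        calls <- gm$calls[row, ]
        calls[is.na(calls)] <- 0L
        eta <- eta + log(pe$odds_ratio[r]) *
          planted_predictor(calls, pe$model[r])
        if (pe$model[r] == "genotypic") {
          or_hom <- if ("odds_ratio_hom" %in% names(pe) &&
                        !is.na(pe$odds_ratio_hom[r])) pe$odds_ratio_hom[r]
                    else pe$odds_ratio[r]^2
          eta <- eta + log(or_hom) * as.numeric(calls == 2L)
        }
      }
    }
    target <- config$n_cases / (config$n_cases + config$n_controls)
    f <- function(alpha) mean(stats::plogis(alpha + eta)) - target
    if (f(-50) > 0 || f(50) < 0) stop("case fraction unattainable")
    alpha <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
    phenotype <- as.integer(runif(n) < stats::plogis(alpha + eta))
    list(phenotype = phenotype, age = age, alpha = alpha)
  })
}

#' Simulate a complete case-control GWAS dataset
#'
#' Generates an oversampled genotype pool, assigns phenotypes under the
#' liability model, then samples exactly `n_cases` cases and `n_controls`
#' controls (error if the pool cannot supply them).
#'
#' @param config A [sim_config()].
#' @param oversample Pool inflation factor (default 3).
#' @return List: `genotypes` (a `genotype_matrix` with phenotype and `age`
#'   covariate attached) and `truth` (data frame of planted markers:
#'   `marker_id`, `model`, `odds_ratio`).
#' @export
simulate_gwas <- function(config, oversample = 3) {
  pool_n <- ceiling((config$n_cases + config$n_controls) * oversample)
  gm <- simulate_genotypes(config, n_samples = pool_n)
  ph <- simulate_phenotype(gm, config)
  cases <- which(ph$phenotype == 1L)
  ctrls <- which(ph$phenotype == 0L)
  if (length(cases) < config$n_cases || length(ctrls) < config$n_controls)
    stop("pool too small for requested case/control counts; ",
         "increase oversample")
  sel <- with_seed(config$seed + 2L,
                   c(sample(cases, config$n_cases),
                     sample(ctrls, config$n_controls)))
  sel <- sort(sel)
  gm <- subset_genotypes(gm, samples = sel)
  gm$samples$phenotype <- ph$phenotype[sel]
  gm$samples$age <- ph$age[sel]
  truth <- if (is.null(config$planted_effects)) {
    data.frame(marker_id = character(), model = character(),
               odds_ratio = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      marker_id = sprintf("snp%05d", config$planted_effects$marker),
      model = config$planted_effects$model,
      odds_ratio = config$planted_effects$odds_ratio,
      stringsAsFactors = FALSE)
  }
  list(genotypes = gm, truth = truth)
}

#' Write a simulated dataset as PED/MAP + covariate + truth files
#'
#' Emits `<prefix>.ped`, `<prefix>.map`, `<prefix>.covar` and
#' `<prefix>.truth.tsv` under `out_dir`, readable back with
#' [read_ped_map()] / [attach_covariates()].
#'
#' @param sim Output of [simulate_gwas()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix (default `"synthetic"`).
#' @return Invisibly, the named list of paths.
#' @export
write_fixture <- function(sim, out_dir, prefix = "synthetic") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ped = file.path(out_dir, paste0(prefix, ".ped")),
                map = file.path(out_dir, paste0(prefix, ".map")),
                covar = file.path(out_dir, paste0(prefix, ".covar")),
                truth = file.path(out_dir, paste0(prefix, ".truth.tsv")))
  write_ped_map(sim$genotypes, paths$ped, paths$map)
  write_covariates(sim$genotypes, paths$covar)
  write.table(sim$truth, paths$truth, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(paths)
}
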