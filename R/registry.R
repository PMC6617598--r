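#' Define one analysis approach
#'
#' An approach is a choice of method, genotype encoding, and implementation
#' variant, with per-approach options (permutation count, CV folds, seeds).
#' Covariate adjustment is a property of the method: regression-based
#' methods (and externally imported mixed/liability model rankings) support
#' it, contingency-table and machine-learning scorers do not.
#'
#' @param name Unique approach name (e.g. `"plink.add"`).
#' @param method One of `"logistic"`, `"allelic_chisq"`, `"allelic_fisher"`,
#'   `"trend"`, `"genotypic"`, `"model_dom"`, `"model_rec"`,
#'   `"model_best_perm"`, `"mdr_ba"`, `"entropy"`, `"dec_tree"`,
#'   `"external_import"`.
#' @param encoding `"additive"`, `"dominant"`, `"recessive"`,
#'   `"codominant"`, or `"none"` for encoding-free methods.
#' @param covariate_adjustment Whether covariates are included; only
#'   allowed for methods that support it.
#' @param options Named list (e.g. `permutations`, `seed`, `path` for
#'   external imports).
#' @return An `approach_spec` object.
#' @export
approach_spec <- function(name, method, encoding = "none",
                          covariate_adjustment = FALSE, options = list()) {
  methods <- c("logistic", "allelic_chisq", "allelic_fisher", "trend",
               "genotypic", "model_dom", "model_rec", "model_best_perm",
               "mdr_ba", "entropy", "dec_tree", "external_import")
  if (!method %in% methods) stop("unknown method: ", method)
  if (!encoding %in% c("additive", "dominant", "recessive", "codominant",
                       "none"))
    stop("unknown encoding: ", encoding)
  supports_cov <- method %in% c("logistic", "external_import")
  if (covariate_adjustment && !supports_cov)
    stop("method ", method, " does not support covariate adjustment")
  structure(list(name = name, method = method, encoding = encoding,
                 covariate_adjustment = covariate_adjustment,
                 options = options),
            class = "approach_spec")
}

#' @export
print.approach_spec <- function(x, ...) {
  cat("approach_spec:", x$name, "(", x$method, "/", x$encoding,
      if (x$covariate_adjustment) "+cov" else "", ")\n")
  invisible(x)
}

#' The default approach registry
#'
#' Enumerates the full suite of 25 univariate (method, encoding,
#' implementation) configurations: PLINK- and PLATO-style logistic
#' regressions under the four encodings, the basic allelic association
#' tests (asymptotic, Fisher exact, and empirically calibrated variants),
#' the five genotype-model tests with a permutation-based best-model
#' selector, the three machine-learning scorers, and import adapters for
#' four externally computed rankings (mixed-model and liability-scale
#' methods whose implementations live outside this package).
#'
#' @param external_paths Optional named character vector mapping the
#'   external approach names (`carat`, `carat.loco`, `ltmlm`, `leap`) to
#'   ranked-list TSV files; entries without a path are kept in the
#'   registry but can only run when a path is configured.
#' @param permutations Permutation count for the empirically calibrated
#'   entries (default 1000).
#' @return Named list of `approach_spec` objects (length 25).
#' @export
default_approach_registry <- function(external_paths = NULL,
                                      permutations = 1000L) {
  sp <- list()
  add <- function(s) sp[[s$name]] <<- s
  # logistic regressions, two implementation variants
  for (enc in c("additive", "dominant", "recessive")) {
    short <- substr(enc, 1, 3)
    add(approach_spec(paste0("plink.", short), "logistic", enc,
                      covariate_adjustment = TRUE))
    add(approach_spec(paste0("plato.", short), "logistic", enc,
                      covariate_adjustment = TRUE,
                      options = list(variant = "plato")))
  }
  add(approach_spec("plato.codom", "logistic", "codominant",
                    covariate_adjustment = TRUE,
                    options = list(variant = "plato")))
  # basic association tests on allele counts
  add(approach_spec("plink.assoc", "allelic_chisq"))
  add(approach_spec("plink.assoc.fisher", "allelic_fisher"))
  add(approach_spec("plink.assoc.perm", "allelic_chisq",
                    options = list(permutations = permutations)))
  add(approach_spec("plink.assoc.mperm", "allelic_chisq",
                    options = list(permutations = permutations,
                                   variant = "maxT")))
  # genotype-model tests
  add(approach_spec("plink.model.allelic", "allelic_chisq",
                    options = list(variant = "model")))
  add(approach_spec("plink.model.trend", "trend"))
  add(approach_spec("plink.model.geno", "genotypic"))
  add(approach_spec("plink.model.dom", "model_dom"))
  add(approach_spec("plink.model.rec", "model_rec"))
  add(approach_spec("plink.model.best", "model_best_perm",
                    options = list(permutations = 1L, asymptotic = TRUE)))
  add(approach_spec("plink.model.best.perm", "model_best_perm",
                    options = list(permutations = permutations)))
  # machine-learning scorers
  add(approach_spec("mdr.ba", "mdr_ba", options = list(folds = 10L)))
  add(approach_spec("entropy", "entropy"))
  add(approach_spec("dec.tree", "dec_tree"))
  # external import adapters
  for (ext in c("carat", "carat.loco", "ltmlm", "leap")) {
    path <- if (!is.null(external_paths) && ext %in% names(external_paths))
      external_paths[[ext]] else NA_character_
    add(approach_spec(ext, "external_import", covariate_adjustment = TRUE,
                      options = list(path = path)))
  }
  sp
}

#' Run one approach over a genotype matrix
#'
#' Dispatches on the approach's method, computes per-marker scores or
#' p-values, and assembles the full ranked list (failed markers ranked
#' last). Covariates are included for approaches with
#' `covariate_adjustment = TRUE`.
#'
#' @param gm A `genotype_matrix` (phenotype 0/1 in `$samples`).
#' @param spec An `approach_spec`.
#' @param seed Base seed for approaches with internal randomness
#'   (permutations, CV); the effective per-approach seed is derived from
#'   it and the approach name, so approaches are decoupled.
#' @return A `ranked_list`.
#' @export
run_approach <- function(gm, spec, seed = 1L) {
  ph <- gm$samples$phenotype
  map <- gm$markers
  aseed <- derive_seed(seed, spec$name)
  covs <- NULL
  if (spec$covariate_adjustment) {
    cn <- covariate_names(gm)
    if (length(cn)) covs <- as.matrix(gm$samples[, cn, drop = FALSE])
  }
  m <- nrow(gm$calls)

  if (spec$method == "external_import") {
    path <- spec$options$path
    if (is.null(path) || is.na(path))
      stop("approach ", spec$name, " has no configured ranking file")
    return(import_external_ranking(path, spec$name, map))
  }

  if (spec$method == "logistic") {
    p <- numeric(m); fl <- logical(m)
    for (i in seq_len(m)) {
      r <- logistic_test(ph, encode_genotype(gm$calls[i, ], spec$encoding),
                         covs)
      p[i] <- r$p_value; fl[i] <- r$flagged
    }
    return(rank_snps(map, p, "p_ascending", fl, spec$name))
  }

  if (spec$method %in% c("allelic_chisq", "allelic_fisher", "trend",
                         "genotypic", "model_dom", "model_rec")) {
    perms <- spec$options$permutations
    p <- numeric(m); fl <- logical(m)
    stat_fn <- function(tab) switch(spec$method,
      allelic_chisq = { al <- table_to_alleles(tab)
                        allelic_test(al$case, al$control, exact = FALSE) },
      allelic_fisher = { al <- table_to_alleles(tab)
                         allelic_test(al$case, al$control, exact = TRUE) },
      trend = trend_test(tab[1, ], tab[2, ]),
      genotypic = genotypic_test(tab),
      model_dom = model_collapsed_test(tab, "dom"),
      model_rec = model_collapsed_test(tab, "rec"))
    for (i in seq_len(m)) {
      r <- stat_fn(genotype_table(gm$calls[i, ], ph))
      p[i] <- r$p_value; fl[i] <- r$flagged
    }
    if (!is.null(perms)) {
      # empirically calibrated variant: pointwise permutation p-values
      rng <- local_rng(aseed)
      perm_p <- matrix(NA_real_, m, perms)
      for (b in seq_len(perms)) {
        php <- rng$sample(ph)
        for (i in seq_len(m))
          perm_p[i, b] <- stat_fn(genotype_table(gm$calls[i, ], php))$p_value
      }
      if (identical(spec$options$variant, "maxT")) {
        best <- apply(perm_p, 2, min, na.rm = TRUE)   # family-wise null
        p <- vapply(p, function(x)
          if (is.na(x)) NA_real_
          else (1 + sum(best <= x)) / (1 + perms), numeric(1))
      } else {
        p <- vapply(seq_len(m), function(i)
          if (is.na(p[i])) NA_real_
          else (1 + sum(perm_p[i, ] <= p[i], na.rm = TRUE)) / (1 + perms),
          numeric(1))
      }
    }
    return(rank_snps(map, p, "p_ascending", fl, spec$name))
  }

  if (spec$method == "model_best_perm") {
    perms <- spec$options$permutations %||% 1000L
    p <- numeric(m); fl <- logical(m)
    for (i in seq_len(m)) {
      r <- model_best_perm(gm$calls[i, ], ph, permutations = perms,
                           seed = aseed + i)
      p[i] <- if (isTRUE(spec$options$asymptotic)) r$observed_min_p
              else r$empirical_p
      fl[i] <- r$flagged
    }
    return(rank_snps(map, p, "p_ascending", fl, spec$name))
  }

  if (spec$method %in% c("mdr_ba", "entropy", "dec_tree")) {
    s <- numeric(m); fl <- logical(m)
    for (i in seq_len(m)) {
      s[i] <- tryCatch(switch(spec$method,
        mdr_ba = mdr_1way(gm$calls[i, ], ph,
                          folds = spec$options$folds %||% 10L,
                          seed = aseed + i),
        entropy = entropy_gain(gm$calls[i, ], ph),
        dec_tree = decision_tree_score(gm$calls[i, ], ph, seed = aseed + i)),
        error = function(e) NA_real_)
      fl[i] <- is.na(s[i])
    }
    return(rank_snps(map, s, "score_descending", fl, spec$name))
  }
  stop("unhandled method: ", spec$method)
}

# stable small-integer seed from a base seed and the approach name
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L) %% 100000L
  (as.integer(seed) * 7919L + h) %% .Machine$integer.max
}
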