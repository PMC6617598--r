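#' Construct a genotype matrix object
#'
#' The central data container: a markers-by-samples matrix of alternate-allele
#' counts (0, 1, 2, or `NA` for missing) together with a marker map and a
#' sample table holding phenotypes and covariates.
#'
#' @param calls Integer matrix, markers in rows, samples in columns; entries
#'   in `{0, 1, 2, NA}` counting alternate alleles.
#' @param markers Data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_ref`, `allele_alt`. Marker ids must be unique and
#'   ref/alt alleles distinct per marker.
#' @param samples Data frame with columns `sample_id` (unique) and `phenotype`
#'   (0 = control, 1 = case, `NA` = missing); any further numeric columns are
#'   treated as covariates.
#'
#' @details Markers are stored sorted by `(chromosome, position_bp)`;
#'   chromosomes are ordered numerically ("1".."22"). Only autosomal
#'   biallelic markers are supported.
#'
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `markers`, `samples`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(markers), is.data.frame(samples))
  req_m <- c("marker_id", "chromosome", "position_bp", "allele_ref", "allele_alt")
  if (!all(req_m %in% names(markers)))
    stop("markers must have columns: ", paste(req_m, collapse = ", "))
  if (!all(c("sample_id", "phenotype") %in% names(samples)))
    stop("samples must have columns sample_id, phenotype")
  if (nrow(calls) != nrow(markers))
    stop("calls has ", nrow(calls), " rows but markers has ", nrow(markers))
  if (ncol(calls) != nrow(samples))
    stop("calls has ", ncol(calls), " columns but samples has ", nrow(samples))
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  if (any(markers$allele_ref == markers$allele_alt))
    stop("allele_ref must differ from allele_alt for every marker")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be 0, 1, 2 or NA")
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  if (any(markers$position_bp < 0L)) stop("position_bp must be non-negative")

  ord <- order(chrom_order(markers$chromosome), markers$position_bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- markers$marker_id
  colnames(calls) <- samples$sample_id
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_matrix")
}

# numeric chromosome ordering with a stable fallback for non-numeric labels
chrom_order <- function(chr) {
  n <- suppressWarnings(as.numeric(chr))
  n[is.na(n)] <- 1e6 + as.numeric(factor(chr[is.na(n)]))
  n
}

#' @export
print.genotype_matrix <- function(x, ...) {
  ph <- x$samples$phenotype
  cat("genotype_matrix: ", nrow(x$calls), " markers x ", ncol(x$calls),
      " samples (", sum(ph == 1L, na.rm = TRUE), " cases, ",
      sum(ph == 0L, na.rm = TRUE), " controls)\n", sep = "")
  covs <- covariate_names(x)
  if (length(covs)) cat("covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Names of covariate columns in the sample table
#' @param gm A `genotype_matrix`.
#' @return Character vector of covariate column names (may be empty).
#' @export
covariate_names <- function(gm) {
  setdiff(names(gm$samples), c("sample_id", "phenotype", "family_id",
                               "father_id", "mother_id", "sex"))
}

#' Subset a genotype matrix by markers and/or samples
#'
#' @param gm A `genotype_matrix`.
#' @param markers Optional marker ids or logical/integer index over markers.
#' @param samples Optional sample ids or logical/integer index over samples.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, markers = NULL, samples = NULL) {
  mi <- resolve_index(markers, gm$markers$marker_id, "marker")
  si <- resolve_index(samples, gm$samples$sample_id, "sample")
  genotype_matrix(gm$calls[mi, si, drop = FALSE],
                  gm$markers[mi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    miss <- setdiff(idx, ids)
    if (length(miss))
      stop("unknown ", what, " id(s): ", paste(head(miss, 5), collapse = ", "))
    return(match(idx, ids))
  }
  seq_along(ids)[idx]
}
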