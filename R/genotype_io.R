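#' Read PLINK PED/MAP text files
#'
#' Reads a whitespace-delimited PED file (6 header fields, then two allele
#' fields per marker) and its MAP companion (chromosome, marker id, genetic
#' distance, base-pair position) into a [genotype_matrix()].
#'
#' Calls count alternate alleles. Unless `alt_alleles` is supplied, the
#' alternate allele at each marker is the minor allele observed across all
#' samples; a 0.5/0.5 tie is broken by taking the alphabetically later allele
#' as alternate. "0 0" allele pairs become missing calls. Phenotype codes
#' follow PLINK: 1 = control, 2 = case, 0/-9 = missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param alt_alleles Optional named character vector `marker_id -> alt allele`
#'   overriding minor-allele assignment.
#' @param drop_multiallelic If `TRUE`, markers with more than two observed
#'   alleles are dropped with a warning; if `FALSE` (default) they raise an
#'   error.
#' @return A `genotype_matrix`.
#' @export
read_ped_map <- function(ped_path, map_path, alt_alleles = NULL,
                         drop_multiallelic = FALSE) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, colClasses = "character",
                    col.names = c("chromosome", "marker_id", "cm", "position_bp"))
  n_mark <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_samp <- length(lines)
  if (n_samp == 0L) stop("PED file is empty: ", ped_path)

  a1 <- matrix(NA_character_, n_mark, n_samp)
  a2 <- matrix(NA_character_, n_mark, n_samp)
  samp <- data.frame(family_id = character(n_samp), sample_id = character(n_samp),
                     phenotype = integer(n_samp), sex = integer(n_samp),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_mark)
      stop("PED line ", i, ": expected ", 6L + 2L * n_mark, " fields (6 + 2 x ",
           n_mark, " markers from MAP), found ", length(f))
    samp$family_id[i] <- f[1]
    samp$sample_id[i] <- f[2]
    samp$sex[i] <- suppressWarnings(as.integer(f[5]))
    samp$phenotype[i] <- decode_plink_pheno(f[6])
    al <- f[-(1:6)]
    a1[, i] <- al[c(TRUE, FALSE)]
    a2[, i] <- al[c(FALSE, TRUE)]
  }
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  # a genotype is missing if either allele is missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA
  a2[miss] <- NA

  calls <- matrix(NA_integer_, n_mark, n_samp)
  ref <- alt <- character(n_mark)
  drop <- logical(n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[j, ], a2[j, ])
    obs <- obs[!is.na(obs)]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      if (drop_multiallelic) {
        warning("marker ", map$marker_id[j], " has >2 alleles (",
                paste(alleles, collapse = ","), "); dropped")
        drop[j] <- TRUE
        next
      }
      stop("marker ", map$marker_id[j], " is multi-allelic: ",
           paste(alleles, collapse = ","))
    }
    aa <- assign_alt_allele(map$marker_id[j], alleles, obs, alt_alleles)
    alt[j] <- aa$alt; ref[j] <- aa$ref
    calls[j, ] <- (a1[j, ] == alt[j]) + (a2[j, ] == alt[j])
  }
  keep <- !drop
  markers <- data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
                        position_bp = as.integer(map$position_bp),
                        allele_ref = ref, allele_alt = alt,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
  samples <- data.frame(sample_id = samp$sample_id, phenotype = samp$phenotype,
                        family_id = samp$family_id, sex = samp$sex,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls[keep, , drop = FALSE], markers, samples)
}

decode_plink_pheno <- function(x) {
  switch(x, "1" = 0L, "2" = 1L, "0" = NA_integer_, "-9" = NA_integer_,
         stop("unrecognized phenotype code: ", x))
}

assign_alt_allele <- function(id, alleles, obs, alt_alleles) {
  if (!is.null(alt_alleles) && id %in% names(alt_alleles)) {
    alt <- alt_alleles[[id]]
    ref <- setdiff(alleles, alt)
    if (length(alleles) == 1L && alleles == alt) ref <- "?"
    if (length(ref) == 0L) ref <- "?"
    return(list(ref = ref[1], alt = alt))
  }
  if (length(alleles) == 0L) return(list(ref = "?", alt = "!"))   # all missing
  if (length(alleles) == 1L) return(list(ref = alleles, alt = "?")) # monomorphic
  f1 <- mean(obs == alleles[1])
  if (f1 < 0.5) list(ref = alleles[2], alt = alleles[1])
  else if (f1 > 0.5) list(ref = alleles[1], alt = alleles[2])
  else list(ref = alleles[1], alt = alleles[2])  # tie: alphabetically later is alt
}

#' Write a genotype matrix as PLINK PED/MAP text files
#'
#' Inverse of [read_ped_map()]: calls are expanded back to allele pairs
#' (missing calls written as "0 0"), phenotypes to PLINK 1/2 coding.
#'
#' @param gm A `genotype_matrix`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the PED path.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  m <- gm$markers
  write.table(data.frame(m$chromosome, m$marker_id, 0, m$position_bp),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n_mark <- nrow(m); n_samp <- nrow(gm$samples)
  ph <- ifelse(is.na(gm$samples$phenotype), "0",
               ifelse(gm$samples$phenotype == 1L, "2", "1"))
  fid <- if ("family_id" %in% names(gm$samples)) gm$samples$family_id
         else gm$samples$sample_id
  sex <- if ("sex" %in% names(gm$samples)) gm$samples$sex else rep(0L, n_samp)
  con <- file(ped_path, "w"); on.exit(close(con))
  for (i in seq_len(n_samp)) {
    g <- gm$calls[, i]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, m$allele_alt, m$allele_ref))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, m$allele_alt, m$allele_ref))
    pair <- character(2L * n_mark)
    pair[c(TRUE, FALSE)] <- al1
    pair[c(FALSE, TRUE)] <- al2
    writeLines(paste(c(fid[i], gm$samples$sample_id[i], "0", "0",
                       sex[i], ph[i], pair), collapse = " "), con)
  }
  invisible(ped_path)
}

#' Read a PLINK-style covariate file
#'
#' Whitespace-delimited with a header line; the first two columns are FID and
#' IID, all remaining columns are numeric covariates. Covariates are merged
#' into the sample table of `gm` by IID.
#'
#' @param gm A `genotype_matrix`.
#' @param path Covariate file path.
#' @return `gm` with covariate columns added to `$samples`.
#' @export
attach_covariates <- function(gm, path) {
  cv <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(cv) < 3L) stop("covariate file needs FID, IID and >=1 covariate column")
  iid <- as.character(cv[[2]])
  miss <- setdiff(gm$samples$sample_id, iid)
  if (length(miss))
    stop("covariate file lacks sample(s): ", paste(head(miss, 5), collapse = ", "))
  idx <- match(gm$samples$sample_id, iid)
  for (nm in names(cv)[-(1:2)]) {
    v <- cv[[nm]][idx]
    if (!is.numeric(v)) stop("covariate column ", nm, " is not numeric")
    gm$samples[[nm]] <- v
  }
  gm
}

#' Write a covariate file (PLINK --covar dialect)
#' @param gm A `genotype_matrix` with covariate columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_covariates <- function(gm, path) {
  covs <- covariate_names(gm)
  fid <- if ("family_id" %in% names(gm$samples)) gm$samples$family_id
         else gm$samples$sample_id
  out <- cbind(data.frame(FID = fid, IID = gm$samples$sample_id),
               gm$samples[, covs, drop = FALSE])
  write.table(out, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}
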