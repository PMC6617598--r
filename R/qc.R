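#' Minor allele frequency of one marker
#'
#' @param calls Integer vector of 0/1/2/NA alternate-allele counts.
#' @return `min(p_alt, 1 - p_alt)` where `p_alt` is the alternate-allele
#'   frequency over non-missing calls; always in `[0, 0.5]`.
#' @export
compute_maf <- function(calls) {
  ok <- !is.na(calls)
  n <- sum(ok)
  if (n == 0L) stop("MAF undefined: all calls missing")
  p <- sum(calls[ok]) / (2 * n)
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Conditional exact test: with the allele counts fixed, heterozygote counts
#' of the same parity as the minor-allele count index all reachable genotype
#' configurations; the two-sided p-value sums the probabilities of every
#' configuration whose conditional probability does not exceed that of the
#' observed one (probability ordering).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n < 1L) stop("at least one genotype required")
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalized probabilities via the standard two-term recurrence,
  # anchored at the distribution mode to avoid overflow
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mi <- match(mid, hets)
  probs <- numeric(length(hets))
  probs[mi] <- 1
  if (mi > 1L) for (i in seq(mi - 1L, 1L)) {
    h <- hets[i + 1L]               # next-larger het count
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    # P(h-2) = P(h) * h*(h-1) / (4*(hom_rare+1)*(hom_common+1))
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (hom_rare + 1) * (hom_common + 1))
  }
  if (mi < length(hets)) for (i in seq(mi + 1L, length(hets))) {
    h <- hets[i - 1L]               # next-smaller het count
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    # P(h+2) = P(h) * 4*hom_rare*hom_common / ((h+2)*(h+1))
    probs[i] <- probs[i - 1L] * 4 * hom_rare * hom_common /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-10)])
}

#' Missing-call rate of a marker or sample
#'
#' @param calls Vector of calls for one marker (across samples) or one sample
#'   (across markers).
#' @return Fraction of missing calls, in `[0, 1]`.
#' @export
marker_missingness <- function(calls) {
  if (length(calls) == 0L) stop("empty call vector")
  mean(is.na(calls))
}

#' @rdname marker_missingness
#' @export
sample_missingness <- marker_missingness

#' Differential missingness between cases and controls
#'
#' Two-sided Fisher exact test on the 2x2 table of called/missing genotype
#' counts by phenotype class, flagging markers whose call rate differs
#' between cases and controls.
#'
#' @param calls Calls for one marker across samples.
#' @param phenotypes 0 = control, 1 = case (NA allowed, excluded).
#' @return Two-sided Fisher exact p-value.
#' @export
differential_missingness_test <- function(calls, phenotypes) {
  keep <- !is.na(phenotypes)
  calls <- calls[keep]; phenotypes <- phenotypes[keep]
  if (!any(phenotypes == 1L) || !any(phenotypes == 0L))
    stop("both phenotype classes required")
  tab <- matrix(c(sum(!is.na(calls[phenotypes == 1L])),
                  sum(is.na(calls[phenotypes == 1L])),
                  sum(!is.na(calls[phenotypes == 0L])),
                  sum(is.na(calls[phenotypes == 0L]))), 2, 2)
  fisher.test(tab)$p.value
}

#' Default QC thresholds
#'
#' Marker and sample missing-call rate caps 0.01, MAF floor 0.05, HWE exact
#' p floor 1e-5, differential-missingness p floor 1e-5.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(marker_missingness = 0.01, sample_missingness = 0.01,
                          maf = 0.05, hwe_p = 1e-5, diff_missingness_p = 1e-5) {
  list(marker_missingness = marker_missingness,
       sample_missingness = sample_missingness,
       maf = maf, hwe_p = hwe_p, diff_missingness_p = diff_missingness_p)
}

#' Apply the QC filter cascade
#'
#' Filters are applied in order: marker missingness, sample missingness, MAF,
#' HWE exact test; that sequence is then repeated once (removals at a later
#' step change the rates seen by an earlier one), and finally markers with
#' differential call rates between cases and controls are removed.
#'
#' @param gm A `genotype_matrix`.
#' @param thresholds As from [qc_thresholds()].
#' @return List with elements `genotypes` (filtered `genotype_matrix`) and
#'   `report` (class `qc_report`: data frames `removed_markers`,
#'   `removed_samples`, the thresholds, and per-step counts).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  removed_m <- data.frame(entity_id = character(), step = character(),
                          value = numeric(), threshold = numeric(),
                          stringsAsFactors = FALSE)
  removed_s <- removed_m

  drop_markers <- function(step, value, thr) {
    bad <- which(!is.na(value) & value_fails(step, value, thr))
    if (length(bad)) {
      removed_m <<- rbind(removed_m, data.frame(
        entity_id = gm$markers$marker_id[bad], step = step,
        value = value[bad], threshold = thr, stringsAsFactors = FALSE))
      gm <<- subset_genotypes(gm, markers = -bad)
    }
    length(bad)
  }
  value_fails <- function(step, value, thr) {
    if (step %in% c("marker_missingness", "sample_missingness")) value > thr
    else value < thr   # maf, hwe_p, diff_missingness_p are floors
  }

  one_pass <- function(pass) {
    if (nrow(gm$calls) == 0L) return(invisible())
    drop_markers("marker_missingness",
                 apply(gm$calls, 1, function(x) mean(is.na(x))),
                 thresholds$marker_missingness)
    check_nonempty(gm)
    smiss <- apply(gm$calls, 2, function(x) mean(is.na(x)))
    bad <- which(smiss > thresholds$sample_missingness)
    if (length(bad)) {
      removed_s <<- rbind(removed_s, data.frame(
        entity_id = gm$samples$sample_id[bad], step = "sample_missingness",
        value = smiss[bad], threshold = thresholds$sample_missingness,
        stringsAsFactors = FALSE))
      gm <<- subset_genotypes(gm, samples = -bad)
    }
    check_nonempty(gm)
    maf <- apply(gm$calls, 1, function(x)
      if (all(is.na(x))) NA_real_ else compute_maf(x))
    drop_markers("maf", ifelse(is.na(maf), -1, maf), thresholds$maf)
    check_nonempty(gm)
    hwe <- apply(gm$calls, 1, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    })
    drop_markers("hwe_p", hwe, thresholds$hwe_p)
    check_nonempty(gm)
  }

  one_pass(1); one_pass(2)

  ph <- gm$samples$phenotype
  if (any(ph == 1L, na.rm = TRUE) && any(ph == 0L, na.rm = TRUE)) {
    dm <- apply(gm$calls, 1, function(x) {
      if (!anyNA(x)) return(1)      # no missingness: cannot differ
      differential_missingness_test(x, ph)
    })
    drop_markers("diff_missingness_p", dm, thresholds$diff_missingness_p)
  }
  check_nonempty(gm)

  counts <- table(factor(c(removed_m$step, removed_s$step),
                         levels = c("marker_missingness", "sample_missingness",
                                    "maf", "hwe_p", "diff_missingness_p")))
  report <- structure(list(removed_markers = removed_m,
                           removed_samples = removed_s,
                           thresholds = thresholds,
                           counts = as.list(counts)),
                      class = "qc_report")
  list(genotypes = gm, report = report)
}

check_nonempty <- function(gm) {
  if (nrow(gm$calls) == 0L || ncol(gm$calls) == 0L)
    stop("QC removed all markers or all samples")
  invisible(gm)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_markers), "markers and",
      nrow(x$removed_samples), "samples removed\n")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per removed entity: `entity_id`, `entity_type`, `step`, `value`,
#' `threshold`.
#' @param report A `qc_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  m <- report$removed_markers; s <- report$removed_samples
  out <- rbind(
    if (nrow(m)) cbind(m[, "entity_id", drop = FALSE], entity_type = "marker",
                       m[, c("step", "value", "threshold")]),
    if (nrow(s)) cbind(s[, "entity_id", drop = FALSE], entity_type = "sample",
                       s[, c("step", "value", "threshold")]))
  if (is.null(out))
    out <- data.frame(entity_id = character(), entity_type = character(),
                      step = character(), value = numeric(), threshold = numeric())
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
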