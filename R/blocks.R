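#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimate of the four haplotype frequencies of two
#' biallelic markers from unphased 0/1/2 genotype calls. All genotype pairs
#' except the double heterozygote have a determined haplotype composition;
#' the cis/trans ambiguity of double heterozygotes is resolved iteratively
#' (EM), to a convergence tolerance of 1e-9 on the frequencies.
#'
#' @param calls_a,calls_b Call vectors for the two markers.
#' @return Numeric vector `c(p11, p10, p01, p00)` of haplotype frequencies,
#'   indices being alt-allele indicators at (marker a, marker b).
#' @export
em_haplotype_freqs <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[ok]; b <- calls_b[ok]
  if (!length(a)) stop("no complete genotype pairs")
  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(a == i & b == j)
  N2 <- 2 * length(a)
  cis <- 0.5
  p <- rep(0.25, 4)  # p11 p10 p01 p00
  for (iter in 1:1000) {
    c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + cis * n[2, 2]
    c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1] + (1 - cis) * n[2, 2]
    c01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2] + (1 - cis) * n[2, 2]
    c00 <- 2 * n[1, 1] + n[2, 1] + n[1, 2] + cis * n[2, 2]
    new_p <- c(c11, c10, c01, c00) / N2
    done <- max(abs(new_p - p)) < 1e-9
    p <- new_p
    denom <- p[1] * p[4] + p[2] * p[3]
    cis <- if (denom > 0) p[1] * p[4] / denom else 0.5
    if (done) break
  }
  names(p) <- c("p11", "p10", "p01", "p00")
  p
}

#' Normalized linkage disequilibrium |D'| between two markers
#'
#' @param calls_a,calls_b Call vectors for the two markers.
#' @return `|D'|` in `[0, 1]`, or `NA` when either marker is monomorphic.
#' @export
dprime <- function(calls_a, calls_b) {
  p <- em_haplotype_freqs(calls_a, calls_b)
  pa <- p[["p11"]] + p[["p10"]]
  pb <- p[["p11"]] + p[["p01"]]
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  D <- p[["p11"]] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) return(NA_real_)
  abs(D) / dmax
}

new_haplotype_blocks <- function(members, gm) {
  pos <- setNames(gm$markers$position_bp, gm$markers$marker_id)
  chr <- setNames(gm$markers$chromosome, gm$markers$marker_id)
  blocks <- lapply(members, function(ms)
    list(chromosome = chr[[ms[1]]],
         start_bp = min(pos[ms]), end_bp = max(pos[ms]), markers = ms))
  structure(list(blocks = blocks, positions = pos),
            class = "haplotype_blocks")
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$markers), integer(1))
  cat("haplotype_blocks:", length(x$blocks), "blocks over",
      sum(sizes), "markers (", sum(sizes > 1L), "multi-marker )\n")
  invisible(x)
}

#' Marker-to-block assignment
#' @param blocks A `haplotype_blocks` object.
#' @return Named integer vector: marker id -> block index.
#' @export
block_assignment <- function(blocks) {
  out <- integer(0)
  for (i in seq_along(blocks$blocks))
    out[blocks$blocks[[i]]$markers] <- i
  out
}

#' Infer haplotype blocks by greedy |D'| extension
#'
#' A simplified block finder: walking each chromosome in coordinate order,
#' an adjacent marker joins the current block while its `|D'|` with the
#' block's last member is at least `dprime_threshold` and the block span
#' stays within `max_span_kb`; otherwise a new block starts. Markers
#' joining no block become singletons. (Confidence-interval block
#' definitions from external tools can be loaded verbatim with
#' [load_blocks()] instead.)
#'
#' @param gm A `genotype_matrix` (markers coordinate-sorted).
#' @param dprime_threshold Minimum `|D'|` to extend a block (default 0.9).
#' @param max_span_kb Maximum block span in kilobases (default 200).
#' @return A `haplotype_blocks` object covering every marker exactly once.
#' @export
infer_blocks <- function(gm, dprime_threshold = 0.9, max_span_kb = 200) {
  members <- list()
  for (chr in unique(gm$markers$chromosome)) {
    idx <- which(gm$markers$chromosome == chr)
    cur <- idx[1]
    for (i in idx[-1]) {
      span_ok <- gm$markers$position_bp[i] -
        gm$markers$position_bp[cur[1]] <= max_span_kb * 1000
      dp <- if (span_ok)
        tryCatch(dprime(gm$calls[cur[length(cur)], ], gm$calls[i, ]),
                 error = function(e) NA_real_)
      else NA_real_
      if (span_ok && !is.na(dp) && dp >= dprime_threshold) {
        cur <- c(cur, i)
      } else {
        members[[length(members) + 1L]] <- gm$markers$marker_id[cur]
        cur <- i
      }
    }
    members[[length(members) + 1L]] <- gm$markers$marker_id[cur]
  }
  new_haplotype_blocks(members, gm)
}

#' Load haplotype blocks from a PLINK .blocks.det-style file
#'
#' Whitespace-delimited with header `CHR BP1 BP2 KB NSNPS SNPS`, marker ids
#' in `SNPS` separated by `|`. Dataset markers not listed in any block
#' become singleton blocks.
#'
#' @param path Blocks file path.
#' @param gm The `genotype_matrix` whose markers the blocks partition.
#' @return A `haplotype_blocks` object.
#' @export
load_blocks <- function(path, gm) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  members <- list()
  spans <- list()
  if (length(lines) > 1L) {
    for (ln in seq(2L, length(lines))) {
      f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
      if (length(f) < 6L)
        stop("malformed blocks line ", ln, ": expected 6 fields, found ",
             length(f))
      bp1 <- suppressWarnings(as.integer(f[2]))
      bp2 <- suppressWarnings(as.integer(f[3]))
      if (is.na(bp1) || is.na(bp2))
        stop("malformed blocks line ", ln, ": non-integer coordinates")
      ids <- strsplit(f[6], "|", fixed = TRUE)[[1]]
      ids <- intersect(ids, gm$markers$marker_id)
      if (!length(ids)) next
      chr <- f[1]
      for (sp in spans[[chr]] %||% list()) {
        if (bp1 <= sp[2] && sp[1] <= bp2)
          stop("overlapping blocks on chromosome ", chr, " (line ", ln, ")")
      }
      spans[[chr]] <- c(spans[[chr]] %||% list(), list(c(bp1, bp2)))
      members[[length(members) + 1L]] <- ids
    }
  }
  assigned <- unlist(members, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop("marker(s) assigned to multiple blocks: ",
         paste(head(unique(assigned[duplicated(assigned)]), 5), collapse = ", "))
  for (id in setdiff(gm$markers$marker_id, assigned))
    members[[length(members) + 1L]] <- id
  new_haplotype_blocks(members, gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write haplotype blocks in the .blocks.det dialect
#' @param blocks A `haplotype_blocks` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("CHR BP1 BP2 KB NSNPS SNPS", con)
  for (b in blocks$blocks) {
    if (length(b$markers) < 2L) next   # .det files list multi-marker blocks
    writeLines(paste(b$chromosome, b$start_bp, b$end_bp,
                     sprintf("%.3f", (b$end_bp - b$start_bp + 1) / 1000),
                     length(b$markers),
                     paste(b$markers, collapse = "|")), con)
  }
  invisible(path)
}
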