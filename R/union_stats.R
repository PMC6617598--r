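#' Top-k union of ranked lists
#'
#' The set of SNPs ranking in the top `k` of at least one of the given
#' rankings, and its cardinality, the union number. With identical top-k
#' sets across all `m` lists (complete stability) the union number equals
#' `k`; with pairwise-disjoint top-k sets (complete instability) it equals
#' `m * k`.
#'
#' @param rankings Named list of rankings (named rank vectors or
#'   `ranked_list` objects) over a common SNP universe.
#' @param k Top-list cutoff, `k <= N`.
#' @return List: `markers` (character vector) and `union_number`.
#' @export
top_k_union <- function(rankings, k) {
  rankings <- normalize_rankings(rankings)
  tops <- lapply(rankings, function(r) names(r)[r <= k])
  markers <- unique(unlist(tops, use.names = FALSE))
  list(markers = markers, union_number = length(markers))
}

normalize_rankings <- function(rankings) {
  rankings <- lapply(rankings, function(r)
    if (inherits(r, "ranked_list")) ranking_of(r) else r)
  ref <- names(rankings[[1]])
  for (r in rankings) {
    if (!setequal(names(r), ref))
      stop("rankings cover different marker universes")
  }
  if (is.null(names(rankings)))
    names(rankings) <- paste0("approach", seq_along(rankings))
  rankings
}

#' Top-k union table with extraction numbers and average positions
#'
#' One row per union SNP: the extraction number (how many approaches rank
#' it in their top k), the average position (mean rank over those
#' approaches), and the per-approach rank where it is in the top k (`NA`
#' otherwise). Rows are sorted by decreasing extraction number, then
#' increasing average position.
#'
#' @inheritParams top_k_union
#' @return A `union_table`: data frame `marker_id`, `extraction_number`,
#'   `average_position`, one rank column per approach; attribute `k`.
#' @export
union_table <- function(rankings, k) {
  rankings <- normalize_rankings(rankings)
  u <- top_k_union(rankings, k)
  ranks <- sapply(rankings, function(r) {
    v <- r[u$markers]
    ifelse(v <= k, v, NA_integer_)
  })
  ranks <- matrix(ranks, nrow = length(u$markers),
                  dimnames = list(NULL, names(rankings)))
  extraction <- rowSums(!is.na(ranks))
  avg_pos <- rowMeans(ranks, na.rm = TRUE)
  out <- data.frame(marker_id = u$markers,
                    extraction_number = as.integer(extraction),
                    average_position = avg_pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  out <- out[order(-out$extraction_number, out$average_position,
                   out$marker_id), ]
  rownames(out) <- NULL
  structure(out, k = k, class = c("union_table", "data.frame"))
}

#' @export
print.union_table <- function(x, n = 6L, ...) {
  cat("union_table: ", nrow(x), " SNPs in the top-", attr(x, "k"),
      " union of ", ncol(x) - 3L, " approaches\n", sep = "")
  print.data.frame(head(x, n))
  invisible(x)
}

#' Union number as a percentage of complete instability
#'
#' `100 * union_number / (m * k)`: 100% when the `m` top-k lists are
#' pairwise disjoint, `100 / m` percent when they are identical. An
#' alternative normalization by `m * k - k` (0% at complete stability) is
#' available via `exclude_stable_floor`.
#'
#' @param union_number The union number.
#' @param k Top-list cutoff.
#' @param m Number of approaches (>= 2).
#' @param exclude_stable_floor If `TRUE`, normalize `(union_number - k)` by
#'   `(m - 1) * k` instead.
#' @return Percentage in `(0, 100]`.
#' @export
stability_fraction <- function(union_number, k, m,
                               exclude_stable_floor = FALSE) {
  if (m < 2L) stop("m must be >= 2")
  if (exclude_stable_floor) 100 * (union_number - k) / ((m - 1) * k)
  else 100 * union_number / (m * k)
}

#' Prune a union table to one SNP per haplotype block
#'
#' Within each haplotype block intersecting the union, keeps the most
#' stable SNP: highest extraction number, then lowest average position,
#' then best (lowest) single per-approach rank, then smallest genomic
#' position.
#'
#' @param utab A `union_table`.
#' @param blocks A `haplotype_blocks` object (see [infer_blocks()]); every
#'   union SNP must be assigned to a block.
#' @return Pruned `union_table` (same columns, one row per block).
#' @export
prune_union <- function(utab, blocks) {
  assign <- block_assignment(blocks)
  missing <- setdiff(utab$marker_id, names(assign))
  if (length(missing))
    stop("union SNP(s) not assigned to any block: ",
         paste(head(missing, 5), collapse = ", "))
  block_of <- assign[utab$marker_id]
  rank_cols <- setdiff(names(utab),
                       c("marker_id", "extraction_number", "average_position"))
  best_rank <- apply(utab[, rank_cols, drop = FALSE], 1,
                     function(r) if (all(is.na(r))) Inf else min(r, na.rm = TRUE))
  pos <- blocks$positions[utab$marker_id]
  keep <- logical(nrow(utab))
  for (b in unique(block_of)) {
    rows <- which(block_of == b)
    o <- order(-utab$extraction_number[rows], utab$average_position[rows],
               best_rank[rows], pos[rows])
    keep[rows[o[1]]] <- TRUE
  }
  out <- utab[keep, , drop = FALSE]
  out <- out[order(-out$extraction_number, out$average_position,
                   out$marker_id), ]
  rownames(out) <- NULL
  structure(out, k = attr(utab, "k"), class = c("union_table", "data.frame"))
}

#' Per-approach extraction-number distributions of a pruned union
#'
#' For each approach, the multiset of extraction numbers of the (pruned)
#' union SNPs that lie in that approach's top k — the data behind the
#' per-approach boxplots: approaches whose top SNPs are corroborated by
#' many others have high distributions, approaches contributing unique
#' signals have distributions near 1.
#'
#' @param utab A (typically pruned) `union_table`.
#' @return List: `values` (named list of integer vectors per approach) and
#'   `summary` (data frame with min, quartiles, median, max per approach).
#' @export
extraction_boxplot_data <- function(utab) {
  if (!nrow(utab)) stop("empty union table")
  rank_cols <- setdiff(names(utab),
                       c("marker_id", "extraction_number", "average_position"))
  values <- lapply(rank_cols, function(a)
    utab$extraction_number[!is.na(utab[[a]])])
  names(values) <- rank_cols
  summary <- do.call(rbind, lapply(rank_cols, function(a) {
    v <- values[[a]]
    if (!length(v)) v <- NA_integer_
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, names = FALSE)
    data.frame(approach = a, n = sum(!is.na(v)), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(summary) <- NULL
  list(values = values, summary = summary)
}

#' Write a union table as TSV
#'
#' Layout: `marker_id`, `extraction_number`, `average_position`, then one
#' column per approach where 0 means the SNP is not in that approach's top
#' k and a non-zero value `k + 1 - rank` says how well it ranks (`k` best,
#' 1 worst).
#'
#' @param utab A `union_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_union_table <- function(utab, path) {
  k <- attr(utab, "k")
  out <- as.data.frame(utab)
  rank_cols <- setdiff(names(out),
                       c("marker_id", "extraction_number", "average_position"))
  for (a in rank_cols)
    out[[a]] <- ifelse(is.na(out[[a]]), 0L, k + 1L - out[[a]])
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write extraction-number boxplot data as TSV
#' @param bp Output of [extraction_boxplot_data()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_boxplot_data <- function(bp, path) {
  raw <- do.call(rbind, lapply(names(bp$values), function(a) {
    v <- bp$values[[a]]
    if (!length(v)) return(NULL)
    data.frame(approach = a, extraction_number = v)
  }))
  write.table(bp$summary, path, quote = FALSE, sep = "\t", row.names = FALSE)
  raw_path <- sub("(\\.tsv)?$", ".raw.tsv", path)
  if (!is.null(raw))
    write.table(raw, raw_path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
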