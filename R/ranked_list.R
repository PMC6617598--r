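#' Build a ranked SNP list from per-marker values
#'
#' Produces integer ranks 1..N, rank 1 being the most associated marker:
#' smallest p-value under `"p_ascending"`, largest score under
#' `"score_descending"`. Ties are broken by genomic order
#' `(chromosome, position_bp, marker_id)`. Flagged (failed) markers are
#' placed after all valid markers, in the same genomic tie-break order, so
#' every ranked list covers the full common SNP universe.
#'
#' @param marker_map Data frame with `marker_id`, `chromosome`,
#'   `position_bp` (one row per analyzed marker; ids unique).
#' @param values Ranking key, one per marker: p-values or scores.
#' @param ordering_key `"p_ascending"` or `"score_descending"`.
#' @param flagged Optional logical vector; `TRUE` (or `NA` in `values`)
#'   marks failed markers.
#' @param approach Approach name attached to the list.
#' @return A `ranked_list`: data frame `marker_id`, `score`, `p_value`,
#'   `rank` sorted by rank, with attributes `approach` and `ordering_key`.
#' @export
rank_snps <- function(marker_map, values,
                      ordering_key = c("p_ascending", "score_descending"),
                      flagged = NULL, approach = "approach") {
  ordering_key <- match.arg(ordering_key)
  ids <- marker_map$marker_id
  if (anyDuplicated(ids))
    stop("duplicate marker ids in ranking input")
  stopifnot(length(values) == length(ids))
  if (is.null(flagged)) flagged <- rep(FALSE, length(ids))
  flagged <- flagged | is.na(values)
  key <- if (ordering_key == "p_ascending") values else -values
  key[flagged] <- Inf                    # failed markers after all valid ones
  ord <- order(key, chrom_order(marker_map$chromosome),
               marker_map$position_bp, ids)
  rk <- integer(length(ids)); rk[ord] <- seq_along(ids)
  out <- data.frame(
    marker_id = ids,
    score = if (ordering_key == "score_descending") values else NA_real_,
    p_value = if (ordering_key == "p_ascending") values else NA_real_,
    rank = rk, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(out, approach = approach, ordering_key = ordering_key,
            class = c("ranked_list", "data.frame"))
}

#' Extract the rank mapping of a ranked list
#' @param rl A `ranked_list`.
#' @return Named integer vector `marker_id -> rank` (a bijection onto 1..N).
#' @export
ranking_of <- function(rl) {
  setNames(rl$rank, rl$marker_id)
}

#' @export
print.ranked_list <- function(x, n = 6L, ...) {
  cat("ranked_list for approach '", attr(x, "approach"), "' (",
      nrow(x), " markers, ", attr(x, "ordering_key"), ")\n", sep = "")
  print.data.frame(head(x, n))
  invisible(x)
}

#' Write a ranked list as TSV
#'
#' Tab-delimited with header `marker_id`, `score`, `p_value`, `rank`;
#' absent values are written empty.
#' @param rl A `ranked_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranked_list <- function(rl, path) {
  out <- as.data.frame(rl)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE, na = "")
  invisible(path)
}

#' Import an externally computed ranking
#'
#' Adapter for rankings produced by external association tools (e.g. mixed
#' model or liability-scale methods run outside this package): a TSV with a
#' `marker_id` column and at least one of `p_value` / `score`. Ranks are
#' rebuilt with [rank_snps()] on the current marker universe.
#'
#' @param tsv_path Path to the TSV file.
#' @param approach_name Name for the resulting list.
#' @param marker_map Marker map of the current dataset (defines the SNP
#'   universe).
#' @param strict If `TRUE` (default), markers in the file but absent from
#'   the dataset raise an error; otherwise they are dropped. Dataset markers
#'   absent from the file are flagged (ranked last) in either mode.
#' @return A `ranked_list` over the dataset's marker universe.
#' @export
import_external_ranking <- function(tsv_path, approach_name, marker_map,
                                    strict = TRUE) {
  tab <- read.table(tsv_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!"marker_id" %in% names(tab))
    stop("ranking file lacks a marker_id column: ", tsv_path)
  has_p <- "p_value" %in% names(tab) && any(!is.na(tab$p_value))
  has_s <- "score" %in% names(tab) && any(!is.na(tab$score))
  if (!has_p && !has_s)
    stop("ranking file needs a p_value or score column: ", tsv_path)
  unknown <- setdiff(tab$marker_id, marker_map$marker_id)
  if (length(unknown)) {
    if (strict)
      stop("ranking file lists marker(s) absent from the dataset: ",
           paste(head(unknown, 5), collapse = ", "))
    tab <- tab[tab$marker_id %in% marker_map$marker_id, , drop = FALSE]
  }
  if (!nrow(tab) || !any(marker_map$marker_id %in% tab$marker_id))
    stop("no overlap between ranking file and dataset markers")
  idx <- match(marker_map$marker_id, tab$marker_id)
  if (has_p)
    rank_snps(marker_map, tab$p_value[idx], "p_ascending",
              flagged = is.na(idx), approach = approach_name)
  else
    rank_snps(marker_map, tab$score[idx], "score_descending",
              flagged = is.na(idx), approach = approach_name)
}
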