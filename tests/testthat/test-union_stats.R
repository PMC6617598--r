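# blocks from explicit member lists (test-only constructor)
load_blocks_from_members <- function(members, gm) {
  gwasrank:::new_haplotype_blocks(members, gm)
}

ranking_from_order <- function(ids_in_rank_order) {
  setNames(seq_along(ids_in_rank_order), ids_in_rank_order)
}

test_that("union numbers hit the stability bounds and hand cases", {
  ids <- sprintf("s%02d", 1:20)
  base <- ranking_from_order(ids)
  # identical rankings: complete stability
  u <- top_k_union(list(a = base, b = base, c = base), 5)
  expect_equal(u$union_number, 5L)
  expect_setequal(u$markers, ids[1:5])
  # pairwise disjoint top-k sets: complete instability
  shifted <- list(
    a = base,
    b = ranking_from_order(ids[c(6:20, 1:5)]),
    c = ranking_from_order(ids[c(11:20, 1:10)]))
  expect_equal(top_k_union(shifted, 5)$union_number, 15L)
  # hand union: {s1,s2,s3} u {s3,s4,s5}
  two <- list(a = base, b = ranking_from_order(ids[c(3, 4, 5, 1, 2, 6:20)]))
  u3 <- top_k_union(two, 3)
  expect_equal(u3$union_number, 5L)
  expect_setequal(u3$markers, ids[1:5])
  expect_error(top_k_union(list(a = base, b = base[1:10]), 3),
               "different marker universes")
})

test_that("k <= union number <= m*k over random ensembles", {
  set.seed(33)
  for (i in 1:20) {
    n <- 50; m <- sample(2:6, 1); k <- sample(1:20, 1)
    rks <- replicate(m, random_ranking(n), simplify = FALSE)
    s <- top_k_union(rks, k)$union_number
    expect_gte(s, k)
    expect_lte(s, m * k)
  }
})

test_that("union table computes extraction numbers and average positions", {
  ids <- sprintf("s%02d", 1:10)
  a <- ranking_from_order(ids)
  b <- ranking_from_order(ids[c(3, 1, 2, 4:10)])  # s03 ranks 3 in a, 1 in b
  ut <- union_table(list(a = a, b = b), 3)
  row <- ut[ut$marker_id == "s03", ]
  expect_equal(row$extraction_number, 2L)
  expect_equal(row$average_position, 2)
  # SNP in one list only
  c_rk <- ranking_from_order(ids[c(7, 8, 9, 10, 1:6)])
  ut2 <- union_table(list(a = a, c = c_rk), 4)
  row7 <- ut2[ut2$marker_id == "s07", ]
  expect_equal(row7$extraction_number, 1L)
  expect_equal(row7$average_position, 1)
  expect_true(is.na(row7$a))
  # identical lists: every extraction number equals m
  ut3 <- union_table(list(a = a, b = a, c = a), 4)
  expect_true(all(ut3$extraction_number == 3L))
  # sorted by decreasing extraction, then increasing average position
  expect_true(all(diff(ut$extraction_number) <= 0))
  for (e in unique(ut$extraction_number)) {
    ap <- ut$average_position[ut$extraction_number == e]
    expect_true(all(diff(ap) >= 0))
  }
})

test_that("stability fraction implements both normalizations", {
  expect_equal(stability_fraction(3 * 100, 100, 3), 100)        # disjoint
  expect_equal(stability_fraction(100, 100, 8), 12.5)           # identical
  expect_equal(stability_fraction(5, 3, 2), 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(stability_fraction(100, 100, 8, exclude_stable_floor = TRUE), 0)
  expect_error(stability_fraction(10, 5, 1), "m must be")
})

test_that("EM haplotype frequencies match direct counts when phase is known", {
  # no double heterozygotes: every haplotype is observable
  a <- c(0L, 0L, 2L, 2L, 1L, 0L)
  b <- c(0L, 0L, 2L, 2L, 0L, 1L)
  p <- em_haplotype_freqs(a, b)
  # haplotype counts by hand: (1,1) x4 from the two (2,2) pairs; (0,0) x
  # 2*2 + 1 + 1; (1,0) x1; (0,1) x1  over 12 haplotypes
  expect_equal(unname(p), c(4, 1, 1, 6) / 12, tolerance = 1e-8)
  # duplicated marker: perfect LD
  g <- c(0L, 1L, 2L, 1L, 0L, 2L)
  expect_equal(dprime(g, g), 1, tolerance = 1e-6)
  expect_true(is.na(dprime(rep(0L, 6), g)))   # monomorphic
})

test_that("block inference groups duplicated neighbors, never across chromosomes", {
  set.seed(41)
  base <- rbinom(60, 2, 0.4)
  calls <- rbind(base, base, base, rbinom(60, 2, 0.4))
  gm <- make_gm(calls, chromosome = c("1", "1", "1", "2"),
                position = c(100L, 200L, 300L, 100L))
  bl <- infer_blocks(gm)
  asg <- block_assignment(bl)
  expect_equal(unname(asg[c("m001", "m002", "m003")]), rep(asg[["m001"]], 3))
  expect_false(asg[["m004"]] == asg[["m001"]])
  # span cap: identical markers too far apart stay apart
  gm2 <- make_gm(rbind(base, base), position = c(100L, 500000L))
  expect_equal(length(infer_blocks(gm2, max_span_kb = 200)$blocks), 2L)
})

test_that("block files load, round-trip, and reject malformed input", {
  dir <- withr::local_tempdir()
  set.seed(43)
  base <- rbinom(80, 2, 0.35)
  calls <- rbind(base, base, rbinom(80, 2, 0.35), rbinom(80, 2, 0.45))
  gm <- make_gm(calls)
  bl <- infer_blocks(gm)
  p <- write_blocks(bl, file.path(dir, "b.blocks.det"))
  bl2 <- load_blocks(p, gm)
  expect_equal(block_assignment(bl2)[gm$markers$marker_id],
               block_assignment(bl)[gm$markers$marker_id])
  # empty file: all singletons
  empty <- file.path(dir, "empty.blocks.det")
  writeLines("CHR BP1 BP2 KB NSNPS SNPS", empty)
  bl3 <- load_blocks(empty, gm)
  expect_equal(length(bl3$blocks), nrow(gm$markers))
  # malformed line carries its line number
  bad <- file.path(dir, "bad.blocks.det")
  writeLines(c("CHR BP1 BP2 KB NSNPS SNPS", "1 100"), bad)
  expect_error(load_blocks(bad, gm), "line 2")
  # overlapping blocks rejected
  over <- file.path(dir, "over.blocks.det")
  writeLines(c("CHR BP1 BP2 KB NSNPS SNPS",
               "1 1000 2000 1.0 2 m001|m002",
               "1 1500 2500 1.0 2 m003|m004"), over)
  expect_error(load_blocks(over, gm), "overlapping")
})

test_that("pruning keeps the most stable SNP per block", {
  ids <- sprintf("s%02d", 1:8)
  a <- ranking_from_order(ids)
  b <- ranking_from_order(ids[c(1, 3, 2, 4:8)])
  c_rk <- ranking_from_order(ids[c(1, 4, 5, 2, 3, 6:8)])
  ut <- union_table(list(a = a, b = b, c = c_rk), 3)
  calls <- matrix(rep(c(0L, 1L, 2L, 0L), 8), 8, 4, byrow = TRUE)
  gm <- make_gm(calls, chromosome = rep("1", 8),
                position = seq(100L, 800L, by = 100L))
  gm$markers$marker_id <- ids

  # s01 (extraction 3) co-blocked with s04 (extraction 2): s01 kept
  blocks <- load_blocks_from_members(list(c("s01", "s04"),
                                          "s02", "s03", "s05", "s06",
                                          "s07", "s08"), gm)
  pu <- prune_union(ut, blocks)
  expect_true("s01" %in% pu$marker_id)
  expect_false("s04" %in% pu$marker_id)
  expect_lte(nrow(pu), nrow(ut))

  # tie on extraction number: lower average position wins
  r1 <- ranking_from_order(ids)
  r2 <- ranking_from_order(ids[c(1, 2, 4, 3, 5:8)])
  ut2 <- union_table(list(a = r1, b = r2), 4)
  # s03: ranks 3 and 4 -> avg 3.5; s04: ranks 4 and 3 -> avg 3.5; use s02 vs s03
  blocks2 <- load_blocks_from_members(list(c("s02", "s03"),
                                           "s01", "s04", "s05", "s06",
                                           "s07", "s08"), gm)
  pu2 <- prune_union(ut2, blocks2)
  expect_true("s02" %in% pu2$marker_id)    # avg 2.0 beats avg 3.5
  expect_false("s03" %in% pu2$marker_id)

  # all union SNPs in distinct blocks: pruning is the identity
  singletons <- load_blocks_from_members(as.list(ids), gm)
  expect_equal(prune_union(ut, singletons)$marker_id, ut$marker_id)
})

test_that("extraction boxplot data matches hand enumeration", {
  ids <- sprintf("s%02d", 1:6)
  a <- ranking_from_order(ids)
  b <- ranking_from_order(ids)
  d <- ranking_from_order(ids[c(4, 5, 6, 1, 2, 3)])  # disjoint top-3
  ut <- union_table(list(a = a, b = b, d = d), 3)
  bp <- extraction_boxplot_data(ut)
  # a's top 3 = s01..s03, each extracted by a and b -> all 2s
  expect_equal(sort(bp$values$a), c(2L, 2L, 2L))
  expect_equal(sort(bp$values$d), c(1L, 1L, 1L))     # d contributes unique SNPs
  # identical rankings only: distribution constant at m
  ut2 <- union_table(list(a = a, b = b), 3)
  bp2 <- extraction_boxplot_data(ut2)
  expect_true(all(unlist(bp2$values) == 2L))
  expect_error(extraction_boxplot_data(ut[0, ]), "empty")
})

test_that("union tables serialize with the k + 1 - rank column coding", {
  dir <- withr::local_tempdir()
  ids <- sprintf("s%02d", 1:6)
  a <- ranking_from_order(ids)
  b <- ranking_from_order(ids[c(2, 1, 4, 3, 5, 6)])
  ut <- union_table(list(a = a, b = b), 3)
  p <- write_union_table(ut, file.path(dir, "u.tsv"))
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(tab$a[tab$marker_id == "s01"], 3L)  # rank 1 -> k+1-1 = 3
  expect_equal(tab$b[tab$marker_id == "s04"], 1L)  # rank 3 -> 1
  # not in top k -> 0
  ut2 <- union_table(list(a = a, d = ranking_from_order(rev(ids))), 2)
  p2 <- write_union_table(ut2, file.path(dir, "u2.tsv"))
  tab2 <- read.table(p2, header = TRUE, sep = "\t")
  expect_equal(tab2$d[tab2$marker_id == "s01"], 0L)
})

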