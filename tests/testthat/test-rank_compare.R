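test_that("Canberra distance matches its displayed-formula evaluations", {
  s3 <- setNames(1:3, c("a", "b", "c"))
  t3 <- setNames(3:1, c("a", "b", "c"))
  expect_equal(canberra(s3, s3), 0)
  expect_equal(canberra(s3, t3), 2 / 4 + 0 + 2 / 4)
  s4 <- setNames(1:4, letters[1:4])
  t4 <- setNames(4:1, letters[1:4])
  expect_equal(canberra_topk(s4, t4, 2), 0.5 + 0.2 + 0.2 + 0.5)
  # agreement on the top k and disagreement only below: distance 0
  s <- setNames(c(1L, 2L, 3L, 4L, 5L), letters[1:5])
  t <- setNames(c(1L, 2L, 5L, 3L, 4L), letters[1:5])
  expect_equal(canberra_topk(s, t, 2), 0)
  expect_error(canberra(s4, setNames(1:4, c("a", "b", "x", "y"))),
               "symmetric difference")
  expect_error(canberra_topk(s4, t4, 5), "1..N")
})

test_that("Canberra metric axioms and top-k properties hold on random pairs", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    s <- random_ranking(n); t <- random_ranking(n)
    d <- canberra(s, t)
    expect_gte(d, 0)
    expect_equal(d, canberra(t, s))
    expect_equal(canberra(s, s), 0)
    expect_equal(d, canberra_oracle(s, t), tolerance = 1e-12)
    # equivalence at location parameter N + 1 and monotonicity in k
    expect_equal(canberra_topk(s, t, n), d, tolerance = 1e-12)
    ks <- sort(sample(n, min(6, n)))
    dk <- vapply(ks, function(k) canberra_topk(s, t, k), numeric(1))
    expect_true(all(diff(dk) >= -1e-12))
    k1 <- sample(n, 1)
    expect_equal(canberra_topk(s, t, k1), canberra_oracle(s, t, k1),
                 tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, and clamp large k", {
  set.seed(14)
  rks <- list(a = random_ranking(30), b = random_ranking(30),
              c = random_ranking(30))
  expect_warning(dm <- pairwise_distance_matrices(rks, c(5L, 10L, 50L)),
                 "clamped")
  expect_named(dm, c("k5", "k10", "full", "k50"))
  for (M in dm) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(0, 3))
  }
  expect_equal(dm$k50, dm$full)
  # brute-force recomputation at k = 5
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(dm$k5[i, j], canberra_oracle(rks[[i]], rks[[j]], 5),
                 tolerance = 1e-12)
})

test_that("average-linkage clustering follows hand agglomeration", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hclust_average(D)
  expect_equal(h$height, c(1, 5))
  U <- ultrametric_matrix(h)
  expect_equal(U["A", "B"], 1)
  expect_equal(U["A", "C"], 5)
  # two items merge at their distance
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hclust_average(D2)$height, 3)
  # ultrametric inequality on a random matrix
  set.seed(26)
  n <- 8
  M <- matrix(runif(n * n), n, n); M <- M + t(M); diag(M) <- 0
  dimnames(M) <- list(letters[1:n], letters[1:n])
  U <- ultrametric_matrix(hclust_average(M))
  for (x in 1:n) for (y in 1:n) for (z in 1:n)
    expect_lte(U[x, z], max(U[x, y], U[y, z]) + 1e-12)
  expect_error(hclust_average(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("cophenetic correlation agrees with pair enumeration", {
  D <- matrix(c(0, 1, 4, 6, 1, 0, 4, 6, 4, 4, 0, 6, 6, 6, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h1 <- hclust_average(D)
  expect_equal(cophenetic_correlation(h1, h1), 1)
  # scaling the matrix leaves the correlation at 1
  h2 <- hclust_average(2 * D)
  expect_equal(cophenetic_correlation(h1, h2), 1)
  # two different 4-leaf dendrograms vs direct enumeration of the 6 pairs
  E <- matrix(c(0, 5, 1, 6, 5, 0, 5, 3, 1, 5, 0, 6, 6, 3, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h3 <- hclust_average(E)
  u1 <- ultrametric_matrix(h1); u3 <- ultrametric_matrix(h3)[letters[1:4],
                                                             letters[1:4]]
  pairs <- combn(4, 2)
  v1 <- apply(pairs, 2, function(p) u1[p[1], p[2]])
  v3 <- apply(pairs, 2, function(p) u3[p[1], p[2]])
  expect_equal(cophenetic_correlation(h1, h3), cor(v1, v3), tolerance = 1e-12)
  # constant ultrametric: undefined
  C <- matrix(1, 3, 3); diag(C) <- 0
  dimnames(C) <- list(letters[1:3], letters[1:3])
  expect_warning(r <- cophenetic_correlation(hclust_average(C),
                                             hclust_average(D[1:3, 1:3])),
                 "constant")
  expect_true(is.na(r))
})

test_that("consensus clustering averages ultrametrics and is order-invariant", {
  D <- matrix(c(0, 1, 4, 6, 1, 0, 4, 6, 4, 4, 0, 6, 6, 6, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  E <- matrix(c(0, 6, 6, 6, 6, 0, 1, 4, 6, 1, 0, 4, 6, 4, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hD <- hclust_average(D); hE <- hclust_average(E)
  cons_same <- consensus_clustering(list(hD, hD, hD))
  expect_equal(cophenetic_correlation(cons_same, hD), 1)
  # consensus of {D, D, D, E} is closer to D than to E
  cons <- consensus_clustering(list(hD, hD, hD, hE))
  dist_to <- function(a, b) {
    ua <- ultrametric_matrix(a); ub <- ultrametric_matrix(b)
    ub <- ub[rownames(ua), colnames(ua)]
    sqrt(sum((ua - ub)^2) / 2)
  }
  expect_lt(dist_to(cons, hD), dist_to(cons, hE))
  # order invariance
  cons2 <- consensus_clustering(list(hE, hD, hD, hD))
  expect_equal(ultrametric_matrix(cons)[letters[1:4], letters[1:4]],
               ultrametric_matrix(cons2)[letters[1:4], letters[1:4]])
})

test_that("tree cutting and representative selection follow the rules", {
  D <- matrix(c(0, 1, 4, 6, 1, 0, 4, 6, 4, 4, 0, 6, 6, 6, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h <- hclust_average(D)
  expect_equal(unname(cut_tree(h, 4)), 1:4)
  expect_equal(length(unique(cut_tree(h, 1))), 1L)
  cl2 <- cut_tree(h, 2)
  expect_equal(unname(cl2[c("a", "b", "c")]), rep(cl2[["a"]], 3))
  expect_false(cl2[["d"]] == cl2[["a"]])
  expect_error(cut_tree(h, 5), "1..4")

  # medoid by enumeration on a 3-member cluster
  M <- matrix(c(0, 2, 9, 2, 0, 3, 9, 3, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  labels <- setNames(c(1L, 1L, 1L), c("x", "y", "z"))
  expect_equal(unname(select_representatives(labels, M)), "y")
  # singleton cluster is its own representative; override wins
  labels2 <- setNames(c(1L, 1L, 2L), c("x", "y", "z"))
  reps <- select_representatives(labels2, M)
  expect_equal(unname(reps["2"]), "z")
  reps_o <- select_representatives(labels, M, override = "x")
  expect_equal(unname(reps_o["1"]), "x")
})

test_that("heatmap normalization divides by the max off-diagonal entry", {
  D <- matrix(c(0, 2, 8, 2, 0, 4, 8, 4, 0), 3, 3)
  N <- normalize_for_heatmap(D)
  expect_equal(max(N), 1)
  expect_equal(unname(diag(N)), rep(0, 3))
  expect_equal(normalize_for_heatmap(2 * D), N)
  expect_error(normalize_for_heatmap(matrix(0, 2, 2)), "zero")
})

test_that("distance matrices and dendrograms round-trip through files", {
  dir <- withr::local_tempdir()
  set.seed(2)
  rks <- list(u = random_ranking(20), v = random_ranking(20),
              w = random_ranking(20))
  D <- pairwise_distance_matrices(rks, 5L)$k5
  p <- write_distance_matrix(D, file.path(dir, "d.tsv"))
  expect_equal(read_distance_matrix(p), D)
  h <- hclust_average(D)
  nwk <- write_dendrogram_newick(h, file.path(dir, "d.nwk"))
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, c("u", "v", "w"))
})
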