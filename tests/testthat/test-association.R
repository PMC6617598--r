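test_that("genotype encodings follow the standard genetic models", {
  calls <- c(0L, 1L, 2L, NA)
  expect_equal(encode_genotype(calls, "additive")[, 1], c(0, 1, 2, NA))
  expect_equal(encode_genotype(calls, "dominant")[, 1], c(0, 1, 1, NA))
  expect_equal(encode_genotype(calls, "recessive")[, 1], c(0, 0, 1, NA))
  cod <- encode_genotype(calls, "codominant")
  expect_equal(cod[, "Het"], c(0, 1, 0, NA))
  expect_equal(cod[, "Hom"], c(0, 0, 1, NA))
  expect_true(all(cod[, "Het"] + cod[, "Hom"] <= 1, na.rm = TRUE))
  expect_error(encode_genotype(calls, "superdominant"), "unknown encoding")
})

test_that("logistic beta equals the closed-form log odds ratio", {
  # cases 30 exposed / 10 unexposed, controls 10 / 30
  y <- rep(c(1, 0), each = 40)
  x <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  r <- logistic_test(y, matrix(x, ncol = 1))
  expect_equal(r$beta, log(9), tolerance = 1e-8)
  expect_false(r$flagged)
  # balanced table: no association, p = 1
  xb <- c(rep(1, 20), rep(0, 20), rep(1, 20), rep(0, 20))
  rb <- logistic_test(y, matrix(xb, ncol = 1))
  expect_equal(rb$beta, 0, tolerance = 1e-10)
  expect_equal(rb$p_value, 1, tolerance = 1e-10)
  # sampled grid of 2x2 tables: beta == log OR (saturated-model identity)
  set.seed(4)
  for (i in 1:60) {
    cells <- sample(1:50, 4, replace = TRUE)
    yy <- rep(c(1, 1, 0, 0), cells)
    xx <- rep(c(1, 0, 1, 0), cells)
    r <- logistic_test(yy, matrix(xx, ncol = 1))
    expect_equal(r$beta, log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
  }
})

test_that("codominant LRT equals twice the saturated-null log-likelihood gap", {
  tab <- matrix(c(10, 25, 15, 30, 10, 10), 2, 3)  # rows case/control
  v <- table_to_vectors(tab)
  r <- logistic_test(v$phenotype, encode_genotype(v$calls, "codominant"))
  lrt_oracle <- 2 * (loglik_2x3_saturated(tab) - loglik_2x3_null(tab))
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, pchisq(lrt_oracle, 2, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("logistic failures are flagged, not dropped", {
  y <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)           # complete separation
  expect_true(logistic_test(y, matrix(x, ncol = 1))$flagged)
  expect_true(logistic_test(rep(1, 6), matrix(x, ncol = 1))$flagged)
  expect_true(logistic_test(y, matrix(0, 6, 1))$flagged)  # rank-deficient
})

test_that("allelic chi-square and Fisher match direct-formula oracles", {
  r0 <- allelic_test(c(20, 20), c(20, 20))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- allelic_test(c(30, 10), c(10, 30))
  expect_equal(r1$statistic, chisq_oracle(rbind(c(30, 10), c(10, 30))))
  expect_equal(r1$statistic, 20)
  rf <- allelic_test(c(3, 0), c(0, 3), exact = TRUE)
  expect_equal(rf$p_value, fisher_oracle(rbind(c(3, 0), c(0, 3))),
               tolerance = 1e-12)
  expect_true(allelic_test(c(0, 0), c(10, 10))$flagged)   # zero margin
  # label-swap invariance
  set.seed(2)
  for (i in 1:20) {
    a <- sample(1:40, 2); b <- sample(1:40, 2)
    expect_equal(allelic_test(a, b)$statistic, allelic_test(b, a)$statistic)
  }
})

test_that("trend test matches the Cochran-Armitage oracle", {
  expect_equal(trend_test(c(10, 10, 10), c(10, 10, 10))$statistic, 0)
  expect_equal(trend_test(c(10, 10, 10), c(10, 10, 10))$p_value, 1)
  r <- trend_test(c(10, 20, 30), c(30, 20, 10))
  # independent implementation of the same statistic
  oracle <- suppressWarnings(
    prop.trend.test(c(10, 20, 30), c(40, 40, 40), score = 0:2))
  expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-12)
  # doubling all counts doubles the statistic
  r2 <- trend_test(2 * c(10, 20, 30), 2 * c(30, 20, 10))
  expect_equal(r2$statistic, 2 * r$statistic, tolerance = 1e-12)
  # label-swap invariance
  expect_equal(trend_test(c(30, 20, 10), c(10, 20, 30))$statistic, r$statistic)
  expect_true(trend_test(c(10, 0, 0), c(30, 0, 0))$flagged)
})

test_that("genotypic and collapsed model tests match chi-square oracles", {
  tab <- rbind(c(10, 20, 30), c(30, 20, 10))
  indep <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(genotypic_test(indep)$p_value, 1)
  g <- genotypic_test(tab)
  expect_equal(g$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(g$p_value, pchisq(chisq_oracle(tab), 2, lower.tail = FALSE))
  # recessive collapse of this table is (30,30 / 50,10)
  r <- model_collapsed_test(tab, "rec")
  expect_equal(r$statistic,
               unname(allelic_test(c(30, 30), c(50, 10))$statistic),
               tolerance = 1e-12)
  d <- model_collapsed_test(tab, "dom")
  expect_equal(d$statistic, chisq_oracle(rbind(c(10, 50), c(30, 30))),
               tolerance = 1e-12)
  # tool-faithful minimum-cell gate
  expect_true(genotypic_test(rbind(c(1, 20, 30), c(30, 20, 10)))$flagged)
  expect_false(genotypic_test(rbind(c(1, 20, 30), c(30, 20, 10)),
                              min_cell = 0)$flagged)
})

test_that("best-model permutation p behaves at the extremes", {
  # perfect separation: no permutation can beat the observed min p
  calls <- rep(c(2L, 0L), each = 20)
  ph <- rep(c(1L, 0L), each = 20)
  r <- model_best_perm(calls, ph, permutations = 100, seed = 3)
  expect_equal(r$empirical_p, 1 / 101)
  expect_error(model_best_perm(calls, ph, permutations = 0), ">= 1")
  # determinism under the seed
  r2 <- model_best_perm(calls, ph, permutations = 100, seed = 3)
  expect_identical(r, r2)
})

test_that("ranking applies genomic tie-breaks and puts failed markers last", {
  map <- data.frame(marker_id = c("A", "B", "C"),
                    chromosome = c("1", "1", "1"),
                    position_bp = c(100L, 200L, 300L))
  rl <- rank_snps(map, c(0.01, 0.5, 0.01), "p_ascending", approach = "t")
  expect_equal(ranking_of(rl)[c("A", "C", "B")], c(A = 1L, C = 2L, B = 3L))
  # all tied: ranks equal genomic order
  rl2 <- rank_snps(map, c(0.2, 0.2, 0.2), "p_ascending")
  expect_equal(ranking_of(rl2)[map$marker_id], setNames(1:3, map$marker_id))
  # one flagged marker among 3 ranks last
  rl3 <- rank_snps(map, c(0.9, 0.5, 0.1), "p_ascending",
                   flagged = c(FALSE, TRUE, FALSE))
  expect_equal(unname(ranking_of(rl3)["B"]), 3L)
  expect_error(rank_snps(rbind(map, map), rep(1, 6), "p_ascending"),
               "duplicate")
  # output is always a permutation of 1..N
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    m <- data.frame(marker_id = sprintf("x%02d", 1:n),
                    chromosome = sample(as.character(1:3), n, replace = TRUE),
                    position_bp = sample.int(1e5, n))
    rl <- rank_snps(m, runif(n), sample(c("p_ascending", "score_descending"), 1),
                    flagged = runif(n) < 0.2)
    expect_setequal(rl$rank, 1:n)
  }
})

test_that("external rankings import strictly and round-trip", {
  dir <- withr::local_tempdir()
  map <- data.frame(marker_id = sprintf("m%02d", 1:6),
                    chromosome = "2", position_bp = 1:6 * 100L)
  rl <- rank_snps(map, c(0.3, 0.01, 0.2, 0.9, 0.05, 0.5), "p_ascending",
                  approach = "ext")
  p <- write_ranked_list(rl, file.path(dir, "r.tsv"))
  back <- import_external_ranking(p, "ext", map)
  expect_equal(ranking_of(back), ranking_of(rl))

  extra <- rbind(read.table(p, header = TRUE, sep = "\t"),
                 data.frame(marker_id = "mysterious", score = NA,
                            p_value = 0.5, rank = 7))
  p2 <- file.path(dir, "extra.tsv")
  write.table(extra, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_external_ranking(p2, "ext", map), "mysterious")
  back2 <- import_external_ranking(p2, "ext", map, strict = FALSE)
  expect_equal(ranking_of(back2), ranking_of(rl))
  expect_error(import_external_ranking(p, "ext",
                                       transform(map, marker_id = paste0("z", marker_id)),
                                       strict = FALSE),
               "no overlap")
})
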