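test_that("theta hits the boundary cases and matches the component oracle", {
  # fixed differences at every locus
  fixed <- tiny_table(c(replicate(5, c(1, 1, 3, 3), simplify = FALSE),
                        replicate(5, c(2, 2, 4, 4), simplify = FALSE)),
                      groups = rep(c("a", "b"), each = 5))
  expect_equal(wc_theta(fixed), 1)

  # one group duplicated as two: no differentiation beyond sampling noise
  set.seed(1)
  dup <- hw_table(list(c(`1` = 0.4, `2` = 0.6), c(`3` = 0.5, `4` = 0.5)),
                  n = 40, seed = 4)
  dup$group_id <- rep(c("a", "b"), 20)
  expect_lte(wc_theta(dup), 0.05)

  # toy table against the independently coded variance-component oracle
  set.seed(8)
  toy <- hw_table(list(c(`1` = 0.3, `2` = 0.3, `3` = 0.4)), n = 20, seed = 8)
  toy$group_id <- rep(c("a", "b"), each = 10)
  toy$a1[c(3, 15), 1] <- NA; toy$a2[c(3, 15), 1] <- NA  # missing handled
  expect_equal(wc_theta(toy),
               oracle_wc_theta(toy$a1, toy$a2, toy$group_id),
               tolerance = 1e-12)

  mono <- tiny_table(list(c(1, 1), c(1, 1), c(1, 1), c(1, 1)),
                     groups = rep(c("a", "b"), each = 2))
  expect_error(wc_theta(mono), "monomorphic")
})

test_that("theta is invariant to allele relabelling and group order", {
  set.seed(2)
  tab <- hw_table(list(c(`1` = 0.2, `2` = 0.8), c(`5` = 0.6, `9` = 0.4)),
                  n = 30, seed = 2)
  tab$group_id <- rep(c("a", "b", "c"), each = 10)
  t0 <- wc_theta(tab)
  relab <- tab
  relab$a1 <- matrix(match(tab$a1, c(1, 2, 5, 9)) + 100L, nrow = 30)
  relab$a2 <- matrix(match(tab$a2, c(1, 2, 5, 9)) + 100L, nrow = 30)
  expect_equal(wc_theta(relab), t0, tolerance = 1e-12)
  ord <- rev(seq_len(n_ind(tab)))
  expect_equal(wc_theta(subset_individuals(tab, ord)), t0, tolerance = 1e-12)
})

test_that("pairwise FST reports thresholds, p-values and the +1 correction", {
  set.seed(3)
  tab <- hw_table(list(c(`1` = 0.5, `2` = 0.5)), n = 30, seed = 3)
  tab$group_id <- rep(c("a", "b", "c"), each = 10)
  pf <- pairwise_fst(tab, "group", n_perm = 99, seed = 1)
  expect_equal(nrow(pf$results), 3)
  expect_equal(pf$bonferroni_threshold, 0.05 / 3)
  expect_true(all(pf$results$p > 0 & pf$results$p <= 1))
  expect_true(all(pf$results$p >= 1 / 100))  # +1 correction floor
  expect_equal(pf$matrix$values["a", "b"], pf$results$theta[1])

  # 14 units give 91 pairs and the printed threshold at 4 decimals
  expect_equal(bonferroni_threshold(0.05, choose(14, 2), digits = 4), 5e-4)
})

test_that("permutation p matches exhaustive enumeration for 3 vs 3 genotypes", {
  tab <- tiny_table(list(c(1, 1), c(1, 2), c(1, 1), c(2, 2), c(2, 2), c(1, 2)),
                    groups = rep(c("a", "b"), each = 3))
  obs <- wc_theta(tab)
  # all 20 ways to choose which 3 genotypes form unit "a"
  splits <- utils::combn(6, 3)
  null <- apply(splits, 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"
    wc_theta(tab, g)
  })
  exact <- mean(null >= obs - 1e-12)
  pf <- pairwise_fst(tab, "group", n_perm = 4999, seed = 9)
  expect_lt(abs(pf$results$p - exact), 0.03)
})

test_that("partition summaries aggregate within and between populations", {
  ids <- c("a", "b", "c", "d")
  v <- matrix(0.5, 4, 4); diag(v) <- 0
  pm <- pairwise_matrix(ids, v, kind = "fst")
  s <- fst_partition_summary(pm, c(a = "p1", b = "p1", c = "p2", d = "p2"))
  expect_equal(s$summary["all", "mean"], 0.5)
  expect_equal(s$summary["within", "mean"], 0.5)
  expect_equal(s$summary["between", "max"], 0.5)
  expect_equal(s$summary["within", "n"], 2)
  expect_equal(s$summary["between", "n"], 4)
  # single population: between summary is empty
  s1 <- fst_partition_summary(pm, c(a = "p", b = "p", c = "p", d = "p"))
  expect_equal(s1$summary["between", "n"], 0)
  expect_true(is.na(s1$summary["between", "mean"]))
})

test_that("units with fewer than two individuals are skipped with a warning", {
  tab <- tiny_table(list(c(1, 1), c(1, 2), c(2, 2), c(1, 2), c(2, 2)),
                    groups = c("a", "a", "b", "b", "c"))
  expect_warning(pf <- pairwise_fst(tab, "group", n_perm = 19, seed = 1),
                 "skipped")
  expect_equal(nrow(pf$results), 1)
})
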