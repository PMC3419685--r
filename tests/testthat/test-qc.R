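test_that("consensus thresholds follow the four/seven replicate rule", {
  het4 <- matrix(rep(c(3, 5), 4), ncol = 2, byrow = TRUE)
  expect_equal(consensus_genotype(het4), c(3L, 5L))
  het3 <- het4[1:3, ]
  expect_equal(consensus_genotype(het3), c(NA_integer_, NA_integer_))
  hom6 <- matrix(rep(c(3, 3), 6), ncol = 2, byrow = TRUE)
  expect_equal(consensus_genotype(hom6), c(NA_integer_, NA_integer_))
  hom7 <- matrix(rep(c(3, 3), 7), ncol = 2, byrow = TRUE)
  expect_equal(consensus_genotype(hom7), c(3L, 3L))
  # simultaneous het and hom support is a conflict, never a guess
  conflict <- rbind(hom7, het4)
  expect_equal(consensus_genotype(conflict), c(NA_integer_, NA_integer_))
  # allele order within a replicate is immaterial
  expect_equal(consensus_genotype(matrix(rep(c(5, 3), 4), ncol = 2,
                                         byrow = TRUE)),
               c(3L, 5L))
})

test_that("consensus is idempotent and the allele-count policy is switchable", {
  g <- c(7L, 9L)
  again <- consensus_genotype(matrix(rep(g, 7), ncol = 2, byrow = TRUE))
  expect_equal(again, g)
  # het supported by allele appearances across mixed calls only under the
  # allele-count reading
  mixed <- rbind(matrix(rep(c(3, 5), 3), ncol = 2, byrow = TRUE),
                 c(3, 5))
  expect_equal(consensus_genotype(mixed), c(3L, 5L))
  dropouty <- rbind(matrix(rep(c(3, 5), 2), ncol = 2, byrow = TRUE),
                    c(3, 3), c(5, 5), c(3, 5), c(3, 5))
  expect_equal(consensus_genotype(dropouty, count_alleles = FALSE),
               c(3L, 5L))
  expect_equal(consensus_genotype(dropouty, count_alleles = TRUE),
               c(3L, 5L))
})

test_that("sample QC keeps only means strictly above the concentration cut", {
  conc <- rbind(a = c(0.6, 0.6), b = c(0.5, 0.5), c = c(0.0, 0.9),
                d = c(0.4, 0.7))
  expect_equal(qc_filter_samples(conc), c("a", "d"))
  expect_error(qc_filter_samples(rbind(c(-0.1, 0.5))), "negative")
})

test_that("locus statistics use the unbiased heterozygosity estimator", {
  tab <- tiny_table(list(c(1, 2), c(1, 1), c(2, 2), c(1, 2)))
  st <- locus_stats(tab)
  # n = 8 genes, p = 0.5: He = (8/7) * 0.5
  expect_equal(st$He, 8 / 7 * 0.5)
  expect_equal(st$Ho, 0.5)
  expect_equal(st$k, 2)
  # converges to gene diversity for large n
  big <- hw_table(list(c(`1` = 0.5, `2` = 0.5)), n = 4000, seed = 3)
  stb <- locus_stats(big)
  expect_lt(abs(stb$He - (1 - sum(c(0.5, 0.5)^2))), 0.02)
})

test_that("HWE permutation test behaves at the null, the alternative and edge cases", {
  hw <- tiny_table(c(replicate(25, c(1, 1), simplify = FALSE),
                     replicate(50, c(1, 2), simplify = FALSE),
                     replicate(25, c(2, 2), simplify = FALSE)))
  p_null <- hwe_test(hw, "g1", "L1", n_perm = 400, seed = 1)
  expect_gt(p_null, 0.5)

  allhom <- tiny_table(c(replicate(20, c(1, 1), simplify = FALSE),
                         replicate(20, c(2, 2), simplify = FALSE)))
  expect_lt(hwe_test(allhom, "g1", "L1", n_perm = 999, seed = 1), 0.01)

  mono <- tiny_table(replicate(6, c(1, 1), simplify = FALSE))
  expect_warning(p <- hwe_test(mono, "g1", "L1", n_perm = 99, seed = 1),
                 "monomorphic")
  expect_equal(p, 1)
  expect_error(hwe_test(tiny_table(list(c(1, 2))), "g1", "L1"), ">= 5")
})

test_that("HWE permutation p agrees with exhaustive re-pairing on a tiny case", {
  # 6 individuals with a biallelic locus: under uniform re-pairing of the 12
  # genes, the statistic depends only on where the allele-1 copies land, so
  # the exact null is an equal-weight enumeration of the C(12,6) placements
  tab <- tiny_table(list(c(1, 1), c(1, 2), c(2, 2), c(1, 1), c(1, 2), c(2, 2)))
  genes <- c(tab$a1[, 1], tab$a2[, 1])
  n <- length(genes) / 2
  p_hat <- table(genes) / length(genes)
  he <- (2 * n / (2 * n - 1)) * (1 - sum((p_hat)^2))
  obs <- abs(mean(tab$a1[, 1] != tab$a2[, 1]) - he)
  pos <- utils::combn(2 * n, sum(genes == 1))
  null <- apply(pos, 2, function(ix) {
    g <- rep(2L, 2 * n); g[ix] <- 1L
    abs(mean(g[seq_len(n)] != g[n + seq_len(n)]) - he)
  })
  exact <- mean(null >= obs - 1e-12)
  p_mc <- hwe_test(tab, "g1", "L1", n_perm = 4000, seed = 5)
  expect_lt(abs(p_mc - exact), 0.03)
})

test_that("null-allele estimator and bootstrap flag behave as specified", {
  # He == Ho gives r = 0 exactly in the direct arithmetic
  expect_equal((0.5 - 0.5) / (1 + 0.5), 0)
  expect_equal((0.5 - 0.25) / (1 + 0.5), 0.25 / 1.5)

  hw <- hw_table(list(c(`1` = 0.5, `2` = 0.5)), n = 60, seed = 2)
  r0 <- null_allele_screen(hw, "L1", n_boot = 300, seed = 1)
  expect_false(r0$flagged)

  # flagging suppressed below 10 individuals
  small <- tiny_table(list(c(1, 1), c(1, 2), c(2, 2), c(1, 1), c(2, 2)))
  rs <- null_allele_screen(small, "L1", n_boot = 50, seed = 1)
  expect_false(rs$flagged)
  expect_null(rs$ci)
})

test_that("a real null allele is flagged in most simulated screens", {
  flags <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    al <- c(1, 2, 3, 4, 0)  # 0 = null
    pr <- c(0.2, 0.2, 0.2, 0.2, 0.2)
    g1 <- sample(al, n, TRUE, pr); g2 <- sample(al, n, TRUE, pr)
    both_null <- g1 == 0 & g2 == 0
    g1 <- g1[!both_null]; g2 <- g2[!both_null]
    # a null paired with a visible allele is scored homozygous visible
    vis1 <- ifelse(g1 == 0, g2, g1)
    vis2 <- ifelse(g2 == 0, g1, g2)
    tab <- genotype_table(paste0("i", seq_along(vis1)),
                          rep("g1", length(vis1)),
                          seq_along(vis1), rep(0, length(vis1)),
                          matrix(pmin(vis1, vis2)), matrix(pmax(vis1, vis2)))
    null_allele_screen(tab, "L1", n_boot = 300, seed = s)$flagged
  }, logical(1))
  expect_gte(mean(flags), 0.8)
})

test_that("whole-table consensus integrates with the replicate generator", {
  truth <- tiny_table(list(c(3, 5, 7, 7), c(4, 4, 8, 9)))
  reps <- make_replicates(truth, 0, 0, n_reps = 7, seed = 1)
  cons <- consensus_table(reps, truth)
  expect_identical(cons$a1, truth$a1)
  expect_identical(cons$a2, truth$a2)
  # with full dropout every het ends missing (hom support never reaches 7
  # identical calls from a het truth only if one allele always kept)
  lossy <- make_replicates(truth, 1, 0, n_reps = 4, seed = 1)
  cons2 <- consensus_table(lossy, truth)
  expect_true(is.na(cons2$a1[1, 1]))
})
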