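test_that("Mantel r hits its algebraic anchors", {
  a <- random_pm(8, seed = 1)
  b <- pairwise_matrix(a$ids, a$values, kind = "least_cost")
  expect_equal(mantel(a, b, n_perm = 19, seed = 1)$r, 1)
  neg <- pairwise_matrix(a$ids, 3 - 2 * a$values, kind = "least_cost")
  m <- mantel(a, neg, n_perm = 19, tail = "less", seed = 1)
  expect_equal(m$r, -1)
  const <- pairwise_matrix(a$ids, matrix(1, 8, 8) - diag(8), kind = "least_cost")
  expect_error(mantel(a, const, n_perm = 9), "zero variance")
})

test_that("Monte-Carlo Mantel p converges to the exhaustive permutation p", {
  set.seed(21)
  for (case in 1:2) {
    a <- random_pm(5, seed = 20 + case)
    bv <- a$values + matrix(rnorm(25, sd = 0.4), 5, 5)
    bv <- (bv + t(bv)) / 2; diag(bv) <- 0
    b <- pairwise_matrix(a$ids, bv, kind = "least_cost")
    exact <- oracle_mantel_exact_p(a$values, b$values, tail = "greater")
    mc <- mantel(a, b, n_perm = 9999, tail = "greater", seed = case)
    expect_lt(abs(mc$p - exact), 0.025)
    expect_equal(mc$r, oracle_mantel_r(a$values, b$values), tolerance = 1e-12)
  }
})

test_that("Mantel r is invariant under simultaneous relabelling", {
  a <- random_pm(7, seed = 2)
  b <- random_pm(7, kind = "least_cost", seed = 3)
  pr <- sample(7)
  ap <- pairwise_matrix(a$ids, a$values[pr, pr], kind = a$kind)
  bp <- pairwise_matrix(a$ids, b$values[pr, pr], kind = b$kind)
  expect_equal(mantel(ap, bp, n_perm = 9, seed = 1)$r,
               mantel(a, b, n_perm = 9, seed = 1)$r, tolerance = 1e-12)
})

test_that("partial Mantel reduces correctly in its degenerate configurations", {
  a <- random_pm(6, seed = 4)
  b <- random_pm(6, kind = "least_cost", seed = 5)
  c6 <- random_pm(6, kind = "resistance", seed = 6)
  # direct closed-form evaluation
  av <- a$values[upper.tri(a$values)]
  bv <- b$values[upper.tri(b$values)]
  cv <- c6$values[upper.tri(c6$values)]
  rab <- cor(av, bv); rac <- cor(av, cv); rbc <- cor(bv, cv)
  want <- (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  got <- partial_mantel(a, b, c6, n_perm = 9, seed = 1)
  expect_equal(got$r, want, tolerance = 1e-12)

  # controlling B by itself is degenerate and must refuse, not guess
  expect_error(partial_mantel(a, b, b, n_perm = 9, seed = 1), "undefined")

  # a control orthogonal to both leaves r_AB unchanged: build C by
  # regressing noise out of both A and B directions
  set.seed(7)
  resid_v <- residuals(lm(rnorm(15) ~ av + bv))
  cm <- matrix(0, 6, 6); cm[upper.tri(cm)] <- resid_v
  co <- pairwise_matrix(a$ids, cm + t(cm), kind = "euclidean")
  expect_equal(partial_mantel(a, b, co, n_perm = 9, seed = 1)$r, rab,
               tolerance = 1e-12)
  expect_error(partial_mantel(a, b, pairwise_matrix(a$ids, 2 * b$values,
                                                    kind = "euclidean"),
                              n_perm = 9), "undefined")
})

test_that("partial Mantel agrees with vegan as an independent cross-check", {
  skip_if_not_installed("vegan")
  a <- random_pm(10, seed = 8)
  b <- random_pm(10, kind = "least_cost", seed = 9)
  c10 <- random_pm(10, kind = "euclidean", seed = 10)
  got <- partial_mantel(a, b, c10, n_perm = 99, seed = 1)
  ref <- vegan::mantel.partial(as.dist(a$values), as.dist(b$values),
                               as.dist(c10$values), permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("pair masks restrict tests to within-population pairs", {
  a <- random_pm(14, seed = 11)
  member <- setNames(rep(c("p1", "p2"), c(5, 9)), a$ids)
  masked <- restrict_pairs(a, member)
  expect_equal(sum(masked$mask[upper.tri(masked$mask)]), choose(5, 2) + choose(9, 2))
  single <- restrict_pairs(a, setNames(rep("p", 14), a$ids))
  expect_equal(sum(single$mask[upper.tri(single$mask)]), choose(14, 2))

  # altering a between-population entry never changes masked r
  b <- random_pm(14, kind = "least_cost", seed = 12)
  r0 <- mantel(masked, b, n_perm = 9, seed = 1)$r
  tweaked <- a$values
  tweaked[1, 14] <- tweaked[14, 1] <- 99
  masked2 <- restrict_pairs(pairwise_matrix(a$ids, tweaked, kind = a$kind),
                            member)
  expect_equal(mantel(masked2, b, n_perm = 9, seed = 1)$r, r0)
  # and the masked r equals the oracle on the same mask
  expect_equal(r0, oracle_mantel_r(a$values, b$values, masked$mask),
               tolerance = 1e-12)
})
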