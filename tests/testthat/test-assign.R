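test_that("assignment likelihood follows Hardy-Weinberg arithmetic", {
  freqs <- list(c(`1` = 0.5, `2` = 0.5))
  expect_equal(assignment_likelihood(1L, 1L, freqs), log(0.25))
  expect_equal(assignment_likelihood(1L, 2L, freqs), log(0.5))

  # three-locus toy equals the brute-force product over loci
  f3 <- list(c(`1` = 0.2, `2` = 0.8), c(`3` = 0.5, `4` = 0.5),
             c(`5` = 0.1, `6` = 0.9))
  a1 <- c(1L, 3L, 6L); a2 <- c(2L, 3L, 6L)
  want <- log(2 * 0.2 * 0.8) + log(0.5 * 0.5) + log(0.9 * 0.9)
  expect_equal(assignment_likelihood(a1, a2, f3), want, tolerance = 1e-12)

  # an unobserved allele gets the substitute frequency with renormalization
  got <- assignment_likelihood(1L, 9L, freqs, zero_sub = 0.01)
  expect_equal(got, log(2 * (0.5 / 1.01) * (0.01 / 1.01)), tolerance = 1e-12)
  # missing locus skipped
  expect_equal(assignment_likelihood(c(1L, NA), c(2L, NA),
                                     list(freqs[[1]], freqs[[1]])), log(0.5))
})

test_that("exclusion p matches the exact tail on a one-locus toy", {
  # population with p(1) = 0.7, p(2) = 0.3; genotype likelihoods:
  # 11: 0.49, 12: 0.42, 22: 0.09 -> P(L <= L(22)) = 0.09,
  # P(L <= L(12)) = 0.51, P(L <= L(11)) = 1
  freqs <- list(c(`1` = 0.7, `2` = 0.3))
  p22 <- exclusion_test(2L, 2L, freqs, n_sim = 20000, seed = 3)
  p12 <- exclusion_test(1L, 2L, freqs, n_sim = 20000, seed = 3)
  p11 <- exclusion_test(1L, 1L, freqs, n_sim = 20000, seed = 3)
  expect_lt(abs(p22 - 0.09), 0.01)
  expect_lt(abs(p12 - 0.51), 0.015)
  expect_equal(p11, 1, tolerance = 0.001)
})

test_that("an individual alien to the population is excluded", {
  set.seed(51)
  freqs <- lapply(1:8, function(l) {
    stats::setNames(rep(1 / 4, 4), as.character((l * 10):(l * 10 + 3)))
  })
  alien1 <- vapply(1:8, function(l) 900L + l, integer(1))
  p <- exclusion_test(alien1, alien1, freqs, n_sim = 2000, seed = 4)
  expect_lt(p, 0.01)
})

test_that("exclusion p is calibrated for genotypes drawn from the population", {
  freqs <- list(c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                c(`4` = 0.6, `5` = 0.4))
  # exact null distribution by enumerating all two-locus genotypes
  enum_geno <- function(f) {
    al <- as.integer(names(f))
    out <- list()
    for (i in seq_along(al)) for (j in i:length(al)) {
      pr <- if (i == j) f[[i]]^2 else 2 * f[[i]] * f[[j]]
      out[[length(out) + 1]] <- list(g = c(al[i], al[j]), pr = pr)
    }
    out
  }
  combos <- expand.grid(a = enum_geno(freqs[[1]]), b = enum_geno(freqs[[2]]))
  pr <- vapply(seq_len(nrow(combos)), function(r)
    combos$a[[r]]$pr * combos$b[[r]]$pr, numeric(1))
  ll <- vapply(seq_len(nrow(combos)), function(r) {
    assignment_likelihood(c(combos$a[[r]]$g[1], combos$b[[r]]$g[1]),
                          c(combos$a[[r]]$g[2], combos$b[[r]]$g[2]), freqs)
  }, numeric(1))
  exact_p <- vapply(ll, function(x) sum(pr[ll <= x + 1e-12]), numeric(1))
  # mean exclusion p over genotype draws should match its exact expectation
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  e_p <- sum(pr * exact_p)
  set.seed(52)
  ps <- vapply(1:150, function(i) {
    r <- sample(length(pr), 1, prob = pr)
    exclusion_test(c(combos$a[[r]]$g[1], combos$b[[r]]$g[1]),
                   c(combos$a[[r]]$g[2], combos$b[[r]]$g[2]),
                   freqs, n_sim = 400, seed = 1000 + i)
  }, numeric(1))
  expect_lt(abs(mean(ps) - e_p), 3.2 * sd(ps) / sqrt(length(ps)) + 0.01)
})

test_that("leave-one-out stops an individual's own alleles inflating L_h", {
  # one individual carries a private allele: with leave-one-out its home
  # likelihood must drop below the all-in value
  genos <- c(replicate(10, c(1, 2), simplify = FALSE), list(c(9, 9)))
  tab <- tiny_table(genos, pop = rep("p1", 11))
  tab2 <- tiny_table(list(c(1, 1), c(2, 2), c(1, 2), c(1, 1)),
                     pop = rep("p2", 4))
  both <- genotype_table(c(tab$ind_id, paste0("q", tab2$ind_id)),
                         c(tab$group_id, tab2$group_id),
                         c(tab$x, tab2$x), c(tab$y, tab2$y),
                         rbind(tab$a1, tab2$a1), rbind(tab$a2, tab2$a2),
                         pop_id = c(tab$pop_id, tab2$pop_id))
  full <- population_freqs(both)
  loo <- population_freqs(both, leave_out = "i11")
  l_full <- assignment_likelihood(9L, 9L, full$p1)
  l_loo <- assignment_likelihood(9L, 9L, loo$p1)
  expect_lt(l_loo, l_full)
  expect_false("9" %in% names(loo$p1[[1]]))
})

test_that("migrant, admixed and resident classifications follow the rules", {
  tab <- simulate_island_model(2, 40, m = 0.005, n_loci = 16, mu = 5e-4,
                               generations = 80, seed = 99)
  tab$pop_id <- tab$group_id
  # plant two unambiguous migrants
  pl <- c(1, 41)
  tab$pop_id[pl] <- rev(tab$pop_id[pl])
  n <- n_ind(tab)
  # Q: residents near 1 at home cluster; one admixture candidate
  Q <- cbind(ifelse(tab$group_id == "d1", 0.95, 0.05),
             ifelse(tab$group_id == "d1", 0.05, 0.95))
  Q[5, ] <- c(0.5, 0.5)
  res <- detect_migrants(tab, Q = Q, alpha = 0.01, n_sim = 600, seed = 2)
  expect_true(all(res$classification[pl] == "migrant"))
  expect_true(all(res$best[pl] != res$home[pl]))
  got_res <- res$classification[-c(pl, 5)]
  expect_gte(mean(got_res == "resident"), 0.95)
  # the planted half-half individual is admixed only if two populations have
  # exclusion probability above the threshold; it must never be a resident
  # with both conditions met
  if (res$p_excl_d1[5] > 0.2 && res$p_excl_d2[5] > 0.2) {
    expect_equal(res$classification[5], "admixed")
  }
  expect_true(all(res$q_home[tab$group_id == "d1" & seq_len(n) != 5 &
                               !seq_len(n) %in% pl] == 0.95))
})
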