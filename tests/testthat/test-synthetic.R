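test_that("generated landscapes honour fractions, contiguity and determinism", {
  cfg <- sim_config(ncols = 200, nrows = 200,
                    class_fractions = c(forest = 0.5, oil_palm = 0.3,
                                        pasture = 0.2),
                    true_costs = c(forest = 1, oil_palm = 50, pasture = 1),
                    seed = 11)
  ls1 <- generate_landscape(cfg)
  ls2 <- generate_landscape(cfg)
  expect_identical(ls1$codes, ls2$codes)  # same seed, same raster

  bmask <- ls1$codes == ls1$legend[["oil_palm"]]
  frac <- mean(bmask)
  expect_gte(frac, 0.28); expect_lte(frac, 0.32)
  # one 8-connected component spanning the full grid width
  expect_equal(oracle_components(bmask), 1)
  expect_true(all(colSums(bmask) > 0))
  # scattered class lands near its request too
  expect_lt(abs(mean(ls1$codes == ls1$legend[["pasture"]]) - 0.2), 0.02)

  uni <- generate_landscape(sim_config(ncols = 30, nrows = 30,
                                       class_fractions = c(forest = 1.0),
                                       true_costs = c(forest = 1), seed = 1))
  expect_true(all(uni$codes == uni$legend[["forest"]]))
  expect_error(sim_config(class_fractions = c(forest = 0.6, oil_palm = 0.3)),
               "sum to 1")
})

test_that("single isolated deme without mutation fixes every locus", {
  cfg <- sim_config(ncols = 20, nrows = 20,
                    class_fractions = c(forest = 1.0),
                    true_costs = c(forest = 1),
                    n_groups = 1, group_size = 10, n_loci = 5, mu = 0,
                    generations = 400, sample_sizes = 8, seed = 2)
  ls1 <- generate_landscape(cfg)
  sim <- simulate_genotypes(ls1, config = cfg)
  st <- locus_stats(sim$table)
  expect_true(all(st$k == 1))
  expect_true(all(st$Ho == 0))
})

test_that("simulation truth records a symmetric bounded migration matrix", {
  cfg <- sim_config(ncols = 40, nrows = 40, n_groups = 6, group_size = 12,
                    sample_sizes = rep(10, 6), generations = 10, seed = 5)
  ls1 <- generate_landscape(cfg)
  sim <- simulate_genotypes(ls1, config = cfg)
  m <- sim$truth$m
  expect_equal(m, t(m))
  expect_true(all(rowSums(m) <= 1 + 1e-12))
  expect_true(all(diag(m) == 0))
  expect_equal(dim(sim$truth$true_least_cost), c(6, 6))
  # demes sit in forest on both sides of the band
  expect_equal(sort(unique(sim$truth$pop_ids)), c("north", "south"))
})

test_that("raising the barrier cost strictly increases between-side distance", {
  cfg <- sim_config(ncols = 60, nrows = 40, n_groups = 6, group_size = 10,
                    sample_sizes = rep(10, 6), generations = 5, seed = 9)
  ls1 <- generate_landscape(cfg)
  costs <- c(10, 100, 1000)
  between_mean <- vapply(costs, function(cst) {
    tc <- cfg$true_costs; tc["oil_palm"] <- cst
    sim <- simulate_genotypes(ls1, true_costs = tc, config = cfg)
    side <- sim$truth$pop_ids
    cross <- outer(side, side, "!=")
    mean(sim$truth$true_least_cost[cross])
  }, numeric(1))
  expect_true(all(diff(between_mean) > 0))
})

test_that("allele sizes stay within the stepwise random-walk envelope", {
  for (s in 1:3) {
    cfg <- sim_config(ncols = 20, nrows = 20,
                      class_fractions = c(forest = 1.0),
                      true_costs = c(forest = 1), n_groups = 2,
                      group_size = 20, sample_sizes = c(15, 15),
                      generations = 25, seed = 100 + s)
    ls1 <- generate_landscape(cfg)
    sim <- simulate_genotypes(ls1, config = cfg)
    rng <- range(c(sim$table$a1, sim$table$a2), na.rm = TRUE)
    # founders span 100..111; +/- 20 repeat units of drift allowed
    expect_gte(rng[1], 100 - 20)
    expect_lte(rng[2], 111 + 20)
  }
})

test_that("replicate generation reproduces dropout and miscall processes", {
  tab <- tiny_table(list(c(3, 5), c(4, 4)))
  clean <- make_replicates(tab, 0, 0, n_reps = 6, seed = 1)
  for (r in 1:6) {
    expect_identical(as.vector(clean$a1[, , r]), as.vector(tab$a1))
    expect_identical(as.vector(clean$a2[, , r]), as.vector(tab$a2))
  }
  full <- make_replicates(tab, 1, 0, n_reps = 8, seed = 1)
  expect_true(all(full$a1[1, 1, ] == full$a2[1, 1, ]))  # het always drops

  # dropout frequency over many replicate draws of one heterozygote
  het <- tiny_table(list(c(3, 5)))
  reps <- make_replicates(het, 0.3, 0, n_reps = 10000, seed = 7)
  observed <- mean(reps$a1[1, 1, ] == reps$a2[1, 1, ])
  expect_lt(abs(observed - 0.3), 0.01)
})
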