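#' Closed-form finite-island FST expectation
#'
#' Exact identity-by-descent recursion for the k-island model with backward
#' migration rate `m` (migrants drawn uniformly from the other k-1 demes),
#' in the low-mutation limit: with
#' `Pw = (1-m)^2 + m^2/(k-1)` (two genes of one deme had parents in one deme)
#' and `Pb = 2m(1-m)/(k-1) + (k-2) m^2/(k-1)^2` (two genes of different demes
#' did), `F' = D/(2N) / (1 - D)` with `D = Pw - Pb`, and
#' `FST = F' / (1 + F')`. To first order in `m` this is the familiar
#' `1 / (1 + 4 N m k/(k-1))`.
#'
#' @param k number of demes.
#' @param N diploid deme size.
#' @param m total emigration rate per deme per generation.
#' @return expected equilibrium FST.
#' @export
island_fst_expectation <- function(k, N, m) {
  pw <- (1 - m)^2 + m^2 / (k - 1)
  pb <- 2 * m * (1 - m) / (k - 1) + (k - 2) * m^2 / (k - 1)^2
  d <- pw - pb
  fp <- d / (2 * N) / (1 - d)
  fp / (1 + fp)
}

#' Island-model FST recovery study
#'
#' Forward-simulates the finite-island model at the given `Nm` values and
#' compares the mean pairwise Weir-Cockerham theta over seeds with the
#' closed-form expectation of [island_fst_expectation()].
#'
#' @param Nm vector of `N * m` values to test.
#' @param k,N demes and deme size.
#' @param n_seeds independent simulations per `Nm`.
#' @param n_loci,mu,generations forward-simulation settings.
#' @param seed master seed.
#' @return data.frame per `Nm`: `mean_pairwise_theta`, `expected`, `rel_dev`.
#' @export
study_island_fst <- function(Nm = c(1, 5), k = 4, N = 50, n_seeds = 10,
                             n_loci = 16, mu = 5e-4, generations = 500,
                             seed = 1L) {
  out <- lapply(Nm, function(nm) {
    m <- nm / N
    th <- vapply(seq_len(n_seeds), function(s) {
      tab <- simulate_island_model(k, N, m, n_loci = n_loci, mu = mu,
                                   generations = generations,
                                   seed = derive_seed(seed, sprintf("isl_%g_%d", nm, s)))
      prs <- utils::combn(unique(tab$group_id), 2)
      mean(apply(prs, 2, function(u) {
        wc_theta(subset_individuals(tab, tab$group_id %in% u))
      }))
    }, numeric(1))
    exp_f <- island_fst_expectation(k, N, m)
    data.frame(Nm = nm, mean_pairwise_theta = mean(th), expected = exp_f,
               rel_dev = abs(mean(th) - exp_f) / exp_f)
  })
  do.call(rbind, out)
}

#' Mantel type-I error study
#'
#' Generates pairs of independent Gaussian-noise symmetric matrices and
#' measures the rejection rate of the two-sided simple Mantel test at
#' `alpha`: a calibrated test rejects at about the nominal rate.
#'
#' @param n_units matrix size.
#' @param reps replicate matrix pairs.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return the rejection rate.
#' @export
study_mantel_type1 <- function(n_units = 30, reps = 2000, n_perm = 999,
                               alpha = 0.05, seed = 1L) {
  set.seed(derive_seed(seed, "type1"))
  ids <- paste0("u", seq_len(n_units))
  rnd <- function() {
    v <- matrix(0, n_units, n_units)
    v[upper.tri(v)] <- stats::rnorm(n_units * (n_units - 1) / 2)
    pairwise_matrix(ids, v + t(v), kind = "euclidean")
  }
  rej <- vapply(seq_len(reps), function(r) {
    a <- rnd(); b <- rnd()
    mantel(a, b, n_perm = n_perm, tail = "two_sided",
           seed = derive_seed(seed, paste0("m", r)))$p <= alpha
  }, logical(1))
  mean(rej)
}

#' Scaled study conditions for the barrier-recovery experiment
#'
#' The desk-scale analogue of the study system: a wide 2 km x 0.8 km
#' land-cover strip at 20 m resolution with the barrier class (oil palm) as a
#' thin contiguous band separating two sets of forest demes, true barrier
#' cost 50, 25 generations since landscape transformation (the study species'
#' plausible post-conversion window), and 12 sampled individuals per group.
#'
#' @param seed simulation seed.
#' @param n_groups number of demes.
#' @return a [sim_config()].
#' @export
barrier_sim_config <- function(seed, n_groups = 10) {
  sim_config(ncols = 100, nrows = 40, cellsize = 20,
             class_fractions = c(forest = 0.55, oil_palm = 0.18,
                                 pasture = 0.10, river = 0.04,
                                 residential = 0.04, other = 0.09),
             barrier_class = "oil_palm",
             true_costs = c(forest = 1, oil_palm = 50, pasture = 1,
                            river = 1, residential = 1, other = 1),
             n_groups = n_groups, group_size = 35,
             sample_sizes = rep(12, n_groups),
             generations = 25, dispersal_scale = 800, m_total = 0.1,
             seed = seed)
}

#' Barrier recovery and scale-dependence study
#'
#' For each seed: simulate the [barrier_sim_config()] landscape and
#' genotypes, run the full cost sweep (all matrix classes, six costs, both
#' genetic metrics, simple and partial Mantel) on all pairs and again with
#' the within-population pair restriction, and apply [barrier_call()].
#'
#' @param seeds simulation seeds.
#' @param n_perm Mantel permutations.
#' @param alpha significance level for [barrier_call()].
#' @return list: per-seed data.frame `per_seed` (`seed`,
#'   `all_flags`, `within_flags`, `only_barrier_all`, `barrier_within`,
#'   `theta_pop`), plus summary counts.
#' @export
study_barrier_recovery <- function(seeds = 1:10, n_perm = 99, alpha = 0.05) {
  rows <- lapply(seeds, function(s) {
    cfg <- barrier_sim_config(seed = s)
    ls1 <- generate_landscape(cfg)
    sim <- simulate_genotypes(ls1, config = cfg)
    tab <- sim$table
    gen <- list(rousset_a = rousset_a_matrix(tab),
                morans_i = morans_i_matrix(tab))
    pts <- cbind(tab$x, tab$y)
    member <- stats::setNames(tab$pop_id, tab$ind_id)
    sw <- cost_sweep(gen, ls1, pts, n_perm = n_perm, seed = s)
    bc <- barrier_call(sw, alpha = alpha)
    genw <- lapply(gen, restrict_pairs, membership = member)
    bcw <- barrier_call(cost_sweep(genw, ls1, pts, n_perm = n_perm, seed = s),
                        alpha = alpha)
    flags <- bc$class[bc$barrier]
    wflags <- bcw$class[bcw$barrier]
    data.frame(seed = s,
               all_flags = paste(flags, collapse = ","),
               within_flags = paste(wflags, collapse = ","),
               only_barrier_all = identical(flags, cfg$barrier_class),
               barrier_within = cfg$barrier_class %in% wflags,
               theta_pop = wc_theta(tab, tab$pop_id),
               stringsAsFactors = FALSE)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       n_only_barrier_all = sum(per_seed$only_barrier_all),
       n_barrier_within = sum(per_seed$barrier_within),
       n_seeds = length(seeds))
}

#' Clustering recovery study (K = 2 truth)
#'
#' Simulates two diverged demes (theta >= 0.15 under the chosen settings),
#' runs the admixture Gibbs sampler over K = 1..4 with replicate chains,
#' picks K by Delta-K, and scores the Q-majority assignment accuracy against
#' the true demes (label switching resolved by the better of the two
#' labelings).
#'
#' @param seeds simulation seeds.
#' @param N deme size; `m` migration rate; `generations` forward time.
#' @param n_sample individuals sampled per deme.
#' @param iters,burnin,replicates Gibbs settings.
#' @return data.frame per seed: `theta`, `best_k`, `accuracy`.
#' @export
study_cluster_recovery <- function(seeds = 1:5, N = 50, m = 0.005,
                                   generations = 90, n_sample = 25,
                                   iters = 400, burnin = 150,
                                   replicates = 2) {
  rows <- lapply(seeds, function(s) {
    tab <- simulate_island_model(2, N, m, n_loci = 16, mu = 5e-4,
                                 generations = generations,
                                 seed = derive_seed(s, "clus_sim"))
    set.seed(derive_seed(s, "clus_sample"))
    keep <- sort(c(sample(which(tab$group_id == "d1"), n_sample),
                   sample(which(tab$group_id == "d2"), n_sample)))
    tab <- subset_individuals(tab, keep)
    lnP <- vapply(seq_len(replicates), function(rep) {
      vapply(1:4, function(K) {
        suppressWarnings(
          gibbs_admixture(tab, K, iters = iters, burnin = burnin,
                          seed = derive_seed(s, sprintf("K%d_r%d", K, rep))))$lnP
      }, numeric(1))
    }, numeric(4))
    rownames(lnP) <- 1:4
    dk <- delta_k(lnP)
    cr <- suppressWarnings(
      gibbs_admixture(tab, 2, iters = iters, burnin = burnin,
                      replicates = replicates, seed = derive_seed(s, "final")))
    assig <- apply(cr$Q, 1, which.max)
    truth <- as.integer(factor(tab$group_id))
    data.frame(seed = s, theta = wc_theta(tab), best_k = dk$best_k,
               accuracy = max(mean(assig == truth), mean(assig == 3 - truth)))
  })
  do.call(rbind, rows)
}

#' Migrant-detection recovery study
#'
#' Simulates two diverged demes, plants first-generation migrants by
#' relabelling sampled individuals into the other population, and measures
#' the recovery rate of [detect_migrants()] at `alpha` together with the
#' false-positive rate on the non-planted residents.
#'
#' @param seeds simulation seeds.
#' @param n_plant planted migrants per seed.
#' @param N,m,generations simulation settings.
#' @param n_sim simulated genotypes per population in the tests.
#' @param alpha migrant-test significance level.
#' @return list: `per_seed` data.frame, aggregate `recovery` and
#'   `false_positive_rate`.
#' @export
study_migrant_recovery <- function(seeds = 1:6, n_plant = 6, N = 50,
                                   m = 0.01, generations = 70, n_sim = 1000,
                                   alpha = 0.01) {
  rows <- lapply(seeds, function(s) {
    tab <- simulate_island_model(2, N, m, n_loci = 16, mu = 5e-4,
                                 generations = generations,
                                 seed = derive_seed(s, "mig_sim"))
    tab$pop_id <- tab$group_id
    set.seed(derive_seed(s, "mig_plant"))
    pl <- c(sample(which(tab$group_id == "d1"), n_plant / 2),
            sample(which(tab$group_id == "d2"), n_plant - n_plant / 2))
    tab$pop_id[pl] <- ifelse(tab$group_id[pl] == "d1", "d2", "d1")
    res <- detect_migrants(tab, Q = NULL, alpha = alpha, n_sim = n_sim,
                           seed = derive_seed(s, "mig_test"))
    got <- res$classification == "migrant"
    data.frame(seed = s, recovered = sum(got[pl]), planted = length(pl),
               false_pos = sum(got[-pl]), controls = length(got) - length(pl))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       recovery = sum(per_seed$recovered) / sum(per_seed$planted),
       false_positive_rate = sum(per_seed$false_pos) / sum(per_seed$controls))
}

#' Bottleneck test battery study (equilibrium calibration and crash power)
#'
#' Equilibrium arm: single demes simulated to mutation-drift equilibrium
#' under SMM; the battery should find no heterozygosity excess (sign test)
#' and an L-shaped allele-frequency spectrum. Crash arm: an equilibrated,
#' diverse population crashes ten-fold and is sampled 20 generations later;
#' the IAM test should detect the transient excess (Wilcoxon is the powerful
#' member of the battery at 16 loci; the sign test is reported alongside).
#'
#' @param seeds_eq,seeds_crash seeds for the two arms.
#' @param reps retained equilibrium replicates per locus in the tests.
#' @return list of two data.frames `equilibrium` (`sign_p`, `wilcoxon_p`,
#'   `mode_shifted`) and `crash` (`sign_p`, `wilcoxon_p`, `n_excess`).
#' @export
study_bottleneck <- function(seeds_eq = 1:10, seeds_crash = 1:6, reps = 300) {
  sample_tab <- function(G, n_take, s) {
    N <- dim(G)[1] %/% 2L
    set.seed(derive_seed(s, "bn_sample"))
    take <- sample.int(N, n_take)
    a1 <- t(vapply(take, function(i) G[2 * i - 1, , 1], numeric(dim(G)[2])))
    a2 <- t(vapply(take, function(i) G[2 * i, , 1], numeric(dim(G)[2])))
    genotype_table(paste0("i", seq_len(n_take)), rep("g", n_take),
                   seq_len(n_take), rep(0, n_take), a1, a2)
  }
  eq_rows <- lapply(seeds_eq, function(s) {
    eq <- simulate_demes(matrix(1, 1, 1), 100, 16, 8e-3, "SMM",
                         generations = 500, seed = derive_seed(s, "bn_eq"))
    tab <- sample_tab(eq$genes, 25, s)
    r <- suppressMessages(het_excess_test(tab, model = "SMM", reps = reps,
                                          seed = derive_seed(s, "bn_eq_test")))
    ms <- mode_shift(tab)
    data.frame(seed = s, sign_p = r$sign_p, wilcoxon_p = r$wilcoxon_p,
               n_excess = r$n_excess, mode_shifted = ms$shifted)
  })
  crash_rows <- lapply(seeds_crash, function(s) {
    eq <- simulate_demes(matrix(1, 1, 1), 250, 16, 8e-3, "SMM",
                         generations = 400, seed = derive_seed(s, "bn_pre"))
    cr <- simulate_demes(matrix(1, 1, 1), 25, 16, 8e-3, "SMM",
                         generations = 20, seed = derive_seed(s, "bn_crash"),
                         init_genes = eq$genes)
    tab <- sample_tab(cr$genes, 25, s)
    r <- suppressMessages(het_excess_test(tab, model = "IAM", reps = reps,
                                          seed = derive_seed(s, "bn_cr_test")))
    data.frame(seed = s, sign_p = r$sign_p, wilcoxon_p = r$wilcoxon_p,
               n_excess = r$n_excess)
  })
  list(equilibrium = do.call(rbind, eq_rows),
       crash = do.call(rbind, crash_rows))
}
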