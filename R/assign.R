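#' Population allele frequencies for assignment tests
#'
#' @param table a [genotype_table()].
#' @param membership population label per individual (defaults to `pop_id`).
#' @param leave_out optional individual id whose two alleles are removed from
#'   its own population's counts (leave-one-out).
#' @return named list population -> list per locus of named frequency vectors.
#' @export
population_freqs <- function(table, membership = table$pop_id,
                             leave_out = NULL) {
  .check(!is.null(membership), "no population labels available")
  pops <- unique(membership)
  out <- lapply(pops, function(p) {
    idx <- which(membership == p)
    if (!is.null(leave_out)) idx <- setdiff(idx, match(leave_out, table$ind_id))
    lapply(seq_len(n_loci(table)), function(l) {
      g <- c(table$a1[idx, l], table$a2[idx, l])
      g <- g[!is.na(g)]
      if (!length(g)) return(stats::setNames(numeric(0), character(0)))
      tb <- table(g)
      stats::setNames(as.numeric(tb) / sum(tb), names(tb))
    })
  })
  stats::setNames(out, pops)
}

#' Frequency-based assignment log-likelihood of one multilocus genotype
#'
#' The Hardy-Weinberg product over loci: `log L = sum_l log(2^het p_a p_b)`,
#' with any allele unobserved in the reference population given frequency
#' `zero_sub` and the locus frequencies renormalized so they still sum to 1.
#' Missing loci are skipped.
#'
#' @param a1,a2 the individual's allele vectors (one entry per locus).
#' @param freqs per-locus list of named allele-frequency vectors (one
#'   population's entry of [population_freqs()]).
#' @param zero_sub substitute frequency for unobserved alleles.
#' @return log-likelihood (finite by construction).
#' @export
assignment_likelihood <- function(a1, a2, freqs, zero_sub = 0.01) {
  ll <- 0
  for (l in seq_along(freqs)) {
    if (is.na(a1[l])) next
    f <- freqs[[l]]
    want <- as.character(c(a1[l], a2[l]))
    unseen <- setdiff(unique(want), names(f))
    if (length(unseen)) {
      f <- c(f, stats::setNames(rep(zero_sub, length(unseen)), unseen))
      f <- f / sum(f)
    }
    pa <- f[[want[1]]]; pb <- f[[want[2]]]
    ll <- ll + log(pa) + log(pb) + if (a1[l] != a2[l]) log(2) else 0
  }
  ll
}

# internal: simulate n multilocus genotypes from per-locus frequencies (HW)
.simulate_genotypes_from_freqs <- function(freqs, n) {
  L <- length(freqs)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    f <- freqs[[l]]
    if (!length(f)) next
    al <- as.integer(names(f))
    if (length(al) == 1L) {  # sample(<scalar>) would read it as 1:al
      a1[, l] <- a2[, l] <- al
      next
    }
    g1 <- sample(al, n, replace = TRUE, prob = f)
    g2 <- sample(al, n, replace = TRUE, prob = f)
    a1[, l] <- pmin(g1, g2); a2[, l] <- pmax(g1, g2)
  }
  list(a1 = a1, a2 = a2)
}

#' Exclusion test of one individual against one population
#'
#' Simulates `n_sim` multilocus genotypes from the population's allele
#' frequencies (Hardy-Weinberg, independent loci), computes the assignment
#' log-likelihood of each, and returns
#' `p = (1 + #{simulated <= observed}) / (n_sim + 1)`: small p means the
#' genotype is less likely than essentially all genotypes the population
#' produces, i.e. the population is excluded as an origin.
#'
#' @param a1,a2 the individual's allele vectors.
#' @param freqs the population's per-locus frequency list.
#' @param n_sim simulated individuals (10,000 in the full analysis).
#' @param zero_sub substitute frequency for unobserved alleles.
#' @param seed integer seed.
#' @return the exclusion p-value.
#' @export
exclusion_test <- function(a1, a2, freqs, n_sim = 10000, zero_sub = 0.01,
                           seed = 1L) {
  k <- vapply(freqs, length, integer(1))
  if (all(k <= 1)) warning("population monomorphic at every locus: test degenerate")
  set.seed(seed)
  sims <- .simulate_genotypes_from_freqs(freqs, n_sim)
  obs <- assignment_likelihood(a1, a2, freqs, zero_sub)
  sim_ll <- vapply(seq_len(n_sim), function(i) {
    assignment_likelihood(sims$a1[i, ], sims$a2[i, ], freqs, zero_sub)
  }, numeric(1))
  (1 + sum(sim_ll <= obs + 1e-12)) / (n_sim + 1)
}

#' Detect first-generation migrants and admixed individuals
#'
#' For every individual, the home-population likelihood `L_h` is computed
#' with leave-one-out frequencies (its own alleles never inflate its home
#' likelihood) and `L_max` is the maximum over candidate populations. Two
#' migrant statistics are tested against `n_sim` genotypes simulated from the
#' home population: `L_h` itself and the ratio `L_h / L_max`. An individual
#' is a *migrant* iff both tests are significant at `alpha` and its
#' highest-likelihood population differs from its sampling population. It is
#' *admixed* iff its mean home-cluster admixture proportion `Q` lies in
#' `(q_lo, q_hi)` (default 0.2-0.8) and the per-population exclusion test
#' assigns probability > `assign_thr` (default 0.2) to more than one
#' population. Everyone else is a *resident*.
#'
#' @param table a [genotype_table()] with `pop_id` sampling populations.
#' @param Q optional n x K admixture matrix from [gibbs_admixture()] (rows in
#'   table order); without it the admixture criterion cannot be evaluated and
#'   individuals failing the migrant test are left `resident` with a note.
#' @param alpha significance level of the migrant tests.
#' @param n_sim simulated genotypes per population.
#' @param zero_sub substitute frequency for unobserved alleles.
#' @param q_lo,q_hi admixture window on the home-cluster Q.
#' @param assign_thr exclusion-probability threshold for multi-population
#'   assignment.
#' @param seed integer seed.
#' @return data.frame per individual: ids, home population, per-population
#'   exclusion p, `L_h`, `L_ratio`, migrant-test p-values, `q_home`,
#'   `classification` in `{resident, migrant, admixed}`.
#' @export
detect_migrants <- function(table, Q = NULL, alpha = 0.01, n_sim = 2000,
                            zero_sub = 0.01, q_lo = 0.2, q_hi = 0.8,
                            assign_thr = 0.2, seed = 1L) {
  .check(!is.null(table$pop_id), "table needs pop_id sampling populations")
  pops <- unique(table$pop_id)
  .check(length(pops) >= 2, "need >= 2 populations")
  full_freqs <- population_freqs(table)
  set.seed(derive_seed(seed, "assign_sims"))
  # one simulated reference set per source population, scored vs every
  # population: all exclusion and migrant nulls are lookups into these
  sim_ll <- lapply(pops, function(src) {
    sims <- .simulate_genotypes_from_freqs(full_freqs[[src]], n_sim)
    vapply(pops, function(ref) {
      vapply(seq_len(n_sim), function(i) {
        assignment_likelihood(sims$a1[i, ], sims$a2[i, ],
                              full_freqs[[ref]], zero_sub)
      }, numeric(1))
    }, numeric(n_sim))
  })
  names(sim_ll) <- pops

  # map clusters to populations by mean Q of each population's members
  q_home <- rep(NA_real_, n_ind(table))
  if (!is.null(Q)) {
    .check(nrow(Q) == n_ind(table), "Q must have one row per individual")
    clus_of <- vapply(pops, function(p) {
      which.max(colMeans(Q[table$pop_id == p, , drop = FALSE]))
    }, integer(1))
    q_home <- Q[cbind(seq_len(n_ind(table)), clus_of[table$pop_id])]
  }

  rows <- lapply(seq_len(n_ind(table)), function(i) {
    home <- table$pop_id[i]
    loo <- population_freqs(table, leave_out = table$ind_id[i])
    ll <- vapply(pops, function(p) {
      assignment_likelihood(table$a1[i, ], table$a2[i, ],
                            if (p == home) loo[[p]] else full_freqs[[p]],
                            zero_sub)
    }, numeric(1))
    lh <- ll[[home]]
    best <- pops[which.max(ll)]
    lratio <- lh - max(ll)
    null <- sim_ll[[home]]
    null_lh <- null[, home]
    null_ratio <- null[, home] - apply(null, 1, max)
    p_lh <- (1 + sum(null_lh <= lh + 1e-12)) / (n_sim + 1)
    p_ratio <- (1 + sum(null_ratio <= lratio + 1e-12)) / (n_sim + 1)
    p_excl <- vapply(pops, function(p) {
      (1 + sum(sim_ll[[p]][, p] <= ll[[p]] + 1e-12)) / (n_sim + 1)
    }, numeric(1))
    migrant <- p_lh < alpha && p_ratio < alpha && best != home
    admixed <- !migrant && !is.na(q_home[i]) &&
      q_home[i] > q_lo && q_home[i] < q_hi && sum(p_excl > assign_thr) > 1
    cls <- if (migrant) "migrant" else if (admixed) "admixed" else "resident"
    out <- data.frame(individual_id = table$ind_id[i], home = home,
                      best = best, L_h = lh, L_ratio = lratio,
                      p_Lh = p_lh, p_ratio = p_ratio,
                      q_home = q_home[i], classification = cls,
                      stringsAsFactors = FALSE)
    for (p in pops) out[[paste0("p_excl_", p)]] <- p_excl[[p]]
    out
  })
  do.call(rbind, rows)
}
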