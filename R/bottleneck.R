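#' Conditional equilibrium heterozygosity distribution by coalescent simulation
#'
#' Simulates the coalescent of `n_genes` genes with mutations under the
#' chosen model (IAM: every mutation a novel allele; SMM: single +/-1 repeat
#' steps; TPM: multi-step with probability `p_multi`, geometric step size),
#' with theta calibrated by bisection so the expected allele count matches
#' `k_alleles`, then retains only replicates whose realized allele count
#' equals `k_alleles` (the conditional-on-k distribution). Returns the
#' unbiased expected heterozygosities of the retained replicates.
#'
#' @param n_genes sampled genes (2 x individuals).
#' @param k_alleles observed allele count to condition on.
#' @param model `"IAM"`, `"SMM"` or `"TPM"`.
#' @param reps retained replicates wanted.
#' @param seed integer seed.
#' @param p_multi,geo_mean TPM parameters.
#' @param max_raw cap on raw simulations before giving up.
#' @return numeric vector of `reps` He values.
#' @export
simulate_he_eq <- function(n_genes, k_alleles, model = c("IAM", "SMM", "TPM"),
                           reps = 1000, seed = 1L, p_multi = 0.3,
                           geo_mean = 2.8, max_raw = 100 * reps) {
  model <- match.arg(model)
  n <- as.integer(n_genes); k <- as.integer(k_alleles)
  .check(k >= 1 && k <= n, "need 1 <= k <= n")
  if (k == 1) return(rep(0, reps))
  theta <- .calibrate_theta(n, k, model, p_multi, geo_mean,
                            seed = derive_seed(seed, "calibrate"))
  set.seed(derive_seed(seed, "condition"))
  he <- numeric(reps)
  got <- 0L; raw <- 0L
  while (got < reps) {
    raw <- raw + 1L
    .check(raw <= max_raw,
           paste("only %d/%d replicates retained after %d simulations",
                 "(k = %d of n = %d is rarely realized); increase max_raw"),
           got, reps, raw, k, n)
    tips <- .sim_coalescent_alleles(n, theta, model, p_multi, geo_mean)
    tb <- tabulate(match(tips, unique(tips)))
    if (length(tb) != k) next
    got <- got + 1L
    p <- tb / n
    he[got] <- (n / (n - 1)) * (1 - sum(p^2))
  }
  he
}

# internal: one coalescent sample of n allele states
.sim_coalescent_alleles <- function(n, theta, model, p_multi, geo_mean) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  times <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0; nxt <- n + 1L
  for (j in n:2) {
    t <- t + stats::rexp(1, j * (j - 1) / 2)
    pick <- sample.int(length(active), 2)
    parent[active[pick]] <- nxt
    times[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  blen <- times[parent[seq_len(n_nodes - 1L)]] - times[seq_len(n_nodes - 1L)]
  nmut <- stats::rpois(n_nodes - 1L, theta / 2 * blen)
  state <- numeric(n_nodes)
  state[n_nodes] <- 100
  new_allele <- 1e6
  for (v in (n_nodes - 1L):1L) {  # parents always have higher index
    s <- state[parent[v]]
    m <- nmut[v]
    if (m > 0) {
      if (model == "IAM") {
        new_allele <- new_allele + 1
        s <- new_allele
      } else {
        steps <- rep(1L, m)
        if (model == "TPM") {
          multi <- stats::runif(m) < p_multi
          steps[multi] <- stats::rgeom(sum(multi), 1 / geo_mean) + 1L
        }
        s <- s + sum(steps * sign(stats::runif(m) - 0.5))
      }
    }
    state[v] <- s
  }
  state[seq_len(n)]
}

# internal: theta such that E[number of alleles] = k under the model.
# IAM uses the exact Ewens expectation; SMM/TPM bisect on a Monte Carlo mean.
.calibrate_theta <- function(n, k, model, p_multi, geo_mean, seed,
                             nsim = 200) {
  if (model == "IAM") {
    ek <- function(th) sum(th / (th + 0:(n - 1)))
    return(stats::uniroot(function(th) ek(th) - k,
                          lower = 1e-8, upper = 1e8, tol = 1e-10)$root)
  }
  mc_k <- function(th, s) {
    set.seed(s)
    mean(vapply(seq_len(nsim), function(i) {
      tips <- .sim_coalescent_alleles(n, th, model, p_multi, geo_mean)
      length(unique(tips))
    }, numeric(1)))
  }
  lo <- 1e-3; hi <- 1e4
  for (it in seq_len(18)) {
    mid <- sqrt(lo * hi)
    if (mc_k(mid, seed + it) < k) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Heterozygosity-excess bottleneck test battery for one population
#'
#' For each polymorphic locus, the observed unbiased He is compared to its
#' conditional equilibrium distribution (given the observed allele count and
#' gene sample size) from [simulate_he_eq()]: the standardized deviation
#' `DH = (He_obs - mean He_eq) / sd(He_eq)` and the per-locus probability of
#' excess at equilibrium. The sign test compares the count of excess loci
#' against its equilibrium expectation (exact Poisson-binomial tail over the
#' per-locus excess probabilities, one-tailed for excess); the Wilcoxon
#' signed-rank test is run one-tailed on the `DH` values. Conditional
#' distributions are cached by (n, k, model) across loci.
#'
#' @param table a [genotype_table()].
#' @param population population (matched against `pop_id` when present,
#'   otherwise `group_id`); `NULL` pools everyone.
#' @param model `"IAM"`, `"SMM"` or `"TPM"`.
#' @param reps retained equilibrium replicates per locus (10,000 in the full
#'   analysis).
#' @param seed integer seed.
#' @param p_multi,geo_mean TPM parameters.
#' @return list of class `bottleneck_result`: per-locus data.frame (`locus`,
#'   `n_genes`, `k`, `He_obs`, `He_eq_mean`, `He_eq_sd`, `DH`, `p_excess`),
#'   `n_excess`, `n_deficit`, `sign_p`, `wilcoxon_p`, `model`, `reps`.
#' @export
het_excess_test <- function(table, population = NULL,
                            model = c("IAM", "SMM", "TPM"), reps = 1000,
                            seed = 1L, p_multi = 0.3, geo_mean = 2.8) {
  model <- match.arg(model)
  labels <- if (!is.null(table$pop_id)) table$pop_id else table$group_id
  idx <- if (is.null(population)) seq_len(n_ind(table)) else
    which(labels == population)
  sub <- subset_individuals(table, idx)
  st <- locus_stats(sub)
  poly <- st[st$k >= 2 & st$n_genes >= 4, ]
  .check(nrow(poly) >= 4, "need >= 4 polymorphic loci (have %d)", nrow(poly))
  skipped <- setdiff(st$locus, poly$locus)
  if (length(skipped)) {
    message("monomorphic/underpowered loci skipped: ",
            paste(skipped, collapse = ","))
  }
  cache <- new.env(parent = emptyenv())
  per <- lapply(seq_len(nrow(poly)), function(i) {
    key <- sprintf("%d|%d", poly$n_genes[i], poly$k[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_he_eq(poly$n_genes[i], poly$k[i], model,
                                     reps = reps,
                                     seed = derive_seed(seed, key),
                                     p_multi = p_multi, geo_mean = geo_mean)
    }
    eq <- cache[[key]]
    mu <- mean(eq); sdv <- stats::sd(eq)
    data.frame(locus = poly$locus[i], n_genes = poly$n_genes[i],
               k = poly$k[i], He_obs = poly$He[i], He_eq_mean = mu,
               He_eq_sd = sdv, DH = (poly$He[i] - mu) / sdv,
               p_excess_eq = mean(eq > mu), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  excess <- per$He_obs > per$He_eq_mean
  # exact Poisson-binomial upper tail of the excess count
  sign_p <- .poisson_binomial_upper(per$p_excess_eq, sum(excess))
  wil <- suppressWarnings(
    stats::wilcox.test(per$DH, alternative = "greater", mu = 0))
  structure(list(per_locus = per, n_excess = sum(excess),
                 n_deficit = sum(!excess), sign_p = sign_p,
                 wilcoxon_p = wil$p.value, model = model, reps = reps),
            class = "bottleneck_result")
}

# internal: P(X >= x) for X a sum of independent Bernoulli(p_i) (exact DP)
.poisson_binomial_upper <- function(p, x) {
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[(x + 1):length(dist)])
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf("bottleneck_result [%s]: %d loci, %d excess / %d deficit\n",
              x$model, nrow(x$per_locus), x$n_excess, x$n_deficit))
  cat(sprintf("  sign test p = %.4g, Wilcoxon (excess) p = %.4g\n",
              x$sign_p, x$wilcoxon_p))
  invisible(x)
}

#' Allele-frequency mode-shift test
#'
#' Pools all alleles across loci into frequency classes of width 0.1. At
#' mutation-drift equilibrium the spectrum is L-shaped: the rarest class
#' (0-0.1] holds the most alleles. A distribution whose lowest class is not
#' the modal class is flagged as shifted (a bottleneck signature).
#'
#' @param table a [genotype_table()].
#' @param population population label (see [het_excess_test()]).
#' @return list: `shifted` (logical), `histogram` (named counts per class),
#'   `n_alleles`; a warning is attached when fewer than 10 alleles inform the
#'   test.
#' @export
mode_shift <- function(table, population = NULL) {
  labels <- if (!is.null(table$pop_id)) table$pop_id else table$group_id
  idx <- if (is.null(population)) seq_len(n_ind(table)) else
    which(labels == population)
  freqs <- c()
  for (l in seq_len(n_loci(table))) {
    g <- c(table$a1[idx, l], table$a2[idx, l])
    g <- g[!is.na(g)]
    if (!length(g)) next
    freqs <- c(freqs, as.numeric(table(g)) / length(g))
  }
  br <- seq(0, 1, by = 0.1)
  h <- table(cut(freqs, br, include.lowest = FALSE))
  if (length(freqs) < 10) {
    warning("fewer than 10 alleles: mode-shift test has low information")
  }
  list(shifted = which.max(as.numeric(h)) != 1L,
       histogram = stats::setNames(as.numeric(h), names(h)),
       n_alleles = length(freqs))
}
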