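#' Bayesian admixture clustering by Gibbs sampling
#'
#' The admixture model with independent allele frequencies: each cluster `k`
#' has per-locus allele frequencies with a Dirichlet(1) prior, each
#' individual an admixture vector `q_i ~ Dirichlet(alpha)`, and every allele
#' copy an origin indicator `z`. The Gibbs sweep updates `z | q, P`, then
#' `P | z` and `q | z` from their Dirichlet full conditionals. The model
#' log-probability of the data is estimated from the post-burn-in likelihood
#' trace as `mean(lnL) - var(lnL)/2`, and admixture proportions `Q` are
#' posterior means. Replicate chains are label-aligned by greedy matching of
#' `Q` columns before averaging.
#'
#' @param table a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param iters,burnin Gibbs sweeps total and discarded (iters > burnin).
#' @param replicates independent chains.
#' @param alpha symmetric Dirichlet parameter of the admixture prior.
#' @param seed integer seed (chains use derived streams).
#' @return list of class `cluster_result`: `K`, `Q` (n x K posterior mean,
#'   replicate-averaged), `lnP` (per replicate), `lnL_trace` (first chain),
#'   `replicates`, `warnings`.
#' @export
gibbs_admixture <- function(table, K, iters = 600, burnin = 200,
                            replicates = 1, alpha = 1, seed = 1L) {
  .check(K >= 1, "K must be >= 1")
  .check(iters > burnin, "iters must exceed burnin")
  enc <- .encode_loci(table)
  runs <- lapply(seq_len(replicates), function(rep) {
    .gibbs_chain(enc, K, iters, burnin, alpha,
                 seed = derive_seed(seed, paste0("chain", rep)))
  })
  Qs <- lapply(runs, `[[`, "Q")
  # resolve label switching against the first chain
  for (r in seq_along(Qs)[-1]) {
    perm <- .match_clusters(Qs[[1]], Qs[[r]])
    Qs[[r]] <- Qs[[r]][, perm, drop = FALSE]
  }
  Q <- Reduce(`+`, Qs) / length(Qs)
  rownames(Q) <- table$ind_id
  warn <- unlist(lapply(runs, `[[`, "warning"))
  structure(list(K = K, Q = Q,
                 lnP = vapply(runs, `[[`, numeric(1), "lnP"),
                 lnL_trace = runs[[1]]$lnL,
                 replicates = replicates, warnings = warn),
            class = "cluster_result")
}

# internal: integer-encode alleles per locus (1..k_l), NA preserved
.encode_loci <- function(table) {
  L <- n_loci(table)
  x1 <- x2 <- matrix(NA_integer_, n_ind(table), L)
  k <- integer(L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(table$a1[, l], table$a2[, l])))
    al <- al[!is.na(al)]
    k[l] <- max(1L, length(al))
    x1[, l] <- match(table$a1[, l], al)
    x2[, l] <- match(table$a2[, l], al)
  }
  list(x1 = x1, x2 = x2, k = k, n = n_ind(table), L = L)
}

.rdirichlet_rows <- function(shape) {
  g <- matrix(stats::rgamma(length(shape), shape = shape), nrow(shape))
  g / rowSums(g)
}

.gibbs_chain <- function(enc, K, iters, burnin, alpha, seed) {
  set.seed(seed)
  n <- enc$n; L <- enc$L
  # cumsum helper: (W %*% cumU)[i, k] = sum_{j <= k} W[i, j]
  cumU <- upper.tri(matrix(1, K, K), diag = TRUE) * 1
  # init from the prior posterior around pooled frequencies
  P <- lapply(seq_len(L), function(l) {
    cnt <- tabulate(c(enc$x1[, l], enc$x2[, l]), enc$k[l])
    .rdirichlet_rows(matrix(rep(1 + cnt, each = K), K))
  })
  Q <- .rdirichlet_rows(matrix(alpha, n, K))
  lnL_keep <- numeric(iters - burnin)
  Qsum <- matrix(0, n, K)
  for (it in seq_len(iters)) {
    nik <- matrix(0, n, K)
    cnt <- lapply(seq_len(L), function(l) matrix(0, K, enc$k[l]))
    lnL <- 0
    for (l in seq_len(L)) {
      for (copy in 1:2) {
        a <- if (copy == 1) enc$x1[, l] else enc$x2[, l]
        obs <- which(!is.na(a))
        if (!length(obs)) next
        W <- Q[obs, , drop = FALSE] *
          t(P[[l]])[a[obs], , drop = FALSE]
        tot <- rowSums(W)
        lnL <- lnL + sum(log(tot))
        cw <- W %*% cumU  # row cumulative sums (K small)
        u <- stats::runif(length(obs)) * tot
        z <- 1L + rowSums(cw < u)
        cnt[[l]] <- cnt[[l]] +
          matrix(tabulate(z + K * (a[obs] - 1L), K * enc$k[l]), K)
        nik[cbind(obs, z)] <- nik[cbind(obs, z)] + 1
      }
      P[[l]] <- .rdirichlet_rows(1 + cnt[[l]])
    }
    Q <- .rdirichlet_rows(alpha + nik)
    if (it > burnin) {
      lnL_keep[it - burnin] <- lnL
      Qsum <- Qsum + Q
    }
  }
  warn <- character(0)
  if (length(lnL_keep) >= 10) {
    tr <- stats::cor(seq_along(lnL_keep), lnL_keep)
    if (is.finite(tr) && abs(tr) > 0.6) {
      warn <- sprintf("lnL trend |r|=%.2f post burn-in: chain may not have mixed", tr)
      warning(warn)
    }
  }
  list(Q = Qsum / (iters - burnin),
       lnP = mean(lnL_keep) - stats::var(lnL_keep) / 2,
       lnL = lnL_keep, warning = warn)
}

# internal: greedy column matching (label switching) of Q2 onto Q1
.match_clusters <- function(Q1, Q2) {
  K <- ncol(Q1)
  S <- crossprod(Q1, Q2)  # similarity of cluster columns
  perm <- integer(K)
  for (step in seq_len(K)) {
    best <- which(S == max(S), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    S[best[1], ] <- -Inf; S[, best[2]] <- -Inf
  }
  perm
}

#' Evanno's Delta-K table from replicate model log-probabilities
#'
#' `DeltaK(K) = |mean lnP(K+1) - 2 mean lnP(K) + mean lnP(K-1)| / sd(lnP(K))`
#' for interior K; the optimum K is the argmax (the K with the sharpest rate
#' of change in the log probability of the data).
#'
#' @param lnP matrix of lnP values, rows named by K (>= 3 consecutive
#'   values), columns replicates (>= 2).
#' @return list of class `delta_k_table`: data.frame `table` (K, mean_lnP,
#'   sd_lnP, delta_k) and `best_k`.
#' @export
delta_k <- function(lnP) {
  lnP <- as.matrix(lnP)
  .check(nrow(lnP) >= 3, "need >= 3 consecutive K values")
  .check(ncol(lnP) >= 2, "need >= 2 replicates per K")
  Ks <- as.integer(rownames(lnP))
  .check(!anyNA(Ks) && all(diff(Ks) == 1), "rows must be consecutive K values")
  mu <- rowMeans(lnP)
  sd_ <- apply(lnP, 1, stats::sd)
  dk <- rep(NA_real_, length(Ks))
  for (i in 2:(length(Ks) - 1)) {
    .check(sd_[i] > 0, "zero sd of lnP at K = %d", Ks[i])
    dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sd_[i]
  }
  tab <- data.frame(K = Ks, mean_lnP = mu, sd_lnP = sd_, delta_k = dk)
  structure(list(table = tab, best_k = Ks[which.max(dk)]),
            class = "delta_k_table")
}
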