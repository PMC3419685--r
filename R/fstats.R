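#' Multilocus Weir-Cockerham theta (FST)
#'
#' The 1984 moment estimator: per locus and allele, the among-group (`a`),
#' among-individual-within-group (`b`) and within-individual (`c`) variance
#' components are computed from allele frequencies, observed heterozygote
#' frequencies and (unequal) sample sizes; theta is the ratio of sums
#' `sum(a) / sum(a + b + c)` over all alleles and loci (ratio-of-sums
#' combining, the estimator's own recommendation). Missing data are handled
#' by per-locus complete cases; negative estimates are reported as computed.
#'
#' @param table a [genotype_table()].
#' @param grouping vector of unit labels per individual (defaults to
#'   `table$group_id`).
#' @param loci locus names to use (default all).
#' @return theta (scalar).
#' @export
wc_theta <- function(table, grouping = table$group_id, loci = table$loci) {
  comps <- wc_components(table, grouping, loci)
  .check(comps$den != 0,
         "theta undefined: all loci monomorphic in these units")
  comps$num / comps$den
}

#' @rdname wc_theta
#' @return `wc_components`: list with summed numerator `num` (= sum a) and
#'   denominator `den` (= sum a+b+c).
#' @export
wc_components <- function(table, grouping = table$group_id,
                          loci = table$loci) {
  grouping <- as.character(grouping)
  lidx <- match(loci, table$loci)
  .check(!anyNA(lidx), "unknown locus name(s)")
  units <- unique(grouping)
  .check(length(units) >= 2, "need >= 2 units")
  num <- den <- 0
  for (l in lidx) {
    a1 <- table$a1[, l]; a2 <- table$a2[, l]
    ok <- !is.na(a1)
    g <- grouping[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    ni <- table(g)
    ni <- ni[ni >= 1]
    if (length(ni) < 2) next
    keep <- g %in% names(ni)
    g <- g[keep]; x1 <- x1[keep]; x2 <- x2[keep]
    r <- length(ni)
    nvec <- as.numeric(ni)
    nbar <- mean(nvec)
    nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    alleles <- sort(unique(c(x1, x2)))
    if (length(alleles) < 2) next
    for (al in alleles) {
      cnt <- (x1 == al) + (x2 == al)
      het <- (x1 == al) != (x2 == al)
      p_i <- tapply(cnt, g, sum)[names(ni)] / (2 * nvec)
      h_i <- tapply(het, g, mean)[names(ni)]
      pbar <- sum(nvec * p_i) / (r * nbar)
      s2 <- sum(nvec * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(nvec * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  list(num = num, den = den)
}

#' Pairwise FST with genotype-permutation significance
#'
#' For every pair of units (groups or populations), computes multilocus theta
#' and a permutation p-value obtained by shuffling whole diploid genotypes
#' between the two units (genotype-level randomization, i.e. not assuming
#' HWE), with the +1 correction. Significance is judged against the
#' Bonferroni-corrected threshold `alpha / n_pairs`.
#'
#' @param table a [genotype_table()].
#' @param level `"group"` or `"population"` (uses `pop_id`).
#' @param n_perm permutations per pair (10,000 in the full analysis).
#' @param alpha family-wise error rate before correction.
#' @param seed integer seed.
#' @return list of class `pairwise_fst`: `results` (data.frame pair, theta,
#'   p, significant), `matrix` (a [pairwise_matrix()] of kind `fst`),
#'   `bonferroni_threshold`, `n_perm`.
#' @export
pairwise_fst <- function(table, level = c("group", "population"),
                         n_perm = 10000, alpha = 0.05, seed = 1L) {
  level <- match.arg(level)
  grouping <- if (level == "group") table$group_id else {
    .check(!is.null(table$pop_id), "table has no population labels")
    table$pop_id
  }
  units <- unique(grouping)
  .check(length(units) >= 2, "need >= 2 units")
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("unit(s) with < 2 individuals skipped: %s",
                    paste(small, collapse = ",")))
    units <- setdiff(units, small)
  }
  prs <- utils::combn(units, 2)
  n_pairs <- ncol(prs)
  thr <- alpha / n_pairs
  set.seed(seed)
  res <- lapply(seq_len(n_pairs), function(pi) {
    u <- prs[, pi]
    idx <- which(grouping %in% u)
    sub <- subset_individuals(table, idx)
    gl <- grouping[idx]
    obs <- wc_theta(sub, gl)
    ge <- vapply(seq_len(n_perm), function(i) {
      wc_theta(sub, sample(gl))
    }, numeric(1))
    p <- (1 + sum(ge >= obs - 1e-12)) / (n_perm + 1)
    data.frame(unit1 = u[1], unit2 = u[2], theta = obs, p = p,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  m <- matrix(NA_real_, length(units), length(units),
              dimnames = list(units, units))
  for (r in seq_len(nrow(res))) {
    m[res$unit1[r], res$unit2[r]] <- m[res$unit2[r], res$unit1[r]] <-
      res$theta[r]
  }
  structure(list(results = res,
                 matrix = pairwise_matrix(units, m, kind = "fst"),
                 bonferroni_threshold = thr, n_perm = n_perm, alpha = alpha),
            class = "pairwise_fst")
}

#' Bonferroni-corrected per-test threshold
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @param digits optional rounding to printed precision.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests, digits = NULL) {
  t <- alpha / n_tests
  if (!is.null(digits)) t <- round(t, digits)
  t
}

#' Partition summaries of a pairwise FST matrix
#'
#' Mean, min and max of the pairwise values over (i) all pairs, (ii) pairs of
#' units in the same population, and (iii) pairs from different populations.
#'
#' @param matrix a [pairwise_matrix()] (kind `fst`).
#' @param partition named character vector mapping every unit to a population.
#' @param digits optional rounding to the printed precision.
#' @return list with data.frame `summary` (rows all / within / between) and
#'   the pair counts.
#' @export
fst_partition_summary <- function(matrix, partition, digits = NULL) {
  ids <- matrix$ids
  .check(all(ids %in% names(partition)), "partition must cover all units")
  pop <- partition[ids]
  ut <- which(upper.tri(matrix$values), arr.ind = TRUE)
  v <- matrix$values[ut]
  same <- pop[ut[, 1]] == pop[ut[, 2]]
  smry <- function(x) {
    if (length(x) == 0) return(c(n = 0, mean = NA, min = NA, max = NA))
    s <- c(n = length(x), mean = mean(x), min = min(x), max = max(x))
    if (!is.null(digits)) s[-1] <- round(s[-1], digits)
    s
  }
  out <- rbind(all = smry(v), within = smry(v[same]), between = smry(v[!same]))
  list(summary = as.data.frame(out),
       n_populations = length(unique(pop)))
}
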