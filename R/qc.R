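#' Consensus genotype from replicate allele calls
#'
#' Implements the multi-tubes consensus convention for error-prone (e.g.
#' fecal) DNA: a heterozygous call is accepted only when the same
#' heterozygote (both alleles present) is seen in at least `het_min`
#' replicates; a homozygous call is accepted only when the same homozygote is
#' seen in at least `hom_min` replicates *and* no heterozygote reaches its
#' own threshold. Simultaneous heterozygous and homozygous support, or
#' insufficient support, yields a missing call - never a guess.
#'
#' The "at least four / at least seven" thresholds are read as counts of
#' concordant whole-genotype replicates; `count_alleles = TRUE` switches to
#' the alternative reading in which the het threshold counts replicates where
#' each allele appears (so a het supported by mixed calls can pass).
#'
#' @param calls two-column integer matrix of replicate calls (one row per
#'   replicate; `NA` rows are failed replicates and are ignored).
#' @param het_min,hom_min support thresholds (defaults 4 and 7).
#' @param count_alleles policy switch, see Details.
#' @return integer vector `c(a1, a2)` or `c(NA, NA)` when no consensus.
#' @export
consensus_genotype <- function(calls, het_min = 4L, hom_min = 7L,
                               count_alleles = FALSE) {
  calls <- matrix(as.integer(calls), ncol = 2)
  calls <- calls[!is.na(calls[, 1]) & !is.na(calls[, 2]), , drop = FALSE]
  .check(nrow(calls) >= 0, "calls must be a 2-column matrix")
  if (nrow(calls) == 0) return(c(NA_integer_, NA_integer_))
  lo <- pmin(calls[, 1], calls[, 2]); hi <- pmax(calls[, 1], calls[, 2])
  key <- paste(lo, hi)
  tab <- table(key)
  is_het <- vapply(strsplit(names(tab), " "),
                   function(p) p[1] != p[2], logical(1))
  if (count_alleles) {
    # het support = replicates in which both of its alleles appear anywhere
    het_support <- vapply(which(is_het), function(i) {
      p <- as.integer(strsplit(names(tab)[i], " ")[[1]])
      sum((lo == p[1] | hi == p[1]) & (lo == p[2] | hi == p[2]))
    }, numeric(1))
  } else {
    het_support <- as.numeric(tab[is_het])
  }
  het_ok <- which(is_het)[het_support >= het_min]
  hom_ok <- which(!is_het)[tab[!is_het] >= hom_min]
  if (length(het_ok) == 1 && length(hom_ok) == 0) {
    return(as.integer(strsplit(names(tab)[het_ok], " ")[[1]]))
  }
  if (length(hom_ok) == 1 && length(het_ok) == 0) {
    return(as.integer(strsplit(names(tab)[hom_ok], " ")[[1]]))
  }
  # no support, or conflicting support -> missing
  c(NA_integer_, NA_integer_)
}

#' Consensus genotypes for a whole replicate-call set
#'
#' Applies [consensus_genotype()] to every individual x locus cell of a
#' [make_replicates()] object (or any object with the same shape).
#'
#' @param reps a `replicate_calls` object.
#' @param meta a [genotype_table()] supplying ids, groups and coordinates for
#'   the output (alleles are ignored).
#' @param ... passed to [consensus_genotype()].
#' @return a [genotype_table()] of consensus calls.
#' @export
consensus_table <- function(reps, meta, ...) {
  n <- dim(reps$a1)[1]; L <- dim(reps$a1)[2]
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      cal <- cbind(reps$a1[i, l, ], reps$a2[i, l, ])
      g <- consensus_genotype(cal, ...)
      a1[i, l] <- g[1]; a2[i, l] <- g[2]
    }
  }
  genotype_table(meta$ind_id, meta$group_id, meta$x, meta$y, a1, a2,
                 pop_id = meta$pop_id, loci = reps$loci)
}

#' Filter samples on replicate DNA concentrations
#'
#' Keeps a sample iff its mean concentration over the two replicate
#' quantification runs exceeds the threshold (strictly greater).
#'
#' @param concentrations two-column numeric matrix of ng/ul values, row names
#'   (or `sample_ids`) identifying samples.
#' @param threshold ng/ul cut-off (default 0.5).
#' @param sample_ids optional sample identifiers.
#' @return character vector of kept sample ids (or kept row indices when no
#'   ids are available).
#' @export
qc_filter_samples <- function(concentrations, threshold = 0.5,
                              sample_ids = rownames(concentrations)) {
  force(sample_ids)
  concentrations <- matrix(as.numeric(as.matrix(concentrations)), ncol = 2)
  .check(all(concentrations >= 0, na.rm = TRUE),
         "negative DNA concentration")
  .check(!anyNA(concentrations), "missing concentration value")
  keep <- rowMeans(concentrations) > threshold
  if (is.null(sample_ids)) which(keep) else sample_ids[keep]
}

#' Per-group per-locus diversity statistics
#'
#' Observed heterozygosity `Ho`, unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - sum p_i^2)` (n = genes), allele count `k`, and gene
#' sample size over non-missing individuals.
#'
#' @param table a [genotype_table()].
#' @param group optional single group label; default pools all individuals.
#' @return data.frame with one row per locus: `locus, n_genes, k, Ho, He`.
#' @export
locus_stats <- function(table, group = NULL) {
  idx <- if (is.null(group)) seq_len(n_ind(table)) else
    which(table$group_id == group)
  out <- lapply(seq_len(n_loci(table)), function(l) {
    a1 <- table$a1[idx, l]; a2 <- table$a2[idx, l]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]
    n2 <- 2L * length(a1)
    if (n2 == 0) {
      return(data.frame(locus = table$loci[l], n_genes = 0L, k = 0L,
                        Ho = NA_real_, He = NA_real_))
    }
    p <- table(c(a1, a2)) / n2
    k <- length(p)
    he <- if (n2 > 1) (n2 / (n2 - 1)) * (1 - sum(p^2)) else 0
    data.frame(locus = table$loci[l], n_genes = n2, k = k,
               Ho = mean(a1 != a2), He = he)
  })
  do.call(rbind, out)
}

#' Permutation test for Hardy-Weinberg equilibrium at one locus
#'
#' Test statistic `|Ho - He|`; the null distribution is generated by pooling
#' the `2n` observed alleles and re-pairing them into random diploids (He is
#' invariant under re-pairing, so only Ho varies). `p = (1 + #{null >= obs})
#' / (n_perm + 1)`.
#'
#' @param table a [genotype_table()].
#' @param group group label.
#' @param locus locus name.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
hwe_test <- function(table, group, locus, n_perm = 1000, seed = 1L) {
  idx <- which(table$group_id == group)
  l <- match(locus, table$loci)
  .check(!is.na(l), "unknown locus %s", locus)
  a1 <- table$a1[idx, l]; a2 <- table$a2[idx, l]
  ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
  .check(length(a1) >= 5, "need >= 5 non-missing individuals (have %d)",
         length(a1))
  genes <- c(a1, a2)
  if (length(unique(genes)) == 1) {
    warning("monomorphic locus: HWE p set to 1")
    return(1)
  }
  n <- length(a1); n2 <- 2L * n
  p <- table(genes) / n2
  he <- (n2 / (n2 - 1)) * (1 - sum(p^2))
  obs <- abs(mean(a1 != a2) - he)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    g <- sample(genes)
    abs(mean(g[seq_len(n)] != g[n + seq_len(n)]) - he)
  }, numeric(1))
  (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
}

#' Null-allele screen (heterozygote-deficit estimator)
#'
#' Estimates the null-allele frequency with the single closed form
#' `r = (He - Ho) / (1 + He)` and flags the locus when a bootstrap
#' (resampling individuals) 95% percentile interval for `r` excludes zero.
#' Flagging is suppressed below 10 individuals.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param group group label (`NULL` pools all).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `r`, `flagged`, `ci` (bootstrap interval or `NULL`), `n`.
#' @export
null_allele_screen <- function(table, locus, group = NULL, n_boot = 500,
                               seed = 1L) {
  idx <- if (is.null(group)) seq_len(n_ind(table)) else
    which(table$group_id == group)
  l <- match(locus, table$loci)
  .check(!is.na(l), "unknown locus %s", locus)
  a1 <- table$a1[idx, l]; a2 <- table$a2[idx, l]
  ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  brook <- function(x1, x2) {
    n2 <- 2L * length(x1)
    p <- table(c(x1, x2)) / n2
    he <- if (n2 > 1) (n2 / (n2 - 1)) * (1 - sum(p^2)) else 0
    (he - mean(x1 != x2)) / (1 + he)
  }
  r <- brook(a1, a2)
  if (n < 10) {
    return(list(r = r, flagged = FALSE, ci = NULL, n = n))
  }
  set.seed(seed)
  bs <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    brook(a1[i], a2[i])
  }, numeric(1))
  ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  list(r = r, flagged = ci[1] > 0 || ci[2] < 0, ci = ci, n = n)
}
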