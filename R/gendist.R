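#' Rousset's a-hat individual pairwise genetic distance matrix
#'
#' For each pair of individuals, over the loci where both are genotyped:
#' the within-individual allelic identity `Q_w` at a locus is the mean of the
#' two individuals' own identities (1 if homozygous, 0 if heterozygous), and
#' the between-individual identity `Q_b` is the mean allelic identity over
#' the four between-individual allele pairings. The multilocus estimate is
#' the ratio of sums `a-hat = sum_l (Q_w - Q_b) / sum_l (1 - Q_w)`
#' (ratio-of-sums combining, consistent with the theta estimator). Loci that
#' are monomorphic for the pair contribute 0/0 and drop out; a pair with zero
#' denominator at every usable locus (both individuals homozygous everywhere)
#' is masked with a warning. Values may be negative.
#'
#' @param table a [genotype_table()].
#' @return a [pairwise_matrix()] of kind `rousset_a`; masked pairs carry `NA`
#'   values and `mask = FALSE`.
#' @export
rousset_a_matrix <- function(table) {
  n <- n_ind(table)
  .check(n >= 2, "need >= 2 individuals")
  num <- den <- matrix(0, n, n)
  for (l in seq_len(n_loci(table))) {
    a1 <- table$a1[, l]; a2 <- table$a2[, l]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    hom <- as.numeric(a1 == a2)
    qb <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
           outer(a2, a1, "==") + outer(a2, a2, "==")) / 4
    qw <- outer(hom, hom, "+") / 2
    use <- outer(ok, ok, "&")
    contrib_n <- (qw - qb); contrib_n[!use] <- 0
    contrib_d <- (1 - qw); contrib_d[!use] <- 0
    num <- num + contrib_n
    den <- den + contrib_d
  }
  vals <- num / den
  bad <- den == 0
  diag(bad) <- TRUE
  vals[bad] <- NA_real_
  if (any(bad[upper.tri(bad)])) {
    warning(sprintf("%d pair(s) with zero denominator masked",
                    sum(bad[upper.tri(bad)])))
  }
  mask <- !bad
  diag(mask) <- FALSE
  pairwise_matrix(table$ind_id, vals, kind = "rousset_a", mask = mask)
}

#' Moran's I individual pairwise genetic similarity matrix
#'
#' Codes each individual's frequency of every allele at every locus as
#' 0, 0.5 or 1 and measures the autocorrelation-style cross-product of two
#' individuals' centered allele-frequency vectors, normalized by the mean
#' centered sum of squares over individuals:
#' `I_ij = sum_{l,a} z_ila z_jla / mean_k sum_{l,a} z_kla^2`, with
#' `z_ila = p_ila - pbar_la` and `pbar` the whole-sample frequency. Higher
#' values mean genetically more similar. Loci missing for an individual
#' contribute nothing to its products; individuals missing at all loci are
#' masked.
#'
#' @param table a [genotype_table()].
#' @param reference centering reference; only `"whole_sample"` is defined.
#' @return a [pairwise_matrix()] of kind `morans_i`.
#' @export
morans_i_matrix <- function(table, reference = c("whole_sample")) {
  reference <- match.arg(reference)
  n <- n_ind(table)
  .check(n >= 3, "need >= 3 individuals")
  zs <- list()
  for (l in seq_len(n_loci(table))) {
    a1 <- table$a1[, l]; a2 <- table$a2[, l]
    ok <- !is.na(a1)
    if (sum(ok) == 0) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    for (al in alleles) {
      p <- ((a1 == al) + (a2 == al)) / 2
      z <- p - mean(p, na.rm = TRUE)
      z[!ok] <- 0  # missing loci contribute nothing
      zs[[length(zs) + 1]] <- z
    }
  }
  Z <- do.call(cbind, zs)
  numer <- Z %*% t(Z)
  all_missing <- rowSums(!is.na(table$a1)) == 0
  w <- mean(rowSums(Z^2)[!all_missing])
  vals <- numer / w
  vals[all_missing, ] <- NA_real_
  vals[, all_missing] <- NA_real_
  mask <- !(outer(all_missing, all_missing, "|"))
  diag(mask) <- FALSE
  pairwise_matrix(table$ind_id, vals, kind = "morans_i", mask = mask)
}
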