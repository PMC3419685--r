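#' Published pairwise-FST fixture for 14 squirrel monkey groups
#'
#' Loads the packaged pairwise Weir-Cockerham FST matrix among the 14 sampled
#' groups of the Central Pacific squirrel monkey study system (five western
#' groups E, G, K, O, PD and nine eastern groups B, C, H, I, M, P, R, T, V),
#' together with per-pair significance flags under the Bonferroni-corrected
#' threshold, per-group sample sizes, and the group-to-population partition.
#'
#' @return a list of class `fst_fixture` with elements `group_ids`, `fst`
#'   (a [pairwise_matrix()] of kind `fst`), `significant` (symmetric logical
#'   matrix), `n` (named sample sizes), `population_of` (named character).
#' @export
load_fst_fixture <- function() {
  f1 <- system.file("extdata", "fst_table1.csv", package = "costsweep",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "fst_table1_groups.csv", package = "costsweep",
                    mustWork = TRUE)
  pairs <- utils::read.csv(f1, stringsAsFactors = FALSE)
  sizes <- utils::read.csv(f2, stringsAsFactors = FALSE)
  ids <- sizes$group
  .check(nrow(pairs) == choose(length(ids), 2),
         "fixture must hold %d pairs", choose(length(ids), 2))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  s <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$group1[r]; j <- pairs$group2[r]
    m[i, j] <- m[j, i] <- pairs$fst[r]
    s[i, j] <- s[j, i] <- pairs$significant[r]
  }
  stopifnot(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  structure(list(group_ids = ids,
                 fst = pairwise_matrix(ids, m, kind = "fst"),
                 significant = s,
                 n = stats::setNames(sizes$n, ids),
                 population_of = stats::setNames(sizes$population, ids)),
            class = "fst_fixture")
}

#' @export
print.fst_fixture <- function(x, ...) {
  cat(sprintf("fst_fixture: %d groups, %d pairs, %d genotyped individuals\n",
              length(x$group_ids), choose(length(x$group_ids), 2), sum(x$n)))
  invisible(x)
}
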