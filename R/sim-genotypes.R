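#' Forward-time Wright-Fisher simulation of diploid microsatellites over demes
#'
#' The core engine behind [simulate_genotypes()] and the island-model checks:
#' non-overlapping generations, individual-level migration by a fixed
#' backward migration matrix, Mendelian inheritance at unlinked loci, and
#' stepwise (SMM) or two-phase (TPM) mutation. All demes descend from one
#' ancestral founder pool whose per-locus allele counts are drawn from 8-12
#' with a triangular frequency profile, matching typical observed
#' microsatellite richness.
#'
#' @param m backward migration matrix (demes x demes): row `d` gives the
#'   probability an offspring in deme `d` draws its parents from each deme;
#'   off-diagonal entries are migration rates, rows must sum to <= 1 (the
#'   diagonal is filled with the remainder).
#' @param group_size diploid deme size N.
#' @param n_loci number of unlinked loci.
#' @param mu per-gamete per-locus mutation rate.
#' @param mutation_model `"SMM"` or `"TPM"`.
#' @param tpm_p_multi,tpm_geo_mean TPM parameters (probability of a
#'   multi-step mutation; mean of its geometric step size).
#' @param generations number of generations.
#' @param seed integer seed for this stream.
#' @param init_genes optional `2N0 x n_loci x n_demes` array of allele sizes
#'   to start from (e.g. the `genes` of an earlier run), enabling multi-epoch
#'   scenarios such as a population crash; `N0` may differ from `group_size`.
#' @return a list with `genes` (array `2N x n_loci x n_demes` of allele
#'   sizes) and `founder_k` (per-locus founder allele counts, `NA` when
#'   `init_genes` is supplied).
#' @export
simulate_demes <- function(m, group_size, n_loci, mu,
                           mutation_model = c("SMM", "TPM"),
                           tpm_p_multi = 0.3, tpm_geo_mean = 2.8,
                           generations = 200, seed = 1L, init_genes = NULL) {
  mutation_model <- match.arg(mutation_model)
  m <- as.matrix(m)
  D <- nrow(m); N <- as.integer(group_size); L <- as.integer(n_loci)
  off <- m; diag(off) <- 0
  .check(all(off >= 0) && all(rowSums(off) <= 1 + 1e-12),
         "off-diagonal migration row sums must be <= 1")
  diag(m) <- 1 - rowSums(off)
  set.seed(seed)

  if (is.null(init_genes)) {
    # ancestral founder pool: 8-12 alleles per locus, triangular frequencies
    founder_k <- sample(8:12, L, replace = TRUE)
    G <- array(0L, dim = c(2L * N, L, D))
    for (l in seq_len(L)) {
      k <- founder_k[l]
      alleles <- 100L + seq_len(k) - 1L
      w <- k:1
      G[, l, ] <- sample(alleles, 2L * N * D, replace = TRUE, prob = w / sum(w))
    }
  } else {
    .check(length(dim(init_genes)) == 3 && dim(init_genes)[2] == L &&
           dim(init_genes)[3] == D && dim(init_genes)[1] %% 2 == 0,
           "init_genes must be a 2N0 x n_loci x n_demes array")
    G <- init_genes
    founder_k <- rep(NA_integer_, L)
  }

  n_off <- N * D
  deme_of <- rep(seq_len(D), each = N)
  for (gen in seq_len(generations)) {
    Np <- dim(G)[1] %/% 2L  # parent pool size (differs in epoch transitions)
    # source deme per offspring individual (whole-genotype migration)
    src <- integer(n_off)
    for (d in seq_len(D)) {
      src[deme_of == d] <- sample.int(D, N, replace = TRUE, prob = m[d, ])
    }
    p1 <- sample.int(Np, n_off, replace = TRUE)
    p2 <- sample.int(Np, n_off, replace = TRUE)
    newG <- array(0L, dim = c(2L * N, L, D))
    base <- 2L * Np * (L * (src - 1L))
    for (l in seq_len(L)) {
      row1 <- 2L * p1 - (stats::runif(n_off) < 0.5)
      row2 <- 2L * p2 - (stats::runif(n_off) < 0.5)
      shift <- 2L * Np * (l - 1L)
      g1 <- G[row1 + shift + base]
      g2 <- G[row2 + shift + base]
      # offspring i occupies rows 2i-1, 2i of its own deme
      i_in <- rep(seq_len(N), times = D)
      dst <- 2L * N * L * (deme_of - 1L) + 2L * N * (l - 1L)
      newG[2L * i_in - 1L + dst] <- g1
      newG[2L * i_in + dst] <- g2
    }
    if (mu > 0) {
      hit <- which(stats::runif(length(newG)) < mu)
      if (length(hit)) {
        steps <- rep(1L, length(hit))
        if (mutation_model == "TPM") {
          multi <- stats::runif(length(hit)) < tpm_p_multi
          steps[multi] <- stats::rgeom(sum(multi), 1 / tpm_geo_mean) + 1L
        }
        sgn <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
        newG[hit] <- pmax(2L, newG[hit] + sgn * steps)
      }
    }
    G <- newG
  }
  list(genes = G, founder_k = founder_k)
}

# internal: turn a deme gene array into a genotype_table, sampling
# `sizes[d]` individuals from deme d placed at coords[d,] with small jitter
.demes_to_table <- function(G, sizes, coords, group_ids, pop_ids = NULL,
                            jitter = 0) {
  D <- dim(G)[3]; N <- dim(G)[1] / 2L; L <- dim(G)[2]
  rows <- list(); k <- 0L
  ind_id <- grp <- pop <- character(0); xs <- ys <- numeric(0)
  a1 <- a2 <- NULL
  for (d in seq_len(D)) {
    take <- sample.int(N, sizes[d])
    for (i in take) {
      k <- k + 1L
      ind_id <- c(ind_id, sprintf("%s_%d", group_ids[d], i))
      grp <- c(grp, group_ids[d])
      if (!is.null(pop_ids)) pop <- c(pop, pop_ids[d])
      xs <- c(xs, coords[d, 1] + stats::runif(1, -jitter, jitter))
      ys <- c(ys, coords[d, 2] + stats::runif(1, -jitter, jitter))
      a1 <- rbind(a1, G[2L * i - 1L, , d])
      a2 <- rbind(a2, G[2L * i, , d])
    }
  }
  genotype_table(ind_id, grp, xs, ys, a1, a2,
                 pop_id = if (!is.null(pop_ids)) pop,
                 loci = paste0("L", seq_len(L)))
}

#' Simulate genotypes over a synthetic landscape with known barrier truth
#'
#' Places demes in forest cells on both sides of the barrier band, computes
#' true least-cost distances on the true cost surface, converts them into a
#' symmetric migration matrix `m_ij = c * exp(-d_LC(i,j) / lambda)` (with `c`
#' scaling the largest row emigration total to `m_total`), runs the forward
#' Wright-Fisher engine, and samples the configured subset of each deme.
#'
#' @param landscape a [landscape_raster()] from [generate_landscape()].
#' @param true_costs named per-class relative costs (>= 1) defining the truth;
#'   defaults to `config$true_costs`.
#' @param config a [sim_config()].
#' @return a list with `table` (a [genotype_table()]; `pop_id` labels the two
#'   sides of the barrier) and `truth` (class `sim_truth`: config echo,
#'   realized migration matrix, true least-cost matrix, group coordinates,
#'   derived seeds).
#' @export
simulate_genotypes <- function(landscape, true_costs = config$true_costs,
                               config) {
  legend <- landscape$legend
  set.seed(derive_seed(config$seed, "placement"))
  forest <- which(landscape$codes == legend[["forest"]], arr.ind = TRUE)
  .check(nrow(forest) >= config$n_groups,
         "no forest cells available for %d groups", config$n_groups)
  barrier_code <- legend[[config$barrier_class]]
  bmask <- landscape$codes == barrier_code
  side <- vapply(seq_len(nrow(forest)), function(i) {
    r <- forest[i, 1]; cc <- forest[i, 2]
    brows <- which(bmask[, cc])
    if (length(brows) == 0) r <= landscape$nrows / 2 else r < min(brows)
  }, logical(1))
  n_north <- ceiling(config$n_groups / 2)
  n_south <- config$n_groups - n_north
  .check(sum(side) >= n_north && sum(!side) >= n_south,
         "no forest cell available for a group on one side of the barrier")
  pick_spread <- function(cells, k) {
    # farthest-point sampling for well-spread deme locations
    if (k == 0L) return(cells[integer(0), , drop = FALSE])
    idx <- sample.int(nrow(cells), 1)
    while (length(idx) < k) {
      d2 <- rep(Inf, nrow(cells))
      for (i in idx) {
        d2 <- pmin(d2, (cells[, 1] - cells[i, 1])^2 +
                       (cells[, 2] - cells[i, 2])^2)
      }
      idx <- c(idx, which.max(d2))
    }
    cells[idx, , drop = FALSE]
  }
  cells <- rbind(pick_spread(forest[side, , drop = FALSE], n_north),
                 pick_spread(forest[!side, , drop = FALSE], n_south))
  pop_ids <- rep(c("north", "south"), c(n_north, n_south))
  coords <- cbind(
    x = landscape$xll + (cells[, 2] - 0.5) * landscape$cellsize,
    y = landscape$yll + (landscape$nrows - cells[, 1] + 0.5) * landscape$cellsize)

  surface <- cost_surface(landscape, true_costs)
  dlc <- least_cost_matrix(surface, coords)$values
  w <- exp(-dlc / config$dispersal_scale)
  diag(w) <- 0
  mscale <- max(rowSums(w))
  m <- if (mscale > 0) config$m_total * w / mscale else w * 0

  demo_seed <- derive_seed(config$seed, "demography")
  sim <- simulate_demes(m, config$group_size, config$n_loci, config$mu,
                        config$mutation_model, config$tpm_p_multi,
                        config$tpm_geo_mean, config$generations,
                        seed = demo_seed)
  set.seed(derive_seed(config$seed, "sampling"))
  sizes <- config$sample_sizes
  if (is.null(sizes)) {
    hi <- min(28L, config$group_size)
    sizes <- sample(10:hi, config$n_groups, replace = TRUE)
  }
  .check(all(sizes <= config$group_size), "sample sizes exceed group_size")
  group_ids <- paste0("g", seq_len(config$n_groups))
  table <- .demes_to_table(sim$genes, sizes, coords, group_ids, pop_ids,
                           jitter = landscape$cellsize / 2)
  truth <- structure(list(config = config, m = m, true_least_cost = dlc,
                          group_coords = coords, group_ids = group_ids,
                          pop_ids = pop_ids, founder_k = sim$founder_k,
                          seeds = c(landscape = derive_seed(config$seed, "landscape"),
                                    placement = derive_seed(config$seed, "placement"),
                                    demography = demo_seed)),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

#' Write a simulation truth record as YAML
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  yaml::write_yaml(list(config = unclass(truth$config),
                        m = apply(truth$m, 1, as.list),
                        true_least_cost = apply(truth$true_least_cost, 1, as.list),
                        group_coords = apply(truth$group_coords, 1, as.list),
                        group_ids = truth$group_ids, pop_ids = truth$pop_ids,
                        seeds = as.list(truth$seeds)), path)
  invisible(path)
}

#' Simulate a finite-island model
#'
#' Convenience wrapper used for calibration checks against the closed-form
#' island-model expectation `FST ~ 1 / (1 + 4 N m)`: `k` demes exchanging
#' migrants uniformly at total rate `m` per deme per generation.
#'
#' @param k number of demes.
#' @param N diploid deme size.
#' @param m total emigration rate per deme per generation.
#' @param n_loci,mu,generations,seed as in [simulate_demes()].
#' @param mutation_model mutation model.
#' @return a [genotype_table()] with all individuals sampled.
#' @export
simulate_island_model <- function(k, N, m, n_loci = 16, mu = 5e-4,
                                  generations = 500, mutation_model = "SMM",
                                  seed = 1L) {
  mm <- matrix(m / (k - 1), k, k); diag(mm) <- 0
  sim <- simulate_demes(mm, N, n_loci, mu, mutation_model,
                        generations = generations, seed = seed)
  coords <- cbind(x = seq_len(k) * 1000, y = rep(0, k))
  .demes_to_table(sim$genes, rep(N, k), coords, paste0("d", seq_len(k)))
}

#' Generate noisy replicate allele calls from true genotypes
#'
#' Emulates the genotyping error process of non-invasive (fecal) samples:
#' in each replicate, every true heterozygote independently drops one random
#' allele with probability `dropout_rate` (appearing homozygous), and every
#' allele call is independently replaced by a one-repeat-unit miscall with
#' probability `misscore_rate`.
#'
#' @param table a [genotype_table()] of true genotypes.
#' @param dropout_rate allelic dropout probability per heterozygote per
#'   replicate, in `[0, 1]`.
#' @param misscore_rate per-allele miscall probability, in `[0, 1]`.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return a list of class `replicate_calls` with arrays `a1`, `a2`
#'   (`n_ind x n_loci x n_reps`) plus the source `ind_id` and `loci`.
#' @export
make_replicates <- function(table, dropout_rate, misscore_rate, n_reps,
                            seed = 1L) {
  .check(dropout_rate >= 0 && dropout_rate <= 1 &&
         misscore_rate >= 0 && misscore_rate <= 1, "rates must lie in [0,1]")
  set.seed(seed)
  n <- n_ind(table); L <- n_loci(table)
  a1 <- array(NA_integer_, c(n, L, n_reps))
  a2 <- array(NA_integer_, c(n, L, n_reps))
  het <- table$a1 != table$a2
  for (r in seq_len(n_reps)) {
    r1 <- table$a1; r2 <- table$a2
    drop_hit <- het & matrix(stats::runif(n * L) < dropout_rate, n, L)
    drop_hit[is.na(drop_hit)] <- FALSE
    keep_first <- matrix(stats::runif(n * L) < 0.5, n, L)
    r1[drop_hit & !keep_first] <- r2[drop_hit & !keep_first]
    r2[drop_hit & keep_first] <- r1[drop_hit & keep_first]
    mis <- function(x) {
      hit <- !is.na(x) & matrix(stats::runif(n * L) < misscore_rate, n, L)
      x[hit] <- pmax(2L, x[hit] +
                     ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L))
      x
    }
    r1 <- mis(r1); r2 <- mis(r2)
    a1[, , r] <- pmin(r1, r2); a2[, , r] <- pmax(r1, r2)
  }
  structure(list(a1 = a1, a2 = a2, ind_id = table$ind_id, loci = table$loci),
            class = "replicate_calls")
}
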