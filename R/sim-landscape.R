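#' Configuration for the synthetic landscape + genotype simulator
#'
#' Bundles every tunable of the forward-time simulator: grid geometry, target
#' land-cover composition, which matrix class is the true dispersal barrier
#' and at what relative cost, demography (number of demes, deme size,
#' generations), the microsatellite mutation model, and the dispersal kernel.
#' Defaults emulate the study system this pipeline was built around: 14 groups
#' genotyped at 16 unlinked microsatellite loci on a 20-m land-cover grid in
#' which one expansive matrix class (oil palm) forms a contiguous band while
#' other matrix classes occur as small scattered patches.
#'
#' @param ncols,nrows grid dimensions (cells).
#' @param cellsize cell edge (m); 20 m mirrors the resolution of the study's
#'   land-cover digitization.
#' @param class_fractions named vector of target cover fractions (must sum to
#'   1); names from [default_legend()].
#' @param barrier_class class laid out as one contiguous band spanning the
#'   grid's width (the true barrier when its `true_costs` entry is > 1).
#' @param true_costs named per-class relative traversal costs (>= 1) used to
#'   compute the true least-cost distances that drive migration.
#' @param n_groups number of demes (sampling groups).
#' @param group_size diploid individuals per deme (Wright-Fisher size).
#' @param sample_sizes optional per-group sampled subset sizes; default draws
#'   each uniformly from 10..min(28, group_size), the published range.
#' @param n_loci number of unlinked microsatellite loci.
#' @param mu mutation rate per gamete per locus (in `[0, 0.01]`).
#' @param mutation_model `"SMM"` (strict single-step) or `"TPM"`.
#' @param tpm_p_multi probability a TPM mutation is multi-step.
#' @param tpm_geo_mean mean of the geometric multi-step size.
#' @param dispersal_scale kernel scale lambda in cost-distance units (metres
#'   on a cost-1 surface): migration `m_ij` decays as `exp(-d_LC(i,j)/lambda)`.
#' @param m_total total emigration fraction per deme per generation used to
#'   scale the kernel (the kernel itself only fixes relative rates).
#' @param generations forward generations to run.
#' @param seed master seed; landscape, demography and error streams are
#'   derived from it via [derive_seed()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(ncols = 150, nrows = 60, cellsize = 20,
                       class_fractions = c(forest = 0.55, oil_palm = 0.18,
                                           pasture = 0.10, river = 0.04,
                                           residential = 0.04, other = 0.09),
                       barrier_class = "oil_palm",
                       true_costs = c(forest = 1, oil_palm = 50, pasture = 1,
                                      river = 1, residential = 1, other = 1),
                       n_groups = 14, group_size = 35, sample_sizes = NULL,
                       n_loci = 16, mu = 5e-4,
                       mutation_model = c("SMM", "TPM"),
                       tpm_p_multi = 0.3, tpm_geo_mean = 2.8,
                       dispersal_scale = 800, m_total = 0.1,
                       generations = 25, seed = 1L) {
  mutation_model <- match.arg(mutation_model)
  .check(abs(sum(class_fractions) - 1) <= 1e-9,
         "class fractions must sum to 1 (got %.12f)", sum(class_fractions))
  .check(all(class_fractions >= 0), "class fractions must be non-negative")
  if (!barrier_class %in% names(class_fractions)) {
    class_fractions[barrier_class] <- 0  # barrier absent from this landscape
  }
  .check(all(names(class_fractions) %in% names(default_legend())),
         "unknown class name(s) in fractions")
  .check(mu >= 0 && mu <= 0.01, "mu must lie in [0, 0.01]")
  .check(all(true_costs >= 1), "true costs must be >= 1")
  .check(n_groups >= 1 && group_size >= 2 && n_loci >= 1 && generations >= 1,
         "counts must be positive")
  .check(m_total >= 0 && m_total < 1, "m_total must lie in [0, 1)")
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 cellsize = cellsize, class_fractions = class_fractions,
                 barrier_class = barrier_class, true_costs = true_costs,
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 sample_sizes = sample_sizes,
                 n_loci = as.integer(n_loci), mu = mu,
                 mutation_model = mutation_model,
                 tpm_p_multi = tpm_p_multi, tpm_geo_mean = tpm_geo_mean,
                 dispersal_scale = dispersal_scale, m_total = m_total,
                 generations = as.integer(generations),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read / write a simulator configuration as YAML
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, c(
    x[c("ncols", "nrows", "cellsize", "barrier_class", "n_groups",
        "group_size", "n_loci", "mu", "mutation_model", "tpm_p_multi",
        "tpm_geo_mean", "dispersal_scale", "m_total", "generations", "seed")],
    list(class_fractions = unlist(x$class_fractions),
         true_costs = unlist(x$true_costs),
         sample_sizes = if (!is.null(x$sample_sizes)) unlist(x$sample_sizes))))
}

#' Generate a synthetic categorical land-cover raster
#'
#' Lays the barrier class out as a single 8-connected band spanning the full
#' grid width (a contiguous expanse, the configuration under which an
#' expansive matrix class can act as a true barrier), fills the background
#' with forest, and scatters the remaining matrix classes as small compact
#' patches. Class fractions land within 2 percentage points of the request;
#' the output is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [landscape_raster()].
#' @export
generate_landscape <- function(config) {
  set.seed(derive_seed(config$seed, "landscape"))
  nr <- config$nrows; nc <- config$ncols
  fr <- config$class_fractions
  legend <- default_legend()
  codes <- matrix(legend[["forest"]], nr, nc)

  fb <- fr[[config$barrier_class]]
  if (fb > 0) {
    h <- round(fb * nr)
    .check(h >= 1 && abs(h / nr - fb) <= 0.02 + 1e-9,
           "barrier fraction %.3f infeasible on %d rows", fb, nr)
    top <- integer(nc)
    top[1] <- max(1L, floor((nr - h) / 2))
    for (j in 2:nc) {
      step <- sample(c(-1L, 0L, 1L), 1)
      top[j] <- min(max(top[j - 1] + step, 1L), nr - h + 1L)
    }
    for (j in seq_len(nc)) codes[top[j]:(top[j] + h - 1L), j] <-
      legend[[config$barrier_class]]
  }

  total <- nr * nc
  scatter <- setdiff(names(fr)[fr > 0], c("forest", config$barrier_class))
  for (cls in scatter) {
    target <- round(fr[[cls]] * total)
    free <- which(codes == legend[["forest"]])
    .check(length(free) >= target,
           "fraction %.3f for class %s infeasible: only %d free cells",
           fr[[cls]], cls, length(free))
    placed <- 0L
    guard <- 0L
    while (placed < target) {
      guard <- guard + 1L
      .check(guard < 50L * target + 1000L,
             "patch placement for class %s did not converge", cls)
      free <- which(codes == legend[["forest"]])
      seed_cell <- free[sample.int(length(free), 1)]
      r0 <- (seed_cell - 1L) %% nr + 1L
      c0 <- (seed_cell - 1L) %/% nr + 1L
      rad <- sample(1:3, 1)
      rows <- max(1, r0 - rad):min(nr, r0 + rad)
      cols <- max(1, c0 - rad):min(nc, c0 + rad)
      block <- as.matrix(expand.grid(rows, cols))
      ok <- codes[block] == legend[["forest"]]
      block <- block[ok, , drop = FALSE]
      take <- min(nrow(block), target - placed)
      if (take > 0) {
        codes[block[seq_len(take), , drop = FALSE]] <- legend[[cls]]
        placed <- placed + take
      }
    }
  }
  out <- landscape_raster(codes, xll = 0, yll = 0, cellsize = config$cellsize,
                          legend = legend)
  realized <- mean(codes == legend[["forest"]])
  .check(abs(realized - fr[["forest"]]) <= 0.02 + 1 / nr,
         "forest fraction %.3f drifted from request %.3f", realized,
         fr[["forest"]])
  out
}
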