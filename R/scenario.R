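#' Describe a multi-environment RIL simulation scenario
#'
#' A scenario bundles every knob of the synthetic-data generator: the map,
#' the number of founder lines, the per-environment line subsets and
#' replicate counts, QTL effects (possibly environment-dependent), trait
#' means and environment offsets, the seed-weight model, analytical run
#' batches, and the analytical-outlier rate.
#'
#' QTL effects are given on the scale of the residual standard deviation
#' when `residual_sd = 1` (the default), so `effect = 1` means the A-vs-B
#' line-mean difference is one residual SD.
#'
#' @param n_lines number of founder RILs.
#' @param map an `ionqtl_map` (see [make_map()]).
#' @param environments list of `list(env_id=, line_subset_size=, n_reps=)`;
#'   each environment phenotypes a random subset of the founder lines.
#' @param traits character vector of trait (element) names.
#' @param qtl_effects list of `list(trait=, chr=, pos_cM=, effect=)`; the
#'   effect is the A-minus-B line-mean difference and may be a single
#'   number (constant across environments) or a named vector keyed by
#'   `env_id` (environment-specific effects; unnamed environments get 0).
#' @param trait_means named (or scalar) baseline trait value(s).
#' @param env_main_effects named numeric of per-environment trait offsets
#'   (applied to all traits), or a list keyed by trait of such vectors.
#' @param residual_sd line-level residual SD (> 0), shared across traits.
#' @param weight_model `list(mean_mg=, sd_mg=, contamination=)`; seed weight
#'   is normal truncated at zero and `contamination` is a weight-independent
#'   additive term on each raw concentration (per element, recycled).
#' @param run_batches `list(n=, offsets=, block_size=)`: number of
#'   analytical runs, an additive per-run offset on every raw value, and the
#'   number of consecutive seeds per block for round-robin run assignment.
#' @param measurement_sd per-seed measurement noise SD on raw values.
#' @param seeds_per_rep single seeds measured per replicate row.
#' @param outlier_rate probability in `[0, 1)` that a (seed, element) raw
#'   value is replaced by an analytical outlier.
#' @param outlier_mads size of injected outliers, in multiples of the
#'   (line, environment) group MAD (>= 10 so the flagging rule recovers
#'   them).
#' @param missing_geno_rate proportion of genotype calls set missing.
#' @param rng_seed integer master seed; per-stage sub-streams are derived
#'   from it by fixed offsets.
#' @return A list of class `ionqtl_scenario`.
#' @seealso [default_scenario()] for the study-scale default.
#' @export
sim_scenario <- function(n_lines,
                         map,
                         environments,
                         traits = "trait1",
                         qtl_effects = list(),
                         trait_means = 10,
                         env_main_effects = NULL,
                         residual_sd = 1,
                         weight_model = list(mean_mg = 250, sd_mg = 50,
                                             contamination = 0),
                         run_batches = list(n = 1, offsets = 0,
                                            block_size = 96),
                         measurement_sd = 0,
                         seeds_per_rep = 4,
                         outlier_rate = 0,
                         outlier_mads = 15,
                         missing_geno_rate = 0,
                         rng_seed = 1L) {
  validate_map(map)
  check_scalar(n_lines, "n_lines", positive = TRUE, integerish = TRUE)
  check_scalar(residual_sd, "residual_sd", positive = TRUE)
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop_arg("outlier_rate must be in [0, 1)")
  for (e in environments) {
    if (is.null(e$env_id) || is.null(e$line_subset_size))
      stop_arg("each environment needs env_id and line_subset_size")
    if (e$line_subset_size > n_lines)
      stop_arg("line_subset_size exceeds n_lines for ", e$env_id)
    if ((e$n_reps %||% 1) < 1) stop_arg("n_reps must be >= 1")
  }
  chr_len <- tapply(map$pos, map$chr, max)
  for (q in qtl_effects) {
    if (!q$chr %in% map$chr || q$pos_cM < 0 || q$pos_cM > chr_len[[as.character(q$chr)]])
      stop_arg("QTL position off the map: chr ", q$chr, " @ ", q$pos_cM, " cM")
    if (!q$trait %in% traits)
      stop_arg("QTL trait not in scenario traits: ", q$trait)
  }
  if (length(trait_means) == 1L && is.null(names(trait_means)))
    trait_means <- stats::setNames(rep(trait_means, length(traits)), traits)
  structure(list(
    n_lines = as.integer(n_lines), map = map, environments = environments,
    traits = traits, qtl_effects = qtl_effects, trait_means = trait_means,
    env_main_effects = env_main_effects, residual_sd = residual_sd,
    weight_model = weight_model, run_batches = run_batches,
    measurement_sd = measurement_sd, seeds_per_rep = as.integer(seeds_per_rep),
    outlier_rate = outlier_rate, outlier_mads = outlier_mads,
    missing_geno_rate = missing_geno_rate, rng_seed = as.integer(rng_seed)
  ), class = "ionqtl_scenario")
}

#' The 20 elements profiled in maize kernel ionomics panels
#' @format Character vector of element symbols.
#' @export
ION_ELEMENTS <- c("B", "Na", "Mg", "Al", "P", "S", "K", "Ca", "Mn", "Fe",
                  "Co", "Ni", "Cu", "Zn", "As", "Se", "Rb", "Sr", "Mo", "Cd")

#' Study-scale default scenario
#'
#' Emulates the design of a 10-environment intermated-RIL ionomics study:
#' 233 founder lines genotyped at dense biallelic markers on 10
#' chromosomes, grown as overlapping subsets of 82-233 lines across 10
#' environments (three of which have replicate rows), 20 elemental traits,
#' a large-effect Mo locus on chromosome 1 present in most environments, a
#' Cd locus on chromosome 2, a location-dependent Ni locus early on
#' chromosome 9, seed-weight-confounded contamination, run-batch offsets,
#' and heavy-tailed analytical outliers.
#'
#' @param markers_per_chr marker density (default 60; the mapping methods
#'   are marker-based, so density only affects resolution and run time).
#' @param rng_seed master seed.
#' @return An `ionqtl_scenario`.
#' @export
default_scenario <- function(markers_per_chr = 60, rng_seed = 1L) {
  map <- make_map(10, markers_per_chr, 300)
  envs <- list(
    list(env_id = "FL05", line_subset_size = 220, n_reps = 1),
    list(env_id = "FL06", line_subset_size = 118, n_reps = 1),
    list(env_id = "IN09", line_subset_size = 193, n_reps = 1),
    list(env_id = "IN10", line_subset_size = 168, n_reps = 1),
    list(env_id = "NC06", line_subset_size = 197, n_reps = 2),
    list(env_id = "NY05", line_subset_size = 233, n_reps = 3),
    list(env_id = "NY06", line_subset_size = 82,  n_reps = 1),
    list(env_id = "NY12", line_subset_size = 168, n_reps = 1),
    list(env_id = "MO06", line_subset_size = 97,  n_reps = 2),
    list(env_id = "SA10", line_subset_size = 87,  n_reps = 1)
  )
  env_ids <- vapply(envs, `[[`, "", "env_id")
  most <- stats::setNames(rep(1.5, 9), setdiff(env_ids, "SA10"))
  inny <- stats::setNames(rep(1.0, 5),
                          c("IN09", "IN10", "NY05", "NY06", "NY12"))
  qtl <- list(
    list(trait = "Mo", chr = 1, pos_cM = 278, effect = most),
    list(trait = "Cd", chr = 2, pos_cM = 215, effect = 1.2),
    list(trait = "Ni", chr = 9, pos_cM = 8,   effect = inny),
    list(trait = "Zn", chr = 4, pos_cM = 157, effect = 0.8)
  )
  offs <- stats::setNames(seq(-1, 1, length.out = length(envs)), env_ids)
  sim_scenario(
    n_lines = 233, map = map, environments = envs, traits = ION_ELEMENTS,
    qtl_effects = qtl, trait_means = 10, env_main_effects = offs,
    residual_sd = 1,
    weight_model = list(mean_mg = 250, sd_mg = 50, contamination = 2),
    run_batches = list(n = 4, offsets = c(0, 1, -1, 0.5), block_size = 576),
    measurement_sd = 0.5, seeds_per_rep = 4,
    outlier_rate = 0.005, outlier_mads = 15, rng_seed = rng_seed
  )
}

#' Read a scenario from a YAML file
#'
#' The YAML mirrors the [sim_scenario()] arguments; `map` is given as
#' `map_spec: {n_chr, markers_per_chr, chr_length_cM}`.
#'
#' @param path YAML file path.
#' @return An `ionqtl_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$map_spec)) stop_arg("scenario YAML needs map_spec")
  map <- make_map(y$map_spec$n_chr, y$map_spec$markers_per_chr,
                  y$map_spec$chr_length_cM)
  y$map_spec <- NULL
  y$map <- map
  for (fld in c("env_main_effects", "trait_means"))
    if (!is.null(y[[fld]])) y[[fld]] <- unlist(y[[fld]])
  if (!is.null(y$qtl_effects))
    y$qtl_effects <- lapply(y$qtl_effects, function(q) {
      if (is.list(q$effect)) q$effect <- unlist(q$effect)
      q
    })
  if (!is.null(y$traits)) y$traits <- unlist(y$traits)
  do.call(sim_scenario, y)
}
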