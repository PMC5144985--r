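# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small because the engines are vectorized and the
# statistical checks only need modest replication.

test_map <- function() make_map(5, 21, 100)

# one environment, optional QTL list, all lines phenotyped
one_env_cross <- function(seed, n_lines = 300, qtl = list(),
                          residual_sd = 1, map = test_map()) {
  sc <- sim_scenario(
    n_lines = n_lines, map = map,
    environments = list(list(env_id = "E", line_subset_size = n_lines,
                             n_reps = 1)),
    traits = "y", qtl_effects = qtl, trait_means = 0,
    residual_sd = residual_sd, rng_seed = seed)
  simulate_crosses(sc)$E
}

# two locations with a single QTL of per-location effects eff1/eff2
two_loc_stack <- function(seed, eff1, eff2, n_per_loc = 200,
                          map = test_map(), qtl_chr = 3, qtl_pos = 50) {
  sc <- sim_scenario(
    n_lines = 2 * n_per_loc, map = map,
    environments = list(
      list(env_id = "loc1", line_subset_size = n_per_loc, n_reps = 1),
      list(env_id = "loc2", line_subset_size = n_per_loc, n_reps = 1)),
    traits = "y",
    qtl_effects = list(list(trait = "y", chr = qtl_chr, pos_cM = qtl_pos,
                            effect = c(loc1 = eff1, loc2 = eff2))),
    env_main_effects = c(loc1 = 0, loc2 = 0.5),
    trait_means = 0, residual_sd = 1, rng_seed = seed)
  stack_locations(simulate_crosses(sc), list(loc1 = "loc1", loc2 = "loc2"))
}

# minimal seed table built directly (one element named "el")
toy_seed_table <- function(raw, line = "L1", env = "E1", rep = "r1",
                           run = "run1", weight = 100) {
  n <- length(raw)
  structure(data.frame(
    line_id = rep_len(line, n), env_id = rep_len(env, n),
    rep_id = rep_len(rep, n), run_id = rep_len(run, n),
    weight_mg = rep_len(weight, n), raw_el = raw,
    stringsAsFactors = FALSE),
    class = c("ionqtl_seeds", "data.frame"))
}

# independent single-marker LOD oracle: direct least squares on the
# printed values, no shared code with the scan engine
lod_oracle <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  (length(y) / 2) * log10(rss0 / rss1)
}
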