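make_env <- function(id, n, reps = 1)
  list(env_id = id, line_subset_size = n, n_reps = reps)

test_that("environment trait tables follow the additive model", {
  map <- make_map(2, 11, 100)
  geno <- simulate_ril_genotypes(map, 200, seed = 3)

  # no QTL, no environment offsets: mean ~ mu
  sc0 <- sim_scenario(200, map, list(make_env("E1", 200)), traits = "t",
                      trait_means = 5, residual_sd = 1, rng_seed = 4)
  tab <- simulate_env_traits(geno, sc0)$E1
  expect_lt(abs(mean(tab$t) - 5), 3 / sqrt(200))

  # constant effect, near-zero noise: env line means differ only by E_e
  sc1 <- sim_scenario(200, map,
                      list(make_env("E1", 200), make_env("E2", 200)),
                      traits = "t",
                      qtl_effects = list(list(trait = "t", chr = 1,
                                              pos_cM = 50, effect = 1)),
                      trait_means = 0,
                      env_main_effects = c(E1 = 0, E2 = 2),
                      residual_sd = 1e-6, rng_seed = 5)
  et <- simulate_env_traits(geno, sc1)
  d <- et$E2$t[match(et$E1$line_id, et$E2$line_id)] - et$E1$t
  expect_equal(d, rep(2, 200), tolerance = 1e-4)

  # opposite per-environment effects cancel when pooled
  sc2 <- sim_scenario(200, map,
                      list(make_env("E1", 200), make_env("E2", 200)),
                      traits = "t",
                      qtl_effects = list(list(
                        trait = "t", chr = 1, pos_cM = 50,
                        effect = c(E1 = 1, E2 = -1))),
                      trait_means = 0, residual_sd = 0.3, rng_seed = 6)
  et2 <- simulate_env_traits(geno, sc2)
  qmk <- map$marker[6]  # 50 cM on chr 1
  s <- 0.5 - geno[, qmk]
  eff <- function(tab) coef(lm(tab$t ~ s[match(tab$line_id,
                                               rownames(geno))]))[2]
  e1 <- eff(et2$E1); e2 <- eff(et2$E2)
  expect_lt(abs(e1 - 1), 0.2)
  expect_lt(abs(e2 + 1), 0.2)
  pooled <- rbind(et2$E1, et2$E2)
  expect_lt(abs(eff(pooled)), 0.15)
})

test_that("line subsets are respected and output is seed-reproducible", {
  map <- make_map(1, 5, 50)
  geno <- simulate_ril_genotypes(map, 50, seed = 2)
  sc <- sim_scenario(50, map, list(make_env("E1", 20, reps = 2)),
                     traits = "t", rng_seed = 9)
  a <- simulate_env_traits(geno, sc)
  b <- simulate_env_traits(geno, sc)
  expect_identical(a, b)
  expect_equal(length(unique(a$E1$line_id)), 20)
  expect_equal(nrow(a$E1), 40)  # 20 lines x 2 replicate rows
  expect_true(all(a$E1$line_id %in% rownames(geno)))
  # replicate rows get independent residuals
  r1 <- a$E1$t[a$E1$rep_id == "r1"]
  r2 <- a$E1$t[a$E1$rep_id == "r2"]
  expect_false(isTRUE(all.equal(r1, r2)))
})

test_that("seed measurements reduce to weight x trait without artifacts", {
  map <- make_map(1, 4, 60)
  geno <- simulate_ril_genotypes(map, 30, seed = 8)
  sc <- sim_scenario(30, map, list(make_env("E1", 30)), traits = "t",
                     trait_means = 5, residual_sd = 0.5,
                     weight_model = list(mean_mg = 100, sd_mg = 20,
                                         contamination = 0),
                     run_batches = list(n = 1, offsets = 0, block_size = 96),
                     measurement_sd = 0, seeds_per_rep = 2, rng_seed = 10)
  et <- simulate_env_traits(geno, sc)
  seeds <- simulate_seed_measurements(et, sc)
  key <- paste(et$E1$line_id, et$E1$rep_id)
  truth <- et$E1$t[match(paste(seeds$line_id, seeds$rep_id), key)]
  expect_equal(seeds$raw_t, seeds$weight_mg * truth, tolerance = 1e-12)
  expect_true(all(seeds$weight_mg > 0))
})

test_that("run batches are assigned round-robin with their offsets", {
  map <- make_map(1, 4, 60)
  geno <- simulate_ril_genotypes(map, 60, seed = 12)
  sc <- sim_scenario(60, map, list(make_env("E1", 60)), traits = "t",
                     trait_means = 3, residual_sd = 1e-9,
                     weight_model = list(mean_mg = 100, sd_mg = 0,
                                         contamination = 0),
                     run_batches = list(n = 2, offsets = c(0, 5),
                                        block_size = 10),
                     measurement_sd = 0.1, seeds_per_rep = 2, rng_seed = 13)
  seeds <- simulate_seed_measurements(simulate_env_traits(geno, sc), sc)
  expect_setequal(unique(seeds$run_id), c("run1", "run2"))
  # blocks of 10 consecutive seeds alternate runs
  expect_equal(seeds$run_id[1:20], rep(c("run1", "run2"), each = 10))
  dmean <- mean(seeds$raw_t[seeds$run_id == "run2"]) -
    mean(seeds$raw_t[seeds$run_id == "run1"])
  expect_lt(abs(dmean - 5), 0.1)
})

test_that("the default scenario reproduces the study design structure", {
  sc <- default_scenario(markers_per_chr = 12)
  expect_equal(sc$n_lines, 233L)
  expect_length(sc$environments, 10)
  sizes <- vapply(sc$environments, `[[`, 0, "line_subset_size")
  expect_equal(range(sizes), c(82, 233))
  expect_length(sc$traits, 20)
  crs <- simulate_crosses(sc)
  expect_length(crs, 10)
  expect_equal(nrow(crs$NY05$traits), 233)
  expect_equal(nrow(crs$NY06$traits), 82)
  # the planted large-effect Mo locus dominates a chromosome-1 scan
  s <- marker_lod_scan(crs$NY05, "Mo")
  expect_equal(s$chr[which.max(s$lod)], 1)
})

test_that("injected analytical outliers are recoverable by the MAD rule", {
  map <- make_map(1, 4, 60)
  geno <- simulate_ril_genotypes(map, 100, seed = 20)
  base <- list(n_lines = 100, map = map,
               environments = list(make_env("E1", 100)),
               traits = "t", trait_means = 10, residual_sd = 0.5,
               weight_model = list(mean_mg = 100, sd_mg = 10,
                                   contamination = 0),
               measurement_sd = 1, seeds_per_rep = 10, rng_seed = 21)
  sc0 <- do.call(sim_scenario, c(base, list(outlier_rate = 0)))
  sc1 <- do.call(sim_scenario, c(base, list(outlier_rate = 0.02)))
  et <- simulate_env_traits(geno, sc0)
  clean <- simulate_seed_measurements(et, sc0)
  dirty <- simulate_seed_measurements(et, sc1)
  injected <- which(clean$raw_t != dirty$raw_t)
  expect_gt(length(injected), 10)          # ~20 expected of 1000 seeds
  expect_lt(length(injected), 40)
  flagged <- which(flag_outliers_mad(dirty)$flag_t)
  expect_gte(mean(injected %in% flagged), 0.95)
})
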