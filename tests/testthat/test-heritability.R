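# independent oracle: sequential two-way ANOVA components computed from
# explicit sums of squares on a balanced table
balanced_h2_oracle <- function(df) {
  n_l <- length(unique(df$line_id)); n_e <- length(unique(df$env_id))
  gm <- mean(df$value)
  lm_ <- tapply(df$value, df$line_id, mean)
  em_ <- tapply(df$value, df$env_id, mean)
  ss_line <- n_e * sum((lm_ - gm)^2)
  ss_env <- n_l * sum((em_ - gm)^2)
  ss_tot <- sum((df$value - gm)^2)
  ss_res <- ss_tot - ss_line - ss_env
  ms_line <- ss_line / (n_l - 1); ms_env <- ss_env / (n_e - 1)
  ms_res <- ss_res / ((n_l - 1) * (n_e - 1))
  vg <- max(0, (ms_line - ms_res) / n_e)
  ve <- max(0, (ms_env - ms_res) / n_l)
  vg / (vg + ve + ms_res)
}

test_that("across-environment H2 is 1 with pure line effects", {
  df <- expand.grid(line_id = paste0("L", 1:5), env_id = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  df$value <- rep(1:5, 3)  # line effects only, equal env offsets, no noise
  h <- h2_across_env(df, "value")
  expect_equal(h$H2, 1)
  expect_equal(h$var_env, 0)
  expect_equal(h$var_resid, 0)
})

test_that("across-environment H2 matches the sequential-ANOVA oracle when balanced", {
  set.seed(41)
  df <- expand.grid(line_id = paste0("L", 1:3), env_id = c("A", "B"),
                    stringsAsFactors = FALSE)
  df$value <- c(1.0, 2.5, 4.0, 2.0, 3.1, 5.2)
  h <- h2_across_env(df, "value")
  expect_equal(h$H2, balanced_h2_oracle(df), tolerance = 1e-10)
})

test_that("across-environment H2 recovers simulated variance fractions", {
  # VG : VE : Vres = 1 : 1 : 2 -> H2 = 0.25 (quick version; the full
  # 20-replicate check lives in the acceptance suite)
  h2s <- vapply(1:6, function(s) {
    set.seed(100 + s)
    lines <- paste0("L", 1:120)
    envs <- paste0("E", 1:4)
    g <- rnorm(120, 0, 1); e <- rnorm(4, 0, 1)
    df <- expand.grid(line_id = lines, env_id = envs,
                      stringsAsFactors = FALSE)
    df$value <- g[match(df$line_id, lines)] + e[match(df$env_id, envs)] +
      rnorm(nrow(df), 0, sqrt(2))
    h2_across_env(df, "value")$H2
  }, 0)
  expect_lt(abs(mean(h2s) - 0.25), 0.1)
})

test_that("across-environment H2 validates its design", {
  df <- data.frame(line_id = c("L1", "L2"), env_id = "A", value = 1:2)
  expect_error(h2_across_env(df, "value"), ">= 2 environments")
  df2 <- data.frame(line_id = c("L1", "L2", "L3", "L4"),
                    env_id = c("A", "A", "B", "B"), value = 1:4)
  expect_error(h2_across_env(df2, "value"), "not separable")
})

test_that("within-environment H2 partitions replicate variance", {
  # identical replicates within line, lines differ: H2 = 1
  df <- data.frame(line_id = rep(c("L1", "L2", "L3"), each = 2),
                   value = rep(c(1, 3, 5), each = 2))
  expect_equal(h2_within_env(df, "value")$H2, 1)

  # all values identical: undefined, reported missing
  df2 <- df; df2$value <- 2
  expect_true(is.na(suppressMessages(h2_within_env(df2, "value"))$H2))

  # toy with one perturbed replicate matches the hand one-way oracle
  df3 <- data.frame(line_id = rep(c("L1", "L2", "L3"), each = 2),
                    value = c(1, 2, 3, 3, 5, 5))
  h <- h2_within_env(df3, "value")
  means <- tapply(df3$value, df3$line_id, mean)
  ss_line <- 2 * sum((means - mean(df3$value))^2)
  ss_res <- sum((df3$value - means[df3$line_id])^2)
  ms_line <- ss_line / 2; ms_res <- ss_res / 3
  vg <- (ms_line - ms_res) / 2
  expect_equal(h$H2, vg / (vg + ms_res), tolerance = 1e-10)

  # singleton lines are removed before the ANOVA
  df4 <- rbind(df3, data.frame(line_id = "L9", value = 100))
  expect_equal(h2_within_env(df4, "value")$H2, h$H2)
  expect_error(h2_within_env(data.frame(line_id = c("L1", "L2"),
                                        value = 1:2), "value"),
               "fewer than 2 lines")
})

test_that("estimated H2 decreases as residual noise grows", {
  mk <- function(res_sd, seed) {
    sc <- sim_scenario(
      80, make_map(1, 4, 60),
      environments = list(
        list(env_id = "A", line_subset_size = 80, n_reps = 1),
        list(env_id = "B", line_subset_size = 80, n_reps = 1),
        list(env_id = "C", line_subset_size = 80, n_reps = 1)),
      traits = "t",
      qtl_effects = list(list(trait = "t", chr = 1, pos_cM = 20,
                              effect = 2)),
      trait_means = 0, residual_sd = res_sd, rng_seed = seed)
    crs <- simulate_crosses(sc)
    h2_across_env(lapply(crs, `[[`, "traits"), "t")$H2
  }
  lo <- vapply(1:10, function(s) mk(0.5, s), 0)
  hi <- vapply(1:10, function(s) mk(2.5, s), 0)
  expect_gt(mean(lo), mean(hi))
})

test_that("effect reversal gives high within- but near-zero across-environment H2", {
  map <- make_map(1, 4, 60)
  geno <- simulate_ril_genotypes(map, 150, seed = 51)
  sc <- sim_scenario(
    150, map,
    environments = list(
      list(env_id = "A", line_subset_size = 150, n_reps = 3),
      list(env_id = "B", line_subset_size = 150, n_reps = 3)),
    traits = "t",
    qtl_effects = list(list(trait = "t", chr = 1, pos_cM = 20,
                            effect = c(A = 3, B = -3))),
    trait_means = 0, residual_sd = 0.5, rng_seed = 52)
  et <- simulate_env_traits(geno, sc)
  within <- vapply(et, function(tab)
    h2_within_env(data.frame(line_id = tab$line_id, value = tab$t),
                  "value")$H2, 0)
  expect_true(all(within > 0.6))
  lm_a <- aggregate(t ~ line_id, et$A, mean)
  lm_b <- aggregate(t ~ line_id, et$B, mean)
  df <- rbind(data.frame(line_id = lm_a$line_id, env_id = "A",
                         value = lm_a$t),
              data.frame(line_id = lm_b$line_id, env_id = "B",
                         value = lm_b$t))
  expect_lt(h2_across_env(df, "value")$H2, 0.15)
})
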