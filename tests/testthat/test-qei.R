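test_that("stacking pools years into locations and validates the design", {
  map <- make_map(1, 4, 60)
  geno <- simulate_ril_genotypes(map, 40, seed = 81)
  mk <- function(lines, env) {
    tr <- data.frame(y = rnorm(length(lines)),
                     row.names = rownames(geno)[lines])
    make_cross(map, geno, tr, env_id = env)
  }
  set.seed(81)
  crosses <- list(FL05 = mk(1:20, "FL05"), FL06 = mk(5:30, "FL06"),
                  IN09 = mk(1:40, "IN09"), IN10 = mk(10:25, "IN10"),
                  NY05 = mk(1:15, "NY05"), NY12 = mk(20:40, "NY12"))
  st <- stack_locations(crosses, list(FL = c("FL05", "FL06"),
                                      IN = c("IN09", "IN10"),
                                      NY = c("NY05", "NY12")))
  expect_setequal(unique(st$obs$location), c("FL", "IN", "NY"))
  expect_equal(nrow(st$obs), 20 + 26 + 40 + 16 + 15 + 21)

  # disjoint lines simply concatenate
  st2 <- stack_locations(list(A = mk(1:10, "A"), B = mk(11:30, "B")),
                         list(a = "A", b = "B"))
  expect_equal(nrow(st2$obs), 30)

  expect_error(stack_locations(list(A = mk(1:10, "A")), list(a = "A")),
               ">= 2 locations")
})

test_that("the interaction LOD is exactly zero under a constant genetic effect", {
  map <- make_map(1, 5, 40)
  geno <- simulate_ril_genotypes(map, 60, seed = 82)
  mk <- function(lines, env, off) {
    g <- geno[lines, 3]
    tr <- data.frame(y = (0.5 - g) * 2 + off,
                     row.names = rownames(geno)[lines])
    make_cross(map, geno, tr, env_id = env)
  }
  st <- stack_locations(list(A = mk(1:30, "A", 0), B = mk(31:60, "B", 5)),
                        list(a = "A", b = "B"))
  sc <- qei_delta_lod(st, "y")
  # at the generating marker the interaction coefficients vanish exactly
  expect_lt(abs(sc$delta_lod[3]), 1e-9)
  expect_gt(sc$lod_add[3], 1)  # the additive signal itself is there

  # with the map reduced to the causal marker, every informative marker
  # of the stacked analysis has zero interaction LOD
  map1 <- data.frame(marker = map$marker[3], chr = 1L, pos = 0)
  mk1 <- function(lines, env, off) {
    g <- geno[lines, 3, drop = FALSE]
    colnames(g) <- map1$marker
    make_cross(map1, g,
               data.frame(y = (0.5 - g[, 1]) * 2 + off,
                          row.names = rownames(geno)[lines]),
               env_id = env)
  }
  st1 <- stack_locations(list(A = mk1(1:30, "A", 0), B = mk1(31:60, "B", 5)),
                         list(a = "A", b = "B"))
  expect_lt(max(abs(qei_delta_lod(st1, "y")$delta_lod), na.rm = TRUE), 1e-9)
})

test_that("delta LOD is nonnegative and matches a per-marker lm oracle", {
  st <- two_loc_stack(seed = 83, eff1 = 1, eff2 = -0.5, n_per_loc = 60,
                      map = make_map(2, 6, 50), qtl_chr = 2, qtl_pos = 25)
  sc <- qei_delta_lod(st, "y")
  expect_true(all(sc$delta_lod >= -1e-9, na.rm = TRUE))
  y <- st$obs$y
  loc <- factor(st$obs$location)
  G <- st$geno[match(st$obs$line_id, rownames(st$geno)), ]
  n <- length(y)
  for (j in c(1, 5, 9)) {
    g <- G[, j]
    r_null <- sum(resid(lm(y ~ loc))^2)
    r_full <- sum(resid(lm(y ~ g * loc))^2)
    r_add <- sum(resid(lm(y ~ g + loc))^2)
    expect_equal(sc$lod_full[j], (n / 2) * log10(r_null / r_full),
                 tolerance = 1e-9)
    expect_equal(sc$lod_add[j], (n / 2) * log10(r_null / r_add),
                 tolerance = 1e-9)
  }
})

test_that("markers lacking both genotype classes in a location are skipped", {
  map <- make_map(1, 3, 20)
  geno <- cbind(m1 = c(rep(0, 10), rep(1, 10)),
                m2 = c(rep(0, 10), rbinom(10, 1, 0.5)),
                m3 = rbinom(20, 1, 0.5))
  colnames(geno) <- map$marker
  rownames(geno) <- paste0("L", 1:20)
  set.seed(84)
  mk <- function(lines, env)
    make_cross(map, geno, data.frame(y = rnorm(length(lines)),
                                     row.names = rownames(geno)[lines]),
               env_id = env)
  st <- stack_locations(list(A = mk(1:10, "A"), B = mk(11:20, "B")),
                        list(a = "A", b = "B"))
  sc <- suppressMessages(qei_delta_lod(st, "y"))
  expect_true(is.na(sc$delta_lod[1]))  # monomorphic within each location
})

test_that("QEI permutation thresholds are reproducible and positive", {
  st <- two_loc_stack(seed = 85, eff1 = 0.5, eff2 = 0.5, n_per_loc = 50,
                      map = make_map(2, 6, 50), qtl_chr = 2, qtl_pos = 25)
  t1 <- qei_permutation_threshold(st, "y", n_perm = 60, alpha = 0.05,
                                  seed = 3)
  t2 <- qei_permutation_threshold(st, "y", n_perm = 60, alpha = 0.05,
                                  seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_gt(as.numeric(t1), 0)
  ml <- attr(t1, "max_lods")
  expect_length(ml, 60)
  expect_gte(quantile(ml, 0.99, names = FALSE),
             quantile(ml, 0.95, names = FALSE))
})

test_that("opposite-sign location effects light up both QEI methods", {
  st <- two_loc_stack(seed = 86, eff1 = 1, eff2 = -1)
  res <- qei_covariate_test(st, "y", n_perm = 100, alpha = 0.05, seed = 4)
  expect_gt(nrow(res$significant), 0)
  expect_true(any(res$significant$chr == 3 &
                    abs(res$significant$pos - 50) <= 10))

  # recast the two locations as two years of one location
  sc <- sim_scenario(
    200, test_map(),
    environments = list(
      list(env_id = "Y1", line_subset_size = 200, n_reps = 1),
      list(env_id = "Y2", line_subset_size = 200, n_reps = 1)),
    traits = "y",
    qtl_effects = list(list(trait = "y", chr = 3, pos_cM = 50,
                            effect = c(Y1 = 1, Y2 = -1))),
    trait_means = 0, residual_sd = 1, rng_seed = 87)
  crs <- simulate_crosses(sc)
  dm <- map_difference_qtl(trait_differences(crs$Y1, crs$Y2), "y",
                           n_perm = 100, alpha = 0.05, seed = 5)
  expect_true(any(dm$loci$chr == 3 & abs(dm$loci$pos - 50) <= 10))
})

test_that("trait differences keep common lines and anticommute", {
  map <- make_map(1, 3, 20)
  geno <- simulate_ril_genotypes(map, 6, seed = 88)
  mk <- function(lines, vals, env)
    make_cross(map, geno, data.frame(y = vals,
                                     row.names = rownames(geno)[lines]),
               env_id = env)
  a <- mk(1:5, c(1, 2, 3, 4, 5), "A")
  b <- mk(2:6, c(10, 20, 30, 40, 50), "B")
  d <- trait_differences(a, b)
  expect_setequal(rownames(d$traits), rownames(geno)[2:5])
  expect_equal(d$traits["L002", "y"], 2 - 10)
  expect_equal(d$env_id, "A-B")

  dba <- trait_differences(b, a)
  expect_equal(as.matrix(d$traits),
               -as.matrix(dba$traits)[rownames(d$traits), , drop = FALSE])

  # identical inputs give all-zero differences and an empty model
  dz <- trait_differences(a, a)
  expect_true(all(dz$traits$y == 0))
  m0 <- map_difference_qtl(dz, "y", n_perm = 20, alpha = 0.05, seed = 1)
  expect_equal(nrow(m0$loci), 0)

  expect_error(trait_differences(mk(1:3, 1:3, "A"), mk(4:6, 1:3, "B")),
               "common lines")
})
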