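#' Simulate per-environment line trait values
#'
#' For each environment `e` and line `i` the trait value is
#' `mu + sum_k a_ke * s_ik + E_e + eps`, where `s_ik` is +1/2 for allele A
#' and -1/2 for allele B at the marker nearest the QTL position (ties to the
#' lower position), `E_e` is the environment main effect, and
#' `eps ~ N(0, residual_sd^2)`.  Only the environment's designated line
#' subset receives values; replicate rows get independent residuals.
#'
#' Each environment draws from its own sub-stream derived from the scenario
#' seed, so the same scenario always yields bit-identical tables.
#'
#' @param geno 0/1 genotype matrix from [simulate_ril_genotypes()].
#' @param scenario an `ionqtl_scenario`.
#' @return Named list (by `env_id`) of data frames with columns `line_id`,
#'   `rep_id`, then one column per trait; class `ionqtl_envtraits`.
#' @export
simulate_env_traits <- function(geno, scenario) {
  stopifnot(inherits(scenario, "ionqtl_scenario"))
  map <- scenario$map
  lines <- rownames(geno)
  if (length(lines) != scenario$n_lines)
    stop_arg("genotype matrix does not match scenario n_lines")
  traits <- scenario$traits
  # per-trait QTL contributions at the nearest marker
  qtl_idx <- lapply(scenario$qtl_effects, function(q)
    nearest_marker(map, q$chr, q$pos_cM))
  out <- vector("list", length(scenario$environments))
  names(out) <- vapply(scenario$environments, `[[`, "", "env_id")
  for (k in seq_along(scenario$environments)) {
    e <- scenario$environments[[k]]
    n_reps <- e$n_reps %||% 1
    withr::with_seed(sub_seed(scenario$rng_seed, k), {
      sub <- sort(sample(scenario$n_lines, e$line_subset_size))
      ids <- lines[sub]
      base <- matrix(rep(scenario$trait_means[traits], each = length(sub)),
                     length(sub), length(traits),
                     dimnames = list(ids, traits))
      for (j in seq_along(scenario$qtl_effects)) {
        q <- scenario$qtl_effects[[j]]
        a <- q$effect
        a_e <- if (length(a) == 1L && is.null(names(a))) a
               else if (e$env_id %in% names(a)) a[[e$env_id]] else 0
        if (a_e != 0) {
          s <- 0.5 - geno[sub, qtl_idx[[j]]]
          s[is.na(s)] <- 0
          base[, q$trait] <- base[, q$trait] + a_e * s
        }
      }
      off <- env_offset(scenario$env_main_effects, e$env_id, traits)
      base <- sweep(base, 2, off, `+`)
      reps <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
        vals <- base + matrix(stats::rnorm(length(base), 0,
                                           scenario$residual_sd),
                              nrow(base), ncol(base))
        data.frame(line_id = ids, rep_id = sprintf("r%d", r), vals,
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
      }))
      out[[k]] <- reps
    })
  }
  structure(out, class = "ionqtl_envtraits")
}

env_offset <- function(em, env_id, traits) {
  if (is.null(em)) return(stats::setNames(rep(0, length(traits)), traits))
  if (is.list(em)) {
    off <- vapply(traits, function(tr) {
      v <- em[[tr]]
      if (is.null(v)) 0 else if (env_id %in% names(v)) v[[env_id]] else 0
    }, 0)
    return(off)
  }
  val <- if (env_id %in% names(em)) em[[env_id]] else 0
  stats::setNames(rep(val, length(traits)), traits)
}

#' Simulate a single-seed measurement table
#'
#' Expands line-level trait values into per-seed raw measurements with the
#' artifacts the normalization stage must undo: seed weight is normal
#' truncated at zero; the raw (non-weight-normalized) concentration is
#' `weight x trait value + contamination + run offset + noise`; analytical
#' runs are assigned round-robin in blocks of consecutive seeds; and a
#' fraction `outlier_rate` of (seed, element) values is displaced by at
#' least `outlier_mads` group MADs so the MAD flagging rule can recover
#' them.
#'
#' @param env_traits output of [simulate_env_traits()].
#' @param scenario the same `ionqtl_scenario`.
#' @return Data frame (class `ionqtl_seeds`) with columns `line_id`,
#'   `env_id`, `rep_id`, `run_id`, `weight_mg`, and one `raw_<element>`
#'   column per trait.
#' @export
simulate_seed_measurements <- function(env_traits, scenario) {
  stopifnot(inherits(scenario, "ionqtl_scenario"))
  traits <- scenario$traits
  wm <- scenario$weight_model
  contam <- rep(wm$contamination %||% 0, length.out = length(traits))
  parts <- vector("list", length(env_traits))
  for (k in seq_along(env_traits)) {
    env_id <- names(env_traits)[k]
    tab <- env_traits[[k]]
    withr::with_seed(sub_seed(scenario$rng_seed, 500 + k), {
      n_seed <- nrow(tab) * scenario$seeds_per_rep
      idx <- rep(seq_len(nrow(tab)), each = scenario$seeds_per_rep)
      w <- stats::rnorm(n_seed, wm$mean_mg, wm$sd_mg)
      while (any(bad <- w <= 0))
        w[bad] <- stats::rnorm(sum(bad), wm$mean_mg, wm$sd_mg)
      raw <- as.matrix(tab[idx, traits, drop = FALSE]) * w
      raw <- sweep(raw, 2, contam, `+`)
      if (scenario$measurement_sd > 0)
        raw <- raw + matrix(stats::rnorm(length(raw), 0,
                                         scenario$measurement_sd),
                            nrow(raw), ncol(raw))
      parts[[k]] <- data.frame(
        line_id = tab$line_id[idx], env_id = env_id, rep_id = tab$rep_id[idx],
        stats::setNames(as.data.frame(raw, optional = TRUE),
                        paste0("raw_", traits)),
        weight_mg = w, row.names = NULL, check.names = FALSE,
        stringsAsFactors = FALSE)
    })
  }
  seeds <- do.call(rbind, parts)
  # analytical runs: round-robin over blocks of consecutive seeds
  rb <- scenario$run_batches
  n_run <- rb$n %||% 1
  block <- (seq_len(nrow(seeds)) - 1) %/% (rb$block_size %||% 96)
  run <- (block %% n_run) + 1
  seeds$run_id <- sprintf("run%d", run)
  offsets <- rep(rb$offsets %||% 0, length.out = n_run)
  rawcols <- paste0("raw_", traits)
  seeds[rawcols] <- seeds[rawcols] + offsets[run]
  # heavy-tailed analytical outliers, sized relative to the group MAD
  if (scenario$outlier_rate > 0) {
    seeds <- withr::with_seed(sub_seed(scenario$rng_seed, 900), {
      grp <- interaction(seeds$line_id, seeds$env_id, drop = TRUE)
      for (tr in rawcols) {
        x <- seeds[[tr]]
        gm <- tapply(x, grp, function(v) stats::mad(v, constant = 1))
        hit <- which(stats::runif(length(x)) < scenario$outlier_rate)
        if (length(hit)) {
          sc <- pmax(gm[as.character(grp[hit])], scenario$measurement_sd,
                     1e-8)
          x[hit] <- x[hit] + sample(c(-1, 1), length(hit), replace = TRUE) *
            scenario$outlier_mads * sc
          seeds[[tr]] <- x
        }
      }
      seeds
    })
  }
  cols <- c("line_id", "env_id", "rep_id", "run_id", "weight_mg", rawcols)
  seeds <- seeds[, cols]
  class(seeds) <- c("ionqtl_seeds", "data.frame")
  seeds
}
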