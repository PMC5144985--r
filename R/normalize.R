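#' Flag grouped analytical outliers by MAD score
#'
#' Within each (line, environment) group and for each element
#' independently, computes `score = |x - median(group)| / MAD(group)` on
#' the raw values and flags values whose score strictly exceeds
#' `threshold`.  Flagged values are treated as missing by every downstream
#' step.  Groups with `MAD = 0` or fewer than 3 seeds are left unflagged.
#' Flagging is a single pass: scores are computed once on the input, not
#' iterated to a fixed point.
#'
#' By default the MAD is the raw median absolute deviation (no
#' 1.4826 normal-consistency constant); set `consistency = TRUE` to scale
#' the MAD so the score is comparable to a z-score under normality.
#'
#' @param seeds a seed table (see [simulate_seed_measurements()] or
#'   [read_seed_csv()]).
#' @param threshold positive score cutoff; the conventional cutoff for
#'   single-seed ionomics panels is 6.2.
#' @param consistency use `1.4826 * MAD` as the scale (default `FALSE`).
#' @return The seed table with one logical `flag_<element>` column per
#'   element.
#' @export
flag_outliers_mad <- function(seeds, threshold = 6.2, consistency = FALSE) {
  check_scalar(threshold, "threshold", positive = TRUE)
  rawcols <- grep("^raw_", names(seeds), value = TRUE)
  if (nrow(seeds) == 0) {
    for (rc in rawcols) seeds[[sub("^raw_", "flag_", rc)]] <- logical(0)
    return(seeds)
  }
  grp <- interaction(seeds$line_id, seeds$env_id, drop = TRUE)
  const <- if (consistency) 1.4826 else 1
  for (rc in rawcols) {
    x <- seeds[[rc]]
    med <- stats::ave(x, grp, FUN = function(v) stats::median(v, na.rm = TRUE))
    madv <- stats::ave(x, grp, FUN = function(v)
      stats::mad(v, constant = const, na.rm = TRUE))
    n <- stats::ave(!is.na(x), grp, FUN = sum)
    score <- abs(x - med) / madv
    flag <- !is.na(x) & n >= 3 & is.finite(score) & madv > 0 &
      score > threshold
    seeds[[sub("^raw_", "flag_", rc)]] <- flag
  }
  seeds
}

#' Estimated concentration difference from the mean (ECDM)
#'
#' Normalizes raw single-seed concentrations for seed-size and run-batch
#' artifacts by taking residuals of the per-element least-squares model
#' `raw ~ intercept + weight + run`, with the analytical run as a
#' categorical factor.  A seed whose concentration is exactly what its
#' weight predicts gets an ECDM of zero; positive/negative ECDMs are
#' estimated concentration differences from the population mean.  Flagged
#' seeds are excluded from the fit and get missing ECDM.
#'
#' If a fit stratum has a single run level the run factor is dropped; if
#' weight is constant the weight term is dropped (both logged).
#'
#' @param seeds a seed table, normally after [flag_outliers_mad()].
#' @param per_env fit separately within each environment (default), or
#'   pooled across the whole table (`FALSE`).
#' @return The seed table with one `ecdm_<element>` column per element.
#' @export
compute_ecdm <- function(seeds, per_env = TRUE) {
  rawcols <- grep("^raw_", names(seeds), value = TRUE)
  strata <- if (per_env) split(seq_len(nrow(seeds)), seeds$env_id)
            else list(all = seq_len(nrow(seeds)))
  for (rc in rawcols) {
    el <- sub("^raw_", "", rc)
    fc <- paste0("flag_", el)
    flagged <- if (fc %in% names(seeds)) seeds[[fc]] else
      rep(FALSE, nrow(seeds))
    res <- rep(NA_real_, nrow(seeds))
    for (sn in names(strata)) {
      idx <- strata[[sn]]
      use <- idx[!flagged[idx] & !is.na(seeds[[rc]][idx]) &
                   !is.na(seeds$weight_mg[idx])]
      if (length(use) < 2) next
      y <- seeds[[rc]][use]
      dat <- data.frame(y = y, w = seeds$weight_mg[use],
                        run = factor(seeds$run_id[use]))
      terms <- character(0)
      if (length(unique(dat$w)) >= 2) terms <- c(terms, "w")
      else iq_log("drop-term", "constant weight; weight term dropped (",
                  el, ", ", sn, ")")
      if (nlevels(dat$run) >= 2) terms <- c(terms, "run")
      else iq_log("drop-term", "single run level; run factor dropped (",
                  el, ", ", sn, ")")
      form <- stats::reformulate(if (length(terms)) terms else "1",
                                 response = "y")
      res[use] <- stats::residuals(stats::lm(form, data = dat))
    }
    seeds[[paste0("ecdm_", el)]] <- res
  }
  seeds
}

#' Per-environment line averages of normalized traits
#'
#' Averages each line's non-flagged, non-missing ECDM values (and seed
#' weights) within an environment, producing the line x trait matrices
#' used for mapping.  A line with no retained seeds for a trait is
#' missing, never zero.
#'
#' @param seeds a seed table after [compute_ecdm()].
#' @return Named list (by environment) of data frames with row names =
#'   line ids and columns `seed_weight` plus one column per element.
#' @seealso [rep_averages()] for replicate-level means used by
#'   within-environment heritability.
#' @export
line_averages <- function(seeds) {
  avg_by(seeds, c("env_id", "line_id"))
}

#' Replicate-row averages of normalized traits
#'
#' Like [line_averages()] but keeps the replicate (pooled-row) structure:
#' one row per (line, replicate) within each environment.  This is the
#' input for within-environment heritability, where a replicate is a
#' pooled row of seeds.
#'
#' @param seeds a seed table after [compute_ecdm()].
#' @return Named list (by environment) of data frames with columns
#'   `line_id`, `rep_id`, `seed_weight`, then one column per element.
#' @export
rep_averages <- function(seeds) {
  avg_by(seeds, c("env_id", "line_id", "rep_id"))
}

avg_by <- function(seeds, keys) {
  eccols <- grep("^ecdm_", names(seeds), value = TRUE)
  if (!length(eccols))
    stop_arg("no ecdm_* columns; run compute_ecdm() first")
  elements <- sub("^ecdm_", "", eccols)
  out <- list()
  for (env in unique(seeds$env_id)) {
    sub <- seeds[seeds$env_id == env, , drop = FALSE]
    key <- interaction(sub[setdiff(keys, "env_id")], drop = TRUE, sep = "\r")
    mean_na <- function(v, k) {
      m <- tapply(v, k, function(x) mean(x, na.rm = TRUE))
      m[is.nan(m)] <- NA_real_
      m
    }
    wt <- mean_na(sub$weight_mg, key)
    mat <- do.call(cbind, lapply(stats::setNames(elements, elements),
                                 function(el)
                                   mean_na(sub[[paste0("ecdm_", el)]], key)))
    df <- data.frame(seed_weight = as.numeric(wt), mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(names(wt), "\r", fixed = TRUE))
    if (length(keys) == 2L) {
      rownames(df) <- parts[, 1]
      df <- df[order(rownames(df)), , drop = FALSE]
    } else {
      df <- data.frame(line_id = parts[, 1], rep_id = parts[, 2], df,
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
      df <- df[order(df$line_id, df$rep_id), , drop = FALSE]
      rownames(df) <- NULL
    }
    out[[env]] <- df
  }
  out
}
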