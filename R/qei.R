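# Vectorized engine for the full-vs-additive location-covariate model
# comparison.  For phenotype columns Y (shared complete rows), genotypes G
# (0/1) and a location factor, computes at every marker the LOD of
#   full:    y ~ genotype + location + genotype:location
#   reduced: y ~ genotype + location
# against the shared null y ~ location, all by least squares, and the
# interaction signal delta LOD = LOD_full - LOD_reduced.  Markers where
# some location lacks both genotype classes are skipped (NA).
.qei_core <- function(Y, G, loc) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y); m <- ncol(G)
  loc <- factor(loc)
  L <- nlevels(loc)
  lod_full <- lod_red <- matrix(NA_real_, m, p)
  na_mark <- which(colSums(is.na(G)) > 0)
  ok <- setdiff(seq_len(m), na_mark)
  if (length(ok)) {
    Gk <- G[, ok, drop = FALSE]
    mk <- length(ok)
    nl <- numeric(L)
    n1 <- matrix(0, mk, L)
    Sl <- matrix(0, L, p); Syyl <- matrix(0, L, p)
    S1l <- vector("list", L)
    for (l in seq_len(L)) {
      idx <- which(loc == levels(loc)[l])
      nl[l] <- length(idx)
      Gl <- Gk[idx, , drop = FALSE]; Yl <- Y[idx, , drop = FALSE]
      S1l[[l]] <- crossprod(Gl, Yl)
      n1[, l] <- colSums(Gl)
      Sl[l, ] <- colSums(Yl)
      Syyl[l, ] <- colSums(Yl * Yl)
    }
    syy_tot <- colSums(Syyl)
    s_tot <- colSums(Sl)
    rss_null <- colSums(Syyl - Sl^2 / nl)           # p-vector
    informative <- rowSums(n1 > 0 & n1 < rep(nl, each = mk)) == L
    # full (cell-means) model
    rss_full <- matrix(0, mk, p)
    for (l in seq_len(L)) {
      S1 <- S1l[[l]]
      S0 <- matrix(Sl[l, ], mk, p, byrow = TRUE) - S1
      n1l <- pmax(n1[, l], 1); n0l <- pmax(nl[l] - n1[, l], 1)
      rss_full <- rss_full + matrix(Syyl[l, ], mk, p, byrow = TRUE) -
        S1^2 / n1l - S0^2 / n0l
    }
    # reduced (additive) model via per-marker normal equations
    sum_g <- rowSums(n1)
    sum_gy <- Reduce(`+`, S1l)
    rss_red <- matrix(NA_real_, mk, p)
    for (j in which(informative)) {
      A <- matrix(0, L + 1, L + 1)
      A[1, 1] <- n
      A[1, 2] <- A[2, 1] <- A[2, 2] <- sum_g[j]
      if (L > 1) for (l in 2:L) {
        A[1, l + 1] <- A[l + 1, 1] <- nl[l]
        A[2, l + 1] <- A[l + 1, 2] <- n1[j, l]
        A[l + 1, l + 1] <- nl[l]
      }
      B <- rbind(s_tot, sum_gy[j, ], Sl[-1, , drop = FALSE])
      bb <- tryCatch(solve(A, B), error = function(e) NULL)
      if (is.null(bb)) next
      rss_red[j, ] <- syy_tot - colSums(bb * B)
    }
    floor_rss <- function(r) pmax(r, 1e-12 *
                                    matrix(rss_null, mk, p, byrow = TRUE))
    lf <- (n / 2) * log10(matrix(rss_null, mk, p, byrow = TRUE) /
                            floor_rss(rss_full))
    lr <- (n / 2) * log10(matrix(rss_null, mk, p, byrow = TRUE) /
                            floor_rss(rss_red))
    lf[!informative, ] <- NA_real_
    lod_full[ok, ] <- lf
    lod_red[ok, ] <- lr
  }
  for (j in na_mark) {
    rows <- which(!is.na(G[, j]))
    g <- G[rows, j]; lj <- droplevels(loc[rows]); Yj <- Y[rows, , drop = FALSE]
    tab <- table(g, lj)
    if (nlevels(lj) < 2 || nrow(tab) < 2 || any(colSums(tab > 0) < 2)) next
    rn <- colSums(qr.resid(qr(stats::model.matrix(~lj)), Yj)^2)
    rf <- colSums(qr.resid(qr(stats::model.matrix(~g * lj)), Yj)^2)
    rr <- colSums(qr.resid(qr(stats::model.matrix(~g + lj)), Yj)^2)
    nj <- length(rows)
    lod_full[j, ] <- (nj / 2) * log10(rn / pmax(rf, 1e-12 * rn))
    lod_red[j, ] <- (nj / 2) * log10(rn / pmax(rr, 1e-12 * rn))
  }
  list(lod_full = lod_full, lod_red = lod_red,
       delta = lod_full - lod_red)
}

#' Stack per-environment crosses by location
#'
#' Combines the data from all years of each location into a single
#' observation table with a location label, for the location-covariate
#' QEI analysis.  Lines grown in multiple years of a location contribute
#' one observation per year with identical genotypes.
#'
#' @param crosses named list of `ionqtl_cross` objects (one per
#'   environment), all sharing one map and genotype set.
#' @param pooling named list mapping each location label to the
#'   environment ids pooled under it, e.g.
#'   `list(FL = c("FL05","FL06"), IN = c("IN09","IN10"), NY = c("NY05","NY12"))`.
#' @return A list of class `ionqtl_stacked` with the map, the genotype
#'   matrix, and an observation table (`line_id`, `env_id`, `location`,
#'   then the traits shared by all pooled crosses).
#' @export
stack_locations <- function(crosses, pooling) {
  if (length(pooling) < 2) stop_arg("need >= 2 locations after pooling")
  envs <- unlist(pooling, use.names = FALSE)
  missing_env <- setdiff(envs, names(crosses))
  if (length(missing_env))
    stop_arg("pooling names unknown crosses: ",
             paste(missing_env, collapse = ", "))
  map <- crosses[[envs[1]]]$map
  geno <- crosses[[envs[1]]]$geno
  for (env in envs[-1]) {         # union of genotyped lines across crosses
    extra <- setdiff(rownames(crosses[[env]]$geno), rownames(geno))
    if (length(extra))
      geno <- rbind(geno, crosses[[env]]$geno[extra, , drop = FALSE])
  }
  shared <- Reduce(intersect, lapply(crosses[envs], function(cr)
    names(cr$traits)))
  parts <- list()
  for (locname in names(pooling)) {
    for (env in pooling[[locname]]) {
      cr <- crosses[[env]]
      if (!identical(cr$map$marker, map$marker))
        stop_arg("crosses do not share one map")
      parts[[length(parts) + 1]] <- data.frame(
        line_id = rownames(cr$traits), env_id = env, location = locname,
        cr$traits[, shared, drop = FALSE], row.names = NULL,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, parts)
  n_per_loc <- table(obs$location)
  if (any(n_per_loc < 2)) stop_arg("every location needs >= 2 lines")
  structure(list(map = map, geno = geno, obs = obs),
            class = "ionqtl_stacked")
}

qei_rows <- function(stacked, trait) {
  if (!trait %in% names(stacked$obs)) stop_arg("trait not found: ", trait)
  y <- stacked$obs[[trait]]
  keep <- !is.na(y)
  list(y = y[keep],
       G = stacked$geno[match(stacked$obs$line_id[keep],
                              rownames(stacked$geno)), , drop = FALSE],
       loc = factor(stacked$obs$location[keep]))
}

#' Per-marker interaction LOD (full vs. additive location covariate)
#'
#' At each marker, fits the full model
#' `y ~ genotype + location + genotype:location` and the reduced model
#' `y ~ genotype + location` and subtracts the reduced-model LOD from the
#' full-model LOD (both against the shared null `y ~ location`), leaving
#' a per-marker LOD score for the genotype-by-location component alone.
#' Markers where some location lacks both genotype classes are skipped
#' (`NA`, logged).
#'
#' @param stacked an `ionqtl_stacked` from [stack_locations()].
#' @param trait trait name.
#' @return Data frame of class `ionqtl_qei_scan` with columns `marker`,
#'   `chr`, `pos`, `lod_full`, `lod_add`, `delta_lod`.
#' @export
qei_delta_lod <- function(stacked, trait) {
  qr_ <- qei_rows(stacked, trait)
  sc <- .qei_core(matrix(qr_$y, ncol = 1), qr_$G, qr_$loc)
  if (anyNA(sc$delta[, 1]))
    iq_log("skipped-marker", sum(is.na(sc$delta[, 1])),
           " marker(s) lacking both genotype classes in some location")
  out <- data.frame(marker = stacked$map$marker, chr = stacked$map$chr,
                    pos = stacked$map$pos, lod_full = sc$lod_full[, 1],
                    lod_add = sc$lod_red[, 1], delta_lod = sc$delta[, 1],
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  class(out) <- c("ionqtl_qei_scan", "data.frame")
  out
}

#' Permutation threshold for the interaction LOD
#'
#' Repeats the three-step procedure (fit the full model, fit the additive
#' model, subtract LOD scores) on permuted data and takes the `1 - alpha`
#' quantile of the genome-wide maximum delta LOD.  Permutations shuffle
#' the line-to-genotype pairing within each location stratum, which
#' preserves location main effects and each location's trait marginals
#' while destroying any genotype effect; all permutations run in one
#' vectorized pass.
#'
#' @param stacked an `ionqtl_stacked`.
#' @param trait trait name.
#' @param n_perm permutations (study convention: 1000).
#' @param alpha genome-wide level (study convention: 0.05).
#' @param seed integer seed.
#' @return Threshold with attributes `max_lods`, `alpha`, `n_perm`,
#'   `seed`.
#' @export
qei_permutation_threshold <- function(stacked, trait, n_perm = 1000,
                                      alpha = 0.05, seed = 1L) {
  check_scalar(n_perm, "n_perm", positive = TRUE, integerish = TRUE)
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  qr_ <- qei_rows(stacked, trait)
  strata <- split(seq_along(qr_$y), qr_$loc)
  Y <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      yp <- qr_$y
      for (s in strata) yp[s] <- yp[sample(s)]
      yp
    }, qr_$y)
  })
  sc <- .qei_core(Y, qr_$G, qr_$loc)
  maxs <- apply(sc$delta, 2, max, na.rm = TRUE)
  thr <- stats::quantile(maxs, 1 - alpha, names = FALSE)
  attr(thr, "max_lods") <- maxs
  attr(thr, "alpha") <- alpha
  attr(thr, "n_perm") <- n_perm
  attr(thr, "seed") <- as.integer(seed)
  thr
}

#' Location-covariate QEI test for one trait
#'
#' Runs [qei_delta_lod()] and [qei_permutation_threshold()] and collects
#' markers whose interaction LOD exceeds the threshold.
#'
#' @inheritParams qei_permutation_threshold
#' @return List of class `ionqtl_qei`: the scan, the threshold, and a
#'   `significant` data frame (marker, chr, pos, delta_lod).
#' @export
qei_covariate_test <- function(stacked, trait, n_perm = 1000, alpha = 0.05,
                               seed = 1L) {
  scan <- qei_delta_lod(stacked, trait)
  thr <- qei_permutation_threshold(stacked, trait, n_perm, alpha, seed)
  sig <- scan[!is.na(scan$delta_lod) & scan$delta_lod > as.numeric(thr),
              c("marker", "chr", "pos", "delta_lod")]
  rownames(sig) <- NULL
  structure(list(trait = trait, scan = scan, threshold = as.numeric(thr),
                 alpha = alpha, significant = sig),
            class = "ionqtl_qei")
}

#' @export
print.ionqtl_qei <- function(x, ...) {
  cat(sprintf("QTL-by-location interaction scan for '%s'\n", x$trait))
  cat(sprintf("  threshold (alpha = %.2f): %.2f; %d significant marker(s)\n",
              x$alpha, x$threshold, nrow(x$significant)))
  if (nrow(x$significant)) print(x$significant, digits = 3)
  invisible(x)
}

#' @export
plot.ionqtl_qei_scan <- function(x, threshold = NULL, ...) {
  y <- x
  y$lod <- y$delta_lod
  class(y) <- c("ionqtl_scan", "data.frame")
  plot(y, threshold = threshold, ...)
}

#' Within-location trait differences between two growouts
#'
#' Builds a difference cross from two environments (typically two years at
#' one location): for every line present in both, each trait becomes
#' `value_a - value_b`; genotypes and map carry over; non-common lines are
#' dropped.  Loci mapped on these differences have year-dependent effects.
#'
#' @param cross_a,cross_b `ionqtl_cross` objects sharing a map.
#' @return An `ionqtl_cross` of differences with env id `"<a>-<b>"`.
#' @export
trait_differences <- function(cross_a, cross_b) {
  if (!identical(cross_a$map$marker, cross_b$map$marker))
    stop_arg("crosses do not share one map")
  shared <- intersect(names(cross_a$traits), names(cross_b$traits))
  common <- intersect(rownames(cross_a$traits), rownames(cross_b$traits))
  common <- sort(common)
  if (length(common) < 3) stop_arg("fewer than 3 common lines")
  d <- cross_a$traits[common, shared, drop = FALSE] -
    cross_b$traits[common, shared, drop = FALSE]
  ok <- vapply(shared, function(tr) sum(!is.na(d[[tr]])) >= 3, TRUE)
  if (!any(ok)) stop_arg("fewer than 3 common lines with non-missing traits")
  make_cross(cross_a$map, cross_a$geno, d[, ok, drop = FALSE],
             env_id = paste0(cross_a$env_id, "-", cross_b$env_id))
}

#' Stepwise QTL mapping on a difference trait
#'
#' Delegates to [permutation_threshold()] and [stepwise_qtl()] on the
#' difference cross: the permutation 95th-percentile penalty is computed
#' on the difference trait and the stepwise additive model is selected
#' with it.
#'
#' @param diff_cross output of [trait_differences()].
#' @param trait trait name.
#' @param n_perm,alpha,seed permutation settings.
#' @param max_qtl maximum loci.
#' @return An `ionqtl_qtlmodel` with a `threshold` attribute.
#' @export
map_difference_qtl <- function(diff_cross, trait, n_perm = 1000,
                               alpha = 0.05, seed = 1L, max_qtl = 10) {
  y <- diff_cross$traits[[trait]]
  if (sum(!is.na(y)) >= 3 && stats::var(y, na.rm = TRUE) == 0)
    return(empty_qtl_model(diff_cross, trait, penalty = Inf))
  thr <- permutation_threshold(diff_cross, trait, n_perm, alpha, seed)
  model <- stepwise_qtl(diff_cross, trait, penalty = as.numeric(thr),
                        max_qtl = max_qtl)
  attr(model, "threshold") <- as.numeric(thr)
  model
}
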