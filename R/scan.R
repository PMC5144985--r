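# Vectorized marker-regression engine.
#
# .lod_scan computes, for every marker and every phenotype column, the LOD
# score (n/2) * log10(RSS0 / RSS1) of the single-marker least-squares model
# against the null model on the same line subset.  Phenotype columns must
# share one complete-case row set (callers subset first); missing genotypes
# are handled per marker via mask algebra (no covariates) or a per-marker
# refit (with covariates), so the likelihood ratio is always computed on a
# consistent subset.  A perfect fit is capped at RSS1 = 1e-12 * RSS0.

.lod_scan <- function(Y, G, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  m <- ncol(G)
  M <- !is.na(G)
  complete <- colSums(M) == n
  lod <- matrix(NA_real_, m, ncol(Y))
  nj <- colSums(M)
  capped <- FALSE
  if (is.null(X)) {
    G0 <- G; G0[!M] <- 0
    SY <- crossprod(M, Y)
    SYY <- crossprod(M, Y * Y)
    SX <- colSums(G0)
    SXY <- crossprod(G0, Y)
    ok <- nj >= 3
    njk <- nj[ok]
    syy <- SYY[ok, , drop = FALSE] - SY[ok, , drop = FALSE]^2 / njk
    sxx <- SX[ok] - SX[ok]^2 / njk
    sxy <- SXY[ok, , drop = FALSE] - SX[ok] * SY[ok, , drop = FALSE] / njk
    expl <- sxy^2 / pmax(sxx, 1e-12)
    expl[sxx <= 1e-12, ] <- 0  # monomorphic marker: model == null
    rss1 <- syy - expl
    cap <- 1e-12 * syy
    if (any(rss1 < cap)) capped <- TRUE
    rss1 <- pmax(rss1, cap)
    l <- ifelse(syy > 0, (njk / 2) * log10(syy / rss1), 0)
    lod[ok, ] <- l
  } else {
    X <- as.matrix(X)
    qq <- qr(cbind(1, X))
    EY <- qr.resid(qq, Y)
    rss0 <- colSums(EY^2)
    if (any(complete)) {
      EG <- qr.resid(qq, G[, complete, drop = FALSE])
      sxx <- colSums(EG^2)
      sxy <- crossprod(EG, EY)
      expl <- sxy^2 / pmax(sxx, 1e-12)
      expl[sxx <= 1e-12, ] <- 0
      rss1 <- matrix(rss0, sum(complete), ncol(Y), byrow = TRUE) - expl
      cap <- 1e-12 * matrix(rss0, sum(complete), ncol(Y), byrow = TRUE)
      if (any(rss1 < cap)) capped <- TRUE
      rss1 <- pmax(rss1, cap)
      l <- ifelse(rss0[col(rss1)] > 0,
                  (n / 2) * log10(matrix(rss0, sum(complete), ncol(Y),
                                         byrow = TRUE) / rss1), 0)
      lod[complete, ] <- l
    }
    for (j in which(!complete & nj >= 3)) {
      rows <- M[, j]
      qs <- qr(cbind(1, X[rows, , drop = FALSE]))
      Ey <- qr.resid(qs, Y[rows, , drop = FALSE])
      r0 <- colSums(Ey^2)
      Eg <- qr.resid(qs, G[rows, j])
      sxx <- sum(Eg^2)
      sxy <- crossprod(Eg, Ey)[1, ]
      r1 <- r0 - if (sxx > 1e-12) sxy^2 / sxx else 0
      cap <- 1e-12 * r0
      if (any(r1 < cap)) capped <- TRUE
      r1 <- pmax(r1, cap)
      lod[j, ] <- ifelse(r0 > 0, (sum(rows) / 2) * log10(r0 / r1), 0)
    }
  }
  if (capped) iq_log("capped-lod", "perfect fit; RSS capped at 1e-12 * RSS0")
  list(lod = lod, n = nj)
}

# rows of the cross usable for a trait (+ covariates): non-missing trait
scan_rows <- function(cross, trait, covariates = NULL) {
  if (!trait %in% names(cross$traits)) stop_arg("trait not found: ", trait)
  y <- cross$traits[[trait]]
  keep <- !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (sum(keep) < 3) stop_arg("fewer than 3 lines with trait data")
  list(y = y[keep],
       geno = cross$geno[match(rownames(cross$traits)[keep],
                               rownames(cross$geno)), , drop = FALSE],
       X = if (is.null(covariates)) NULL
           else as.matrix(covariates)[keep, , drop = FALSE])
}

#' Single-marker LOD genome scan
#'
#' At each marker, fits the alternative model `trait ~ genotype`
#' (optionally plus covariates) and the null model without genotype by
#' least squares on the lines with non-missing genotype and trait at that
#' marker, and reports `LOD = (n/2) log10(RSS0 / RSS1)` with both residual
#' sums of squares computed on the same line subset.  Markers with
#' all-missing genotypes are reported as `NA` (logged); a zero-variance
#' trait gives an all-zero profile with a warning.
#'
#' @param cross an `ionqtl_cross`.
#' @param trait trait name.
#' @param covariates optional numeric design columns (one row per
#'   phenotyped line of the cross).
#' @return Data frame of class `ionqtl_scan` with columns `marker`, `chr`,
#'   `pos`, `lod` (one row per map marker) and attributes `trait` and `n`.
#' @export
marker_lod_scan <- function(cross, trait, covariates = NULL) {
  sr <- scan_rows(cross, trait, covariates)
  if (stats::var(sr$y) == 0) {
    warning("zero-variance trait '", trait, "': all LOD scores are 0")
    lod <- rep(0, nrow(cross$map))
  } else {
    sc <- .lod_scan(matrix(sr$y, ncol = 1), sr$geno, sr$X)
    lod <- sc$lod[, 1]
    if (anyNA(lod))
      iq_log("skipped-marker", sum(is.na(lod)),
             " marker(s) with < 3 informative lines skipped")
  }
  out <- data.frame(marker = cross$map$marker, chr = cross$map$chr,
                    pos = cross$map$pos, lod = lod,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "n") <- length(sr$y)
  class(out) <- c("ionqtl_scan", "data.frame")
  out
}

#' Genome-wide permutation threshold for a LOD scan
#'
#' Shuffles trait values across lines (genotypes fixed), re-runs the full
#' genome scan for each permutation, records the genome-wide maximum LOD,
#' and returns the empirical `1 - alpha` quantile of that null
#' distribution.  All permutations are scanned in one vectorized pass, so
#' the default 1000 permutations are cheap.  Reproducible given `seed`.
#'
#' @param cross an `ionqtl_cross`.
#' @param trait trait name.
#' @param n_perm number of permutations (study convention: 1000).
#' @param alpha genome-wide type-I error level (study convention: 0.05).
#' @param seed integer seed.
#' @param covariates optional covariates, permuted jointly with nothing
#'   (held fixed to the lines).
#' @return The threshold (numeric scalar) with attributes `max_lods` (the
#'   `n_perm` null maxima), `alpha`, `n_perm` and `seed`.
#' @export
permutation_threshold <- function(cross, trait, n_perm = 1000, alpha = 0.05,
                                  seed = 1L, covariates = NULL) {
  check_scalar(n_perm, "n_perm", positive = TRUE, integerish = TRUE)
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  sr <- scan_rows(cross, trait, covariates)
  Y <- withr::with_seed(as.integer(seed),
    vapply(seq_len(n_perm), function(i) sample(sr$y), sr$y))
  sc <- .lod_scan(Y, sr$geno, sr$X)
  maxs <- apply(sc$lod, 2, max, na.rm = TRUE)
  thr <- stats::quantile(maxs, 1 - alpha, names = FALSE)
  attr(thr, "max_lods") <- maxs
  attr(thr, "alpha") <- alpha
  attr(thr, "n_perm") <- n_perm
  attr(thr, "seed") <- as.integer(seed)
  thr
}

#' @export
print.ionqtl_scan <- function(x, ...) {
  cat(sprintf("LOD genome scan for '%s' (%d markers, %d chromosomes, n = %s)\n",
              attr(x, "trait") %||% "?", nrow(x),
              length(unique(x$chr)), attr(x, "n") %||% "?"))
  top <- x[which.max(x$lod), ]
  cat(sprintf("  max LOD %.2f at %s (chr %d, %.1f cM)\n",
              top$lod, top$marker, top$chr, top$pos))
  invisible(x)
}

#' @export
summary.ionqtl_scan <- function(object, threshold = NULL, ...) {
  peaks <- do.call(rbind, lapply(split(object, object$chr), function(ch)
    ch[which.max(ch$lod), ]))
  if (!is.null(threshold)) peaks <- peaks[!is.na(peaks$lod) &
                                            peaks$lod >= threshold, ]
  rownames(peaks) <- NULL
  peaks
}

#' Plot a LOD profile along the genome
#'
#' @param x an `ionqtl_scan` (or `ionqtl_qei_scan`).
#' @param threshold optional horizontal significance line.
#' @param lod_col column to plot (default `"lod"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ionqtl_scan <- function(x, threshold = NULL, lod_col = "lod", ...) {
  chr_off <- c(0, cumsum(tapply(x$pos, x$chr, max) + 10))
  xs <- x$pos + chr_off[match(x$chr, sort(unique(x$chr)))]
  graphics::plot(xs, x[[lod_col]], type = "l", xlab = "position (cM)",
                 ylab = "LOD", ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}
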