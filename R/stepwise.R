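# multi-QTL model fit: LOD of y ~ selected markers vs y ~ 1, on the
# complete-case subset across the selected markers; genotypes coded
# s = +1/2 (A) / -1/2 (B) so each coefficient is the A-minus-B difference
model_lod <- function(sr, loci) {
  if (!length(loci)) return(list(lod = 0, n = length(sr$y),
                                 effects = numeric(0)))
  X <- 0.5 - sr$geno[, loci, drop = FALSE]
  rows <- stats::complete.cases(X)
  y <- sr$y[rows]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[rows, , drop = FALSE]), y)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- max(rss1, 1e-12 * rss0)
  list(lod = if (rss0 > 0) (length(y) / 2) * log10(rss0 / rss1) else 0,
       n = length(y), effects = fit$coefficients[-1])
}

empty_qtl_model <- function(cross, trait, penalty) {
  structure(list(
    trait = trait, env_id = cross$env_id,
    loci = data.frame(marker = character(0), chr = integer(0),
                      pos = numeric(0), effect = numeric(0),
                      lod_drop = numeric(0), stringsAsFactors = FALSE),
    model_lod = 0, penalty = penalty, plod = 0),
    class = "ionqtl_qtlmodel")
}

finish_qtl_model <- function(cross, trait, sr, loci, penalty) {
  if (!length(loci)) return(empty_qtl_model(cross, trait, penalty))
  ord <- order(cross$map$chr[loci], cross$map$pos[loci])
  loci <- loci[ord]
  full <- model_lod(sr, loci)
  drops <- vapply(seq_along(loci), function(i)
    full$lod - model_lod(sr, loci[-i])$lod, 0)
  structure(list(
    trait = trait, env_id = cross$env_id,
    loci = data.frame(marker = cross$map$marker[loci],
                      chr = cross$map$chr[loci],
                      pos = cross$map$pos[loci],
                      effect = as.numeric(full$effects),
                      lod_drop = drops, stringsAsFactors = FALSE),
    model_lod = full$lod, penalty = penalty,
    plod = full$lod - penalty * length(loci)),
    class = "ionqtl_qtlmodel")
}

#' Penalized stepwise multi-QTL model selection
#'
#' Forward selection followed by backward elimination over purely additive
#' multi-QTL marker models, scored by the penalized LOD
#' `pLOD = model LOD - penalty * (number of QTL)`.  At each forward step
#' the genome is scanned with the current loci as additive covariates and
#' the marker maximizing the joint model LOD is added while the penalized
#' LOD keeps increasing and fewer than `max_qtl` loci are in the model
#' (ties broken toward the lowest chromosome, then lowest position).
#' Backward elimination then drops any locus whose removal increases the
#' penalized LOD.  The penalized-LOD-maximal model visited is returned;
#' interaction terms never enter (interaction penalties are zero and the
#' model is solely additive).
#'
#' The penalty is normally the genome-wide permutation threshold from
#' [permutation_threshold()].
#'
#' @param cross an `ionqtl_cross`.
#' @param trait trait name.
#' @param penalty per-QTL penalty (> 0), on the LOD scale.
#' @param max_qtl maximum number of loci (study convention: 10).
#' @return An `ionqtl_qtlmodel` with one row per locus (marker, chr,
#'   position, additive A-minus-B effect, LOD drop), the model LOD, the
#'   penalty and the penalized LOD.  Empty if no marker clears the
#'   penalty.
#' @export
stepwise_qtl <- function(cross, trait, penalty, max_qtl = 10) {
  check_scalar(penalty, "penalty", positive = TRUE)
  check_scalar(max_qtl, "max_qtl", positive = TRUE, integerish = TRUE)
  sr <- scan_rows(cross, trait)
  if (stats::var(sr$y) == 0) return(empty_qtl_model(cross, trait, penalty))
  Y1 <- matrix(sr$y, ncol = 1)
  loci <- integer(0)
  plod_cur <- 0
  best <- list(loci = integer(0), plod = 0)
  tol <- 1e-9
  # forward
  while (length(loci) < max_qtl) {
    X <- if (length(loci)) 0.5 - sr$geno[, loci, drop = FALSE] else NULL
    prof <- .lod_scan(Y1, sr$geno, X)$lod[, 1]
    prof[loci] <- -Inf
    prof[is.na(prof)] <- -Inf
    cand <- which.max(prof)
    if (!is.finite(prof[cand])) break
    newloci <- c(loci, cand)
    plod_new <- model_lod(sr, newloci)$lod - penalty * length(newloci)
    if (plod_new <= plod_cur + tol) break
    loci <- newloci
    plod_cur <- plod_new
    if (plod_cur > best$plod) best <- list(loci = loci, plod = plod_cur)
  }
  # backward
  while (length(loci) > 1) {
    plods <- vapply(seq_along(loci), function(i)
      model_lod(sr, loci[-i])$lod - penalty * (length(loci) - 1), 0)
    i <- which.max(plods)
    if (plods[i] <= plod_cur + tol) break
    loci <- loci[-i]
    plod_cur <- plods[i]
    if (plod_cur > best$plod) best <- list(loci = loci, plod = plod_cur)
  }
  if (best$plod <= tol) return(empty_qtl_model(cross, trait, penalty))
  finish_qtl_model(cross, trait, sr, best$loci, penalty)
}

#' Refine QTL positions one locus at a time
#'
#' Visits the model's loci in seeded-random order and, for each, re-scans
#' its chromosome with all other loci held fixed as additive covariates,
#' relocating the locus to the maximum-LOD marker.  Passes repeat until no
#' locus moves or 10 iterations.  The model LOD never decreases.
#'
#' @param cross an `ionqtl_cross`.
#' @param model a non-empty `ionqtl_qtlmodel` for the same cross.
#' @param seed integer seed controlling the visiting order.
#' @return The refined `ionqtl_qtlmodel`.
#' @export
refine_positions <- function(cross, model, seed = 1L) {
  stopifnot(inherits(model, "ionqtl_qtlmodel"))
  if (!nrow(model$loci)) stop_arg("cannot refine an empty model")
  sr <- scan_rows(cross, model$trait)
  Y1 <- matrix(sr$y, ncol = 1)
  loci <- match(model$loci$marker, cross$map$marker)
  cur_lod <- model_lod(sr, loci)$lod
  withr::with_seed(as.integer(seed), {
    for (iter in 1:10) {
      moved <- FALSE
      for (i in sample(seq_along(loci))) {
        others <- loci[-i]
        X <- if (length(others)) 0.5 - sr$geno[, others, drop = FALSE]
             else NULL
        on_chr <- which(cross$map$chr == cross$map$chr[loci[i]])
        prof <- .lod_scan(Y1, sr$geno[, on_chr, drop = FALSE], X)$lod[, 1]
        prof[is.na(prof)] <- -Inf
        prof[on_chr %in% others] <- -Inf
        cand <- on_chr[which.max(prof)]
        if (cand != loci[i]) {
          new_lod <- model_lod(sr, replace(loci, i, cand))$lod
          if (new_lod > cur_lod + 1e-9) {
            loci[i] <- cand
            cur_lod <- new_lod
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
  })
  finish_qtl_model(cross, model$trait, sr, loci, model$penalty)
}

#' Merge QTL models across environments into a locus table
#'
#' Per trait and chromosome, clusters locus positions from all models by
#' single linkage with a 5 cM linkage distance: peaks within 5 cM of some
#' other member of a cluster belong to the same locus, so chains of peaks
#' at 0, 4 and 8 cM merge into one cluster.  One row per cluster reports
#' the member environments, the position range, and the per-environment
#' LOD contributions.
#'
#' @param models list of `ionqtl_qtlmodel` objects sharing one map (e.g.,
#'   one per environment).
#' @param window linkage distance in cM (study convention: 5).
#' @return Data frame of class `ionqtl_merged`: `trait`, `chr`,
#'   `pos_min`, `pos_max`, `pos_mean`, `n_env`, `environments`, `lods`.
#' @export
merge_qtl <- function(models, window = 5) {
  rows <- do.call(rbind, lapply(models, function(m) {
    if (!nrow(m$loci)) return(NULL)
    data.frame(trait = m$trait, env = m$env_id, m$loci,
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(trait = character(0), chr = integer(0),
                    pos_min = numeric(0), pos_max = numeric(0),
                    pos_mean = numeric(0), n_env = integer(0),
                    environments = character(0), lods = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(rows) && nrow(rows)) {
    for (key in unique(paste(rows$trait, rows$chr, sep = "\r"))) {
      sub <- rows[paste(rows$trait, rows$chr, sep = "\r") == key, ]
      sub <- sub[order(sub$pos), , drop = FALSE]
      cl <- cumsum(c(1, diff(sub$pos) > window))
      for (k in unique(cl)) {
        s <- sub[cl == k, , drop = FALSE]
        out <- rbind(out, data.frame(
          trait = s$trait[1], chr = s$chr[1],
          pos_min = min(s$pos), pos_max = max(s$pos),
          pos_mean = mean(s$pos), n_env = length(unique(s$env)),
          environments = paste(s$env, collapse = ";"),
          lods = paste(sprintf("%.2f", s$lod_drop), collapse = ";"),
          stringsAsFactors = FALSE))
      }
    }
    out <- out[order(out$trait, out$chr, out$pos_mean), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("ionqtl_merged", "data.frame")
  out
}

#' @export
print.ionqtl_qtlmodel <- function(x, ...) {
  cat(sprintf("Stepwise QTL model for '%s' (%s): %d loci, model LOD %.2f, penalty %.2f, pLOD %.2f\n",
              x$trait, x$env_id %||% "?", nrow(x$loci), x$model_lod,
              x$penalty, x$plod))
  if (nrow(x$loci)) print(x$loci, digits = 3)
  invisible(x)
}

#' @export
summary.ionqtl_qtlmodel <- function(object, ...) object$loci
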