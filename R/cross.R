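#' Assemble a cross object
#'
#' A cross bundles the genetic map, the RIL genotype matrix and the
#' line x trait matrix for one environment; it is the input to every
#' mapping function.
#'
#' @param map an `ionqtl_map`.
#' @param geno numeric 0/1 genotype matrix (0 = A, 1 = B, `NA` = missing),
#'   lines x markers, with line ids as row names and marker ids matching
#'   the map.
#' @param traits data frame of trait values with line ids as row names; the
#'   lines must be a subset of the genotyped lines.
#' @param env_id environment label.
#' @return A list of class `ionqtl_cross`.
#' @export
make_cross <- function(map, geno, traits, env_id = "env") {
  validate_map(map)
  if (ncol(geno) != nrow(map) || !identical(colnames(geno), map$marker))
    stop_arg("genotype columns must match the map markers")
  if (!all(geno %in% c(0, 1, NA)))
    stop_arg("genotypes must be coded 0 (A), 1 (B) or NA")
  if (is.null(rownames(geno))) stop_arg("genotype matrix needs line ids")
  if (!all(rownames(traits) %in% rownames(geno)))
    stop_arg("trait rows must be a subset of genotyped lines")
  structure(list(map = map, geno = geno, traits = traits,
                 env_id = env_id),
            class = "ionqtl_cross")
}

#' @export
print.ionqtl_cross <- function(x, ...) {
  cat(sprintf("ionqtl cross '%s': %d lines genotyped at %d markers on %d chromosomes\n",
              x$env_id, nrow(x$geno), ncol(x$geno),
              length(unique(x$map$chr))))
  cat(sprintf("  %d phenotyped lines, %d traits\n",
              nrow(x$traits), ncol(x$traits)))
  invisible(x)
}

#' Build one cross per environment from simulation output
#'
#' Convenience wrapper chaining the generator stages for line-mean crosses
#' (no seed-level artifacts): simulates genotypes and environment traits,
#' averages replicate rows, and returns one cross per environment.
#'
#' @param scenario an `ionqtl_scenario`.
#' @return Named list of `ionqtl_cross` objects.
#' @export
simulate_crosses <- function(scenario) {
  geno <- simulate_ril_genotypes(scenario$map, scenario$n_lines,
                                 sub_seed(scenario$rng_seed, 17),
                                 scenario$missing_geno_rate)
  envt <- simulate_env_traits(geno, scenario)
  lapply(stats::setNames(names(envt), names(envt)), function(env) {
    tab <- envt[[env]]
    traits <- setdiff(names(tab), c("line_id", "rep_id"))
    agg <- stats::aggregate(tab[traits], by = list(line_id = tab$line_id),
                            FUN = mean)
    rn <- agg$line_id
    agg <- agg[traits]
    rownames(agg) <- rn
    make_cross(scenario$map, geno, agg, env_id = env)
  })
}
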