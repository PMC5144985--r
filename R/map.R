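#' Build an evenly spaced genetic map
#'
#' Constructs a marker map with `markers_per_chr` markers evenly spaced from
#' 0 to `chr_length_cM` centimorgans on each of `n_chr` chromosomes.  The
#' map is the coordinate system for every genome scan in the package.
#'
#' @param n_chr number of chromosomes (>= 1).
#' @param markers_per_chr markers per chromosome (>= 2).
#' @param chr_length_cM chromosome length in centimorgans (> 0).
#' @return A data frame of class `ionqtl_map` with columns `marker`
#'   (unique id), `chr` (integer) and `pos` (cM, nondecreasing within
#'   chromosome).
#' @examples
#' make_map(1, 3, 100)  # markers at 0, 50, 100 cM
#' @export
make_map <- function(n_chr, markers_per_chr, chr_length_cM) {
  check_scalar(n_chr, "n_chr", positive = TRUE, integerish = TRUE)
  check_scalar(markers_per_chr, "markers_per_chr", positive = TRUE,
               integerish = TRUE)
  check_scalar(chr_length_cM, "chr_length_cM", positive = TRUE)
  if (markers_per_chr < 2) stop_arg("markers_per_chr must be >= 2")
  pos <- seq(0, chr_length_cM, length.out = markers_per_chr)
  map <- data.frame(
    marker = sprintf("c%d_m%d", rep(seq_len(n_chr), each = markers_per_chr),
                     rep(seq_len(markers_per_chr), n_chr)),
    chr = rep(as.integer(seq_len(n_chr)), each = markers_per_chr),
    pos = rep(pos, n_chr),
    stringsAsFactors = FALSE
  )
  class(map) <- c("ionqtl_map", "data.frame")
  map
}

validate_map <- function(map) {
  if (!all(c("marker", "chr", "pos") %in% names(map)))
    stop_arg("map must have columns marker, chr, pos")
  if (anyDuplicated(map$marker)) stop_arg("marker ids must be unique")
  if (any(map$pos < 0)) stop_arg("map positions must be non-negative")
  bad <- tapply(map$pos, map$chr, function(p) any(diff(p) < 0))
  if (any(unlist(bad)))
    stop_arg("positions must be nondecreasing within each chromosome")
  invisible(map)
}

#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction
#' assuming no crossover interference: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM distance in centimorgans (vectorized).
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Simulate RIL genotypes along a genetic map
#'
#' Each line is an independent two-state Markov chain along each chromosome:
#' the first marker is allele A or B with probability 1/2 and adjacent
#' markers switch with the Haldane recombination fraction of their map
#' distance.  Map distances are treated as realized RIL distances (maps for
#' intermated populations already incorporate the expansion from
#' intermating), so no extra inflation is applied.  Lines are fully
#' homozygous; genotypes are coded 0 (allele A) and 1 (allele B).
#'
#' @param map an `ionqtl_map`.
#' @param n_lines number of lines to simulate (>= 1).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param missing_rate optional proportion of calls set to `NA`
#'   (default 0), for exercising missing-data handling in scans.
#' @return numeric matrix of 0/1 calls, lines x markers, with line ids as
#'   row names and marker ids as column names.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed, missing_rate = 0) {
  validate_map(map)
  check_scalar(n_lines, "n_lines", positive = TRUE, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop_arg("missing_rate must be in [0, 1)")
  withr::with_seed(as.integer(seed), {
    geno <- matrix(NA_real_, n_lines, nrow(map))
    for (ch in unique(map$chr)) {
      idx <- which(map$chr == ch)
      m <- length(idx)
      g <- matrix(0, n_lines, m)
      g[, 1] <- stats::rbinom(n_lines, 1, 0.5)
      if (m > 1) {
        r <- haldane_r(diff(map$pos[idx]))
        sw <- matrix(stats::rbinom(n_lines * (m - 1), 1, rep(r, each = n_lines)),
                     n_lines, m - 1)
        for (j in 2:m) g[, j] <- (g[, j - 1] + sw[, j - 1]) %% 2
      }
      geno[, idx] <- g
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(geno)) < missing_rate
      geno[drop] <- NA_real_
    }
    dimnames(geno) <- list(sprintf("L%03d", seq_len(n_lines)), map$marker)
    geno
  })
}

# nearest marker (index into map) to a cM position on a chromosome;
# ties broken toward the lower position
nearest_marker <- function(map, chr, pos) {
  idx <- which(map$chr == chr)
  if (!length(idx)) stop_arg("no markers on chromosome ", chr)
  d <- abs(map$pos[idx] - pos)
  idx[which.min(d)]  # which.min takes the first (lower-position) tie
}
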