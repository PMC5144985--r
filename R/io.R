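# Readers/writers for the rotated cross CSV dialect and seed tables.
#
# Cross CSV layout: row 1 = trait names then marker names; row 2 = blank
# cells under the traits, chromosome ids under the markers; row 3 = blank
# cells under the traits, cM positions under the markers; each following
# row = one RIL (trait values, then genotype codes A/B/"-").  The line id
# is carried as a trait column named "id".  UTF-8, comma separator, "."
# decimal.

#' Write a cross to the rotated CSV dialect
#'
#' @param cross an `ionqtl_cross`.
#' @param path output file.
#' @export
write_cross_csv <- function(cross, path) {
  traits <- cross$traits
  lines <- rownames(traits)
  geno <- cross$geno[match(lines, rownames(cross$geno)), , drop = FALSE]
  codes <- matrix("-", nrow(geno), ncol(geno))
  codes[!is.na(geno) & geno == 0] <- "A"
  codes[!is.na(geno) & geno == 1] <- "B"
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  tcols <- c("id", names(traits))
  header <- c(tcols, cross$map$marker)
  row2 <- c(rep("", length(tcols)), as.character(cross$map$chr))
  row3 <- c(rep("", length(tcols)), num(cross$map$pos))
  body <- cbind(lines,
                do.call(cbind, lapply(traits, num)),
                codes)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","),
               paste(row2, collapse = ","),
               paste(row3, collapse = ",")), con)
  utils::write.table(body, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cross from the rotated CSV dialect
#'
#' @param path input file (see [write_cross_csv()] for the layout).
#' @param env_id environment label for the cross (default: file name).
#' @return An `ionqtl_cross`.
#' @export
read_cross_csv <- function(path, env_id = NULL) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 4) stop_arg("cross CSV needs >= 4 rows (", path, ")")
  header <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])
  pos_row <- as.character(raw[3, ])
  is_trait <- chr_row == "" | is.na(chr_row)
  if (!any(is_trait) || all(is_trait))
    stop_arg("parse error at row 2: cannot separate traits from markers")
  if (any(diff(is_trait) > 0))
    stop_arg("parse error at row 1: trait columns must precede markers")
  tcols <- which(is_trait)
  mcols <- which(!is_trait)
  if (any(pos_row[tcols] != "" & !is.na(pos_row[tcols])))
    stop_arg("parse error at row 3: positions present under trait columns")
  map <- data.frame(marker = header[mcols],
                    chr = as.integer(chr_row[mcols]),
                    pos = as.numeric(pos_row[mcols]),
                    stringsAsFactors = FALSE)
  if (anyNA(map$chr) || anyNA(map$pos))
    stop_arg("parse error at rows 2-3: non-numeric chromosome or position")
  class(map) <- c("ionqtl_map", "data.frame")
  validate_map(map)
  body <- raw[-(1:3), , drop = FALSE]
  codes <- as.matrix(body[, mcols, drop = FALSE])
  bad <- matrix(!(codes %in% c("A", "B", "-", "−", "")), nrow(codes))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_arg("parse error: unknown genotype code '", codes[bad][1],
             "' at data row ", w[1], ", marker column ", w[2])
  }
  geno <- matrix(NA_real_, nrow(codes), ncol(codes))
  geno[codes == "A"] <- 0
  geno[codes == "B"] <- 1
  ids <- if ("id" %in% header[tcols]) body[[which(header == "id")[1]]]
         else sprintf("L%03d", seq_len(nrow(body)))
  dimnames(geno) <- list(ids, map$marker)
  tr_names <- setdiff(header[tcols], "id")
  traits <- as.data.frame(lapply(body[, tcols[header[tcols] != "id"],
                                      drop = FALSE], as.numeric),
                          optional = TRUE)
  names(traits) <- tr_names
  rownames(traits) <- ids
  make_cross(map, geno, traits,
             env_id = env_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write a seed table to CSV
#'
#' Columns: `line_id`, `env_id`, `rep_id`, `run_id`, `weight_mg`, then one
#' `raw_<element>` (and, when present, `ecdm_<element>` and
#' `flag_<element>`) column per element.
#'
#' @param seeds a seed table.
#' @param path output file.
#' @export
write_seed_csv <- function(seeds, path) {
  utils::write.csv(seeds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a seed table from CSV
#'
#' @param path input file.
#' @return A seed table (`ionqtl_seeds` data frame).
#' @export
read_seed_csv <- function(path) {
  seeds <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("line_id", "env_id", "rep_id", "run_id", "weight_mg")
  miss <- setdiff(need, names(seeds))
  if (length(miss))
    stop_arg("seed CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!any(grepl("^raw_", names(seeds))))
    stop_arg("seed CSV has no raw_<element> columns")
  for (fc in grep("^flag_", names(seeds), value = TRUE))
    seeds[[fc]] <- as.logical(seeds[[fc]])
  class(seeds) <- c("ionqtl_seeds", "data.frame")
  seeds
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

#' Write a deterministic TSV report
#'
#' Fixed column orders per report kind, LOD/H2 at 2 decimals, cM at 1
#' decimal, rows ordered by (trait, chromosome, position); running twice
#' on the same results gives byte-identical files.
#'
#' @param results stage results: a list of `ionqtl_herit` (kind
#'   `"herit"`), of `ionqtl_qtlmodel` (kind `"qtl"` and `"qei_diff"`), or
#'   of `ionqtl_qei` (kind `"qei_cov"`).
#' @param kind one of `"herit"`, `"qtl"`, `"qei_cov"`, `"qei_diff"`.
#' @param path output file.
#' @export
write_report <- function(results, kind = c("herit", "qtl", "qei_cov",
                                           "qei_diff"), path) {
  kind <- match.arg(kind)
  if (inherits(results, c("ionqtl_herit", "ionqtl_qtlmodel", "ionqtl_qei")))
    results <- list(results)
  df <- switch(kind,
    herit = {
      rows <- lapply(results, function(h) data.frame(
        Trait = h$trait, Scope = as.character(h$scope),
        H2 = fmt_num(h$H2, 2), VarG = fmt_num(h$var_genetic, 4),
        VarE = fmt_num(h$var_env, 4), VarRes = fmt_num(h$var_resid, 4),
        stringsAsFactors = FALSE))
      d <- do.call(rbind, rows)
      if (is.null(d)) d <- data.frame(Trait = character(0),
                                      Scope = character(0),
                                      H2 = character(0), VarG = character(0),
                                      VarE = character(0),
                                      VarRes = character(0))
      d[order(d$Trait, d$Scope), , drop = FALSE]
    },
    qtl = {
      rows <- lapply(results, function(m) {
        if (!nrow(m$loci)) return(NULL)
        data.frame(Trait = m$trait, Env = m$env_id, Chr = m$loci$chr,
                   `Pos (cM)` = fmt_num(m$loci$pos, 1),
                   LOD = fmt_num(m$loci$lod_drop, 2),
                   Effect = fmt_num(m$loci$effect, 3),
                   check.names = FALSE, stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, rows)
      if (is.null(d)) d <- data.frame(Trait = character(0),
                                      Env = character(0),
                                      Chr = integer(0),
                                      `Pos (cM)` = character(0),
                                      LOD = character(0),
                                      Effect = character(0),
                                      check.names = FALSE)
      d[order(d$Trait, d$Chr, as.numeric(d$`Pos (cM)`)), , drop = FALSE]
    },
    qei_cov = {
      rows <- lapply(results, function(q) {
        if (!nrow(q$significant)) return(NULL)
        data.frame(Trait = q$trait, Chr = q$significant$chr,
                   `Pos (cM)` = fmt_num(q$significant$pos, 1),
                   LOD = fmt_num(q$significant$delta_lod, 2),
                   `Significance Threshold` = fmt_num(q$threshold, 2),
                   check.names = FALSE, stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, rows)
      if (is.null(d)) d <- data.frame(Trait = character(0),
                                      Chr = integer(0),
                                      `Pos (cM)` = character(0),
                                      LOD = character(0),
                                      `Significance Threshold` = character(0),
                                      check.names = FALSE)
      d[order(d$Trait, d$Chr, as.numeric(d$`Pos (cM)`)), , drop = FALSE]
    },
    qei_diff = {
      rows <- lapply(results, function(m) {
        if (!nrow(m$loci)) return(NULL)
        yrs <- gsub("-", "_", m$env_id %||% "")
        data.frame(Location = gsub("[0-9_-]", "",
                                   strsplit(m$env_id %||% "", "-")[[1]][1]),
                   `Years Compared` = yrs, Trait = m$trait,
                   Chr = m$loci$chr,
                   `Pos (cM)` = fmt_num(m$loci$pos, 1),
                   LOD = fmt_num(m$loci$lod_drop, 2),
                   `Significance Threshold` =
                     fmt_num(attr(m, "threshold") %||% NA_real_, 2),
                   check.names = FALSE, stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, rows)
      if (is.null(d)) d <- data.frame(Location = character(0),
                                      `Years Compared` = character(0),
                                      Trait = character(0),
                                      Chr = integer(0),
                                      `Pos (cM)` = character(0),
                                      LOD = character(0),
                                      `Significance Threshold` = character(0),
                                      check.names = FALSE)
      d[order(d$Trait, d$Chr, as.numeric(d$`Pos (cM)`)), , drop = FALSE]
    })
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
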