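#' Stack per-environment trait tables into long format
#'
#' @param tables named list (by environment) of line x trait data frames
#'   with line ids as row names (the output of [line_averages()]).
#' @param trait trait column to extract.
#' @return Long data frame with columns `line_id`, `env_id`, `value`.
#' @export
stack_trait_tables <- function(tables, trait) {
  parts <- lapply(names(tables), function(env) {
    tab <- tables[[env]]
    if (!trait %in% names(tab)) stop_arg("trait not found: ", trait)
    data.frame(line_id = rownames(tab), env_id = env,
               value = tab[[trait]], stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Broad-sense heritability across environments
#'
#' Partitions phenotypic variance into genetic, environmental and residual
#' components from an unbalanced two-way layout (lines x environments, no
#' interaction term) using type-II sums of squares obtained from two
#' sequential fits: `trait ~ line + environment` and
#' `trait ~ environment + line`.  The genetic sum of squares is taken from
#' the fit where line enters second (adjusted for environment) and the
#' environmental sum of squares from the fit where environment enters
#' second, which is what type-II ANOVA amounts to for a two-term model and
#' what an unbalanced design requires.
#'
#' Variance components are recovered from the adjusted mean squares by the
#' expected-mean-square (method-of-moments) relations
#' `VG = (MS_line - MS_res) / c_g` and `VE = (MS_env - MS_res) / c_e`,
#' where `c` is the effective replication of the term
#' (`(N - sum(n_i^2)/N) / df`); negative estimates are clipped to zero
#' (logged).  `H2 = VG / (VG + VE + Vres)`.  The raw mean-square and
#' sum-of-squares ratios are also reported (`ms_ratio`, `ss_ratio`) since
#' "the genetic variance" is sometimes read as the adjusted MS or SS
#' itself.
#'
#' @param data either a long data frame with columns `line_id`, `env_id`
#'   and the trait, or a named list of per-environment line-mean tables
#'   (see [line_averages()]).
#' @param trait trait/column name (default `"value"`).
#' @return An object of class `ionqtl_herit`.
#' @export
h2_across_env <- function(data, trait = "value") {
  if (is.list(data) && !is.data.frame(data))
    data <- stack_trait_tables(data, trait) else {
    if (!trait %in% names(data)) stop_arg("trait not found: ", trait)
    data <- data.frame(line_id = data$line_id, env_id = data$env_id,
                       value = data[[trait]], stringsAsFactors = FALSE)
    trait <- "value"
  }
  df <- data[!is.na(data$value), , drop = FALSE]
  df$line <- factor(df$line_id)
  df$env <- factor(df$env_id)
  if (nlevels(df$env) < 2) stop_arg("need >= 2 environments")
  if (nlevels(df$line) < 2) stop_arg("need >= 2 lines")
  n_env_per_line <- rowSums(table(df$line, df$env) > 0)
  if (sum(n_env_per_line >= 2) < 2)
    stop_arg("need >= 2 lines present in >= 2 environments; ",
             "genetic and environmental variance are not separable")
  a1 <- anova_q(stats::lm(value ~ line + env, data = df))
  a2 <- anova_q(stats::lm(value ~ env + line, data = df))
  ms_line <- a2["line", "Mean Sq"]; ss_line <- a2["line", "Sum Sq"]
  ms_env <- a1["env", "Mean Sq"];  ss_env <- a1["env", "Sum Sq"]
  ms_res <- a1["Residuals", "Mean Sq"]
  ss_res <- a1["Residuals", "Sum Sq"]
  if (!is.finite(ms_res)) ms_res <- 0  # saturated zero-residual layouts
  c_g <- ems_coef(table(df$line), a2["line", "Df"])
  c_e <- ems_coef(table(df$env), a1["env", "Df"])
  vg <- clip0((ms_line - ms_res) / c_g, "genetic")
  ve <- clip0((ms_env - ms_res) / c_e, "environmental")
  tot <- vg + ve + ms_res
  new_herit(trait, "all_env",
            var_genetic = vg, var_env = ve, var_resid = ms_res,
            H2 = if (tot > 0) vg / tot else NA_real_,
            ms_ratio = ratio0(ms_line, ms_line + ms_env + ms_res),
            ss_ratio = ratio0(ss_line, ss_line + ss_env + ss_res),
            n = nrow(df))
}

#' Broad-sense heritability within one environment
#'
#' One-way ANOVA of replicate-level trait values on line, after removing
#' missing values and lines with fewer than two replicates.  The genetic
#' variance component is `(MS_line - MS_res) / r` with `r` the effective
#' replicate number, clipped at zero; `H2 = VG / (VG + Vres)`, the
#' proportion of total (genetic plus residual) variance that is genetic.
#'
#' @param data data frame with a `line_id` column and replicate-level
#'   trait values (one row per replicate; see [rep_averages()]).
#' @param trait trait/column name.
#' @param env_id environment label recorded in the result scope.
#' @return An `ionqtl_herit`; `H2` is `NA` when all surviving values are
#'   identical (no variance to partition).
#' @export
h2_within_env <- function(data, trait = "value", env_id = NA_character_) {
  if (!trait %in% names(data)) stop_arg("trait not found: ", trait)
  df <- data.frame(line = data$line_id, value = data[[trait]],
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$value), , drop = FALSE]
  keep <- names(which(table(df$line) >= 2))
  df <- df[df$line %in% keep, , drop = FALSE]
  if (length(keep) < 2)
    stop_arg("fewer than 2 lines with >= 2 replicates survive filtering")
  df$line <- factor(df$line)
  if (stats::var(df$value) == 0) {
    iq_log("degenerate", "all replicate values identical; H2 undefined")
    return(new_herit(trait, env_id, var_genetic = 0, var_env = NA_real_,
                     var_resid = 0, H2 = NA_real_, ms_ratio = NA_real_,
                     ss_ratio = NA_real_, n = nrow(df)))
  }
  a <- anova_q(stats::lm(value ~ line, data = df))
  ms_line <- a["line", "Mean Sq"]; ss_line <- a["line", "Sum Sq"]
  ms_res <- a["Residuals", "Mean Sq"]; ss_res <- a["Residuals", "Sum Sq"]
  if (!is.finite(ms_res)) ms_res <- 0
  r_eff <- ems_coef(table(df$line), a["line", "Df"])
  vg <- clip0((ms_line - ms_res) / r_eff, "genetic")
  tot <- vg + ms_res
  new_herit(trait, env_id, var_genetic = vg, var_env = NA_real_,
            var_resid = ms_res,
            H2 = if (tot > 0) vg / tot else NA_real_,
            ms_ratio = ratio0(ms_line, ms_line + ms_res),
            ss_ratio = ratio0(ss_line, ss_line + ss_res),
            n = nrow(df))
}

# anova() warns about F statistics on zero-residual fits; those degenerate
# layouts are legitimate here (H2 = 1 cases), so muffle only that warning
anova_q <- function(fit) {
  withCallingHandlers(stats::anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# effective replication of a term: (N - sum(n_i^2)/N) / df
ems_coef <- function(counts, df) {
  n <- sum(counts)
  (n - sum(counts^2) / n) / df
}

clip0 <- function(x, what) {
  if (is.na(x)) return(0)
  if (x < 0) {
    iq_log("clipped-variance", what, " variance estimate ",
           format(x, digits = 3), " clipped to 0")
    return(0)
  }
  x
}

ratio0 <- function(num, den) {
  if (is.finite(den) && den > 0) num / den else NA_real_
}

new_herit <- function(trait, scope, ...) {
  structure(c(list(trait = trait, scope = scope), list(...)),
            class = "ionqtl_herit")
}

#' @export
print.ionqtl_herit <- function(x, ...) {
  cat(sprintf("Broad-sense heritability: %s (%s)\n", x$trait,
              if (identical(x$scope, "all_env")) "across environments"
              else paste0("within ", x$scope)))
  cat(sprintf("  H2 = %s  (VG = %.4g, %sVres = %.4g, n = %d)\n",
              ifelse(is.na(x$H2), "NA", sprintf("%.3f", x$H2)),
              x$var_genetic,
              if (!is.na(x$var_env)) sprintf("VE = %.4g, ", x$var_env)
              else "", x$var_resid, x$n))
  invisible(x)
}
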