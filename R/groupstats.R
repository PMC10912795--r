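# Group-comparison stage: Kolmogorov-Smirnov normality screening, one-way
# ANOVA and Tukey's HSD post-hoc test, applied to per-seizure metric tables
# (band power, band coherence, band MI) across experimental groups
# (control, DBS, Pilo, Pilo+DBS).

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample mean and standard deviation. Because the reference parameters
#' are estimated from the same sample, the p-value uses the Lilliefors
#' correction (via `nortest::lillie.test`) rather than the plain KS null
#' distribution, which would be strongly conservative.
#'
#' @param values numeric vector, n >= 4, non-degenerate.
#' @return list with `statistic` (D) and `p`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop_lfpdbs("normality test requires at least 4 values",
                "lfpdbs_validation_error")
  if (stats::sd(values) == 0)
    stop_lfpdbs("zero-variance sample", "lfpdbs_degenerate_error")
  r <- nortest::lillie.test(values)
  list(statistic = unname(r$statistic), p = r$p.value)
}

check_group_table <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_lfpdbs("need at least 2 groups", "lfpdbs_validation_error")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop_lfpdbs("every group needs at least 2 values",
                "lfpdbs_validation_error")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

groups_to_df <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1)))))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' mean-square ratio) via `stats::aov`. With k groups of N total values the
#' degrees of freedom are (k - 1, N - k); four groups of 16 give the
#' (3, 60) pattern typical of per-seizure LFP metric tables.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @examples
#' one_way_anova(list(a = rnorm(16), b = rnorm(16), c = rnorm(16),
#'                    d = rnorm(16)))
#' @export
one_way_anova <- function(groups) {
  groups <- check_group_table(groups)
  d <- groups_to_df(groups)
  tab <- stats::anova(stats::aov(value ~ group, data = d))
  list(F = tab$`F value`[1L],
       df_between = tab$Df[1L],
       df_within = tab$Df[2L],
       p = tab$`Pr(>F)`[1L])
}

#' Tukey's honestly-significant-difference post-hoc test
#'
#' All pairwise group comparisons with studentized-range adjusted p-values
#' (`stats::TukeyHSD`, Tukey-Kramer for unequal group sizes). The q
#' statistic reported per pair is `|mean diff| / sqrt((MSE/2)(1/ni + 1/nj))`
#' and its adjusted p is `ptukey(q, k, df_within)`.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return data.frame with one row per pair: `pair`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- check_group_table(groups)
  d <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit)$group
  mse <- stats::anova(fit)$`Mean Sq`[2L]
  ns <- vapply(groups, length, integer(1))
  pairs <- rownames(tk)
  q <- vapply(seq_along(pairs), function(i) {
    gg <- strsplit(pairs[i], "-", fixed = TRUE)[[1L]]
    se <- sqrt(mse / 2 * (1 / ns[gg[1L]] + 1 / ns[gg[2L]]))
    abs(tk[i, "diff"]) / se
  }, numeric(1))
  data.frame(pair = pairs, diff = unname(tk[, "diff"]), q = q,
             p_adj = unname(tk[, "p adj"]), row.names = NULL)
}
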