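#' Per-field averages of soil properties
#'
#' Arithmetic mean of every numeric soil-property column.  Missing CaCO3
#' determinations (carbonate-free plots) are handled per policy: `"zero"`
#' imputes 0 % (the convention of the printed average rows), `"exclude"`
#' drops them from the mean.
#'
#' @param props soil-property data.frame (see [read_soil_properties()]).
#' @param missing_policy `"zero"` or `"exclude"`.
#' @param digits if non-`NULL`, round the result to this many decimals with
#'   [round_decimal()].
#' @return named numeric vector of column means.
#' @export
field_averages <- function(props, missing_policy = c("zero", "exclude"),
                           digits = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(props) == 0) stop("no plots to average", call. = FALSE)
  num <- names(props)[vapply(props, is.numeric, logical(1))]
  num <- setdiff(num, "year")
  out <- vapply(num, function(cc) {
    x <- props[[cc]]
    if (missing_policy == "zero") x[is.na(x)] <- 0
    if (all(is.na(x))) {
      warning(sprintf("column '%s' is all-missing under policy 'exclude'", cc))
      return(NA_real_)
    }
    mean(x, na.rm = TRUE)
  }, numeric(1))
  if (!is.null(digits)) out <- round_decimal(out, digits)
  out
}

sig_tier <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("<0.001", "<0.01", "<0.05", "ns"))
}

#' Pearson correlation screen over a plot-level variable matrix
#'
#' Product-moment correlation for every pair of numeric columns, with the
#' exact t-transform p-value on n - 2 degrees of freedom (via
#' [stats::cor.test()]) and the conventional significance tiers
#' (0.05 / 0.01 / 0.001).  Pairs are formed over complete observations;
#' zero-variance variables yield undefined entries.
#'
#' @param table data.frame; non-numeric columns are ignored.
#' @param vars optional subset of column names to screen.
#' @return data.frame with `var_x`, `var_y`, `r`, `n`, `p`, `tier`;
#'   undefined entries carry `NA` r/p and tier `"undefined"`.
#' @export
pearson_screen <- function(table, vars = NULL) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (!is.null(vars)) num <- intersect(vars, num)
  if (length(num) < 2) stop("need at least two numeric variables", call. = FALSE)
  pairs <- utils::combn(num, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- table[[pairs[1, i]]]; y <- table[[pairs[2, i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(var_x = pairs[1, i], var_y = pairs[2, i],
                        r = NA_real_, n = n, p = NA_real_,
                        tier = "undefined"))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var_x = pairs[1, i], var_y = pairs[2, i],
               r = unname(ct$estimate), n = n, p = ct$p.value,
               tier = as.character(sig_tier(ct$p.value)))
  })
  do.call(rbind, rows)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition via [stats::aov()]: F on
#' (g - 1, N - g) degrees of freedom.
#'
#' @param values numeric measurements.
#' @param groups grouping factor (>= 2 groups, each with >= 2 values).
#' @return list with `F`, `p`, `df`, `group_means`, and the fitted `aov`
#'   object (`fit`) for downstream post-hoc tests.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least two values",
                                   call. = FALSE)
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
       group_means = c(tapply(values, groups, mean)), fit = fit)
}

#' Tukey honest-significant-difference comparisons
#'
#' Studentized-range post-hoc test on a one-way layout (via
#' [stats::TukeyHSD()]).  For two groups the decision coincides with the
#' one-way F test at the same level.
#'
#' @inheritParams anova_oneway
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  a <- anova_oneway(values, groups)
  tk <- stats::TukeyHSD(a$fit, conf.level = 1 - alpha)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha, row.names = NULL)
}
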