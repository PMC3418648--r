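#' Dunnett many-to-one comparisons with Monte-Carlo critical values
#'
#' Compares every group against a designated baseline using the Dunnett
#' max-|t| statistic, with the null distribution of the maximum absolute
#' t-statistic estimated by seeded Monte-Carlo simulation (shared pooled
#' variance, shared baseline mean — the same correlation structure as the
#' classical tabulated procedure, but valid for arbitrary group counts and
#' unbalanced sizes).
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor).
#' @param baseline baseline group label.
#' @param alpha familywise error level for the reported critical value.
#' @param R number of Monte-Carlo draws.
#' @param seed integer seed for the draws.
#' @return A data.frame, one row per non-baseline group: `group`, `diff`
#'   (mean difference to baseline), `t`, `p_adj` (Monte-Carlo adjusted),
#'   `crit` (critical |t| at `alpha`), `significant`.
#' @export
dunnett_mc <- function(values, groups, baseline, alpha = 0.05, R = 1e5,
                       seed = 1L) {
  groups <- factor(groups)
  if (!baseline %in% levels(groups))
    stop_fmt("dunnett_mc: baseline '%s' not among the groups", baseline)
  groups <- stats::relevel(groups, ref = as.character(baseline))
  lev <- levels(groups)
  k <- length(lev) - 1L
  if (k < 1) stop_fmt("dunnett_mc: need at least 2 groups")
  ns <- as.integer(table(groups)[lev])
  if (any(ns < 2)) stop_fmt("dunnett_mc: every group needs n >= 2")
  ms <- tapply(values, groups, mean)[lev]
  df <- sum(ns) - length(lev)
  s2 <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  sed <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  tobs <- (ms[-1] - ms[1]) / sed

  maxT <- with_seed(seed, {
    z0 <- rnorm(R, sd = 1 / sqrt(ns[1]))
    s <- sqrt(rchisq(R, df) / df)
    m <- matrix(rnorm(R * k), R, k)
    m <- sweep(m, 2, sqrt(ns[-1]), "/")
    mx <- rep(-Inf, R)
    for (j in seq_len(k))
      mx <- pmax(mx, abs(m[, j] - z0) /
                   (s * sqrt(1 / ns[-1][j] + 1 / ns[1])))
    mx
  })
  crit <- as.numeric(quantile(maxT, 1 - alpha))
  p_adj <- vapply(abs(tobs), function(t) mean(maxT >= t), numeric(1))
  data.frame(group = lev[-1], diff = as.numeric(ms[-1] - ms[1]),
             t = as.numeric(tobs), p_adj = p_adj, crit = crit,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

#' One-way group comparison report
#'
#' The classical one-way toolbox on a pooled observation table: ANOVA
#' (F, p), Kruskal-Wallis (H, p), Tukey HSD pairwise comparisons, and —
#' when a baseline group is named — Monte-Carlo Dunnett many-to-one
#' comparisons.  When every group has zero within-group variance the
#' parametric tests are meaningless; a warning is issued and only the rank
#' test is reported.
#'
#' @param data data.frame of pooled observations.
#' @param value,group column names of the response and the group label.
#' @param baseline optional baseline group for Dunnett comparisons.
#' @param alpha significance level used for flags.
#' @param seed seed for the Dunnett Monte-Carlo draws.
#' @param R Monte-Carlo draw count.
#' @return List of class `group_comparison`: `anova` (F, df, p),
#'   `kruskal` (H, df, p), `tukey` (data.frame), `dunnett` (data.frame or
#'   `NULL`), `n` (group sizes).
#' @export
group_compare <- function(data, value = "strain", group = "group",
                          baseline = NULL, alpha = 0.05, seed = 1L,
                          R = 1e5) {
  v <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2) stop_fmt("group_compare: need at least 2 groups")
  if (any(table(g) < 2)) stop_fmt("group_compare: every group needs n >= 2")
  kw <- kruskal.test(v, g)
  wvar <- tapply(v, g, stats::var)
  if (all(wvar == 0)) {
    warning("group_compare: zero within-group variance in all groups; reporting the rank test only")
    return(structure(list(anova = NULL,
                          kruskal = list(H = unname(kw$statistic),
                                         df = unname(kw$parameter),
                                         p = kw$p.value),
                          tukey = NULL, dunnett = NULL,
                          n = as.integer(table(g))),
                     class = "group_comparison"))
  }
  fit <- aov(v ~ g)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  dn <- if (!is.null(baseline))
    dunnett_mc(v, g, baseline, alpha = alpha, R = R, seed = seed) else NULL
  structure(list(anova = list(F = an$`F value`[1], df = an$Df[1:2],
                              p = an$`Pr(>F)`[1]),
                 kruskal = list(H = unname(kw$statistic),
                                df = unname(kw$parameter), p = kw$p.value),
                 tukey = tukey, dunnett = dn,
                 n = as.integer(table(g))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  if (!is.null(x$anova))
    cat(sprintf("  one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
                x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat(sprintf("  Kruskal-Wallis: H(%d) = %.3f, p = %.4g\n",
              x$kruskal$df, x$kruskal$H, x$kruskal$p))
  if (!is.null(x$dunnett)) {
    sig <- x$dunnett$group[x$dunnett$significant]
    cat(sprintf("  Dunnett vs baseline: %s significant\n",
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Turning point of an age-ordered stiffness series
#'
#' Identifies the earliest age whose Dunnett-adjusted comparison against
#' the youngest (baseline) age group is significant — the age around which
#' the stiffness change mainly takes place.
#'
#' @param data data.frame of pooled observations.
#' @param value,age column names of the response and the (numeric) age.
#' @param alpha familywise significance level.
#' @param seed,R Monte-Carlo settings for [dunnett_mc()].
#' @return List: `age` (the turning point, or `NA` when no group differs),
#'   `dunnett` (the full comparison table).
#' @export
turning_point <- function(data, value = "strain", age = "age", alpha = 0.05,
                          seed = 1L, R = 1e5) {
  ages <- data[[age]]
  if (!is.numeric(ages)) stop_fmt("turning_point: '%s' must be numeric", age)
  u <- sort(unique(ages))
  if (length(u) < 3) stop_fmt("turning_point: need at least 3 age groups")
  dn <- dunnett_mc(data[[value]], ages, baseline = u[1], alpha = alpha,
                   R = R, seed = seed)
  sig_ages <- as.numeric(dn$group[dn$significant])
  list(age = if (length(sig_ages)) min(sig_ages) else NA_real_,
       dunnett = dn)
}
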