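## Group comparisons ---------------------------------------------------------
##
## Two-group measures are compared with pooled-variance Student t-tests
## (df = n1 + n2 - 2), three-group measures with one-way ANOVA, and each
## two-group test is accompanied by a default Jeffreys-Zellner-Siow Bayes
## factor (Cauchy prior with scale sqrt(2)/2 on the standardized effect).
## No multiple-testing correction is applied; each measure is tested
## separately.

#' Pooled two-sample t-test
#'
#' Student's t-test with pooled variance (so two groups of 41 give the
#' conventional df = 80), two-sided. A Welch test is available via
#' `var_equal = FALSE`. The degenerate case of zero variance in both groups
#' with equal means returns t = 0, p = 1.
#'
#' @param a,b Numeric vectors (one per group), n >= 2 each.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE).
#' @return A list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    return(list(statistic = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' One-way between-subjects ANOVA
#'
#' Standard between/within decomposition over two or more groups. Zero
#' variance everywhere with equal means returns F = 0, p = 1.
#'
#' @param groups A list of numeric vectors, each n >= 2.
#' @return A list with `statistic` (F), `df` (c(df1, df2)), `p_value`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  k <- length(groups)
  n <- sum(vapply(groups, length, 1L))
  dfs <- c(k - 1, n - k)
  if (all(vapply(groups, sd, 1) == 0)) {
    m <- vapply(groups, mean, 1)
    if (max(m) == min(m)) return(list(statistic = 0, df = dfs, p_value = 1))
    return(list(statistic = Inf, df = dfs, p_value = 0))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), vapply(groups, length, 1L)))
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(ft$parameter), p_value = ft$p.value)
}

#' Default Bayes factor from a t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor BF10 for a two-sample design, from
#' the observed t statistic. The alternative places a Cauchy prior with
#' scale `scale` on the standardized effect size; writing that prior as a
#' scale mixture of normals, the marginal likelihood ratio reduces to a
#' one-dimensional integral over the mixing variance g,
#' `BF10 = Int (1 + N g s^2)^(-1/2) * (1 + t^2 / (nu (1 + N g s^2)))^(-(nu+1)/2)
#'  * (2 pi)^(-1/2) g^(-3/2) exp(-1/(2g)) dg / (1 + t^2/nu)^(-(nu+1)/2)`,
#' with `N = n1 n2 / (n1 + n2)` and `nu = n1 + n2 - 2`, evaluated by
#' adaptive quadrature.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes.
#' @param scale Cauchy prior scale (default sqrt(2)/2 = 0.707...).
#' @return BF10 (> 1 favors a group difference; < 1/3 is conventionally
#'   moderate support for the null).
#' @export
bf10_from_t <- function(t, n1, n2, scale = sqrt(2) / 2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  neff <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  f <- function(g) {
    q <- 1 + neff * g * scale^2
    q^(-0.5) * (1 + t^2 / (nu * q))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  num <- tryCatch(
    integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value,
    error = function(e) stop("Bayes factor quadrature failed: ",
                             conditionMessage(e), call. = FALSE))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

#' Default Bayes factor for a two-group comparison
#'
#' @param a,b Numeric vectors (one per group).
#' @param scale Cauchy prior scale on the standardized effect.
#' @return BF10.
#' @seealso [bf10_from_t()]
#' @export
bayes_factor_ttest <- function(a, b, scale = sqrt(2) / 2) {
  tt <- two_sample_t(a, b)
  bf10_from_t(tt$statistic, sum(is.finite(a)), sum(is.finite(b)), scale = scale)
}

measure_labels <- function() {
  c(rate_d1 = "Initial adaptation rate",
    extent_d1 = "Initial adaptation extent",
    aftereffect_d1 = "First cycle of decay",
    residue_d1 = "Decay residue",
    crossday = "Cross-day retention",
    rate_d2 = "Re-adaptation rate",
    extent_d2 = "Re-adaptation extent",
    aftereffect_d2 = "First cycle of decay (day 2)",
    residue_d2 = "Decay residue (day 2)",
    rt_d2 = "Reaction time",
    delta_rt_d2 = "Delta RT")
}

fmt_cell <- function(x, unit) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_character_)
  if (unit == "ms") sprintf("%.0f ± %.0f ms", mean(x), sd(x))
  else if (unit == "deg") sprintf("%.2f ± %.2f°", mean(x), sd(x))
  else sprintf("%.2f ± %.2f", mean(x), sd(x))
}

measure_unit <- function(m, gradual = FALSE) {
  if (m %in% c("rt_d2", "delta_rt_d2")) "ms"
  else if (m == "rate_d1" && gradual) "unitless"
  else "deg"
}

#' Group-comparison report
#'
#' Builds a publication-style table over the per-participant adaptation
#' summaries: one row per measure with per-group "mean +- SD" cells and,
#' for two groups, the pooled t statistic, df, p and JZS Bayes factor; for
#' three or more groups the one-way ANOVA F, (df1, df2) and p. Decay-rate
#' rows (bootstrap CIs) can be appended via `decay_fits`, a named list of
#' label -> named list of per-group [bootstrap_decay()] fits.
#'
#' @param summary Per-participant summary tibble from
#'   [summarize_adaptation()] (columns `participant`, `group` and measure
#'   columns).
#' @param decay_fits Optional named list; each element a named (by group)
#'   list of `decay_fit` objects, keyed by row label.
#' @param gradual Was the day-1 learning phase a gradual ramp (affects the
#'   unit of the day-1 rate).
#' @param scale Cauchy prior scale for the Bayes factors.
#' @return Tibble with columns `measure`, one formatted cell per group,
#'   `statistic`, `df`, `p_value`, `bf10`.
#' @export
build_report <- function(summary, decay_fits = NULL, gradual = FALSE,
                         scale = sqrt(2) / 2) {
  groups <- unique(summary$group)
  measures <- intersect(names(measure_labels()), names(summary))
  rows <- vector("list", 0)
  for (m in measures) {
    unit <- measure_unit(m, gradual)
    vals <- lapply(groups, function(g) summary[[m]][summary$group == g])
    cells <- vapply(vals, fmt_cell, "", unit = unit)
    names(cells) <- groups
    stat <- df <- p <- bf <- NA_real_
    dfs <- NA_character_
    ok <- vapply(vals, function(v) sum(is.finite(v)) >= 2, TRUE)
    if (length(groups) == 2 && all(ok)) {
      tt <- two_sample_t(vals[[1]], vals[[2]])
      stat <- abs(tt$statistic); dfs <- as.character(tt$df); p <- tt$p_value
      bf <- bf10_from_t(tt$statistic, sum(is.finite(vals[[1]])),
                        sum(is.finite(vals[[2]])), scale = scale)
    } else if (length(groups) > 2 && all(ok)) {
      an <- oneway_anova(vals)
      stat <- an$statistic
      dfs <- paste(an$df, collapse = ", ")
      p <- an$p_value
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      measure = unname(measure_labels()[m]),
      !!!as.list(cells), statistic = stat, df = dfs,
      p_value = p, bf10 = bf)
  }
  tab <- dplyr::bind_rows(rows)

  if (!is.null(decay_fits)) {
    for (lab in names(decay_fits)) {
      fits <- decay_fits[[lab]]
      cells <- vapply(groups, function(g) {
        if (g %in% names(fits)) format_ci(fits[[g]]) else NA_character_
      }, "")
      names(cells) <- groups
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        measure = lab, !!!as.list(cells), statistic = NA_real_,
        df = NA_character_, p_value = NA_real_, bf10 = NA_real_))
    }
  }
  tab
}

#' Render a report table as aligned text
#'
#' @param report Output of [build_report()].
#' @return Character vector of lines (also printed via `cat` when
#'   `print = TRUE`).
#' @param print Print to the console.
#' @export
format_report <- function(report, print = TRUE) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "",
                                                formatC(x, digits = 3, format = "fg")))
  df[is.na(df)] <- ""
  widths <- pmax(nchar(names(df)), apply(df, 2, function(col) max(nchar(col), 0)))
  fmt_row <- function(cells) paste(mapply(formatC, cells, width = widths,
                                          MoreArgs = list(flag = "-")),
                                   collapse = "  ")
  lines <- c(fmt_row(names(df)), fmt_row(rep("-", ncol(df))),
             apply(df, 1, fmt_row))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
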