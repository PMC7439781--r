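#' Split a cohort into nondilated and dilated groups by aortic Z score
#'
#' Ranks patients by the ascending-aortic-diameter Z score and assigns the
#' lower half to the nondilated group and the upper half to the dilated
#' group. Ties are broken by patient id (lexicographic), so the split is
#' deterministic and invariant to input order. The cohort size must be
#' even.
#'
#' @param cohort data.frame with at least columns `id` and `z_score`.
#' @return the cohort with a `group` factor column
#'   (`"nondilated"`/`"dilated"`), rows in the original order.
#' @export
split_by_zscore <- function(cohort) {
  if (!all(c("id", "z_score") %in% names(cohort)))
    stop("cohort needs columns 'id' and 'z_score'")
  n <- nrow(cohort)
  if (n %% 2 != 0) stop("configuration error: cohort size must be even")
  ord <- order(cohort$z_score, as.character(cohort$id))
  grp <- character(n)
  grp[ord[seq_len(n / 2)]] <- "nondilated"
  grp[ord[seq(n / 2 + 1, n)]] <- "dilated"
  cohort$group <- factor(grp, levels = c("nondilated", "dilated"))
  cohort
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length >= 2.
#' @return named vector `c(mean, sd)` (sample SD, n - 1 denominator).
#' @export
summarize_values <- function(values) {
  if (length(values) < 2) stop("degenerate sample: need n >= 2")
  if (anyNA(values) || !all(is.finite(values))) stop("values must be finite")
  c(mean = mean(values), sd = stats::sd(values))
}

#' Shapiro-Wilk normality p-value
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return p-value.
#' @export
normality_p <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::var(values) == 0)
    stop("degenerate sample: constant values")
  stats::shapiro.test(values)$p.value
}

#' Levene's test for equality of variances between two groups
#'
#' Median-centered by default (the Brown-Forsythe variant), which is the
#' variant this pipeline's reference tables were produced with; the
#' mean-centered variant is available through `center`.
#'
#' @param values_a,values_b numeric vectors, each n >= 2.
#' @param center `"median"` (default) or `"mean"`.
#' @return p-value.
#' @export
variance_equality_p <- function(values_a, values_b,
                                center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("degenerate sample: each group needs n >= 2")
  y <- c(values_a, values_b)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  centerfun <- if (center == "median") stats::median else mean
  # groups of 2 saturate the ANOVA on absolute deviations; the fit warning
  # is expected there and the p-value is still well-defined
  tab <- withCallingHandlers(
    car::leveneTest(y, g, center = centerfun),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- tab[["Pr(>F)"]][1]
  if (is.nan(p)) 1 else p  # identical dispersion in both groups
}

#' Two-sample comparison following the Levene-gated t-test protocol
#'
#' Runs the small-sample inference protocol: Shapiro-Wilk normality per
#' group (recorded), Levene's test (median-centered) on the two groups,
#' then a pooled-variance Student t-test when the Levene p-value exceeds
#' `alpha` and a Welch unequal-variances t-test otherwise. All tests are
#' two-sided. Normality is recorded but does not gate the choice by
#' default; with `gate_normality = TRUE` a Shapiro-Wilk p below `alpha`
#' in either group switches to a Wilcoxon rank-sum test instead
#' (`test_used = "nonparametric"`).
#'
#' @param values_a,values_b numeric vectors (e.g. nondilated, dilated).
#' @param alpha decision threshold for the gates, default 0.05.
#' @param gate_normality logical; strict mode, see above.
#' @param labels length-2 character, names of the groups.
#' @return object of class `group_comparison`: list with `shapiro_p`
#'   (per group), `levene_p`, `test_used`, `t_statistic`, `p_value`,
#'   `means`, `sds`, `n`, `labels`.
#' @examples
#' compare_groups(rnorm(10), rnorm(10, 1))
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           gate_normality = FALSE,
                           labels = c("nondilated", "dilated")) {
  sa <- summarize_values(values_a)
  sb <- summarize_values(values_b)
  # Shapiro-Wilk needs n >= 3; smaller groups get NA recorded
  shap <- c(if (length(values_a) >= 3) normality_p(values_a) else NA_real_,
            if (length(values_b) >= 3) normality_p(values_b) else NA_real_)
  names(shap) <- labels
  lev <- variance_equality_p(values_a, values_b)
  if (gate_normality && any(shap < alpha)) {
    wt <- stats::wilcox.test(values_a, values_b, exact = FALSE)
    test_used <- "nonparametric"
    t_stat <- unname(wt$statistic)
    p_val <- wt$p.value
  } else {
    equal_var <- lev > alpha
    tt <- stats::t.test(values_a, values_b, var.equal = equal_var)
    test_used <- if (equal_var) "student" else "welch"
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  structure(
    list(shapiro_p = shap, levene_p = lev, test_used = test_used,
         t_statistic = t_stat, p_value = p_val,
         means = stats::setNames(c(sa["mean"], sb["mean"]), labels),
         sds = stats::setNames(c(sa["sd"], sb["sd"]), labels),
         n = stats::setNames(c(length(values_a), length(values_b)), labels),
         alpha = alpha, labels = labels),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s vs %s):\n", x$labels[1], x$labels[2]))
  cat(sprintf("  %s: %.4g +/- %.4g (n=%d); %s: %.4g +/- %.4g (n=%d)\n",
              x$labels[1], x$means[1], x$sds[1], x$n[1],
              x$labels[2], x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("  Shapiro-Wilk p: %.3g / %.3g; Levene p: %.3g\n",
              x$shapiro_p[1], x$shapiro_p[2], x$levene_p))
  cat(sprintf("  %s test: statistic %.4g, p = %.4g\n",
              x$test_used, x$t_statistic, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a categorical variable
#'
#' The nonparametric comparison used for categorical fields such as sex.
#'
#' @param values_a,values_b vectors of category labels per group.
#' @return p-value.
#' @export
categorical_p <- function(values_a, values_b) {
  tab <- table(
    group = rep(c("a", "b"), c(length(values_a), length(values_b))),
    value = c(as.character(values_a), as.character(values_b)))
  stats::fisher.test(tab)$p.value
}

#' Build per-metric results tables with summary and test rows
#'
#' From a long table of per-patient metric values (columns `metric`,
#' `phase`, `group`, `value`, optionally `units`), builds for each
#' metric/phase the rendered table analog: values sorted ascending within
#' each group, plus Mean, SD, Shapiro-Wilk p, Levene p and the two-sample
#' p-value from [compare_groups()]. Missing metric/group combinations are
#' listed in a completeness report rather than silently dropped.
#'
#' @param metrics long-format data.frame as above.
#' @param alpha,gate_normality passed to [compare_groups()].
#' @return object of class `results_tables`: list of per-metric entries
#'   (`values` data.frame, `comparison`), plus `incomplete`, a character
#'   vector of metric/phase keys that lacked both groups.
#' @export
build_results_tables <- function(metrics, alpha = 0.05,
                                 gate_normality = FALSE) {
  stopifnot(all(c("metric", "phase", "group", "value") %in% names(metrics)))
  keys <- unique(metrics[, c("metric", "phase")])
  out <- list()
  incomplete <- character()
  for (k in seq_len(nrow(keys))) {
    m <- keys$metric[k]
    ph <- keys$phase[k]
    sub <- metrics[metrics$metric == m & metrics$phase == ph, ]
    va <- sort(sub$value[sub$group == "nondilated"])
    vb <- sort(sub$value[sub$group == "dilated"])
    key <- paste(m, ph, sep = ".")
    if (length(va) < 2 || length(vb) < 2) {
      incomplete <- c(incomplete, key)
      next
    }
    cmp <- compare_groups(va, vb, alpha = alpha,
                          gate_normality = gate_normality)
    pad <- max(length(va), length(vb))
    out[[key]] <- list(
      metric = m, phase = ph,
      units = if ("units" %in% names(sub)) sub$units[1] else NA_character_,
      values = data.frame(rank = seq_len(pad),
                          nondilated = c(va, rep(NA, pad - length(va))),
                          dilated = c(vb, rep(NA, pad - length(vb)))),
      comparison = cmp)
  }
  structure(list(tables = out, incomplete = incomplete),
            class = "results_tables")
}

#' @export
print.results_tables <- function(x, ...) {
  for (tb in x$tables) {
    cmp <- tb$comparison
    cat(sprintf("%s (%s pressure)%s\n", tb$metric, tb$phase,
                if (is.na(tb$units)) "" else paste0(" [", tb$units, "]")))
    cat(sprintf("  Mean +/- SD: %0.2f +/- %0.2f | %0.2f +/- %0.2f\n",
                cmp$means[1], cmp$sds[1], cmp$means[2], cmp$sds[2]))
    cat(sprintf("  Shapiro-Wilk: %0.2f | %0.2f   Levene: %0.2f   p value (%s): %0.3f\n",
                cmp$shapiro_p[1], cmp$shapiro_p[2], cmp$levene_p,
                cmp$test_used, cmp$p_value))
  }
  if (length(x$incomplete))
    cat("incomplete:", paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

#' Write results tables to CSV
#'
#' One CSV per metric/phase (sorted values plus summary rows) under `dir`.
#'
#' @param tables a [build_results_tables()] result.
#' @param dir output directory, created if needed.
#' @return paths written, invisibly.
#' @export
write_results_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (key in names(tables$tables)) {
    tb <- tables$tables[[key]]
    cmp <- tb$comparison
    df <- tb$values
    extra <- data.frame(
      rank = NA_integer_,
      nondilated = c(cmp$means[1], cmp$sds[1], cmp$shapiro_p[1],
                     cmp$levene_p, cmp$p_value),
      dilated = c(cmp$means[2], cmp$sds[2], cmp$shapiro_p[2], NA, NA))
    rownames(extra) <- NULL
    df <- rbind(df, extra)
    df$row <- c(rep("value", nrow(tb$values)),
                "mean", "sd", "shapiro_p", "levene_p", "p_value")
    path <- file.path(dir, paste0(key, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
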