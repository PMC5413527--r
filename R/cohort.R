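#' Run the per-subject pipeline over a simulated cohort
#'
#' Generates every subject of a [cohort_spec()], runs [analyze_study()] on
#' each study and collects one record per subject. Failures are flagged in
#' the `ok`/`message` columns, never silently dropped. Fully deterministic
#' under the cohort seed.
#'
#' @param cohort a [cohort_spec()].
#' @param config a [dyssync_config()]; `config$volumes` selects whether
#'   EDV/ESV/EF come from the threshold estimator or from phantom truth.
#' @param progress print one line per subject.
#' @return a data frame of class `cohort_table` with columns `id`, `sex`,
#'   `edv_ml`, `esv_ml`, `ef_pct`, `psd_deg`, `bandwidth_deg`,
#'   `entropy_pct`, `mdtes_pct`, `sdtes_pct`, `dtes_ls_pct`, `seed`, `ok`,
#'   `message`. Entropy is reported in percent, the table convention.
#' @export
run_cohort <- function(cohort, config = dyssync_config(), progress = FALSE) {
  subjects <- make_cohort(cohort)
  empty <- data.frame(id = character(), sex = character(),
                      edv_ml = numeric(), esv_ml = numeric(),
                      ef_pct = numeric(), psd_deg = numeric(),
                      bandwidth_deg = numeric(), entropy_pct = numeric(),
                      mdtes_pct = numeric(), sdtes_pct = numeric(),
                      dtes_ls_pct = numeric(), seed = integer(),
                      ok = logical(), message = character(),
                      stringsAsFactors = FALSE)
  if (!length(subjects)) {
    class(empty) <- c("cohort_table", "data.frame")
    return(empty)
  }
  rows <- lapply(subjects, function(sub) {
    rec <- tryCatch({
      study <- generate_study(sub$spec)
      an <- analyze_study(study, config)
      vols <- if (config$volumes == "truth")
        list(edv_ml = sub$truth$edv_ml, esv_ml = sub$truth$esv_ml,
             ef_pct = 100 * sub$truth$ef)
      else an$volumes
      data.frame(id = sub$id, sex = sub$sex,
                 edv_ml = vols$edv_ml, esv_ml = vols$esv_ml,
                 ef_pct = vols$ef_pct,
                 psd_deg = an$metrics$psd_deg,
                 bandwidth_deg = as.numeric(an$metrics$bandwidth_deg),
                 entropy_pct = 100 * an$metrics$entropy,
                 mdtes_pct = if (is.null(an$tes)) NA_real_
                             else an$tes$mdtes_pct,
                 sdtes_pct = if (is.null(an$tes)) NA_real_
                             else an$tes$sdtes_pct,
                 dtes_ls_pct = if (is.null(an$tes)) NA_real_
                               else an$tes$dtes_ls_pct,
                 seed = sub$spec$seed, ok = TRUE, message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = sub$id, sex = sub$sex, edv_ml = NA_real_,
                 esv_ml = NA_real_, ef_pct = NA_real_, psd_deg = NA_real_,
                 bandwidth_deg = NA_real_, entropy_pct = NA_real_,
                 mdtes_pct = NA_real_, sdtes_pct = NA_real_,
                 dtes_ls_pct = NA_real_, seed = sub$spec$seed, ok = FALSE,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if (progress) cat(rec$id, rec$sex, if (rec$ok) "ok" else rec$message, "\n")
    rec
  })
  out <- do.call(rbind, rows)
  attr(out, "cohort") <- cohort
  attr(out, "config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

metric_column <- function(table, metric) {
  if (!metric %in% names(table))
    stop("validation error: unknown metric '", metric, "'")
  table[[metric]]
}

#' Compare a metric between the sexes by one-way ANOVA
#'
#' With two groups this is equivalent to the two-sample t test; reported as
#' the F statistic and p-value, plus group means and SDs.
#'
#' @param table a [run_cohort()] table (or any data frame with a `sex`
#'   column).
#' @param metric column name, e.g. `"psd_deg"`.
#' @return list with `f`, `p`, `means`, `sds`, `n`.
#' @export
compare_sexes <- function(table, metric) {
  value <- metric_column(table, metric)
  keep <- !is.na(value) & !is.na(table$sex)
  value <- value[keep]; sex <- factor(table$sex[keep])
  if (nlevels(sex) < 2 || any(tabulate(sex) < 2))
    stop("validation error: both groups need n >= 2")
  fit <- stats::lm(value ~ sex)
  an <- stats::anova(fit)
  list(f = an$`F value`[1], p = an$`Pr(>F)`[1],
       means = tapply(value, sex, mean), sds = tapply(value, sex, sd),
       n = tabulate(sex))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact p-value by enumeration when both groups have at most 10
#' observations and no ties; otherwise the normal approximation with tie
#' correction. All-tied data returns p = 1 with `flag = "all tied"`.
#'
#' @param table cohort table, or a numeric vector (first group) when `y` is
#'   given.
#' @param metric metric column name (table interface).
#' @param groups list of two index/logical vectors defining the groups.
#' @param y second group (vector interface).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic`, `p`, `n`, and optionally `flag`.
#' @export
wilcoxon_groups <- function(table, metric = NULL, groups = NULL, y = NULL,
                            alternative = "two.sided") {
  if (is.numeric(table) && !is.null(y)) {
    x <- table
  } else {
    value <- metric_column(table, metric)
    if (is.null(groups) || length(groups) != 2)
      stop("validation error: need two group definitions")
    x <- value[groups[[1]]]; y <- value[groups[[2]]]
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("validation error: empty group")
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                n = c(length(x), length(y)), flag = "all tied"))
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)))
}

# 95% confidence interval for a Pearson correlation via the Fisher
# z-transform.
fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param table cohort table, or a numeric vector when `y` is given.
#' @param x,y metric column names (table interface) or numeric vectors.
#' @return list with `r`, `ci_low`, `ci_high`, `p`, `n`; zero variance in
#'   either variable yields `r = NA` with `flag = "undefined"`.
#' @export
correlate <- function(table, x, y = NULL) {
  if (is.numeric(table) && is.numeric(x)) {
    xv <- table; yv <- x
  } else {
    xv <- metric_column(table, x); yv <- metric_column(table, y)
  }
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 4) stop("validation error: need n >= 4")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, n = n, flag = "undefined"))
  r <- stats::cor(xv, yv)
  ci <- fisher_ci(r, n)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci_low = ci[1], ci_high = ci[2],
       p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Ordinary least-squares regression of one metric on another
#'
#' @param table cohort table, or a numeric predictor vector when `y` is
#'   given.
#' @param x,y metric column names or numeric vectors (`y ~ x`).
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
regress <- function(table, x, y = NULL) {
  if (is.numeric(table) && is.numeric(x)) {
    xv <- table; yv <- x
  } else {
    xv <- metric_column(table, x); yv <- metric_column(table, y)
  }
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("validation error: need n >= 3")
  if (stats::sd(xv) == 0) stop("validation error: zero x-variance")
  fit <- stats::lm(yv ~ xv)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary warning
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = sm$coefficients[2, 4],
       n = length(xv))
}

#' Volume-matched sex contrast
#'
#' Compares males with smaller hearts against females with larger hearts —
#' the design that asks whether a sex difference survives once ventricular
#' volume is matched. Default thresholds are the per-sex EDV medians of the
#' table itself. The EDV balance check is reported first; each metric is
#' then compared by the Wilcoxon rank-sum test.
#'
#' @param table a [run_cohort()] table.
#' @param male_max_edv males with EDV strictly below this enter (default:
#'   male median).
#' @param female_min_edv females with EDV at or above this enter (default:
#'   female median).
#' @param metrics metric columns to compare.
#' @return list with `n`, `thresholds`, `edv_balance`, and one Wilcoxon
#'   result per metric.
#' @export
volume_matched_contrast <- function(table, male_max_edv = NULL,
                                    female_min_edv = NULL,
                                    metrics = c("psd_deg", "bandwidth_deg",
                                                "entropy_pct")) {
  ok <- !is.na(table$edv_ml)
  male <- ok & table$sex == "M"
  female <- ok & table$sex == "F"
  if (is.null(male_max_edv))
    male_max_edv <- stats::median(table$edv_ml[male])
  if (is.null(female_min_edv))
    female_min_edv <- stats::median(table$edv_ml[female])
  g_m <- which(male & table$edv_ml < male_max_edv)
  g_f <- which(female & table$edv_ml >= female_min_edv)
  if (!length(g_m) || !length(g_f))
    stop("validation error: empty volume-matched subgroup")
  out <- list(n = c(male = length(g_m), female = length(g_f)),
              thresholds = c(male_max_edv = male_max_edv,
                             female_min_edv = female_min_edv),
              edv_balance = wilcoxon_groups(table, "edv_ml",
                                            list(g_m, g_f)))
  for (m in metrics)
    out[[m]] <- wilcoxon_groups(table, m, list(g_m, g_f))
  out
}

#' Normal-database style cohort report
#'
#' Renders the standard summary of a simulated normal cohort: per-sex means
#' with ANOVA p-values, normal limits (mean +/- 2 SD), pairwise metric
#' correlations, and the volume-matched sex contrast.
#'
#' @param table a [run_cohort()] table.
#' @param metrics metric columns to summarize.
#' @return invisibly, a list with the computed pieces.
#' @export
report_cohort <- function(table,
                          metrics = c("ef_pct", "edv_ml", "esv_ml",
                                      "psd_deg", "bandwidth_deg",
                                      "entropy_pct")) {
  tab <- table[table$ok & !is.na(table$psd_deg), , drop = FALSE]
  if (!nrow(tab)) {
    cat("no subjects\n")
    return(invisible(list(n = 0)))
  }
  cat(sprintf("Cohort: %d subjects (%d M / %d F)%s\n", nrow(tab),
              sum(tab$sex == "M"), sum(tab$sex == "F"),
              if (any(!table$ok)) sprintf(" [%d failed]", sum(!table$ok))
              else ""))
  res <- list(n = nrow(tab))
  cat("\nMetric            male mean+-SD  female mean+-SD   P (ANOVA)\n")
  for (m in metrics) {
    cs <- tryCatch(compare_sexes(tab, m), error = function(e) NULL)
    if (is.null(cs)) next
    cat(sprintf("%-16s %7.1f+-%-5.1f  %7.1f+-%-5.1f   %8.4f\n", m,
                cs$means["M"], cs$sds["M"], cs$means["F"], cs$sds["F"],
                cs$p))
    res$sex[[m]] <- cs
  }
  cat("\nNormal limits (mean +- 2SD):\n")
  for (m in metrics) {
    nl <- normal_limits(tab[[m]])
    cat(sprintf("%-16s %7.1f +- %-5.1f  [%.1f, %.1f]\n", m, nl$mean, nl$sd,
                nl$lower, nl$upper))
    res$limits[[m]] <- nl
  }
  dys <- intersect(c("psd_deg", "bandwidth_deg", "entropy_pct"), metrics)
  if (length(dys) > 1) {
    cat("\nPairwise correlations:\n")
    for (i in seq_along(dys)) for (j in seq_along(dys)) if (i < j) {
      co <- correlate(tab, dys[i], dys[j])
      cat(sprintf("%s ~ %s: r = %.2f (95%% CI %.2f-%.2f), P = %.4f\n",
                  dys[i], dys[j], co$r, co$ci_low, co$ci_high, co$p))
      res$cor[[paste(dys[i], dys[j], sep = "~")]] <- co
    }
  }
  vm <- tryCatch(volume_matched_contrast(tab), error = function(e) NULL)
  if (!is.null(vm)) {
    cat(sprintf("\nVolume-matched contrast (M < %.0f mL, n = %d vs F >= %.0f mL, n = %d):\n",
                vm$thresholds[1], vm$n[1], vm$thresholds[2], vm$n[2]))
    cat(sprintf("  EDV balance P = %.2f\n", vm$edv_balance$p))
    for (m in c("psd_deg", "bandwidth_deg", "entropy_pct"))
      if (!is.null(vm[[m]]))
        cat(sprintf("  %-14s P = %.4f\n", m, vm[[m]]$p))
    res$volume_matched <- vm
  }
  invisible(res)
}
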