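#' @include AllClasses.R
NULL

.TIME_BIN_LABELS <- c("<=96h", "4-7d", "8-21d", ">=22d")

#' Assign times to the clinical follow-up bins
#'
#' Bins partition the positive time axis as \[0, 96) hours, \[96, 168\]
#' hours (4-7 days; a recorded "4 days" = 96 h falls here), (168, 504\]
#' hours (8-21 days), and (504, Inf) hours (>= 22 days).  The same edge
#' rule is used for onset and post-treatment times.
#'
#' @param time_h positive time(s) in hours.
#' @return factor with levels `<=96h`, `4-7d`, `8-21d`, `>=22d`.
#' @examples
#' assignTimeBin(c(12, 96, 168, 169, 34 * 24))
#' @export
assignTimeBin <- function(time_h) {
  if (any(!is.finite(time_h)) || any(time_h <= 0))
    stop("times must be positive and finite")
  idx <- ifelse(time_h < 96, 1L,
         ifelse(time_h <= 168, 2L,
         ifelse(time_h <= 504, 3L, 4L)))
  factor(.TIME_BIN_LABELS[idx], levels = .TIME_BIN_LABELS)
}

.statResult <- function(method, statistic, p_value, df = NA_real_,
                        estimate = NA_real_, group_ns = NULL,
                        pairwise = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, df = df, estimate = estimate,
                 group_ns = group_ns, pairwise = pairwise),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (LSD, unadjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance).
#' @return a `StatResult` with `estimate` = r.
#' @export
pearsonCor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  .statResult("Pearson correlation", statistic = unname(ct$statistic),
              p_value = ct$p.value, df = unname(ct$parameter),
              estimate = unname(ct$estimate), group_ns = length(x))
}

#' One-way ANOVA with LSD post-hoc comparisons
#'
#' Fisher's F across groups, followed by the least-significant-difference
#' test: for every pair, a two-sided t-test on the group means using the
#' pooled within-group mean square and its residual degrees of freedom,
#' deliberately without any multiplicity adjustment (that is the
#' definition of LSD).  Groups with fewer than 2 observations are
#' reported in `group_ns` but excluded from the model.
#'
#' @param groups named list of numeric vectors.
#' @return a `StatResult`; `pairwise` holds the LSD table.
#' @export
anovaLSD <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  ns_all <- vapply(groups, length, integer(1))
  keep <- groups[ns_all >= 2L]
  if (length(keep) < 2L) stop("need at least 2 groups with n >= 2")
  v <- unlist(keep, use.names = FALSE)
  g <- factor(rep(names(keep), vapply(keep, length, integer(1))),
              levels = names(keep))
  if (stats::var(v) == 0)
    stop("all values identical across groups: F undefined")
  an <- stats::anova(stats::lm(v ~ g))
  mse <- an[["Mean Sq"]][2L]
  df_res <- an[["Df"]][2L]
  means <- vapply(keep, mean, numeric(1))
  ns <- vapply(keep, length, numeric(1))
  pairs <- utils::combn(names(keep), 2L)
  pw <- do.call(rbind, apply(pairs, 2L, function(p) {
    d <- means[p[1L]] - means[p[2L]]
    se <- sqrt(mse * (1 / ns[p[1L]] + 1 / ns[p[2L]]))
    tt <- d / se
    data.frame(group1 = p[1L], group2 = p[2L], diff = d, t = tt,
               p = 2 * stats::pt(-abs(tt), df_res))
  }))
  rownames(pw) <- NULL
  .statResult("one-way ANOVA + LSD", statistic = an[["F value"]][1L],
              p_value = an[["Pr(>F)"]][1L],
              df = c(an[["Df"]][1L], df_res), group_ns = ns_all,
              pairwise = pw)
}

#' Independent-samples t-test
#'
#' Pooled-variance (equal-variance) two-sided t-test by default, the
#' common clinical-statistics convention; a Welch variant is available
#' behind `var_equal = FALSE`.  With zero pooled variance the statistic
#' is defined as 0 (p = 1) when the means agree and is an error
#' otherwise.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal use the pooled-variance form (default TRUE).
#' @return a `StatResult`; `estimate` is the mean difference `a - b`.
#' @export
ttestInd <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(.statResult("independent-samples t-test", 0, 1,
                         df = length(a) + length(b) - 2,
                         estimate = 0, group_ns = c(length(a), length(b))))
    stop("zero variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  .statResult("independent-samples t-test",
              statistic = unname(tt$statistic), p_value = tt$p.value,
              df = unname(tt$parameter),
              estimate = mean(a) - mean(b),
              group_ns = c(length(a), length(b)))
}

.meanSdRow <- function(v) {
  v <- v[is.finite(v)]
  data.frame(n = length(v),
             mean = if (length(v)) mean(v) else NA_real_,
             sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
}

#' Build the treatment-response summary tables
#'
#' Reproduces the structure of the clinical analysis on a cohort table:
#'
#' * `by_post_treatment`: per post-treatment time bin, mean +/- SD and n
#'   of lesion APTW, CNAWM APTW, APTW contrast and NIHSS, with one-way
#'   ANOVA + LSD p-values of each post bin against the pre-treatment
#'   group;
#' * `by_onset`: within each onset-time bin, pre- vs post-treatment
#'   group summaries compared by independent-samples t-tests;
#' * `correlations`: Pearson r of each measure against onset time
#'   (untreated scans) and against post-treatment time and onset time
#'   (treated scans).
#'
#' Post-treatment scans of patients flagged `effective = FALSE` are
#' excluded throughout; empty bins are reported with n = 0 and excluded
#' from tests.
#'
#' @param cohort a validated cohort data.frame.
#' @param measures measurement columns to summarize.
#' @return list with data.frames `by_post_treatment`, `by_onset`,
#'   `correlations`.
#' @export
buildCohortTables <- function(cohort,
                              measures = c("lesion_aptw_pct",
                                           "cnawm_aptw_pct",
                                           "contrast_pct", "nihss")) {
  validateCohortTable(cohort)
  pre <- cohort[cohort$phase == "pre", , drop = FALSE]
  post <- cohort[cohort$phase == "post" &
                 !(cohort$effective %in% FALSE), , drop = FALSE]
  post$pt_bin <- if (nrow(post))
    assignTimeBin(post$post_treatment_time_h) else
    factor(character(), levels = .TIME_BIN_LABELS)

  t2 <- list()
  for (m in measures) {
    groups <- c(list(pre = pre[[m]][is.finite(pre[[m]])]),
                lapply(split(post[[m]], post$pt_bin),
                       function(v) v[is.finite(v)]))
    lsd <- tryCatch(anovaLSD(groups), error = function(e) NULL)
    for (gname in names(groups)) {
      row <- cbind(data.frame(measure = m, group = gname),
                   .meanSdRow(groups[[gname]]))
      row$p_vs_pre <- NA_real_
      if (!is.null(lsd) && gname != "pre") {
        hit <- lsd$pairwise$group1 == "pre" & lsd$pairwise$group2 == gname |
               lsd$pairwise$group2 == "pre" & lsd$pairwise$group1 == gname
        if (any(hit)) row$p_vs_pre <- lsd$pairwise$p[hit][1L]
      }
      t2[[length(t2) + 1L]] <- row
    }
  }
  t2 <- do.call(rbind, t2)

  pre$onset_bin <- assignTimeBin(pre$onset_time_h)
  post$onset_bin <- if (nrow(post)) assignTimeBin(post$onset_time_h) else
    factor(character(), levels = .TIME_BIN_LABELS)
  t3 <- list()
  for (bin in .TIME_BIN_LABELS) for (m in measures) {
    va <- pre[[m]][pre$onset_bin == bin]
    vb <- post[[m]][post$onset_bin == bin]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    tt <- if (length(va) >= 2L && length(vb) >= 2L)
      tryCatch(ttestInd(va, vb), error = function(e) NULL) else NULL
    t3[[length(t3) + 1L]] <- cbind(
      data.frame(onset_bin = bin, measure = m),
      setNames(.meanSdRow(va), c("n_pre", "mean_pre", "sd_pre")),
      setNames(.meanSdRow(vb), c("n_post", "mean_post", "sd_post")),
      data.frame(p = if (is.null(tt)) NA_real_ else tt$p_value))
  }
  t3 <- do.call(rbind, t3)

  corRows <- function(d, label, time_col) {
    do.call(rbind, lapply(setdiff(measures, "nihss"), function(m) {
      ok <- is.finite(d[[m]]) & is.finite(d[[time_col]])
      res <- if (sum(ok) >= 3L)
        tryCatch(pearsonCor(d[[m]][ok], d[[time_col]][ok]),
                 error = function(e) NULL) else NULL
      data.frame(subset = label, time_axis = time_col, measure = m,
                 n = sum(ok),
                 r = if (is.null(res)) NA_real_ else res$estimate,
                 p = if (is.null(res)) NA_real_ else res$p_value)
    }))
  }
  correlations <- rbind(
    corRows(pre, "untreated", "onset_time_h"),
    corRows(post, "treated", "post_treatment_time_h"),
    corRows(post, "treated", "onset_time_h"))

  list(by_post_treatment = t2, by_onset = t3, correlations = correlations)
}
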