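#' Two-way ANOVA with Tukey HSD post hoc
#'
#' Least-squares two-way factorial ANOVA of one climbing metric, followed by
#' Tukey's honestly-significant-difference pairwise comparisons. Undefined
#' metric values (e.g. velocities of motionless flies) are dropped listwise
#' with a logged count. Unbalanced designs use Type II sums of squares by
#' default (the conventional choice when interest is in main effects);
#' Type III (sum-to-zero contrasts) is available.
#'
#' @param data data frame, e.g. from [compute_metrics_table()].
#' @param response name of the response column.
#' @param factor_a,factor_b names of the two factor columns.
#' @param ss_type `"II"` (default) or `"III"`.
#' @param tukey `"cells"` (all pairwise comparisons of factor-level cells,
#'   default) or `"margins"` (marginal comparisons per factor).
#' @param alpha family-wise level for the Tukey intervals.
#' @return Object of class `anova_tukey`: list with `anova` (term table:
#'   `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`), `tukey` (data frame of
#'   pairwise comparisons with Tukey-adjusted p), `n_dropped`, `ss_type`.
#' @export
two_way_anova_tukey <- function(data, response, factor_a, factor_b,
                                ss_type = c("II", "III"),
                                tukey = c("cells", "margins"),
                                alpha = 0.05) {
  ss_type <- match.arg(ss_type)
  tukey <- match.arg(tukey)
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) stop("column not found: ", col)
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  keep <- is.finite(y) & !is.na(A) & !is.na(B)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " observation(s) with undefined '", response, "' dropped")
  y <- y[keep]; A <- droplevels(A[keep]); B <- droplevels(B[keep])
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need at least 2 levels after dropping undefined values")
  cells <- table(A, B)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s = %s, %s = %s", factor_a,
                 rownames(cells)[bad[1]], factor_b, colnames(cells)[bad[2]]))
  }
  df <- data.frame(y = y, A = A, B = B)
  full <- stats::lm(y ~ A * B, data = df)
  ss_res <- stats::deviance(full)
  df_res <- stats::df.residual(full)
  if (df_res == 0)
    stop("zero residual degrees of freedom (one observation per cell?)")
  rss <- function(form) stats::deviance(stats::lm(form, data = df))
  if (ss_type == "II") {
    ss_a <- rss(y ~ B) - rss(y ~ A + B)
    ss_b <- rss(y ~ A) - rss(y ~ A + B)
    ss_ab <- rss(y ~ A + B) - ss_res
  } else {
    X <- stats::model.matrix(~ A * B, df,
                             contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
    asn <- attr(X, "assign")
    rss_cols <- function(cols) {
      fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
      sum(fit$residuals^2)
    }
    drop_term <- function(k) rss_cols(which(asn != k)) - ss_res
    ss_a <- drop_term(1L); ss_b <- drop_term(2L); ss_ab <- drop_term(3L)
  }
  dfs <- c(nlevels(A) - 1L, nlevels(B) - 1L,
           (nlevels(A) - 1L) * (nlevels(B) - 1L), df_res)
  ss <- c(ss_a, ss_b, ss_ab, ss_res)
  ms <- ss / dfs
  Fv <- c(ms[1:3] / ms[4], NA)
  pv <- c(stats::pf(Fv[1:3], dfs[1:3], df_res, lower.tail = FALSE), NA)
  tab <- data.frame(term = c(factor_a, factor_b,
                             paste(factor_a, factor_b, sep = ":"), "Residuals"),
                    df = dfs, sum_sq = ss, mean_sq = ms, F = Fv, p = pv,
                    stringsAsFactors = FALSE)
  tuk <- if (tukey == "cells") {
    cell <- interaction(A, B, sep = ":", drop = TRUE)
    d2 <- data.frame(y = y, cell = cell)
    tidy_tukey(stats::TukeyHSD(stats::aov(y ~ cell, data = d2),
                               conf.level = 1 - alpha)$cell, "cell")
  } else {
    fit <- stats::aov(y ~ A + B, data = df)
    th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)
    rbind(tidy_tukey(th$A, factor_a), tidy_tukey(th$B, factor_b))
  }
  structure(list(anova = tab, tukey = tuk, n_dropped = n_dropped,
                 ss_type = ss_type, response = response),
            class = "anova_tukey")
}

tidy_tukey <- function(m, factor_name) {
  data.frame(factor = factor_name, comparison = rownames(m),
             diff = m[, "diff"], lwr = m[, "lwr"], upr = m[, "upr"],
             p_adj = m[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s SS) of %s\n", x$ss_type, x$response))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d undefined observation(s) dropped)\n", x$n_dropped))
  print(x$anova, row.names = FALSE, digits = 5)
  cat("\nTukey HSD:\n")
  print(x$tukey, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Exact two-sided p value computed by summing all hypergeometric table
#' probabilities not exceeding that of the observed table (at fixed margins).
#'
#' @param tab 2x2 matrix (or coercible) of non-negative integer counts with
#'   positive row and column margins.
#' @return Two-sided p value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("'tab' must be a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || !all(is_whole(tab)))
    stop("'tab' must contain non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(supp, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Marascuilo procedure for multiple proportions
#'
#' Omnibus chi-square comparison of several proportions followed by the
#' Marascuilo pairwise procedure: the pair `(i, j)` is significant when
#' `|p_i - p_j|` exceeds the critical range
#' `sqrt(qchisq(1 - alpha/m, g - 1)) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`,
#' with a Bonferroni correction over the `m` comparisons actually made. When
#' a control group is designated only control-versus-treatment pairs are
#' compared (and `m` defaults to their number); otherwise all pairs.
#'
#' @param k integer vector of successes per group.
#' @param n integer vector of group sizes.
#' @param labels group labels (defaults to `names(k)` or `g1, g2, ...`).
#' @param alpha significance level.
#' @param control optional label of the control group.
#' @param bonferroni_m Bonferroni divisor; defaults to the number of
#'   comparisons made.
#' @return Object of class `proportion_comparison`: `groups` table, omnibus
#'   `chisq`/`df`/`p`, `pairs` table (`|diff|`, critical range, significance),
#'   and `fisher_p` for two-group designs.
#' @export
marascuilo <- function(k, n, labels = NULL, alpha = 0.05, control = NULL,
                       bonferroni_m = NULL) {
  if (length(k) != length(n) || length(k) < 2)
    stop("need at least 2 groups with matching 'k' and 'n'")
  if (any(!is_whole(k)) || any(!is_whole(n)) || any(n < 1) || any(k < 0) || any(k > n))
    stop("counts must satisfy 0 <= k <= n, n >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  g <- length(k)
  labels <- labels %||% names(k) %||% paste0("g", seq_len(g))
  p <- k / n
  om <- suppressWarnings(stats::chisq.test(rbind(k, n - k), correct = FALSE))
  if (!is.null(control)) {
    ci <- match(control, labels)
    if (is.na(ci)) stop("control label not found: ", control)
    pairs <- cbind(ci, setdiff(seq_len(g), ci))
  } else {
    pairs <- t(utils::combn(g, 2))
  }
  m <- bonferroni_m %||% nrow(pairs)
  m <- check_count(m, "bonferroni_m", min = 1L)
  chi_crit <- stats::qchisq(1 - alpha / m, df = g - 1)
  i <- pairs[, 1]; j <- pairs[, 2]
  se <- sqrt(p[i] * (1 - p[i]) / n[i] + p[j] * (1 - p[j]) / n[j])
  crit <- sqrt(chi_crit) * se
  diffs <- abs(p[i] - p[j])
  pair_tab <- data.frame(group_i = labels[i], group_j = labels[j],
                         abs_diff = diffs, critical_range = crit,
                         significant = diffs > crit,
                         stringsAsFactors = FALSE)
  fisher_p <- if (g == 2)
    fisher_exact(matrix(c(k[1], n[1] - k[1], k[2], n[2] - k[2]), 2,
                        byrow = TRUE)) else NA_real_
  structure(list(groups = data.frame(label = labels, k = k, n = n,
                                     proportion = p, stringsAsFactors = FALSE),
                 chisq = unname(om$statistic), df = unname(om$parameter),
                 p = unname(om$p.value),
                 pairs = pair_tab, alpha = alpha, bonferroni_m = m,
                 fisher_p = fisher_p),
            class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("Marascuilo multiple-proportion comparison (alpha = %g, m = %d)\n",
              x$alpha, x$bonferroni_m))
  print(x$groups, row.names = FALSE, digits = 4)
  cat(sprintf("Omnibus chi-square = %.4g, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  print(x$pairs, row.names = FALSE, digits = 4)
  if (!is.na(x$fisher_p))
    cat(sprintf("Fisher exact (2 groups): p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' Therapeutic-window analysis of flight outcomes
#'
#' For each genotype and each treatment start day, runs a Fisher exact test
#' of nicotine-treated flies (dose > 0) against matched untreated flies
#' (dose 0; same start day when available, otherwise the genotype's pooled
#' untreated flies). The empirical window edge per genotype is the last start
#' day of the unbroken run of significant effects, in a consistent direction,
#' beginning at the earliest start day; `NA` when even the earliest day shows
#' no effect.
#'
#' @param flight data frame of flight records (see [read_flight_table()]).
#' @param alpha significance level for the per-day Fisher tests.
#' @return Object of class `window_analysis`: `table` (one row per
#'   genotype/start day) and `edges` (named integer vector per genotype,
#'   `NA` = no window).
#' @export
window_analysis <- function(flight, alpha = 0.05) {
  needed <- c("genotype", "dose_ug_per_ml", "start_day", "flew")
  missing_cols <- setdiff(needed, names(flight))
  if (length(missing_cols))
    stop("flight table is missing columns: ", paste(missing_cols, collapse = ", "))
  treated <- flight$dose_ug_per_ml > 0
  days <- sort(unique(flight$start_day[treated & !is.na(flight$start_day)]))
  if (length(days) < 2)
    stop("window analysis needs treated records spanning at least 2 start days")
  rows <- list()
  for (g in unique(flight$genotype)) {
    fg <- flight[flight$genotype == g, , drop = FALSE]
    for (d in days) {
      tr <- fg[fg$dose_ug_per_ml > 0 & !is.na(fg$start_day) & fg$start_day == d, ]
      un <- fg[fg$dose_ug_per_ml == 0 & !is.na(fg$start_day) & fg$start_day == d, ]
      if (!nrow(un)) un <- fg[fg$dose_ug_per_ml == 0, , drop = FALSE]
      if (!nrow(tr) || !nrow(un)) {
        message("stratum skipped (missing arm): genotype ", g, ", start day ", d)
        next
      }
      tab <- matrix(c(sum(tr$flew), sum(!tr$flew),
                      sum(un$flew), sum(!un$flew)), 2, byrow = TRUE)
      # a zero column margin (all flew or none flew in both arms) carries no
      # evidence of a difference
      pval <- if (any(colSums(tab) == 0)) 1 else fisher_exact(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, start_day = d,
        n_treated = nrow(tr), k_treated = sum(tr$flew),
        n_untreated = nrow(un), k_untreated = sum(un$flew),
        p_treated = mean(tr$flew), p_untreated = mean(un$flew),
        fisher_p = pval,
        significant = pval < alpha,
        direction = sign(mean(tr$flew) - mean(un$flew)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no testable genotype/start-day strata")
  edges <- sapply(unique(tab$genotype), function(g) {
    sub <- tab[tab$genotype == g, , drop = FALSE]
    sub <- sub[order(sub$start_day), , drop = FALSE]
    if (!nrow(sub) || !sub$significant[1]) return(NA_integer_)
    dir0 <- sub$direction[1]
    edge <- sub$start_day[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$significant[i] && sub$direction[i] == dir0)
        edge <- sub$start_day[i]
      else break
    }
    as.integer(edge)
  })
  structure(list(table = tab, edges = edges, alpha = alpha),
            class = "window_analysis")
}

#' @export
print.window_analysis <- function(x, ...) {
  cat(sprintf("Therapeutic-window analysis (alpha = %g)\n", x$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  cat("Window edges (last start day of unbroken significant run):\n")
  for (g in names(x$edges))
    cat(sprintf("  %s: %s\n", g,
                if (is.na(x$edges[[g]])) "none" else paste0("day ", x$edges[[g]])))
  invisible(x)
}
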