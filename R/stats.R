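sem <- function(x) stats::sd(x) / sqrt(length(x))

group_summary <- function(values, groups) {
  out <- do.call(rbind, lapply(split(values, groups), function(x) {
    data.frame(n = length(x), mean = mean(x), sem = sem(x))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n", "mean", "sem")]
}

#' Two-group comparison with a normality gate
#'
#' Mirrors the standard analysis pipeline: Shapiro-Wilk normality test on
#' each group at `alpha_normality`; when both pass, a two-sided Student's
#' t-test (pooled variance by default), otherwise a Mann-Whitney (Wilcoxon
#' rank-sum) test. Summaries are reported as mean +/- SEM (SEM uses the
#' n - 1 sd). Zero-variance degenerate inputs return p = 1 with
#' `test_name = "degenerate"`.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param alpha_normality normality-gate significance level (default 0.05).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return A `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `design = "two_group"`, `summary` (mean/SEM/n per group),
#'   `normality_p`.
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05,
                               var_equal = TRUE) {
  if (length(a) < 3 || length(b) < 3) stop("each sample must have n >= 3")
  summ <- group_summary(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  if (stats::var(c(a, b)) == 0) {
    return(structure(list(test_name = "degenerate", statistic = 0,
                          p_value = 1, design = "two_group",
                          summary = summ, normality_p = c(NA, NA)),
                     class = "group_comparison"))
  }
  sw <- function(x) if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  np <- c(sw(a), sw(b))
  if (all(np > alpha_normality)) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(test_name = if (var_equal) "t" else "welch_t",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    res <- list(test_name = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(c(res, list(design = "two_group", summary = summ,
                        normality_p = np)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g\n",
              x$test_name, x$design, x$statistic, x$p_value))
  print(x$summary, digits = 4)
  invisible(x)
}

# Dunn's rank-based post-hoc test after Kruskal-Wallis (with tie correction)
dunn_posthoc <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[g1] + 1 / ns[g2]))
    z[i] <- (rbar[g1] - rbar[g2]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], statistic = z,
             p_unadjusted = p, p_adjusted = stats::p.adjust(p, p_adjust))
}

#' Omnibus test with post-hoc pairwise comparisons
#'
#' One-way ANOVA (post-hoc Tukey HSD or Bonferroni-corrected pairwise t),
#' two-way ANOVA with interaction (Bonferroni pairwise on the first factor;
#' unbalanced designs with empty cells are rejected), or Kruskal-Wallis
#' (post-hoc Dunn with the stated correction). Zero-variance inputs return
#' p = 1 with no post-hoc flags.
#'
#' @param values numeric response.
#' @param factors a factor, or data frame of 1-2 factors (two-way).
#' @param design `"one_way"`, `"two_way"` or `"kruskal"`.
#' @param posthoc `"tukey"`, `"bonferroni"` or `"dunn"`; defaults per
#'   design (`tukey`, `bonferroni`, `dunn` respectively).
#' @return A `group_comparison` with `posthoc` (tidy data frame of pairwise
#'   adjusted p-values) and per-group mean +/- SEM summary.
#' @export
omnibus_with_posthoc <- function(values, factors,
                                 design = c("one_way", "two_way", "kruskal"),
                                 posthoc = NULL) {
  design <- match.arg(design)
  if (is.data.frame(factors)) {
    fl <- lapply(factors, factor)
  } else fl <- list(f1 = factor(factors))
  if (design == "two_way" && length(fl) < 2)
    stop("two_way design needs two factors")
  f1 <- fl[[1]]
  if (any(table(f1) == 0) || nlevels(f1) < 2)
    stop("each factor needs >= 2 non-empty levels")
  if (is.null(posthoc))
    posthoc <- switch(design, one_way = "tukey", two_way = "bonferroni",
                      kruskal = "dunn")
  summ <- group_summary(values, f1)

  if (stats::var(values) == 0) {
    return(structure(list(test_name = "degenerate", statistic = 0,
                          p_value = 1, design = design, posthoc = NULL,
                          summary = summ),
                     class = "group_comparison"))
  }

  if (design == "kruskal") {
    kw <- stats::kruskal.test(values, f1)
    ph <- dunn_posthoc(values, f1,
                       if (posthoc == "dunn") "bonferroni" else posthoc)
    return(structure(list(test_name = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          p_value = kw$p.value, design = design,
                          posthoc = ph, summary = summ),
                     class = "group_comparison"))
  }

  if (design == "two_way") {
    f2 <- fl[[2]]
    if (any(table(f1, f2) == 0))
      stop("two_way design has empty cells")
    fit <- stats::aov(values ~ f1 * f2)
    tab <- summary(fit)[[1]]
    stat <- tab[["F value"]][1:3]
    pv <- tab[["Pr(>F)"]][1:3]
    names(stat) <- names(pv) <- c("factor1", "factor2", "interaction")
  } else {
    fit <- stats::aov(values ~ f1)
    tab <- summary(fit)[[1]]
    stat <- tab[["F value"]][1]
    pv <- tab[["Pr(>F)"]][1]
  }

  ph <- if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, "f1")$f1
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    data.frame(group1 = vapply(nm, `[`, "", 2),
               group2 = vapply(nm, `[`, "", 1),
               diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
               row.names = NULL)
  } else {
    pt <- stats::pairwise.t.test(values, f1, p.adjust.method = "bonferroni")
    m <- pt$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(group1 = rownames(m)[idx[, 1]],
               group2 = colnames(m)[idx[, 2]],
               p_adjusted = m[idx], row.names = NULL)
  }
  structure(list(test_name = if (design == "two_way") "two_way_anova"
                             else "one_way_anova",
                 statistic = stat, p_value = pv, design = design,
                 posthoc = ph, summary = summ),
            class = "group_comparison")
}
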