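#' Gatekept comparison of measurement groups
#'
#' Implements the conventional normality/variance gatekeeping used for
#' group comparisons in cell-biology datasets: each group is tested for
#' normality (Shapiro-Wilk) and the groups jointly for homogeneity of
#' variance (Levene's test, mean-centered). If both gates pass, a
#' parametric test is run: an unpaired two-tailed t-test with equal
#' variances assumed for two groups, or one-way ANOVA with Tukey's HSD
#' post-hoc for more. If either gate fails, the rank-based alternative is
#' used instead: Mann-Whitney U for two groups, Kruskal-Wallis with Dunn's
#' post-hoc (Holm-adjusted) for more. Every decision is recorded in an
#' ordered trail.
#'
#' Shapiro-Wilk requires at least 3 non-constant observations per group,
#' and Levene's test degenerates below 3 observations per group; an
#' untestable gate is recorded in the trail and treated as passed (for
#' variance, this matches the "equal variances assumed" convention for
#' replicate-level comparisons at very small n).
#'
#' @param groups Named list of numeric vectors, one per group; at least 2
#'   groups with at least 2 observations each.
#' @param design \code{"two_group"} (exactly 2 groups) or
#'   \code{"multi_group"}.
#' @param alpha Gatekeeping significance level for the Shapiro-Wilk and
#'   Levene tests (default 0.05).
#' @return An object of class \code{"stat_result"}: \code{test_name},
#'   \code{statistic}, \code{p_value}, \code{normality_p} (named vector),
#'   \code{variance_homogeneity_p}, \code{posthoc} (pairwise table after a
#'   multi-group omnibus, else NULL) and \code{trail} (ordered character
#'   record of the gatekeeping).
#' @examples
#' compare_groups(list(ctrl = c(1, 2, 3), trt = c(101, 102, 103)),
#'                design = "two_group")
#' @export
compare_groups <- function(groups, design = c("two_group", "multi_group"),
                           alpha = 0.05) {
  design <- match.arg(design)
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of >= 2 numeric vectors", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs >= 2 observations", call. = FALSE)
  if (design == "two_group" && length(groups) != 2L)
    stop("design 'two_group' requires exactly 2 groups", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  trail <- character()

  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))))

  # degenerate guard: no variation anywhere
  if (stats::sd(values) == 0) {
    trail <- c(trail, "all observations identical across groups: no test needed")
    return(structure(list(test_name = "degenerate (identical data)",
                          statistic = 0, p_value = 1,
                          normality_p = stats::setNames(rep(NA_real_, length(groups)),
                                                        names(groups)),
                          variance_homogeneity_p = NA_real_,
                          posthoc = NULL, trail = trail, alpha = alpha),
                     class = "stat_result"))
  }

  testable <- vapply(groups, function(g)
    length(g) >= 3L && stats::sd(g) > 0, logical(1))
  norm_p <- stats::setNames(rep(NA_real_, length(groups)), names(groups))
  if (all(testable)) {
    norm_p[] <- vapply(groups, function(g) stats::shapiro.test(g)$p.value,
                       numeric(1))
    normal_ok <- all(norm_p > alpha)
    trail <- c(trail, sprintf(
      "Shapiro-Wilk per group: min p = %.4g -> normality %s at alpha = %g",
      min(norm_p), if (normal_ok) "not rejected" else "rejected", alpha))
  } else {
    normal_ok <- TRUE
    trail <- c(trail, paste0(
      "Shapiro-Wilk untestable (group with n < 3 or constant values); ",
      "normality assumed"))
  }

  # Levene's statistic is degenerate below 3 observations per group: the
  # absolute deviations within a 2-observation group are identical, so the
  # within-group variance of deviations collapses to 0.
  lev_p <- if (all(vapply(groups, length, integer(1)) >= 3L))
    suppressWarnings(car::leveneTest(values ~ grp, center = mean))[["Pr(>F)"]][1]
  else NA_real_
  if (is.na(lev_p)) {
    var_ok <- TRUE
    trail <- c(trail, paste0(
      "Levene untestable (group with n < 3 or degenerate deviations); ",
      "equal variances assumed"))
  } else {
    var_ok <- lev_p > alpha
    trail <- c(trail, sprintf(
      "Levene (mean-centered): p = %.4g -> variances %s at alpha = %g",
      lev_p, if (var_ok) "homogeneous" else "heterogeneous", alpha))
  }

  parametric <- normal_ok && var_ok
  posthoc <- NULL
  if (parametric) {
    if (design == "two_group") {
      if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
        # constant within groups but different means: infinitely separated
        test_name <- "unpaired t-test (equal variances)"
        statistic <- Inf; p_value <- 0
        trail <- c(trail, "within-group variance 0 with distinct means: p -> 0")
      } else {
        tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
        test_name <- "unpaired t-test (equal variances)"
        statistic <- unname(tt$statistic); p_value <- tt$p.value
        trail <- c(trail, "parametric branch: unpaired two-tailed t-test, equal variances")
      }
    } else {
      fit <- stats::aov(values ~ grp)
      an <- summary(fit)[[1]]
      test_name <- "one-way ANOVA"
      statistic <- an[["F value"]][1]; p_value <- an[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$grp
      posthoc <- data.frame(comparison = rownames(tk), tk,
                            row.names = NULL, check.names = FALSE)
      trail <- c(trail, "parametric branch: one-way ANOVA with Tukey HSD post-hoc")
    }
  } else {
    if (design == "two_group") {
      wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      test_name <- "Mann-Whitney U"
      statistic <- unname(wt$statistic); p_value <- wt$p.value
      trail <- c(trail, "nonparametric branch: Mann-Whitney U test")
    } else {
      kt <- stats::kruskal.test(values, grp)
      test_name <- "Kruskal-Wallis"
      statistic <- unname(kt$statistic); p_value <- kt$p.value
      posthoc <- .dunn_posthoc(values, grp)
      trail <- c(trail, "nonparametric branch: Kruskal-Wallis with Dunn post-hoc (Holm)")
    }
  }

  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, normality_p = norm_p,
                 variance_homogeneity_p = if (is.na(lev_p)) NA_real_ else lev_p,
                 posthoc = posthoc, trail = trail, alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic,
              x$p_value))
  for (s in x$trail) cat("  -", s, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

# Dunn's rank-based z-test for all pairwise comparisons after a
# Kruskal-Wallis omnibus, with tie correction and Holm adjustment.
.dunn_posthoc <- function(values, grp) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(r, grp, mean)
  ns <- tapply(r, grp, length)
  gl <- names(mr)
  pairs <- utils::combn(gl, 2)
  out <- apply(pairs, 2, function(p) {
    z <- (mr[[p[1]]] - mr[[p[2]]]) /
      sqrt(v0 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = out["z", ], p_raw = out["p", ],
             p_holm = stats::p.adjust(out["p", ], method = "holm"),
             row.names = NULL)
}
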