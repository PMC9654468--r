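# Construct validity and internal consistency: Spearman correlations,
# Cronbach's alpha (raw and standardized), quartile trend regression and
# normality-gated group comparisons.

#' Spearman rank-order correlation
#'
#' Pearson correlation of average ranks, with the usual t approximation on
#' n - 2 degrees of freedom for the two-sided p-value.  Constant input is
#' flagged (rho `NA`) rather than silently reported as zero.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n` and `note` (`NA` unless flagged).
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                note = "constant input: rank correlation undefined"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, note = NA_character_)
}

#' Cronbach's alpha, raw and standardized
#'
#' Raw: `k/(k-1) * (1 - sum(item variances) / variance(row sums))`.
#' Standardized: `k * rbar / (1 + (k-1) * rbar)` with `rbar` the mean
#' off-diagonal Pearson correlation.
#'
#' @param items Numeric matrix or data frame, participants x components
#'   (items or sub-scores), no missing cells, k >= 2 columns.
#' @return List with `alpha_raw`, `alpha_standardized`, `k`, `n`.
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  if (anyNA(X)) stop("missing cells in item matrix")
  k <- ncol(X)
  if (k < 2L) stop("need at least 2 components")
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("zero total-score variance: alpha undefined")
  item_vars <- apply(X, 2, stats::var)
  alpha_raw <- k / (k - 1) * (1 - sum(item_vars) / total_var)

  if (any(item_vars == 0)) {
    # a constant column has undefined correlations; standardized alpha is
    # computed over the remaining columns' correlation structure
    R <- stats::cor(X[, item_vars > 0, drop = FALSE])
  } else {
    R <- stats::cor(X)
  }
  if (ncol(R) < 2L) stop("fewer than 2 non-constant components")
  rbar <- mean(R[lower.tri(R)])
  alpha_std <- ncol(R) * rbar / (1 + (ncol(R) - 1) * rbar)
  list(alpha_raw = alpha_raw, alpha_standardized = alpha_std,
       k = k, n = nrow(X))
}

#' Linear trend across score quartiles
#'
#' Ordinary least squares of the dependent variable on the quartile index
#' treated as numeric (1..4), with the two-sided t test for the slope.
#'
#' @param values Dependent variable.
#' @param quartile Quartile index per observation (integer 1..4).
#' @return List with `slope`, `p_value`, `n`, `note`.
#' @export
quartile_trend <- function(values, quartile) {
  ok <- stats::complete.cases(values, quartile)
  values <- values[ok]; quartile <- as.numeric(quartile[ok])
  if (length(unique(quartile)) < 2L) {
    stop("need at least 2 distinct quartiles for a trend")
  }
  if (stats::sd(values) == 0) {
    return(list(slope = 0, p_value = 1, n = length(values),
                note = "constant dependent variable"))
  }
  fit <- stats::lm(values ~ quartile)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["quartile", "Estimate"]),
       p_value = unname(sm["quartile", "Pr(>|t|)"]),
       n = length(values), note = NA_character_)
}

#' Compare a variable between groups with normality gating
#'
#' Two groups: Shapiro-Wilk per group at `normality_alpha` gates the choice
#' between Welch's t test (both groups normal) and the Wilcoxon-Mann-Whitney
#' rank-sum test (normal approximation with tie correction).  Three or more
#' groups: one-way ANOVA F test with Bonferroni-adjusted pairwise t-test
#' follow-ups.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 members).
#' @param normality_alpha Shapiro-Wilk significance threshold.
#' @return List with `test`, `statistic`, `p_value`, `normal` (per-group
#'   logical, `NA` if not assessed) and `pairwise` (data frame of
#'   Bonferroni-adjusted pairwise p-values for >= 3 groups, else `NULL`).
#' @export
group_compare <- function(values, groups, normality_alpha = 0.05) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("empty or singleton group: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }

  if (nlevels(groups) == 2L) {
    normal <- vapply(levels(groups), function(g) {
      v <- values[groups == g]
      if (length(unique(v)) < 3L || length(v) < 3L) return(FALSE)
      stats::shapiro.test(v)$p.value >= normality_alpha
    }, logical(1))
    if (all(normal)) {
      ht <- stats::t.test(values ~ groups)
      res <- list(test = "t", statistic = unname(ht$statistic),
                  p_value = ht$p.value, normal = normal, pairwise = NULL)
    } else {
      if (stats::sd(values) == 0) {
        res <- list(test = "wilcoxon", statistic = 0, p_value = 1,
                    normal = normal, pairwise = NULL)
      } else {
        ht <- suppressWarnings(
          stats::wilcox.test(values ~ groups, exact = FALSE, correct = TRUE))
        res <- list(test = "wilcoxon", statistic = unname(ht$statistic),
                    p_value = ht$p.value, normal = normal, pairwise = NULL)
      }
    }
    return(res)
  }

  if (stats::sd(values) == 0) {
    return(list(test = "anova", statistic = 0, p_value = 1,
                normal = rep(NA, nlevels(groups)), pairwise = NULL))
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pw$p.value
  pairs <- do.call(rbind, lapply(rownames(pm), function(r) {
    cols <- colnames(pm)[!is.na(pm[r, ])]
    if (length(cols) == 0L) return(NULL)
    data.frame(group1 = cols, group2 = r,
               p_adjusted = pm[r, cols], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(test = "anova",
       statistic = sm[["F value"]][1],
       p_value = sm[["Pr(>F)"]][1],
       normal = rep(NA, nlevels(groups)),
       pairwise = pairs)
}

#' Assemble a construct-validity and internal-consistency report
#'
#' Pairs each requested score component with an intake variable via Spearman
#' correlation, computes Cronbach's alpha over the eight sub-scores (or the
#' item points), fits linear trends of every intake variable across total
#' score quartiles, and (when demographics are supplied) compares the total
#' score between sexes and across age bands.
#'
#' @param scores Data frame from [score_cohort()], plus a `quartile` column
#'   (see [assign_quartiles()]).
#' @param usual Wide usual-intake data frame (`participant_id` + one column
#'   per variable), typically `estimate_usual()$usual`.
#' @param pairs Data frame with columns `component` (sub-score name or
#'   `"total"`) and `variable` (column of `usual`).
#' @param demographics Optional data frame with `participant_id`, `sex`,
#'   `age_band`.
#' @param alpha_on `"sub_scores"` (default) or `"items"` is reported in
#'   `alpha`; requires the respective columns to be present.
#' @param normality_alpha Threshold for the Shapiro-Wilk gate.
#' @return List of class `validity_report` with elements `pairs`, `alpha`,
#'   `trend` and `group_tests`.
#' @export
validity_report <- function(scores, usual, pairs,
                            demographics = NULL,
                            alpha_on = c("sub_scores", "items"),
                            normality_alpha = 0.05) {
  alpha_on <- match.arg(alpha_on)
  merged <- merge(scores, usual, by = "participant_id")

  pair_rows <- lapply(seq_len(nrow(pairs)), function(i) {
    comp <- pairs$component[i]
    var <- pairs$variable[i]
    col <- if (comp == "total") "total" else paste0("sub_", comp)
    if (!col %in% names(merged) || !var %in% names(merged)) return(NULL)
    sc <- spearman_cor(merged[[col]], merged[[var]])
    data.frame(component = comp, variable = var, rho = sc$rho,
               p_value = sc$p_value, n = sc$n, stringsAsFactors = FALSE)
  })
  pair_df <- do.call(rbind, pair_rows)

  sub_cols <- grep("^sub_", names(scores), value = TRUE)
  alpha <- cronbach_alpha(scores[, sub_cols, drop = FALSE])
  if (alpha_on == "items") {
    item_cols <- grep("^item_", names(scores), value = TRUE)
    if (length(item_cols) >= 2L) {
      alpha <- cronbach_alpha(scores[, item_cols, drop = FALSE])
    }
  }

  trend_rows <- NULL
  if ("quartile" %in% names(merged)) {
    vars <- intersect(names(usual), names(merged))
    vars <- setdiff(vars, "participant_id")
    trend_rows <- do.call(rbind, lapply(vars, function(v) {
      tr <- quartile_trend(merged[[v]], merged$quartile)
      data.frame(variable = v, slope = tr$slope, p_value = tr$p_value,
                 n = tr$n, stringsAsFactors = FALSE)
    }))
  }

  group_tests <- list()
  if (!is.null(demographics)) {
    dm <- merge(scores, demographics, by = "participant_id")
    if ("sex" %in% names(dm) && length(unique(dm$sex)) == 2L) {
      group_tests$total_by_sex <- group_compare(dm$total, dm$sex,
                                                normality_alpha)
    }
    if ("age_band" %in% names(dm) && length(unique(dm$age_band)) >= 2L) {
      sizes <- table(dm$age_band)
      if (all(sizes >= 2L)) {
        group_tests$total_by_age <- group_compare(dm$total, dm$age_band,
                                                  normality_alpha)
      }
    }
  }

  structure(list(pairs = pair_df, alpha = alpha, trend = trend_rows,
                 group_tests = group_tests),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  if (!is.null(x$pairs)) {
    cat(" validity correlations:\n")
    print(x$pairs, row.names = FALSE, digits = 3)
  }
  cat(" Cronbach alpha: raw =", format(x$alpha$alpha_raw, digits = 3),
      ", standardized =", format(x$alpha$alpha_standardized, digits = 3), "\n")
  if (!is.null(x$trend)) {
    cat(" quartile trends:", nrow(x$trend), "variables\n")
  }
  if (length(x$group_tests) > 0L) {
    cat(" group tests:", paste(names(x$group_tests), collapse = ", "), "\n")
  }
  invisible(x)
}
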