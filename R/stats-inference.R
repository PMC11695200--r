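#' GLM group contrast for a single feature
#'
#' Ordinary least squares of the feature on an intercept, a binary group
#' indicator and the covariate columns; the reported effect is the group
#' coefficient with its t statistic (`df = n - p`) and two-sided p value.
#' With no covariates this reduces exactly to the pooled two-sample t test.
#'
#' @param y Numeric feature vector, one value per subject.
#' @param group Two-level factor/character/binary vector; the contrast is
#'   second level minus first (alphabetical for characters).
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return One-row tibble: `estimate`, `t`, `df`, `p`.
#' @export
glm_group_test <- function(y, group, covariates = NULL) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) abort("`group` must have exactly two levels")
  x <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    x <- cbind(x, cv)
  }
  n <- length(y)
  if (n <= ncol(x)) abort("more predictors than observations")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(sprintf("rank-deficient design: collinear column(s) %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(x, y)
  df <- n - ncol(x)
  rss <- sum(fit$residuals^2)
  if (rss < 1e-24) {
    return(tibble(estimate = 0, t = 0, df = df, p = 1))
  }
  sigma2 <- rss / df
  xtxi <- solve(crossprod(x))
  se <- sqrt(sigma2 * xtxi[2, 2])
  est <- unname(fit$coefficients["group"])
  tval <- est / se
  tibble(estimate = est, t = tval, df = df,
         p = 2 * stats::pt(-abs(tval), df))
}

#' Group contrasts across a feature table
#'
#' Applies [glm_group_test()] to every feature column, then adjusts the p
#' values by Benjamini-Hochberg (optionally disabled, e.g. for the
#' temporal state properties, which are conventionally reported
#' uncorrected).
#'
#' @param features Data frame/tibble with a `subject_id` column and one
#'   column per feature, rows aligned with `manifest`.
#' @param manifest Tibble with `subject_id`, `group` and covariate columns.
#' @param covariates Character vector of manifest columns to adjust for
#'   (default `c("age", "gender", "education")`).
#' @param fdr Apply BH adjustment (default `TRUE`).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return A `glm_result`: tibble with `feature`, `estimate`, `t`, `df`,
#'   `p`, `q`, `significant`.
#' @export
group_glm <- function(features, manifest,
                      covariates = c("age", "gender", "education"),
                      fdr = TRUE, q_threshold = 0.05) {
  features <- as_tibble(features)
  manifest <- as_tibble(manifest)
  stopifnot("subject_id" %in% names(features))
  dat <- dplyr::inner_join(features, manifest, by = "subject_id")
  if (nrow(dat) != nrow(features)) abort("features/manifest subject mismatch")
  cv <- if (length(covariates)) dat[, covariates, drop = FALSE] else NULL
  feat_cols <- setdiff(names(features), "subject_id")
  rows <- purrr::map(feat_cols, function(f) {
    dplyr::mutate(glm_group_test(dat[[f]], dat$group, cv), feature = f,
                  .before = 1)
  }) |> purrr::list_rbind()
  if (fdr) {
    adj <- bh_fdr(rows$p, q_threshold)
    rows$q <- adj$q
    rows$significant <- adj$significant
  } else {
    rows$q <- rows$p
    rows$significant <- rows$p < q_threshold
  }
  class(rows) <- c("glm_result", class(rows))
  attr(rows, "q_threshold") <- q_threshold
  rows
}

#' @method tidy glm_result
#' @export
tidy.glm_result <- function(x, ...) as_tibble(x)

#' @method glance glm_result
#' @export
glance.glm_result <- function(x, ...) {
  tibble(n_features = nrow(x), n_significant = sum(x$significant),
         q_threshold = attr(x, "q_threshold"))
}

#' @method autoplot glm_result
#' @export
autoplot.glm_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, -log10(.data$q),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "group effect", y = expression(-log[10](q)),
                  title = "Group contrasts (BH-adjusted)") +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1; the mask flags
#' `q <= q_threshold`. Delegates the adjustment to `stats::p.adjust`.
#'
#' @param pvals Numeric p values in \[0, 1\].
#' @param q_threshold FDR level (default 0.05).
#' @return List with `q` and logical `significant`.
#' @export
bh_fdr <- function(pvals, q_threshold = 0.05) {
  if (length(pvals) == 0L) {
    return(list(q = numeric(0), significant = logical(0)))
  }
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q <= q_threshold)
}

#' Partial correlation adjusted for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS on an
#' intercept plus the covariates, with
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2 - #covariates`.
#' With no covariates this is the plain Pearson correlation (df = n - 2).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame.
#' @return One-row tibble: `r`, `df`, `t`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  ncov <- 0L
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    ncov <- ncol(cv)
    if (n <= ncov + 3L) abort("too few observations for the covariate set")
    z <- cbind(1, cv)
    x <- stats::lm.fit(z, x)$residuals
    y <- stats::lm.fit(z, y)$residuals
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    abort("constant residuals: partial correlation undefined")
  }
  r <- stats::cor(x, y)
  df <- n - 2L - ncov
  tval <- r * sqrt(df / max(1 - r^2, 1e-300))
  tibble(r = r, df = df, t = tval, p = 2 * stats::pt(-abs(tval), df))
}

check_summary_args <- function(sd1, n1, sd2, n2) {
  if (any(c(n1, n2) < 2) || any(c(sd1, sd2) <= 0)) {
    abort("need n >= 2 and sd > 0 in both groups")
  }
}

#' Welch two-sample t statistic from summary statistics
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite degrees of
#' freedom; used to reproduce printed cohort-table statistics from
#' mean/SD/n summaries.
#'
#' @param mean1,sd1,n1 Group-1 summary statistics.
#' @param mean2,sd2,n2 Group-2 summary statistics.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_summary_args(sd1, n1, sd2, n2)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' Classic equal-variance t with `df = n1 + n2 - 2`.
#'
#' @inheritParams welch_t
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_summary_args(sd1, n1, sd2, n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return One-row tibble: `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin in 2x2 table")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  tibble(chisq = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Subgroup contrast within one group
#'
#' Splits the subjects of `within_group` at a threshold on a manifest
#' column (e.g. MoCA >= 26 or age >= 60) and runs the same GLM machinery
#' across the split, BH-corrected.
#'
#' @param features Feature table with `subject_id`.
#' @param manifest Subject manifest.
#' @param split_var Manifest column to split on.
#' @param threshold Split point; subjects with `split_var >= threshold`
#'   form the upper subgroup.
#' @param within_group Group label to restrict to (default: use all rows).
#' @param covariates Covariate columns (default age/gender/education).
#' @param q_threshold FDR level.
#' @return A `glm_result` for the subgroup contrast.
#' @export
subgroup_contrast <- function(features, manifest, split_var, threshold,
                              within_group = NULL,
                              covariates = c("age", "gender", "education"),
                              q_threshold = 0.05) {
  manifest <- as_tibble(manifest)
  if (!is.null(within_group)) {
    manifest <- dplyr::filter(manifest, .data$group == within_group)
    features <- dplyr::semi_join(as_tibble(features), manifest,
                                 by = "subject_id")
  }
  split <- manifest[[split_var]] >= threshold
  if (!any(split) || all(split)) {
    abort(sprintf("split `%s >= %s` leaves an empty subgroup", split_var,
                  format(threshold)))
  }
  manifest$group <- ifelse(split, "upper", "lower")
  group_glm(features, manifest, covariates = covariates,
            q_threshold = q_threshold)
}
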