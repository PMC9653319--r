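check_grouped <- function(values, groups, min_per_group = 2) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  g <- factor(groups)
  g <- droplevels(g)
  n <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < min_per_group))
    stop(sprintf("every group needs at least %d values", min_per_group),
         call. = FALSE)
  g
}

#' One-way ANOVA with eta-squared effect size
#'
#' Classical between/within sum-of-squares decomposition; the effect size
#' is \eqn{\eta^2 = SS_{between}/SS_{total}}.
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor).
#' @return list with `f`, `p_value`, `eta_sq`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  g <- check_grouped(values, groups)
  fit <- stats::aov(values ~ g)
  tab <- stats::anova(fit)
  ss_b <- tab$`Sum Sq`[1]
  ss_w <- tab$`Sum Sq`[2]
  list(f = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       eta_sq = ss_b / (ss_b + ss_w),
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise group comparisons that assume neither equal variances nor equal
#' group sizes: each pair uses the Welch standard error
#' \eqn{se = \sqrt{s_i^2/n_i + s_j^2/n_j}}, Welch-Satterthwaite degrees of
#' freedom, and refers \eqn{q = |\bar{x}_i - \bar{x}_j|\sqrt{2}/se} to the
#' studentized-range distribution with the total number of groups.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param subject optional subject identifiers. When given, values are
#'   first averaged per subject within each group (one mean per subject
#'   per group) so the comparison units are independent subjects rather
#'   than correlated fellow eyes. The default eye-level analysis matches
#'   the per-eye group sizes.
#' @return data frame of class `games_howell` with one row per pair:
#'   `group_a`, `group_b`, `mean_difference` (absolute), `se`, `df`,
#'   `statistic` (q) and `p_value`.
#' @examples
#' set.seed(1)
#' games_howell(c(rnorm(10), rnorm(10, 1), rnorm(10, 2)),
#'              rep(c("h", "gs", "ppg"), each = 10))
#' @export
games_howell <- function(values, groups, subject = NULL) {
  if (!is.null(subject)) {
    if (length(subject) != length(values))
      stop("subject must parallel values", call. = FALSE)
    key <- interaction(subject, groups, drop = TRUE)
    values <- as.numeric(tapply(values, key, mean))
    groups <- tapply(as.character(groups), key, `[`, 1)
  }
  g <- check_grouped(values, groups)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  vars <- tapply(values, g, stats::var)
  ns <- tapply(values, g, length)
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    if (vars[[i]] == 0 && vars[[j]] == 0)
      stop(sprintf("zero within-group variance in both '%s' and '%s'", i, j),
           call. = FALSE)
    vi <- vars[[i]] / ns[[i]]; vj <- vars[[j]] / ns[[j]]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (ns[[i]] - 1) + vj^2 / (ns[[j]] - 1))
    q <- abs(means[[i]] - means[[j]]) * sqrt(2) / se
    c(diff = abs(means[[i]] - means[[j]]), se = se, df = df, q = q,
      p = stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    mean_difference = res["diff", ], se = res["se", ],
                    df = res["df", ], statistic = res["q", ],
                    p_value = res["p", ], row.names = NULL)
  class(out) <- c("games_howell", "data.frame")
  out
}

#' Squared Pearson correlation with significance test
#'
#' @param x,y paired numeric vectors (n >= 3, both non-constant).
#' @return list with `r`, `r_squared`, `p_value` (t-transform, n - 2 df).
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value)
}

#' Welch two-sample t-test (variance not assumed equal)
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value` (two-sided),
#'   and the two sample means.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate samples: both have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' ROC curve area via the Mann-Whitney statistic
#'
#' AUC is the proportion of between-class score pairs in which the positive
#' class scores higher, counting ties at half weight (the Mann-Whitney
#' U/(n1 n0) identity). Orientation is chosen so the reported AUC is
#' >= 0.5, with the direction recorded. The p-value tests AUC = 0.5 by the
#' normal approximation to U with tie correction.
#'
#' @param scores numeric classifier scores.
#' @param labels two-class labels.
#' @param positive which label is the positive class; defaults to the last
#'   factor level.
#' @return object of class `roc_result`: list with `auc`, `p_value`,
#'   `direction` (`"positive_higher"` or `"positive_lower"`), `positive`,
#'   `n_positive`, `n_negative`.
#' @examples
#' roc_auc(c(1, 2, 3, 4, 5, 6), c("h", "h", "h", "g", "g", "g"), positive = "g")
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  f <- droplevels(factor(labels))
  if (nlevels(f) != 2) stop("labels must contain exactly 2 classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(f)[2]
  if (!positive %in% levels(f)) stop("positive label not present", call. = FALSE)
  pos <- f == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  direction <- if (auc >= 0.5) "positive_higher" else "positive_lower"
  auc_oriented <- max(auc, 1 - auc)

  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  p <- if (var_u == 0) 1 else
    2 * stats::pnorm(abs(u - n1 * n0 / 2) / sqrt(var_u), lower.tail = FALSE)
  structure(list(auc = auc_oriented, p_value = min(p, 1),
                 direction = direction, positive = positive,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC = %.3f (positive class '%s' scores %s; n = %d/%d), p = %.3g\n",
              x$auc, x$positive,
              if (x$direction == "positive_higher") "higher" else "lower",
              x$n_positive, x$n_negative, x$p_value))
  invisible(x)
}
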