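#' Two-way factorial ANOVA (Type II sums of squares)
#'
#' The study-level group comparison: a two-factor between-subject ANOVA with
#' interaction, reporting per-effect F, degrees of freedom and p. Type II
#' sums of squares (via `car::Anova`) are used so unbalanced designs are
#' handled with the common factorial convention; in the balanced case the
#' effect and residual sums of squares partition the total exactly.
#'
#' @param data a data.frame.
#' @param response,factor_a,factor_b column names: a numeric response and two
#'   factors with >= 2 levels each (e.g. genotype and treatment, or
#'   treatment and age).
#' @return A data.frame with columns `effect`, `sum_sq`, `df1`, `df2`, `F`,
#'   `p` for the two main effects and the interaction.
#' @export
two_way_anova <- function(data, response = "value", factor_a = "genotype",
                          factor_b = "treatment") {
  for (v in c(response, factor_a, factor_b))
    if (!v %in% names(data)) stop("column not found: ", v)
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels")
  tab <- table(a, b)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factor_a,
                 levels(a)[bad[1L]], factor_b, levels(b)[bad[2L]]))
  }
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  d <- data.frame(y = y, a = a, b = b)
  effects <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  if (stats::var(y) == 0) {
    return(data.frame(effect = effects, sum_sq = 0,
                      df1 = c(nlevels(a) - 1L, nlevels(b) - 1L,
                              (nlevels(a) - 1L) * (nlevels(b) - 1L)),
                      df2 = nrow(d) - nlevels(a) * nlevels(b),
                      F = 0, p = 1))
  }
  fit <- stats::lm(y ~ a * b, data = d)
  if (fit$df.residual < 1L)
    stop("no residual degrees of freedom: need replication within cells")
  an <- car::Anova(fit, type = 2)
  rows <- c("a", "b", "a:b")
  data.frame(effect = effects,
             sum_sq = an[rows, "Sum Sq"],
             df1 = as.integer(an[rows, "Df"]),
             df2 = as.integer(an["Residuals", "Df"]),
             F = an[rows, "F value"],
             p = an[rows, "Pr(>F)"],
             row.names = NULL)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, the family-wise correction applied to post-hoc
#' comparisons.
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot_scalar(m, "m", lo = 1, integer = TRUE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Bonferroni-corrected post-hoc pairwise comparisons
#'
#' Pooled-variance Student's t-tests between requested cell pairs of a
#' two-factor design, Bonferroni-adjusted for the number of comparisons.
#' Cells are named `"<levelA>:<levelB>"`.
#'
#' @inheritParams two_way_anova
#' @param comparisons list of length-2 character vectors of cell names.
#' @return A data.frame with `comparison`, `estimate` (difference in means),
#'   `t`, `df`, `p`, `p_adj`.
#' @export
bonferroni_posthoc <- function(data, comparisons, response = "value",
                               factor_a = "genotype",
                               factor_b = "treatment") {
  cell <- paste(data[[factor_a]], data[[factor_b]], sep = ":")
  y <- data[[response]]
  m <- length(comparisons)
  if (m < 1L) stop("no comparisons requested")
  res <- lapply(comparisons, function(cmp) {
    if (length(cmp) != 2L) stop("each comparison must name two cells")
    y1 <- y[cell == cmp[1L]]; y2 <- y[cell == cmp[2L]]
    if (length(y1) < 2L || length(y2) < 2L)
      stop("cells must have >= 2 observations: ",
           paste(cmp, collapse = " vs "))
    tt <- stats::t.test(y1, y2, var.equal = TRUE)
    data.frame(comparison = paste(cmp, collapse = " vs "),
               estimate = mean(y1) - mean(y2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni_adjust(out$p, m)
  out
}

#' Iterative two-sided Grubbs outlier test
#'
#' Screens a sample for outliers by the Grubbs statistic
#' G = max|x - mean(x)| / sd(x), comparing against the exact critical value
#' ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with t the upper
#' alpha/(2n) quantile of the t distribution on n - 2 degrees of freedom.
#' One observation is removed per iteration until no outlier remains.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return Integer indices (into `values`) of flagged outliers, possibly
#'   empty, in removal order.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("Grubbs test needs at least 3 values")
  stopifnot_scalar(alpha, "alpha", 1e-12, 1 - 1e-12)
  if (anyNA(values)) stop("missing values not allowed")
  idx <- seq_along(values)
  out <- integer(0)
  x <- values
  while (length(x) >= 3L) {
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    n <- length(x)
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g <= crit) break
    worst <- which.max(dev)
    out <- c(out, idx[worst])
    idx <- idx[-worst]
    x <- x[-worst]
  }
  out
}

#' Kaplan-Meier curves and Mantel-Cox log-rank test
#'
#' Product-limit survival curves per group and the standard two-group
#' log-rank chi-square on the pooled event-time table (hypergeometric
#' variance, no continuity correction - the Mantel-Cox convention).
#'
#' @param data a data.frame with columns `time` (>= 0), `event` (logical or
#'   0/1; TRUE = end-stage event, FALSE = censored) and `group` (exactly two
#'   levels).
#' @return A list with `fit` (a `survival::survfit` object), `chisq`, `df`
#'   (1) and `p.value`.
#' @export
km_logrank <- function(data) {
  for (v in c("time", "event", "group"))
    if (!v %in% names(data)) stop("column not found: ", v)
  if (any(data$time < 0)) stop("times must be >= 0")
  g <- factor(data$group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  ev <- as.logical(data$event)
  if (!any(ev)) stop("degenerate input: no events in either group")
  d <- data.frame(time = data$time, event = as.integer(ev), group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d,
                           rho = 0)
  list(fit = fit, chisq = unname(sd$chisq), df = 1L,
       p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' RNA-seq gene-retention filter
#'
#' Retains genes with a count of at least `min_count` in at least
#' `min_samples` samples (the published rule: count >= 2 in >= 10 of the 79
#' samples). Order-preserving and idempotent.
#'
#' @param counts gene x sample numeric matrix.
#' @param min_count,min_samples filter parameters.
#' @return Retained gene identifiers (rownames if present, else row
#'   indices), in input order.
#' @export
gene_filter <- function(counts, min_count = 2, min_samples = 10) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  stopifnot_scalar(min_count, "min_count", lo = 0)
  stopifnot_scalar(min_samples, "min_samples", lo = 0)
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' qPCR fold change with geometric-mean housekeeping normalization
#'
#' Per-sample target copy numbers are normalized to the geometric mean of
#' three housekeeping genes (the published panel: Atp5b, Actb, Sdha); fold
#' change per group is the group mean normalized value over the reference
#' group mean.
#'
#' @param target positive numeric vector of target copy numbers per sample.
#' @param housekeeping positive numeric matrix, samples x 3 housekeeping
#'   genes.
#' @param group group label per sample.
#' @param reference the reference group name (fold change 1).
#' @return Named numeric vector of fold changes per group.
#' @export
qpcr_fold_change <- function(target, housekeeping, group, reference) {
  housekeeping <- as.matrix(housekeeping)
  if (ncol(housekeeping) != 3L)
    stop("`housekeeping` must have three genes (columns)")
  if (length(target) != nrow(housekeeping) ||
      length(group) != length(target))
    stop("`target`, `housekeeping` rows and `group` must align")
  if (any(target <= 0) || any(housekeeping <= 0))
    stop("copy numbers must be strictly positive")
  if (!reference %in% group) stop("reference group not present: ", reference)
  geo <- exp(rowMeans(log(housekeeping)))
  norm <- target / geo
  means <- tapply(norm, group, mean)
  out <- means / means[[reference]]
  out[order(names(out) != reference)]  # reference first
}
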