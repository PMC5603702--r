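#' Intra-subject coefficient of variation
#'
#' Per subject, the sample standard deviation of the repeat-session values
#' divided by the subject mean, as a percentage. Subjects may have
#' different numbers of sessions (`NA` entries are dropped per subject)
#' but each needs at least two. The across-subject mean and standard
#' deviation are returned, matching the "CoV (%) mean +/- sd" convention
#' of repeatability tables.
#'
#' @param values numeric matrix, subjects x sessions; `NA` marks a missed
#'   session.
#' @return List: `mean_pct`, `sd_pct`, `per_subject_pct`.
#' @export
cov_intra <- function(values) {
  values <- as.matrix(values)
  per <- apply(values, 1, function(row) {
    row <- row[is.finite(row)]
    if (length(row) < 2)
      stop("each subject needs at least 2 sessions", call. = FALSE)
    m <- mean(row)
    if (m == 0)
      stop("undefined CoV: a subject mean is zero", call. = FALSE)
    sd(row) / m * 100
  })
  list(mean_pct = mean(per), sd_pct = sd(per), per_subject_pct = per)
}

#' ICC: two-way random effects, absolute agreement, average measures
#'
#' McGraw-Wong ICC(A,k) for a complete subjects x sessions table:
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)` where MSR, MSC and MSE are the
#' row (subject), column (session) and residual mean squares of the
#' two-way ANOVA, n the number of subjects and k the number of sessions
#' averaged. Equals 1 when sessions agree perfectly while subjects
#' differ; can be negative when within-subject variability dominates.
#'
#' @param values complete numeric matrix, subjects x sessions (no `NA`).
#' @return The ICC (scalar). `NA` with a warning when the table is
#'   constant (agreement undefined).
#' @export
icc_2way_random_avg <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop("ICC requires at least 2 subjects and 2 sessions", call. = FALSE)
  if (anyNA(values))
    stop("ICC requires a complete table (no imputation is performed)",
         call. = FALSE)
  if (stats::var(as.vector(values)) == 0) {
    warning("constant table: ICC undefined")
    return(NA_real_)
  }
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), times = k)),
                   session = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subject + session, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

#' Paired t-test
#'
#' Classical two-sided paired t-test. A degenerate pair set whose
#' differences have zero standard deviation is reported as `t = 0, p = 1`
#' when the mean difference is zero, and as signed-infinite t with p = 0
#' otherwise (flagged via the `degenerate` element).
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return List: `t`, `p`, `df`, `mean_difference`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2)
    stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = length(d) - 1L, mean_difference = md,
                degenerate = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate),
       degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects F-test across groups (equal variances
#' assumed), as used for multi-group comparisons of cohort summary
#' parameters.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return List: `F`, `p`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  df <- data.frame(
    y = unlist(groups),
    g = factor(rep(seq_along(groups), vapply(groups, length, integer(1)))))
  tab <- anova(lm(y ~ g, data = df))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}
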