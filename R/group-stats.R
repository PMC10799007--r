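#' Two-by-two mixed-design ANOVA with partial eta squared
#'
#' One between-subject factor (treatment group) crossed with one
#' within-subject factor (learning context), fitted by the classical
#' sums-of-squares decomposition: the treatment effect is tested against
#' subjects-within-groups, the context and interaction effects against the
#' within-subject residual. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#' With a two-level within factor sphericity holds trivially (epsilon = 1),
#' so a Greenhouse-Geisser correction is a pass-through; a note records
#' this.
#'
#' @param table long-format data.frame with columns `subject`, `group`
#'   (two levels, between), `context` (two levels, within), `value`; each
#'   subject contributes exactly one value per context and belongs to
#'   exactly one group, with at least two subjects per group.
#' @return an `anova_result` data.frame with one row per effect
#'   (`treatment`, `context`, `treatment:context`): `F`, `df1`, `df2`, `p`,
#'   and `pes` (partial eta squared). The sphericity note is attached as
#'   attribute `"note"`.
#' @export
mixed_anova_2x2 <- function(table) {
  need <- c("subject", "group", "context", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(subject = factor(table$subject),
                    group = factor(table$group),
                    context = factor(table$context),
                    value = as.numeric(table$value))
  if (nlevels(tab$group) != 2L || nlevels(tab$context) != 2L) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  counts <- table(tab$subject, tab$context)
  if (any(counts != 1L)) {
    stop("each subject needs exactly one value per context level",
         call. = FALSE)
  }
  gmap <- unique(tab[, c("subject", "group")])
  if (anyDuplicated(gmap$subject)) {
    stop("subjects must be nested in exactly one group", call. = FALSE)
  }
  if (any(table(gmap$group) < 2L)) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  fit <- stats::aov(value ~ group * context + Error(subject), data = tab)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  ss <- function(tabdf, rn, eff) tabdf[match(eff, rn), "Sum Sq"]
  df_ <- function(tabdf, rn, eff) tabdf[match(eff, rn), "Df"]
  zero_tol <- 1e-12 * max(sum((tab$value - mean(tab$value))^2), 1)
  eff_row <- function(name, ss_eff, df_eff, ss_err, df_err) {
    # a zero-SS effect has F = 0 by convention, even against a zero error term
    f <- if (ss_eff <= zero_tol) 0 else (ss_eff / df_eff) / (ss_err / df_err)
    pes <- if (ss_eff <= zero_tol) 0 else ss_eff / (ss_eff + ss_err)
    data.frame(effect = name, F = f, df1 = df_eff, df2 = df_err,
               p = stats::pf(f, df_eff, df_err, lower.tail = FALSE),
               pes = pes,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff_row("treatment",
            ss(between, rn_b, "group"), df_(between, rn_b, "group"),
            ss(between, rn_b, "Residuals"), df_(between, rn_b, "Residuals")),
    eff_row("context",
            ss(within, rn_w, "context"), df_(within, rn_w, "context"),
            ss(within, rn_w, "Residuals"), df_(within, rn_w, "Residuals")),
    eff_row("treatment:context",
            ss(within, rn_w, "group:context"), df_(within, rn_w, "group:context"),
            ss(within, rn_w, "Residuals"), df_(within, rn_w, "Residuals")))
  class(out) <- c("anova_result", "data.frame")
  attr(out, "note") <-
    "two-level within factor: sphericity holds (epsilon = 1), Greenhouse-Geisser correction is a pass-through"
  out
}

#' Simple effect of treatment at one context level
#'
#' Two-sample t-test comparing the groups at a fixed within-factor level
#' (post-hoc simple effect, no multiplicity correction). Groups are ordered
#' alphabetically for the sign of `t`.
#'
#' @param table long-format table as in [mixed_anova_2x2()].
#' @param within_level the context level at which to compare groups.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p`, and `groups` (the subtraction order).
#' @export
simple_effects <- function(table, within_level, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  sub <- table[table$context == within_level, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows at context level '", within_level, "'",
                            call. = FALSE)
  gl <- sort(unique(as.character(sub$group)))
  if (length(gl) != 2L) stop("need exactly two groups", call. = FALSE)
  x <- sub$value[sub$group == gl[1]]
  y <- sub$value[sub$group == gl[2]]
  tt <- independent_t(x, y, variant)
  list(t = tt$t, df = tt$df, p = tt$p, groups = paste(gl, collapse = " - "))
}

#' Correlation coefficient with t-approximation p-value
#'
#' Pearson's product-moment correlation, or Spearman's rank correlation
#' computed on average ranks (midranks for ties); in both cases the p-value
#' comes from the t approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `r`, `p`, `n`, and `method`.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Fisher z test comparing two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. The sign of `z` follows the caller's argument
#' order (`r1` minus `r2`); swapping the pairs negates `z`.
#'
#' @param r1,r2 independent sample correlations, strictly inside (-1, 1).
#' @param n1,n2 their sample sizes, each > 3.
#' @return list with `z` and two-sided `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Independent two-sample t-test
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
independent_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs >= 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      df <- if (variant == "student") length(x) + length(y) - 2 else NA_real_
      return(list(t = 0, df = df, p = 1))
    }
    stop("zero variance with unequal means: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
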