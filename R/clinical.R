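#' Cohen's d effect size
#'
#' Paired: `mean(y - x) / SD(y - x)`. Unpaired: difference of means over
#' the pooled SD (n-1 weights).
#'
#' @param x,y numeric vectors (equal length when paired).
#' @param paired paired design?
#' @return scalar d.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired requires equal lengths")
    if (length(x) < 2L) stop("need at least 2 pairs")
    d <- y - x
    s <- stats::sd(d)
    if (s == 0) {
      if (mean(d) == 0) return(0)       # identical pairs: no effect
      stop("zero SD of paired differences; d undefined")
    }
    return(mean(d) / s)
  }
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) stop("zero pooled SD; d undefined")
  (mean(y) - mean(x)) / sp
}

#' Percent improvement of a score
#'
#' `100 * (mean(pre) - mean(post)) / mean(pre)`; negative when the score
#' worsened.
#'
#' @param pre,post numeric vectors of baseline and follow-up scores.
#' @return percentage.
#' @export
percent_improvement <- function(pre, post) {
  if (mean(pre) <= 0) stop("baseline mean must be positive")
  100 * (mean(pre) - mean(post)) / mean(pre)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y numeric vectors, length >= 5.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Welch two-sample t-test with effect size
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return list: `t`, `df`, `p`, `d` (unpaired Cohen's d).
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = cohens_d(y, x))
}

#' Longitudinal random-intercept mixed model
#'
#' Fits `value ~ timepoint + (1 | subject)` by REML with the timepoint as
#' a categorical factor (baseline = smallest timepoint is the reference
#' level), reports a Wald omnibus test on the timepoint factor, and
#' post-hoc contrasts of each follow-up level against baseline using the
#' normal approximation, with a paired Cohen's d computed from the
#' subjects observed at both levels. Unbalanced follow-up is allowed;
#' contrasts are unadjusted unless `adjust = "holm"`.
#'
#' @param data data frame with columns `subject_id`, `timepoint_months`
#'   and the outcome.
#' @param outcome name of the outcome column (default `"value"`).
#' @param adjust `"none"` (default) or `"holm"` for the contrast p-values.
#' @return object of class `lmm_longitudinal`: `model` (the `lmerMod`),
#'   `fixed` (estimates), `omnibus` (`chisq`, `F`, `df`, `p`),
#'   `contrasts` (data frame: level, estimate, se, statistic, p, d, n_pairs).
#' @export
fit_longitudinal_lmm <- function(data, outcome = "value", adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("subject_id", "timepoint_months", outcome) %in% names(data)))
  lv <- sort(unique(data$timepoint_months))
  if (length(lv) < 2L) stop("need at least 2 timepoint levels")
  if (length(unique(data$subject_id)) < 5L) stop("need at least 5 subjects")
  d <- data.frame(subject_id = factor(data$subject_id),
                  timepoint = factor(data$timepoint_months, levels = lv),
                  value = data[[outcome]])
  fit <- lme4::lmer(value ~ timepoint + (1 | subject_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  cc <- fit@optinfo$conv$lme4
  if (!is.null(cc$code) && cc$code < 0)
    stop("mixed model failed to converge: ",
         paste(unlist(cc$messages), collapse = "; "))
  b <- lme4::fixef(fit)
  Vb <- as.matrix(stats::vcov(fit))
  ii <- seq_along(b)[-1]
  chisq <- as.numeric(t(b[ii]) %*% solve(Vb[ii, ii, drop = FALSE], b[ii]))
  df1 <- length(ii)
  omnibus <- list(chisq = chisq, F = chisq / df1, df = df1,
                  p = stats::pchisq(chisq, df1, lower.tail = FALSE))
  ctr <- vector("list", length(ii))
  for (j in seq_along(ii)) {
    est <- b[ii[j]]; se <- sqrt(Vb[ii[j], ii[j]])
    z <- est / se
    lev <- lv[j + 1]
    base <- d[d$timepoint == lv[1], c("subject_id", "value")]
    post <- d[d$timepoint == lev, c("subject_id", "value")]
    common <- intersect(base$subject_id, post$subject_id)
    dd <- NA_real_
    if (length(common) >= 2L) {
      xb <- base$value[match(common, base$subject_id)]
      xp <- post$value[match(common, post$subject_id)]
      dd <- tryCatch(cohens_d(xb, xp, paired = TRUE), error = function(e) NA_real_)
    }
    ctr[[j]] <- data.frame(level = sprintf("m%g vs m%g", lev, lv[1]),
                           estimate = unname(est), se = unname(se),
                           statistic = unname(z),
                           p = 2 * stats::pnorm(-abs(z)),
                           d = dd, n_pairs = length(common),
                           stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, ctr)
  if (adjust == "holm") contrasts$p <- stats::p.adjust(contrasts$p, "holm")
  structure(list(model = fit, fixed = b, omnibus = omnibus,
                 contrasts = contrasts, adjust = adjust,
                 df_method = "normal approximation"),
            class = "lmm_longitudinal")
}

#' @export
print.lmm_longitudinal <- function(x, ...) {
  cat("Longitudinal random-intercept model (REML)\n")
  cat(sprintf("  omnibus Wald chisq(%d) = %.3f, p = %.4g\n",
              x$omnibus$df, x$omnibus$chisq, x$omnibus$p))
  cat("  contrasts vs baseline (", x$df_method, "):\n", sep = "")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
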