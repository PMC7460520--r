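#' Diagnostic concordance summary of staged cases
#'
#' Compares predicted FIGO stages with the pathology reference:
#' `compatible` when they agree, `over` when IB is called on a true IA
#' (over-staging), `under` when IA is called on a true IB. The over- and
#' under-diagnosis rates are fractions of the *incompatible* cases.
#'
#' @param pred_stages,true_stages Equal-length vectors over
#'   `c("IA", "IB")`.
#' @return A one-row tibble: `n`, `n_compatible`, `n_over`, `n_under`,
#'   `accuracy`, `over_diagnosis_rate`, `under_diagnosis_rate`,
#'   `rates_defined` (FALSE when there are no incompatible cases, in which
#'   case both rates are reported as 0).
#' @export
diagnostic_summary <- function(pred_stages, true_stages) {
  if (length(pred_stages) != length(true_stages)) {
    abort_myo("stage vectors must have equal length")
  }
  pred_stages <- as.character(pred_stages)
  true_stages <- as.character(true_stages)
  if (!all(c(pred_stages, true_stages) %in% c("IA", "IB"))) {
    abort_myo("stages must be 'IA' or 'IB'")
  }
  n <- length(pred_stages)
  n_over <- sum(pred_stages == "IB" & true_stages == "IA")
  n_under <- sum(pred_stages == "IA" & true_stages == "IB")
  n_compat <- n - n_over - n_under
  n_bad <- n_over + n_under
  tibble::tibble(
    n = n, n_compatible = n_compat, n_over = n_over, n_under = n_under,
    accuracy = n_compat / n,
    over_diagnosis_rate = if (n_bad > 0) n_over / n_bad else 0,
    under_diagnosis_rate = if (n_bad > 0) n_under / n_bad else 0,
    rates_defined = n_bad > 0
  )
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with df = 1 (no
#' Yates continuity correction, matching the source software's convention
#' for these tables). Expected cell counts below 5 raise a flag, not an
#' error.
#'
#' @param tab A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @return A `myo_chi2` object with `chi2`, `df`, `p`, `expected`,
#'   `small_expected` flag and the input `table`.
#' @export
pearson_chi2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0)) {
    abort_myo("a 2x2 table of non-negative counts is required")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_myo("chi-square statistic undefined: zero row or column total",
              class = "myoinvade_degenerate_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(
      chi2 = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value, expected = ht$expected,
      small_expected = any(ht$expected < 5), table = tab
    ),
    class = "myo_chi2"
  )
}

#' @export
print.myo_chi2 <- function(x, ...) {
  cat(sprintf("Pearson chi-square (no continuity correction): X2 = %.4f, df = %d, p = %.4f\n",
              x$chi2, x$df, x$p))
  if (x$small_expected) cat("  note: expected cell count < 5\n")
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return A `myo_cor` object with `r`, `p` (two-sided, t-transform with
#'   n - 2 df) and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort_myo("x and y must have equal length")
  if (length(x) < 3) abort_myo("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_myo("correlation undefined for constant input",
              class = "myoinvade_degenerate_error")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ht$estimate), p = ht$p.value, n = length(x)),
    class = "myo_cor"
  )
}

#' @export
print.myo_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via a linear model on the group
#' factor. A degenerate design with zero within-group variance but
#' separated means is reported as `F = Inf`, `p = 0` with a flag.
#'
#' @param groups A list of (>= 2) numeric vectors.
#' @return A `myo_anova` object with `F`, `df_between`, `df_within`, `p`,
#'   `degenerate` flag.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_myo("at least two groups are required")
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- length(groups) - 1L
  df_w <- length(value) - length(groups)
  if (df_w < 1) abort_myo("at least 2 residual degrees of freedom required")
  # perfect-fit warnings are handled explicitly via the degenerate branch
  aov_tab <- suppressWarnings(stats::anova(stats::lm(value ~ grp)))
  ssb <- aov_tab$`Sum Sq`[1]
  ssw <- aov_tab$`Sum Sq`[2]
  if (ssw <= .Machine$double.eps * sum(value^2) && ssb > 0) {
    return(structure(
      list(F = Inf, df_between = df_b, df_within = df_w, p = 0,
           degenerate = TRUE),
      class = "myo_anova"
    ))
  }
  structure(
    list(
      F = aov_tab$`F value`[1], df_between = df_b, df_within = df_w,
      p = aov_tab$`Pr(>F)`[1], degenerate = FALSE
    ),
    class = "myo_anova"
  )
}

#' @export
print.myo_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

#' Five-number summary
#'
#' Minimum, lower quartile, median, upper quartile, maximum with
#' linear-interpolation quartiles (`stats::quantile` type 7, the common
#' convention; switchable).
#'
#' @param values Non-empty numeric vector.
#' @param type Quantile convention passed to [stats::quantile()].
#' @return A one-row tibble `min`, `q1`, `median`, `q3`, `max`.
#' @export
five_number_summary <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort_myo("empty input")
  q <- stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                       type = type, names = FALSE)
  tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

# ---- broom-style tidiers -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.myo_chi2 <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi2, df = x$df, p.value = x$p,
    method = "Pearson chi-square (no continuity correction)"
  )
}

#' @export
glance.myo_chi2 <- function(x, ...) tidy.myo_chi2(x)

#' @export
tidy.myo_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n = x$n,
                 method = "Pearson correlation")
}

#' @export
tidy.myo_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df = x$df_between, df.residual = x$df_within,
    p.value = x$p, method = "one-way ANOVA"
  )
}

#' @export
tidy.myo_training <- function(x, ...) x$history

#' @export
glance.myo_training <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    return(tibble::tibble(epochs = 0L, best_epoch = x$best_epoch))
  }
  best <- h[h$epoch == x$best_epoch, ]
  tibble::tibble(
    epochs = nrow(h), best_epoch = x$best_epoch,
    best_val_loss = best$val_loss,
    val_iou_uterus = best$val_iou_uterus,
    val_iou_lesion = best$val_iou_lesion
  )
}
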