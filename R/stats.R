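# Statistical layer: Relative Response Ratio normalization, pooled and
# nested two-sample t tests, significance stars, mean +/- SEM.

#' Bundle the six integrated-density inputs of the RRR
#'
#' `I` is the integrated density per cell for the test construct, the
#' negative-control construct (empty vector) and the positive-control
#' construct (reference scaffold), each measured in the mutant and the
#' wild-type background.
#'
#' @param I_test_mut,I_test_wt Test construct in mutant / wild-type.
#' @param I_neg_mut,I_neg_wt Negative control (empty vector).
#' @param I_pos_mut,I_pos_wt Positive control (reference scaffold).
#' @return An object of class `rrr_inputs`.
#' @export
rrr_inputs <- function(I_test_mut, I_test_wt, I_neg_mut, I_neg_wt,
                       I_pos_mut, I_pos_wt) {
  vals <- c(I_test_mut = I_test_mut, I_test_wt = I_test_wt,
            I_neg_mut = I_neg_mut, I_neg_wt = I_neg_wt,
            I_pos_mut = I_pos_mut, I_pos_wt = I_pos_wt)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("all RRR inputs must be finite")
  if (I_test_wt <= 0 || I_neg_wt <= 0 || I_pos_wt <= 0)
    stop(errorCondition(
      "all wild-type integrated densities must be strictly positive",
      class = c("pq_zero_denominator", "error")))
  if (abs(I_pos_mut / I_pos_wt - I_neg_mut / I_neg_wt) < .Machine$double.eps)
    stop(errorCondition(
      "positive- and negative-control ratios coincide: RRR denominator is zero",
      class = c("pq_degenerate_controls", "error")))
  structure(as.list(vals), class = "rrr_inputs")
}

#' Relative Response Ratio
#'
#' Maps the test construct's mutant-vs-wild-type response onto a scale
#' anchored at the controls:
#' \deqn{RRR = \frac{I_{test,mut}/I_{test,wt} - I_{neg,mut}/I_{neg,wt}}
#'                  {I_{pos,mut}/I_{pos,wt} - I_{neg,mut}/I_{neg,wt}}}
#' so the negative control maps to 0 and the positive control to 1 by
#' construction.  Values below 0 indicate a response attenuated even
#' relative to the empty vector; values near 1 indicate a response as
#' preserved as the reference scaffold's.
#'
#' @param inputs An [rrr_inputs] object (or a list/vector with the same
#'   six named elements).
#' @return The RRR, a single number.
#' @export
compute_rrr <- function(inputs) {
  if (!inherits(inputs, "rrr_inputs"))
    inputs <- do.call(rrr_inputs, as.list(inputs))
  r_test <- inputs$I_test_mut / inputs$I_test_wt
  r_neg <- inputs$I_neg_mut / inputs$I_neg_wt
  r_pos <- inputs$I_pos_mut / inputs$I_pos_wt
  (r_test - r_neg) / (r_pos - r_neg)
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p,
                 stars = star_code(p), method = method),
            class = "pq_test_result")
}

#' @export
print.pq_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4f, df = %g, p = %.4g (%s)\n",
              x$method, x$statistic, x$df, x$p, x$stars))
  invisible(x)
}

#' Two-sample Student's t test
#'
#' Classical pooled-variance two-sided t test (`df = n_a + n_b - 2`);
#' Welch's unequal-variance form is available behind a flag.  If the
#' pooled variance is zero, equal means give `t = 0, p = 1` by convention
#' and unequal means are an error (the statistic is undefined).
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param welch Use Welch's correction instead of pooling.
#' @return A `pq_test_result` (statistic, df, p, stars, method).
#' @export
student_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, length(a) + length(b) - 2L, 1, "student"))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (welch) "welch" else "student")
}

#' Build a nested sample (values grouped by experiment)
#'
#' @param values Numeric measurements.
#' @param experiment Replicate-experiment id for each value.
#' @param group Optional group label.
#' @return An object of class `nested_sample`.
#' @export
nested_sample <- function(values, experiment, group = NA_character_) {
  stopifnot(length(values) == length(experiment), length(values) >= 1L)
  structure(list(group = group, values = as.numeric(values),
                 experiment = as.character(experiment)),
            class = "nested_sample")
}

#' Nested (hierarchical) two-sample t test
#'
#' Respects the replicate structure of values nested within independent
#' experiments, guarding against pseudoreplication: the group comparison
#' uses the between-experiment mean square as its error term.  With
#' experiments `e = 1..m_a + m_b`,
#' `t^2 = MS(group) / MS(experiment within group)` and
#' `df = m_a + m_b - 2`, the one-way nested-ANOVA ratio (the closed-form
#' equivalent of Prism's nested t test in the balanced case; unbalanced
#' designs use the same sums of squares and df convention).  When every
#' experiment contributes exactly one value this reduces exactly to
#' [student_t] on the values.
#'
#' @param a,b [nested_sample] objects, each with >= 2 experiments.
#' @return A `pq_test_result` with method `"nested"`.
#' @export
nested_t <- function(a, b) {
  stopifnot(inherits(a, "nested_sample"), inherits(b, "nested_sample"))
  ma <- length(unique(a$experiment))
  mb <- length(unique(b$experiment))
  if (ma < 2L || mb < 2L)
    stop("the nested t test needs >= 2 experiments per group")
  grand <- c(a$values, b$values)
  gmean <- mean(grand)

  ss_group <- 0; ss_expt <- 0
  sign_diff <- sign(mean(a$values) - mean(b$values))
  for (s in list(a, b)) {
    gm <- mean(s$values)
    ss_group <- ss_group + length(s$values) * (gm - gmean)^2
    for (vals in split(s$values, s$experiment))
      ss_expt <- ss_expt + length(vals) * (mean(vals) - gm)^2
  }
  df_expt <- ma + mb - 2L
  ms_group <- ss_group / 1
  ms_expt <- ss_expt / df_expt
  if (ms_expt == 0) {
    if (ms_group == 0) return(test_result(0, df_expt, 1, "nested"))
    stop("zero between-experiment mean square with unequal group means: ",
         "t is undefined")
  }
  tval <- if (sign_diff == 0) 0 else sign_diff * sqrt(ms_group / ms_expt)
  p <- 2 * stats::pt(-abs(tval), df_expt)
  test_result(tval, df_expt, p, "nested")
}

#' Significance stars for a p-value
#'
#' Strict-inequality coding: `"****"` for p < 0.0001, `"***"` for
#' p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, otherwise `"n.s."`
#' (so p = 0.05 exactly is non-significant).
#'
#' @param p A p-value in \[0, 1\].
#' @return A character significance label.
#' @export
star_code <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "n.s."
}

#' Mean and standard error of the mean
#'
#' `SEM = sd(x) / sqrt(n)` with the sample (n - 1) SD.  A single value
#' yields its mean with `NA` SEM.
#'
#' @param values Numeric vector (non-empty).
#' @return Named numeric `c(mean, sem)`.
#' @export
mean_sem <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (length(values) == 1L)
    return(c(mean = values[[1]], sem = NA_real_))
  c(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}
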