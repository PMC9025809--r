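## Two-group trait comparison from printed summaries (Welch t) and qPCR
## 2^-ddCt relative expression.

#' Two-sample t test from group summaries
#'
#' Computes the t statistic from means, standard deviations and group sizes
#' alone, so printed summary tables can be re-tested. Welch's unequal
#' variance form is the default (matching the default of R's `t.test`); the
#' pooled-variance form is available via `pooled = TRUE`. The sign convention
#' is group 1 minus group 2 in the order given.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param pooled Use the pooled-variance (classic Student) form.
#' @return List with `t`, `df` (Welch-Satterthwaite or `n1 + n2 - 2`) and the
#'   two-sided `p_value`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  v1 <- sd1^2; v2 <- sd2^2
  if (v1 == 0 && v2 == 0) {
    if (mean1 == mean2)
      return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' t tests for a table of trait summaries
#'
#' @param traits Data frame with columns `trait`, `mean_1`, `sd_1`, `n_1`,
#'   `mean_2`, `sd_2`, `n_2` (group 1 minus group 2 sign convention).
#' @param pooled Passed to [welch_t_from_summary()].
#' @return `traits` with `t`, `df` and `p_value` columns appended.
#' @export
trait_table_tests <- function(traits, pooled = FALSE) {
  res <- lapply(seq_len(nrow(traits)), function(i)
    welch_t_from_summary(traits$mean_1[i], traits$sd_1[i], traits$n_1[i],
                         traits$mean_2[i], traits$sd_2[i], traits$n_2[i],
                         pooled = pooled))
  traits$t <- vapply(res, `[[`, 0, "t")
  traits$df <- vapply(res, `[[`, 0, "df")
  traits$p_value <- vapply(res, `[[`, 0, "p_value")
  traits
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Replicate cycle thresholds are averaged per sample; delta Ct is target
#' minus reference gene; delta-delta Ct subtracts the mean delta Ct of the
#' calibrator group; relative expression is `2^(-ddCt)`. The calibrator
#' group's mean ddCt is exactly zero (its mean *relative expression* need not
#' be exactly 1, the geometric/arithmetic mean gap).
#'
#' @param ct Data frame with columns `sample_id`, `group`, `target_ct`,
#'   `reference_ct` (one row per replicate; a `replicate` column is allowed
#'   and ignored).
#' @param calibrator_group Group name used as the baseline.
#' @return Data frame per sample: `sample_id`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `relative_expression`.
#' @export
ddct_relative_expression <- function(ct, calibrator_group) {
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns ", paste(need, collapse = ", "))
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' not present")
  bad <- unique(ct$sample_id[is.na(ct$reference_ct)])
  if (length(bad))
    stop("missing reference-gene Ct for sample(s): ",
         paste(bad, collapse = ", "))
  if (any(ct$target_ct <= 0, na.rm = TRUE) || any(ct$reference_ct <= 0))
    stop("Ct values must be positive")
  tgt <- tapply(ct$target_ct, ct$sample_id, mean)
  ref <- tapply(ct$reference_ct, ct$sample_id, mean)
  grp <- tapply(as.character(ct$group), ct$sample_id, `[`, 1L)
  samples <- names(tgt)
  dct <- tgt[samples] - ref[samples]
  ddct <- dct - mean(dct[grp[samples] == calibrator_group])
  data.frame(sample_id = samples, group = unname(grp[samples]),
             delta_ct = unname(dct), delta_delta_ct = unname(ddct),
             relative_expression = unname(2^(-ddct)),
             row.names = NULL, stringsAsFactors = FALSE)
}
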