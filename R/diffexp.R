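#' Moderated two-group differential enrichment test
#'
#' Tests bait vs control group means on a log2 protein matrix with an
#' empirical-Bayes moderated t-statistic. Per-protein residual variances
#' s_g^2 (pooled over the two groups, d_g = n1 + n2 - 2 df) are shrunk
#' toward a prior (d0, s0^2) estimated from the observed variance
#' distribution under a scaled-F model, giving the posterior variance
#'
#' \deqn{s_{post}^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#'
#' and `t_mod = log2_fc / (s_post * sqrt(1/n1 + 1/n2))` with `d0 + d_g`
#' degrees of freedom. The prior is fitted by matching the first two moments
#' of `log(s_g^2)` to the log scaled-F distribution via digamma/trigamma
#' identities, with the trigamma inverted by a monotone Newton iteration;
#' when the method-of-moments dispersion is non-positive the prior df is
#' infinite and all posterior variances collapse to s0^2.
#'
#' @param matrix an imputed, log2 [protein_matrix()].
#' @param design a [study_design()] covering the matrix columns.
#' @param bait_group,control_group group labels; the contrast is always
#'   bait minus control.
#' @param prior_df optional override of the prior degrees of freedom d0.
#'   `0` disables moderation (classical pooled t-test), `Inf` forces
#'   complete shrinkage; `NULL` (default) estimates d0 from the data.
#' @param var_floor per-protein variances below this are floored before
#'   prior estimation (guards zero variances from constant imputation).
#'
#' @return list with `result` (a [diff_result()]; `call` is filled by
#'   [classify_calls()]) and `fit` (an `ebayes_fit` with `d0`, `s0_sq`,
#'   per-protein `s_g_sq`, `d_g`, `s_post_sq`).
#' @export
fit_moderated <- function(matrix, design, bait_group, control_group,
                          prior_df = NULL, var_floor = 1e-12) {
  stopifnot(inherits(matrix, "protein_matrix"),
            inherits(design, "study_design"))
  if (!pm_flag(matrix, "log2") || !pm_flag(matrix, "imputed")) {
    stop("fit_moderated needs an imputed, log2-transformed matrix",
         call. = FALSE)
  }
  s1 <- intersect(colnames(matrix), samples_of(design, bait_group))
  s2 <- intersect(colnames(matrix), samples_of(design, control_group))
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2 || n2 < 2) {
    stop("both groups need at least 2 samples in the matrix", call. = FALSE)
  }

  x1 <- unclass(matrix)[, s1, drop = FALSE]
  x2 <- unclass(matrix)[, s2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  log2_fc <- m1 - m2
  d_g <- n1 + n2 - 2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s_g_sq <- ss / d_g
  if (all(s_g_sq <= 0)) {
    stop("all residual variances are zero; the fit is degenerate",
         call. = FALSE)
  }
  s_g_sq <- pmax(s_g_sq, var_floor)

  if (is.null(prior_df)) {
    pri <- fit_f_prior(s_g_sq, d_g)
    d0 <- pri$d0
    s0_sq <- pri$s0_sq
  } else {
    stopifnot(prior_df >= 0)
    d0 <- prior_df
    s0_sq <- if (is.infinite(d0)) exp(mean(log(s_g_sq))) else
      mean(s_g_sq)
  }

  s_post_sq <- if (is.infinite(d0)) rep(s0_sq, length(s_g_sq)) else
    (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  df_total <- d0 + d_g
  t_mod <- log2_fc / sqrt(s_post_sq * (1 / n1 + 1 / n2))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)

  res <- diff_result(data.frame(
    protein_group = rownames(matrix),
    log2_fc = log2_fc,
    t_mod = t_mod,
    df_total = df_total,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    pi_value = pi_value(p_raw, log2_fc),
    call = "not_significant",
    stringsAsFactors = FALSE
  ))
  fit <- structure(
    list(d0 = d0, s0_sq = s0_sq, s_g_sq = s_g_sq,
         d_g = rep(d_g, length(s_g_sq)), s_post_sq = s_post_sq),
    class = "ebayes_fit")
  list(result = res, fit = fit)
}

# Moment estimation of the scaled-F prior (d0, s0^2) from per-protein
# variances s2 with d df each: match mean/var of log s2 to the theoretical
# log-F moments through digamma/trigamma.
fit_f_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2) return(list(d0 = Inf, s0_sq = exp(emean)))
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar <= 0) {
    # no excess dispersion over chi-squared sampling noise: infinite prior df
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the monotone
# decreasing trigamma; converges globally for x > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed significance score (pi-value)
#'
#' `-log10(p) * sign(log2_fc)`; zero fold change gives 0. A p-value of
#' exactly 0 is clamped to the smallest representable positive double with
#' a warning.
#'
#' @param p_raw raw p-values in `(0, 1]`.
#' @param log2_fc log2 fold changes.
#' @return numeric vector of pi-values.
#' @export
pi_value <- function(p_raw, log2_fc) {
  stopifnot(length(p_raw) == length(log2_fc),
            all(p_raw >= 0 & p_raw <= 1))
  if (any(p_raw == 0)) {
    warning("p-value of 0 clamped to .Machine$double.xmin")
    p_raw[p_raw == 0] <- .Machine$double.xmin
  }
  -log10(p_raw) * sign(log2_fc)
}

#' Classify proteins as enriched / de-enriched / not significant
#'
#' A protein is enriched when its fold change exceeds `fc_threshold` and its
#' BH-adjusted p-value is below `alpha`; de-enriched symmetric on the
#' negative side; everything else is not significant.
#'
#' @param result a [diff_result()].
#' @param fc_threshold fold-change threshold on the linear scale (default 2,
#'   i.e. |log2 FC| > 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the [diff_result()] with the `call` column filled.
#' @export
classify_calls <- function(result, fc_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(result, "diff_result"), fc_threshold > 0)
  lfc <- log2(fc_threshold)
  call <- rep("not_significant", nrow(result))
  call[result$log2_fc > lfc & result$p_adj < alpha] <- "enriched"
  call[result$log2_fc < -lfc & result$p_adj < alpha] <- "de_enriched"
  result$call <- call
  result
}
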