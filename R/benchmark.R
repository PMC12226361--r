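#' Cross-control occurrence-frequency consensus
#'
#' Counts, for every protein, in how many differential comparisons it was
#' called enriched. Proteins with a high occurrence frequency across
#' independent control comparisons are treated as high-confidence
#' interactors; background proteins that slip through one comparison rarely
#' recur across controls with different expression levels.
#'
#' @param results list of [diff_result()]s over comparable protein universes
#'   (at least 2). A protein absent from one result contributes 0 for it.
#' @param threshold occurrence frequency at or above which a protein is
#'   flagged high-confidence (e.g. 3 of 6 controls).
#' @return a [consensus_result()].
#' @export
occurrence_frequency <- function(results, threshold = 3L) {
  stopifnot(is.list(results), length(results) >= 2)
  lapply(results, function(r) stopifnot(inherits(r, "diff_result")))
  if (threshold > length(results)) {
    stop("threshold (", threshold, ") exceeds the number of comparisons (",
         length(results), ")", call. = FALSE)
  }
  proteins <- sort(unique(unlist(lapply(results, `[[`, "protein_group"))))
  freq <- integer(length(proteins))
  names(freq) <- proteins
  for (r in results) {
    enriched <- r$protein_group[r$call == "enriched"]
    freq[enriched] <- freq[enriched] + 1L
  }
  consensus_result(data.frame(
    protein_group = proteins,
    occurrence_frequency = as.integer(freq),
    n_comparisons = length(results),
    high_confidence = freq >= threshold,
    stringsAsFactors = FALSE
  ))
}

#' ROC analysis of a differential result against known interactors
#'
#' Proteins are ranked by pi-value (descending); every quantified protein
#' not in the positive set is a negative. The AUROC is the rank
#' (Mann-Whitney) statistic with ties averaged, which equals trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param result a [diff_result()].
#' @param positives character vector of known-interactor protein ids.
#' @return list with `auroc`, `n_pos`, `n_neg` and `curve` (data.frame of
#'   `fpr`, `tpr` points including the (0,0) and (1,1) endpoints).
#' @export
roc_analysis <- function(result, positives) {
  stopifnot(inherits(result, "diff_result"))
  lab <- result$protein_group %in% positives
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0) {
    stop("no positives among the quantified proteins", call. = FALSE)
  }
  if (n_neg == 0) stop("no negatives among the quantified proteins",
                       call. = FALSE)
  score <- result$pi_value
  r <- rank(score, ties.method = "average")
  auroc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # empirical curve: sweep thresholds from high to low score
  ord <- order(score, decreasing = TRUE)
  lab_o <- lab[ord]
  score_o <- score[ord]
  # collapse tied scores into single thresholds
  last_of_tie <- c(score_o[-1] != score_o[-length(score_o)], TRUE)
  tpr <- cumsum(lab_o)[last_of_tie] / n_pos
  fpr <- cumsum(!lab_o)[last_of_tie] / n_neg
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(auroc = auroc, n_pos = n_pos, n_neg = n_neg, curve = curve)
}

#' Assign abundance quartiles from a whole-cell proteome
#'
#' Rank-based quartiles of whole-cell abundance: `Q1_top` is the top 25%,
#' then `Q2` (25-50%), `Q3` (50-75%), `Q4_bottom`. Ties are broken by
#' stable protein-id order so the assignment is deterministic; quartile
#' sizes differ by at most one. The top 1% most abundant proteins are also
#' flagged.
#'
#' @param wholecell named numeric vector of positive abundances.
#' @return data.frame with `protein_group`, `abundance_quartile` (factor
#'   with levels `Q1_top`, `Q2`, `Q3`, `Q4_bottom`) and `top1pct`.
#' @export
abundance_quartiles <- function(wholecell) {
  if (length(wholecell) == 0) stop("empty abundance table", call. = FALSE)
  if (any(is.na(wholecell) | wholecell <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (is.null(names(wholecell))) {
    stop("abundances must be named by protein", call. = FALSE)
  }
  n <- length(wholecell)
  ord <- order(-wholecell, names(wholecell))  # abundant first; stable ties
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  q <- ceiling(4 * pos / n)
  levels_q <- c("Q1_top", "Q2", "Q3", "Q4_bottom")
  data.frame(
    protein_group = names(wholecell),
    abundance_quartile = factor(levels_q[q], levels = levels_q),
    top1pct = pos <= ceiling(0.01 * n),
    stringsAsFactors = FALSE
  )
}

group_mean_matrix <- function(matrix, design) {
  groups <- unique(design$group)
  out <- matrix(NA_real_, nrow(matrix), length(groups),
                dimnames = list(rownames(matrix), groups))
  for (g in groups) {
    cols <- intersect(colnames(matrix), samples_of(design, g))
    if (!length(cols)) next
    sub <- unclass(matrix)[, cols, drop = FALSE]
    mg <- rowMeans(sub, na.rm = TRUE)
    mg[!is.finite(mg)] <- NA_real_
    out[, g] <- mg
  }
  out
}

#' Relative intensities against a baseline expression group
#'
#' Per protein, the ratio of each group's mean (unlogged) intensity to the
#' baseline group's mean; proteins without a baseline mean get missing
#' ratios and are excluded from quartile summaries. When a quartile map is
#' supplied, per-quartile (and top-1%) arithmetic means of the ratios are
#' reported — the quantity that reveals how much more low-abundance proteins
#' gain from rising TurboID expression than high-abundance proteins do.
#'
#' @param matrix a non-log2 [protein_matrix()] (missing cells allowed).
#' @param design a [study_design()].
#' @param baseline_group label of the baseline (lowest-expression) group.
#' @param quartiles optional result of [abundance_quartiles()].
#' @return list with `ratios` (protein x group matrix) and, when quartiles
#'   are given, `quartile_means` (data.frame group x quartile) with a
#'   `top1pct` column.
#' @export
relative_intensity <- function(matrix, design, baseline_group,
                               quartiles = NULL) {
  stopifnot(inherits(matrix, "protein_matrix"),
            inherits(design, "study_design"))
  if (pm_flag(matrix, "log2")) {
    stop("relative_intensity uses unlogged intensities", call. = FALSE)
  }
  if (!baseline_group %in% design$group) {
    stop("baseline group '", baseline_group, "' is not in the design",
         call. = FALSE)
  }
  gm <- group_mean_matrix(matrix, design)
  base <- gm[, baseline_group]
  ratios <- gm / base  # rows without baseline become NA
  ratios[is.na(base), ] <- NA_real_

  out <- list(ratios = ratios)
  if (!is.null(quartiles)) {
    qm <- quartiles[match(rownames(ratios), quartiles$protein_group), ]
    groups <- colnames(ratios)
    levels_q <- levels(qm$abundance_quartile)
    qmeans <- matrix(NA_real_, length(groups), length(levels_q) + 1L,
                     dimnames = list(groups, c(levels_q, "top1pct")))
    for (g in groups) {
      for (q in levels_q) {
        sel <- !is.na(qm$abundance_quartile) & qm$abundance_quartile == q
        qmeans[g, q] <- mean(ratios[sel, g], na.rm = TRUE)
      }
      qmeans[g, "top1pct"] <- mean(ratios[which(qm$top1pct), g],
                                   na.rm = TRUE)
    }
    out$quartile_means <- as.data.frame(qmeans)
  }
  out
}

#' Per-protein linear response to TurboID expression
#'
#' Fits, for every protein, an ordinary least-squares line of group-mean
#' intensity against the group's TurboID expression, and summarizes the
#' fraction of proteins whose coefficient of determination exceeds a
#' threshold. Proteins quantified in fewer than 3 groups are excluded;
#' a zero-variance response is assigned R-squared 0.
#'
#' @param matrix a non-log2 [protein_matrix()] (missing cells allowed), or a
#'   precomputed protein x group mean matrix.
#' @param design a [study_design()] with >= 3 groups of distinct expression.
#' @param r2_threshold threshold for the summary fraction (default 0.5).
#' @return list with `fits` (data.frame: `protein_group`, `slope`,
#'   `intercept`, `r_squared`, `n_groups_used`) and `frac_r2_above`
#'   (fraction of included proteins with R-squared above the threshold).
#' @export
expression_response_fit <- function(matrix, design, r2_threshold = 0.5) {
  stopifnot(inherits(design, "study_design"))
  E_g <- group_expression(design)
  if (length(unique(E_g)) < 3) {
    stop("need >= 3 groups with distinct TurboID expression", call. = FALSE)
  }
  gm <- if (inherits(matrix, "protein_matrix")) {
    if (pm_flag(matrix, "log2")) {
      stop("expression_response_fit uses unlogged intensities",
           call. = FALSE)
    }
    group_mean_matrix(matrix, design)
  } else {
    as.matrix(matrix)
  }
  gm <- gm[, intersect(colnames(gm), names(E_g)), drop = FALSE]
  E <- E_g[colnames(gm)]

  n_used <- rowSums(!is.na(gm))
  fits <- data.frame(protein_group = rownames(gm),
                     slope = NA_real_, intercept = NA_real_,
                     r_squared = NA_real_, n_groups_used = n_used,
                     stringsAsFactors = FALSE)
  for (i in which(n_used >= 3)) {
    y <- gm[i, ]
    ok <- !is.na(y)
    x <- E[ok]; y <- y[ok]
    sxx <- sum((x - mean(x))^2)
    sst <- sum((y - mean(y))^2)
    if (sxx == 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    ssr <- sum((y - (a + b * x))^2)
    fits$slope[i] <- b
    fits$intercept[i] <- a
    # flat response: no expression dependence by construction
    fits$r_squared[i] <- if (sst == 0) 0 else 1 - ssr / sst
  }
  incl <- fits$n_groups_used >= 3 & !is.na(fits$r_squared)
  list(fits = fits,
       frac_r2_above = if (any(incl)) {
         mean(fits$r_squared[incl] > r2_threshold)
       } else NA_real_)
}

#' Control-matching report
#'
#' Summarizes, for every candidate control, how far its TurboID expression
#' sits from the bait's (log2 mismatch of group-mean expression), the number
#' of enriched and de-enriched calls it produces, and — when simulator
#' ground truth is available — the false-positive, false-negative and
#' true-positive counts of its enriched set. Only the enriched arm counts as
#' discoveries. The recommended control is the one minimizing the absolute
#' expression mismatch.
#'
#' @param diff_results named list of [diff_result()]s, one per control group
#'   (names = control group labels), all against the same bait.
#' @param design a [study_design()].
#' @param bait_group bait group label.
#' @param truth optional ground-truth data.frame from
#'   [simulate_experiment()].
#' @return list with `report` (data.frame per control) and
#'   `recommended_control`.
#' @export
matching_report <- function(diff_results, design, bait_group, truth = NULL) {
  stopifnot(is.list(diff_results), length(diff_results) >= 1,
            !is.null(names(diff_results)),
            inherits(design, "study_design"))
  E_g <- group_expression(design)
  if (!bait_group %in% names(E_g)) {
    stop("bait group '", bait_group, "' is not in the design", call. = FALSE)
  }
  if (E_g[bait_group] == 0) {
    stop("bait group has zero TurboID expression", call. = FALSE)
  }
  interactors <- if (!is.null(truth)) {
    truth$protein_group[truth$is_interactor]
  } else NULL

  rows <- lapply(names(diff_results), function(ctrl) {
    r <- diff_results[[ctrl]]
    stopifnot(inherits(r, "diff_result"))
    enriched <- r$protein_group[r$call == "enriched"]
    out <- data.frame(
      control = ctrl,
      expression_mismatch = log2(E_g[ctrl] / E_g[bait_group]),
      n_enriched = length(enriched),
      n_de_enriched = sum(r$call == "de_enriched"),
      stringsAsFactors = FALSE
    )
    if (!is.null(interactors)) {
      out$true_positives <- sum(enriched %in% interactors)
      out$false_positives <- sum(!enriched %in% interactors)
      out$false_negatives <- sum(!interactors %in% enriched)
    }
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  rec <- report$control[which.min(abs(report$expression_mismatch))]
  list(report = report, recommended_control = rec)
}
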