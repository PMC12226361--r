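mk_diff <- function(proteins, calls, pi = NULL, fc = NULL) {
  n <- length(proteins)
  diff_result(data.frame(
    protein_group = proteins,
    log2_fc = fc %||% rep(1, n),
    t_mod = 0, df_total = 4, p_raw = 0.5, p_adj = 0.5,
    pi_value = pi %||% rep(0, n),
    call = calls, stringsAsFactors = FALSE
  ))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("occurrence frequency counts enriched calls across comparisons", {
  prot <- c("A", "B", "C")
  results <- lapply(1:6, function(i) {
    mk_diff(prot, c(if (i <= 4) "enriched" else "not_significant",
                    "not_significant",
                    if (i == 1) "enriched" else "de_enriched"))
  })
  cons <- occurrence_frequency(results, threshold = 3)
  expect_equal(cons$occurrence_frequency[cons$protein_group == "A"], 4L)
  expect_true(cons$high_confidence[cons$protein_group == "A"])
  expect_equal(cons$occurrence_frequency[cons$protein_group == "B"], 0L)
  # de-enriched never counts toward the consensus
  expect_equal(cons$occurrence_frequency[cons$protein_group == "C"], 1L)
  expect_error(occurrence_frequency(results, threshold = 7), "exceeds")

  # permutation invariance and absent-protein handling
  shuffled <- occurrence_frequency(rev(results), threshold = 3)
  expect_equal(cons, shuffled)
  results2 <- results
  results2[[1]] <- mk_diff("D", "enriched")
  cons2 <- occurrence_frequency(results2, threshold = 2)
  expect_equal(cons2$occurrence_frequency[cons2$protein_group == "A"], 3L)
  expect_equal(cons2$occurrence_frequency[cons2$protein_group == "D"], 1L)
})

test_that("AUROC equals the rank formula and the trapezoidal curve area", {
  # perfect separation
  r <- mk_diff(sprintf("P%02d", 1:10), rep("not_significant", 10),
               pi = c(5, 4, 3, 2.5, 2, 1, 0.5, 0, -1, -2))
  roc <- roc_analysis(r, positives = sprintf("P%02d", 1:3))
  expect_equal(roc$auroc, 1)

  # single positive at the exact median rank
  r2 <- mk_diff(sprintf("P%02d", 1:9), rep("not_significant", 9),
                pi = 9:1)
  expect_equal(roc_analysis(r2, "P05")$auroc, 0.5)

  # label-independent scores give AUROC near 0.5; rank formula equals
  # trapezoidal integration of the returned curve
  withr::local_seed(77)
  aucs <- replicate(30, {
    n <- 400
    r3 <- mk_diff(sprintf("P%04d", 1:n), rep("not_significant", n),
                  pi = rnorm(n))
    pos <- sample(sprintf("P%04d", 1:n), 40)
    roc3 <- roc_analysis(r3, pos)
    cv <- roc3$curve
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(roc3$auroc, trap, tolerance = 1e-12)
    roc3$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  expect_error(roc_analysis(r, positives = "missing"), "no positives")
})

test_that("abundance quartiles are rank-based with stable tie-breaks", {
  ab <- setNames(as.numeric(1:100), sprintf("P%03d", 1:100))
  qm <- abundance_quartiles(ab)
  top <- qm$protein_group[qm$abundance_quartile == "Q1_top"]
  expect_setequal(top, sprintf("P%03d", 76:100))
  expect_equal(sum(qm$top1pct), 1)
  expect_equal(qm$protein_group[qm$top1pct], "P100")

  # 8 proteins -> quartiles of size 2
  qm8 <- abundance_quartiles(setNames(c(8, 7, 6, 5, 4, 3, 2, 1),
                                      letters[1:8]))
  expect_equal(as.vector(table(qm8$abundance_quartile)), rep(2L, 4))

  # ties at the boundary resolved by protein-id order (deterministic)
  tied <- setNames(c(4, 3, 3, 1), c("d", "b", "a", "z"))
  qt <- abundance_quartiles(tied)
  expect_equal(qt$abundance_quartile[qt$protein_group == "a"],
               factor("Q2", levels = levels(qt$abundance_quartile)))
  expect_equal(qt$abundance_quartile[qt$protein_group == "b"],
               factor("Q3", levels = levels(qt$abundance_quartile)))
  expect_error(abundance_quartiles(numeric(0)), "empty")
  expect_error(abundance_quartiles(setNames(c(1, -2), c("a", "b"))),
               "positive")
})

test_that("relative intensities are ratios to the baseline group mean", {
  m <- matrix(c(10, 10, 200, 200,
                5, 5, NA, NA), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), c("g1_1", "g1_2", "g2_1", "g2_2")))
  d <- study_design(colnames(m), rep(c("g1", "g2"), each = 2),
                    rep("control", 4), rep(1:2, 2), rep(1, 4))
  pm <- protein_matrix(m, "sum")
  ri <- relative_intensity(pm, d, "g1")
  expect_equal(ri$ratios["A", "g2"], 20)
  expect_equal(ri$ratios["A", "g1"], 1)  # baseline vs itself
  expect_true(is.na(ri$ratios["B", "g2"]))  # absent in g2

  # a protein missing in the baseline is excluded from quartile means
  m2 <- rbind(m, C = c(NA, NA, 50, 50))
  pm2 <- protein_matrix(m2, "sum")
  qm <- abundance_quartiles(setNames(c(3, 2, 1), c("A", "B", "C")))
  ri2 <- relative_intensity(pm2, d, "g1", quartiles = qm)
  expect_true(all(is.na(ri2$ratios["C", ])))
  expect_equal(ri2$quartile_means["g2", "Q2"], 20)  # only A contributes
  expect_error(relative_intensity(pm, d, "nope"), "baseline")
})

test_that("expression-response fits recover exact linearity and exclusions", {
  d <- study_design(paste0("g", 1:4, "_1"), paste0("g", 1:4),
                    rep("control", 4), rep(1L, 4), c(0.5, 1, 2, 4))
  E <- c(0.5, 1, 2, 4)
  m <- rbind(
    lin = 10 * E,            # perfect line through origin
    off = 3 + 2 * E,         # perfect line with intercept
    two = c(1, 2, NA, NA),   # only 2 groups: excluded
    flat = c(7, 7, 7, 7)     # zero-variance response: R^2 = 0
  )
  colnames(m) <- paste0("g", 1:4, "_1")
  fit <- expression_response_fit(protein_matrix(m, "sum"), d)
  f <- fit$fits
  expect_equal(f$r_squared[f$protein_group == "lin"], 1)
  expect_equal(f$slope[f$protein_group == "lin"], 10)
  expect_equal(f$r_squared[f$protein_group == "off"], 1)
  expect_true(is.na(f$r_squared[f$protein_group == "two"]))
  expect_equal(f$r_squared[f$protein_group == "flat"], 0)
  expect_equal(fit$frac_r2_above, 2 / 3)  # lin, off of {lin, off, flat}

  d2 <- study_design(c("a", "b"), c("g1", "g2"), rep("control", 2),
                     c(1L, 1L), c(1, 2))
  expect_error(expression_response_fit(protein_matrix(m[, 1:2], "sum"), d2),
               "3 groups")
})

test_that("matching report recommends the expression-matched control", {
  d <- study_design(
    c("b_1", "b_2", "l_1", "l_2", "m_1", "m_2", "h_1", "h_2"),
    rep(c("bait", "low", "mid", "high"), each = 2),
    rep(c("bait", "control", "control", "control"), each = 2),
    rep(1:2, 4), rep(c(2, 0.5, 2, 8), each = 2)
  )
  truth <- data.frame(protein_group = c("A", "B", "C"),
                      is_interactor = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  diffs <- list(
    low = mk_diff(c("A", "B", "C"), c("enriched", "enriched",
                                      "not_significant")),
    mid = mk_diff(c("A", "B", "C"), c("enriched", "not_significant",
                                      "not_significant")),
    high = mk_diff(c("A", "B", "C"), c("not_significant", "not_significant",
                                       "de_enriched"))
  )
  mr <- matching_report(diffs, d, "bait", truth)
  expect_equal(mr$recommended_control, "mid")
  rep <- mr$report
  expect_equal(rep$expression_mismatch, log2(c(0.5, 2, 8) / 2))
  expect_equal(rep$false_positives[rep$control == "low"], 1)
  expect_equal(rep$true_positives[rep$control == "mid"], 1)
  expect_equal(rep$false_negatives[rep$control == "high"], 1)
  # de-enriched calls are not discoveries
  expect_equal(rep$n_de_enriched[rep$control == "high"], 1)
  expect_equal(rep$false_positives[rep$control == "high"], 0)

  # zero interactors: TP = FN = 0 everywhere
  truth0 <- truth; truth0$is_interactor <- FALSE
  mr0 <- matching_report(diffs, d, "bait", truth0)
  expect_true(all(mr0$report$true_positives == 0))
  expect_true(all(mr0$report$false_negatives == 0))

  d0 <- study_design("x_1", "bait0", "no_turbo", 1L, 0)
  expect_error(matching_report(diffs["low"], d0, "bait0"), "zero TurboID")
})
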