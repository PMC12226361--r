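# small in-code fixtures shared across test files

# a toy two-protein, two-sample precursor table
toy_table <- function() {
  precursor_table(
    sample_id     = c("s1", "s1", "s1", "s2", "s2", "s2"),
    protein_group = c("A", "A", "B", "A", "A", "B"),
    peptide_seq   = c("PEPK", "SEQR", "OTHK", "PEPK", "SEQR", "OTHK"),
    precursor_id  = c("PEPK2", "SEQR2", "OTHK2",
                      "PEPK2", "SEQR2", "OTHK2"),
    intensity     = c(100, 200, 50, 400, 800, 100)
  )
}

toy_design <- function() {
  study_design(
    sample_id = c("b1", "b2", "b3", "c1", "c2", "c3"),
    group = rep(c("bait", "ctrl"), each = 3),
    role = rep(c("bait", "control"), each = 3),
    replicate = rep(1:3, 2),
    turboid_expression = rep(1, 6)
  )
}

# random precursor table for property tests (seed controlled by caller)
random_table <- function(n_prot = 8, n_prec = 3, samples = c("s1", "s2",
                                                             "s3", "s4"),
                         missing_frac = 0.2) {
  prot <- sprintf("P%02d", seq_len(n_prot))
  pep <- paste0("PEP", seq_len(n_prot * n_prec), "K")
  prec <- paste0(pep, "2")
  rows <- expand.grid(prec_i = seq_along(prec), sample_id = samples,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(rows)) > missing_frac
  rows <- rows[keep, ]
  precursor_table(
    sample_id = rows$sample_id,
    protein_group = rep(prot, each = n_prec)[rows$prec_i],
    peptide_seq = pep[rows$prec_i],
    precursor_id = prec[rows$prec_i],
    intensity = stats::rlnorm(nrow(rows), log(1e4), 1)
  )
}

# a tiny log2 matrix + design for diffexp tests, built from given group values
two_group_matrix <- function(bait_vals, ctrl_vals) {
  m <- rbind(c(bait_vals, ctrl_vals))
  rownames(m) <- "P1"
  colnames(m) <- c("b1", "b2", "b3", "c1", "c2", "c3")[
    seq_len(ncol(m))]
  protein_matrix(m, "sum", log2 = TRUE, imputed = TRUE)
}

# independent classical pooled two-sample t-test (the moderation-off oracle)
classical_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

pm_flag2 <- function(x, f) isTRUE(attr(x, f))

pm_subset_loses_flags <- function(pm) {
  sub <- pm[1, , drop = FALSE]
  !identical(attr(sub, "aggregation_method"),
             attr(pm, "aggregation_method"))
}

pm_logless <- function() {
  m <- matrix(runif(12) + 1, 2, 6,
              dimnames = list(c("A", "B"),
                              c("b1", "b2", "b3", "c1", "c2", "c3")))
  protein_matrix(m, "sum", imputed = TRUE)
}

expect_silent_ish <- function(expr) testthat::expect_error(expr, NA)

# independent brute-force BH step-up from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}
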