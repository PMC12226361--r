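test_that("unique-peptide filter is charge-agnostic and k=1 is the identity", {
  # one sequence seen at two charges is a single unique peptide
  tab <- precursor_table(
    sample_id = c("s1", "s1", "s1", "s1"),
    protein_group = c("A", "A", "B", "B"),
    peptide_seq = c("AAK", "AAK", "CCK", "DDK"),
    precursor_id = c("AAK2", "AAK3", "CCK2", "DDK2"),
    intensity = c(10, 20, 30, 40)
  )
  out <- filter_min_unique_peptides(tab, 2)
  expect_setequal(unique(out$protein_group), "B")
  expect_identical(filter_min_unique_peptides(tab, 1), tab)
})

test_that("total-intensity normalization hits the target total and is idempotent", {
  # a sample already summing to the target scale is a fixed point
  tab <- precursor_table(
    sample_id = rep("s1", 3), protein_group = rep("A", 3),
    peptide_seq = c("AK", "BK", "CK"), precursor_id = c("AK2", "BK2", "CK2"),
    intensity = c(2e6, 3e6, 5e6)
  )
  expect_equal(normalize_total_intensity(tab)$intensity, tab$intensity)

  # forced rescale: (1, 1) -> (5e6, 5e6)
  tab2 <- precursor_table(
    sample_id = c("s1", "s1"), protein_group = c("A", "B"),
    peptide_seq = c("AK", "BK"), precursor_id = c("AK2", "BK2"),
    intensity = c(1, 1)
  )
  expect_equal(normalize_total_intensity(tab2)$intensity, c(5e6, 5e6))

  # random tables: all per-sample totals equal the scale; idempotent
  withr::local_seed(42)
  for (rep in 1:5) {
    tab <- random_table(n_prot = 12, n_prec = 4)
    norm <- normalize_total_intensity(tab)
    totals <- tapply(norm$intensity, norm$sample_id, sum)
    expect_equal(as.vector(totals), rep(1e7, length(totals)),
                 tolerance = 1e-9)
    norm2 <- normalize_total_intensity(norm)
    expect_equal(norm2$intensity, norm$intensity, tolerance = 1e-12)
  }
})

test_that("sum aggregation conserves totals and cells are missing iff undetected", {
  tab <- toy_table()
  mat <- aggregate_proteins(tab, "sum")
  expect_equal(mat["A", "s1"], 300)
  expect_equal(mat["B", "s2"], 100)
  # conservation: column totals equal precursor-table sample totals
  expect_equal(colSums(mat, na.rm = TRUE),
               c(tapply(tab$intensity, tab$sample_id, sum)[colnames(mat)]))

  # a protein absent from a sample gives a missing cell
  tab2 <- precursor_table(
    sample_id = c("s1", "s1", "s2"), protein_group = c("A", "B", "A"),
    peptide_seq = c("AK", "BK", "AK"), precursor_id = c("AK2", "BK2", "AK2"),
    intensity = c(1, 2, 3)
  )
  m2 <- aggregate_proteins(tab2, "sum")
  expect_true(is.na(m2["B", "s2"]))
})

test_that("top1 picks one consistent precursor and never exceeds the sum", {
  # precursor with largest cross-sample total wins, ties by id
  tab <- precursor_table(
    sample_id = c("s1", "s1", "s2", "s2"),
    protein_group = rep("A", 4),
    peptide_seq = c("AK", "BK", "AK", "BK"),
    precursor_id = c("AK2", "BK2", "AK2", "BK2"),
    intensity = c(100, 90, 10, 300)  # totals: AK2 = 110, BK2 = 390
  )
  m <- aggregate_proteins(tab, "top1")
  expect_equal(unname(m["A", ]), c(90, 300))  # BK2 row, even where smaller

  withr::local_seed(7)
  for (rep in 1:5) {
    tab <- random_table()
    s <- aggregate_proteins(tab, "sum")
    t1 <- aggregate_proteins(tab, "top1")
    both <- !is.na(s) & !is.na(t1)
    expect_true(all(t1[both] <= s[both] + 1e-12))
  }
})

test_that("maxlfq recovers exact ratios on complete noise-free data", {
  # every precursor's s2/s1 ratio is exactly 2 -> protein ratio 2
  tab <- precursor_table(
    sample_id = rep(c("s1", "s2"), each = 3),
    protein_group = rep("A", 6),
    peptide_seq = rep(c("AK", "BK", "CK"), 2),
    precursor_id = rep(c("AK2", "BK2", "CK2"), 2),
    intensity = c(100, 200, 400, 200, 400, 800)
  )
  m <- aggregate_proteins(tab, "maxlfq")
  expect_equal(m["A", "s2"] / m["A", "s1"], 2, tolerance = 1e-9)

  # multi-sample exact multiplicative structure: all pairwise ratios recovered
  withr::local_seed(3)
  fracs <- c(0.2, 0.3, 0.5)
  scales <- c(1, 2.5, 0.75, 4)
  tab2 <- precursor_table(
    sample_id = rep(paste0("s", 1:4), each = 3),
    protein_group = rep("A", 12),
    peptide_seq = rep(c("AK", "BK", "CK"), 4),
    precursor_id = rep(c("AK2", "BK2", "CK2"), 4),
    intensity = as.vector(outer(fracs * 1000, scales))
  )
  m2 <- aggregate_proteins(tab2, "maxlfq")
  row <- m2["A", paste0("s", 1:4)]
  expect_equal(unname(row / row[1]), scales, tolerance = 1e-9)
  # rescaled to the sum-aggregate total
  s2 <- aggregate_proteins(tab2, "sum")
  expect_equal(sum(row), sum(s2["A", ]), tolerance = 1e-9)
})

test_that("single-precursor proteins are identical across aggregation methods", {
  tab <- precursor_table(
    sample_id = c("s1", "s2", "s3"), protein_group = rep("A", 3),
    peptide_seq = rep("AK", 3), precursor_id = rep("AK2", 3),
    intensity = c(5, 50, 500)
  )
  s <- aggregate_proteins(tab, "sum")
  t1 <- aggregate_proteins(tab, "top1")
  lf <- aggregate_proteins(tab, "maxlfq")
  expect_equal(unclass(t1), unclass(s), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(lf), unclass(s), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("quantile imputation follows the linear-interpolation convention", {
  # present values 10, 20, ..., 1000; q = 0.01 -> h = 1.99 -> 19.9
  m <- matrix(c(seq(10, 1000, by = 10), NA), ncol = 1,
              dimnames = list(sprintf("P%03d", 1:101), "s1"))
  pm <- protein_matrix(m, "sum")
  imp <- impute_quantile(pm, 0.01)
  expect_equal(imp["P101", "s1"], 19.9)
  expect_true(pm_flag2(imp, "imputed"))

  # q = 0 imputes the sample minimum
  imp0 <- impute_quantile(pm, 0)
  expect_equal(imp0["P101", "s1"], 10)

  # no missing cells: unchanged values
  full <- protein_matrix(m[1:100, , drop = FALSE], "sum")
  expect_equal(unclass(impute_quantile(full, 0.01)), unclass(full),
               ignore_attr = TRUE)

  # per-sample vs global convention differ when samples differ
  m2 <- cbind(s1 = c(1:10, NA), s2 = c(101:110, NA))
  rownames(m2) <- sprintf("P%02d", 1:11)
  pm2 <- protein_matrix(m2, "sum")
  per <- impute_quantile(pm2, 0)
  glob <- impute_quantile(pm2, 0, global = TRUE)
  expect_equal(per["P11", "s2"], 101)
  expect_equal(glob["P11", "s2"], 1)
})


test_that("log2 transform and the pipeline-order guards", {
  m <- matrix(c(8, 1, 2, 4), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  pm <- protein_matrix(m, "sum", imputed = TRUE)
  lg <- log2_transform(pm)
  expect_equal(unname(lg["A", "s1"]), 3)
  expect_equal(unname(lg["B", "s1"]), 0)

  # order violations raise errors instead of silently proceeding
  not_imputed <- protein_matrix(m, "sum")
  expect_error(log2_transform(not_imputed), "impute")
  expect_error(log2_transform(lg), "already")
  expect_error(impute_quantile(lg, 0.01), "log2")
  d <- toy_design()
  expect_error(fit_moderated(pm_logless(), d, "bait", "ctrl"), "log2")
})

test_that("identified-protein counting respects the unique-peptide rule", {
  tab <- precursor_table(
    sample_id = c("b1", "b1", "c1"),
    protein_group = c("A", "A", "B"),
    peptide_seq = c("AK", "BK", "CK"),
    precursor_id = c("AK2", "BK2", "CK2"),
    intensity = c(1, 2, 3)
  )
  d <- toy_design()
  cnt <- count_identified_proteins(tab, d, min_unique_peptides = 2)
  expect_equal(unname(cnt["bait"]), 1L)  # A has 2 peptides
  expect_equal(unname(cnt["ctrl"]), 0L)  # B has only 1
})
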