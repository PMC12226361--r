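#' Remove proteins with too few unique peptides
#'
#' Proteins identified by fewer than `k` distinct peptide sequences across
#' the whole table are excluded. "Unique peptide" is charge-agnostic: two
#' charge states of the same modified sequence count once.
#'
#' @param table a [precursor_table()].
#' @param k minimum number of distinct peptide sequences; `k = 1` is the
#'   identity.
#' @return the filtered [precursor_table()].
#' @export
filter_min_unique_peptides <- function(table, k = 2L) {
  stopifnot(inherits(table, "precursor_table"), k >= 1)
  if (k == 1L || nrow(table) == 0L) return(table)
  pp <- unique(table[, c("protein_group", "peptide_seq")])
  n_pep <- table(pp$protein_group)
  keep <- names(n_pep)[n_pep >= k]
  out <- table[table$protein_group %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Total-intensity normalization at the precursor level
#'
#' Scales every precursor intensity by `scale / (total present intensity of
#' its sample)`, so that each sample's post-normalization total equals
#' `scale` (default 1e7). Idempotent.
#'
#' @param table a [precursor_table()].
#' @param scale target per-sample total intensity.
#' @return the normalized [precursor_table()].
#' @export
normalize_total_intensity <- function(table, scale = 1e7) {
  stopifnot(inherits(table, "precursor_table"), scale > 0)
  if (nrow(table) == 0L) return(table)
  totals <- tapply(table$intensity, table$sample_id, sum)
  if (any(totals <= 0)) {
    stop("sample '", names(totals)[totals <= 0][1L],
         "' has zero total intensity", call. = FALSE)
  }
  table$intensity <- table$intensity *
    as.vector(scale / totals[table$sample_id])
  class(table) <- c("precursor_table", "data.frame")
  attr(table, "normalized") <- TRUE
  table
}

#' Aggregate precursor intensities to protein level
#'
#' Three strategies:
#' \describe{
#'   \item{`sum`}{per protein and sample, the sum of present precursor
#'     intensities; a cell is missing iff no precursor is present.}
#'   \item{`top1`}{per protein, the single precursor with the largest total
#'     intensity across all samples is chosen once (ties broken by
#'     lexicographic precursor id) and its per-sample intensities become the
#'     protein row. One consistent precursor keeps response factors
#'     comparable across samples.}
#'   \item{`maxlfq`}{a MaxLFQ-style pairwise-ratio solver: for each protein,
#'     each pair of samples gets a log-ratio estimated as the median of
#'     per-precursor log-ratios over precursors present in both samples;
#'     per-sample log-abundances are then solved by least squares over the
#'     pairwise-ratio graph (independently per connected component) and
#'     rescaled so the protein's total over samples matches the `sum`
#'     aggregate. The delayed-normalization stage of full MaxLFQ is not
#'     part of this solver.}
#' }
#'
#' @param table a [precursor_table()].
#' @param method `"sum"`, `"top1"` or `"maxlfq"`.
#' @param samples optional character vector fixing the column order;
#'   defaults to the samples present in the table, sorted.
#' @return a [protein_matrix()].
#' @export
aggregate_proteins <- function(table, method = c("sum", "top1", "maxlfq"),
                               samples = NULL) {
  stopifnot(inherits(table, "precursor_table"))
  if (nrow(table) == 0L) stop("cannot aggregate an empty table",
                              call. = FALSE)
  method <- match.arg(method)
  if (is.null(samples)) samples <- sort(unique(table$sample_id))
  proteins <- sort(unique(table$protein_group))

  prot_i <- match(table$protein_group, proteins)
  samp_i <- match(table$sample_id, samples)
  if (anyNA(samp_i)) stop("table contains samples not in 'samples'",
                          call. = FALSE)

  sum_mat <- matrix(NA_real_, length(proteins), length(samples),
                    dimnames = list(proteins, samples))
  agg <- rowsum(table$intensity, group = (samp_i - 1L) * length(proteins) +
                  prot_i)
  sum_mat[as.integer(rownames(agg))] <- agg[, 1L]

  if (method == "sum") {
    return(protein_matrix(sum_mat, "sum",
                          normalized = isTRUE(attr(table, "normalized"))))
  }

  if (method == "top1") {
    tot <- tapply(table$intensity, table$precursor_id, sum)
    out <- matrix(NA_real_, length(proteins), length(samples),
                  dimnames = list(proteins, samples))
    for (pi in seq_along(proteins)) {
      rows <- which(prot_i == pi)
      precs <- unique(table$precursor_id[rows])
      precs <- precs[order(-tot[precs], precs)]  # ties: lexicographic id
      best <- precs[1L]
      sel <- rows[table$precursor_id[rows] == best]
      out[pi, samp_i[sel]] <- table$intensity[sel]
    }
    return(protein_matrix(out, "top1",
                          normalized = isTRUE(attr(table, "normalized"))))
  }

  # maxlfq
  out <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  for (pi in seq_along(proteins)) {
    rows <- which(prot_i == pi)
    # precursor x sample log-intensity sub-matrix
    precs <- unique(table$precursor_id[rows])
    sub <- matrix(NA_real_, length(precs), length(samples))
    sub[cbind(match(table$precursor_id[rows], precs), samp_i[rows])] <-
      log(table$intensity[rows])
    out[pi, ] <- maxlfq_solve(sub, sum_mat[pi, ])
  }
  protein_matrix(out, "maxlfq",
                 normalized = isTRUE(attr(table, "normalized")))
}

# Least-squares solve of per-sample log-abundances from median pairwise
# precursor log-ratios. `logmat`: precursors x samples, NA = absent;
# `sum_row`: the protein's sum-aggregate intensities used to anchor each
# connected component's total. Single-sample components carry their sum
# intensity directly. Returns linear-scale intensities, NA where no data.
maxlfq_solve <- function(logmat, sum_row) {
  n_s <- ncol(logmat)
  has_data <- colSums(!is.na(logmat)) > 0
  # median log-ratio for each sample pair sharing >= 1 precursor
  R <- matrix(NA_real_, n_s, n_s)
  for (i in seq_len(n_s)) {
    if (i == n_s) break
    for (j in seq(i + 1, n_s)) {
      d <- logmat[, j] - logmat[, i]
      d <- d[!is.na(d)]
      if (length(d)) R[i, j] <- stats::median(d)
    }
  }
  adj <- (!is.na(R) | !is.na(t(R))) | diag(n_s) > 0
  comp <- graph_components(adj)
  x <- rep(NA_real_, n_s)
  for (cc in unique(comp[has_data])) {
    members <- which(comp == cc & has_data)
    if (length(members) == 1L) {
      # singleton component: carry that sample's summed intensity
      x[members] <- sum_row[members]
      next
    }
    pairs <- which(!is.na(R), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] %in% members & pairs[, 2] %in% members, ,
                   drop = FALSE]
    m <- length(members)
    A <- matrix(0, nrow(pairs) + 1L, m)
    b <- numeric(nrow(pairs) + 1L)
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1], members)
      j <- match(pairs[r, 2], members)
      A[r, j] <- 1; A[r, i] <- -1
      b[r] <- R[pairs[r, 1], pairs[r, 2]]
    }
    A[nrow(pairs) + 1L, ] <- 1  # anchor the free translation
    sol <- stats::lsfit(A, b, intercept = FALSE)$coefficients
    xi <- exp(sol)
    # component total matches the sum-aggregate total over its samples
    xi <- xi * sum(sum_row[members]) / sum(xi)
    x[members] <- xi
  }
  x
}

# connected components of an undirected adjacency matrix (small n)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (comp[u] > 0L) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  comp
}

#' Impute missing cells with a per-sample low quantile
#'
#' Each sample's missing cells are replaced by the `q`-quantile of that
#' sample's present values, computed with the linear-interpolation convention
#' `h = (n - 1) q + 1` between order statistics. Run before
#' [log2_transform()].
#'
#' @param matrix a non-log2 [protein_matrix()].
#' @param q quantile in `[0, 1]`; default 0.01. `q = 0` imputes the sample
#'   minimum.
#' @param global if `TRUE`, a single quantile over all present values of the
#'   matrix is used instead of per-sample quantiles.
#' @return the imputed [protein_matrix()] with the `imputed` flag set.
#' @export
impute_quantile <- function(matrix, q = 0.01, global = FALSE) {
  stopifnot(inherits(matrix, "protein_matrix"), q >= 0, q <= 1)
  if (pm_flag(matrix, "log2")) {
    stop("impute before log2-transforming, not after", call. = FALSE)
  }
  x <- unclass(matrix)
  if (global) {
    vals <- x[!is.na(x)]
    if (!length(vals)) stop("matrix has no present values", call. = FALSE)
    x[is.na(x)] <- stats::quantile(vals, q, type = 7, names = FALSE)
  } else {
    for (j in seq_len(ncol(x))) {
      col <- x[, j]
      if (all(is.na(col))) {
        stop("sample '", colnames(x)[j], "' has no present values",
             call. = FALSE)
      }
      miss <- is.na(col)
      if (any(miss)) {
        x[miss, j] <- stats::quantile(col[!miss], q, type = 7, names = FALSE)
      }
    }
  }
  protein_matrix(x, attr(matrix, "aggregation_method"),
                 normalized = pm_flag(matrix, "normalized"),
                 log2 = FALSE, imputed = TRUE)
}

#' Log2-transform a fully imputed protein matrix
#'
#' @param matrix an imputed [protein_matrix()] with all values positive.
#' @return the transformed matrix with the `log2` flag set.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (pm_flag(matrix, "log2")) {
    stop("matrix is already log2-transformed", call. = FALSE)
  }
  if (!pm_flag(matrix, "imputed")) {
    stop("impute missing values before log2-transforming", call. = FALSE)
  }
  if (any(matrix <= 0)) {
    stop("log2 transform requires strictly positive values", call. = FALSE)
  }
  protein_matrix(log2(unclass(matrix)), attr(matrix, "aggregation_method"),
                 normalized = pm_flag(matrix, "normalized"),
                 log2 = TRUE, imputed = TRUE)
}

#' Count identified proteins per group
#'
#' A protein counts as identified in a group when at least
#' `min_unique_peptides` distinct peptide sequences are detected in at least
#' one sample set of that group (any sample).
#'
#' @param table a [precursor_table()].
#' @param design a [study_design()].
#' @param min_unique_peptides minimum distinct peptides (charge-agnostic).
#' @return named integer vector of identified-protein counts per group.
#' @export
count_identified_proteins <- function(table, design,
                                      min_unique_peptides = 2L) {
  stopifnot(inherits(table, "precursor_table"),
            inherits(design, "study_design"))
  grp <- design$group[match(table$sample_id, design$sample_id)]
  out <- integer(0)
  for (g in unique(design$group)) {
    sub <- unique(table[!is.na(grp) & grp == g,
                        c("protein_group", "peptide_seq")])
    n_pep <- table(sub$protein_group)
    out[g] <- sum(n_pep >= min_unique_peptides)
  }
  out
}
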