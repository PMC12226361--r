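#' Construct a validated precursor table
#'
#' Long-format table of precursor-level intensities, one row per detected
#' (sample, precursor) cell. Absent cells are simply not present as rows:
#' a precursor not detected in a sample has no row for that sample.
#'
#' @param sample_id character vector of sample identifiers.
#' @param protein_group character vector; the protein group each precursor
#'   maps to. A precursor must map to exactly one protein group across the
#'   whole table.
#' @param peptide_seq character vector; modified peptide sequence without the
#'   charge state.
#' @param precursor_id character vector; peptide sequence plus charge.
#' @param intensity numeric vector of non-negative intensities (arbitrary MS
#'   units). Zero or missing intensities are treated as "not detected" and
#'   dropped.
#'
#' @return A `precursor_table`, a data.frame with columns `sample_id`,
#'   `protein_group`, `peptide_seq`, `precursor_id`, `intensity`.
#' @export
precursor_table <- function(sample_id, protein_group, peptide_seq,
                            precursor_id, intensity) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    protein_group = as.character(protein_group),
    peptide_seq = as.character(peptide_seq),
    precursor_id = as.character(precursor_id),
    intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
  if (any(df$intensity < 0, na.rm = TRUE)) {
    stop("precursor intensities must be non-negative", call. = FALSE)
  }
  # zero / NA intensity means "not quantified": store as absent
  df <- df[!is.na(df$intensity) & df$intensity > 0, , drop = FALSE]
  rownames(df) <- NULL
  validate_precursor_table(df)
  class(df) <- c("precursor_table", "data.frame")
  df
}

validate_precursor_table <- function(df) {
  if (any(df$intensity < 0)) {
    stop("precursor intensities must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(df$intensity))) {
    stop("precursor intensities must be finite", call. = FALSE)
  }
  key <- paste(df$sample_id, df$precursor_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$precursor_id[duplicated(key)][1L]
    stop("duplicate (sample_id, precursor_id) pair for precursor '", dup, "'",
         call. = FALSE)
  }
  map <- unique(df[, c("precursor_id", "protein_group")])
  if (anyDuplicated(map$precursor_id)) {
    bad <- map$precursor_id[duplicated(map$precursor_id)][1L]
    stop("precursor '", bad, "' maps to more than one protein group",
         call. = FALSE)
  }
  invisible(df)
}

#' @export
print.precursor_table <- function(x, ...) {
  cat(sprintf(
    "precursor_table: %d cells | %d precursors | %d proteins | %d samples\n",
    nrow(x), length(unique(x$precursor_id)),
    length(unique(x$protein_group)), length(unique(x$sample_id))
  ))
  NextMethod()
}

#' Construct a validated study design
#'
#' Per-sample metadata for a proximity-labeling experiment: the group label,
#' the role of the group, the replicate number, and the relative TurboID
#' abundance of the group measured by whole-cell proteomics.
#'
#' @param sample_id unique sample identifiers.
#' @param group group label (e.g. `"RNF10"`, `"eGFP_6h"`).
#' @param role one of `"bait"`, `"control"`, `"no_turbo"` per sample.
#' @param replicate positive integer replicate index within group.
#' @param turboid_expression non-negative relative TurboID abundance. Zero is
#'   only allowed for `no_turbo` samples.
#'
#' @return A `study_design` data.frame.
#' @export
study_design <- function(sample_id, group, role, replicate,
                         turboid_expression) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    role = as.character(role),
    replicate = as.integer(replicate),
    turboid_expression = as.numeric(turboid_expression),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("bait", "control", "no_turbo"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$turboid_expression) | df$turboid_expression < 0)) {
    stop("turboid_expression must be non-negative", call. = FALSE)
  }
  zero_e <- df$turboid_expression == 0 & df$role != "no_turbo"
  if (any(zero_e)) {
    stop("turboid_expression 0 is only allowed for role 'no_turbo' (sample ",
         df$sample_id[zero_e][1L], ")", call. = FALSE)
  }
  if (any(is.na(df$replicate) | df$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Per-group mean TurboID expression
#'
#' @param design a `study_design`.
#' @return named numeric vector, one entry per group.
#' @export
group_expression <- function(design) {
  c(tapply(design$turboid_expression, design$group, mean))
}

samples_of <- function(design, group) {
  design$sample_id[design$group == group]
}

#' Construct a protein-by-sample intensity matrix
#'
#' Carries provenance flags so the pipeline order (filter, normalize,
#' aggregate, impute, log2) can be enforced rather than assumed.
#'
#' @param x numeric matrix, proteins in rows, samples in columns, `NA` for
#'   missing cells. Must have row and column names.
#' @param aggregation_method one of `"sum"`, `"top1"`, `"maxlfq"`.
#' @param normalized,log2,imputed logical provenance flags.
#'
#' @return A `protein_matrix` (numeric matrix with attributes).
#' @export
protein_matrix <- function(x, aggregation_method,
                           normalized = FALSE, log2 = FALSE,
                           imputed = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("x must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("protein matrix needs row (protein) and column (sample) names",
         call. = FALSE)
  }
  aggregation_method <- match.arg(aggregation_method,
                                  c("sum", "top1", "maxlfq"))
  if (imputed && anyNA(x)) {
    stop("an imputed matrix cannot contain missing cells", call. = FALSE)
  }
  if (!log2 && any(x < 0, na.rm = TRUE)) {
    stop("non-log2 intensities must be non-negative", call. = FALSE)
  }
  structure(x,
            aggregation_method = aggregation_method,
            normalized = normalized, log2 = log2, imputed = imputed,
            class = c("protein_matrix", "matrix", "array"))
}

pm_flag <- function(x, flag) isTRUE(attr(x, flag))

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf(
    "protein_matrix: %d proteins x %d samples [%s%s%s%s] (%.1f%% missing)\n",
    nrow(x), ncol(x), attr(x, "aggregation_method"),
    if (pm_flag(x, "normalized")) ", normalized" else "",
    if (pm_flag(x, "imputed")) ", imputed" else "",
    if (pm_flag(x, "log2")) ", log2" else "",
    100 * mean(is.na(x))
  ))
  invisible(x)
}

# subsetting keeps provenance flags while the result is still a matrix
#' @export
`[.protein_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attributes(out) <- c(attributes(out),
                         attributes(x)[c("aggregation_method", "normalized",
                                         "log2", "imputed")])
    class(out) <- class(x)
  }
  out
}

#' Construct a differential-enrichment result table
#'
#' @param df data.frame with columns `protein_group`, `log2_fc`, `t_mod`,
#'   `df_total`, `p_raw`, `p_adj`, `pi_value`, `call`.
#' @return A `diff_result` data.frame.
#' @export
diff_result <- function(df) {
  need <- c("protein_group", "log2_fc", "t_mod", "df_total", "p_raw",
            "p_adj", "pi_value", "call")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("diff_result missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    stopifnot(all(df$p_raw >= 0 & df$p_raw <= 1),
              all(df$p_adj >= 0 & df$p_adj <= 1))
    bad_call <- setdiff(unique(df$call),
                        c("enriched", "de_enriched", "not_significant"))
    if (length(bad_call)) {
      stop("unknown call value(s): ", paste(bad_call, collapse = ", "),
           call. = FALSE)
    }
  }
  df <- df[, need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("diff_result", "data.frame")
  df
}

#' Construct a consensus (occurrence-frequency) result
#'
#' @param df data.frame with columns `protein_group`, `occurrence_frequency`,
#'   `n_comparisons`, `high_confidence`.
#' @return A `consensus_result` data.frame.
#' @export
consensus_result <- function(df) {
  need <- c("protein_group", "occurrence_frequency", "n_comparisons",
            "high_confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("consensus_result missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(df$occurrence_frequency >= 0),
            all(df$occurrence_frequency <= df$n_comparisons))
  df <- df[, need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("consensus_result", "data.frame")
  df
}
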