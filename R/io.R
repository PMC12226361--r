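#' Read a DIA-NN-style precursor report
#'
#' Parses a tab-separated long-format precursor report as exported by DIA-NN
#' and similar search engines. Rows with zero or missing intensity are stored
#' as absent cells (DIA-NN uses 0/blank interchangeably for non-quantified
#' precursors).
#'
#' @param path path to a TSV file with a header line.
#' @param column_map named character vector mapping the roles
#'   `run`, `protein`, `precursor`, `intensity` (and optionally `peptide`)
#'   to column names in the file. Defaults match the DIA-NN main report.
#'
#' @details When the file has no explicit peptide column, the peptide
#'   sequence is derived from the precursor id by stripping the trailing
#'   charge integer, so that charge states of the same modified sequence
#'   collapse to one unique peptide.
#'
#' @return a [precursor_table()].
#' @export
read_precursor_report <- function(path,
                                  column_map = c(run = "Run",
                                                 protein = "Protein.Group",
                                                 precursor = "Precursor.Id",
                                                 intensity = "Precursor.Quantity")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  internal <- c(run = "sample_id", protein = "protein_group",
                precursor = "precursor_id", intensity = "intensity",
                peptide = "peptide_seq")
  if (!all(column_map[c("run", "protein", "precursor", "intensity")] %in%
             names(df)) &&
      all(internal[c("run", "protein", "precursor", "intensity")] %in%
            names(df))) {
    # table written by this package (e.g. the simulator): canonical names
    column_map <- internal
  }
  for (role in c("run", "protein", "precursor", "intensity")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(df)) {
      stop("precursor report is missing mapped column '",
           if (is.null(col)) role else col, "'", call. = FALSE)
    }
  }
  pep_col <- if ("peptide" %in% names(column_map)) {
    column_map[["peptide"]]
  } else NULL
  peptide <- if (!is.null(pep_col) && pep_col %in% names(df)) {
    as.character(df[[pep_col]])
  } else {
    strip_charge(as.character(df[[column_map[["precursor"]]]]))
  }
  precursor_table(
    sample_id = df[[column_map[["run"]]]],
    protein_group = df[[column_map[["protein"]]]],
    peptide_seq = peptide,
    precursor_id = df[[column_map[["precursor"]]]],
    intensity = suppressWarnings(as.numeric(df[[column_map[["intensity"]]]]))
  )
}

# "SEQ2" -> "SEQ"; ids without a trailing integer are returned unchanged
strip_charge <- function(precursor_id) {
  sub("[0-9]+$", "", precursor_id)
}

#' Read a study-design table
#'
#' @param path TSV file with columns `sample_id`, `group`, `role`,
#'   `replicate`, `turboid_expression`.
#' @return a [study_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "role", "replicate", "turboid_expression")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  study_design(df$sample_id, df$group, df$role, df$replicate,
               df$turboid_expression)
}

#' Write pipeline results to TSV
#'
#' Writes a [protein_matrix()], [diff_result()] or [consensus_result()]
#' (or any plain data.frame) to a tab-separated file. Missing cells are
#' encoded as `NA`; numbers are written with full precision so that
#' write/read round-trips are exact to within 1e-12 relative tolerance.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_results <- function(x, path) UseMethod("write_results")

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

write_tsv_checked <- function(df, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path) {
  write_tsv_checked(as.data.frame(x), path)
}

#' @export
write_results.protein_matrix <- function(x, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  # provenance flags ride along as comment headers so round-trips restore them
  writeLines(c(
    sprintf("# aggregation_method=%s", attr(x, "aggregation_method")),
    sprintf("# normalized=%s", pm_flag(x, "normalized")),
    sprintf("# log2=%s", pm_flag(x, "log2")),
    sprintf("# imputed=%s", pm_flag(x, "imputed"))
  ), con)
  df <- data.frame(protein_group = rownames(x), stringsAsFactors = FALSE)
  for (s in colnames(x)) df[[s]] <- fmt_num(x[, s])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  close(con)
  invisible(path)
}

#' Read a protein matrix written by [write_results()]
#'
#' @param path TSV path.
#' @return a [protein_matrix()] with its provenance flags restored.
#' @export
read_protein_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  flags <- list(aggregation_method = "sum", normalized = FALSE,
                log2 = FALSE, imputed = FALSE)
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    flags[[kv[1]]] <- if (kv[1] == "aggregation_method") kv[2] else
      as.logical(kv[2])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "# ")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  protein_matrix(m, flags$aggregation_method, normalized = flags$normalized,
                 log2 = flags$log2, imputed = flags$imputed)
}

#' Read a differential-result table written by [write_results()]
#' @param path TSV path.
#' @return a [diff_result()].
#' @export
read_diff_result <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  diff_result(df)
}

#' Read a consensus table written by [write_results()]
#' @param path TSV path.
#' @return a [consensus_result()].
#' @export
read_consensus_result <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  consensus_result(df)
}

#' Read a whole-cell protein abundance table
#'
#' @param path TSV with columns `protein_group` and `abundance`.
#' @return named numeric vector of abundances.
#' @export
read_wholecell <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("protein_group", "abundance") %in% names(df))) {
    stop("whole-cell table needs columns 'protein_group' and 'abundance'",
         call. = FALSE)
  }
  stats::setNames(as.numeric(df$abundance), df$protein_group)
}

#' Read a known-interactor list (one id per line)
#' @param path plain-text file, one protein/gene id per line.
#' @return character vector of ids.
#' @export
read_interactors <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
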