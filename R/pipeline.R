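#' Run the full expression-matched-control analysis pipeline
#'
#' Executes the complete workflow: obtain a precursor report (simulated or
#' read from disk), filter proteins on unique peptides, optionally apply
#' total-intensity normalization, aggregate to protein level, impute,
#' log2-transform, run the moderated differential test of the bait against
#' every candidate control, build the cross-control consensus, and emit a
#' control-matching report. The normalized and non-normalized branches can
#' run side by side in one invocation, since comparing exactly these two is
#' how normalization distortion is diagnosed.
#'
#' @param config a named list or the path to a YAML file. Recognized blocks:
#' \describe{
#'   \item{`simulation`}{arguments for [sim_config()] (`groups` may be a
#'     list of `label`/`role`/`turboid_expression` records). Mutually
#'     exclusive with `inputs`.}
#'   \item{`inputs`}{paths: `report`, `design`, optional `wholecell`,
#'     optional `positives`.}
#'   \item{`quantify`}{`min_peptides` (2), `normalize` — subset of
#'     `c("total", "none")` selecting the branches (default `"total"`),
#'     `scale` (1e7), `method` (`"sum"`), `impute_q` (0.01).}
#'   \item{`diffexp`}{`bait` (defaults to the design's single bait-role
#'     group), `controls` (defaults to all control-role groups),
#'     `fc` (2), `alpha` (0.05), `prior_df` (NULL = estimate).}
#'   \item{`consensus`}{`threshold` (3); applied when >= 2 controls.}
#'   \item{`seed`}{integer; forwarded to the simulator.}
#' }
#' @param out_dir output directory for TSVs and `run.log`; created if
#'   needed.
#' @param overwrite refuse to clobber existing outputs unless `TRUE`.
#' @param quiet suppress the stderr log (the file log is always written).
#'
#' @return invisibly, a list with the per-branch matrices, differential
#'   results, consensus, matching report, and the design/truth used.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- validate_pipeline_config(config)

  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  } else if (!overwrite && length(list.files(out_dir))) {
    stop("output directory '", out_dir,
         "' is not empty; pass overwrite = TRUE to replace its contents",
         call. = FALSE)
  }
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  wholecell <- NULL
  positives <- NULL
  if (!is.null(cfg$simulation)) {
    sc <- do.call(sim_config, cfg$simulation)
    say("simulate: n_proteins=", sc$n_proteins, " n_replicates=",
        sc$n_replicates, " seed=", sc$seed, " groups=",
        paste(sprintf("%s(E=%g)", sc$groups$label,
                      sc$groups$turboid_expression), collapse = ","))
    sim <- simulate_experiment(sc)
    report <- sim$report
    design <- sim$design
    truth <- sim$truth
    wholecell <- sim$wholecell
    write_results(as.data.frame(report), file.path(out_dir, "report.tsv"))
    write_results(as.data.frame(design), file.path(out_dir, "design.tsv"))
    write_results(data.frame(protein_group = names(wholecell),
                             abundance = wholecell),
                  file.path(out_dir, "wholecell.tsv"))
    write_results(as.data.frame(truth), file.path(out_dir, "truth.tsv"))
  } else {
    say("read report: ", cfg$inputs$report)
    report <- read_precursor_report(cfg$inputs$report)
    design <- read_design(cfg$inputs$design)
    if (!is.null(cfg$inputs$wholecell)) {
      wholecell <- read_wholecell(cfg$inputs$wholecell)
    }
    if (!is.null(cfg$inputs$positives)) {
      positives <- read_interactors(cfg$inputs$positives)
    }
  }

  q <- cfg$quantify
  d <- cfg$diffexp
  bait <- d$bait %||% design$group[design$role == "bait"][1]
  if (is.na(bait) || !bait %in% design$group) {
    stop("no bait group found in the design", call. = FALSE)
  }
  controls <- d$controls %||%
    unique(design$group[design$role %in% c("control", "no_turbo") &
                          design$turboid_expression > 0])
  if (!length(controls)) stop("no control groups to compare against",
                              call. = FALSE)

  say("filter: min unique peptides = ", q$min_peptides)
  filtered <- filter_min_unique_peptides(report, q$min_peptides)

  branches <- list()
  for (branch in q$normalize) {
    tab <- if (branch == "total") {
      say("normalize: total intensity, scale = ", format(q$scale))
      normalize_total_intensity(filtered, q$scale)
    } else {
      say("normalize: none")
      filtered
    }
    say("aggregate: ", q$method, "; impute q = ", q$impute_q, "; log2")
    mat <- aggregate_proteins(tab, q$method)
    logmat <- log2_transform(impute_quantile(mat, q$impute_q))
    write_results(mat, file.path(out_dir,
                                 sprintf("matrix_%s.tsv", branch)))

    diffs <- list()
    for (ctrl in controls) {
      say("diffexp [", branch, "]: ", bait, " vs ", ctrl,
          " (fc=", d$fc, ", alpha=", d$alpha, ")")
      fit <- fit_moderated(logmat, design, bait, ctrl,
                           prior_df = d$prior_df)
      res <- classify_calls(fit$result, d$fc, d$alpha)
      diffs[[ctrl]] <- res
      write_results(res, file.path(out_dir,
                                   sprintf("diff_%s_%s.tsv", branch, ctrl)))
    }

    consensus <- NULL
    if (length(diffs) >= 2) {
      thr <- min(cfg$consensus$threshold, length(diffs))
      say("consensus [", branch, "]: threshold = ", thr)
      consensus <- occurrence_frequency(diffs, thr)
      write_results(consensus,
                    file.path(out_dir, sprintf("consensus_%s.tsv", branch)))
    }

    say("matching report [", branch, "]")
    match_rep <- matching_report(diffs, design, bait, truth)
    write_results(match_rep$report,
                  file.path(out_dir, sprintf("matching_%s.tsv", branch)))

    branches[[branch]] <- list(matrix = mat, log_matrix = logmat,
                               diff = diffs, consensus = consensus,
                               matching = match_rep)
  }
  say("done")
  invisible(list(branches = branches, design = design, truth = truth,
                 wholecell = wholecell, positives = positives,
                 bait = bait, controls = controls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(config) {
  known <- c("simulation", "inputs", "quantify", "diffexp", "consensus",
             "seed")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  has_sim <- !is.null(config$simulation)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in) {
    stop("config must name exactly one of 'simulation' or 'inputs'",
         call. = FALSE)
  }
  if (has_in) {
    for (f in c("report", "design")) {
      if (is.null(config$inputs[[f]])) {
        stop("inputs block is missing '", f, "'", call. = FALSE)
      }
      if (!file.exists(config$inputs[[f]])) {
        stop("input file does not exist: ", config$inputs[[f]],
             call. = FALSE)
      }
    }
  }
  if (has_sim) {
    sim <- config$simulation
    if (!is.null(config$seed)) sim$seed <- config$seed
    if (!is.null(sim$groups) && !is.data.frame(sim$groups)) {
      sim$groups <- do.call(rbind, lapply(sim$groups, function(g) {
        data.frame(label = g$label, role = g$role,
                   turboid_expression = g$turboid_expression,
                   stringsAsFactors = FALSE)
      }))
    }
    config$simulation <- sim
  }
  q <- config$quantify %||% list()
  q$min_peptides <- q$min_peptides %||% 2L
  q$normalize <- q$normalize %||% "total"
  if (!all(q$normalize %in% c("total", "none"))) {
    stop("quantify$normalize entries must be 'total' or 'none'",
         call. = FALSE)
  }
  q$scale <- q$scale %||% 1e7
  q$method <- q$method %||% "sum"
  q$impute_q <- q$impute_q %||% 0.01
  config$quantify <- q

  d <- config$diffexp %||% list()
  d$fc <- d$fc %||% 2
  d$alpha <- d$alpha %||% 0.05
  config$diffexp <- d

  cns <- config$consensus %||% list()
  cns$threshold <- cns$threshold %||% 3L
  config$consensus <- cns
  config
}
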