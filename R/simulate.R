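#' Configuration for the proximity-labeling simulator
#'
#' Builds the parameter set for [simulate_experiment()]. The defaults encode
#' the experimental structure the pipeline is designed around: a bait group
#' and candidate TurboID-eGFP controls spanning a 16-fold expression range,
#' three biological replicates per group, a streptavidin-bead background
#' biased toward abundant, high-pI proteins, a small set of endogenously
#' biotinylated (carboxylase-like) background proteins, labeling proportional
#' to TurboID expression, and a detection limit that makes identification
#' depend on labeling intensity.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_replicates biological replicates per group.
#' @param groups data.frame with columns `label`, `role`
#'   (`bait`/`control`/`no_turbo`) and `turboid_expression` (relative TurboID
#'   abundance E; only ratios matter).
#' @param frac_interactors fraction of proteins that are true bait
#'   interactors.
#' @param interactor_boost proximity factor rho (> 1) multiplying the
#'   labeling rate of true interactors in bait samples.
#' @param interactor_boost_sdlog log-normal spread of per-interactor
#'   proximity factors around `interactor_boost` (truncated below at 1), so
#'   interactors range from intimate partners to grazing contacts. Weakly
#'   boosted interactors are the ones an over-expressed control drowns out.
#'   Set 0 for a uniform boost.
#' @param frac_endogenous_biotin fraction of proteins carrying biotin
#'   independently of TurboID (ACACA-like); sampled preferentially from the
#'   top abundance decile.
#' @param endog_level additive captured signal D for endogenously
#'   biotinylated proteins, in the same units as `abundance_meanlog` implies.
#' @param bead_beta0,bead_gamma,bead_delta streptavidin-bead background
#'   B_i = beta0 * A_i^gamma * exp(delta * (pI_i - pI_mean)): scale, abundance
#'   exponent (> 1 skews background toward abundant proteins), and pI
#'   coefficient (> 0 favors basic proteins).
#' @param abundance_meanlog,abundance_sdlog natural-log mean/sd of the
#'   log-normal whole-cell abundance distribution.
#' @param pI_mean,pI_sd isoelectric-point distribution (Normal).
#' @param precursors_lambda precursors per protein are 1 + Poisson(lambda);
#'   relative response fractions are a symmetric Dirichlet(1) draw, fixed per
#'   protein across samples.
#' @param noise_sdlog multiplicative log-normal measurement noise (natural-log
#'   sd) applied independently per precursor cell.
#' @param response_sdlog sd of the per-protein labeling-response exponent
#'   eta_i: the capture term scales as `E^(1 + eta_i)` instead of exactly
#'   `E`, so individual proteins deviate from strict proportionality to
#'   TurboID expression. The deviation cancels exactly when bait and control
#'   expression match, and is exposed (as extra protein-level fold-change
#'   scatter the replicate variance cannot see) when they do not — the
#'   mechanism that makes expression matching matter. Set 0 for a strictly
#'   proportional response.
#' @param lod detection limit: precursor cells below this intensity are
#'   recorded as missing.
#' @param dropout_softness 0 for a hard threshold; > 0 switches to logistic
#'   dropout with this log-scale width around `lod`.
#' @param seed integer seed; identical config gives byte-identical output.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000L,
                       n_replicates = 3L,
                       groups = data.frame(
                         label = c("bait", "ctrl_low", "ctrl_matched",
                                   "ctrl_high"),
                         role = c("bait", "control", "control", "control"),
                         turboid_expression = c(1, 0.25, 1, 4),
                         stringsAsFactors = FALSE),
                       frac_interactors = 0.10,
                       interactor_boost = 5,
                       interactor_boost_sdlog = 0.5,
                       frac_endogenous_biotin = 0.02,
                       endog_level = 2e5,
                       bead_beta0 = 5e-5,
                       bead_gamma = 1.6,
                       bead_delta = 0.25,
                       abundance_meanlog = log(1e4),
                       abundance_sdlog = 2,
                       pI_mean = 7,
                       pI_sd = 1.5,
                       precursors_lambda = 4,
                       noise_sdlog = 0.3,
                       response_sdlog = 0.2,
                       lod = 400,
                       dropout_softness = 0,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_replicates = as.integer(n_replicates),
              groups = as.data.frame(groups, stringsAsFactors = FALSE),
              frac_interactors = frac_interactors,
              interactor_boost = interactor_boost,
              interactor_boost_sdlog = interactor_boost_sdlog,
              frac_endogenous_biotin = frac_endogenous_biotin,
              endog_level = endog_level,
              bead_beta0 = bead_beta0,
              bead_gamma = bead_gamma,
              bead_delta = bead_delta,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              pI_mean = pI_mean,
              pI_sd = pI_sd,
              precursors_lambda = precursors_lambda,
              noise_sdlog = noise_sdlog,
              response_sdlog = response_sdlog,
              lod = lod,
              dropout_softness = dropout_softness,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- cfg[!(names(cfg) %in% "groups")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("all simulator parameters must be finite", call. = FALSE)
  }
  g <- cfg$groups
  if (!all(c("label", "role", "turboid_expression") %in% names(g))) {
    stop("groups needs columns label, role, turboid_expression",
         call. = FALSE)
  }
  if (!all(is.finite(g$turboid_expression)) ||
      any(g$turboid_expression < 0)) {
    stop("group turboid_expression must be finite and >= 0", call. = FALSE)
  }
  probs <- c(cfg$frac_interactors, cfg$frac_endogenous_biotin)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$interactor_boost < 1) {
    stop("interactor_boost must be >= 1", call. = FALSE)
  }
  if (cfg$interactor_boost_sdlog < 0) {
    stop("interactor_boost_sdlog must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sdlog < 0 || cfg$abundance_sdlog < 0 || cfg$pI_sd < 0 ||
      cfg$response_sdlog < 0) {
    stop("spread parameters must be >= 0", call. = FALSE)
  }
  if (cfg$n_proteins < 1 || cfg$n_replicates < 1) {
    stop("n_proteins and n_replicates must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# deterministic RNG scope: seed on entry, restore caller's RNG state on exit
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# random tryptic-looking peptide strings, unique across the experiment
random_peptides <- function(n, min_len = 8L, max_len = 15L) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internal, no digits
  len <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(len, function(l) {
    paste0(paste(sample(aa, l, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(len[dup], function(l) {
      paste0(paste(sample(aa, l, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
  }
  seqs
}

#' Simulate a TurboID proximity-labeling experiment
#'
#' Generates a precursor-level report, study design, whole-cell abundance
#' table and ground truth under a generative model of streptavidin capture.
#' For protein i in a sample of group g with relative TurboID expression
#' E_g, the expected captured signal is
#'
#' \deqn{S_{ig} = B_i + E_g A_i P_{ig} + D \cdot 1[\mathrm{endog}_i]}
#'
#' where `B_i = beta0 * A_i^gamma * exp(delta (pI_i - pI_mean))` is the
#' bead background, `A_i` the whole-cell abundance, `P_ig` the proximity
#' factor (rho for true interactors in bait groups, 1 otherwise) and `D` the
#' endogenous-biotin level. Each protein has a fixed set of precursors with
#' Dirichlet(1) response fractions; each observed precursor cell is
#' `S_ig * fraction * exp(eps)` with `eps ~ N(0, noise_sdlog^2)` drawn
#' independently per cell, and cells below the detection limit are missing.
#'
#' @param config a [sim_config()].
#' @return list with elements `report` ([precursor_table()]), `design`
#'   ([study_design()]), `wholecell` (named abundance vector) and `truth`
#'   (data.frame with per-protein abundance, pI, interactor and
#'   endogenous-biotin flags, bead background, and per-group proximity
#'   factors in columns `pf_<label>`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_sim_seed(config$seed, {
    n <- config$n_proteins
    gtab <- config$groups
    protein <- sprintf("SIMP%05d", seq_len(n))

    A <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    pI <- stats::rnorm(n, config$pI_mean, config$pI_sd)
    B <- config$bead_beta0 * A^config$bead_gamma *
      exp(config$bead_delta * (pI - config$pI_mean))

    is_interactor <- stats::runif(n) < config$frac_interactors
    # endogenously biotinylated proteins: carboxylases are abundant, so
    # sampling is weighted 10:1 toward the top abundance decile
    n_endog <- stats::rbinom(1L, n, config$frac_endogenous_biotin)
    w <- ifelse(A >= stats::quantile(A, 0.9), 10, 1)
    endog_idx <- if (n_endog > 0) sample.int(n, n_endog, prob = w) else
      integer(0)
    is_endog <- seq_len(n) %in% endog_idx

    k <- 1L + stats::rpois(n, config$precursors_lambda)
    # Dirichlet(1) response fractions, fixed per protein across all samples
    frac <- unlist(lapply(k, function(ki) {
      g <- stats::rgamma(ki, 1)
      g / sum(g)
    }), use.names = FALSE)
    prot_of_prec <- rep.int(seq_len(n), k)
    peptides <- random_peptides(sum(k))
    charge <- sample(2:3, sum(k), replace = TRUE)
    precursor_id <- paste0(peptides, charge)

    design <- study_design(
      sample_id = paste(rep(gtab$label, each = config$n_replicates),
                        seq_len(config$n_replicates), sep = "_"),
      group = rep(gtab$label, each = config$n_replicates),
      role = rep(gtab$role, each = config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), times = nrow(gtab)),
      turboid_expression = rep(gtab$turboid_expression,
                               each = config$n_replicates)
    )

    # proximity factors: proteins x groups
    rho <- rep(1, n)
    rho[is_interactor] <- if (config$interactor_boost_sdlog > 0) {
      pmax(1, config$interactor_boost *
             exp(stats::rnorm(sum(is_interactor), 0,
                              config$interactor_boost_sdlog)))
    } else config$interactor_boost
    pf <- matrix(1, n, nrow(gtab), dimnames = list(protein, gtab$label))
    pf[, gtab$role == "bait"] <- rho

    # expected protein signal per group, then expand to precursor cells;
    # the capture term is A_i * P_ig * E_g^(1 + eta_i) with kappa = 1
    eta <- if (config$response_sdlog > 0) {
      stats::rnorm(n, 0, config$response_sdlog)
    } else rep(0, n)
    E <- gtab$turboid_expression
    L <- if (config$response_sdlog > 0) {
      l <- exp(outer(1 + eta, log(pmax(E, .Machine$double.xmin))))
      l[, E == 0] <- 0
      l
    } else {
      matrix(E, n, length(E), byrow = TRUE)  # exact in E, no log round-trip
    }
    S <- B + pf * A * L + config$endog_level * is_endog
    # S: proteins x groups -> precursors x samples
    Sprec <- S[prot_of_prec, design$group, drop = FALSE] * frac

    n_cells <- length(Sprec)
    eps <- if (config$noise_sdlog > 0) {
      matrix(stats::rnorm(n_cells, 0, config$noise_sdlog), nrow(Sprec))
    } else {
      matrix(0, nrow(Sprec), ncol(Sprec))
    }
    obs <- Sprec * exp(eps)

    detected <- if (config$dropout_softness > 0) {
      p <- stats::plogis((log(pmax(obs, .Machine$double.xmin)) -
                            log(config$lod)) / config$dropout_softness)
      matrix(stats::runif(n_cells) < p, nrow(obs))
    } else {
      obs >= config$lod
    }
    detected[obs <= 0] <- FALSE

    idx <- which(detected)
    row_i <- (idx - 1L) %% nrow(obs) + 1L
    col_i <- (idx - 1L) %/% nrow(obs) + 1L
    report <- precursor_table(
      sample_id = design$sample_id[col_i],
      protein_group = protein[prot_of_prec[row_i]],
      peptide_seq = peptides[row_i],
      precursor_id = precursor_id[row_i],
      intensity = obs[idx]
    )

    truth <- data.frame(
      protein_group = protein,
      abundance = A,
      pI = pI,
      is_interactor = is_interactor,
      is_endogenous_biotin = is_endog,
      bead_background = B,
      response_eta = eta,
      stringsAsFactors = FALSE
    )
    for (g in gtab$label) truth[[paste0("pf_", g)]] <- pf[, g]
    class(truth) <- c("ground_truth", "data.frame")

    list(report = report,
         design = design,
         wholecell = stats::setNames(A, protein),
         truth = truth)
  })
}

#' Positive/negative labels from simulator ground truth
#'
#' True interactors are the positives; every other simulated protein
#' (bead background, endogenous biotin, unlabeled) is a negative.
#'
#' @param truth the `truth` data.frame from [simulate_experiment()].
#' @return named logical vector: `TRUE` for interactors.
#' @export
truth_labels <- function(truth) {
  stopifnot(all(c("protein_group", "is_interactor") %in% names(truth)))
  stats::setNames(truth$is_interactor, truth$protein_group)
}
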