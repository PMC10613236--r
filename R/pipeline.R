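#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministic hash of the global seed and a stage name, kept below
#' 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483629)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. All thresholds are config
#' fields, never hard-coded: inclusion z > 10 once per 10 min, movement
#' likelihood 0.95 and 3 x MAD, Wilcoxon p < 0.05, elastic-net alpha 0.95
#' with a 100-lambda path and 5-fold CV on a 70/30 split, 2-s shuffle
#' blocks with 1000 shuffles at FDR q = 0.05, correlation-graph
#' P < 1e-4, RRR threshold 0.0274 with 20-neuron subsamples, 40-trial
#' balancing, 100 ablation iterations, and the RNN profile.
#'
#' @param sim A [sim_config()] describing the synthetic world.
#' @param seed Global seed; every stochastic stage gets a derived,
#'   logged sub-seed.
#' @param glm List of encoding-model settings.
#' @param decode List of decoding settings.
#' @param motifs List of motif/ablation settings.
#' @param rrr List of reduced-rank settings.
#' @param rnn RNN profile: `desk` (64 + 16 units, 100 epochs) or `paper`
#'   (807 + 128 units, 500 epochs), or an explicit list.
#' @param glm_targets Optional cap on the number of fitted target neurons
#'   (demo runs); `NULL` fits all.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L,
                            glm = list(alpha = 0.95, n_lambda = 100,
                                       cv_folds = 5, train_frac = 0.7,
                                       n_shuffles = 1000, block_s = 2,
                                       q = 0.05),
                            decode = list(n_shuffles = 1000,
                                          p_threshold = 0.05),
                            motifs = list(iters = 100,
                                          corr_p_thresh = 1e-4),
                            rrr = list(rank = 4, corr_threshold = 0.0274,
                                       n_sample = 20, iters = 20),
                            rnn = "desk", glm_targets = NULL) {
  if (identical(rnn, "desk")) {
    rnn <- list(n_principal = 64, n_external = 16, epochs = 100, g = 1.2,
                n_trials = 30)
  } else if (identical(rnn, "paper")) {
    rnn <- list(n_principal = 807, n_external = 128, epochs = 500, g = 1.2,
                n_trials = 100)
  }
  structure(list(sim = sim, seed = as.integer(seed), glm = glm,
                 decode = decode, motifs = motifs, rrr = rrr, rnn = rnn,
                 glm_targets = glm_targets),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic learning series
#'
#' simulate -> movement cleaning -> modes -> decoding -> encoding GLM ->
#' motif indices (with ground-truth recovery) -> reduced-rank regression ->
#' FORCE RNN, writing a machine-readable JSON report. Rerunning with the
#' same config and seed reproduces the report bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the report (`report.json`); `NULL`
#'   skips writing.
#' @return The report (named list), invisibly written as JSON.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(sim = derive_seed(config$seed, "simulate"),
                glm = derive_seed(config$seed, "glm"),
                decode = derive_seed(config$seed, "decode"),
                motifs = derive_seed(config$seed, "motifs"),
                rrr = derive_seed(config$seed, "rrr"),
                rnn = derive_seed(config$seed, "rnn"))
  report <- list(seed = config$seed, sub_seeds = seeds)
  series <- generate_learning_series(config$sim, seed = seeds$sim)
  regions <- names(config$sim$n_neurons)
  stage_out <- list()
  graphs <- list(); labels <- list(); sglms <- list()
  for (st in names(series)) {
    s <- series[[st]]$session
    gt <- series[[st]]$ground_truth
    movement <- clean_movement_trace(series[[st]]$movement)
    st_rep <- list(n_neurons = n_neurons(s), n_trials = nrow(s$trials),
                   correct_rate = mean(s$trials$correct))
    # population modes for the first region with enough neurons
    reg <- regions[[1L]]
    axis <- tryCatch(compute_mode_axis(s, reg, "choice"),
                     error = function(e) NULL)
    if (!is.null(axis)) {
      tp <- project_trials(s, axis)
      st_rep$choice_selectivity <- choice_selectivity(tp)
      em <- projection_epoch_means(tp, default_epochs()$pre_action)
      ok <- !is.na(em)
      st_rep$population_choice_auc <-
        auc(em[ok & tp$side == "L"], em[ok & tp$side == "R"])
    }
    labels[[st]] <- tuning_labels(s)
    targets <- s$neuron_ids
    if (!is.null(config$glm_targets)) {
      targets <- targets[seq_len(min(config$glm_targets, length(targets)))]
    }
    sglm <- fit_session_glms(
      s, movement = movement, targets = targets,
      alpha = config$glm$alpha, n_lambda = config$glm$n_lambda,
      cv_folds = config$glm$cv_folds, train_frac = config$glm$train_frac,
      n_shuffles = config$glm$n_shuffles, block_s = config$glm$block_s,
      q = config$glm$q, seed = seeds$glm)
    sglms[[st]] <- sglm
    graphs[[st]] <- sglm$graph
    st_rep$mean_pseudo_ev <- mean(sglm$pseudo_ev)
    st_rep$mean_convergence <- mean_convergence(sglm$graph)
    st_rep$mean_choice_enrichment <-
      mean_enrichment(sglm$graph, labels[[st]], "choice")$mean
    rec <- coupling_recovery(sglm$graph, gt)
    st_rep$coupling_sensitivity <- rec$sensitivity
    st_rep$coupling_false_positive_rate <- rec$false_positive_rate
    stage_out[[st]] <- st_rep
  }
  report$stages <- stage_out
  part <- retained_eliminated(graphs$intermediate, graphs$expert)
  report$retained_fraction <- part$retained_fraction
  report$eliminated_fraction <- part$eliminated_fraction
  if (length(regions) >= 2L) {
    rr <- correlation_matched_rrr(
      lapply(series, `[[`, "session"), regions[1L], regions[2L],
      rank = config$rrr$rank, corr_threshold = config$rrr$corr_threshold,
      n_sample = config$rrr$n_sample, iters = config$rrr$iters,
      seed = seeds$rrr)
    report$rrr_performance <- as.list(rr)
  }
  # RNN on smooth synthetic two-condition targets shaped like the task
  tg <- synthetic_rnn_targets(config$rnn$n_principal, config$rnn$n_external,
                              seed = seeds$rnn)
  model <- init_rnn(config$rnn$n_principal, config$rnn$n_external,
                    g = config$rnn$g, seed = seeds$rnn)
  model <- force_train(model, tg, epochs = config$rnn$epochs,
                       seed = seeds$rnn)
  report$rnn <- list(mse = model$mse, nmse = model$nmse)
  report <- rapply(report, function(x) round(x, 10), classes = "numeric",
                   how = "replace")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Smooth synthetic two-condition FORCE targets
#'
#' Two documented target families on the trial time base, both smooth and
#' condition-selective:
#'
#' * `style = "driven"` — input-driven responses: heterogeneous baselines
#'   placed in the transfer function's stable operating zones (low
#'   `x < ~1.5` and high `x ~ 4.5-5.8`, avoiding the band around theta
#'   where the self-consistency gain `beta x (1 - r)` exceeds 1 and fixed
#'   points destabilize), plus a stimulus-locked Gaussian bump on right
#'   trials only. No persistent memory is required, so a FORCE-trained
#'   network can track these targets to high precision; used for
#'   convergence checks of the trainer.
#' * `style = "attractor"` — a double-well memory: every unit starts in a
#'   baseline well and right trials carry a smoothstep ramp (stimulus
#'   onset to mid-delay) into the opposite well, with the wells placed
#'   symmetrically around theta so the midpoint sits at maximum transfer
#'   slope (the separatrix) and the wells in lower-slope regions. The
#'   trained network holds the chosen well through the delay; used for
#'   distractor-perturbation and ablation assays.
#'
#' @param n_principal,n_external Unit counts.
#' @param n_samples Target samples at 93.5 Hz (default 327 = 3.5 s).
#' @param style `"driven"` or `"attractor"`.
#' @param selectivity Scale of the condition-dependent component
#'   (default 0.8 for driven, well separation 1.6 for attractor).
#' @param seed Integer seed.
#' @return An `rnn_targets`.
#' @export
synthetic_rnn_targets <- function(n_principal, n_external = 0,
                                  n_samples = 327,
                                  style = c("driven", "attractor"),
                                  selectivity = NULL, seed = 1L) {
  style <- match.arg(style)
  set.seed(seed)
  n <- n_principal + n_external
  t <- seq(0, 3.5, length.out = n_samples) - 3.5   # rel action
  if (style == "driven") {
    if (is.null(selectivity)) selectivity <- 0.8
    bump <- exp(-((t + 2.3) / 0.5)^2)
    base <- c(stats::runif(n %/% 2, -2, 1),
              stats::runif(n - n %/% 2, 4.5, 5.8))[sample(n)]
    amp <- stats::runif(n, 0.5, 1) * selectivity *
      sample(c(-1, 1), n, replace = TRUE)
    f_r <- matrix(base, n, n_samples) + outer(amp, bump)
    f_l <- matrix(base, n, n_samples)
  } else {
    if (is.null(selectivity)) selectivity <- 1.6
    u <- pmin(pmax((t + 3) / 1.5, 0), 1)           # stimulus -> mid-delay
    ramp <- u^2 * (3 - 2 * u)                      # smoothstep
    half <- selectivity / 2
    pref <- sample(c(1, -1), n, replace = TRUE, prob = c(0.7, 0.3))
    lo <- 3 - half + stats::rnorm(n, 0, 0.1)
    hi <- 3 + half + stats::rnorm(n, 0, 0.1)
    b0 <- ifelse(pref > 0, lo, hi)
    b1 <- ifelse(pref > 0, hi, lo)
    f_l <- matrix(b0, n, n_samples)
    f_r <- matrix(b0, n, n_samples) + outer(b1 - b0, ramp)
  }
  structure(list(f_right = f_r, f_left = f_l,
                 roles = rep(c("principal", "external"),
                             c(n_principal, n_external)),
                 beta = 0.8, theta = 3.0, rate_hz = 93.5),
            class = "rnn_targets")
}

#' Command-line entry point
#'
#' Subcommands: `validate <session-dir>` (schema report + inclusion-filter
#' summary), `simulate --seed S --out DIR [--trials N]` (writes a session
#' directory, ground-truth JSON and movement CSV), and
#' `run --seed S --out DIR` (demo-scale [run_pipeline()]).
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Exit status, invisibly.
#' @export
motifnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: motifnet <validate|simulate|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  seed <- as.integer(opts$seed %||% 1L)
  if (cmd == "validate") {
    s <- read_session(opts$positional[[1L]])
    print(s)
    kept <- tryCatch(n_neurons(filter_active_neurons(s)),
                     error = function(e) 0L)
    cat(sprintf("inclusion filter (z>10 per 10 min): %d of %d neurons kept\n",
                kept, n_neurons(s)))
  } else if (cmd == "simulate") {
    cfg <- sim_config(n_trials = as.integer(opts$trials %||% 60L))
    out <- opts$out %||% "."
    g <- generate_session(cfg, seed = seed)
    write_session(g$session, file.path(out, "session"))
    jsonlite::write_json(g$ground_truth[c("coupling", "tuning")],
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(as.data.frame(g$movement),
                     file.path(out, "movement.csv"), row.names = FALSE)
    cat("wrote session to", file.path(out, "session"), "\n")
  } else if (cmd == "run") {
    cfg <- pipeline_config(
      sim = sim_config(n_neurons = c(ALM = 10, PPC = 10), n_trials = 40),
      seed = seed,
      glm = list(alpha = 0.95, n_lambda = 20, cv_folds = 3,
                 train_frac = 0.7, n_shuffles = 100, block_s = 2, q = 0.05),
      rrr = list(rank = 2, corr_threshold = 0.0274, n_sample = 5,
                 iters = 5),
      rnn = list(n_principal = 16, n_external = 4, epochs = 10, g = 1.2,
                 n_trials = 10),
      glm_targets = 8)
    run_pipeline(cfg, out_dir = opts$out %||% ".")
    cat("report written to", file.path(opts$out %||% ".", "report.json"), "\n")
  } else {
    stop("motifnet: unknown subcommand '", cmd, "'")
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  opts <- list(positional = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3L)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts$positional[[length(opts$positional) + 1L]] <- a
      i <- i + 1L
    }
  }
  opts
}
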