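#' Fit encoding models for many neurons and extract the coupling graph
#'
#' Runs [fit_poisson_glm()] and [significant_predictors()] for each target
#' neuron (task predictors and lagged-activity columns are built once and
#' shared) and collects the directed functional-coupling graph: an edge
#' source -> target exists when either lag's coupling group survives FDR
#' within the target neuron.
#'
#' @param s A [session()].
#' @param movement Optional 60 Hz `movement_trace` for movement predictors.
#' @param targets Neuron ids to fit (default all).
#' @param alpha,n_lambda,cv_folds,train_frac Passed to [fit_poisson_glm()].
#' @param n_shuffles,block_s,q Passed to [significant_predictors()].
#' @param seed Integer seed; each neuron gets a derived sub-seed.
#' @return List of class `session_glm`: `fits` (named by target id),
#'   `significance` (named list), `graph` (a `coupling_graph`),
#'   `pseudo_ev` (named vector).
#' @export
fit_session_glms <- function(s, movement = NULL, targets = s$neuron_ids,
                             alpha = 0.95, n_lambda = 100, cv_folds = 5,
                             train_frac = 0.7, n_shuffles = 1000,
                             block_s = 2, q = 0.05, seed = 1L) {
  task <- task_predictors(s, movement)
  cpl <- coupling_predictors(s)
  fits <- list(); sigs <- list(); ev <- c()
  edges <- list()
  for (tid in targets) {
    keep <- s$neuron_ids != tid
    X <- cbind(task$X, cpl$L1[, keep, drop = FALSE],
               cpl$L2[, keep, drop = FALSE])
    groups <- c(task$groups, colnames(cpl$L1)[keep], colnames(cpl$L2)[keep])
    z <- zscore_cols(X)
    groups <- groups[colnames(X) %in% colnames(z$X)]
    design <- structure(list(X = z$X, groups = groups, dropped = z$dropped,
                             target_id = tid), class = "design_matrix")
    y <- s$activity[match(tid, s$neuron_ids), ]
    sub_seed <- derive_seed(seed, paste0("glm", tid))
    fit <- fit_poisson_glm(design, y, alpha = alpha, n_lambda = n_lambda,
                           cv_folds = cv_folds, train_frac = train_frac,
                           seed = sub_seed)
    sig <- significant_predictors(fit, design, y, n_shuffles = n_shuffles,
                                  block_s = block_s, q = q,
                                  frame_rate = s$frame_rate, seed = sub_seed)
    key <- as.character(tid)
    fits[[key]] <- fit
    sigs[[key]] <- sig
    ev[key] <- fit$pseudo_ev_test
    cg <- sig[startsWith(sig$group, "cpl_"), , drop = FALSE]
    if (nrow(cg)) {
      m <- regmatches(cg$group, regexec("^cpl_(\\d+)_lag([12])$", cg$group))
      src <- as.integer(vapply(m, `[`, "", 2L))
      lag <- as.integer(vapply(m, `[`, "", 3L))
      for (sid in unique(src[cg$significant])) {
        sel <- src == sid
        edges[[length(edges) + 1L]] <- data.frame(
          source_id = sid, target_id = tid,
          lag1_sig = any(cg$significant[sel & lag == 1L]),
          lag2_sig = any(cg$significant[sel & lag == 2L]),
          delta_ev = max(cg$delta_ev[sel & cg$significant]),
          p_value = min(cg$p_value[sel & cg$significant]))
      }
    }
  }
  graph <- coupling_graph(
    if (length(edges)) do.call(rbind, edges)
    else data.frame(source_id = integer(0), target_id = integer(0),
                    lag1_sig = logical(0), lag2_sig = logical(0),
                    delta_ev = numeric(0), p_value = numeric(0)),
    regions = stats::setNames(s$regions, s$neuron_ids),
    stage = s$stage, targets = targets)
  structure(list(fits = fits, significance = sigs, graph = graph,
                 pseudo_ev = ev),
            class = "session_glm")
}

#' Directed functional-coupling graph
#'
#' An edge list (source predictor neuron -> target predicted neuron) with
#' per-lag significance flags, plus per-neuron region labels and the stage
#' tag. Self-edges are forbidden.
#'
#' @param edges Data.frame with columns `source_id`, `target_id`,
#'   `lag1_sig`, `lag2_sig`, `delta_ev`, `p_value`.
#' @param regions Named character vector (names = neuron ids).
#' @param stage Stage tag.
#' @param targets Neuron ids whose incoming edges were actually tested
#'   (defaults to all neurons in `regions`).
#' @return Object of class `coupling_graph`.
#' @export
coupling_graph <- function(edges, regions, stage = "expert",
                           targets = as.integer(names(regions))) {
  stopifnot(is.data.frame(edges), !is.null(names(regions)))
  if (nrow(edges)) {
    if (any(edges$source_id == edges$target_id)) {
      stop("coupling_graph: self-edges are not allowed")
    }
    ids <- as.integer(names(regions))
    if (!all(edges$source_id %in% ids) || !all(edges$target_id %in% ids)) {
      stop("coupling_graph: edge endpoint missing from the neuron set")
    }
  }
  structure(list(edges = edges, regions = regions, stage = stage,
                 targets = as.integer(targets)),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("coupling_graph (%s): %d edges over %d neurons\n",
              x$stage, nrow(x$edges), length(x$regions)))
  invisible(x)
}

#' Ground-truth coupling graph helper
#'
#' Converts a generator `ground_truth` into a `coupling_graph` so planted
#' and estimated graphs share an interface.
#'
#' @param gt A `ground_truth` from [generate_session()].
#' @param s The matching [session()].
#' @return A `coupling_graph`.
#' @export
ground_truth_graph <- function(gt, s) {
  e <- gt$coupling
  agg_key <- paste(e$source_id, e$target_id)
  first <- !duplicated(agg_key)
  edges <- data.frame(
    source_id = e$source_id[first], target_id = e$target_id[first],
    lag1_sig = as.logical(tapply(e$lag == 1L, agg_key, any)[agg_key[first]]),
    lag2_sig = as.logical(tapply(e$lag == 2L, agg_key, any)[agg_key[first]]),
    delta_ev = NA_real_, p_value = NA_real_)
  coupling_graph(edges, stats::setNames(s$regions, s$neuron_ids), s$stage)
}

#' Compare an estimated coupling graph with planted ground truth
#'
#' @param graph Estimated `coupling_graph`.
#' @param gt A `ground_truth`.
#' @return List `sensitivity`, `false_positive_rate`, `n_true`, `n_detected`.
#' @export
coupling_recovery <- function(graph, gt) {
  targets <- graph$targets
  ids <- as.integer(names(graph$regions))
  true_pairs <- unique(paste(gt$coupling$source_id, gt$coupling$target_id))
  est_pairs <- paste(graph$edges$source_id, graph$edges$target_id)
  all_pairs <- as.vector(outer(ids, targets, function(a, b) paste(a, b)))
  all_pairs <- all_pairs[rep(ids, times = length(targets)) !=
                           rep(targets, each = length(ids))]
  true_pairs <- intersect(true_pairs, all_pairs)
  tp <- sum(est_pairs %in% true_pairs)
  fp <- length(est_pairs) - tp
  n_neg <- length(all_pairs) - length(true_pairs)
  list(sensitivity = if (length(true_pairs)) tp / length(true_pairs) else NA,
       false_positive_rate = if (n_neg) fp / n_neg else NA,
       n_true = length(true_pairs), n_detected = length(est_pairs))
}

#' Export / import a coupling graph as a TSV edge list
#'
#' @param graph A `coupling_graph`.
#' @param path TSV path.
#' @export
write_coupling_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
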