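graph_ids <- function(graph) as.integer(names(graph$regions))

incoming_edges <- function(graph, target) {
  graph$edges[graph$edges$target_id == target, , drop = FALSE]
}

#' Convergence index of a target neuron
#'
#' Fraction of candidate predictor neurons in `source_region` with a
#' significant coupling onto `target`: `n_coupled / n_candidates`. The
#' target itself is excluded from the candidates when it lives in the
#' source region. `source_region = NULL` pools all regions.
#'
#' @param graph A `coupling_graph`.
#' @param target Target neuron id.
#' @param source_region Region label or `NULL`.
#' @return Fraction in `[0, 1]`; NA if the source region has no candidates.
#' @export
convergence_index <- function(graph, target, source_region = NULL) {
  ids <- graph_ids(graph)
  cand <- if (is.null(source_region)) ids
          else ids[graph$regions[as.character(ids)] == source_region]
  cand <- setdiff(cand, target)
  if (!length(cand)) return(NA_real_)
  inc <- incoming_edges(graph, target)
  sum(inc$source_id %in% cand) / length(cand)
}

#' Mean convergence index over target neurons
#'
#' @inheritParams convergence_index
#' @param targets Target ids (default: the graph's tested targets).
#' @return Mean of per-neuron [convergence_index()] values (NAs dropped).
#' @export
mean_convergence <- function(graph, source_region = NULL,
                             targets = graph$targets) {
  v <- vapply(targets, convergence_index, numeric(1), graph = graph,
              source_region = source_region)
  mean(v, na.rm = TRUE)
}

label_for <- function(labels, id, variable) {
  col <- if (variable == "stimulus") "stimulus_encoding" else "choice_encoding"
  lab <- labels[[col]][match(id, labels$neuron_id)]
  ifelse(is.na(lab), "none", lab)
}

#' Enrichment index of a target neuron
#'
#' Among the neuron's significant incoming couplings, the fraction whose
#' source shares its tuning: same variable, same preferred side, both
#' significant by the Wilcoxon classifier. Defined only for neurons
#' labelled `<side>-pref` on `variable` with at least one incoming edge;
#' otherwise NA.
#'
#' @param graph A `coupling_graph`.
#' @param labels A [tuning_labels()] data.frame.
#' @param target Target neuron id.
#' @param variable `"stimulus"` or `"choice"`.
#' @param side `"L"` or `"R"`; default uses the target's own preference.
#' @param source_region Optionally restrict counted edges to one source
#'   region.
#' @return Fraction in `[0, 1]` or NA.
#' @export
enrichment_index <- function(graph, labels, target,
                             variable = c("choice", "stimulus"),
                             side = NULL, source_region = NULL) {
  variable <- match.arg(variable)
  tgt_lab <- label_for(labels, target, variable)
  if (is.null(side)) {
    if (tgt_lab == "none") return(NA_real_)
    side <- substr(tgt_lab, 1L, 1L)
  }
  want <- paste0(side, "-pref")
  if (tgt_lab != want) return(NA_real_)
  inc <- incoming_edges(graph, target)
  if (!is.null(source_region)) {
    inc <- inc[graph$regions[as.character(inc$source_id)] == source_region, ,
               drop = FALSE]
  }
  if (!nrow(inc)) return(NA_real_)
  mean(label_for(labels, inc$source_id, variable) == want)
}

#' Mean enrichment index over tuned neurons
#'
#' Averages [enrichment_index()] at each neuron's own preferred side over
#' all `variable`-encoding target neurons with incoming edges. With
#' `pooled = TRUE` the estimator is edge-weighted instead: the same-tuned
#' fraction of all qualifying incoming edges pooled across neurons — the
#' same planted quantity with lower variance when per-neuron edge counts
#' are small.
#'
#' @inheritParams enrichment_index
#' @param targets Target ids (default: the graph's tested targets).
#' @param pooled Pool edges across neurons (default `FALSE`).
#' @return List `mean`, `values` (named by neuron), `n_undefined`.
#' @export
mean_enrichment <- function(graph, labels, variable = c("choice", "stimulus"),
                            source_region = NULL, targets = graph$targets,
                            pooled = FALSE) {
  variable <- match.arg(variable)
  v <- vapply(targets, enrichment_index, numeric(1), graph = graph,
              labels = labels, variable = variable,
              source_region = source_region)
  names(v) <- targets
  m <- if (pooled) {
    tot <- same <- 0
    for (tgt in targets) {
      lab <- label_for(labels, tgt, variable)
      if (lab == "none") next
      inc <- incoming_edges(graph, tgt)
      if (!is.null(source_region)) {
        inc <- inc[graph$regions[as.character(inc$source_id)] ==
                     source_region, , drop = FALSE]
      }
      if (!nrow(inc)) next
      tot <- tot + nrow(inc)
      same <- same + sum(label_for(labels, inc$source_id, variable) == lab)
    }
    if (tot > 0) same / tot else NA_real_
  } else {
    mean(v, na.rm = TRUE)
  }
  list(mean = m, values = v, n_undefined = sum(is.na(v)))
}

#' Region-pair enrichment
#'
#' Per-target-neuron enrichment restricted to couplings arriving from
#' `source_region`, averaged over the target region's qualifying neurons.
#' Self-edges never exist, so the intra-region case is well defined.
#'
#' @inheritParams enrichment_index
#' @param target_region Region of the predicted neurons.
#' @return Mean index, or NA if no neuron qualifies.
#' @export
region_pair_enrichment <- function(graph, labels, source_region,
                                   target_region,
                                   variable = c("choice", "stimulus"),
                                   side = NULL) {
  variable <- match.arg(variable)
  ids <- graph_ids(graph)
  tgts <- intersect(graph$targets,
                    ids[graph$regions[as.character(ids)] == target_region])
  v <- vapply(tgts, enrichment_index, numeric(1), graph = graph,
              labels = labels, variable = variable, side = side,
              source_region = source_region)
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Random-coupling null for a learning change in enrichment
#'
#' Draws null graphs preserving each target's incoming edge count with
#' sources resampled uniformly from its candidates, recomputes the mean
#' enrichment per stage, and compares the observed stage difference
#' (stage 2 minus stage 1) against the null-difference distribution
#' (one-tailed, add-one).
#'
#' @param graph1,graph2 `coupling_graph`s for the two stages.
#' @param labels1,labels2 [tuning_labels()] per stage.
#' @param variable `"choice"` or `"stimulus"`.
#' @param iters Null draws (default 1000, must be >= 1).
#' @param seed Integer seed.
#' @return List `observed_diff`, `null_diff`, `p_value`.
#' @export
null_enrichment <- function(graph1, graph2, labels1, labels2,
                            variable = c("choice", "stimulus"),
                            iters = 1000, seed = 1L) {
  variable <- match.arg(variable)
  if (iters < 1) stop("null_enrichment: iters must be >= 1")
  obs <- mean_enrichment(graph2, labels2, variable)$mean -
    mean_enrichment(graph1, labels1, variable)$mean
  set.seed(seed)
  resample <- function(graph) {
    ids <- graph_ids(graph)
    deg <- table(factor(graph$edges$target_id, levels = ids))
    src <- integer(0); tgt <- integer(0)
    for (i in seq_along(ids)) {
      k <- as.integer(deg[i])
      if (!k) next
      cand <- setdiff(ids, ids[i])
      pick <- cand[sample.int(length(cand), min(k, length(cand)))]
      src <- c(src, pick); tgt <- c(tgt, rep(ids[i], length(pick)))
    }
    coupling_graph(
      data.frame(source_id = src, target_id = tgt, lag1_sig = TRUE,
                 lag2_sig = FALSE, delta_ev = NA_real_, p_value = NA_real_),
      graph$regions, graph$stage, graph$targets)
  }
  null_diff <- vapply(seq_len(iters), function(i) {
    mean_enrichment(resample(graph2), labels2, variable)$mean -
      mean_enrichment(resample(graph1), labels1, variable)$mean
  }, numeric(1))
  list(observed_diff = obs, null_diff = null_diff,
       p_value = addone_p(obs, null_diff))
}

#' Partition couplings into retained and eliminated
#'
#' Retained edges are present (as source -> target pairs) in both graphs;
#' eliminated edges are present in the first but not the second. The two
#' sets partition the first graph's edges exactly, so the fractions sum
#' to 1.
#'
#' @param graph1,graph2 `coupling_graph`s sharing the same matched neuron
#'   ids (disjoint sets error).
#' @return List `retained`, `eliminated` (edge data.frames),
#'   `retained_fraction`, `eliminated_fraction`.
#' @export
retained_eliminated <- function(graph1, graph2) {
  if (!length(intersect(graph_ids(graph1), graph_ids(graph2)))) {
    stop("retained_eliminated: graphs have disjoint neuron sets")
  }
  k1 <- paste(graph1$edges$source_id, graph1$edges$target_id)
  k2 <- paste(graph2$edges$source_id, graph2$edges$target_id)
  keep <- k1 %in% k2
  n1 <- nrow(graph1$edges)
  list(retained = graph1$edges[keep, , drop = FALSE],
       eliminated = graph1$edges[!keep, , drop = FALSE],
       retained_fraction = if (n1) sum(keep) / n1 else NA_real_,
       eliminated_fraction = if (n1) sum(!keep) / n1 else NA_real_)
}

# z-scored design matrix for one target (shared helper; movement optional)
session_design <- function(s, tid, movement = NULL, task = NULL, cpl = NULL) {
  if (is.null(task)) task <- task_predictors(s, movement)
  if (is.null(cpl)) cpl <- coupling_predictors(s)
  keep <- s$neuron_ids != tid
  X <- cbind(task$X, cpl$L1[, keep, drop = FALSE], cpl$L2[, keep, drop = FALSE])
  groups <- c(task$groups, colnames(cpl$L1)[keep], colnames(cpl$L2)[keep])
  z <- zscore_cols(X)
  groups <- groups[colnames(X) %in% colnames(z$X)]
  structure(list(X = z$X, groups = groups, dropped = z$dropped,
                 target_id = tid), class = "design_matrix")
}

coupling_cols_for <- function(fit, source_id, lags = c(1L, 2L)) {
  want <- paste0("cpl_", source_id, "_lag", lags)
  intersect(want, names(fit$beta))
}

#' Coupling-only reconstructions from retained vs eliminated edges
#'
#' For every target neuron with at least one retained and one eliminated
#' incoming edge, equal-sized random subsamples (the smaller count) of the
#' two edge sets drive coupling-only reconstructions
#' `exp(X_coupling beta_coupling + beta0)`.
#'
#' @param sglm A `session_glm` fit on the earlier-stage session.
#' @param s The earlier-stage [session()].
#' @param partition Output of [retained_eliminated()].
#' @param movement Optional movement trace matching the fits.
#' @param seed Integer seed for the subsampling.
#' @return List `retained`, `eliminated` (matrices, neurons x frames,
#'   rownames = target ids), `skipped` (ids lacking one side).
#' @export
reconstruct_retained_eliminated <- function(sglm, s, partition,
                                            movement = NULL, seed = 1L) {
  set.seed(seed)
  task <- task_predictors(s, movement)
  cpl <- coupling_predictors(s)
  ret <- partition$retained; eli <- partition$eliminated
  out_r <- list(); out_e <- list(); skipped <- integer(0)
  for (tid in intersect(unique(c(ret$target_id, eli$target_id)),
                        as.integer(names(sglm$fits)))) {
    r_src <- ret$source_id[ret$target_id == tid]
    e_src <- eli$source_id[eli$target_id == tid]
    if (!length(r_src) || !length(e_src)) { skipped <- c(skipped, tid); next }
    k <- min(length(r_src), length(e_src))
    r_src <- r_src[sample.int(length(r_src), k)]
    e_src <- e_src[sample.int(length(e_src), k)]
    design <- session_design(s, tid, task = task, cpl = cpl)
    fit <- sglm$fits[[as.character(tid)]]
    cols_r <- unlist(lapply(r_src, coupling_cols_for, fit = fit))
    cols_e <- unlist(lapply(e_src, coupling_cols_for, fit = fit))
    out_r[[as.character(tid)]] <- reconstruct(fit, design, cols_r)
    out_e[[as.character(tid)]] <- reconstruct(fit, design, cols_e)
  }
  list(retained = do.call(rbind, out_r), eliminated = do.call(rbind, out_e),
       skipped = skipped)
}

#' In-silico ablation of region-specific coupling
#'
#' Reconstructs coupling-only activity for the target region's neurons
#' after removing couplings either from `source_region` (`targeted`) or an
#' equal per-neuron count from all other regions (`control`), projects the
#' reconstructed population onto the choice axis, subtracts the baseline at
#' stimulus offset, normalizes by the SD of the resulting trace, and
#' averages over iterations. With `replace_with = "scrambled_ITI"` the
#' ablated couplings are kept but their pre-action predictor values are
#' replaced by resampled ITI values.
#'
#' @param sglm A `session_glm` whose fits cover the target region.
#' @param s The matching [session()].
#' @param axis Choice-mode [compute_mode_axis()] over the target region
#'   (observed-activity axis).
#' @param source_region Region whose couplings are ablated.
#' @param mode `"targeted"` or `"control"`.
#' @param iters Iterations (default 100).
#' @param replace_with `"zero"` or `"scrambled_ITI"`.
#' @param movement Optional movement trace matching the fits.
#' @param seed Integer seed.
#' @return List `trace` (side x window-frame matrix, iteration-averaged
#'   normalized projection), `preaction_selectivity` (mean R - L in the
#'   pre-action epoch), `offsets_s`.
#' @export
ablate_coupling <- function(sglm, s, axis, source_region,
                            mode = c("targeted", "control"), iters = 100,
                            replace_with = c("zero", "scrambled_ITI"),
                            movement = NULL, seed = 1L) {
  mode <- match.arg(mode)
  replace_with <- match.arg(replace_with)
  set.seed(seed)
  task <- task_predictors(s, movement)
  cpl <- coupling_predictors(s)
  graph <- sglm$graph
  tids <- intersect(axis$neuron_ids, as.integer(names(sglm$fits)))
  if (!length(tids)) stop("ablate_coupling: no fits for the axis neurons")
  reg_of <- function(ids) graph$regions[as.character(ids)]
  # per-target significant incoming sources, split by provenance
  per_target <- lapply(tids, function(tid) {
    inc <- incoming_edges(graph, tid)
    list(from_src = inc$source_id[reg_of(inc$source_id) == source_region],
         from_other = inc$source_id[reg_of(inc$source_id) != source_region])
  })
  names(per_target) <- tids
  designs <- lapply(tids, function(tid)
    session_design(s, tid, task = task, cpl = cpl))
  names(designs) <- tids
  fr <- s$frame_rate
  w <- axis$weights[match(tids, axis$neuron_ids)]
  # go-cue-locked window wide enough to include the stimulus offset
  # (2 s before the cue), where the baseline is taken
  window <- c(-2.5, 2)
  off <- seq.int(sec_to_frames(window[1L], fr),
                 sec_to_frames(window[2L], fr) - 1L)
  pre_rel <- NULL
  acc <- matrix(0, 2L, length(off), dimnames = list(c("L", "R"), NULL))
  acc_sel <- 0
  iti <- default_epochs()$spontaneous_iti
  pre <- default_epochs()$pre_action
  for (it in seq_len(iters)) {
    recon <- matrix(NA_real_, length(tids), n_frames(s))
    for (i in seq_along(tids)) {
      tid <- tids[i]
      fit <- sglm$fits[[as.character(tid)]]
      pt <- per_target[[as.character(tid)]]
      k <- length(pt$from_src)
      ablate <- if (mode == "targeted") pt$from_src else {
        if (k > length(pt$from_other)) {
          stop("ablate_coupling: control needs ", k, " couplings but only ",
               length(pt$from_other), " exist outside '", source_region, "'")
        }
        pt$from_other[sample.int(length(pt$from_other), k)]
      }
      keep_src <- setdiff(c(pt$from_src, pt$from_other), ablate)
      design <- designs[[as.character(tid)]]
      if (replace_with == "zero" || !length(ablate)) {
        cols <- unlist(lapply(keep_src, coupling_cols_for, fit = fit))
        recon[i, ] <- reconstruct(fit, design, cols)
      } else {
        X <- design$X
        scr_cols <- unlist(lapply(ablate, coupling_cols_for, fit = fit))
        pre_idx <- unique(unlist(lapply(seq_len(nrow(s$trials)), function(kk)
          tryCatch(frame_cols(epoch_frames(pre, s$trials[kk, ], fr,
                                           n_frames(s))),
                   error = function(e) integer(0)))))
        iti_idx <- unique(unlist(lapply(seq_len(nrow(s$trials)), function(kk)
          tryCatch(frame_cols(epoch_frames(iti, s$trials[kk, ], fr,
                                           n_frames(s))),
                   error = function(e) integer(0)))))
        for (cc in scr_cols) {
          X[pre_idx, cc] <- X[iti_idx[sample.int(length(iti_idx),
                                                 length(pre_idx),
                                                 replace = TRUE)], cc]
        }
        design2 <- design; design2$X <- X
        cols <- unlist(lapply(c(keep_src, ablate), coupling_cols_for,
                              fit = fit))
        recon[i, ] <- reconstruct(fit, design2, cols)
      }
    }
    # choice-axis projection of the reconstructed population
    proj_trial <- function(rows) {
      m <- matrix(NA_real_, length(rows), length(off))
      for (jj in seq_along(rows)) {
        cols <- s$trials$go_cue_frame[rows[jj]] + off + 1L
        if (cols[1L] < 1L || cols[length(cols)] > n_frames(s)) next
        m[jj, ] <- as.numeric(crossprod(recon[, cols, drop = FALSE], w))
      }
      colMeans(m, na.rm = TRUE)
    }
    tr <- rbind(L = proj_trial(which(s$trials$choice_side == "L")),
                R = proj_trial(which(s$trials$choice_side == "R")))
    # baseline at stimulus offset; go-cue-locked window, stimulus offset is
    # 2 s before the cue
    bl_pos <- match(sec_to_frames(-2, fr), off)
    tr <- tr - tr[, bl_pos]
    sd_tr <- stats::sd(as.numeric(tr))
    if (sd_tr > 0) tr <- tr / sd_tr
    acc <- acc + tr
    if (is.null(pre_rel)) {
      pre_rel <- which(off >= sec_to_frames(-1, fr) & off < 0L)
    }
    acc_sel <- acc_sel + mean(tr["R", pre_rel]) - mean(tr["L", pre_rel])
  }
  list(trace = acc / iters, preaction_selectivity = acc_sel / iters,
       offsets_s = off / fr, mode = mode, source_region = source_region)
}

#' Correlation-based functional connectivity
#'
#' Pearson correlation of neuron pairs over concatenated epoch frames
#' (spontaneous ITI or pre-action); pairs with correlation p-value below
#' `p_thresh` become (undirected) edges, stored symmetrically so the
#' convergence/enrichment machinery applies unchanged. Constant neurons
#' are excluded.
#'
#' @param s A [session()].
#' @param epoch `"spontaneous_iti"` or `"pre_action"`.
#' @param p_thresh Edge p-value threshold (default 1e-4).
#' @return A `coupling_graph` with attribute-free symmetric edges.
#' @export
corr_connectivity <- function(s, epoch = c("spontaneous_iti", "pre_action"),
                              p_thresh = 1e-4) {
  epoch <- match.arg(epoch)
  ep <- default_epochs()[[epoch]]
  cols <- unique(unlist(lapply(seq_len(nrow(s$trials)), function(k)
    tryCatch(frame_cols(epoch_frames(ep, s$trials[k, ], s$frame_rate,
                                     n_frames(s))),
             error = function(e) integer(0)))))
  if (length(cols) < 10L) stop("corr_connectivity: fewer than 10 epoch samples")
  a <- s$activity[, sort(cols), drop = FALSE]
  sd_ <- apply(a, 1L, stats::sd)
  ok <- which(sd_ > 0)
  r <- stats::cor(t(a[ok, , drop = FALSE]))
  n <- ncol(a)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(pv) <- 1
  hit <- which(pv < p_thresh & upper.tri(pv), arr.ind = TRUE)
  ids <- s$neuron_ids[ok]
  edges <- if (nrow(hit)) {
    e1 <- data.frame(source_id = ids[hit[, 1L]], target_id = ids[hit[, 2L]],
                     lag1_sig = NA, lag2_sig = NA,
                     delta_ev = NA_real_,
                     p_value = pv[hit])
    rbind(e1, data.frame(source_id = e1$target_id, target_id = e1$source_id,
                         lag1_sig = NA, lag2_sig = NA, delta_ev = NA_real_,
                         p_value = e1$p_value))
  } else {
    data.frame(source_id = integer(0), target_id = integer(0),
               lag1_sig = logical(0), lag2_sig = logical(0),
               delta_ev = numeric(0), p_value = numeric(0))
  }
  g <- coupling_graph(edges, stats::setNames(s$regions, s$neuron_ids),
                      s$stage, targets = s$neuron_ids)
  g$undirected <- TRUE
  g
}
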