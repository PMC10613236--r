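#' ROC area under the curve
#'
#' AUC for separating group B from group A; equals the Mann-Whitney
#' statistic `U / (nA * nB)` with ties counted as 0.5 (midranks).
#' `auc(A, B) = 1` means every B value exceeds every A value.
#'
#' @param values_a,values_b Numeric vectors (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("auc: empty group")
  na <- length(values_a); nb <- length(values_b)
  r <- rank(c(values_b, values_a))
  (sum(r[seq_len(nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

#' Decoding accuracy from an AUC
#'
#' `2 * |AUC - 0.5|`: the absolute deviation of the AUC from chance,
#' rescaled to `[0, 1]`. Invariant to swapping class labels.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @return Accuracy in `[0, 1]`.
#' @export
decoding_accuracy <- function(auc_value) {
  stopifnot(all(auc_value >= 0 & auc_value <= 1))
  2 * abs(auc_value - 0.5)
}

# add-one permutation p-value: P(null >= observed)
addone_p <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Label-shuffle null for single-variable decoding
#'
#' Shuffles trial labels `n_shuffles` times to build a null AUC
#' distribution, and reports a one-tailed add-one p-value for the observed
#' decoding accuracy: `p = (1 + #{null acc >= observed}) / (1 + n)`.
#'
#' @param values Numeric vector (one value per trial).
#' @param labels Two-level labels aligned to `values`.
#' @param n_shuffles Number of label permutations (default 1000; must be
#'   >= 1).
#' @param seed Integer seed.
#' @return List `auc`, `accuracy`, `p_value`, `null_auc`, `n_shuffles`
#'   (class `decoding_result`).
#' @export
shuffle_null_decoding <- function(values, labels, n_shuffles = 1000, seed = 1L) {
  if (n_shuffles < 1) stop("shuffle_null_decoding: n_shuffles must be >= 1")
  lv <- unique(labels)
  if (length(lv) != 2L || min(table(labels)) < 2L) {
    stop("shuffle_null_decoding: need >= 2 trials of each of 2 labels")
  }
  lv <- sort(lv)
  obs_auc <- auc(values[labels == lv[1L]], values[labels == lv[2L]])
  obs_acc <- decoding_accuracy(obs_auc)
  set.seed(seed)
  null_auc <- vapply(seq_len(n_shuffles), function(i) {
    sl <- sample(labels)
    auc(values[sl == lv[1L]], values[sl == lv[2L]])
  }, numeric(1))
  structure(
    list(auc = obs_auc, accuracy = obs_acc,
         p_value = addone_p(obs_acc, decoding_accuracy(null_auc)),
         null_auc = null_auc, n_shuffles = n_shuffles),
    class = "decoding_result")
}

#' Shuffle test for a learning-stage increase in decoding accuracy
#'
#' Compares the observed accuracy difference (last stage minus first) with
#' the distribution of differences between stagewise label-shuffle nulls;
#' one-tailed add-one p for an increase.
#'
#' @param values_by_stage Named list (stage order = learning order) of
#'   lists with elements `values` and `labels`.
#' @param n_shuffles Permutations per stage (default 1000).
#' @param seed Integer seed.
#' @return List with `observed_diff`, `null_diff`, `p_value`.
#' @export
learning_trend_null <- function(values_by_stage, n_shuffles = 1000, seed = 1L) {
  if (length(values_by_stage) < 2L) stop("learning_trend_null: need >= 2 stages")
  if (n_shuffles < 1) stop("learning_trend_null: n_shuffles must be >= 1")
  acc_of <- function(v, l) {
    lv <- sort(unique(l))
    decoding_accuracy(auc(v[l == lv[1L]], v[l == lv[2L]]))
  }
  first <- values_by_stage[[1L]]
  last <- values_by_stage[[length(values_by_stage)]]
  obs <- acc_of(last$values, last$labels) - acc_of(first$values, first$labels)
  set.seed(seed)
  null_stage <- function(stg) {
    vapply(seq_len(n_shuffles),
           function(i) acc_of(stg$values, sample(stg$labels)), numeric(1))
  }
  null_diff <- null_stage(last) - null_stage(first)
  list(observed_diff = obs, null_diff = null_diff,
       p_value = addone_p(obs, null_diff))
}

#' One-tailed bootstrap test for a stagewise increase
#'
#' Resamples units (sessions or neurons) with replacement within each
#' stage, recomputes `statistic` per stage, and reports the add-one
#' fraction of replicates in which the last stage does not exceed the
#' first. Replicates on which the statistic is undefined (NA/NaN) are
#' redrawn, with the redraw count reported.
#'
#' @param values_by_stage Named list of numeric vectors (stage order =
#'   learning order), each with >= 2 units.
#' @param n_boot Bootstrap replicates (default 1000, must be >= 1).
#' @param statistic Function applied to each resampled stage (default mean).
#' @param seed Integer seed.
#' @return List `p_value`, `boot_diff`, `n_redrawn`.
#' @export
bootstrap_increase <- function(values_by_stage, n_boot = 1000,
                               statistic = mean, seed = 1L) {
  if (n_boot < 1) stop("bootstrap_increase: n_boot must be >= 1")
  if (any(lengths(values_by_stage) < 2L)) {
    stop("bootstrap_increase: need >= 2 units per stage")
  }
  set.seed(seed)
  first <- values_by_stage[[1L]]
  last <- values_by_stage[[length(values_by_stage)]]
  diffs <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      d <- statistic(last[sample.int(length(last), replace = TRUE)]) -
        statistic(first[sample.int(length(first), replace = TRUE)])
      if (is.finite(d)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) stop("bootstrap_increase: statistic ",
                                          "undefined on too many replicates")
    }
    diffs[b] <- d
  }
  list(p_value = (1 + sum(diffs <= 0)) / (1 + n_boot),
       boot_diff = diffs, n_redrawn = n_redrawn)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Standard step-up rule at level `q`: reject hypotheses 1..i* in p-value
#' order, where `i*` is the largest i with `p(i) <= i q / m`.
#'
#' @param p_values Numeric vector in `[0, 1]` (no NAs).
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask aligned to `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (anyNA(p_values)) stop("bh_fdr: NaN/NA p-values")
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (!m) return(logical(0))
  o <- order(p_values)
  ok <- p_values[o] <= seq_len(m) * q / m
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0L) mask[o[seq_len(k)]] <- TRUE
  mask
}

#' Classify stimulus/choice encoding of single neurons
#'
#' Stimulus encoding compares stimulus-epoch mean activity between correct
#' left and correct right trials; choice encoding compares pre-action-epoch
#' activity grouped by lick side (all responded trials). A neuron is
#' labelled by its preferred side (sign of mean R - mean L) when the
#' Wilcoxon rank-sum p-value is below `p_threshold`, else `"none"`.
#'
#' @param s A [session()].
#' @param region Region label, or `NULL` for all neurons.
#' @param variable `"stimulus"` or `"choice"`.
#' @param epoch Defining epoch (defaults by variable).
#' @param p_threshold Wilcoxon p-value cutoff (default 0.05).
#' @return Data.frame `neuron_id, label, p_value` with `label` in
#'   `{"L-pref", "R-pref", "none"}`.
#' @export
classify_encoding <- function(s, region = NULL,
                              variable = c("stimulus", "choice"),
                              epoch = NULL, p_threshold = 0.05) {
  variable <- match.arg(variable)
  if (is.null(epoch)) {
    epoch <- default_epochs()[[if (variable == "stimulus") "stimulus"
                               else "pre_action"]]
  }
  idx <- if (is.null(region)) seq_len(n_neurons(s)) else region_index(s, region)
  if (variable == "stimulus") {
    use <- s$trials$correct
    side <- s$trials$stimulus_side
  } else {
    use <- s$trials$choice_side %in% c("L", "R")
    side <- s$trials$choice_side
  }
  em <- trial_epoch_means(s, idx, epoch)
  ok <- use & !is.na(em[, 1L])
  lab <- rep("none", length(idx)); pv <- rep(NA_real_, length(idx))
  if (sum(ok & side == "L") < 2L || sum(ok & side == "R") < 2L) {
    warning("classify_encoding: < 2 trials in a group; all labels 'none'")
  } else {
    for (j in seq_along(idx)) {
      l <- em[ok & side == "L", j]; r <- em[ok & side == "R", j]
      pv[j] <- suppressWarnings(stats::wilcox.test(r, l)$p.value)
      if (!is.na(pv[j]) && pv[j] < p_threshold) {
        lab[j] <- if (mean(r) >= mean(l)) "R-pref" else "L-pref"
      }
    }
  }
  data.frame(neuron_id = s$neuron_ids[idx], label = lab, p_value = pv,
             stringsAsFactors = FALSE)
}

#' Joint stimulus and choice tuning labels
#'
#' Convenience wrapper returning both [classify_encoding()] calls merged by
#' neuron.
#'
#' @inheritParams classify_encoding
#' @return Data.frame `neuron_id, stimulus_encoding, choice_encoding`.
#' @export
tuning_labels <- function(s, region = NULL, p_threshold = 0.05) {
  st <- classify_encoding(s, region, "stimulus", p_threshold = p_threshold)
  ch <- classify_encoding(s, region, "choice", p_threshold = p_threshold)
  data.frame(neuron_id = st$neuron_id,
             stimulus_encoding = st$label,
             choice_encoding = ch$label,
             stringsAsFactors = FALSE)
}
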