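mk_graph <- function(edges, regions, targets = NULL) {
  e <- data.frame(source_id = edges[, 1], target_id = edges[, 2],
                  lag1_sig = TRUE, lag2_sig = FALSE,
                  delta_ev = 0.01, p_value = 0.001)
  if (is.null(targets)) targets <- as.integer(names(regions))
  coupling_graph(e, regions, targets = targets)
}

test_that("coupling_graph validates endpoints and self-edges", {
  regions <- setNames(rep("A", 3), 1:3)
  expect_error(mk_graph(cbind(1, 1), regions), "self-edges")
  expect_error(mk_graph(cbind(1, 9), regions), "missing")
})

test_that("convergence index counts significant inputs over candidates", {
  regions <- setNames(rep(c("A", "B"), c(20, 4)), 1:24)
  # 5 of the 20 region-A neurons couple onto neuron 21 (region B)
  g <- mk_graph(cbind(1:5, 21), regions)
  expect_equal(convergence_index(g, 21, "A"), 5 / 20)
  expect_equal(convergence_index(g, 22, "A"), 0)
  # all candidates coupled
  g2 <- mk_graph(cbind(1:20, 21), regions)
  expect_equal(convergence_index(g2, 21, "A"), 1)
  # target excluded from its own region's candidates
  g3 <- mk_graph(cbind(2:6, 1), regions)
  expect_equal(convergence_index(g3, 1, "A"), 5 / 19)
  expect_true(is.na(convergence_index(g, 1, "C")))
})

test_that("enrichment index is the same-tuned fraction of incoming edges", {
  regions <- setNames(rep("A", 8), 1:8)
  labels <- data.frame(neuron_id = 1:8,
                       stimulus_encoding = "none",
                       choice_encoding = c("R-pref", "R-pref", "R-pref",
                                           "L-pref", "R-pref", "none",
                                           "L-pref", "R-pref"))
  # neuron 8 (R-pref) receives from 1,2,3 (R-pref) and 4 (L-pref)
  g <- mk_graph(cbind(1:4, 8), regions)
  expect_equal(enrichment_index(g, labels, 8, "choice"), 0.75)
  g_all <- mk_graph(cbind(c(1, 2, 3, 5), 8), regions)
  expect_equal(enrichment_index(g_all, labels, 8, "choice"), 1)
  g_none <- mk_graph(cbind(c(4, 6, 7), 8), regions)
  expect_equal(enrichment_index(g_none, labels, 8, "choice"), 0)
  # undefined for untuned targets or targets without incoming edges
  expect_true(is.na(enrichment_index(g, labels, 6, "choice")))
  expect_true(is.na(enrichment_index(g, labels, 5, "choice")))
})

test_that("region-pair enrichment averages over qualifying targets", {
  regions <- setNames(rep(c("P", "A"), each = 4), 1:8)
  labels <- data.frame(neuron_id = 1:8, stimulus_encoding = "none",
                       choice_encoding = c("R-pref", "R-pref", "L-pref",
                                           "L-pref", "R-pref", "R-pref",
                                           "none", "none"))
  # fully same-tuned planted block P -> A
  g <- mk_graph(rbind(c(1, 5), c(2, 5), c(1, 6), c(2, 6)), regions)
  expect_equal(region_pair_enrichment(g, labels, "P", "A", "choice"), 1)
  expect_true(is.na(region_pair_enrichment(g, labels, "A", "P", "choice")))
})

test_that("random tuning gives ~0.5 enrichment over seeds", {
  regions <- setNames(rep("A", 30), 1:30)
  vals <- sapply(1:30, function(seed) {
    set.seed(seed)
    labels <- data.frame(neuron_id = 1:30, stimulus_encoding = "none",
                         choice_encoding = sample(c("R-pref", "L-pref"), 30,
                                                  TRUE))
    edges <- cbind(sample(1:29, 10, TRUE), 30)
    edges <- edges[edges[, 1] != 30, , drop = FALSE]
    g <- mk_graph(unique(edges), regions)
    enrichment_index(g, labels, 30, "choice")
  })
  expect_lt(abs(mean(vals, na.rm = TRUE) - 0.5), 0.1)
})

test_that("retained/eliminated is exact set arithmetic with fractions summing to 1", {
  regions <- setNames(rep("A", 6), 1:6)
  g1 <- mk_graph(rbind(c(1, 2), c(2, 3), c(3, 4)), regions)   # A, B, C
  g2 <- mk_graph(rbind(c(1, 2), c(3, 4), c(4, 5)), regions)   # A, C, D
  part <- retained_eliminated(g1, g2)
  expect_equal(nrow(part$retained), 2L)
  expect_equal(nrow(part$eliminated), 1L)
  expect_equal(part$retained_fraction, 2 / 3)
  expect_equal(part$retained_fraction + part$eliminated_fraction, 1)
  # subset and disjoint cases
  expect_equal(retained_eliminated(g1, g1)$eliminated_fraction, 0)
  g3 <- mk_graph(rbind(c(5, 6)), regions)
  expect_equal(retained_eliminated(g1, g3)$retained_fraction, 0)
  g_other <- mk_graph(rbind(c(7, 8)), setNames(rep("A", 2), 7:8))
  expect_error(retained_eliminated(g1, g_other), "disjoint")
})

test_that("null_enrichment calibrates under label-independent edges", {
  regions <- setNames(rep("A", 16), 1:16)
  set.seed(3)
  labels <- data.frame(neuron_id = 1:16, stimulus_encoding = "none",
                       choice_encoding = sample(c("R-pref", "L-pref"), 16, TRUE))
  mk_rand <- function(seed) {
    set.seed(seed)
    e <- unique(cbind(sample(1:16, 30, TRUE), sample(1:16, 30, TRUE)))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    mk_graph(e, regions)
  }
  res <- null_enrichment(mk_rand(1), mk_rand(2), labels, labels,
                         "choice", iters = 200, seed = 5)
  expect_gt(res$p_value, 0.01)   # no planted change: not strongly significant
  expect_error(null_enrichment(mk_rand(1), mk_rand(2), labels, labels,
                               iters = 0), ">= 1")
})

test_that("corr_connectivity links duplicated neurons and respects the null rate", {
  g <- small_sim(seed = 8, n_neurons = c(ALM = 10, PPC = 10), n_trials = 30,
                 coupling_density = 0)
  s <- g$session
  s$activity[2, ] <- s$activity[1, ]          # duplicate neuron
  cg <- corr_connectivity(s, "spontaneous_iti")
  pairs <- paste(cg$edges$source_id, cg$edges$target_id)
  expect_true("1 2" %in% pairs && "2 1" %in% pairs)
  # independent neurons: edge rate near the p threshold (loose bound)
  g0 <- small_sim(seed = 9, n_neurons = c(ALM = 15, PPC = 15), n_trials = 30,
                  coupling_density = 0, tuning_snr = 0)
  cg0 <- corr_connectivity(g0$session, "spontaneous_iti", p_thresh = 1e-2)
  n_pairs <- choose(30, 2)
  expect_lt(nrow(cg0$edges) / 2 / n_pairs, 0.12)
})
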