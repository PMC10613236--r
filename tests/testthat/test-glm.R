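test_that("raised cosine bases tile the span with unit peaks", {
  b1 <- raised_cosine_basis(1, 1, 9.35)
  expect_equal(dim(b1), c(9L, 1L))
  expect_equal(max(b1), 1)
  expect_equal(which.max(b1[, 1]), 5L)   # peak near span centre

  b3 <- raised_cosine_basis(3, 1, 9.35)
  expect_equal(dim(b3), c(9L, 3L))
  expect_true(all(b3 >= 0))
  peaks <- apply(b3, 2, which.max)
  expect_true(all(diff(peaks) > 0))
  expect_equal(apply(b3, 2, max), rep(1, 3))

  # interior tiling: the (un-renormalized) cosine set sums to a constant
  # away from the edges; after per-column peak scaling it stays within 10%
  bfine <- raised_cosine_basis(5, 2, 50)
  mid <- 21:80
  s <- rowSums(bfine)[mid]
  expect_lt((max(s) - min(s)) / mean(s), 0.1)

  expect_error(raised_cosine_basis(3, 0.01, 9.35), "span")
})

test_that("design matrix has the documented column structure", {
  g <- small_sim(seed = 2, n_neurons = c(ALM = 15, PPC = 15), n_trials = 30)
  d <- suppressWarnings(build_design_matrix(g$session, 1, g$movement))
  task <- d$groups[!startsWith(d$groups, "cpl_")]
  # 2x3 stim + 2x5 delay + 2x5 resp + 3 reward + 2x3 movement = 35 task
  # columns, minus any constant columns that were dropped
  expect_equal(length(task) + sum(!startsWith(d$dropped, "cpl")), 35L)
  cpl <- d$groups[startsWith(d$groups, "cpl_")]
  expect_equal(length(cpl), 29L * 2L)
  expect_false(any(grepl("^cpl_1_", cpl)))        # never its own predictor
  # z-scored columns
  expect_lt(max(abs(colMeans(d$X))), 1e-8)
  expect_equal(unname(apply(d$X[, 1:5], 2, sd)), rep(1, 5), tolerance = 1e-8)
})

test_that("pseudo_ev matches the closed form and the loglik oracle", {
  expect_equal(pseudo_ev(c(1, 0, 2), c(1, 0, 2)), 1, tolerance = 1e-12)
  y <- c(1, 0, 2)
  expect_equal(pseudo_ev(y, rep(mean(y), 3)), 0, tolerance = 1e-12)
  # D(yhat) = 2 ln 2, D(ybar) = 4 ln 2 -> EV 0.5
  expect_equal(pseudo_ev(c(1, 0, 2), c(0.5, 0.5, 2)), 0.5, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    y <- rpois(n, 1.2)
    if (var(y) == 0) next
    mu <- rgamma(n, 2, 2)
    expect_equal(pseudo_ev(y, mu), pseudo_ev_oracle(y, mu), tolerance = 1e-10)
  }
  expect_error(pseudo_ev(c(1, 1), c(1, 1)), "constant")
  expect_error(pseudo_ev(c(1, 0), c(0, 1)), "> 0")
})

test_that("intercept-only fit is the Poisson closed form", {
  set.seed(4)
  y <- rpois(100, 2)
  fit <- fit_poisson_glm(NULL, y)
  expect_equal(fit$beta0, log(mean(y[1:70])))
  expect_length(fit$beta, 0)
})

test_that("reconstruct obeys the log-linear decomposition", {
  g <- small_sim(seed = 5, n_neurons = c(ALM = 8, PPC = 8), n_trials = 25)
  s <- g$session
  d <- suppressWarnings(build_design_matrix(s, 3, NULL))
  y <- s$activity[3, ]
  fit <- fit_poisson_glm(d, y, n_lambda = 15, cv_folds = 3, seed = 2)
  full <- reconstruct(fit, d, "full")
  task <- reconstruct(fit, d, "task_only")
  cpl <- reconstruct(fit, d, "coupling_only")
  expect_equal(full, task * cpl / exp(fit$beta0), tolerance = 1e-8)
  expect_equal(reconstruct(fit, d, character(0)),
               rep(exp(fit$beta0), length(y)))
  expect_equal(reconstruct(fit, d, colnames(d$X)), full)
  expect_error(reconstruct(fit, d, "nope"), "unknown")
})

test_that("summarize_weights returns the signed maximum", {
  fit <- structure(list(beta = c(a1 = -0.5, a2 = -0.1, b1 = 0),
                        groups = c("a", "a", "b"), beta0 = 0),
                   class = "glm_fit")
  expect_equal(summarize_weights(fit, "a"), -0.1)
  expect_equal(summarize_weights(fit, "b"), 0)
  expect_error(summarize_weights(fit, "zz"), "unknown")
})

test_that("zero-coefficient groups are never significant; fit order-invariant", {
  g <- small_sim(seed = 6, n_neurons = c(ALM = 8, PPC = 8), n_trials = 25)
  s <- g$session
  d <- suppressWarnings(build_design_matrix(s, 2, NULL))
  y <- s$activity[2, ]
  fit <- fit_poisson_glm(d, y, n_lambda = 15, cv_folds = 3, seed = 2)
  sig <- significant_predictors(fit, d, y, n_shuffles = 60,
                                frame_rate = s$frame_rate, seed = 3)
  zero_groups <- sapply(unique(fit$groups), function(gr)
    all(fit$beta[fit$groups == gr] == 0))
  expect_true(all(sig$delta_ev[zero_groups[sig$group]] == 0))
  expect_true(all(!sig$significant[zero_groups[sig$group]]))

  # column order invariance of the fit at fixed lambda path
  o <- sample(ncol(d$X))
  d2 <- d; d2$X <- d$X[, o]; d2$groups <- d$groups[o]
  fit2 <- fit_poisson_glm(d2, y, n_lambda = 15, cv_folds = 3, seed = 2)
  expect_equal(fit2$lambda, fit$lambda)
  # coordinate descent converges to ~1e-4; identical selections either way
  expect_equal(fit2$beta[names(fit$beta)], fit$beta, tolerance = 1e-3)
})

test_that("negative delta-EV values are tolerated by the significance test", {
  set.seed(9)
  X <- matrix(rnorm(600), 200, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rpois(200, 1)
  d <- structure(list(X = scale(X), groups = colnames(X), dropped = character(0)),
                 class = "design_matrix")
  fit <- fit_poisson_glm(d, y, n_lambda = 10, cv_folds = 3, seed = 1)
  fit$beta[] <- c(0.05, -0.03, 0.02)   # force nonzero, spurious coefficients
  expect_silent(sig <- significant_predictors(fit, d, y, n_shuffles = 50,
                                              block_s = 2, frame_rate = 9.35,
                                              seed = 2))
  expect_true(all(is.finite(sig$p_value)))
})
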