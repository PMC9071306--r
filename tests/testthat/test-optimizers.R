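test_that("in-sample criterion matches its definition", {
  d <- overlap_fixture()
  Xm <- range_std(d$X)
  spec <- classifier_spec("knn")
  # degenerate single-class input: every prediction is correct
  expect_equal(criterion_accuracy(Xm, rep("a", nrow(Xm)), c(1, 1), spec), 1.0)
  # lambda = 1 only shifts, and the shift is absorbed by standardization
  base <- {
    Xs <- standard_apply(standard_fit(Xm), Xm)
    clf <- train_classifier(make_classifier(spec), Xs, d$Y)
    mean(predict_classifier(clf, Xs) == d$Y)
  }
  expect_equal(criterion_accuracy(Xm, d$Y, c(1, 1), spec), base)
  # independent 5-NN re-implementation at lambda = [0, 0]
  d12 <- overlap_fixture(n_per = 6L, seed = 21L)
  X12 <- range_std(d12$X)
  expect_equal(criterion_accuracy(X12, d12$Y, c(0, 0), spec),
               oracle_knn_criterion(X12, d12$Y, c(0, 0)))
})

test_that("grid searches match brute-force oracles and tie rules", {
  d <- overlap_fixture()
  Xm <- range_std(d$X)
  g5 <- grid_spec(candidates = seq(-2, 2, 1))
  for (name in c("knn", "bayesian")) {
    spec <- classifier_spec(name)
    # exhaustive double loop with first-maximizer tie rule
    best_a <- 0; best <- c(-2, -2)
    for (l1 in g5$candidates) for (l2 in g5$candidates) {
      a <- criterion_accuracy(Xm, d$Y, c(l1, l2), spec)
      if (a > best_a) { best_a <- a; best <- c(l1, l2) }
    }
    expect_equal(grid_search_2d(Xm, d$Y, spec, g5), best)
    # scalar loop oracle for spherical
    bs_a <- 0; bs <- -2
    for (l in g5$candidates) {
      a <- criterion_accuracy(Xm, d$Y, c(l, l), spec)
      if (a > bs_a) { bs_a <- a; bs <- l }
    }
    expect_equal(spherical_search(Xm, d$Y, spec, g5), c(bs, bs))
    # axis-scan oracle for diagonal (others fixed at 1)
    dg <- vapply(1:2, function(dir) {
      bd_a <- 0; bd <- -2
      for (l in g5$candidates) {
        lam <- c(1, 1); lam[dir] <- l
        a <- criterion_accuracy(Xm, d$Y, lam, spec)
        if (a > bd_a) { bd_a <- a; bd <- l }
      }
      bd
    }, numeric(1))
    expect_equal(diagonal_search(Xm, d$Y, spec, g5), dg)
    # spherical optimum is contained in the full grid
    expect_lte(bs_a, best_a)
  }
  # flat criterion: strict improvement keeps the first cell
  flat <- function(X, Y, lambda, spec) 0.5
  expect_equal(grid_search_2d(Xm, d$Y, NULL, g5, criterion = flat), c(-2, -2))
  expect_error(grid_search_2d(Xm[, 1, drop = FALSE], d$Y, NULL, g5),
               "2 features")
})

test_that("independently optimized directions can combine to a joint loss", {
  # per-axis winners (other coordinate at 1) land on a poor joint cell
  cands <- c(-1, 1, 3)
  tab <- matrix(c(
    0.50, 0.60, 0.40,   # lambda1 = -1
    0.70, 0.55, 0.72,   # lambda1 =  1
    0.40, 0.45, 0.20),  # lambda1 =  3
    3, 3, byrow = TRUE)
  crit <- table_criterion(tab, cands)
  X <- matrix(1.5, 4, 2)
  lam <- diagonal_search(X, rep(c("a", "b"), 2), NULL,
                         grid_spec(candidates = cands), criterion = crit)
  # axis winners: lambda1 = -1 (col at lambda2=1: .60,.55,.45),
  # lambda2 = 3 (row at lambda1=1: .70,.55,.72)
  expect_equal(lam, c(-1, 3))
  # ... whose joint value is below the untransformed cell [1, 1]
  expect_lt(crit(X, NULL, lam, NULL), crit(X, NULL, c(1, 1), NULL))
})

test_that("grid refinement scales candidates and attaches locally", {
  g <- grid_spec()
  expect_equal(g$candidates, seq(-5, 5, 1))
  r <- refine_grid(g)
  expect_equal(r$candidates, seq(-2.5, 2.5, 0.5))
  expect_length(r$candidates, 11L)
  expect_equal(r$mode, "local")
  r2 <- refine_grid(r)
  expect_equal(r2$candidates, seq(-1.25, 1.25, 0.25))
  expect_equal(grid_spec(gridsize = 21)$candidates, seq(-5, 5, 0.5))
})

test_that("random start points are bounded and reproducible", {
  g <- grid_spec()
  p1 <- withr::with_seed(9, generate_initial_point(5, g))
  p2 <- withr::with_seed(9, generate_initial_point(5, g))
  expect_identical(p1, p2)
  expect_true(all(p1 >= -5 & p1 <= 5))
  # refinement does not shrink the restart domain
  expect_equal(refine_grid(g)$domain, c(-5, 5))
})

test_that("iterative search follows the coordinate-descent contract", {
  cands <- 1:3
  tab <- matrix(c(
    0.50, 0.55, 0.40,
    0.60, 0.70, 0.45,
    0.55, 0.90, 0.65), 3, 3, byrow = TRUE)
  crit <- table_criterion(tab, cands)
  X <- matrix(1.5, 6, 2)
  Y <- rep(c("a", "b"), 3)
  g <- grid_spec(candidates = cands)
  cfg1 <- optimizer_config(epochs = 1, start_policy = "ones",
                           use_shift = FALSE, use_shuffle = FALSE,
                           use_finer = FALSE)
  r1 <- iterative_search(X, Y, NULL, cfg1, g, criterion = crit)
  expect_equal(r1$lambda, c(2, 2))     # epoch 1 stops at the coordinate optimum
  cfg2 <- optimizer_config(epochs = 2, start_policy = "ones",
                           use_shift = FALSE, use_shuffle = FALSE,
                           use_finer = FALSE)
  r2 <- iterative_search(X, Y, NULL, cfg2, g, criterion = crit)
  expect_equal(r2$lambda, c(3, 2))     # epoch 2 reaches the global optimum
  expect_equal(r2$trace$final_accuracy, 0.90)
  # evaluation count and monotone best accuracy
  expect_equal(r2$trace$n_evaluations, 2 * 2 * length(cands))
  expect_true(all(diff(r2$trace$best_accuracy) >= 0))
  expect_error(optimizer_config(epochs = 0), "positive")
})

test_that("iterative search never beats the exhaustive grid on shared grids", {
  d <- overlap_fixture()
  Xm <- range_std(d$X)
  g5 <- grid_spec(candidates = seq(-2, 2, 1))
  spec <- classifier_spec("bayesian")
  cfg <- optimizer_config(epochs = 3, start_policy = "ones",
                          use_shift = FALSE, use_shuffle = FALSE,
                          use_finer = FALSE)
  it <- iterative_search(Xm, d$Y, spec, cfg, g5)
  full <- grid_search_2d(Xm, d$Y, spec, g5)
  expect_lte(it$trace$final_accuracy,
             criterion_accuracy(Xm, d$Y, full, spec) + 1e-12)
  expect_true(all(diff(it$trace$best_accuracy) >= 0))
})

test_that("the mle start policy seeds the search at column-wise MLE", {
  d <- overlap_fixture()
  Xm <- range_std(d$X)
  cfg <- optimizer_config(epochs = 1, start_policy = "mle",
                          use_shift = FALSE, use_shuffle = FALSE,
                          use_finer = FALSE)
  r <- iterative_search(Xm, d$Y, classifier_spec("knn"), cfg, grid_spec())
  expect_equal(r$trace$start, unname(apply(Xm, 2, mle_lambda)))
})

test_that("a restart epoch explores from the fresh start point", {
  # spy criterion records every trial vector; the surface is flat except at
  # the all-ones start, so no strict improvement ever clears shift mode
  seen <- list()
  spy <- function(X, Y, lambda, spec) {
    seen[[length(seen) + 1L]] <<- lambda
    0.5
  }
  cands <- c(-5, 0, 5)
  X <- matrix(1.5, 4, 2)
  Y <- rep(c("a", "b"), 2)
  cfg <- optimizer_config(epochs = 2, shift_epoch = 2, start_policy = "ones",
                          use_shift = TRUE, use_shuffle = FALSE,
                          use_finer = FALSE, seed = 5)
  r <- iterative_search(X, Y, NULL, cfg, grid_spec(candidates = cands),
                        criterion = spy)
  expect_equal(r$trace$n_evaluations, 2 * 2 * 3)
  # the ones policy consumes no randomness, so the restart draw is the first
  # use of the seeded stream
  G <- withr::with_seed(cfg$seed, stats::runif(2, -5, 5))
  # epoch 2, direction 1 (evaluations 7..9): lambda2 comes from G
  eps2 <- do.call(rbind, seen[7:9])
  expect_equal(eps2[, 1], cands)
  expect_equal(eps2[, 2], rep(G[2], 3))
  # direction 2 (evaluations 10..12): the base carries direction 1's best
  # (first candidate on a flat scan)
  eps3 <- do.call(rbind, seen[10:12])
  expect_equal(eps3[, 1], rep(-5, 3))
  expect_equal(eps3[, 2], cands)
  # no strict improvement after the first evaluation: incumbent stays put
  expect_equal(r$lambda, c(-5, 1))
})

test_that("column-wise MLE recovers known exponents", {
  # lognormal data is normalized by the log branch
  y <- withr::with_seed(100, exp(stats::rnorm(2000, sd = 0.25)))
  expect_lt(abs(mle_lambda(y)), 0.15)
  # near-Gaussian positive data keeps lambda near 1
  y2 <- withr::with_seed(101, {
    v <- stats::rnorm(4000, mean = 1, sd = 0.25)
    v[v > 0][1:2000]
  })
  expect_lt(abs(mle_lambda(y2) - 1), 0.5)
  expect_error(mle_lambda(rep(2, 10)), "constant")
})

test_that("MLE agrees with the regression profile likelihood", {
  skip_if_not_installed("MASS")
  y <- withr::with_seed(102, stats::rgamma(500, shape = 2, rate = 1))
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.005), plotit = FALSE)
  expect_lt(abs(mle_lambda(y) - bc$x[which.max(bc$y)]), 0.01)
})
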