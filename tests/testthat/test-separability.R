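test_that("Tukey fences remove exactly the hand-computed outliers", {
  # [1,2,3,4,100]: Q1 = 2, Q3 = 4, IQR = 2, fence [-1, 7] -> 100 removed
  fm <- fence_fm(c(1, 2, 3, 4, 100))
  expect_identical(tukey_fence_filter(fm), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # all equal: degenerate fence keeps everything (equality allowed)
  expect_true(all(tukey_fence_filter(fence_fm(rep(7, 6)))))
  # nothing outside the fence: identity mask
  expect_true(all(tukey_fence_filter(fence_fm(c(10, 11, 12, 13, 14)))))
})

test_that("fence masks are invariant to affine rescaling of one feature", {
  fm <- random_fm(31)
  base <- suppressWarnings(tukey_fence_filter(fm))
  fm2 <- fm
  fm2$duration <- 3.7 * fm2$duration - 11
  expect_identical(suppressWarnings(tukey_fence_filter(fm2)), base)
})

test_that("small groups pass through the fence with a warning", {
  fm <- rbind(fence_fm(c(1, 2, 3, 4, 100)), fence_fm(c(5, 1000), "IL-10"))
  expect_warning(keep <- tukey_fence_filter(fm), "fewer than 4")
  expect_true(all(keep[6:7]))
})

test_that("standardisation matches the hand z-score and is idempotent", {
  z <- standardize_features(matrix(c(0, 2), ncol = 1,
                                   dimnames = list(NULL, "amplitude")))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  x <- with_seed(5, matrix(rnorm(60), ncol = 3,
                           dimnames = list(NULL, c("a", "b", "c"))))
  z1 <- standardize_features(x)
  expect_equal(standardize_features(z1), z1, tolerance = 1e-9)
  x[, 2] <- 4
  expect_error(standardize_features(x), "'b'")
})

test_that("nearest-neighbor pruning removes the hand-worked point", {
  # 1D points A = {0, 10}, B = {1, 20}: cross-group NN distances 1, 9, 1, 10;
  # the tie between A's 0 and B's 1 resolves to group A -> remove A's 0
  x <- matrix(c(0, 10, 1, 20), ncol = 1)
  g <- c("A", "A", "B", "B")
  expect_identical(iterative_nn_prune(x, g, 0.25),
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(iterative_nn_prune(x, g, 0)))   # drop_fraction 0: identity
})

test_that("pruning is deterministic and stops when a group empties", {
  fm <- random_fm(77)
  x <- standardize_features(fm[, separability_features()])
  m1 <- iterative_nn_prune(x, fm$group, 0.25)
  m2 <- iterative_nn_prune(x, fm$group, 0.25)
  expect_identical(m1, m2)
  expect_identical(sum(!m1), as.integer(ceiling(0.25 * nrow(x))))
  # a tiny group is protected by the early stop
  x2 <- matrix(c(0, 0.5, 1, 1.5, 0.2), ncol = 1)
  g2 <- c("A", "A", "A", "A", "B")
  expect_warning(m3 <- iterative_nn_prune(x2, g2, 0.8), "emptied")
})

test_that("the CH index matches hand-worked values and the definition", {
  expect_identical(calinski_harabasz(c(0, 1, 10, 11), c("a", "a", "b", "b")),
                   200)
  # identical group means: zero between-group dispersion
  expect_identical(calinski_harabasz(c(0, 2, 0, 2), c("a", "a", "b", "b")), 0)
  # zero within-group dispersion: +Inf sentinel
  expect_identical(calinski_harabasz(c(0, 0, 5, 5), c("a", "a", "b", "b")),
                   Inf)
  # brute-force oracle on random small instances
  with_seed(11, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      k <- sample(2:4, 1)
      d <- sample(1:5, 1)
      x <- matrix(rnorm(n * d, sd = 3), ncol = d)
      g <- sample(rep(seq_len(k), length.out = n))
      ours <- calinski_harabasz(x, g)
      ref <- ch_bruteforce(x, g)
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  })
})

test_that("CH is invariant to rigid motions and increases with separation", {
  with_seed(13, {
    x <- matrix(rnorm(40), ncol = 2)
    g <- rep(c("a", "b"), each = 10)
    x[g == "b", ] <- x[g == "b", ] + 4
    base <- calinski_harabasz(x, g)
    th <- 0.83
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(calinski_harabasz(x %*% rot, g), base, tolerance = 1e-9)
    expect_equal(calinski_harabasz(sweep(x, 2, c(100, -7)), g), base,
                 tolerance = 1e-9)
  })
  # 1D two-cluster family with growing mean separation
  half <- c(-1, -0.5, 0, 0.5, 1)
  ch_at <- vapply(c(2, 4, 8, 16), function(delta) {
    calinski_harabasz(c(half, half + delta), rep(c("a", "b"), each = 5))
  }, numeric(1))
  expect_true(all(diff(ch_at) > 0))
})

test_that("CH rejects degenerate groupings", {
  expect_error(calinski_harabasz(c(1, 2, 3), c("a", "a", "a")), "2 groups")
  expect_error(calinski_harabasz(c(1, 2), c("a", "b")), "more points")
})

test_that("Mann-Whitney micro-example and enumeration oracle agree", {
  gt <- group_tests(c(1, 2, 3, 100, 101, 102), rep(c("a", "b"), each = 3))
  expect_equal(gt$mann_whitney$p, 0.1, tolerance = 1e-12)
  expect_identical(gt$mann_whitney$method, "exact")
  # random small instance against exhaustive enumeration
  with_seed(23, {
    x <- rnorm(4); y <- rnorm(5) + 0.8
    gt2 <- group_tests(c(x, y), rep(c("a", "b"), c(4, 5)))
    expect_equal(gt2$mann_whitney$p, mw_exact_enum(x, y), tolerance = 1e-12)
  })
})

test_that("group tests behave on identical and multi-group inputs", {
  vals <- rep(c(5, 6, 7), 2)
  gt <- group_tests(vals, rep(c("a", "b"), each = 3))
  expect_lt(gt$anova$F, 1e-20)
  expect_gt(gt$mann_whitney$p, 0.5)
  with_seed(3, {
    gt3 <- group_tests(rnorm(30), rep(c("a", "b", "c"), each = 10))
    expect_identical(nrow(gt3$tukey), 3L)
    expect_true(all(gt3$tukey$p_adj >= 0 & gt3$tukey$p_adj <= 1))
    expect_null(gt3$mann_whitney)
  })
  expect_warning(group_tests(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "n < 2")
})

test_that("the permutative Mann-Whitney detects a strong contrast", {
  d <- null_feature_data(41)
  # pull the dss-condition group means together, keeping within-group spread
  x <- d$x
  for (g in unique(d$group)) {
    rows <- d$condition == "dss" & d$group == g
    mu <- colMeans(x[rows, , drop = FALSE])
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, 0.8 * mu)
  }
  res <- permutative_mann_whitney(x, d$group, d$condition, S = 20, m = 10,
                                  P = 199, seed = 4)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$ch["control"], res$ch["dss"])
  # deterministic under a fixed seed
  res2 <- permutative_mann_whitney(x, d$group, d$condition, S = 20, m = 10,
                                   P = 199, seed = 4)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$u_statistic, res2$u_statistic)
})

test_that("the full separability analysis records each pruning step", {
  fm <- random_fm(55, n_per = 20)
  res <- suppressWarnings(
    separability_analysis(fm, S = 10, m = NULL, P = 99, seed = 2))
  expect_s3_class(res, "separability_result")
  expect_identical(unname(res$n_steps["input"]), nrow(fm))
  expect_lte(res$n_steps["after_fence"], res$n_steps["input"])
  expect_lte(res$n_steps["after_prune"], res$n_steps["after_fence"])
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(all(res$ch >= 0))
  expect_output(print(res), "separability_result")
})
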