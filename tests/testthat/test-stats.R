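test_that("paired t matches the closed form and the loop oracle", {
  # d = (1, 2, 3): t = mean/sd * sqrt(3) = 2 / (1/sqrt(3)) = 2*sqrt(3)
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x))
    got <- paired_t(x, y)
    want <- oracle_paired_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    # antisymmetry
    flip <- paired_t(y, x)
    expect_equal(flip$t, -got$t, tolerance = 1e-10)
    expect_equal(flip$p, got$p, tolerance = 1e-10)
  }
})

test_that("degenerate paired differences are flagged", {
  res <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  res2 <- paired_t(c(2, 3, 4), c(1, 2, 3)) # constant nonzero difference
  expect_true(res2$degenerate)
  expect_equal(res2$t, Inf)
})

test_that("pearson matches closed forms, the toy vectors and the loop oracle", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  # covariance-formula hand computation: r = 3 / 5
  toy <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(toy$r, 0.6, tolerance = 1e-12)
  expect_equal(toy$r, oracle_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r)

  set.seed(82)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x))
    got <- pearson_cor(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # invariance under positive affine transforms
    expect_equal(pearson_cor(3 * x + 7, y)$r, got$r, tolerance = 1e-10)
  }
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the 27% extreme-group split gives nine of thirty-one", {
  set.seed(83)
  scores <- rnorm(31)
  g <- quantile_split(scores, sprintf("S%02d", 1:31))
  expect_length(g$high, 9)
  expect_length(g$low, 9)
  expect_length(intersect(g$high, g$low), 0)
  # the top group really holds the largest scores
  ids <- sprintf("S%02d", 1:31)
  expect_setequal(g$high, ids[order(-scores)[1:9]])

  expect_length(quantile_split(rnorm(100))$high, 27)
  # invariance under affine transforms of the scores
  g2 <- quantile_split(5 * scores - 2, sprintf("S%02d", 1:31))
  expect_identical(g2, g)
})

test_that("tied scores still give disjoint deterministic groups", {
  g <- quantile_split(rep(1, 31), sprintf("S%02d", 1:31))
  expect_length(g$high, 9)
  expect_length(g$low, 9)
  expect_length(intersect(g$high, g$low), 0)
  expect_identical(g$low, sprintf("S%02d", 1:9)) # bottom end of the ranking
  expect_identical(g, quantile_split(rep(1, 31), sprintf("S%02d", 1:31)))
  expect_error(quantile_split(rnorm(3), fraction = 0.5), "overlap")
})

test_that("identical conditions give all-zero contrasts", {
  feats <- simulate_edge_features(n_subjects = 10, planted_edge = NULL, seed = 84)
  feats$value[feats$condition == "far"] <-
    feats$value[feats$condition == "near"]
  ct <- contrast_report(feats, "condition")
  expect_true(all(ct$t == 0))
  expect_true(all(ct$degenerate)) # sd of differences is 0
})

test_that("a planted paired effect is found at its edge", {
  feats <- simulate_edge_features(
    n_subjects = 31, planted_edge = "LOFA-ROFA",
    d = 1.2, seed = 85
  )
  ct <- contrast_report(feats, "condition")
  expect_equal(nrow(ct), 45)
  hit <- ct[ct$unit == "LOFA-ROFA", ]
  expect_lt(hit$p, 0.05)
  expect_equal(unname(hit$df), 30)
  expect_identical(
    feats,
    simulate_edge_features(31, "LOFA-ROFA", d = 1.2, seed = 85)
  )
})

test_that("the prior-level split contrast rank-matches extreme groups", {
  feats <- simulate_edge_features(n_subjects = 31, seed = 86)
  prior <- stats::setNames(rnorm(31), sprintf("S%02d", 1:31))
  gs <- contrast_report(feats, "prior_split",
    conditions = "near",
    prior_scores = prior
  )
  expect_equal(nrow(gs), 45)
  expect_true(all(gs$df == 8)) # groups of nine, paired by rank
  expect_error(
    contrast_report(feats, "prior_split", conditions = "near"),
    "prior_scores"
  )
})

test_that("feature-performance correlations return tidy results", {
  feats <- simulate_edge_features(n_subjects = 20, seed = 87)
  # performance equal to the feature at one edge: r = 1 there
  target <- feats[feats$unit == "LFOA-RFOA" & feats$condition == "near", ]
  perf <- stats::setNames(target$value, target$subject_id)
  cp <- correlate_performance(feats, perf, condition = "near")
  expect_equal(cp$r[cp$unit == "LFOA-RFOA"], 1, tolerance = 1e-12)
  expect_true(all(cp$n == 20))
  expect_true(all(cp$q >= cp$p, na.rm = TRUE))
})
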