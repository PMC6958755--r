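test_that("majority vote implements the reader quorum exactly", {
  dims <- c(3, 3, 3)
  # four identical masks, quorum 3 -> that mask
  m <- make_mask(dims, cbind(1:2, 1:2, 1:2))
  expect_identical(majority_vote(list(m, m, m, m), 3)$data, m$data)

  # exhaustive one-voxel truth table over all 16 vote patterns of 4 readers
  for (pattern in 0:15) {
    votes <- as.integer(intToBits(pattern))[1:4]
    masks <- lapply(votes, function(v)
      make_mask(dims, if (v == 1) cbind(2, 2, 2) else NULL))
    got <- majority_vote(masks, 3)$data[2, 2, 2]
    expect_identical(got, sum(votes) >= 3)
  }

  expect_error(majority_vote(list(m, m), 3), "quorum")

  # quorum monotonicity: lower quorum is never smaller
  set.seed(1)
  masks <- lapply(1:4, function(i)
    binary_mask(array(runif(27) < 0.5, dims)))
  for (q in 1:3) {
    lo <- majority_vote(masks, q)
    hi <- majority_vote(masks, q + 1)
    expect_true(all(lo$data[hi$data]))
  }
})

test_that("dice coefficient: worked values, symmetry, bounds", {
  dims <- c(4, 4, 4)
  a <- make_mask(dims, cbind(1:2, 1, 1))               # |A| = 2
  b <- make_mask(dims, rbind(c(2, 1, 1), c(3, 1, 1), c(4, 1, 1), c(1, 2, 1))) # |B| = 4, overlap 1
  expect_equal(dice(a, b), 2 * 1 / 6)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  disj <- make_mask(dims, cbind(1, 4, 4))
  expect_equal(dice(a, disj), 0)
  empty <- make_mask(dims)
  expect_true(is.na(dice(empty, empty)))               # undefined, not 0
  set.seed(2)
  for (i in 1:20) {
    x <- binary_mask(array(runif(64) < 0.4, dims))
    y <- binary_mask(array(runif(64) < 0.4, dims))
    d <- dice(x, y)
    if (!is.na(d)) expect_true(d >= 0 && d <= 1)
  }
})

test_that("lesion matching counts overlaps once per lesion and per prediction", {
  # identical maps: everything perfect
  m <- make_mask(c(8, 4, 4), rbind(c(1, 1, 1), c(5, 2, 2)))
  cc <- connected_components(m)
  perfect <- match_lesions(cc, cc)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$dsc, 1)

  # one predicted blob spanning two gold-standard lesions
  gs <- connected_components(
    make_mask(c(10, 3, 3), rbind(c(2, 2, 2), c(6, 2, 2))))
  pred <- connected_components(
    make_mask(c(10, 3, 3), cbind(2:6, rep(2, 5), rep(2, 5))))
  m2 <- match_lesions(pred, gs)
  expect_equal(m2$n_gs_detected, 2)
  expect_equal(m2$n_pred_correct, 1)

  # brute-force pairwise-overlap oracle on random label maps
  set.seed(3)
  for (i in 1:10) {
    p <- connected_components(binary_mask(array(runif(12^3) < 0.1, c(12, 12, 12))))
    g <- connected_components(binary_mask(array(runif(12^3) < 0.1, c(12, 12, 12))))
    got <- match_lesions(p, g)
    det <- 0
    for (gid in seq_len(n_components(g)))
      if (any(p$labels[g$labels == gid] > 0)) det <- det + 1
    cor <- 0
    for (pid in seq_len(n_components(p)))
      if (any(g$labels[p$labels == pid] > 0)) cor <- cor + 1
    expect_equal(got$n_gs_detected, det)
    expect_equal(got$n_pred_correct, cor)
  }

  # undefined ratios are NA, never silently 0
  none <- connected_components(make_mask(c(4, 4, 4)))
  some <- connected_components(make_mask(c(4, 4, 4), cbind(1, 1, 1)))
  expect_true(is.na(match_lesions(some, none)$sensitivity))
  expect_true(is.na(match_lesions(none, some)$ppv))
})

test_that("lesion matching is invariant to label permutation", {
  set.seed(4)
  p <- connected_components(binary_mask(array(runif(10^3) < 0.12, c(10, 10, 10))))
  g <- connected_components(binary_mask(array(runif(10^3) < 0.12, c(10, 10, 10))))
  base <- match_lesions(p, g)
  # permute prediction labels
  k <- n_components(p)
  perm <- sample(k)
  lp <- p$labels
  lp[p$labels > 0] <- perm[p$labels[p$labels > 0]]
  p2 <- labeled_components(lp, p$spacing, p$origin, p$direction)
  got <- match_lesions(p2, g)
  expect_equal(got$sensitivity, base$sensitivity)
  expect_equal(got$ppv, base$ppv)
  expect_equal(got$dsc, base$dsc)
})

test_that("ICC(2,1) absolute agreement matches an ANOVA oracle", {
  # perfect agreement
  x <- c(1, 2, 3, 4, 5.5)
  expect_equal(icc(x, x)$icc, 1)

  # small worked table against mean squares from aov()
  set.seed(5)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    a <- rnorm(n, 10, 2)
    b <- a + rnorm(n, 0.5, 1)
    got <- icc(a, b)
    df <- data.frame(y = c(a, b),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    want <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
    expect_equal(got$icc, want, tolerance = 1e-10)
    expect_equal(got$msr, msr, tolerance = 1e-10)
    expect_equal(got$mse, mse, tolerance = 1e-10)
  }

  # independent pairs: ICC near zero (Monte-Carlo under the null)
  set.seed(6)
  z <- icc(rnorm(200), rnorm(200))
  expect_lt(abs(z$icc), 0.15)

  # degenerate input
  expect_true(is.na(icc(rep(1, 5), rep(1, 5))$icc))
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("metric printing truncates toward zero at 3 decimals", {
  expect_equal(format_metric(4 / 6), "0.666")
  expect_equal(format_metric(1), "1.000")
  expect_equal(format_metric(NA_real_), "NA")
})
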