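test_that("clusters on a 3-participant toy match per-point t tests", {
  X <- rbind(c(1.0, 1.2, 0.9, 0.1, -1.1),
             c(0.8, 1.1, 1.0, -0.2, -0.9),
             c(1.2, 0.9, 1.1, 0.3, -1.0))
  cl <- find_clusters(X, alpha = 0.05)
  # independent oracle: stats::t.test per column
  tt <- apply(X, 2, function(col) {
    ht <- t.test(col)
    c(statistic = unname(ht$statistic), p.value = ht$p.value)
  })
  sig <- tt["p.value", ] < 0.05
  expect_equal(attr(cl, "tvals"), unname(tt["statistic", ]))
  # columns 1:3 significant positive, 4 not, 5 significant negative
  expect_equal(sig, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(1L, 5L))
  expect_equal(cl$end, c(3L, 5L))
  expect_equal(cl$sign, c(1L, -1L))
  expect_equal(cl$mass, c(sum(tt["statistic", 1:3]), tt[["statistic", 5]]))
})

test_that("degenerate inputs are handled: no clusters and zero variance", {
  X0 <- matrix(0, 5, 10)
  cl <- find_clusters(X0)
  expect_equal(nrow(cl), 0)
  expect_equal(attr(cl, "n_degenerate"), 10)
  # constant effect with tiny noise: one cluster spanning everything
  set.seed(51)
  X1 <- matrix(1 + rnorm(8 * 20, 0, 1e-3), 8, 20)
  cl1 <- find_clusters(X1)
  expect_equal(nrow(cl1), 1)
  expect_equal(c(cl1$start, cl1$end), c(1L, 20L))
})

test_that("permutation p values behave under symmetry, ties and determinism", {
  set.seed(52)
  X <- matrix(rnorm(8 * 40), 8, 40) + rep(c(2, rep(0, 39)), each = 8)
  r1 <- permutation_test(X, n_perm = 500, seed = 9)
  r2 <- permutation_test(X, n_perm = 500, seed = 9)
  expect_equal(r1$clusters$p, r2$clusters$p)
  expect_equal(r1$null_max, r2$null_max)
  # sign-flipped copy of the data gives identical p values
  r3 <- permutation_test(-X, n_perm = 500, seed = 9)
  expect_equal(r3$clusters$p, r1$clusters$p)
  # literal proportion rule: mass above every permuted max reports "< 1/n"
  strong <- matrix(5 + rnorm(8 * 40, 0, 0.1), 8, 40)
  r4 <- permutation_test(strong, n_perm = 200, seed = 1)
  big <- which.max(abs(r4$clusters$mass))
  if (r4$clusters$p[big] == 0)
    expect_match(r4$clusters$p_label[big], "< 0.005")
  expect_warning(permutation_test(X, n_perm = 50, seed = 1), "100")
})

test_that("exhaustive enumeration at n = 4 matches an independent enumeration and Monte Carlo", {
  set.seed(53)
  X <- matrix(rnorm(4 * 12), 4, 12) + rep(c(rep(1.2, 4), rep(0, 8)),
                                          each = 4)
  ex <- permutation_test(X, exhaustive = TRUE)
  expect_equal(ex$n_perm, 16)
  # independent enumeration of all 16 sign patterns
  crit <- qt(0.975, 3)
  null_max <- numeric(0)
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1))
    for (s4 in c(-1, 1)) {
      Xs <- X * c(s1, s2, s3, s4)
      tv <- apply(Xs, 2, function(col) mean(col) / (sd(col) / 2))
      sig <- abs(tv) > crit
      best <- 0
      i <- 1
      while (i <= length(tv)) {
        if (sig[i]) {
          j <- i
          while (j < length(tv) && sig[j + 1] &&
                 sign(tv[j + 1]) == sign(tv[i])) j <- j + 1
          best <- max(best, abs(sum(tv[i:j])))
          i <- j + 1
        } else i <- i + 1
      }
      null_max <- c(null_max, best)
    }
  expect_equal(sort(ex$null_max), sort(null_max))
  for (k in seq_len(nrow(ex$clusters)))
    expect_equal(ex$clusters$p[k],
                 mean(null_max >= abs(ex$clusters$mass[k])))
  # Monte-Carlo estimate agrees within Monte-Carlo error
  mc <- permutation_test(X, n_perm = 4000, seed = 3)
  p_ex <- min_cluster_p(ex)
  p_mc <- min_cluster_p(mc)
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 4000) + 1e-3)
})

test_that("stronger planted effects do not get larger cluster p values", {
  set.seed(54)
  worse <- 0
  for (s in 1:20) {
    base <- matrix(rnorm(10 * 60), 10, 60)
    bump <- rep(c(rep(0, 20), rep(1, 10), rep(0, 30)), each = 10)
    p_small <- min_cluster_p(permutation_test(base + 0.5 * bump,
                                              n_perm = 300, seed = s))
    p_large <- min_cluster_p(permutation_test(base + 1.5 * bump,
                                              n_perm = 300, seed = s))
    worse <- worse + (p_large > p_small)
  }
  expect_lte(worse, 3)  # monotone on average over seeds
})

test_that("2D maps cluster with 4-connectivity and respect sign", {
  tmpl <- matrix(0, 6, 8)
  tmpl[2:3, 2:3] <- 1         # positive blob
  tmpl[5, 6:8] <- -1          # negative run, diagonal-separated from blob
  tmpl[1, 8] <- 1             # isolated corner cell
  set.seed(55)
  # noise only on active cells; null cells have zero variance and are
  # deterministically non-significant
  noise <- array(rnorm(12 * 6 * 8, 0, 0.2), c(12, 6, 8)) *
    rep(abs(tmpl), each = 12)
  X <- array(rep(tmpl, each = 12) * 2, c(12, 6, 8)) + noise
  cl <- find_clusters(X)
  expect_equal(nrow(cl), 3)
  expect_equal(sort(cl$n_points), c(1L, 3L, 4L))
  expect_equal(cl$sign[order(cl$n_points)], c(1L, -1L, 1L))
  r <- permutation_test(X, n_perm = 200, seed = 2)
  expect_true(all(r$clusters$p >= 0 & r$clusters$p <= 1))
  expect_lt(min_cluster_p(r), 0.05)
})
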