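test_that("taper weights are symmetric, normalized, and match a brute-force convolution", {
  w <- build_taper(20, 3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_gt(w[10], w[1])

  # independent direct-summation convolution oracle
  half <- ceiling(3 * 3)
  g <- exp(-(-half:half)^2 / (2 * 3^2))
  g <- g / sum(g)
  rect <- rep(1, 20)
  full <- sapply(seq_len(20 + 2 * half), function(m) {
    acc <- 0
    for (j in seq_along(g)) {
      ri <- m - (j - 1)
      if (ri >= 1 && ri <= 20) acc <- acc + g[j] * rect[ri]
    }
    acc
  })
  oracle <- full[(half + 1):(half + 20)]
  oracle <- oracle / sum(oracle)
  expect_equal(w, oracle, tolerance = 1e-12)
  expect_equal(w[10] / w[1], oracle[10] / oracle[1], tolerance = 1e-12)
})

test_that("taper tends to uniform weights as sigma -> 0", {
  w <- build_taper(20, 1e-6)
  expect_lt(max(abs(w - 1 / 20)), 1e-9)
})

test_that("window count follows floor((T - width)/step) + 1 for all geometries", {
  set.seed(42)
  for (i in 1:20) {
    width <- sample(2:30, 1)
    t_len <- width + sample(0:200, 1)
    step <- sample(1:5, 1)
    ts <- matrix(rnorm(t_len * 3), t_len, 3)
    res <- windowed_fnc(ts, window_spec(width, 3, step))
    expect_equal(dim(res$z)[3], floor((t_len - width) / step) + 1)
  }
  # T = width: exactly one window
  ts <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(dim(windowed_fnc(ts, window_spec(20, 3, 1))$z)[3], 1)
  # the reference geometry: 234 volumes, width 20, step 1
  ts <- matrix(rnorm(234 * 2), 234, 2)
  expect_equal(dim(windowed_fnc(ts, window_spec(20, 3, 1))$z)[3], 215)
})

test_that("windowed correlations average to the full-series correlation when stationary", {
  set.seed(1)
  t_len <- 5000
  r_true <- 0.5
  l <- chol(matrix(c(1, r_true, r_true, 1), 2))
  x <- matrix(rnorm(t_len * 2), t_len, 2) %*% l
  res <- windowed_fnc(x, window_spec(40, 1e-6, 10))  # near-uniform taper
  mean_r <- mean(tanh(res$z[2, 1, ]))
  expect_lt(abs(mean_r - cor(x)[1, 2]), 0.03)
})

test_that("constant channel inside a window warns and zeroes its pairs", {
  ts <- cbind(a = rnorm(30), b = c(rep(1, 25), rnorm(5)))
  expect_warning(res <- windowed_fnc(ts, window_spec(20, 3, 1)), "constant")
  expect_equal(res$z[1, 2, 1], 0)
})

test_that("k-means separates well-separated clouds exactly and honors duplication", {
  set.seed(7)
  x <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
             matrix(rnorm(200, 10, 0.1), 100, 2))
  truth <- rep(1:2, each = 100)
  sm <- cluster_states(x, k = 2, n_restarts = 5, seed = 3)
  expect_equal(ari(sm$assignments$state, truth), 1)

  # duplicating every window: identical centroids, doubled sizes
  sm2 <- cluster_states(rbind(x, x), k = 2, n_restarts = 5, seed = 3)
  expect_equal(sort(sm2$centroids[, 1]), sort(sm$centroids[, 1]),
               tolerance = 1e-8)
  expect_equal(2 * tabulate(sm$assignments$state),
               tabulate(sm2$assignments$state))

  # k = 1: centroid is the pooled per-coordinate center
  sm1 <- cluster_states(x, k = 1, distance = "euclidean", n_restarts = 2,
                        seed = 3)
  expect_equal(as.numeric(sm1$centroids), colMeans(x), tolerance = 1e-10)
})

test_that("k-means with squared-Euclidean metric matches stats::kmeans on separated data", {
  set.seed(8)
  x <- rbind(matrix(rnorm(120, 0, 0.2), 60, 2),
             matrix(rnorm(120, 5, 0.2), 60, 2),
             matrix(rnorm(120, -5, 0.2), 60, 2))
  sm <- cluster_states(x, k = 3, distance = "euclidean", n_restarts = 5,
                       seed = 1)
  km <- stats::kmeans(x, centers = 3, nstart = 5)
  expect_equal(ari(sm$assignments$state, km$cluster), 1)
  expect_equal(sm$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("cluster objective is a fixpoint: centroids equal their cluster centers", {
  set.seed(9)
  x <- matrix(rnorm(300), 100, 3)
  for (metric in c("euclidean", "cityblock")) {
    sm <- cluster_states(x, k = 4, distance = metric, n_restarts = 3, seed = 5)
    a <- sm$assignments$state
    for (j in 1:4) {
      rows <- which(a == j)
      if (!length(rows)) next
      expected <- if (metric == "euclidean") {
        colMeans(x[rows, , drop = FALSE])
      } else {
        apply(x[rows, , drop = FALSE], 2, median)
      }
      expect_equal(as.numeric(sm$centroids[j, ]), as.numeric(expected),
                   tolerance = 1e-8)
    }
  }
})

test_that("state labels are ordered by pooled occurrence", {
  set.seed(10)
  x <- rbind(matrix(rnorm(300, 0, 0.1), 150, 2),
             matrix(rnorm(60, 8, 0.1), 30, 2))
  sm <- cluster_states(x, k = 2, n_restarts = 3, seed = 2)
  counts <- tabulate(sm$assignments$state)
  expect_true(all(diff(counts) <= 0))
})

test_that("state_metrics reproduces hand-enumerated run structure", {
  m <- state_metrics(c(1, 1, 2, 2, 2), 2)
  expect_equal(m$fraction_time, c(0.4, 0.6))
  expect_equal(m$mean_dwell_time, c(2, 3))
  expect_equal(m$n_transitions, 1)

  const <- state_metrics(rep(2, 7), 3)
  expect_equal(const$fraction_time, c(0, 1, 0))
  expect_equal(const$mean_dwell_time, c(NA, 7, NA))
  expect_equal(const$n_transitions, 0)

  alt <- state_metrics(c(1, 2, 1, 2), 2)
  expect_equal(alt$n_transitions, 3)
  expect_equal(alt$mean_dwell_time, c(1, 1))

  expect_error(state_metrics(integer(0), 2), "empty")
  expect_error(state_metrics(c(1, 5), 2), "1..k")
})

test_that("dfnc variability matches closed forms and correlation invariances", {
  # identical windows: zero variability matrix
  zm <- fisher_z(matrix(c(1, 0.4, 0.4, 1), 2)); diag(zm) <- 0
  fake <- structure(list(
    z = list(S1 = array(rep(zm, 5), c(2, 2, 5))),
    channels = tibble::tibble(channel = c("a", "b"), network = c("x", "x"))),
    class = "dfnc_result")
  expect_equal(dfnc_variability(fake)$sd[[1]], matrix(0, 2, 2))

  ch <- tiny_cohort(n = 1, t_len = 50, seed = 1)
  dk <- dfnc(ch$panel, window_spec(20, 3, 1))
  v <- dfnc_variability(dk)
  expect_true(all(tidy(v)$sd_r >= 0))
  expect_equal(diag(v$sd[[1]]), rep(0, 13))

  # alternating +-0.5 two-point sequence: SD = 0.5*sqrt(W/(W-1))
  w_count <- 10
  r_seq <- rep(c(0.5, -0.5), w_count / 2)
  expect_equal(sd(r_seq), 0.5 * sqrt(w_count / (w_count - 1)))

  # scaling a channel leaves windowed correlations, hence variability, unchanged
  x <- ch$panel$series[[1]]
  x2 <- x
  x2[, 1] <- 3.7 * x2[, 1]
  p2 <- ts_panel(list(S001 = x2), ch$panel$channels,
                 ch$panel$manifest[1, ], tr = 2)
  v2 <- dfnc_variability(dfnc(p2, window_spec(20, 3, 1)))
  expect_equal(v2$sd[[1]], v$sd[[1]], tolerance = 1e-10)
})

test_that("true_window_states uses taper-mass majority", {
  spec <- window_spec(4, 1e-6)  # uniform taper
  s <- c(1, 1, 1, 2, 2, 2)
  # windows: 1112 -> 1, 1122 -> tie -> smaller label 1, 1222 -> 2
  expect_equal(true_window_states(s, spec), c(1, 1, 2))
})
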