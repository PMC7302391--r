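test_that("EM recovers the generating two-component mixture", {
  set.seed(17)
  n <- 10000
  z <- rbinom(n, 1, 0.5) + 1
  x <- rnorm(n, c(0.2, 0.8)[z], sqrt(0.01))
  theta <- fit_gmm_em(x, K = 2, seed = 1)
  expect_lt(max(abs(theta$means - c(0.2, 0.8))), 0.02)
  expect_lt(max(abs(theta$weights - c(0.5, 0.5))), 0.05)
  expect_lt(max(abs(theta$variances - 0.01)), 0.005)
})

test_that("K = 1 EM reproduces the sample moments exactly", {
  set.seed(6)
  x <- rnorm(500, 3, 2)
  theta <- fit_gmm_em(x, K = 1, seed = 1)
  expect_equal(theta$means, mean(x), tolerance = 1e-10)
  expect_equal(theta$variances, mean((x - mean(x))^2), tolerance = 1e-8)
  expect_equal(theta$weights, 1)
})

test_that("EM log-likelihood is non-decreasing on assorted inputs", {
  set.seed(25)
  for (r in 1:5) {
    x <- c(rnorm(300, 0.3, 0.05), rnorm(200, 0.6, 0.1), runif(100))
    theta <- fit_gmm_em(x, K = 3, seed = r)
    tr <- attr(theta, "loglik_trace")
    expect_true(all(diff(tr) >= -1e-8))
    expect_true(all(diff(theta$means) >= 0))  # sorted by mean
  }
})

test_that("EM on hard two-valued data reproduces the group moments", {
  x <- rep(c(0.2, 0.7), times = c(300, 200))
  x <- x + rep(c(-0.001, 0.001), length.out = 500)  # break exact ties
  theta <- fit_gmm_em(x, K = 2, seed = 2)
  expect_equal(theta$means[1], mean(x[x < 0.5]), tolerance = 1e-3)
  expect_equal(theta$means[2], mean(x[x > 0.5]), tolerance = 1e-3)
  expect_equal(theta$weights, c(0.6, 0.4), tolerance = 1e-3)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(33)
  x <- c(rnorm(2000, 0.25, 0.04), rnorm(1200, 0.5, 0.06),
         rnorm(800, 0.85, 0.03))
  theta <- fit_gmm_em(x, K = 3, seed = 5)
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(theta$means, as.numeric(sort(mc$parameters$mean)),
               tolerance = 0.02)
  expect_gt(theta$loglik, mc$loglik - 1)  # same optimum to within slack
})

test_that("posteriors are symmetric at the midpoint and sum to one", {
  theta <- gmm_params(c(0.5, 0.5), c(0.2, 0.8), c(0.01, 0.01))
  img <- intensity_image(matrix(c(0.5, 0.2, 0.35, 0.65, 0.8, 0.5, 0.5, 0.5,
                                  0.5), 3))
  post <- posterior_map(img, theta)
  expect_equal(post[1, 1, ], c(0.5, 0.5))
  sums <- apply(post, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a pixel at one mean far from the other is classified surely", {
  theta <- gmm_params(c(0.5, 0.5), c(0.2, 0.2 + 10 * 0.03), c(0.03^2, 0.03^2))
  img <- intensity_image(matrix(0.2, 3, 3))
  post <- posterior_map(img, theta)
  expect_gt(post[1, 1, 1], 0.999)
})

test_that("stopping map is the absolute posterior difference", {
  theta <- gmm_params(c(1, 1, 1) / 3, c(0.2, 0.5, 0.8),
                      c(0.01, 0.01, 0.01))
  img <- intensity_image(matrix(c(0.35, 0.5, 0.2, rep(0.5, 6)), 3))
  post <- posterior_map(img, theta)
  S <- stopping_map(post, nodule_k = 2, background_k = 1)
  expect_equal(unclass(S)[1, 1], abs(post[1, 1, 2] - post[1, 1, 1]))
  expect_true(all(S >= 0 & S <= 1))
  # midpoint of components 1 and 2 -> equal posteriors -> S = 0
  expect_lt(S[1, 1], 1e-6)
  expect_error(stopping_map(post, 2, 2), "distinct")
  expect_error(stopping_map(post, 4, 1), "distinct|<=")
})

test_that("stopping map ignores permutation of unselected components", {
  theta <- gmm_params(c(0.3, 0.4, 0.3), c(0.2, 0.5, 0.8),
                      c(0.01, 0.02, 0.01))
  set.seed(3)
  img <- intensity_image(matrix(runif(25), 5))
  S12 <- stopping_map(posterior_map(img, theta), 1, 2)
  S21 <- stopping_map(posterior_map(img, theta), 2, 1)
  expect_equal(unclass(S12), unclass(S21), ignore_attr = TRUE)
})

test_that("the stopping-map minimum localises a sigmoid-blurred edge", {
  # two-region image with a sigmoid transition: the minimum of S along a
  # transect must sit within 1 px of the 50%-intensity crossing. K = 3
  # (the method's default) gives the transition band its own component;
  # with K = 2 the transition pixels skew one component's variance and
  # bias the equal-posterior locus away from the edge.
  set.seed(44)
  N <- 64
  errs <- numeric(10)
  for (r in 1:10) {
    edge_col <- runif(1, 25, 40)
    width <- runif(1, 1, 3)
    jj <- matrix(seq_len(N), N, N, byrow = TRUE)
    px <- 0.25 + 0.3 / (1 + exp(-(jj - edge_col) / width))
    px <- px + rnorm(N * N, 0, 0.01)
    img <- intensity_image(pmin(pmax(px, 0), 1))
    theta <- fit_gmm_em(img, K = 3, seed = r)
    S <- stopping_map(posterior_map(img, theta), nodule_k = 3,
                      background_k = 1)
    transect <- unclass(S)[N / 2, ]
    errs[r] <- abs(which.min(transect) - edge_col)
  }
  expect_true(all(errs <= 1))
})
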