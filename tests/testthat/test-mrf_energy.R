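two_region_labels <- function(M = 8, N = 8) {
  lab <- matrix(1L, M, N)
  lab[, (N / 2 + 1):N] <- 2L
  label_field(lab, 2L)
}

test_that("moment class statistics are the per-class mean and population sd", {
  img <- intensity_image(matrix(c(0.2, 0.4, 0.6, 0.8, 0.5, 0.5, 0.5, 0.5,
                                  0.5), 3))
  lab <- label_field(matrix(c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L, 1L), 3), 2L)
  st <- estimate_class_stats(img, lab, method = "moment")
  expect_equal(st$means[2], 0.7)
  expect_equal(st$sds[2], 0.1)
  expect_equal(st$means[1], mean(c(0.2, 0.4, rep(0.5, 5))))
})

test_that("a class with too few pixels is a degeneracy error", {
  img <- intensity_image(matrix(runif(9), 3))
  lab <- label_field(matrix(c(2L, rep(1L, 8)), 3), 2L)
  expect_error(estimate_class_stats(img, lab), "at least 2 pixels")
})

test_that("EM class statistics recover a generating two-class mixture", {
  set.seed(21)
  n <- 10000
  truth_lab <- rbinom(n, 1, 0.3) + 1L
  x <- rnorm(n, mean = c(0.3, 0.7)[truth_lab], sd = 0.05)
  m <- matrix(x, 100)
  # start from a deliberately noisy labelling (10% flipped)
  flip <- as.logical(rbinom(n, 1, 0.1))
  lab0 <- ifelse(flip, 3L - truth_lab, truth_lab)
  st <- estimate_class_stats(intensity_image(m),
                             label_field(matrix(lab0, 100), 2L),
                             method = "em")
  expect_lt(abs(st$means[1] - 0.3), 0.01)
  expect_lt(abs(st$means[2] - 0.7), 0.01)
  expect_lt(abs(st$sds[1] - 0.05), 0.01)
})

test_that("Potts energy matches hand-counted neighbour cases", {
  lab <- matrix(1L, 5, 5)
  lab[3, 3] <- 2L          # interior pixel, all 8 neighbours differ
  lf <- label_field(lab, 2L)
  u <- potts_energy(lf, mrf_config(beta = 0.5))$energy
  expect_equal(u[3, 3], 4.0)
  lab2 <- matrix(1L, 5, 5); lab2[1, 1] <- 2L  # corner: 3 neighbours differ
  expect_equal(potts_energy(label_field(lab2, 2L),
                            mrf_config(beta = 0.5))$energy[1, 1], 1.5)
  const <- label_field(matrix(1L, 5, 5), 2L)
  expect_true(all(potts_energy(const)$energy == 0))  # equal-label case
})

test_that("Potts energy equals the brute-force neighbour count oracle", {
  set.seed(4)
  for (nb in c(4L, 8L)) {
    lab <- matrix(sample(1:2, 48, replace = TRUE), 6)
    u <- potts_energy(label_field(lab, 2L),
                      mrf_config(beta = 0.5, neighbourhood = nb))$energy
    expect_equal(u, bf_potts(lab, 0.5, nb))
  }
})

test_that("feature energy matches its closed form", {
  st <- class_stats(c(0.5, 0), c(0.1, 1))
  img <- intensity_image(matrix(c(0, 1, 0.9, rep(0, 6)), 3))
  lab <- label_field(matrix(c(2L, 2L, 1L, rep(2L, 6)), 3), 2L)
  u <- feature_energy(img, lab, st)$energy
  expect_equal(u[1, 1], log(sqrt(2 * pi)))          # y = mu, sigma = 1
  expect_equal(u[2, 1], log(sqrt(2 * pi)) + 0.5)    # y = mu + sigma
  expect_equal(u[3, 1], log(sqrt(2 * pi) * 0.1) + 8.0)
})

test_that("assigned-mode energy with no ICM is feature + Potts elementwise", {
  set.seed(9)
  px <- matrix(runif(64), 8)
  lab <- two_region_labels()
  st <- class_stats(c(0.3, 0.7), c(0.1, 0.1))
  u <- mrf_energy_map(intensity_image(px), lab, st, mrf_config(),
                      icm_passes = 0L, normalize = FALSE,
                      assembly = "assigned")$energy
  expect_equal(u, feature_energy(px, lab, st)$energy +
                 potts_energy(lab)$energy)
})

test_that("Potts energy of a correct two-region labelling is confined to the boundary band", {
  px <- matrix(0.3, 8, 8); px[, 5:8] <- 0.7
  lab <- two_region_labels()
  st <- class_stats(c(0.3, 0.7), c(0.05, 0.05))
  u <- mrf_energy_map(intensity_image(px), lab, st, mrf_config(),
                      icm_passes = 1L, normalize = FALSE,
                      assembly = "assigned")$energy
  pot <- u - feature_energy(px, lab, st)$energy
  expect_true(all(pot[, c(1:3, 6:8)] == 0))
  expect_true(all(pot[, 4:5] > 0))
})

test_that("ICM sweeps never increase the joint labelling energy", {
  set.seed(31)
  for (r in 1:5) {
    px <- matrix(runif(100), 10)
    lab <- label_field(matrix(sample(1:2, 100, replace = TRUE), 10), 2L)
    st <- class_stats(c(0.25, 0.75), c(0.15, 0.15))
    em <- mrf_energy_map(intensity_image(px), lab, st, icm_passes = 3L)
    tr <- attr(em, "energy_trace")
    expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("normalized energy maps span [0, 1]", {
  set.seed(2)
  px <- matrix(runif(64), 8)
  lab <- two_region_labels()
  st <- class_stats(c(0.3, 0.7), c(0.1, 0.1))
  u <- mrf_energy_map(intensity_image(px), lab, st)$energy
  expect_equal(range(u), c(0, 1))
})

test_that("assigned-mode energy is invariant to a 1<->2 relabelling swap", {
  set.seed(13)
  px <- matrix(runif(64), 8)
  lab <- two_region_labels()
  swapped <- label_field(3L - lab$labels, 2L)
  st <- class_stats(c(0.3, 0.7), c(0.1, 0.12))
  st_sw <- class_stats(rev(st$means), rev(st$sds))
  a <- mrf_energy_map(px, lab, st, icm_passes = 1L, normalize = FALSE,
                      assembly = "assigned")$energy
  b <- mrf_energy_map(px, swapped, st_sw, icm_passes = 1L,
                      normalize = FALSE, assembly = "assigned")$energy
  expect_equal(a, b)
})

test_that("the energy map separates nodule from background more than raw intensity", {
  # the contrast-enhancement mechanism: on inhomogeneous low-contrast
  # phantoms the min-max-normalized energy map shows a larger
  # nodule-vs-background mean difference than the equally normalized image
  wins <- 0L
  for (s in 1:20) {
    ph <- make_phantom(phantom_spec(scenario = "inhomogeneous",
                                    seed = 3000 + s))
    norm <- normalize_image(ph$image)
    l2 <- reduce_to_two_classes(kmeans_presegment(norm, 3, seed = 42), norm)
    st <- estimate_class_stats(norm, l2)
    u <- mrf_energy_map(norm, l2, st)$energy
    tr <- unclass(ph$mask) == 1
    c_energy <- abs(mean(u[tr]) - mean(u[!tr]))
    c_img <- abs(mean(norm$pixels[tr]) - mean(norm$pixels[!tr]))
    if (c_energy > c_img) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
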