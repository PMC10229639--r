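test_that("nearest-neighbour distances match simple constructions and a brute-force oracle", {
  pts <- data.frame(x_nm = c(0, 100, 250), y_nm = c(0, 0, 0))
  expect_equal(nearest_neighbor_distances(pts), c(100, 100, 150))

  two <- data.frame(x_nm = c(0, 30), y_nm = c(0, 40))
  expect_equal(nearest_neighbor_distances(two), c(50, 50))

  set.seed(71)
  n <- 600
  rnd <- data.frame(x_nm = runif(n, 0, 3000), y_nm = runif(n, 0, 3000))
  d <- nearest_neighbor_distances(rnd)
  dm <- as.matrix(dist(rnd))
  diag(dm) <- Inf
  expect_equal(d, unname(apply(dm, 1, min)), tolerance = 1e-12)

  dup <- data.frame(x_nm = c(0, 0, 10), y_nm = c(0, 0, 0))
  expect_warning(dd <- nearest_neighbor_distances(dup), "coincident")
  expect_equal(dd[1], 0)
})

test_that("Poisson point fields give the closed-form mean spacing", {
  set.seed(72)
  n <- 1e4
  L <- 10000  # nm; lambda = n / L^2
  pts <- data.frame(x_nm = runif(n, 0, L), y_nm = runif(n, 0, L))
  d <- nearest_neighbor_distances(pts)
  expect_equal(mean(d), 0.5 / sqrt(n / L^2), tolerance = 0.05)
})

test_that("the Gaussian histogram fit recovers the spacing distribution centre", {
  set.seed(73)
  d <- rnorm(5000, 119, 25)
  fit <- fit_nn_center(d)
  expect_false(fit$fallback)
  expect_equal(fit$center, 119, tolerance = 2 / 119)
  expect_equal(fit$sd, 25, tolerance = 0.1)
  # symmetric input: centre agrees with the sample mean to within a bin
  expect_lte(abs(fit$center - mean(d)), fit$bin_width)
  # near-constant distances centre on that constant
  fit2 <- fit_nn_center(rnorm(200, 50, 1e-3), bin_width = 0.001)
  expect_equal(fit2$center, 50, tolerance = 1e-3)
  expect_error(fit_nn_center(rnorm(10)), "at least 50")
})

test_that("accessible filament length follows the chord geometry", {
  expect_equal(accessible_length(1500, 20), 2 * sqrt(2 * 1500 * 20 - 400))
  expect_equal(accessible_length(1500, 20), 488.26, tolerance = 1e-4)
  # monotone in radius and reach
  expect_gt(accessible_length(2000, 20), accessible_length(1500, 20))
  expect_gt(accessible_length(1500, 30), accessible_length(1500, 20))
  # vanishing reach: vanishing length
  expect_lt(accessible_length(1500, 1e-9), 1e-2)
  expect_error(accessible_length(1500, 1500), "smaller")
  expect_error(accessible_length(1500, 0), "positive")
})

test_that("heads-in-reach combines spacing and chord length", {
  hr <- heads_in_reach(119)
  expect_equal(hr$accessible_length_nm, 488.26, tolerance = 1e-4)
  expect_equal(hr$heads_in_reach, 488.26 / 119, tolerance = 1e-4)
  expect_gte(hr$heads_in_reach, 4)
  expect_lte(hr$heads_in_reach, 5)
})

test_that("localization CSV reader validates its columns", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm", "0,0", "100,50"), p)
  df <- read_localizations(p)
  expect_equal(nrow(df), 2)
  writeLines(c("a,b", "0,0"), p)
  expect_error(read_localizations(p), "x_nm")
  unlink(p)
})
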