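test_that("density2d normalizes histogram mass and handles corner cases", {
  pts <- rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.1, 0.9), c(0.9, 0.9))
  d <- density2d(pts, bins = 2, range = list(x = c(0, 1), y = c(0, 1)))
  expect_equal(as.numeric(d$mass), rep(0.25, 4))
  one <- density2d(matrix(c(0.5, 0.5), 1), bins = 3,
                   range = list(x = c(0, 1), y = c(0, 1)))
  expect_equal(sum(one$mass), 1)
  expect_equal(max(one$mass), 1)
  expect_error(density2d(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("density of a seeded 2D Gaussian has unit mass and its mode at the mean", {
  set.seed(31)
  pts <- cbind(rnorm(1e4, mean = 2, sd = 0.5), rnorm(1e4, mean = -1, sd = 0.5))
  d <- density2d(pts, bins = 25)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  mode_bin <- which(d$mass == max(d$mass), arr.ind = TRUE)[1, ]
  cx <- conjmap:::.bin_centers(d$x_edges)[mode_bin[1]]
  cy <- conjmap:::.bin_centers(d$y_edges)[mode_bin[2]]
  bw <- c(diff(d$x_edges[1:2]), diff(d$y_edges[1:2]))
  expect_lt(abs(cx - 2), 1.5 * bw[1])
  expect_lt(abs(cy + 1), 1.5 * bw[2])
})

test_that("density normalization is preserved under grid refinement", {
  set.seed(7)
  pts <- matrix(rnorm(600), ncol = 2)
  for (b in c(10, 40, 160))
    expect_equal(sum(density2d(pts, bins = b)$mass), 1, tolerance = 1e-12)
})

test_that("Boltzmann inversion: equal masses level, ln identity, kT at 300 K", {
  d <- density2d(rbind(c(0.25, 0.5), c(0.75, 0.5)), bins = 2,
                 range = list(x = c(0, 1), y = c(0, 1)))
  f <- free_energy_surface(d, 300)
  vals <- f$energy_kt[f$mask]
  expect_equal(vals, c(0, 0))
  # masses in ratio e give exactly 1 kT
  n_hi <- 2718; n_lo <- 1000
  pts <- rbind(matrix(rep(c(0.25, 0.5), n_hi), ncol = 2, byrow = TRUE),
               matrix(rep(c(0.75, 0.5), n_lo), ncol = 2, byrow = TRUE))
  f2 <- free_energy_surface(density2d(pts, bins = 2,
                                      range = list(x = c(0, 1), y = c(0, 1))))
  dd <- max(f2$energy_kt[f2$mask]) - min(f2$energy_kt[f2$mask])
  expect_equal(dd, log(n_hi / n_lo), tolerance = 1e-12)
  # kT = 0.0083145 * 300 = 2.494 kJ/mol scales the kJ/mol grid
  expect_equal(f2$kT_kjmol, 2.49435, tolerance = 1e-6)
  expect_equal(max(f2$energy_kjmol[f2$mask]),
               log(n_hi / n_lo) * 0.0083145 * 300, tolerance = 1e-12)
})

test_that("a single-basin paraboloid FES has exactly one minimum at the bottom", {
  set.seed(12)
  pts <- matrix(rnorm(4000, sd = 0.6), ncol = 2)
  fes <- free_energy_surface(density2d(pts, bins = 15))
  mins <- find_minima(fes, k = 5)
  expect_true(attr(mins, "fewer_than_requested"))
  expect_equal(mins$depth_kt[1], 0)
  main <- which(fes$energy_kt == 0, arr.ind = TRUE)
  expect_equal(unname(c(mins$ix[1], mins$iy[1])), unname(main[1, ]))
})

test_that("a 3-component mixture yields 3 minima at the mode bins (brute-force checked)", {
  set.seed(9)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(2 * c(3000, 2000, 1000)[i], sd = 0.4), ncol = 2),
          2, centers[i, ], "+")))
  fes <- free_energy_surface(density2d(pts, bins = 40))
  mins <- find_minima(fes, k = 5, min_count = 5)
  # brute-force enumeration over all populated bins
  E <- fes$energy_kt; E[!(fes$mask & fes$counts >= 5)] <- NA
  nx <- nrow(E); ny <- ncol(E)
  brute <- 0
  for (i in 1:nx) for (j in 1:ny) {
    if (is.na(E[i, j])) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny && !is.na(E[ii, jj]))
        nb <- c(nb, E[ii, jj])
    }
    if (!length(nb) || E[i, j] < min(nb)) brute <- brute + 1
  }
  expect_equal(nrow(mins), 3)
  expect_equal(brute, 3)
  # minima sit near the mixture centers
  got <- mins[order(mins$depth_kt), c("x", "y")]
  expect_lt(min(sqrt(rowSums(sweep(as.matrix(got), 2, centers[1, ])^2))), 1)
})

test_that("find_minima flags shortfalls, rejects bad k and ignores constant shifts", {
  ens <- two_basin_ensemble(n_frames = 800, seed = 2)
  rmd <- rmd_series(ens$trajectory)
  lm <- select_landmarks(rmd, 50, gamma = 0.1, seed = 1)
  model <- fit_sketchmap(lm, sigmoid_params(sigma = 2), seed = 1,
                         n_restarts = 0)
  proj <- sketchmap_project(rmd, model)
  fes <- free_energy_surface(density2d(proj, bins = 25))
  expect_error(find_minima(fes, k = 0), "k must be")
  m5 <- find_minima(fes, k = 5)
  expect_equal(nrow(m5), 2)
  expect_true(attr(m5, "fewer_than_requested"))
  shifted <- fes
  shifted$energy_kt <- shifted$energy_kt + 3.3
  shifted$energy_kjmol <- shifted$energy_kjmol + 3.3 * fes$kT_kjmol
  ms <- find_minima(shifted, k = 5)
  expect_equal(ms[, c("x", "y", "depth_kt")], m5[, c("x", "y", "depth_kt")])
})

test_that("basin-frame selection is seeded, honours radius and falls back to the nearest frame", {
  ens <- two_basin_ensemble(n_frames = 600, seed = 8)
  rmd <- rmd_series(ens$trajectory)
  lm <- select_landmarks(rmd, 50, gamma = 0.1, seed = 1)
  model <- fit_sketchmap(lm, sigmoid_params(sigma = 2), seed = 1,
                         n_restarts = 0)
  proj <- sketchmap_project(rmd, model)
  fes <- free_energy_surface(density2d(proj, bins = 25))
  g1 <- select_basin_frames(fes, proj, n_minima = 2, n_random = 10,
                            radius = Inf, seed = 5)
  g2 <- select_basin_frames(fes, proj, n_minima = 2, n_random = 10,
                            radius = Inf, seed = 5)
  expect_identical(g1, g2)
  g0 <- select_basin_frames(fes, proj, n_minima = 2, n_random = 0,
                            radius = Inf, seed = 5)
  expect_true(all(vapply(g0, function(g) length(g$random) == 0, TRUE)))
  # representatives are the frames nearest each minimum
  mins <- find_minima(fes, k = 2)
  d1 <- sqrt((proj[, 1] - mins$x[1])^2 + (proj[, 2] - mins$y[1])^2)
  expect_equal(g0[[1]]$representative, which.min(d1))
  expect_warning(
    select_basin_frames(fes, proj, n_minima = 1, n_random = 5,
                        radius = 1e-9, seed = 1),
    "no frames within")
})

test_that("two-basin occupancies are recovered as a depth difference of -kT ln((1-q)/q)", {
  ens <- two_basin_ensemble(n_frames = 4000, seed = 17, noise_sd = 0.03)
  rmd <- rmd_series(ens$trajectory)
  lm <- select_landmarks(rmd, 60, gamma = 0.1, seed = 3)
  model <- fit_sketchmap(lm, sigmoid_params(sigma = 2), seed = 1,
                         n_restarts = 0)
  proj <- sketchmap_project(rmd, model)
  # bins chosen so one bin comfortably contains a whole basin blob: the
  # depth difference then measures the occupancy ratio, not basin shape
  fes <- free_energy_surface(density2d(proj, bins = 14))
  mins <- find_minima(fes, k = 2)
  n1 <- sum(ens$labels == 1); n2 <- sum(ens$labels == 2)
  expected <- log(n1 / n2)
  se <- sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(mins$depth_kt[2] - expected), 3 * se + 1e-9)
})
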