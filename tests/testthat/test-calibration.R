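test_that("model-complex calibration matches closed-form least squares", {
  pts <- ttb_model_complexes(subset = 2:6)
  # independent closed-form route
  x <- pts$rho100
  y <- pts$dE
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope_cf <- sxy / sxx
  int_cf <- mean(y) - slope_cf * mean(x)
  r_cf <- sxy / sqrt(sxx * sum((y - mean(y))^2))

  m <- fit_calibration(pts)
  expect_equal(m$slope, slope_cf, tolerance = 1e-12)
  expect_equal(m$intercept, int_cf, tolerance = 1e-12)
  expect_equal(m$pearson_r, r_cf, tolerance = 1e-12)
  expect_equal(m$n_points, 5L)
  expect_lt(m$slope, 0)          # denser contact binds more strongly
  expect_gt(abs(m$pearson_r), 0.9)
  expect_lte(abs(m$pearson_r), 1)
})

test_that("two points give an exact line and degenerate inputs error", {
  two <- data.frame(rho100 = c(0.5, 1.0), dE = c(-1.0, -3.0))
  expect_error(fit_calibration(two), "at least 3")
  three <- rbind(two, data.frame(rho100 = 0.75, dE = -2.0))  # exactly colinear
  m <- fit_calibration(three)
  expect_equal(abs(m$pearson_r), 1, tolerance = 1e-12)
  expect_equal(m$slope * 0.5 + m$intercept, -1.0, tolerance = 1e-12)

  same <- data.frame(rho100 = rep(0.7, 5), dE = c(-1, -2, -1.5, -1.2, -1.8))
  expect_error(fit_calibration(same), "degenerate")
})

test_that("energy estimates reproduce tabulated peptide energies at 1 decimal", {
  m <- default_calibration()
  est <- estimate_ttb_energy(c(0.77, 0.51), m)
  expect_equal(round_half_away(est$dE_ttb, 1L), c(-1.2, -0.5))
  # the line's root maps to exactly zero tetrel-bond energy
  root <- -m$intercept / m$slope
  expect_equal(round_half_away(estimate_ttb_energy(root, m)$dE_ttb, 1L), 0)
  expect_gt(root, 0.3)
  expect_lt(root, 0.4)
  # strictly decreasing in density
  grid <- seq(0.3, 2.0, by = 0.05)
  vals <- estimate_ttb_energy(grid, m)$dE_ttb
  expect_true(all(diff(vals) < 0))
  # outside the calibrated density range: warn, do not fail
  expect_warning(estimate_ttb_energy(0.1, m), "extrapolat")
  expect_error(estimate_ttb_energy(0, m), "positive")
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_away(-1.755, 1L), -1.8)
  expect_equal(round_half_away(1.755, 1L), 1.8)
  expect_equal(round_half_away(-0.25, 1L), -0.3)
  expect_equal(round_half_away(2.349, 1L), 2.3)
  expect_equal(round_half_away(c(-1.44, 1.45), 1L), c(-1.4, 1.5))
})

test_that("distance-density surrogate recovers noiseless parameters and ranks the tables", {
  d <- seq(2.6, 3.5, length.out = 8)
  exact <- data.frame(d_OC = d, rho100 = 50 * exp(-1.2 * d))
  m <- fit_distance_density(exact)
  expect_equal(m$A, 50, tolerance = 1e-6)
  expect_equal(m$B, 1.2, tolerance = 1e-6)
  expect_equal(m$spearman_check, 1)

  dflt <- default_distance_density()
  expect_equal(dflt$fit_points, 21L)
  expect_gte(dflt$spearman_check, 0.85)
  # predictions decrease strictly with distance
  pr <- predict(dflt, seq(2.5, 4, by = 0.1))
  expect_true(all(diff(pr) < 0))

  expect_error(fit_distance_density(exact[1:3, ]), "at least 5")
  const <- data.frame(d_OC = rep(3, 6), rho100 = c(1, 2, 1.5, 1.2, 1.8, 1.1))
  expect_error(fit_distance_density(const), "degenerate")
})

test_that("calibration recovery from noisy simulated data stays within three standard errors", {
  true_slope <- -5.5
  true_int <- 1.8
  set.seed(4242)
  hits <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    rho <- stats::runif(20, 0.4, 1.7)
    dE <- true_slope * rho + true_int + stats::rnorm(20, 0, 0.15)
    fit <- stats::lm(dE ~ rho)
    se <- summary(fit)$coefficients["rho", "Std. Error"]
    if (abs(stats::coef(fit)[["rho"]] - true_slope) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("promolecular density surrogate decays, is rigid-motion invariant and ranks contacts", {
  # two-carbonyl toy geometry at a given O...C separation
  toy <- function(d, shift = c(0, 0, 0), R = diag(3)) {
    pts <- rbind(c(-1.231, 0, 0),   # donor C
                 c(0, 0, 0),        # donor O
                 c(d, 0, 0),        # acceptor C
                 c(d + 0.4, 1.16, 0))  # acceptor O, tilted off-axis
    pts <- t(R %*% t(pts)) + matrix(shift, 4, 3, byrow = TRUE)
    list(o = pts[2L, ], c = pts[3L, ],
         atoms = data.frame(element = c("C", "O", "C", "O"),
                            x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]))
  }
  g3 <- toy(3.0)
  g4 <- toy(4.0)
  expect_gt(estimate_density_promolecular(g3$o, g3$c, g3$atoms),
            estimate_density_promolecular(g4$o, g4$c, g4$atoms))

  gm <- toy(3.0, shift = c(7, -2, 5), R = ttbscan:::rotation_matrix(c(1, 1, 0), 63))
  expect_equal(estimate_density_promolecular(gm$o, gm$c, gm$atoms),
               estimate_density_promolecular(g3$o, g3$c, g3$atoms),
               tolerance = 1e-9)

  bad <- g3$atoms
  bad$element[1L] <- "XX"
  expect_error(estimate_density_promolecular(g3$o, g3$c, bad), "unsupported element")

  # evaluated at the printed ATSP cluster distances, the surrogate ranks
  # contacts like the tabulated isosurface densities
  atsp <- ttb_peptide_contacts("ATSP")
  dens <- vapply(atsp$d, function(d) {
    g <- toy(d)
    estimate_density_promolecular(g$o, g$c, g$atoms)
  }, numeric(1L))
  expect_gt(stats::cor(dens, atsp$rho100, method = "spearman"), 0.8)
})

test_that("reference energies show the monotone density trend and HB reinforcement", {
  tab <- ttb_model_complexes()
  plain <- tab[tab$complex %in% 2:6, ]
  reinforced <- tab[tab$complex %in% 8:12, ]
  # matched donors: complex k vs complex k+6 share the Lewis base
  expect_true(all(reinforced$dE < plain$dE))
  # denser tetrel bond, stronger binding, within the fitting subset
  expect_lt(stats::cor(plain$rho100, plain$dE), 0)
})
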