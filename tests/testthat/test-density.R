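test_that("Silverman bandwidth follows the robust rule of thumb", {
  # x = 1..5: sd = 1.5811, IQR/1.349 = 2/1.349 = 1.4826 (the min)
  h <- silverman_bandwidth(1:5)
  expect_equal(h, 0.9 * (2 / 1.349) * 5^(-1 / 5), tolerance = 1e-12)

  withr::with_seed(3, x <- rnorm(100))
  expect_equal(silverman_bandwidth(2.5 * x), 2.5 * silverman_bandwidth(x))

  expect_error(silverman_bandwidth(rep(0.3, 20)), "zero spread",
               class = "pavca_validation_error")
})

test_that("the KDE matches the exact mixture-of-kernels form", {
  # single kernel: peak density 1/(h*sqrt(2*pi)) at the data point
  d1 <- estimate_density(c(0, 0), h = 1, n_grid = 101)
  expect_lt(abs(max(d1$f) - 1 / sqrt(2 * pi)), 1e-6)
  expect_equal(d1$x[which.max(d1$f)], 0)
  expect_true(all(d1$f >= 0))

  withr::with_seed(21, x <- c(rnorm(40, -0.5, 0.1), rnorm(40, 0.5, 0.1)))
  d <- estimate_density(x)
  h <- attr(d, "h")
  mass_trap <- trapezoid(d$x, d$f)
  mass_quad <- kde_mass_quadrature(x, h, min(d$x), max(d$x))
  expect_lt(abs(mass_trap - mass_quad), 1e-3)
  expect_gte(mass_trap, 0.95)

  # independent cross-check against stats::density on the same grid
  ref <- stats::density(x, bw = h, kernel = "gaussian", n = 100,
                        from = min(d$x), to = max(d$x))
  expect_equal(d$f, ref$y, tolerance = 5e-3)

  expect_error(estimate_density(x, n_grid = 5),
               class = "pavca_validation_error")
})

test_that("bounded support reflects mass instead of losing it", {
  withr::with_seed(4, x <- pmin(pmax(rnorm(200, 0.8, 0.3), -1), 1))
  d <- estimate_density(x, support = c(-1, 1), n_grid = 200)
  expect_equal(trapezoid(d$x, d$f), 1, tolerance = 0.01)
  expect_error(estimate_density(c(-1.2, 0.3), support = c(-1, 1)),
               "within the stated support", class = "pavca_validation_error")
})

test_that("the discrete derivative telescopes back to the density", {
  lin <- structure(
    tibble::tibble(x = seq(0, 1, length.out = 50),
                   f = 2 * seq(0, 1, length.out = 50) + 1),
    class = c("pavca_density", "tbl_df", "tbl", "data.frame")
  )
  dv <- differentiate(lin)
  expect_equal(nrow(dv), 49)
  expect_true(all(abs(dv$dfdx - 2) < 1e-9))

  withr::with_seed(8, x <- rnorm(60))
  d <- estimate_density(x)
  dv <- differentiate(d)
  rebuilt <- d$f[1] + cumsum(dv$dfdx * diff(d$x))
  expect_lt(max(abs(rebuilt - d$f[-1])), 1e-9)

  # symmetric unimodal density -> antisymmetric derivative about the mode
  d0 <- estimate_density(c(-0.3, 0.3), h = 0.5, n_grid = 101)
  dv0 <- differentiate(d0)
  expect_equal(dv0$dfdx, -rev(dv0$dfdx), tolerance = 1e-9)
})

test_that("extrema detection finds the bimodal signature and filters wiggles", {
  grid <- seq(-1.2, 1.2, length.out = 200)
  f <- 0.5 * dnorm(grid, -0.6, 0.15) + 0.5 * dnorm(grid, 0.6, 0.15)
  curve <- tibble::tibble(x = grid, f = f)
  ext <- find_extrema(differentiate(curve))
  expect_equal(ext$kind, c("max", "min", "max", "min"))
  expect_true(all(diff(ext$position) > 0))

  mono <- tibble::tibble(x = grid[-1], dfdx = seq(0, 1, length.out = 199))
  expect_equal(nrow(find_extrema(structure(mono, class = class(curve)))), 0)

  # raising the prominence floor can only remove extrema
  withr::with_seed(12, noisy <- estimate_density(runif(30, -1, 1), h = 0.05))
  dv <- differentiate(noisy)
  counts <- vapply(c(0, 0.02, 0.05, 0.2, 0.5),
                   function(p) nrow(find_extrema(dv, min_prominence = p)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak statistics recover location and half-prominence width", {
  d1 <- estimate_density(c(0, 0), h = 1, n_grid = 401)
  ps <- density_peak_stats(d1)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$location, 0, tolerance = 1e-6)
  expect_equal(ps$width, 2 * sqrt(2 * log(2)), tolerance = 0.02)

  withr::with_seed(31, {
    x <- c(rnorm(500, -0.6, 0.15), rnorm(500, 0.6, 0.15))
  })
  d <- estimate_density(c(x, -x)) # exactly symmetric sample
  ps2 <- density_peak_stats(d)
  expect_equal(nrow(ps2), 2)
  expect_equal(ps2$location[1], -ps2$location[2], tolerance = 0.02)
  expect_true(all(ps2$width > 0))
  expect_true(all(ps2$width <= diff(range(d$x))))
})

test_that("derivative cutoffs sit between the modes of a symmetric mixture", {
  spec <- mixture_spec(
    tibble::tibble(weight = c(0.5, 0.5), mean = c(-0.6, 0.6),
                   sd = 0.15, skew = 0),
    n = 2000, seed = 42
  )
  x <- simulate_scores(spec)
  ct <- derivative_cutoffs(x)
  expect_lt(abs(ct$gt_cutoff + ct$st_cutoff), 0.05)
  expect_gt(ct$gt_cutoff, -0.6)
  expect_lt(ct$st_cutoff, 0.6)
  expect_lt(ct$gt_cutoff, ct$st_cutoff)

  # the cutoffs lie on the flanks: density there is below the peak density
  peaks <- ct$diagnostics$peaks
  dens <- ct$curves$density
  f_at <- function(x0) dens$f[which.min(abs(dens$x - x0))]
  expect_lt(f_at(ct$gt_cutoff), peaks$height[1])
  expect_lt(f_at(ct$st_cutoff), peaks$height[nrow(peaks)])

  withr::with_seed(77, uni <- rnorm(300, 0, 0.1))
  expect_error(derivative_cutoffs(uni), "not bimodal",
               class = "pavca_not_bimodal")
})

test_that("cutoffs are symmetric on mirrored samples and stable in the grid", {
  withr::with_seed(55, x <- c(rnorm(400, -0.55, 0.18), rnorm(400, 0.55, 0.18)))
  pooled <- c(x, -x)
  ct <- derivative_cutoffs(pooled)
  step <- diff(ct$curves$density$x[1:2])
  expect_lt(abs(ct$gt_cutoff + ct$st_cutoff), step + 1e-12)

  ct400 <- derivative_cutoffs(pooled, n_grid = 400)
  expect_lt(abs(ct400$gt_cutoff - ct$gt_cutoff), 2 * step)
  expect_lt(abs(ct400$st_cutoff - ct$st_cutoff), 2 * step)
})
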