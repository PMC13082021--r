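# Cylinder fitting, membrane unrolling, necklace row detection, spacing
# and stoichiometry.

test_that("cylinder fits recover thin-filament diameters exactly", {
  expect_equal(fit_cylinder(cylinder_points(3.5, seed = 1))$diameter, 7,
               tolerance = 1e-6)
  expect_equal(fit_cylinder(cylinder_points(5, seed = 2))$diameter, 10,
               tolerance = 1e-6)
  # tilted, translated cylinder
  f <- fit_cylinder(cylinder_points(20, seed = 3, axis = c(1, 1, 0.5),
                                    origin = c(10, -5, 3), height = 60))
  expect_equal(f$radius, 20, tolerance = 1e-5)
  expect_error(fit_cylinder(cbind(0, 0, 1:10)), "degenerate")
})

test_that("noisy cylinder radius is recovered within sampling error", {
  set.seed(4)
  n <- 400
  pts <- cylinder_points(150, n = n, height = 120, seed = 4)
  pts <- pts + rnorm(3 * n, 0, 0.2)
  f <- fit_cylinder(pts)
  expect_lt(abs(f$radius - 150), 3 * 0.2 / sqrt(n) * 3)
  expect_lt(f$rms, 0.3)
})

test_that("unrolling is isometric and invertible on the surface", {
  fit <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                        radius = 150, diameter = 300, rms = 0),
                   class = "cylinder_fit")
  p1 <- c(150, 0, 0); p2 <- c(150, 0, 10)
  fm <- unroll_membrane(rbind(p1, p2), fit)
  expect_equal(diff(fm$u), 10)
  expect_equal(diff(fm$v), 0)
  # half-turn at fixed height: arc distance R * pi
  q <- rbind(c(150, 0, 0), c(-150, 0, 0))
  fq <- unroll_membrane(q, fit)
  dv <- abs(diff(fq$v))
  dv <- min(dv, attr(fq, "period") - dv)
  expect_equal(dv, 150 * pi, tolerance = 1e-9)
  # chord <= unrolled geodesic; equality in the small-separation limit
  set.seed(5)
  th <- runif(40, 0, 2 * pi); h <- runif(40, 0, 50)
  pts <- cbind(150 * cos(th), 150 * sin(th), h)
  fm2 <- unroll_membrane(pts, fit)
  per <- attr(fm2, "period")
  for (k in 1:20) {
    i <- sample(40, 2)
    chord <- sqrt(sum((pts[i[1], ] - pts[i[2], ])^2))
    dv <- abs(fm2$v[i[1]] - fm2$v[i[2]])
    dv <- min(dv, per - dv)
    geo <- sqrt((fm2$u[i[1]] - fm2$u[i[2]])^2 + dv^2)
    expect_gte(geo + 1e-9, chord)
  }
  near <- unroll_membrane(rbind(c(150, 0, 0),
                                c(150 * cos(1e-4), 150 * sin(1e-4), 0.01)), fit)
  chord <- sqrt(sum((c(150, 0, 0) -
                       c(150 * cos(1e-4), 150 * sin(1e-4), 0.01))^2))
  expect_equal(sqrt(diff(near$u)^2 + diff(near$v)^2), chord, tolerance = 1e-6)
  # exact round trip for on-surface points
  back <- flatmap_to_3d(fm2, fit)
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("row detection counts rings and hits its kernel resolution limit", {
  fit0 <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                         radius = 150, diameter = 300, rms = 0),
                    class = "cylinder_fit")
  ring <- gen_necklace(necklace_model(n_rows = 1, seed = 1))
  fm1 <- unroll_membrane(ring$points[, c("x", "y", "z")], fit0)
  expect_equal(detect_rows(fm1)$n_rows, 1)
  # 7 rows at 17.5 nm pitch, sigma 1: all recovered
  nk <- gen_necklace(necklace_model(noise_sigma = 1, seed = 6))
  fm7 <- unroll_membrane(nk$points[, c("x", "y", "z")],
                         fit_cylinder(nk$points[, c("x", "y", "z")]))
  rows <- detect_rows(fm7)
  expect_equal(rows$n_rows, 7)
  expect_equal(diff(rows$centers), rep(17.5, 6), tolerance = 0.05)
  # pitch below twice the bandwidth merges rows (documented failure mode)
  tight <- gen_necklace(necklace_model(row_spacing = 6, noise_sigma = 0.5,
                                       seed = 7))
  fmt <- unroll_membrane(tight$points[, c("x", "y", "z")], fit0)
  expect_lt(detect_rows(fmt, bandwidth = 4)$n_rows, 7)
})

test_that("row spacing pools periodic gaps including the wrap-around", {
  fit <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                        radius = 40 / (2 * pi), diameter = 40 / pi, rms = 0),
                   class = "cylinder_fit")
  mkfm <- function(v) {
    fm <- data.frame(u = rep(0, length(v)), v = v)
    class(fm) <- c("flat_map", "data.frame")
    attr(fm, "period") <- 40
    fm
  }
  rows1 <- structure(list(row_id = rep(1L, 4), centers = 0, n_rows = 1L),
                     class = "row_assignment")
  sp <- row_spacing(mkfm(c(0, 10, 20, 30)), rows1)
  expect_equal(sp$gaps, rep(10, 4))
  expect_equal(sp$sd, 0)
  sp2 <- row_spacing(mkfm(c(0, 10, 25)),
                     structure(list(row_id = rep(1L, 3), centers = 0,
                                    n_rows = 1L), class = "row_assignment"))
  expect_equal(sort(sp2$gaps), c(10, 15, 15))
  # gap count equals particle count per row (periodic closure)
  expect_equal(sp2$n, 3)
  expect_true(inherits(fit, "cylinder_fit"))
})

test_that("lattice statistics are rigid-motion invariant and recover truth", {
  nk <- gen_necklace(necklace_model(noise_sigma = 0.5, missing_fraction = 0.1,
                                    seed = 8))
  run <- function(pts) {
    f <- fit_cylinder(pts)
    fm <- unroll_membrane(pts, f)
    r <- detect_rows(fm)
    sp <- row_spacing(fm, r)
    list(n_rows = r$n_rows, mean = sp$mean, pitch = sp$pitch)
  }
  base <- run(nk$points[, c("x", "y", "z")])
  R <- rotation_xyz(0.7, -0.2, 0.9)
  moved <- as.matrix(nk$points[, c("x", "y", "z")]) %*% t(R)
  moved <- sweep(moved, 2, c(-30, 55, 12), `+`)
  rot <- run(moved)
  expect_equal(rot$n_rows, base$n_rows)
  expect_equal(rot$mean, base$mean, tolerance = 1e-3)
  # peak positions are quantized by the density grid (~0.1 nm)
  expect_equal(rot$pitch, base$pitch, tolerance = 0.02)
  expect_equal(base$n_rows, 7)
  expect_equal(base$pitch, 17.5, tolerance = 0.2)
})

test_that("row recovery holds across the noise and dropout sweep", {
  for (ns in c(0, 1, 2)) for (mf in c(0, 0.2)) {
    nk <- gen_necklace(necklace_model(noise_sigma = ns, missing_fraction = mf,
                                      seed = 11))
    pts <- nk$points[, c("x", "y", "z")]
    fm <- unroll_membrane(pts, fit_cylinder(pts))
    r <- detect_rows(fm)
    expect_equal(r$n_rows, 7)
    if (mf == 0) {
      sp <- row_spacing(fm, r)
      expect_equal(sp$mean, 17.5, tolerance = 0.2)
    }
  }
})

test_that("per-doublet stoichiometry is the mean row count over doublets", {
  expect_equal(per_doublet_stoichiometry(54)$ratio, 6)
  expect_equal(per_doublet_stoichiometry(9)$ratio, 1)
  expect_equal(per_doublet_stoichiometry(c(52, 54, 56))$ratio, 6)
  expect_equal(per_doublet_stoichiometry(c(52, 54, 56))$rounded, 6)
  expect_error(per_doublet_stoichiometry(54, n_doublets = 0), "n_doublets")
})
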