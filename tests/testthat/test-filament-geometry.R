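# Spline resampling, distance cleaning, half-set tagging, axis fitting
# and diameter/length measurement.

test_that("a straight trace resamples to evenly spaced axial particles", {
  tr <- filament_trace("f1", rbind(c(0, 0, 0), c(0, 0, 50), c(0, 0, 100)))
  ps <- resample_spline(tr, step = 4, seed = 1)
  expect_equal(nrow(ps), 26)
  expect_equal(ps$s, seq(0, 100, by = 4))
  for (i in c(1, 13, 26))
    expect_lt(sum(abs(particle_rotation(ps, i)[, 3] - c(0, 0, 1))), 1e-6)
  expect_equal(formals(resample_spline)$step, 4)
  expect_error(filament_trace("bad", rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})

test_that("arc spacing on a curved trace stays within 1% of the step", {
  th <- seq(0, pi / 2, length.out = 25)
  tr <- filament_trace("arc", cbind(100 * cos(th), 100 * sin(th), 0))
  ps <- resample_spline(tr, step = 4, seed = 2)
  # quarter circle of radius 100: arc 157.08 -> 40 particles
  expect_equal(nrow(ps), 40)
  # numeric arc length between consecutive particles via dense chords
  pos <- as.matrix(ps[, c("x", "y", "z")])
  chord <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(abs(chord - 4) < 0.04))
  expect_equal(max(ps$s), 156, tolerance = 0.01)
  # orientations follow the rotating tangent
  mid <- 20
  tg <- particle_rotation(ps, mid)[, 3]
  expect_equal(sum(tg * c(0, 0, 1)), 0, tolerance = 1e-6)
})

test_that("greedy distance cleaning matches a brute-force oracle", {
  mk <- function(pos) particle_set(data.frame(
    filament_id = 1, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    s = seq_len(nrow(pos))))
  two <- mk(rbind(c(0, 0, 0), c(0, 0, 5)))
  expect_equal(nrow(clean_by_distance(two, 8)), 1)
  expect_equal(clean_by_distance(two, 8)$particle_id, 1)
  eleven <- mk(cbind(0, 0, seq(0, 40, by = 4)))
  kept <- clean_by_distance(eleven, 8)
  expect_equal(kept$z, c(0, 8, 16, 24, 32, 40))
  expect_equal(formals(clean_by_distance)$min_dist, 8)
  # randomized sets vs the oracle; idempotence; all-pairs separation
  for (seed in 1:5) {
    set.seed(seed)
    pos <- matrix(runif(150, 0, 30), ncol = 3)
    ps <- mk(pos)
    out <- clean_by_distance(ps, 8)
    expect_equal(out$particle_id, oracle_greedy_clean(pos, 8))
    expect_identical(as.data.frame(clean_by_distance(out, 8)),
                     as.data.frame(out))
    d <- as.matrix(dist(out[, c("x", "y", "z")]))
    expect_true(all(d[upper.tri(d)] >= 8))
  }
})

test_that("half-sets split at the filament midpoint with A taking ties", {
  mk <- function(n, fid = 1) data.frame(filament_id = fid, x = 0, y = 0,
                                        z = seq_len(n), s = seq_len(n) * 4)
  ps10 <- split_halfsets(particle_set(mk(10)))
  expect_equal(table(ps10$halfset), table(c(rep("A", 5), rep("B", 5))))
  ps11 <- split_halfsets(particle_set(mk(11)))
  expect_equal(sum(ps11$halfset == "A"), 6)
  expect_equal(sum(ps11$halfset == "B"), 5)
  # halves contiguous in s, A proximal
  expect_true(max(ps11$s[ps11$halfset == "A"]) < min(ps11$s[ps11$halfset == "B"]))
  # two filaments split independently at their own midpoints
  both <- split_halfsets(particle_set(rbind(mk(10), mk(7, fid = 2))))
  expect_equal(sum(both$halfset == "A" & both$filament_id == 2), 4)
  expect_equal(sum(both$halfset == "B" & both$filament_id == 2), 3)
})

test_that("barrel axis recovery is exact on cylinders and equivariant", {
  ps <- gen_cilium(cilium_model(jitter_sigma = 0, seed = 1))
  ax <- fit_barrel_axis(ps)
  expect_equal(abs(sum(ax$direction * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_lt(max(abs(ax$centers$x)), 1e-6)
  expect_lt(max(abs(ax$centers$y)), 1e-6)
  shifted <- ps
  shifted$x <- shifted$x + 50
  shifted$y <- shifted$y + 30
  ax2 <- fit_barrel_axis(shifted)
  expect_equal(unique(round(ax2$centers$x, 6)), 50)
  expect_equal(unique(round(ax2$centers$y, 6)), 30)
  few <- particle_set(data.frame(filament_id = rep(1:2, each = 5),
                                 x = runif(10), y = runif(10),
                                 z = rep(1:5, 2), s = rep(1:5, 2)))
  expect_error(fit_barrel_axis(few), "3 filaments")
})

test_that("diameter profile reads off the generator diameters", {
  ps <- gen_cilium(cilium_model(jitter_sigma = 0, radius_smoothing = 0,
                                seed = 1))
  ax <- fit_barrel_axis(ps)
  prof <- diameter_profile(ps, ax, bin = 10, label_col = "true_label")
  expected <- default_zones()
  # bins fully inside one zone read the generator diameter exactly
  # (axial coordinate is centred on the particle centroid, so shift bounds)
  bounds <- c(0, cumsum(expected$length)) - mean(ps$s)
  interior <- vapply(seq_len(nrow(prof)), function(i) {
    k <- match(prof$label[i], expected$zone)
    prof$a_mid[i] - 5 >= bounds[k] && prof$a_mid[i] + 5 <= bounds[k + 1]
  }, logical(1))
  expect_gt(sum(interior), 80)
  expect_equal(prof$diameter[interior],
               expected$diameter[match(prof$label, expected$zone)][interior],
               tolerance = 1e-9)
  # zone means within the boundary-bin mixing tolerance
  zm <- zone_means(prof)
  for (z in expected$zone)
    expect_equal(zm$diameter[zm$zone == z],
                 expected$diameter[expected$zone == z], tolerance = 0.01)
  # rigid motions leave diameters unchanged up to the re-anchored binning
  R <- rotation_xyz(0.4, -0.3, 1.1)
  moved <- apply_rigid(ps, R, c(120, -40, 60))
  zm2 <- zone_means(diameter_profile(moved, fit_barrel_axis(moved), bin = 10,
                                     label_col = "true_label"))
  expect_equal(zm2$diameter[match(zm$zone, zm2$zone)], zm$diameter,
               tolerance = 0.01)
})

test_that("zone lengths follow the count-times-step rule", {
  mk <- function(labels) particle_set(data.frame(
    filament_id = 1, x = 0, y = 0, z = seq_along(labels),
    s = (seq_along(labels) - 1) * 4, class_label = labels))
  zl <- zone_lengths(mk(rep("P", 52)), step = 4)
  expect_equal(zl$per_filament$length, 208)
  zl2 <- zone_lengths(mk(c(rep("P", 3), "B", rep("TZ", 4))), step = 4)
  expect_equal(zl2$per_filament$length[zl2$per_filament$zone == "B"], 4)
  expect_error(zone_lengths(mk(c("P", "C", "P"))), "contiguous")
  # generator zone lengths recovered within one step on a noise-free barrel
  ps <- gen_cilium(cilium_model(jitter_sigma = 0, seed = 1))
  zl3 <- zone_lengths(ps, label_col = "true_label")
  expected <- default_zones()
  m <- merge(zl3$means, expected, by = "zone")
  expect_true(all(abs(m$length.x - m$length.y) <= 4))
})
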