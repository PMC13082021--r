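# Filament geometry: spline resampling of traces into oriented particles,
# distance cleaning, half-set splitting, barrel axis fitting and
# diameter/length measurement.

#' Resample a traced filament into oriented particles
#'
#' Fits a natural cubic spline through the control points, reparameterizes
#' by arc length (dense numeric integration), and places particles at
#' `s = 0, step, 2*step, ...` up to the total length. Each particle's
#' orientation has its Z axis along the local spline tangent with the
#' in-plane angle drawn uniformly at random, the standard starting point
#' for subtomogram averaging of filamentous structures.
#'
#' @param trace a [filament_trace()].
#' @param step arc spacing in nm (default 4).
#' @param seed seed for the in-plane angle draws (`NULL` uses the session
#'   RNG stream).
#' @return a [particle_set()].
#' @export
resample_spline <- function(trace, step = 4, seed = NULL) {
  stopifnot(inherits(trace, "filament_trace"))
  if (step <= 0) stopf("resample_spline: step must be > 0")
  cp <- trace$control_points
  n <- nrow(cp)
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-n, , drop = FALSE])^2))
  tpar <- c(0, cumsum(seg))
  fx <- stats::splinefun(tpar, cp[, 1], method = "natural")
  fy <- stats::splinefun(tpar, cp[, 2], method = "natural")
  fz <- stats::splinefun(tpar, cp[, 3], method = "natural")
  # dense evaluation for arc-length inversion; resolution well below step
  m <- max(2000L, 400L * (n - 1L))
  td <- seq(0, tpar[n], length.out = m)
  px <- fx(td); py <- fy(td); pz <- fz(td)
  darc <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
  cum <- c(0, cumsum(darc))
  total <- cum[m]
  s <- seq(0, total, by = step)
  ts <- stats::approx(cum, td, xout = s, rule = 2)$y
  pos <- cbind(fx(ts), fy(ts), fz(ts))
  tg <- cbind(fx(ts, deriv = 1), fy(ts, deriv = 1), fz(ts, deriv = 1))
  psi <- with_seed(seed, stats::runif(length(s), 0, 360))
  ang <- t(vapply(seq_along(s), function(i)
    euler_from_tangent(tg[i, ], psi[i]), numeric(3)))
  particle_set(data.frame(
    particle_id = seq_along(s),
    filament_id = trace$filament_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3], s = s,
    rot = ang[, 1], tilt = ang[, 2], psi = ang[, 3],
    stringsAsFactors = FALSE))
}

#' Remove particles closer than a minimum distance
#'
#' Greedy pass in stored order: a particle is kept iff its Euclidean
#' distance to every already-kept particle is at least `min_dist`. The
#' pass is deterministic, order-preserving and idempotent; 8 nm is the
#' conventional cleaning distance for 4 nm-oversampled microtubule
#' particles.
#'
#' @param ps a [particle_set()].
#' @param min_dist minimum pairwise distance, nm (default 8).
#' @return the cleaned [particle_set()].
#' @export
clean_by_distance <- function(ps, min_dist = 8) {
  stopifnot(is_particle_set(ps))
  if (min_dist <= 0) stopf("clean_by_distance: min_dist must be > 0")
  n <- nrow(ps)
  if (n == 0) return(ps)
  pos <- as.matrix(ps[, c("x", "y", "z")])
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0 ||
        min(sqrt(rowSums((kept - matrix(pos[i, ], nrow(kept), 3, byrow = TRUE))^2))) >= min_dist) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, ])
    }
  }
  out <- ps[keep, , drop = FALSE]
  class(out) <- class(ps)
  out
}

#' Tag half-sets at the filament midpoint
#'
#' Splits each filament's particles at its arc-length midpoint: the
#' proximal half (lowest `s`) is tagged `A`, the rest `B`; with an odd
#' count the extra particle goes to `A`. Splitting at the filament
#' midpoint keeps heavily overlapping neighbouring particles inside the
#' same half-set, which avoids spurious correlation between the
#' half-maps used for resolution estimation.
#'
#' @param ps a [particle_set()].
#' @return the particle set with `halfset` filled in.
#' @export
split_halfsets <- function(ps) {
  stopifnot(is_particle_set(ps))
  for (fid in unique(ps$filament_id)) {
    idx <- which(ps$filament_id == fid)
    ord <- idx[order(ps$s[idx])]
    na <- ceiling(length(ord) / 2)
    ps$halfset[ord] <- c(rep("A", na), rep("B", length(ord) - na))
  }
  ps
}

#' Fit the barrel axis of a multi-filament particle set
#'
#' The principal direction of all particle positions defines the axial
#' coordinate; the axis polyline is the running centroid of positions in
#' overlapping axial windows, which tracks gentle bends of the barrel.
#'
#' @param ps a [particle_set()] with at least 3 filaments.
#' @param window axial window width in nm (default 40); window centers are
#'   spaced half a window apart.
#' @return a `barrel_axis`: list with `origin`, `direction` (unit vector)
#'   and `centers` (data.frame `a`, `x`, `y`, `z` of windowed centroids).
#' @export
fit_barrel_axis <- function(ps, window = 40) {
  stopifnot(is_particle_set(ps))
  if (length(unique(ps$filament_id)) < 3)
    stopf("fit_barrel_axis: need at least 3 filaments")
  if (window <= 0) stopf("fit_barrel_axis: window must be > 0")
  pos <- as.matrix(ps[, c("x", "y", "z")])
  origin <- colMeans(pos)
  pc <- stats::prcomp(pos, center = TRUE, scale. = FALSE)
  e1 <- pc$rotation[, 1]
  if (e1[which.max(abs(e1))] < 0) e1 <- -e1   # deterministic sign
  a <- drop((pos - matrix(origin, nrow(pos), 3, byrow = TRUE)) %*% e1)
  centers <- seq(min(a), max(a), by = window / 2)
  rows <- lapply(centers, function(cc) {
    inw <- abs(a - cc) <= window / 2
    if (!any(inw)) return(NULL)
    cm <- colMeans(pos[inw, , drop = FALSE])
    data.frame(a = cc, x = cm[1], y = cm[2], z = cm[3])
  })
  centers_df <- do.call(rbind, rows)
  structure(list(origin = origin, direction = e1, centers = centers_df,
                 window = window),
            class = "barrel_axis")
}

#' @export
print.barrel_axis <- function(x, ...) {
  cat(sprintf("barrel_axis: direction (%.3f, %.3f, %.3f), %d centroid windows\n",
              x$direction[1], x$direction[2], x$direction[3], nrow(x$centers)))
  invisible(x)
}

# Axial coordinate and perpendicular (radial) distance of each particle
# relative to a fitted barrel axis.
axis_coordinates <- function(ps, axis) {
  pos <- as.matrix(ps[, c("x", "y", "z")])
  e1 <- axis$direction
  rel <- pos - matrix(axis$origin, nrow(pos), 3, byrow = TRUE)
  a <- drop(rel %*% e1)
  cx <- stats::approx(axis$centers$a, axis$centers$x, xout = a, rule = 2)$y
  cy <- stats::approx(axis$centers$a, axis$centers$y, xout = a, rule = 2)$y
  cz <- stats::approx(axis$centers$a, axis$centers$z, xout = a, rule = 2)$y
  d <- pos - cbind(cx, cy, cz)
  d_axial <- drop(d %*% e1)
  dperp <- d - outer(d_axial, e1)
  list(a = a, r = sqrt(rowSums(dperp^2)))
}

#' Axial diameter profile of a barrel
#'
#' Bins particles along the fitted axis (half-open bins `[start, end)`)
#' and reports, per bin, the diameter as twice the mean perpendicular
#' particle distance to the axis — i.e. axis-to-particle-center, not
#' tubule-wall based — together with the particle count and the modal
#' class label of the bin's members.
#'
#' @param ps a [particle_set()].
#' @param axis a `barrel_axis` from [fit_barrel_axis()].
#' @param bin axial bin width, nm (default 10).
#' @param label_col column used for the per-bin modal label (default
#'   `class_label`).
#' @return a `diameter_profile`: data.frame with `a_mid`, `diameter`, `n`,
#'   `label`, ordered by axial position; empty bins are omitted.
#' @export
diameter_profile <- function(ps, axis, bin = 10, label_col = "class_label") {
  stopifnot(is_particle_set(ps), inherits(axis, "barrel_axis"))
  if (bin <= 0) stopf("diameter_profile: bin must be > 0")
  ac <- axis_coordinates(ps, axis)
  lo <- floor(min(ac$a) / bin) * bin
  idx <- floor((ac$a - lo) / bin)
  labs <- if (label_col %in% names(ps)) ps[[label_col]] else rep(NA_character_, nrow(ps))
  rows <- lapply(sort(unique(idx)), function(k) {
    inb <- idx == k
    lab <- if (all(is.na(labs[inb]))) NA_character_ else
      names(which.max(table(labs[inb])))
    data.frame(a_mid = lo + (k + 0.5) * bin,
               diameter = 2 * mean(ac$r[inb]),
               n = sum(inb), label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diameter_profile", "data.frame")
  attr(out, "bin") <- bin
  out
}

#' Per-zone mean diameters from a diameter profile
#'
#' Averages profile bins by their majority class label, weighting each bin
#' by its particle count.
#'
#' @param profile a [diameter_profile()].
#' @return data.frame `zone`, `diameter`, `n_bins`, `n_particles`.
#' @export
zone_means <- function(profile) {
  stopifnot(inherits(profile, "diameter_profile"))
  p <- profile[!is.na(profile$label), , drop = FALSE]
  if (nrow(p) == 0) stopf("zone_means: profile has no labelled bins")
  rows <- lapply(unique(p$label), function(z) {
    q <- p[p$label == z, , drop = FALSE]
    data.frame(zone = z,
               diameter = sum(q$diameter * q$n) / sum(q$n),
               n_bins = nrow(q), n_particles = sum(q$n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-zone arc-length extents
#'
#' For each filament, each zone's length is the arc span of its particles
#' plus one step (`s_last - s_first + step`), so a single-particle zone has
#' length `step`. Labels must be contiguous per filament (run
#' [enforce_ordering()] first if they are not).
#'
#' @param ps a labelled [particle_set()].
#' @param step particle arc spacing, nm; inferred from the median arc
#'   increment when `NULL`.
#' @param label_col label column (default `class_label`).
#' @return list with `per_filament` (data.frame `filament_id`, `zone`,
#'   `length`, `n`) and `means` (across-filament mean length per zone).
#' @export
zone_lengths <- function(ps, step = NULL, label_col = "class_label") {
  stopifnot(is_particle_set(ps))
  labs <- ps[[label_col]]
  if (any(is.na(labs))) stopf("zone_lengths: unlabelled particles present")
  rows <- list()
  for (fid in unique(ps$filament_id)) {
    idx <- which(ps$filament_id == fid)
    idx <- idx[order(ps$s[idx])]
    st <- step %||% stats::median(diff(ps$s[idx]))
    r <- rle(labs[idx])
    if (anyDuplicated(r$values))
      stopf(paste0("zone_lengths: labels not contiguous on filament %s; ",
                   "apply enforce_ordering() first"), fid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    rows[[length(rows) + 1]] <- data.frame(
      filament_id = fid, zone = r$values,
      length = ps$s[idx[ends]] - ps$s[idx[starts]] + st,
      n = r$lengths, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  means <- stats::aggregate(length ~ zone, data = per, FUN = mean)
  list(per_filament = per, means = means)
}
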