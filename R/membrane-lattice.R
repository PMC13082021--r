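# Membrane lattice: least-squares cylinder fitting, unrolling of picked
# particles into flattened membrane coordinates, and ciliary-necklace row,
# spacing and stoichiometry statistics.

# Orthonormal frame perpendicular to a unit direction d, smooth in the
# spherical parameterization used by the optimizer.
perp_frame <- function(d) {
  phi <- atan2(d[2], d[1])
  p <- c(-sin(phi), cos(phi), 0)
  q <- cross3(d, p)
  list(p = p, q = q)
}

dir_from_angles <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

#' Least-squares cylinder fit
#'
#' Fits axis and radius minimizing squared radial residuals. The axis is
#' initialized from the principal directions of the point cloud (both the
#' largest- and smallest-variance directions are tried, covering tall
#' cylinders and flat rings) and refined by Nelder-Mead over axis
#' orientation and its in-plane offset; the radius is the mean radial
#' distance, which is optimal given the axis.
#'
#' @param points numeric matrix or data.frame of 3D coordinates (nm), at
#'   least 6 non-degenerate points.
#' @return a `cylinder_fit`: list with `point` (a point on the axis),
#'   `direction` (unit vector), `radius`, `diameter`, `rms` residual (nm).
#' @export
fit_cylinder <- function(points) {
  pts <- as.matrix(points[, 1:3])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 6) stopf("fit_cylinder: need at least 6 points")
  ctr <- colMeans(pts)
  rel0 <- sweep(pts, 2, ctr)
  sv <- svd(rel0)$d / sqrt(nrow(pts))
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("fit_cylinder: degenerate (collinear or coincident) points")
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  objective <- function(par) {
    d <- dir_from_angles(par[1], par[2])
    fr <- perp_frame(d)
    cc <- ctr + par[3] * fr$p + par[4] * fr$q
    rel <- sweep(pts, 2, cc)
    ax <- drop(rel %*% d)
    rad <- sqrt(pmax(0, rowSums(rel^2) - ax^2))
    sum((rad - mean(rad))^2)
  }
  best <- NULL
  for (init_dir in list(pc$rotation[, 1], pc$rotation[, 3])) {
    theta0 <- acos(max(-1, min(1, init_dir[3])))
    phi0 <- atan2(init_dir[2], init_dir[1])
    fit <- stats::optim(c(theta0, phi0, 0, 0), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  d <- dir_from_angles(best$par[1], best$par[2])
  if (d[which.max(abs(d))] < 0) d <- -d
  fr <- perp_frame(dir_from_angles(best$par[1], best$par[2]))
  cc <- ctr + best$par[3] * fr$p + best$par[4] * fr$q
  rel <- sweep(pts, 2, cc)
  ax <- drop(rel %*% d)
  rad <- sqrt(pmax(0, rowSums(rel^2) - ax^2))
  structure(list(point = cc, direction = d, radius = mean(rad),
                 diameter = 2 * mean(rad),
                 rms = sqrt(best$value / nrow(pts))),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder_fit: radius %.3f nm (diameter %.3f), rms residual %.3g nm\n",
              x$radius, x$diameter, x$rms))
  invisible(x)
}

#' Unroll points into flattened membrane coordinates
#'
#' Maps each point to `u` (axial coordinate along the fitted axis, nm) and
#' `v` (circumferential arc `R * theta`, wrapped to `[0, 2*pi*R)`), the
#' membranogram-style flattening in which lattice statistics are computed.
#' The unrolling is isometric for on-surface points.
#'
#' @param points 3D coordinates (matrix or data.frame, nm).
#' @param fit a [fit_cylinder()] result.
#' @return a `flat_map`: data.frame `u`, `v` with attributes `period`
#'   (`2*pi*R`), `radius` and `fit`.
#' @export
unroll_membrane <- function(points, fit) {
  stopifnot(inherits(fit, "cylinder_fit"))
  pts <- as.matrix(points[, 1:3])
  rel <- sweep(pts, 2, fit$point)
  d <- fit$direction
  fr <- perp_frame(d)
  u <- drop(rel %*% d)
  px <- drop(rel %*% fr$p)
  qy <- drop(rel %*% fr$q)
  theta <- atan2(qy, px) %% (2 * pi)
  period <- 2 * pi * fit$radius
  out <- data.frame(u = u, v = fit$radius * theta)
  class(out) <- c("flat_map", "data.frame")
  attr(out, "period") <- period
  attr(out, "radius") <- fit$radius
  attr(out, "fit") <- fit
  out
}

#' Map flattened coordinates back to 3D
#'
#' Inverse of [unroll_membrane()] for on-surface points (radial distance
#' set to the fitted radius).
#'
#' @param fm a `flat_map`.
#' @param fit the [fit_cylinder()] used to unroll.
#' @return matrix of 3D coordinates.
#' @export
flatmap_to_3d <- function(fm, fit = attr(fm, "fit")) {
  stopifnot(inherits(fm, "flat_map"), inherits(fit, "cylinder_fit"))
  fr <- perp_frame(fit$direction)
  theta <- fm$v / fit$radius
  t(vapply(seq_len(nrow(fm)), function(i)
    fit$point + fm$u[i] * fit$direction +
      fit$radius * (cos(theta[i]) * fr$p + sin(theta[i]) * fr$q),
    numeric(3)))
}

#' Detect necklace rows in flattened coordinates
#'
#' Rows are local maxima of a 1D Gaussian kernel density over the axial
#' coordinate `u`; each particle is assigned to its nearest row center.
#' Rows closer than about twice the bandwidth merge — the resolution limit
#' of the kernel estimate.
#'
#' @param fm a `flat_map` with at least 2 particles.
#' @param bandwidth kernel SD in nm (default 4, about a quarter of the
#'   observed 17.5 nm pitch).
#' @param min_height_frac density maxima below this fraction of the global
#'   maximum are ignored (guards against ripples in sparse tails).
#' @return a `row_assignment`: list with `row_id` (per particle),
#'   `centers` (sorted u positions), `n_rows`.
#' @export
detect_rows <- function(fm, bandwidth = 4, min_height_frac = 0.05) {
  stopifnot(inherits(fm, "flat_map"))
  if (nrow(fm) < 2) stopf("detect_rows: need at least 2 particles")
  u <- fm$u
  if (diff(range(u)) < .Machine$double.eps) {
    return(structure(list(row_id = rep(1L, length(u)), centers = u[1],
                          n_rows = 1L), class = "row_assignment"))
  }
  den <- stats::density(u, bw = bandwidth, n = 2048,
                        from = min(u) - 3 * bandwidth,
                        to = max(u) + 3 * bandwidth)
  y <- den$y
  peak <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) &
                  y >= min_height_frac * max(y))
  centers <- sort(den$x[peak])
  row_id <- vapply(u, function(ui) which.min(abs(centers - ui)), integer(1))
  structure(list(row_id = row_id, centers = centers,
                 n_rows = length(centers)),
            class = "row_assignment")
}

#' @export
print.row_assignment <- function(x, ...) {
  cat(sprintf("row_assignment: %d rows at u = %s nm\n", x$n_rows,
              paste(sprintf("%.1f", x$centers), collapse = ", ")))
  invisible(x)
}

#' Within-row spacing and inter-row pitch
#'
#' Within each row, particles are sorted by circumferential arc `v` and
#' neighbour gaps computed including the wrap-around gap (rows are closed
#' rings, so a row of n particles contributes n gaps). Gaps are pooled
#' over rows; rows with fewer than 2 particles are excluded.
#'
#' @param fm a `flat_map`.
#' @param rows a [detect_rows()] result.
#' @return list with `mean`, `sd`, `n` (pooled gaps), `gaps`, `pitch`
#'   (mean difference of successive row centers; `NA` for a single row)
#'   and `per_row` (data.frame `row_id`, `n`, `mean_gap`).
#' @export
row_spacing <- function(fm, rows) {
  stopifnot(inherits(fm, "flat_map"), inherits(rows, "row_assignment"))
  period <- attr(fm, "period")
  gaps <- numeric(0)
  per <- list()
  for (r in seq_len(rows$n_rows)) {
    v <- sort(fm$v[rows$row_id == r])
    if (length(v) < 2) next
    g <- c(diff(v), period - (v[length(v)] - v[1]))
    gaps <- c(gaps, g)
    per[[length(per) + 1]] <- data.frame(row_id = r, n = length(v),
                                         mean_gap = mean(g))
  }
  if (length(gaps) == 0) stopf("row_spacing: no row has at least 2 particles")
  list(mean = mean(gaps), sd = stats::sd(gaps), n = length(gaps), gaps = gaps,
       pitch = if (rows$n_rows > 1) mean(diff(rows$centers)) else NA_real_,
       per_row = do.call(rbind, per))
}

#' Necklace particles per doublet microtubule
#'
#' The mean per-row particle count divided by the number of doublet
#' microtubules (9 in the canonical axoneme).
#'
#' @param row_counts particle counts per row.
#' @param n_doublets number of doublet microtubules (default 9).
#' @return list with `ratio` (float) and `rounded` (nearest integer).
#' @export
per_doublet_stoichiometry <- function(row_counts, n_doublets = 9) {
  if (n_doublets < 1) stopf("per_doublet_stoichiometry: n_doublets must be >= 1")
  if (any(row_counts < 1)) stopf("per_doublet_stoichiometry: counts must be >= 1")
  ratio <- mean(row_counts) / n_doublets
  list(ratio = ratio, rounded = round(ratio))
}
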