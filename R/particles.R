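# ParticleSet: the central currency of the geometry and classification
# stages. A data.frame with one row per oriented particle; orientations are
# stored as ZYZ Euler angles in degrees (RELION STAR convention) whose
# rotation matrix has the local filament tangent as its third column.

PARTICLE_COLUMNS <- c("particle_id", "filament_id", "x", "y", "z", "s",
                      "rot", "tilt", "psi", "class_label", "halfset")

#' Construct a particle set
#'
#' A `particle_set` is a `data.frame` with one row per oriented particle and
#' columns `particle_id`, `filament_id`, `x`, `y`, `z` (nm), `s` (arc length
#' along the filament, nm), `rot`, `tilt`, `psi` (ZYZ Euler angles, degrees),
#' `class_label` (zone name or `NA`) and `halfset` (`"A"`, `"B"` or `NA`).
#' Extra columns (e.g. a generator's `true_label`) are preserved.
#'
#' @param df data.frame carrying at least the coordinate and arc columns;
#'   missing metadata columns are filled with `NA`.
#' @return a `particle_set` (a classed data.frame).
#' @export
particle_set <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("filament_id", "x", "y", "z", "s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("particle_set: missing column(s): %s", paste(miss, collapse = ", "))
  if (!"particle_id" %in% names(df)) df$particle_id <- seq_len(nrow(df))
  for (col in c("rot", "tilt", "psi"))
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  if (!"class_label" %in% names(df))
    df$class_label <- rep(NA_character_, nrow(df))
  if (!"halfset" %in% names(df)) df$halfset <- rep(NA_character_, nrow(df))
  df$class_label <- as.character(df$class_label)
  df$halfset <- as.character(df$halfset)
  # within each filament arc position must be strictly increasing in stored order
  for (fid in unique(df$filament_id)) {
    s <- df$s[df$filament_id == fid]
    if (length(s) > 1 && any(diff(s) <= 0))
      stopf("particle_set: arc length not strictly increasing on filament %s", fid)
  }
  front <- intersect(PARTICLE_COLUMNS, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  class(df) <- c("particle_set", "data.frame")
  rownames(df) <- NULL
  df
}

#' @export
print.particle_set <- function(x, n = 6, ...) {
  cat(sprintf("particle_set: %d particles on %d filament(s)\n",
              nrow(x), length(unique(x$filament_id))))
  if (any(!is.na(x$class_label)))
    cat("  classes:", paste(names(table(x$class_label)), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat(sprintf("  ... %d more particles\n", nrow(x) - n))
  invisible(x)
}

is_particle_set <- function(x) inherits(x, "particle_set")

#' Rotation matrix from ZYZ Euler angles
#'
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`, angles in degrees. The third
#' column of `R` is the particle's Z axis (the local filament tangent).
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  a <- deg2rad(rot); b <- deg2rad(tilt); g <- deg2rad(psi)
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

#' ZYZ Euler angles (degrees) from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At the gimbal singularity (`tilt` 0 or
#' 180 degrees) `rot` is set to 0 and the in-plane angle absorbed into `psi`.
#'
#' @param R 3x3 proper rotation matrix.
#' @return named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  b <- acos(max(-1, min(1, R[3, 3])))
  if (sin(b) > 1e-9) {
    a <- atan2(R[2, 3], R[1, 3])
    g <- atan2(R[3, 2], -R[3, 1])
  } else {
    a <- 0
    g <- atan2(R[2, 1], R[1, 1]) * sign(R[3, 3])
  }
  c(rot = rad2deg(a), tilt = rad2deg(b), psi = rad2deg(g))
}

# Euler angles whose rotation matrix carries unit tangent `t` as third
# column, with in-plane angle psi (degrees) about the tangent.
euler_from_tangent <- function(tangent, psi) {
  t <- normalize(tangent)
  tilt <- rad2deg(acos(max(-1, min(1, t[3]))))
  rot <- if (abs(abs(t[3]) - 1) < 1e-12) 0 else rad2deg(atan2(t[2], t[1]))
  c(rot = rot, tilt = tilt, psi = psi)
}

#' Orientation matrix of one particle
#'
#' @param ps particle_set.
#' @param i row index.
#' @return 3x3 rotation matrix (third column = filament tangent).
#' @export
particle_rotation <- function(ps, i) {
  stopifnot(is_particle_set(ps), i >= 1, i <= nrow(ps))
  euler_to_matrix(ps$rot[i], ps$tilt[i], ps$psi[i])
}

#' A traced filament
#'
#' Ordered 3D control points of one manually traced filament, always stored
#' proximal to distal.
#'
#' @param filament_id identifier.
#' @param control_points numeric matrix (n x 3), nm.
#' @param polarity logical; `TRUE` when points run proximal to distal.
#' @return a `filament_trace` object.
#' @export
filament_trace <- function(filament_id, control_points, polarity = TRUE) {
  cp <- as.matrix(control_points)
  if (!is.numeric(cp) || ncol(cp) != 3)
    stopf("filament_trace: control_points must be an n x 3 numeric matrix")
  if (nrow(unique(cp)) < 2)
    stopf("filament_trace: need at least 2 distinct control points")
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  if (any(seg < .Machine$double.eps))
    stopf("filament_trace: consecutive control points coincide")
  structure(list(filament_id = filament_id, control_points = cp,
                 polarity = isTRUE(polarity)),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("filament_trace %s: %d control points, %s\n", x$filament_id,
              nrow(x$control_points),
              if (x$polarity) "proximal->distal" else "unknown polarity"))
  invisible(x)
}
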