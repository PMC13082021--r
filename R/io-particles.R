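# Particle I/O: RELION-dialect STAR, CSV, and IMOD model2point text.
# Coordinates are nm throughout; STAR Euler angles are ZYZ in degrees.

STAR_COLUMN_MAP <- c(
  x = "rlnCoordinateX", y = "rlnCoordinateY", z = "rlnCoordinateZ",
  rot = "rlnAngleRot", tilt = "rlnAngleTilt", psi = "rlnAnglePsi",
  filament_id = "rlnHelicalTubeID",
  particle_id = "cbParticleId", s = "cbArcLength",
  class_label = "cbClassLabel", halfset = "cbHalfset")

#' Write a particle set to a RELION-dialect STAR file
#'
#' One `data_particles` loop with RELION column names for coordinates
#' (nm), ZYZ Euler angles (degrees) and helical tube id, plus package
#' columns for arc length, class label and half-set. Numeric fields are
#' written at 6 significant digits, which round-trips through
#' [read_particles_star()].
#'
#' @param ps a [particle_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_particles_star <- function(ps, path) {
  stopifnot(is_particle_set(ps))
  cols <- names(STAR_COLUMN_MAP)
  lines <- c("# ciliabase particle set; coordinates nm, angles ZYZ degrees", "",
             "data_particles", "", "loop_",
             sprintf("_%s #%d", STAR_COLUMN_MAP, seq_along(STAR_COLUMN_MAP)))
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "<NA>", sprintf("%.6g", v))
    else ifelse(is.na(v), "<NA>", as.character(v))
  }
  body <- do.call(paste, c(lapply(cols, function(cc) fmt(ps[[cc]])), sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a RELION-dialect STAR particle file
#'
#' Parses the first `loop_` block. Missing angle columns yield
#' orientation-less particles with a warning; unknown columns are kept
#' under their STAR names.
#'
#' @param path STAR file path.
#' @return a [particle_set()].
#' @export
read_particles_star <- function(path) {
  if (!file.exists(path)) stopf("read_particles_star: no such file: %s", path)
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*#", raw)]
  loop_at <- which(trimws(raw) == "loop_")
  if (length(loop_at) == 0) stopf("read_particles_star: no loop_ block in %s", path)
  i <- loop_at[1] + 1
  star_names <- character(0)
  while (i <= length(raw) && grepl("^_", trimws(raw[i]))) {
    star_names <- c(star_names, sub("^_(\\S+).*$", "\\1", trimws(raw[i])))
    i <- i + 1
  }
  body <- raw[i:length(raw)]
  body <- body[nzchar(trimws(body))]
  body <- body[!grepl("^data_", trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != length(star_names))
  if (length(bad) > 0)
    stopf("read_particles_star: unparseable row at line %d of the loop body", bad[1])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- star_names
  tab[tab == "<NA>"] <- NA
  inv <- stats::setNames(names(STAR_COLUMN_MAP), STAR_COLUMN_MAP)
  known <- intersect(star_names, STAR_COLUMN_MAP)
  out <- stats::setNames(tab[, known, drop = FALSE], inv[known])
  for (cc in c("x", "y", "z", "s", "rot", "tilt", "psi"))
    if (cc %in% names(out)) out[[cc]] <- as.numeric(out[[cc]])
  for (cc in c("particle_id", "filament_id"))
    if (cc %in% names(out)) {
      v <- suppressWarnings(as.numeric(out[[cc]]))
      out[[cc]] <- if (all(is.na(v) == is.na(out[[cc]]))) v else out[[cc]]
    }
  if (!all(c("rot", "tilt", "psi") %in% names(out))) {
    warning("read_particles_star: angle columns missing; particles loaded without orientations")
  }
  if (!"s" %in% names(out)) {
    # fall back to cumulative chord length per filament
    out$s <- NA_real_
    for (fid in unique(out$filament_id)) {
      idx <- which(out$filament_id == fid)
      p <- as.matrix(out[idx, c("x", "y", "z")])
      out$s[idx] <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    }
  }
  extra <- setdiff(star_names, STAR_COLUMN_MAP)
  for (e in extra) out[[e]] <- tab[[e]]
  particle_set(out)
}

#' Write / read particle sets as CSV
#'
#' Plain CSV with the canonical particle columns (nm, degrees), 6
#' significant digits.
#'
#' @param ps a [particle_set()].
#' @param path file path.
#' @return `path` (writer, invisibly) or a [particle_set()] (reader).
#' @export
write_particles_csv <- function(ps, path) {
  stopifnot(is_particle_set(ps))
  out <- as.data.frame(ps)
  for (cc in names(out))
    if (is.numeric(out[[cc]])) out[[cc]] <- signif(out[[cc]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  if (!file.exists(path)) stopf("read_particles_csv: no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("class_label", "halfset"))
    if (cc %in% names(df)) df[[cc]][!nzchar(as.character(df[[cc]])) |
                                      is.na(df[[cc]])] <- NA
  particle_set(df)
}

#' Read IMOD model2point traces
#'
#' Parses `model2point -object` text output (`object contour x y z`, one
#' point per line, 1-based contours) into filament traces, one trace per
#' (object, contour); a 4-column file (`contour x y z`) is treated as a
#' single object. Coordinates are scaled by `pixel_size` to nm.
#'
#' @param path point file path.
#' @param pixel_size nm per pixel (default 1, coordinates already nm).
#' @return list of [filament_trace()] objects.
#' @export
read_imod_points <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stopf("read_imod_points: no such file: %s", path)
  tab <- tryCatch(utils::read.table(path), error = function(e)
    stopf("read_imod_points: cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(tab) == 4) tab <- cbind(V0 = 1, tab)
  if (ncol(tab) != 5)
    stopf("read_imod_points: expected 4 or 5 columns, found %d", ncol(tab))
  names(tab) <- c("object", "contour", "x", "y", "z")
  ids <- unique(tab[, c("object", "contour")])
  lapply(seq_len(nrow(ids)), function(i) {
    sel <- tab$object == ids$object[i] & tab$contour == ids$contour[i]
    filament_trace(
      filament_id = sprintf("obj%d_cont%d", ids$object[i], ids$contour[i]),
      control_points = as.matrix(tab[sel, c("x", "y", "z")]) * pixel_size)
  })
}

#' Read particles or traces with an explicit dialect
#'
#' Dispatcher over the supported particle dialects: `star` and `csv`
#' return a [particle_set()]; `imod_point` returns a list of
#' [filament_trace()]s (traces carry no orientations yet).
#'
#' @param path input file.
#' @param dialect one of `star`, `csv`, `imod_point`.
#' @param ... passed to the dialect reader.
#' @return a [particle_set()] or list of traces.
#' @export
read_particles <- function(path, dialect = c("star", "csv", "imod_point"), ...) {
  dialect <- match.arg(dialect)
  switch(dialect,
         star = read_particles_star(path),
         csv = read_particles_csv(path),
         imod_point = read_imod_points(path, ...))
}
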