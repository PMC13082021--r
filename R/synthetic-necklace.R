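# Synthetic ciliary-necklace lattice: periodic rows of intramembrane
# particles on a cylindrical membrane, with positional noise and dropout.

#' Parameter bundle for the synthetic ciliary necklace
#'
#' @param cylinder_radius membrane radius, nm. The measured in-row spacing
#'   of 17.5 nm with ~54 particles per row corresponds to a circumference
#'   of 945 nm (radius ~150.4 nm), the default.
#' @param n_rows number of circumferential rows (default 7).
#' @param row_spacing axial center-to-center row pitch, nm (default 17.5).
#' @param particles_per_row particles equally spaced around each row
#'   (default 54).
#' @param noise_sigma isotropic Gaussian positional noise, nm.
#' @param missing_fraction probability each particle is dropped.
#' @param seed integer RNG seed.
#' @return a `necklace_model` object.
#' @export
necklace_model <- function(cylinder_radius = 945 / (2 * pi), n_rows = 7,
                           row_spacing = 17.5, particles_per_row = 54,
                           noise_sigma = 0, missing_fraction = 0, seed = 1) {
  if (cylinder_radius <= 0) stopf("necklace_model: radius must be > 0")
  if (n_rows < 1) stopf("necklace_model: need n_rows >= 1")
  if (particles_per_row < 2) stopf("necklace_model: need particles_per_row >= 2")
  if (row_spacing <= 0) stopf("necklace_model: row_spacing must be > 0")
  if (missing_fraction < 0 || missing_fraction > 1)
    stopf("necklace_model: missing_fraction must lie in [0, 1]")
  if (noise_sigma < 0) stopf("necklace_model: noise_sigma must be >= 0")
  structure(list(cylinder_radius = cylinder_radius, n_rows = as.integer(n_rows),
                 row_spacing = row_spacing,
                 particles_per_row = as.integer(particles_per_row),
                 noise_sigma = noise_sigma, missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "necklace_model")
}

#' @export
print.necklace_model <- function(x, ...) {
  cat(sprintf(
    "necklace_model: %d rows x %d particles, pitch %g nm, radius %g nm (circumference %g nm)\n",
    x$n_rows, x$particles_per_row, x$row_spacing, x$cylinder_radius,
    2 * pi * x$cylinder_radius))
  invisible(x)
}

#' Generate a synthetic necklace particle cloud
#'
#' Rows are rings of equally spaced particles on a cylinder about the z
#' axis, separated axially by `row_spacing`; positions get isotropic
#' Gaussian noise and each particle is independently dropped with
#' `missing_fraction`. Each row draws from its own derived substream, so
#' the output is deterministic given the seed.
#'
#' @param model a [necklace_model()].
#' @return list with `cylinder` (axis point, direction, radius), `points`
#'   (data.frame `x`, `y`, `z` in nm plus ground-truth `row_id` and
#'   `index_in_row`), and `model`.
#' @export
gen_necklace <- function(model) {
  stopifnot(inherits(model, "necklace_model"))
  R <- model$cylinder_radius
  ppr <- model$particles_per_row
  pieces <- vector("list", model$n_rows)
  row_seeds <- substream_seeds(model$seed, model$n_rows)
  for (i in seq_len(model$n_rows)) {
    z0 <- (i - 1) * model$row_spacing
    theta <- 2 * pi * (seq_len(ppr) - 1) / ppr
    pts <- cbind(x = R * cos(theta), y = R * sin(theta), z = rep(z0, ppr))
    pts <- with_seed(row_seeds[i], {
      if (model$noise_sigma > 0)
        pts <- pts + matrix(stats::rnorm(3 * ppr, 0, model$noise_sigma), ppr, 3)
      keep <- stats::runif(ppr) >= model$missing_fraction
      cbind(pts[keep, , drop = FALSE], idx = which(keep))
    })
    if (nrow(pts) > 0)
      pieces[[i]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                row_id = i, index_in_row = pts[, 4])
  }
  points <- do.call(rbind, pieces)
  rownames(points) <- NULL
  list(cylinder = list(point = c(0, 0, 0), direction = c(0, 0, 1), radius = R),
       points = points, model = model)
}
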