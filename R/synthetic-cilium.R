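# Synthetic nine-filament ciliary barrel with zone-dependent diameter and
# noisy class labels: ground truth for the geometry and classification
# stages.

#' Default subzone model of the ciliary base
#'
#' Five ordered subzones, proximal to distal: proximal centriole (P), core
#' centriole (C), boundary/distal-ring region (B), transition zone (TZ) and
#' early axoneme (AX). Lengths and barrel diameters (nm) follow the
#' measured tomogram means for P/C/TZ and the diameters of all four
#' measured regions; the short boundary region and the simulated axoneme
#' length are free defaults (the axoneme continues far beyond the base).
#'
#' @return data.frame with columns `zone`, `length` (nm), `diameter` (nm).
#' @export
default_zones <- function() {
  data.frame(zone = c("P", "C", "B", "TZ", "AX"),
             length = c(205, 230, 30, 253, 300),
             diameter = c(215, 197, 190, 169, 178),
             stringsAsFactors = FALSE)
}

#' Parameter bundle for the synthetic ciliary barrel
#'
#' @param zones data.frame (`zone`, `length`, `diameter`), ordered proximal
#'   to distal; defaults to [default_zones()].
#' @param n_filaments number of microtubule filaments on the barrel
#'   (default 9).
#' @param step arc spacing of generated particles, nm (default 4).
#' @param label_noise fraction of particles whose observed label is flipped
#'   to a uniformly chosen different zone.
#' @param jitter_sigma isotropic Gaussian positional jitter, nm.
#' @param radius_smoothing window (nm) of the moving-average smoothing of
#'   the stepwise zone radius profile, so the barrel tapers continuously;
#'   0 disables smoothing.
#' @param seed integer RNG seed.
#' @return a `cilium_model` object.
#' @export
cilium_model <- function(zones = default_zones(), n_filaments = 9, step = 4,
                         label_noise = 0, jitter_sigma = 0,
                         radius_smoothing = 20, seed = 1) {
  zones <- as.data.frame(zones)
  if (nrow(zones) == 0) stopf("cilium_model: zone list is empty")
  need <- c("zone", "length", "diameter")
  if (!all(need %in% names(zones)))
    stopf("cilium_model: zones needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(zones$zone)) stopf("cilium_model: zone names must be unique")
  if (any(zones$length <= 0)) stopf("cilium_model: zone lengths must be > 0")
  if (any(zones$diameter <= 0)) stopf("cilium_model: zone diameters must be > 0")
  if (n_filaments < 3) stopf("cilium_model: need at least 3 filaments")
  if (step <= 0) stopf("cilium_model: step must be > 0")
  if (label_noise < 0 || label_noise > 1)
    stopf("cilium_model: label_noise must lie in [0, 1]")
  if (jitter_sigma < 0) stopf("cilium_model: jitter_sigma must be >= 0")
  structure(list(zones = zones, n_filaments = as.integer(n_filaments),
                 step = step, label_noise = label_noise,
                 jitter_sigma = jitter_sigma,
                 radius_smoothing = radius_smoothing,
                 seed = as.integer(seed)),
            class = "cilium_model")
}

#' @export
print.cilium_model <- function(x, ...) {
  cat(sprintf("cilium_model: %d filaments, %d zones (%s), total length %g nm, step %g nm\n",
              x$n_filaments, nrow(x$zones), paste(x$zones$zone, collapse = "/"),
              sum(x$zones$length), x$step))
  invisible(x)
}

# Smoothed barrel radius at axial positions z: moving average of the
# stepwise per-zone radius over a window, window clipped at the barrel ends.
zone_radius_profile <- function(z, zones, window = 0) {
  bounds <- c(0, cumsum(zones$length))
  radii <- zones$diameter / 2
  if (window <= 0) {
    idx <- pmin(findInterval(z, bounds, rightmost.closed = TRUE,
                             left.open = FALSE), nrow(zones))
    idx[idx < 1] <- 1
    return(radii[idx])
  }
  total <- bounds[length(bounds)]
  lo <- pmax(z - window / 2, 0)
  hi <- pmin(z + window / 2, total)
  out <- numeric(length(z))
  for (k in seq_len(nrow(zones))) {
    ov <- pmax(0, pmin(hi, bounds[k + 1]) - pmax(lo, bounds[k]))
    out <- out + ov * radii[k]
  }
  out / (hi - lo)
}

# True zone label at axial position z: half-open bins [start, end), last
# zone closed on the right.
zone_label_at <- function(z, zones) {
  bounds <- c(0, cumsum(zones$length))
  idx <- findInterval(z, bounds, rightmost.closed = TRUE, left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(zones))
  zones$zone[idx]
}

#' Generate a synthetic ciliary barrel particle set
#'
#' Places `n_filaments` straight generatrices evenly around the barrel; the
#' barrel radius follows the zone model (optionally smoothed over
#' `radius_smoothing` nm so the taper is continuous). Particles sit every
#' `step` nm of arc along each filament, carry the true zone label plus a
#' noisy observed label (`class_label`), a randomized in-plane angle, and
#' isotropic Gaussian positional jitter. Deterministic given the model
#' seed; each filament draws from its own derived substream.
#'
#' @param model a [cilium_model()].
#' @return a [particle_set()] with extra columns `true_label` and
#'   `phi` (the filament's azimuth, degrees); attribute `model` holds the
#'   generating model.
#' @export
gen_cilium <- function(model) {
  stopifnot(inherits(model, "cilium_model"))
  zones <- model$zones
  total <- sum(zones$length)
  s <- seq(0, total, by = model$step)
  r <- zone_radius_profile(s, zones, model$radius_smoothing)
  # tangent of the generatrix curve (dr/ds, 0, 1) in the filament's plane
  eps <- 1e-3
  drds <- (zone_radius_profile(pmin(s + eps, total), zones, model$radius_smoothing) -
           zone_radius_profile(pmax(s - eps, 0), zones, model$radius_smoothing)) /
    (pmin(s + eps, total) - pmax(s - eps, 0))
  truth <- zone_label_at(s, zones)
  pieces <- vector("list", model$n_filaments)
  fil_seeds <- substream_seeds(model$seed, model$n_filaments)
  for (j in seq_len(model$n_filaments)) {
    phi <- 2 * pi * (j - 1) / model$n_filaments
    out <- with_seed(fil_seeds[j], {
      n <- length(s)
      jit <- if (model$jitter_sigma > 0)
        matrix(stats::rnorm(3 * n, 0, model$jitter_sigma), n, 3) else matrix(0, n, 3)
      psi <- stats::runif(n, 0, 360)
      obs <- truth
      if (model$label_noise > 0 && nrow(zones) > 1) {
        flip <- stats::runif(n) < model$label_noise
        for (i in which(flip))
          obs[i] <- sample(setdiff(zones$zone, truth[i]), 1)
      }
      list(jit = jit, psi = psi, obs = obs)
    })
    ang <- t(vapply(seq_along(s), function(i) {
      tg <- normalize(c(drds[i] * cos(phi), drds[i] * sin(phi), 1))
      euler_from_tangent(tg, out$psi[i])
    }, numeric(3)))
    pieces[[j]] <- data.frame(
      filament_id = j,
      x = r * cos(phi) + out$jit[, 1],
      y = r * sin(phi) + out$jit[, 2],
      z = s + out$jit[, 3],
      s = s,
      rot = ang[, 1], tilt = ang[, 2], psi = ang[, 3],
      class_label = out$obs,
      true_label = truth,
      phi = rad2deg(phi),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pieces)
  df$particle_id <- seq_len(nrow(df))
  ps <- particle_set(df)
  attr(ps, "model") <- model
  ps
}
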