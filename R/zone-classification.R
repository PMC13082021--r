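# Zone classification: sharpen noisy per-particle class labels into
# contiguous, ordered ciliary subzones by nearest-neighbour voting plus
# ordering-constrained segmentation.

#' Ordered subzone naming
#'
#' @param zones zone names ordered proximal to distal (default
#'   `P, C, B, TZ, AX`: proximal centriole, core centriole, boundary
#'   region, transition zone, early axoneme).
#' @param optional_zones subset allowed to be empty on a filament; the
#'   short boundary region is optional by default.
#' @return a `zone_ordering` object.
#' @export
zone_ordering <- function(zones = c("P", "C", "B", "TZ", "AX"),
                          optional_zones = "B") {
  zones <- as.character(zones)
  if (length(zones) < 2) stopf("zone_ordering: need at least 2 zones")
  if (anyDuplicated(zones)) stopf("zone_ordering: zone names must be unique")
  if (!all(optional_zones %in% zones))
    stopf("zone_ordering: optional zones must come from the ordering")
  structure(list(zones = zones, optional_zones = as.character(optional_zones)),
            class = "zone_ordering")
}

#' @export
print.zone_ordering <- function(x, ...) {
  cat("zone_ordering:", paste(x$zones, collapse = " -> "))
  if (length(x$optional_zones) > 0)
    cat("  (optional:", paste(x$optional_zones, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Voting configuration for label reassignment
#'
#' @param window half-width of the 1D arc window on the particle's own
#'   filament, nm (default 8, about 5 particles at 4 nm spacing; the
#'   half-width must stay below half the shortest expected zone or the
#'   vote erodes it).
#' @param use_3d_neighbors vote among k nearest 3D neighbours across all
#'   filaments instead of the 1D arc window.
#' @param k neighbour count for the 3D mode (default 15).
#' @param max_iter maximum voting iterations (default 50).
#' @return a `voting_config` object.
#' @export
voting_config <- function(window = 8, use_3d_neighbors = FALSE, k = 15,
                          max_iter = 50) {
  if (!use_3d_neighbors && window <= 0) stopf("voting_config: window must be > 0")
  if (use_3d_neighbors && k < 1) stopf("voting_config: k must be >= 1")
  if (max_iter < 1) stopf("voting_config: max_iter must be >= 1")
  structure(list(window = window, use_3d_neighbors = isTRUE(use_3d_neighbors),
                 k = as.integer(k), max_iter = as.integer(max_iter)),
            class = "voting_config")
}

#' Reassign particle classes by neighbourhood voting
#'
#' Iterated synchronous majority vote: every particle takes the modal
#' label of its neighbourhood (itself included); on a tie the particle
#' keeps its current label, which guarantees a fixed point exists. The
#' neighbourhood is either all particles within `window` nm of arc on the
#' same filament (default) or the particle's `k` nearest 3D neighbours on
#' any filament. Iteration stops at a fixed point or after `max_iter`
#' rounds. The vote never invents labels absent from the input.
#'
#' @param ps a fully labelled [particle_set()].
#' @param cfg a [voting_config()].
#' @return the particle set with sharpened `class_label`s; attribute
#'   `iterations` records the rounds used.
#' @export
vote_reassign <- function(ps, cfg = voting_config()) {
  stopifnot(is_particle_set(ps), inherits(cfg, "voting_config"))
  labs <- ps$class_label
  if (any(is.na(labs))) stopf("vote_reassign: unlabelled particles present")
  n <- nrow(ps)
  levels <- sort(unique(labs))
  # neighbour lists are fixed across iterations
  if (cfg$use_3d_neighbors) {
    pos <- as.matrix(ps[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(pos))
    nb <- lapply(seq_len(n), function(i)
      order(d[i, ])[seq_len(min(cfg$k, n))])
  } else {
    nb <- vector("list", n)
    for (fid in unique(ps$filament_id)) {
      idx <- which(ps$filament_id == fid)
      s <- ps$s[idx]
      for (ii in seq_along(idx))
        nb[[idx[ii]]] <- idx[abs(s - s[ii]) <= cfg$window]
    }
  }
  lab_i <- match(labs, levels)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_i <- vapply(seq_len(n), function(i) {
      counts <- tabulate(lab_i[nb[[i]]], nbins = length(levels))
      m <- max(counts)
      winners <- which(counts == m)
      if (length(winners) == 1L) winners else lab_i[i]
    }, integer(1))
    if (identical(new_i, lab_i) || iter >= cfg$max_iter) {
      lab_i <- new_i
      break
    }
    lab_i <- new_i
  }
  ps$class_label <- levels[lab_i]
  attr(ps, "iterations") <- iter
  ps
}

# Dynamic-programming segmentation of one filament's label sequence into
# at most one contiguous segment per zone, in the prescribed order,
# minimizing the number of relabelled particles. Mandatory zones must be
# non-empty; optional zones may be skipped.
dp_segment <- function(labels, ordering) {
  K <- length(ordering$zones)
  n <- length(labels)
  opt <- ordering$zones %in% ordering$optional_zones
  obs <- match(labels, ordering$zones)
  # preds[[z]]: states allowed immediately before z at the previous particle
  preds <- lapply(seq_len(K), function(z) {
    p <- z
    zz <- z - 1
    while (zz >= 1) {
      p <- c(p, zz)
      if (!opt[zz]) break
      zz <- zz - 1
    }
    p
  })
  start_ok <- vapply(seq_len(K), function(z) z == 1 || all(opt[seq_len(z - 1)]),
                     logical(1))
  end_ok <- vapply(seq_len(K), function(z) z == K || all(opt[seq(z + 1, K)]),
                   logical(1))
  f <- matrix(Inf, n, K)
  ptr <- matrix(NA_integer_, n, K)
  cost <- function(i, z) as.numeric(obs[i] != z)
  f[1, start_ok] <- vapply(which(start_ok), function(z) cost(1, z), numeric(1))
  if (n > 1) for (i in 2:n) for (z in seq_len(K)) {
    cand <- f[i - 1, preds[[z]]]
    b <- which.min(cand)
    if (is.finite(cand[b])) {
      f[i, z] <- cand[b] + cost(i, z)
      ptr[i, z] <- preds[[z]][b]
    }
  }
  finals <- which(end_ok & is.finite(f[n, ]))
  if (length(finals) == 0) stopf("enforce_ordering: no admissible segmentation")
  z <- finals[which.min(f[n, finals])]
  path <- integer(n)
  path[n] <- z
  if (n > 1) for (i in n:2) path[i - 1] <- ptr[i, path[i]]
  list(labels = ordering$zones[path], cost = f[n, z])
}

#' Enforce the proximal-to-distal zone ordering
#'
#' Per filament, segments the particle sequence (ordered by arc length)
#' into at most one contiguous segment per zone in the prescribed order,
#' minimizing the number of particles whose label changes (dynamic
#' programming, exact). Mandatory zones get at least one particle;
#' `optional_zones` may vanish. The result is always monotone in the
#' ordering.
#'
#' @param ps a labelled [particle_set()].
#' @param ordering a [zone_ordering()].
#' @return the particle set with ordered contiguous labels; attribute
#'   `dp_cost` holds the per-filament relabelling counts.
#' @export
enforce_ordering <- function(ps, ordering = zone_ordering()) {
  stopifnot(is_particle_set(ps), inherits(ordering, "zone_ordering"))
  labs <- ps$class_label
  if (any(is.na(labs))) stopf("enforce_ordering: unlabelled particles present")
  bad <- setdiff(unique(labs), ordering$zones)
  if (length(bad) > 0)
    stopf("enforce_ordering: label(s) outside the ordering: %s",
          paste(bad, collapse = ", "))
  costs <- c()
  for (fid in unique(ps$filament_id)) {
    idx <- which(ps$filament_id == fid)
    idx <- idx[order(ps$s[idx])]
    res <- dp_segment(labs[idx], ordering)
    ps$class_label[idx] <- res$labels
    costs[as.character(fid)] <- res$cost
  }
  attr(ps, "dp_cost") <- costs
  ps
}

#' Count contiguous label segments per filament
#'
#' @param ps a labelled [particle_set()].
#' @return named integer vector: per filament, the number of maximal
#'   contiguous label runs along arc length (0 for an empty filament).
#' @export
count_segments <- function(ps) {
  stopifnot(is_particle_set(ps))
  fids <- unique(ps$filament_id)
  out <- integer(length(fids))
  names(out) <- as.character(fids)
  for (i in seq_along(fids)) {
    idx <- which(ps$filament_id == fids[i])
    idx <- idx[order(ps$s[idx])]
    out[i] <- if (length(idx) == 0) 0L else length(rle(ps$class_label[idx])$lengths)
  }
  out
}

#' Locate zone boundaries along each filament
#'
#' A boundary sits midway (in arc length) between the two particles that
#' flank a label change. Requires contiguous labels (post
#' [enforce_ordering()]).
#'
#' @param ps a labelled [particle_set()] with contiguous labels.
#' @return list with `per_filament` (data.frame `filament_id`, `from`,
#'   `to`, `position`) and `summary` (mean, SD and n per transition across
#'   filaments).
#' @export
zone_boundaries <- function(ps) {
  stopifnot(is_particle_set(ps))
  rows <- list()
  for (fid in unique(ps$filament_id)) {
    idx <- which(ps$filament_id == fid)
    idx <- idx[order(ps$s[idx])]
    labs <- ps$class_label[idx]
    if (any(is.na(labs))) stopf("zone_boundaries: unlabelled particles present")
    if (anyDuplicated(rle(labs)$values))
      stopf("zone_boundaries: labels not contiguous on filament %s", fid)
    ch <- which(labs[-1] != labs[-length(labs)])
    if (length(ch) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        filament_id = fid, from = labs[ch], to = labs[ch + 1],
        position = (ps$s[idx[ch]] + ps$s[idx[ch + 1]]) / 2,
        stringsAsFactors = FALSE)
  }
  per <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(filament_id = character(0), from = character(0),
               to = character(0), position = numeric(0))
  rownames(per) <- NULL
  summ <- if (nrow(per) > 0) {
    key <- paste(per$from, per$to, sep = "->")
    agg <- lapply(unique(key), function(k) {
      p <- per$position[key == k]
      data.frame(transition = k, mean = mean(p),
                 sd = if (length(p) > 1) stats::sd(p) else NA_real_,
                 n = length(p), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  } else data.frame(transition = character(0), mean = numeric(0),
                    sd = numeric(0), n = integer(0))
  list(per_filament = per, summary = summ)
}
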