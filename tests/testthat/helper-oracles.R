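# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they check the package implementations from a
# different angle.

# Exact points on a cylinder surface about an arbitrary axis.
cylinder_points <- function(radius, n = 60, height = 30, seed = 1,
                            axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- ref - sum(ref * axis) * axis
  p <- p / sqrt(sum(p^2))
  q <- c(axis[2] * p[3] - axis[3] * p[2],
         axis[3] * p[1] - axis[1] * p[3],
         axis[1] * p[2] - axis[2] * p[1])
  h <- runif(n, 0, height)
  a <- runif(n, 0, 2 * pi)
  t(vapply(seq_len(n), function(i)
    origin + h[i] * axis + radius * (cos(a[i]) * p + sin(a[i]) * q),
    numeric(3)))
}

# Brute-force greedy distance cleaning, written independently of the
# package (index arithmetic instead of matrix accumulation).
oracle_greedy_clean <- function(pos, min_dist) {
  kept <- integer(0)
  for (i in seq_len(nrow(pos))) {
    ok <- TRUE
    for (j in kept) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_dist) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Exhaustive ordered segmentation: enumerates every placement of zone
# boundaries (zones in fixed order, optional zones may be empty) and
# returns the minimum number of label changes. Feasible for <= ~15
# particles and <= 5 zones.
oracle_best_segmentation <- function(labels, zones, optional) {
  n <- length(labels)
  K <- length(zones)
  best <- Inf
  # boundaries b[1] <= ... <= b[K-1] in 0..n; segment k = (b[k-1], b[k]]
  recurse <- function(k, lo, bounds) {
    if (k == K) {
      b <- c(0, bounds, n)
      lens <- diff(b)
      if (any(lens == 0 & !(zones %in% optional))) return()
      cost <- 0
      for (z in seq_len(K)) {
        if (lens[z] > 0) {
          seg <- labels[(b[z] + 1):b[z + 1]]
          cost <- cost + sum(seg != zones[z])
        }
      }
      best <<- min(best, cost)
      return()
    }
    for (b in lo:n) recurse(k + 1, b, c(bounds, b))
  }
  recurse(1, 0, integer(0))
  best
}

# Brute-force restraint satisfaction from a plain coordinate lookup.
oracle_satisfaction <- function(links, sm, cutoff) {
  n_map <- 0; n_sat <- 0
  for (i in seq_len(nrow(links))) {
    ca <- sm[sm$protein == links$protein_a[i] & sm$residue == links$residue_a[i], ]
    cb <- sm[sm$protein == links$protein_b[i] & sm$residue == links$residue_b[i], ]
    if (nrow(ca) == 0 || nrow(cb) == 0) next
    dmin <- Inf
    for (ii in seq_len(nrow(ca))) for (jj in seq_len(nrow(cb))) {
      if (ca$chain[ii] == cb$chain[jj] && ca$residue[ii] == cb$residue[jj]) next
      dd <- sqrt((ca$x[ii] - cb$x[jj])^2 + (ca$y[ii] - cb$y[jj])^2 +
                   (ca$z[ii] - cb$z[jj])^2)
      dmin <- min(dmin, dd)
    }
    if (!is.finite(dmin)) next
    n_map <- n_map + 1
    if (dmin <= cutoff) n_sat <- n_sat + 1
  }
  list(n_mapped = n_map, fraction = if (n_map > 0) n_sat / n_map else NA_real_)
}

# Minimal single-model PDB text for structure-reading tests.
write_toy_pdb <- function(path, atoms) {
  # atoms: data.frame chain, resno, x, y, z, elety (default CA), altloc, occ
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %4s%1sALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, sprintf(" %-3s", a$elety %||% "CA"),
            a$altloc %||% " ", a$chain, a$resno, a$x, a$y, a$z,
            a$occ %||% 1.00, 0.00)
  }, character(1))
  writeLines(c(lines, "END"), path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Rigid motion helpers for equivariance checks.
rotation_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

apply_rigid <- function(ps, R, tvec) {
  pos <- as.matrix(ps[, c("x", "y", "z")]) %*% t(R)
  ps$x <- pos[, 1] + tvec[1]
  ps$y <- pos[, 2] + tvec[2]
  ps$z <- pos[, 3] + tvec[3]
  ps
}

link_key_df <- function(df)
  paste(df$protein_a, df$residue_a, df$protein_b, df$residue_b)
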