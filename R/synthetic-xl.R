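# Synthetic cross-linking MS inputs: idealized structures with known
# inter-residue distances, and paired search-engine result tables with
# planted true links and decoys.

#' Construct a structure map
#'
#' A `structure_map` is the (protein, residue) -> Calpha coordinate lookup
#' used for distance-restraint mapping: a data.frame with columns
#' `protein`, `chain`, `residue` (1-based) and `x`, `y`, `z` in Angstrom.
#' A protein may appear on several chains (homomers); distance lookups
#' then take the minimum over chain combinations.
#'
#' @param df data.frame with the columns above.
#' @return a `structure_map`.
#' @export
structure_map <- function(df) {
  need <- c("protein", "chain", "residue", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("structure_map: missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$residue < 1)) stopf("structure_map: residues are 1-based")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stopf("structure_map: coordinates must be finite")
  if (anyDuplicated(df[, c("chain", "residue")]))
    stopf("structure_map: one coordinate per (chain, residue)")
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  class(df) <- c("structure_map", "data.frame")
  rownames(df) <- NULL
  df
}

#' @export
print.structure_map <- function(x, ...) {
  cat(sprintf("structure_map: %d residues, %d protein(s), %d chain(s)\n",
              nrow(x), length(unique(x$protein)), length(unique(x$chain))))
  invisible(x)
}

#' Generate an idealized multi-chain Calpha trace
#'
#' Straight parallel chains with a constant inter-residue rise; every
#' (chain, residue) maps to exactly one coordinate, and all inter-residue
#' distances are known in closed form, which makes the map a convenient
#' ground truth for restraint-satisfaction tests.
#'
#' @param n_chains number of chains (each its own protein `P1`, `P2`, ...).
#' @param n_res residues per chain.
#' @param rise inter-residue rise in nm (default 0.38, the Calpha virtual
#'   bond length).
#' @param chain_offset lateral offset between neighbouring chains, nm.
#' @return a [structure_map()] (coordinates in Angstrom).
#' @export
gen_structure <- function(n_chains, n_res, rise = 0.38, chain_offset = 2) {
  if (n_chains < 1) stopf("gen_structure: need n_chains >= 1")
  if (n_res < 2) stopf("gen_structure: need n_res >= 2")
  grid <- expand.grid(residue = seq_len(n_res), ci = seq_len(n_chains))
  structure_map(data.frame(
    protein = paste0("P", grid$ci),
    chain = LETTERS[(grid$ci - 1) %% 26 + 1],
    residue = grid$residue,
    x = (grid$ci - 1) * chain_offset * 10,
    y = 0,
    z = (grid$residue - 1) * rise * 10,
    stringsAsFactors = FALSE))
}

#' Parameter bundle for simulated cross-link searches
#'
#' @param n_true number of planted true links (residue pairs within the
#'   linker span).
#' @param n_decoy number of planted decoys (pairs beyond the span that an
#'   engine may nevertheless report).
#' @param cutoff linker Calpha-Calpha span in Angstrom (default 35, the
#'   DSSO-compatible restraint).
#' @param engine_detect_prob length-2 vector: per-engine probability that a
#'   true link is reported.
#' @param decoy_rate length-2 vector: per-engine probability that a decoy
#'   is reported.
#' @param seed integer RNG seed.
#' @return an `xl_sim_model` object.
#' @export
xl_sim_model <- function(n_true = 100, n_decoy = 20, cutoff = 35,
                         engine_detect_prob = c(0.9, 0.8),
                         decoy_rate = c(0.02, 0.02), seed = 1) {
  if (cutoff <= 0) stopf("xl_sim_model: cutoff must be > 0")
  engine_detect_prob <- rep_len(engine_detect_prob, 2)
  decoy_rate <- rep_len(decoy_rate, 2)
  if (any(engine_detect_prob < 0 | engine_detect_prob > 1) ||
      any(decoy_rate < 0 | decoy_rate > 1))
    stopf("xl_sim_model: probabilities must lie in [0, 1]")
  structure(list(n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
                 cutoff = cutoff, engine_detect_prob = engine_detect_prob,
                 decoy_rate = decoy_rate, seed = as.integer(seed)),
            class = "xl_sim_model")
}

# All unordered residue pairs of a structure map with their minimum
# Calpha-Calpha distance (Angstrom). Used by the generator on small maps.
all_residue_pairs <- function(sm) {
  d <- as.matrix(stats::dist(sm[, c("x", "y", "z")]))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(protein_a = sm$protein[idx[, 1]], residue_a = sm$residue[idx[, 1]],
                      protein_b = sm$protein[idx[, 2]], residue_b = sm$residue[idx[, 2]],
                      distance = d[idx], stringsAsFactors = FALSE)
  # same (protein, residue) on two chains is the same link target: drop
  # self-pairs and keep the minimum distance per residue pair
  pairs <- pairs[!(pairs$protein_a == pairs$protein_b &
                     pairs$residue_a == pairs$residue_b), , drop = FALSE]
  pairs <- canonicalize_links(pairs)
  k <- link_key(pairs)
  ord <- order(k, pairs$distance)
  pairs <- pairs[ord, , drop = FALSE]
  pairs[!duplicated(link_key(pairs)), , drop = FALSE]
}

#' Simulate two cross-link search-engine result tables
#'
#' Plants `n_true` residue pairs drawn from pairs within the linker span on
#' `structure` and `n_decoy` pairs from beyond it. Each of two engines
#' reports each true link with its `engine_detect_prob` and each decoy with
#' its `decoy_rate`, with per-record scores and CSM-FDR values below the
#' conventional reporting cutoffs. A truth table labels every emitted
#' record.
#'
#' @param model an [xl_sim_model()].
#' @param structure a [structure_map()].
#' @return list with `engine_a`, `engine_b` (data.frames in the engine
#'   table schema `protein_a,residue_a,protein_b,residue_b,score,csm_fdr`),
#'   `truth` (all emitted records with `is_true`), `planted` (the planted
#'   true link set) and `model`.
#' @export
gen_crosslinks <- function(model, structure) {
  stopifnot(inherits(model, "xl_sim_model"), inherits(structure, "structure_map"))
  if (nrow(structure) == 0) stopf("gen_crosslinks: empty structure")
  pairs <- all_residue_pairs(structure)
  near <- pairs[pairs$distance <= model$cutoff, , drop = FALSE]
  far <- pairs[pairs$distance > model$cutoff, , drop = FALSE]
  if (nrow(near) == 0)
    stopf("gen_crosslinks: no residue pair within the %g A cutoff", model$cutoff)
  if (nrow(near) < model$n_true)
    stopf("gen_crosslinks: only %d pairs within cutoff, %d requested",
          nrow(near), model$n_true)
  if (nrow(far) < model$n_decoy)
    stopf("gen_crosslinks: only %d pairs beyond cutoff, %d decoys requested",
          nrow(far), model$n_decoy)
  with_seed(model$seed, {
    true_set <- near[sample.int(nrow(near), model$n_true), , drop = FALSE]
    decoy_set <- if (model$n_decoy > 0)
      far[sample.int(nrow(far), model$n_decoy), , drop = FALSE]
    else far[0, , drop = FALSE]
    emit <- function(engine_idx) {
      keep_t <- stats::runif(nrow(true_set)) < model$engine_detect_prob[engine_idx]
      keep_d <- if (nrow(decoy_set) > 0)
        stats::runif(nrow(decoy_set)) < model$decoy_rate[engine_idx] else logical(0)
      tab <- rbind(
        cbind(true_set[keep_t, , drop = FALSE], is_true = TRUE),
        cbind(decoy_set[keep_d, , drop = FALSE], is_true = rep(FALSE, sum(keep_d))))
      n <- nrow(tab)
      tab$score <- ifelse(tab$is_true, stats::rnorm(n, 30, 5), stats::rnorm(n, 15, 5))
      tab$csm_fdr <- stats::runif(n, 0, 0.009)
      tab$engine <- c("engineA", "engineB")[engine_idx]
      tab$distance <- NULL
      rownames(tab) <- NULL
      tab[, c("protein_a", "residue_a", "protein_b", "residue_b",
              "score", "csm_fdr", "engine", "is_true"), drop = FALSE]
    }
    a <- emit(1L)
    b <- emit(2L)
    truth <- rbind(a, b)
    truth <- truth[!duplicated(link_key(truth)),
                   c("protein_a", "residue_a", "protein_b", "residue_b", "is_true"),
                   drop = FALSE]
    rownames(truth) <- NULL
    planted <- true_set[, c("protein_a", "residue_a", "protein_b", "residue_b",
                            "distance"), drop = FALSE]
    rownames(planted) <- NULL
    list(engine_a = a[, setdiff(names(a), "is_true"), drop = FALSE],
         engine_b = b[, setdiff(names(b), "is_true"), drop = FALSE],
         truth = truth, planted = planted, model = model)
  })
}
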