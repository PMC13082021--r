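# XL/MS interactome: per-engine filtering, two-engine consensus, network
# statistics, and distance-restraint mapping onto coordinate models.

XL_COLUMNS <- c("protein_a", "residue_a", "protein_b", "residue_b",
                "score", "csm_fdr")

link_key <- function(df)
  paste(df$protein_a, df$residue_a, df$protein_b, df$residue_b, sep = "|")

ppi_key <- function(df) paste(df$protein_a, df$protein_b, sep = "|")

#' Canonicalize cross-link records
#'
#' Orders each record's endpoints so that `(protein_a, residue_a)` is
#' lexicographically no greater than `(protein_b, residue_b)`; unordered
#' residue pairs then have a unique representation.
#'
#' @param df data.frame with `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b` (plus any other columns, preserved).
#' @return the canonicalized data.frame.
#' @export
canonicalize_links <- function(df) {
  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$residue_a > df$residue_b)
  if (any(swap)) {
    pa <- df$protein_a[swap]; ra <- df$residue_a[swap]
    df$protein_a[swap] <- df$protein_b[swap]
    df$residue_a[swap] <- df$residue_b[swap]
    df$protein_b[swap] <- pa
    df$residue_b[swap] <- ra
  }
  df
}

#' Load and filter a search-engine cross-link table
#'
#' Reads an engine export (CSV or data.frame) with columns `protein_a`,
#' `residue_a`, `protein_b`, `residue_b`, `score`, `csm_fdr`, keeps
#' records at or below the CSM-level FDR cutoff, canonicalizes endpoint
#' order and de-duplicates at the residue-pair level keeping the best
#' score. Conventional cutoffs are 1% for the primary engine and 5% for
#' the secondary one.
#'
#' @param x path to a CSV file, or a data.frame.
#' @param engine engine tag stored with each record.
#' @param fdr_cutoff CSM FDR cutoff as a fraction (default 0.01).
#' @return canonical, de-duplicated data.frame of records with an
#'   `engine` column.
#' @export
load_engine_table <- function(x, engine, fdr_cutoff = 0.01) {
  if (is.character(x) && !file.exists(x))
    stopf("load_engine_table: no such file: %s", x)
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else
    as.data.frame(x)
  miss <- setdiff(XL_COLUMNS, names(df))
  if (length(miss) > 0)
    stopf("load_engine_table: missing column(s): %s", paste(miss, collapse = ", "))
  ra <- suppressWarnings(as.numeric(df$residue_a))
  rb <- suppressWarnings(as.numeric(df$residue_b))
  bad <- is.na(ra) | is.na(rb) | ra < 1 | rb < 1 | ra != round(ra) | rb != round(rb)
  if (any(bad)) {
    warning(sprintf("load_engine_table: dropped %d row(s) with malformed residues",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
    ra <- ra[!bad]; rb <- rb[!bad]
  }
  df$residue_a <- as.integer(ra)
  df$residue_b <- as.integer(rb)
  df <- df[df$csm_fdr <= fdr_cutoff, , drop = FALSE]
  df <- canonicalize_links(df)
  df <- df[order(link_key(df), -df$score), , drop = FALSE]
  df <- df[!duplicated(link_key(df)), , drop = FALSE]
  df$engine <- engine
  rownames(df) <- NULL
  df
}

#' Two-engine consensus cross-link set
#'
#' The consensus keeps links whose canonical residue-pair identity appears
#' in both engines' filtered tables; each kept link is annotated with both
#' engines' scores. The operation is commutative, idempotent and monotone.
#' At `level = "protein"` a link of engine A is kept when its protein pair
#' appears in engine B (coarser, for engines with divergent residue-level
#' localization).
#'
#' @param a,b canonical record sets from [load_engine_table()].
#' @param level `"residue"` (default) or `"protein"`.
#' @return consensus data.frame with `score_a`, `score_b`.
#' @export
xl_consensus <- function(a, b, level = c("residue", "protein")) {
  level <- match.arg(level)
  a <- canonicalize_links(as.data.frame(a))
  b <- canonicalize_links(as.data.frame(b))
  if (level == "residue") {
    keep <- link_key(a) %in% link_key(b)
    out <- a[keep, , drop = FALSE]
    out$score_a <- out$score
    out$score_b <- b$score[match(link_key(out), link_key(b))]
    out$csm_fdr_b <- b$csm_fdr[match(link_key(out), link_key(b))]
  } else {
    keep <- ppi_key(a) %in% ppi_key(b)
    out <- a[keep, , drop = FALSE]
    out$score_a <- out$score
    out$score_b <- NA_real_
  }
  out$engine <- NULL
  rownames(out) <- NULL
  out
}

#' Interactome network statistics
#'
#' Counts unique residue-level links, distinct proteins, and
#' protein-protein interactions (distinct unordered pairs of *different*
#' proteins; homotypic pairs are excluded by default), and builds the
#' protein-pair interaction graph with per-edge support counts.
#'
#' @param links canonical link data.frame.
#' @param include_homotypic count same-protein pairs as PPIs (default
#'   `FALSE`).
#' @return list with `stats` (named vector `n_unique_links`, `n_proteins`,
#'   `n_ppi`), `edges` (data.frame `protein_a`, `protein_b`, `n_links`)
#'   and `network` (an igraph graph).
#' @export
network_stats <- function(links, include_homotypic = FALSE) {
  links <- canonicalize_links(as.data.frame(links))
  links <- links[!duplicated(link_key(links)), , drop = FALSE]
  n_links <- nrow(links)
  prots <- unique(c(links$protein_a, links$protein_b))
  hetero <- links[links$protein_a != links$protein_b, , drop = FALSE]
  ppi_links <- if (include_homotypic) links else hetero
  pk <- unique(ppi_key(ppi_links))
  edges <- if (nrow(links) > 0) {
    tab <- table(ppi_key(ppi_links))
    sp <- strsplit(names(tab), "|", fixed = TRUE)
    data.frame(protein_a = vapply(sp, `[`, "", 1),
               protein_b = vapply(sp, `[`, "", 2),
               n_links = as.integer(tab), stringsAsFactors = FALSE)
  } else data.frame(protein_a = character(0), protein_b = character(0),
                    n_links = integer(0))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = prots, stringsAsFactors = FALSE))
  list(stats = c(n_unique_links = n_links, n_proteins = length(prots),
                 n_ppi = length(pk)),
       edges = edges, network = g)
}

#' Map cross-links onto a coordinate model
#'
#' A link is mapped iff both of its (protein, residue) endpoints resolve
#' in the structure map; its distance is the Euclidean Calpha-Calpha
#' distance in Angstrom, taking the minimum over chain combinations when a
#' protein occurs on several chains (homodimeric ambiguity).
#'
#' @param links canonical link data.frame.
#' @param sm a [structure_map()].
#' @return the links with added `distance` (Angstrom, `NA` when unmapped)
#'   and `mapped` columns.
#' @export
map_links <- function(links, sm) {
  stopifnot(inherits(sm, "structure_map"))
  links <- as.data.frame(links)
  sm_key <- paste(sm$protein, sm$residue, sep = "|")
  dist_one <- function(pa, ra, pb, rb) {
    ia <- which(sm_key == paste(pa, ra, sep = "|"))
    ib <- which(sm_key == paste(pb, rb, sep = "|"))
    if (length(ia) == 0 || length(ib) == 0) return(NA_real_)
    dmin <- Inf
    for (i in ia) for (j in ib) {
      if (i == j) next  # same atom: self-pair on the same chain copy
      dd <- sqrt(sum((c(sm$x[i], sm$y[i], sm$z[i]) -
                        c(sm$x[j], sm$y[j], sm$z[j]))^2))
      if (dd < dmin) dmin <- dd
    }
    if (is.finite(dmin)) dmin else NA_real_
  }
  links$distance <- vapply(seq_len(nrow(links)), function(i)
    dist_one(links$protein_a[i], links$residue_a[i],
             links$protein_b[i], links$residue_b[i]), numeric(1))
  links$mapped <- !is.na(links$distance)
  links
}

#' Distance-restraint satisfaction
#'
#' Fraction of mapped links whose Calpha-Calpha distance lies within the
#' linker restraint (35 Angstrom for DSSO). Unmapped links are excluded
#' from the denominator; with zero mapped links the fraction is `NA`, an
#' explicit sentinel rather than 0.
#'
#' @param distances numeric vector of distances (Angstrom, `NA` for
#'   unmapped) or the data.frame from [map_links()].
#' @param cutoff restraint in Angstrom (default 35).
#' @return list with `n_mapped`, `n_satisfied`, `fraction`.
#' @export
restraint_satisfaction <- function(distances, cutoff = 35) {
  if (cutoff <= 0) stopf("restraint_satisfaction: cutoff must be > 0")
  d <- if (is.data.frame(distances)) distances$distance else as.numeric(distances)
  d <- d[!is.na(d)]
  n_sat <- sum(d <= cutoff)
  list(n_mapped = length(d), n_satisfied = n_sat,
       fraction = if (length(d) == 0) NA_real_ else n_sat / length(d))
}

#' Proteins cross-linked to tubulin
#'
#' @param links canonical link data.frame.
#' @param tubulin_ids nonempty set of tubulin protein identifiers.
#' @return character vector of partner proteins with at least one link to
#'   any tubulin id, excluding the tubulin ids themselves.
#' @export
tubulin_partners <- function(links, tubulin_ids) {
  if (length(tubulin_ids) == 0) stopf("tubulin_partners: tubulin_ids is empty")
  links <- as.data.frame(links)
  hit_a <- links$protein_a %in% tubulin_ids
  hit_b <- links$protein_b %in% tubulin_ids
  partners <- c(links$protein_b[hit_a], links$protein_a[hit_b])
  sort(setdiff(unique(partners), tubulin_ids))
}

#' Lumen/exterior topology call per tubulin partner
#'
#' Cross-link positions on tubulin discriminate microtubule inner proteins
#' from surface-associated ones: a partner is called `lumen` when all
#' tubulin-side residues it cross-links to are annotated lumenal,
#' `exterior` when all are exterior, `mixed` when both occur, and
#' `unknown` otherwise.
#'
#' @param links canonical link data.frame.
#' @param annotation data.frame `protein`, `residue`, `topology`
#'   (`lumen`, `exterior` or `unknown`) for tubulin residues.
#' @param tubulin_ids tubulin protein identifiers.
#' @return data.frame `partner`, `topology`.
#' @export
topology_call <- function(links, annotation, tubulin_ids) {
  links <- as.data.frame(links)
  ann_key <- paste(annotation$protein, annotation$residue, sep = "|")
  partners <- tubulin_partners(links, tubulin_ids)
  calls <- vapply(partners, function(p) {
    sel_a <- links$protein_a == p & links$protein_b %in% tubulin_ids
    sel_b <- links$protein_b == p & links$protein_a %in% tubulin_ids
    tub_res <- c(paste(links$protein_b[sel_a], links$residue_b[sel_a], sep = "|"),
                 paste(links$protein_a[sel_b], links$residue_a[sel_b], sep = "|"))
    topo <- annotation$topology[match(tub_res, ann_key)]
    topo[is.na(topo)] <- "unknown"
    if (all(topo == "lumen")) "lumen"
    else if (all(topo == "exterior")) "exterior"
    else if (any(topo == "lumen") && any(topo == "exterior")) "mixed"
    else "unknown"
  }, character(1))
  data.frame(partner = partners, topology = unname(calls),
             stringsAsFactors = FALSE)
}
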