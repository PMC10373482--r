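# Molecular and molecular-crystal graph construction: cutoff-radius edges,
# zeroth-order spherical Bessel radial embeddings, and the periodic
# feature-overwrite primitive.

#' Graph construction configuration
#'
#' @param r_c Convolution cutoff radius in Angstrom (default 6).
#' @param n_basis Number of radial basis functions (default 32).
#' @param inter_edge_mode When the discriminator uses intermolecular edges:
#'   `"final_layer_only"` (default; all earlier layers intramolecular) or
#'   `"all_layers"`.
#' @param N Supercell dimension (odd, default 3).
#' @return Object of class `graph_config`.
#' @export
graph_config <- function(r_c = 6, n_basis = 32,
                         inter_edge_mode = c("final_layer_only", "all_layers"),
                         N = 3) {
  inter_edge_mode <- match.arg(inter_edge_mode)
  if (r_c <= 0) stop("r_c must be positive")
  if (n_basis < 1) stop("n_basis must be at least 1")
  structure(list(r_c = r_c, n_basis = n_basis,
                 inter_edge_mode = inter_edge_mode, N = N),
            class = "graph_config")
}

#' Radial Bessel edge embedding
#'
#' Zeroth-order spherical Bessel basis on `(0, r_c]`: component `n` equals
#' `sqrt(2 / r_c) * sin(n * pi * d / r_c) / d`.  The basis vanishes at
#' `d = r_c`, so no additional polynomial envelope is applied (a toggle is
#' deliberately not exposed: edges do not exist beyond the cutoff).
#'
#' @param d Numeric vector of distances, each in `(0, r_c]`.
#' @param config A [graph_config()].
#' @return Matrix `length(d) x n_basis`.
#' @export
radial_embedding <- function(d, config = graph_config()) {
  if (any(d <= 0)) stop("distances must be positive")
  if (any(d > config$r_c + 1e-12)) stop("distance exceeds cutoff r_c")
  n <- seq_len(config$n_basis)
  sqrt(2 / config$r_c) * sin(outer(d, n) * pi / config$r_c) / d
}

new_crystal_graph <- function(src, tgt, dist, type, n_nodes, canonical_nodes,
                              symmetry_map, config) {
  emb <- if (length(dist)) radial_embedding(dist, config) else
    matrix(0, 0, config$n_basis)
  structure(list(
    n_nodes = n_nodes,
    edges = data.frame(src = as.integer(src), tgt = as.integer(tgt),
                       dist = as.numeric(dist), type = as.character(type),
                       stringsAsFactors = FALSE),
    embeddings = emb,
    canonical_nodes = canonical_nodes,
    symmetry_map = symmetry_map,
    config = config
  ), class = "crystal_graph")
}

#' @export
print.crystal_graph <- function(x, ...) {
  cat(sprintf("<crystal_graph: %d nodes, %d intra + %d inter edges>\n",
              x$n_nodes, sum(x$edges$type == "intra"),
              sum(x$edges$type == "inter")))
  invisible(x)
}

# all directed pairs within r_c between row sets A (sources) and B (targets);
# exact all-pairs scan, adequate at desk scale
pairs_within <- function(A, B, r_c, exclude_equal_index = FALSE) {
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(list(src = integer(0), tgt = integer(0), dist = numeric(0)))
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- d2 <= r_c^2 + 1e-12
  if (exclude_equal_index) diag(hit) <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  list(src = idx[, 1], tgt = idx[, 2], dist = sqrt(d2[hit]))
}

#' Build the graph of an isolated molecule
#'
#' Directed edges both ways between every atom pair within the cutoff; no
#' self-edges.
#'
#' @param mol A featurized [molecule_record()].
#' @param config A [graph_config()].
#' @return A `crystal_graph` whose edges are all intramolecular.
#' @export
build_molecule_graph <- function(mol, config = graph_config()) {
  n <- nrow(mol$coords)
  if (n < 1) stop("empty molecule")
  p <- pairs_within(mol$coords, mol$coords, config$r_c,
                    exclude_equal_index = TRUE)
  new_crystal_graph(p$src, p$tgt, p$dist,
                    rep("intra", length(p$src)), n,
                    canonical_nodes = seq_len(n),
                    symmetry_map = seq_len(n), config)
}

#' Build the molecular-crystal graph from a labeled supercell
#'
#' Intramolecular edges run both ways among canonical-conformer (label-0)
#' atoms; intermolecular edges run strictly outside-in, from label-1 atoms
#' to label-0 atoms within the cutoff.  Label-2 atoms were discarded during
#' supercell construction and never appear.
#'
#' @param supercell A [build_supercell()] result.
#' @param config A [graph_config()].
#' @return A `crystal_graph`; node indices refer to rows of
#'   `supercell$coords`.
#' @export
build_crystal_graph <- function(supercell, config = graph_config()) {
  can <- which(supercell$labels == 0L)
  img <- which(supercell$labels == 1L)
  if (!length(can)) stop("supercell has no canonical (label-0) atoms")
  Xc <- supercell$coords[can, , drop = FALSE]
  Xi <- supercell$coords[img, , drop = FALSE]
  intra <- pairs_within(Xc, Xc, config$r_c, exclude_equal_index = TRUE)
  inter <- pairs_within(Xi, Xc, config$r_c)
  new_crystal_graph(
    src = c(can[intra$src], img[inter$src]),
    tgt = c(can[intra$tgt], can[inter$tgt]),
    dist = c(intra$dist, inter$dist),
    type = c(rep("intra", length(intra$src)), rep("inter", length(inter$src))),
    n_nodes = nrow(supercell$coords),
    canonical_nodes = can,
    symmetry_map = supercell$symmetry_map,
    config = config
  )
}

#' Overwrite symmetry-image node states from the canonical conformer
#'
#' After each node update, every label-1 atom's state is replaced by the
#' state of its canonical-conformer counterpart, enforcing periodicity: the
#' result equals a convolution on the infinite crystal graph.  Idempotent.
#'
#' @param node_states Numeric matrix, one row per supercell node.
#' @param symmetry_map Integer vector mapping every node to its canonical
#'   atom's row (identity on canonical atoms).
#' @return The overwritten state matrix.
#' @export
periodic_overwrite <- function(node_states, symmetry_map) {
  if (length(symmetry_map) != nrow(node_states)) {
    stop("symmetry_map length must equal the node count")
  }
  if (any(symmetry_map < 1 | symmetry_map > nrow(node_states))) {
    stop("symmetry_map contains unmapped nodes")
  }
  node_states[symmetry_map, , drop = FALSE]
}

#' Serialize a graph's edge list to a table
#'
#' @param graph A `crystal_graph`.
#' @return Data frame with source, target, distance and edge type.
#' @export
graph_edge_table <- function(graph) graph$edges
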