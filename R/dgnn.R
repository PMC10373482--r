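# The graph network architecture: node initialization from atom and
# molecule features, bottlenecked message passing conditioned on radial
# edge embeddings, four-way global aggregation, and the output MLP.  Two
# heads: a scalar packing-coefficient regressor working on isolated
# conformers, and a two-logit real-vs-fake discriminator working on
# molecular-crystal graphs with periodic feature overwrite.
#
# Node states live only on canonical-conformer atoms: because every
# symmetry image's state is overwritten from its canonical counterpart
# after each update, the canonical states are a complete representation
# and image states are gathered through the symmetry map when they act as
# message sources.

#' Model architecture configuration
#'
#' @param n_gc Number of graph convolution layers (default 4).
#' @param node_width Node state width (default 256).
#' @param message_width Bottleneck width inside message passing
#'   (default 128).
#' @param edge_embed_width Width the radial basis is boosted to
#'   (default 128).
#' @param n_basis Radial basis size (default 32).
#' @param dropout Dropout rate in convolutions and output MLP
#'   (default 0.1).
#' @param atomic_embedding_dim Learned element-embedding width
#'   (default 32).
#' @param head `"density"` (1 output) or `"discriminator"` (2 logits).
#' @param inter_edge_mode `"final_layer_only"` (default) or
#'   `"all_layers"`; discriminator only.
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.01).
#' @param seed Weight-initialization seed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_gc = 4, node_width = 256, message_width = 128,
                         edge_embed_width = 128, n_basis = 32, dropout = 0.1,
                         atomic_embedding_dim = 32,
                         head = c("density", "discriminator"),
                         inter_edge_mode = c("final_layer_only", "all_layers"),
                         leaky_slope = 0.01, seed = 1L) {
  head <- match.arg(head)
  inter_edge_mode <- match.arg(inter_edge_mode)
  stopifnot(n_gc >= 1, node_width > 0, message_width > 0,
            edge_embed_width > 0, n_basis >= 1,
            dropout >= 0, dropout < 1, atomic_embedding_dim > 0)
  structure(list(
    n_gc = n_gc, node_width = node_width, message_width = message_width,
    edge_embed_width = edge_embed_width, n_basis = n_basis,
    dropout = dropout, atomic_embedding_dim = atomic_embedding_dim,
    head = head, inter_edge_mode = inter_edge_mode,
    out_dim = if (head == "density") 1L else 2L,
    leaky_slope = leaky_slope, seed = as.integer(seed)
  ), class = "model_config")
}

xavier_uniform <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -s, s), fin, fout)
}

#' Initialize a model
#'
#' Variance-scaled uniform weight initialization, fully determined by the
#' configuration seed.
#'
#' @param config A [model_config()].
#' @return Object of class `xtal_model` with fields `config` and `weights`
#'   (a flat named list of numeric matrices that can be edited directly).
#' @export
init_model <- function(config = model_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  nw <- config$node_width; mw <- config$message_width
  ew <- config$edge_embed_width; eb <- config$atomic_embedding_dim
  w <- list()
  w$emb <- 0.1 * matrix(stats::rnorm(100 * eb), 100, eb)
  d_in <- eb + 7 + 16
  w$init_W <- xavier_uniform(d_in, nw); w$init_b <- matrix(0, 1, nw)
  for (t in seq_len(config$n_gc)) {
    w[[paste0("nm_W", t)]] <- xavier_uniform(nw, mw)
    w[[paste0("nm_b", t)]] <- matrix(0, 1, mw)
    w[[paste0("em_W", t)]] <- xavier_uniform(config$n_basis, ew)
    w[[paste0("em_b", t)]] <- matrix(0, 1, ew)
    w[[paste0("fc1_W", t)]] <- xavier_uniform(2 * mw + ew, mw)
    w[[paste0("fc1_b", t)]] <- matrix(0, 1, mw)
    w[[paste0("fc2_W", t)]] <- xavier_uniform(mw, nw)
    w[[paste0("fc2_b", t)]] <- matrix(0, 1, nw)
  }
  w$agg_q <- xavier_uniform(nw, 1)
  w$agg_W <- xavier_uniform(4 * nw, nw); w$agg_b <- matrix(0, 1, nw)
  h_in <- nw + 16
  for (l in seq_len(config$n_gc)) {
    w[[paste0("head_W", l)]] <- xavier_uniform(h_in, nw)
    w[[paste0("head_b", l)]] <- matrix(0, 1, nw)
    h_in <- nw
  }
  w[[paste0("head_W", config$n_gc + 1)]] <- xavier_uniform(h_in, config$out_dim)
  w[[paste0("head_b", config$n_gc + 1)]] <- matrix(0, 1, config$out_dim)
  structure(list(config = config, weights = w), class = "xtal_model")
}

#' @export
print.xtal_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<xtal_model (%s head): n_gc=%d, width=%d, %d parameters>\n",
              x$config$head, x$config$n_gc, x$config$node_width, np))
  invisible(x)
}

#' Fully connected layer
#'
#' `sigma(x W + b)` with a leaky-ReLU `sigma` (identity when
#' `activation = FALSE`); the reference single-layer primitive the whole
#' architecture is assembled from.
#'
#' @param x Input matrix (rows are samples).
#' @param W,b Weight matrix and bias row.
#' @param slope Leaky-ReLU negative slope.
#' @param activation Apply the nonlinearity (default `TRUE`).
#' @return Output matrix.
#' @export
fc_layer <- function(x, W, b, slope = 0.01, activation = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(W)) stop("fc_layer width mismatch")
  y <- sweep(x %*% W, 2, as.vector(b), "+")
  if (activation) ifelse(y > 0, y, slope * y) else y
}

ag_fc <- function(tape, x, W, b, slope, activation = TRUE) {
  y <- ag_add_bias(tape, ag_matmul(tape, x, W), b)
  if (activation) ag_leaky_relu(tape, y, slope) else y
}

# turn a weight list into tracked tape nodes
param_nodes <- function(tape, weights) {
  lapply(weights, function(w) ag_param(tape, w))
}

# ---- batch assembly -------------------------------------------------------

# A forward batch: concatenated canonical-node features plus edge sets.
# Intra edges index canonical-local rows directly; inter edges carry the
# source already mapped through the symmetry map to canonical-local rows
# (the periodic-overwrite identity), with the geometric distance taken
# from the actual image atom.
new_forward_batch <- function(z, atom_feats7, mol_feat_rows, seg, n_graphs,
                              intra, inter, mol_feats_graph, zero_inter,
                              r_c = 6) {
  list(z = z, atom_feats7 = atom_feats7, mol_feat_rows = mol_feat_rows,
       seg = seg, n_graphs = n_graphs, n_nodes = length(z),
       intra = intra, inter = inter, r_c = r_c,
       mol_feats_graph = mol_feats_graph, zero_inter = zero_inter)
}

require_features <- function(mol) {
  if (is.null(mol$atom_features) || is.null(mol$mol_features)) {
    stop("molecule must be featurized first (see featurize())")
  }
  mol
}

#' Assemble a batch of isolated-molecule graphs
#'
#' @param mols List of featurized [molecule_record()]s.
#' @param gconfig A [graph_config()].
#' @return An opaque forward batch consumed by [forward_density()].
#' @export
molecule_batch <- function(mols, gconfig = graph_config()) {
  offs <- 0L
  z <- integer(0); af <- NULL; mfr <- NULL; seg <- integer(0)
  src <- integer(0); tgt <- integer(0); dd <- numeric(0)
  mf_graph <- NULL
  for (gi in seq_along(mols)) {
    mol <- require_features(mols[[gi]])
    n <- nrow(mol$coords)
    g <- build_molecule_graph(mol, gconfig)
    z <- c(z, mol$atom_features[, 1])
    af <- rbind(af, mol$atom_features[, -1, drop = FALSE])
    mfr <- rbind(mfr, matrix(mol$mol_features, n, 16, byrow = TRUE))
    mf_graph <- rbind(mf_graph, mol$mol_features)
    seg <- c(seg, rep(gi, n))
    src <- c(src, g$edges$src + offs); tgt <- c(tgt, g$edges$tgt + offs)
    dd <- c(dd, g$edges$dist)
    offs <- offs + n
  }
  new_forward_batch(as.integer(z), af, mfr, seg, length(mols),
                    intra = list(src = src, tgt = tgt, dist = dd),
                    inter = list(src = integer(0), tgt = integer(0),
                                 dist = numeric(0)),
                    mol_feats_graph = mf_graph,
                    zero_inter = rep(NA, length(mols)),
                    r_c = gconfig$r_c)
}

#' Assemble a batch of molecular-crystal graphs
#'
#' Builds (or accepts) labeled supercells, constructs the crystal graphs,
#' and concatenates the canonical-conformer node sets; intermolecular edge
#' sources are pre-mapped to canonical rows through the symmetry map.
#'
#' @param entries List of [crystal_entry()] or `supercell_structure`
#'   objects.
#' @param gconfig A [graph_config()].
#' @param mols Optional list of featurized molecules (defaults to each
#'   entry's own molecule, featurized on the fly).
#' @param auto_expand_N Grow N (up to 9) until the supercell encloses the
#'   label-1 sphere; with `FALSE`, a too-small supercell is an error.
#' @return An opaque forward batch consumed by [forward_discriminator()].
#' @export
crystal_batch <- function(entries, gconfig = graph_config(), mols = NULL,
                          auto_expand_N = TRUE) {
  offs <- 0L
  z <- integer(0); af <- NULL; mfr <- NULL; seg <- integer(0)
  isrc <- integer(0); itgt <- integer(0); idd <- numeric(0)
  xsrc <- integer(0); xtgt <- integer(0); xdd <- numeric(0)
  mf_graph <- NULL; zero_inter <- logical(length(entries))
  for (gi in seq_along(entries)) {
    e <- entries[[gi]]
    if (inherits(e, "crystal_entry")) {
      N <- gconfig$N
      if (!supercell_encloses_check(e, N, gconfig$r_c)) {
        if (!auto_expand_N) {
          stop("supercell N=", N, " does not enclose the r_max + r_c ",
               "sphere; use a larger N")
        }
        while (N < 9 && !supercell_encloses_check(e, N, gconfig$r_c)) {
          N <- N + 2
        }
      }
      sc <- build_supercell(e, N, gconfig$r_c)
    } else sc <- e
    mol <- if (is.null(mols)) NULL else mols[[gi]]
    if (is.null(mol)) {
      mol <- if (inherits(e, "crystal_entry")) e$molecule else
        stop("supply featurized molecules alongside bare supercells")
      if (is.null(mol$atom_features)) mol <- featurize(mol)
    }
    require_features(mol)
    g <- build_crystal_graph(sc, gconfig)
    can <- g$canonical_nodes
    can_local <- match(seq_len(g$n_nodes), can)  # node -> canonical-local
    n <- length(can)
    z <- c(z, mol$atom_features[, 1])
    af <- rbind(af, mol$atom_features[, -1, drop = FALSE])
    mfr <- rbind(mfr, matrix(mol$mol_features, n, 16, byrow = TRUE))
    mf_graph <- rbind(mf_graph, mol$mol_features)
    seg <- c(seg, rep(gi, n))
    ed <- g$edges
    ia <- ed$type == "intra"
    isrc <- c(isrc, can_local[ed$src[ia]] + offs)
    itgt <- c(itgt, can_local[ed$tgt[ia]] + offs)
    idd <- c(idd, ed$dist[ia])
    ix <- ed$type == "inter"
    zero_inter[gi] <- !any(ix)
    # overwrite identity: image source state == canonical counterpart state
    xsrc <- c(xsrc, can_local[sc$symmetry_map[ed$src[ix]]] + offs)
    xtgt <- c(xtgt, can_local[ed$tgt[ix]] + offs)
    xdd <- c(xdd, ed$dist[ix])
    offs <- offs + n
  }
  new_forward_batch(as.integer(z), af, mfr, seg, length(entries),
                    intra = list(src = isrc, tgt = itgt, dist = idd),
                    inter = list(src = xsrc, tgt = xtgt, dist = xdd),
                    mol_feats_graph = mf_graph, zero_inter = zero_inter,
                    r_c = gconfig$r_c)
}

# ---- forward core ---------------------------------------------------------

# Run the full network on a batch, on the given tape.  Returns the output
# node plus the tracked parameter nodes.  `edge_emb` optionally supplies
# tape nodes for the intra/inter radial embeddings (used by the
# differentiable-builder gradient path); by default they are constants.
forward_core <- function(tape, batch, model, training = FALSE,
                         edge_emb = NULL) {
  cfg <- model$config
  P <- param_nodes(tape, model$weights)
  sl <- cfg$leaky_slope
  n_nodes <- batch$n_nodes

  if (any(batch$z < 1 | batch$z > 100)) {
    stop("atomic number outside the 1..100 embedding table")
  }

  # node initialization: embed(z) || remaining atom features ||
  # molecule features, through one FC + activation
  ztab <- ag_gather(tape, P$emb, batch$z)
  V <- ag_cbind(tape, ztab, ag_const(tape, batch$atom_feats7),
                ag_const(tape, batch$mol_feat_rows))
  states <- ag_fc(tape, V, P$init_W, P$init_b, sl)

  r_c_used <- batch$r_c %||% 6
  intra_emb <- if (length(batch$intra$dist)) {
    ag_const(tape, radial_embedding(batch$intra$dist,
                                    graph_config(r_c = r_c_used,
                                                 n_basis = cfg$n_basis)))
  } else NULL
  if (!is.null(edge_emb$intra)) intra_emb <- edge_emb$intra
  inter_emb <- if (length(batch$inter$dist)) {
    ag_const(tape, radial_embedding(batch$inter$dist,
                                    graph_config(r_c = r_c_used,
                                                 n_basis = cfg$n_basis)))
  } else NULL
  if (!is.null(edge_emb$inter)) inter_emb <- edge_emb$inter

  is_disc <- cfg$head == "discriminator"
  has_inter <- length(batch$inter$src) > 0 || is_disc

  for (t in seq_len(cfg$n_gc)) {
    final_inter <- is_disc && cfg$inter_edge_mode == "final_layer_only" &&
      t == cfg$n_gc
    use_intra <- !final_inter
    use_inter <- is_disc &&
      (cfg$inter_edge_mode == "all_layers" || final_inter)

    Fn <- ag_fc(tape, states, P[[paste0("nm_W", t)]],
                P[[paste0("nm_b", t)]], sl)
    msg_parts <- list(); tgt_all <- integer(0)
    add_edges <- function(set, emb) {
      if (!length(set$src) || is.null(emb)) return(NULL)
      Em <- ag_fc(tape, emb, P[[paste0("em_W", t)]],
                  P[[paste0("em_b", t)]], sl)
      m_in <- ag_cbind(tape, ag_gather(tape, Fn, set$tgt),
                       ag_gather(tape, Fn, set$src), Em)
      ag_leaky_relu(tape, ag_add_bias(
        tape, ag_matmul(tape, m_in, P[[paste0("fc1_W", t)]]),
        P[[paste0("fc1_b", t)]]), sl)
    }
    if (use_intra) {
      mi <- add_edges(batch$intra, intra_emb)
      if (!is.null(mi)) { msg_parts <- c(msg_parts, list(mi))
        tgt_all <- c(tgt_all, batch$intra$tgt) }
    }
    if (use_inter) {
      mx <- add_edges(batch$inter, inter_emb)
      if (!is.null(mx)) { msg_parts <- c(msg_parts, list(mx))
        tgt_all <- c(tgt_all, batch$inter$tgt) }
    }
    msum <- if (length(msg_parts)) {
      m_all <- if (length(msg_parts) > 1) {
        do.call(function(...) ag_rbind(tape, ...), msg_parts)
      } else msg_parts[[1]]
      ag_segment_sum(tape, m_all, tgt_all, n_nodes)
    } else ag_const(tape, matrix(0, n_nodes, cfg$message_width))
    upd <- ag_fc(tape, msum, P[[paste0("fc2_W", t)]],
                 P[[paste0("fc2_b", t)]], sl)
    states <- if (final_inter) upd else ag_add(tape, states, upd)
    states <- ag_layer_norm(tape, states)
    states <- ag_dropout(tape, states, cfg$dropout, training)
  }

  # four-way global aggregation over each graph's canonical nodes
  seg <- batch$seg; ng <- batch$n_graphs
  a_max <- ag_segment_max(tape, states, seg, ng)
  a_sum <- ag_segment_sum(tape, states, seg, ng)
  a_mean <- ag_segment_mean(tape, states, seg, ng)
  sc <- ag_matmul(tape, states, P$agg_q)
  sc <- ag_new(tape, sc$val / sqrt(cfg$node_width), list(sc),
               function(g) list(g / sqrt(cfg$node_width)))
  smax <- ag_segment_max(tape, sc, seg, ng)
  e <- ag_exp(tape, ag_sub(tape, sc, ag_gather(tape, smax, seg)))
  den <- ag_segment_sum(tape, e, seg, ng)
  wts <- ag_div(tape, e, ag_gather(tape, den, seg))
  a_sa <- ag_segment_sum(tape, ag_scale_rows(tape, states, wts), seg, ng)
  gvec <- ag_fc(tape, ag_cbind(tape, a_max, a_sum, a_mean, a_sa),
                P$agg_W, P$agg_b, sl)

  # output MLP over (graph vector || molecule features), n_gc + 1 layers
  x <- ag_cbind(tape, gvec, ag_const(tape, batch$mol_feats_graph))
  for (l in seq_len(cfg$n_gc)) {
    x <- ag_fc(tape, x, P[[paste0("head_W", l)]],
               P[[paste0("head_b", l)]], sl)
    x <- ag_layer_norm(tape, x)
    x <- ag_dropout(tape, x, cfg$dropout, training)
  }
  out <- ag_fc(tape, x, P[[paste0("head_W", cfg$n_gc + 1)]],
               P[[paste0("head_b", cfg$n_gc + 1)]], sl, activation = FALSE)
  list(out = out, params = P, states = states)
}

#' Predict packing coefficients from single conformers
#'
#' Full density-model forward pass: node initialization, `n_gc` molecule
#' graph convolutions, four-way aggregation, output MLP.  Deterministic
#' (dropout off) and invariant under rigid motion and atom permutation.
#'
#' @param mols A featurized [molecule_record()] or list of them.
#' @param model An `xtal_model` with the density head.
#' @param gconfig A [graph_config()].
#' @return Numeric vector of packing-coefficient estimates.
#' @export
forward_density <- function(mols, model, gconfig = graph_config()) {
  if (model$config$head != "density") stop("model head is not 'density'")
  if (inherits(mols, "molecule_record")) mols <- list(mols)
  batch <- molecule_batch(mols, gconfig)
  tape <- ag_tape()
  as.vector(ag_value(forward_core(tape, batch, model)$out))
}

#' Score crystals with the discriminator
#'
#' Full discriminator forward pass: supercell construction and labeling,
#' crystal-graph assembly, intramolecular convolutions with the periodic
#' overwrite identity, a final outside-in intermolecular convolution
#' (omitting the residual), aggregation over the canonical conformer, and
#' the two-logit head.
#'
#' @param entries A [crystal_entry()], `supercell_structure`, or list of
#'   them.
#' @param model An `xtal_model` with the discriminator head.
#' @param gconfig A [graph_config()].
#' @param mols Optional featurized molecules matching `entries`.
#' @param auto_expand_N See [crystal_batch()].
#' @return `n x 2` matrix of raw logits (columns: real, fake), with
#'   attribute `zero_inter` flagging crystals that had no intermolecular
#'   contact within the cutoff.
#' @export
forward_discriminator <- function(entries, model, gconfig = graph_config(),
                                  mols = NULL, auto_expand_N = TRUE) {
  if (model$config$head != "discriminator") {
    stop("model head is not 'discriminator'")
  }
  if (inherits(entries, c("crystal_entry", "supercell_structure"))) {
    entries <- list(entries)
  }
  batch <- crystal_batch(entries, gconfig, mols = mols,
                         auto_expand_N = auto_expand_N)
  tape <- ag_tape()
  out <- ag_value(forward_core(tape, batch, model)$out)
  colnames(out) <- c("real", "fake")
  attr(out, "zero_inter") <- batch$zero_inter
  out
}

# ---- exported single-step operations (numeric wrappers) -------------------

#' Initialize node states for a featurized molecule
#'
#' @param mol A featurized [molecule_record()].
#' @param model An `xtal_model`.
#' @return Numeric matrix `n_atoms x node_width`.
#' @export
init_node_states <- function(mol, model) {
  require_features(mol)
  z <- as.integer(mol$atom_features[, 1])
  if (any(z < 1 | z > 100)) stop("atomic number outside the embedding table")
  n <- length(z)
  V <- cbind(model$weights$emb[z, , drop = FALSE],
             mol$atom_features[, -1, drop = FALSE],
             matrix(mol$mol_features, n, 16, byrow = TRUE))
  fc_layer(V, model$weights$init_W, model$weights$init_b,
           model$config$leaky_slope)
}

#' One graph convolution step (numeric)
#'
#' Applies layer `t`'s message passing to explicit node states over the
#' given edges: bottleneck, message construction from
#' `(F_target || F_source || E_edge)`, FC1, sum over in-edges, FC2,
#' residual (optional), layer norm.
#'
#' @param states Numeric `n x node_width` matrix.
#' @param graph A `crystal_graph` (all edges are used as given).
#' @param model An `xtal_model`.
#' @param t Layer index.
#' @param residual Include the residual connection (default `TRUE`).
#' @param layer_norm Apply layer normalization (default `TRUE`).
#' @return Updated state matrix.
#' @export
graph_convolution <- function(states, graph, model, t = 1, residual = TRUE,
                              layer_norm = TRUE) {
  w <- model$weights; sl <- model$config$leaky_slope
  n <- nrow(states)
  ed <- graph$edges
  if (nrow(ed) > 0 && (max(ed$src) > n || max(ed$tgt) > n)) {
    stop("edge indices exceed the node count")
  }
  Fn <- fc_layer(states, w[[paste0("nm_W", t)]], w[[paste0("nm_b", t)]], sl)
  if (nrow(ed) > 0) {
    Em <- fc_layer(graph$embeddings, w[[paste0("em_W", t)]],
                   w[[paste0("em_b", t)]], sl)
    m_in <- cbind(Fn[ed$tgt, , drop = FALSE], Fn[ed$src, , drop = FALSE], Em)
    m <- fc_layer(m_in, w[[paste0("fc1_W", t)]], w[[paste0("fc1_b", t)]], sl)
    msum <- matrix(0, n, ncol(m))
    agg <- rowsum(m, group = ed$tgt)
    msum[as.integer(rownames(agg)), ] <- agg
  } else {
    msum <- matrix(0, n, model$config$message_width)
  }
  upd <- fc_layer(msum, w[[paste0("fc2_W", t)]], w[[paste0("fc2_b", t)]], sl)
  out <- if (residual) states + upd else upd
  if (layer_norm) layer_norm_rows(out) else out
}

layer_norm_rows <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  xc / sqrt(rowMeans(xc^2) + eps)
}

#' Final intermolecular convolution (numeric)
#'
#' The discriminator's last layer: canonical-conformer states are replaced
#' by the non-residual convolution output computed from intermolecular
#' (outside-in) edges only; image states are never updated.
#'
#' @param states Numeric states over all retained supercell nodes.
#' @param graph A `crystal_graph` from [build_crystal_graph()].
#' @param model An `xtal_model`.
#' @param t Layer index holding the weights (default `n_gc`).
#' @return States restricted to canonical nodes (rows follow
#'   `graph$canonical_nodes`), with attribute `zero_inter` set when the
#'   crystal had no intermolecular edge.
#' @export
final_intermolecular_convolution <- function(states, graph, model,
                                             t = model$config$n_gc) {
  inter <- graph$edges[graph$edges$type == "inter", , drop = FALSE]
  emb <- graph$embeddings[graph$edges$type == "inter", , drop = FALSE]
  sub <- graph
  sub$edges <- inter
  sub$embeddings <- emb
  out <- graph_convolution(states, sub, model, t, residual = FALSE,
                           layer_norm = TRUE)
  res <- out[graph$canonical_nodes, , drop = FALSE]
  attr(res, "zero_inter") <- nrow(inter) == 0
  res
}

#' Global four-way aggregation (numeric)
#'
#' Concatenates per-column max, sum, mean, and a single-head dot-product
#' self-attention over node states, then passes through a fully connected
#' layer to the graph vector.
#'
#' @param states Numeric `n x node_width` matrix (n >= 1).
#' @param model An `xtal_model`.
#' @return Length-`node_width` graph vector.
#' @export
global_aggregate <- function(states, model) {
  if (nrow(states) < 1) stop("cannot aggregate an empty node set")
  w <- model$weights
  sc <- as.vector(states %*% w$agg_q) / sqrt(model$config$node_width)
  al <- exp(sc - max(sc)); al <- al / sum(al)
  agg <- c(apply(states, 2, max), colSums(states), colMeans(states),
           colSums(states * al))
  as.vector(fc_layer(matrix(agg, 1), w$agg_W, w$agg_b,
                     model$config$leaky_slope))
}

#' Output network (numeric)
#'
#' The `n_gc + 1`-layer MLP over the concatenation of the graph vector and
#' the 16 molecule features; the density head returns one value, the
#' discriminator head two logits.
#'
#' @param graph_vector Length-`node_width` vector from
#'   [global_aggregate()].
#' @param mol_features Length-16 molecule feature vector.
#' @param model An `xtal_model`.
#' @return Numeric vector of length 1 (density) or 2 (discriminator).
#' @export
output_head <- function(graph_vector, mol_features, model) {
  cfg <- model$config; w <- model$weights
  x <- matrix(c(graph_vector, mol_features), 1)
  for (l in seq_len(cfg$n_gc)) {
    x <- fc_layer(x, w[[paste0("head_W", l)]], w[[paste0("head_b", l)]],
                  cfg$leaky_slope)
    x <- layer_norm_rows(x)
  }
  as.vector(fc_layer(x, w[[paste0("head_W", cfg$n_gc + 1)]],
                     w[[paste0("head_b", cfg$n_gc + 1)]],
                     cfg$leaky_slope, activation = FALSE))
}
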