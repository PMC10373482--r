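# Shared fixtures and small model/graph configurations.  Everything is
# generated in code with fixed seeds; no data files.

test_gconfig <- function(r_c = 6, n_basis = 8) {
  graph_config(r_c = r_c, n_basis = n_basis)
}

small_model <- function(head = "density", n_gc = 2, seed = 7,
                        inter_edge_mode = "final_layer_only",
                        dropout = 0) {
  init_model(model_config(
    n_gc = n_gc, node_width = 32, message_width = 16, edge_embed_width = 16,
    n_basis = 8, dropout = dropout, atomic_embedding_dim = 8, head = head,
    inter_edge_mode = inter_edge_mode, seed = seed))
}

# a featurized fixture molecule (cached per index)
.test_mols <- new.env(parent = emptyenv())
test_molecule <- function(index = 1L, seed = 31L) {
  key <- paste(index, seed)
  if (is.null(.test_mols[[key]])) {
    .test_mols[[key]] <- make_molecule(
      fixture_spec(seed = seed, n_atoms_range = c(5L, 8L)), index,
      volume_points = 5e3)
  }
  .test_mols[[key]]
}

# a small P-1 crystal fixture with params, entry and standardized conformer
.test_xtals <- new.env(parent = emptyenv())
test_crystal <- function(index = 1L, sg = "P-1", seed = 31L) {
  key <- paste(index, sg, seed)
  if (is.null(.test_xtals[[key]])) {
    .test_xtals[[key]] <- make_crystal(
      fixture_spec(seed = seed, n_atoms_range = c(5L, 8L)), index,
      space_group = sg)
  }
  .test_xtals[[key]]
}

featurized_conformer <- function(fx) {
  conf <- fx$conformer
  if (is.null(conf$atom_features)) conf <- featurize(conf,
                                                     volume_points = 5e3)
  conf
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  v <- stats::rnorm(3)
  rotvec_decode(v / sqrt(sum(v^2)) * stats::runif(1, 0.2, 3))
}
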