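# Independent oracles, deliberately written as naive loops so they share
# no code path with the implementation they check.

# O(n^2) directed edge scan between two coordinate sets (or within one);
# row-at-a-time so it shares no code with the implementation's blocked scan
oracle_edges <- function(A, B = A, r_c, exclude_self = identical(A, B)) {
  rows <- vector("list", nrow(A))
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                (B[, 3] - A[i, 3])^2)
    j <- which(d <= r_c)
    if (exclude_self) j <- setdiff(j, i)
    if (length(j)) rows[[i]] <- cbind(i, j, d[j])
  }
  do.call(rbind, rows)
}

# plain-R network layers mirroring the architecture, used by the explicit
# supercell oracle; fc_layer and radial_embedding are primitives with their
# own tests
oracle_init_states <- function(mol, n_atoms_each, n_mols, model) {
  one <- init_node_states(mol, model)
  do.call(rbind, rep(list(one), n_mols))
}

oracle_layer_norm <- function(x, eps = 1e-5) {
  t(apply(x, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
}

# Explicit dense supercell convolution with NO periodic overwrite: every
# atom of every molecule image receives messages from all neighbors within
# r_c (same molecule and others), exactly as on an infinite crystal graph.
# Returns final states of the molecule image `central` (1-based).
oracle_dense_forward <- function(entry, model, gconfig, N = 5,
                                 central_image = NULL) {
  cfg <- model$config
  M <- do.call(cell_matrix, as.list(entry$cell))
  h <- (N - 1) / 2
  offs <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  k_can <- select_canonical_conformer(entry)
  coords <- NULL; molid <- NULL
  img <- 0
  central <- NA
  for (o in seq_len(nrow(offs))) {
    for (m in seq_len(entry$Z)) {
      img <- img + 1
      X <- sweep(entry$unit_cell_coords[[m]], 2,
                 as.vector(offs[o, , drop = FALSE] %*% M), "+")
      coords <- rbind(coords, X)
      molid <- c(molid, rep(img, nrow(X)))
      if (all(offs[o, ] == 0) && m == k_can) central <- img
    }
  }
  n_at <- nrow(entry$unit_cell_coords[[1]])
  mol <- entry$molecule
  states <- oracle_init_states(mol, n_at, img, model)
  w <- model$weights; sl <- cfg$leaky_slope

  ed <- oracle_edges(coords, coords, gconfig$r_c)
  same_mol <- molid[ed[, 1]] == molid[ed[, 2]]
  emb_all <- radial_embedding(ed[, 3], graph_config(r_c = gconfig$r_c,
                                                    n_basis = cfg$n_basis))
  conv <- function(states, t, sel, residual) {
    Fn <- fc_layer(states, w[[paste0("nm_W", t)]], w[[paste0("nm_b", t)]], sl)
    msum <- matrix(0, nrow(states), cfg$message_width)
    if (any(sel)) {
      Em <- fc_layer(emb_all[sel, , drop = FALSE], w[[paste0("em_W", t)]],
                     w[[paste0("em_b", t)]], sl)
      m_in <- cbind(Fn[ed[sel, 2], , drop = FALSE],
                    Fn[ed[sel, 1], , drop = FALSE], Em)
      m <- fc_layer(m_in, w[[paste0("fc1_W", t)]], w[[paste0("fc1_b", t)]],
                    sl)
      tg <- ed[sel, 2]
      for (i in seq_along(tg)) {
        msum[tg[i], ] <- msum[tg[i], ] + m[i, ]
      }
    }
    upd <- fc_layer(msum, w[[paste0("fc2_W", t)]], w[[paste0("fc2_b", t)]],
                    sl)
    out <- if (residual) states + upd else upd
    oracle_layer_norm(out)
  }

  if (cfg$inter_edge_mode == "final_layer_only") {
    for (t in seq_len(cfg$n_gc - 1)) {
      states <- conv(states, t, same_mol, residual = TRUE)
    }
    states <- conv(states, cfg$n_gc, !same_mol, residual = FALSE)
  } else {
    for (t in seq_len(cfg$n_gc)) {
      states <- conv(states, t, rep(TRUE, nrow(ed)), residual = TRUE)
    }
  }
  states[molid == central, , drop = FALSE]
}

# hand-rolled regression metrics used against evaluate_density
oracle_regression <- function(pred, y) {
  err <- pred - y
  list(mae_rel = mean(abs(err) / y),
       r = sum((pred - mean(pred)) * (y - mean(y))) /
         sqrt(sum((pred - mean(pred))^2) * sum((y - mean(y))^2)),
       slope = sum((y - mean(y)) * (pred - mean(pred))) /
         sum((y - mean(y))^2))
}
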