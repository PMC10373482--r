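# Differentiable route through the cell builder: the discriminator output
# as a smooth function of the 12 crystal parameters.  The graph topology
# (edge set, wrap shifts, supercell labeling) is frozen from a numeric
# build; coordinates, distances and radial embeddings are then re-derived
# on the autodiff tape so the network output can be backpropagated to the
# parameters.  Valid away from wrap boundaries, where the builder is
# genuinely non-smooth.

# scalar helpers on the tape
sc_const <- function(tape, x) ag_const(tape, matrix(x, 1, 1))
sc_mul <- function(tape, a, b) ag_mul(tape, a, b)

# pack 1x1 nodes into a row (1 x k)
pack_row <- function(tape, nodes) do.call(function(...) ag_cbind(tape, ...),
                                          nodes)

# lattice matrix rows from the six cell-parameter scalar nodes (degrees)
tape_cell_matrix <- function(tape, a, b, c, al, be, ga) {
  d2r <- pi / 180
  rad <- function(x) ag_mul(tape, x, sc_const(tape, d2r))
  ca <- ag_cos(tape, rad(al)); cb <- ag_cos(tape, rad(be))
  cg <- ag_cos(tape, rad(ga)); sg <- ag_sin(tape, rad(ga))
  one <- sc_const(tape, 1); two <- sc_const(tape, 2)
  vfac <- ag_add(tape,
    ag_sub(tape, one,
      ag_add(tape, ag_mul(tape, ca, ca),
        ag_add(tape, ag_mul(tape, cb, cb), ag_mul(tape, cg, cg)))),
    ag_mul(tape, two, ag_mul(tape, ca, ag_mul(tape, cb, cg))))
  z <- sc_const(tape, 0)
  r1 <- pack_row(tape, list(a, z, z))
  r2 <- pack_row(tape, list(ag_mul(tape, b, cg), ag_mul(tape, b, sg), z))
  m32 <- ag_div(tape, ag_mul(tape, c, ag_sub(tape, ca, ag_mul(tape, cb, cg))),
                sg)
  m33 <- ag_div(tape, ag_mul(tape, c, ag_sqrt(tape, vfac)), sg)
  r3 <- pack_row(tape, list(ag_mul(tape, c, cb), m32, m33))
  ag_rbind(tape, r1, r2, r3)
}

# closed-form inverse of the lower-triangular lattice matrix
tape_cell_inverse <- function(tape, M) {
  m11 <- ag_slice(tape, M, 1, 1); m21 <- ag_slice(tape, M, 2, 1)
  m22 <- ag_slice(tape, M, 2, 2); m31 <- ag_slice(tape, M, 3, 1)
  m32 <- ag_slice(tape, M, 3, 2); m33 <- ag_slice(tape, M, 3, 3)
  one <- sc_const(tape, 1); z <- sc_const(tape, 0)
  i11 <- ag_div(tape, one, m11)
  i22 <- ag_div(tape, one, m22)
  i33 <- ag_div(tape, one, m33)
  i21 <- ag_neg(tape, ag_div(tape, m21, ag_mul(tape, m11, m22)))
  i32 <- ag_neg(tape, ag_div(tape, m32, ag_mul(tape, m22, m33)))
  i31 <- ag_div(tape,
    ag_sub(tape, ag_mul(tape, m21, m32), ag_mul(tape, m31, m22)),
    ag_mul(tape, m11, ag_mul(tape, m22, m33)))
  ag_rbind(tape,
           pack_row(tape, list(i11, z, z)),
           pack_row(tape, list(i21, i22, z)),
           pack_row(tape, list(i31, i32, i33)))
}

# Rodrigues rotation matrix from the three rotation-vector scalar nodes
tape_rotation <- function(tape, vx, vy, vz) {
  v2 <- ag_add(tape, ag_mul(tape, vx, vx),
               ag_add(tape, ag_mul(tape, vy, vy), ag_mul(tape, vz, vz)))
  th <- ag_sqrt(tape, v2)
  kx <- ag_div(tape, vx, th); ky <- ag_div(tape, vy, th)
  kz <- ag_div(tape, vz, th)
  z <- sc_const(tape, 0)
  K <- ag_rbind(tape,
    pack_row(tape, list(z, ag_neg(tape, kz), ky)),
    pack_row(tape, list(kz, z, ag_neg(tape, kx))),
    pack_row(tape, list(ag_neg(tape, ky), kx, z)))
  st <- ag_sin(tape, th)
  omc <- ag_sub(tape, sc_const(tape, 1), ag_cos(tape, th))
  I3 <- ag_const(tape, diag(3))
  st3 <- ag_matmul(tape, ag_const(tape, matrix(1, 3, 1)),
                   ag_matmul(tape, st, ag_const(tape, matrix(1, 1, 3))))
  omc3 <- ag_matmul(tape, ag_const(tape, matrix(1, 3, 1)),
                    ag_matmul(tape, omc, ag_const(tape, matrix(1, 1, 3))))
  ag_add(tape, I3,
         ag_add(tape, ag_mul(tape, st3, K),
                ag_mul(tape, omc3, ag_matmul(tape, K, K))))
}

#' Discriminator gradient with respect to the 12 crystal parameters
#'
#' Rebuilds the supercell coordinates on the autodiff tape as a smooth
#' function of the crystal parameters (cell matrix, Rodrigues rotation,
#' fractional placement, symmetry images, lattice offsets), re-derives the
#' edge distances and radial embeddings of the frozen graph topology, runs
#' the discriminator, and backpropagates the logit difference
#' (real - fake) to the parameter vector.
#'
#' @param params A [crystal_params()] (away from wrap boundaries).
#' @param conformer Featurized, standardized [molecule_record()].
#' @param model A discriminator `xtal_model`.
#' @param gconfig A [graph_config()].
#' @param what `"score"` differentiates the logit difference (real - fake)
#'   through the whole network; `"edge_distances"` differentiates the sum
#'   of all graph edge distances, the builder's smooth geometric core
#'   (the network itself has leaky-ReLU kinks, so exact finite-difference
#'   agreement at moderate steps is only defined for the builder part).
#' @return List with `value` (the logit difference), `grad` (length-12
#'   gradient, names as in [params_vector()]), and `objective` — the plain
#'   numeric function of a 12-vector used for finite-difference checks
#'   (for `"edge_distances"` it sums distances over the frozen edge list,
#'   so it is smooth under small perturbations).
#' @export
discriminator_param_gradient <- function(params, conformer, model,
                                         gconfig = graph_config(),
                                         what = c("score",
                                                  "edge_distances")) {
  what <- match.arg(what)
  sg <- params$space_group
  frozen <- build_crystal_graph(
    build_supercell(build_unit_cell(params, conformer), gconfig$N,
                    gconfig$r_c), gconfig)$edges
  objective <- function(v) {
    p <- vector_to_params(v, sg)
    e <- build_unit_cell(p, conformer)
    sc <- build_supercell(e, gconfig$N, gconfig$r_c)
    if (what == "edge_distances") {
      d <- sqrt(rowSums((sc$coords[frozen$src, , drop = FALSE] -
                           sc$coords[frozen$tgt, , drop = FALSE])^2))
      return(sum(d))
    }
    lg <- forward_discriminator(sc, model, gconfig, mols = list(conformer),
                                auto_expand_N = FALSE)
    lg[1, 1] - lg[1, 2]
  }

  # frozen topology from the numeric build
  entry <- build_unit_cell(params, conformer)
  sc <- build_supercell(entry, gconfig$N, gconfig$r_c)
  g <- build_crystal_graph(sc, gconfig)
  M_num <- do.call(cell_matrix, as.list(params$cell))
  f0_num <- cart_to_frac(
    sweep(conformer$coords %*% t(rotvec_decode(params$orientation)), 2,
          as.vector(params$frac_centroid %*% M_num), "+"), M_num)
  wrap_shifts <- lapply(sg$ops, function(op) {
    f <- sweep(f0_num %*% t(op$W), 2, op$t, "+")
    floor(colMeans(f))
  })

  tape <- ag_tape()
  pv <- params_vector(params)
  p_node <- ag_param(tape, matrix(pv, 1, 12))
  s <- lapply(1:12, function(j) ag_slice(tape, p_node, 1, j))
  M <- tape_cell_matrix(tape, s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]])
  Minv <- tape_cell_inverse(tape, M)
  R <- tape_rotation(tape, s[[10]], s[[11]], s[[12]])
  fc_row <- pack_row(tape, s[7:9])
  X0 <- ag_matmul(tape, ag_const(tape, conformer$coords), ag_t(tape, R))
  X0 <- ag_add_bias(tape, X0, ag_matmul(tape, fc_row, M))
  f0 <- ag_matmul(tape, X0, Minv)
  images <- lapply(seq_along(sg$ops), function(m) {
    op <- sg$ops[[m]]
    f <- ag_add_bias(tape, ag_matmul(tape, f0, ag_const(tape, t(op$W))),
                     ag_const(tape, matrix(op$t - wrap_shifts[[m]], 1)))
    ag_matmul(tape, f, M)
  })

  # supercell rows in build order: blocks over (offset, molecule)
  Z <- entry$Z
  h <- (gconfig$N - 1) / 2
  offsets <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  blocks <- list()
  img_ids <- unique(sc$molecule_image)
  for (im in img_ids) {
    rows <- which(sc$molecule_image == im)
    m <- (im - 1L) %% Z + 1L
    o <- (im - 1L) %/% Z + 1L
    blk <- ag_gather(tape, images[[m]], sc$within_molecule[rows])
    off_row <- ag_matmul(tape, ag_const(tape, matrix(offsets[o, ], 1)), M)
    blocks[[length(blocks) + 1]] <- ag_add_bias(tape, blk, off_row)
  }
  SC <- do.call(function(...) ag_rbind(tape, ...), blocks)
  stopifnot(max(abs(ag_value(SC) - sc$coords)) < 1e-8)

  edge_dist <- function(src, tgt) {
    diff <- ag_sub(tape, ag_gather(tape, SC, src), ag_gather(tape, SC, tgt))
    ag_sqrt(tape, ag_rowsum_cols(tape, ag_mul(tape, diff, diff)))
  }
  embed <- function(d) {
    n <- seq_len(model$config$n_basis)
    S <- ag_sin(tape, ag_matmul(tape, d,
                                ag_const(tape, matrix(n * pi / gconfig$r_c,
                                                      1))))
    inv <- ag_div(tape, ag_const(tape,
                                 matrix(sqrt(2 / gconfig$r_c),
                                        nrow(d$val), 1)), d)
    ag_scale_rows(tape, S, inv)
  }
  ed <- g$edges
  ia <- ed$type == "intra"; ix <- ed$type == "inter"
  emb <- list(intra = NULL, inter = NULL)
  if (any(ia)) emb$intra <- embed(edge_dist(ed$src[ia], ed$tgt[ia]))
  if (any(ix)) emb$inter <- embed(edge_dist(ed$src[ix], ed$tgt[ix]))

  if (what == "edge_distances") {
    d_all <- edge_dist(ed$src, ed$tgt)
    obj <- ag_sum(tape, d_all)
    ag_backward(tape, obj)
    grad <- as.vector(p_node$grad)
    names(grad) <- names(pv)
    return(list(value = as.numeric(ag_value(obj)), grad = grad,
                objective = objective))
  }

  batch <- crystal_batch(list(sc), gconfig, mols = list(conformer))
  fw <- forward_core(tape, batch, model, edge_emb = emb)
  obj <- ag_sub(tape, ag_slice(tape, fw$out, 1, 1),
                ag_slice(tape, fw$out, 1, 2))
  ag_backward(tape, obj)
  grad <- as.vector(p_node$grad)
  names(grad) <- names(pv)
  list(value = as.numeric(ag_value(obj)), grad = grad,
       objective = objective)
}
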