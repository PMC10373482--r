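# A compact reverse-mode automatic differentiation tape over numeric
# matrices.  Every value is stored as a matrix (scalars are 1 x 1); nodes
# are recorded in creation order, which is a valid topological order, and
# the backward pass walks the tape in reverse.  Only nodes with a parameter
# ancestor participate in the backward pass.
#
# This is deliberately minimal: just the operations needed by the graph
# networks and by the differentiable cell builder.

ag_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- vector("list", 256)
  env$n <- 0L
  class(env) <- "ag_tape"
  env
}

ag_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ag_new <- function(tape, val, parents = list(), vjp = NULL) {
  val <- as.matrix(val)
  track <- any(vapply(parents, function(p) p$track, logical(1)))
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$parents <- if (track) parents else list()
  node$vjp <- if (track) vjp else NULL
  node$track <- track
  node$grad <- NULL
  ag_push(tape, node)
}

ag_const <- function(tape, x) {
  node <- new.env(parent = emptyenv())
  node$val <- as.matrix(x)
  node$parents <- list(); node$vjp <- NULL
  node$track <- FALSE; node$grad <- NULL
  ag_push(tape, node)
}

ag_param <- function(tape, x) {
  node <- ag_const(tape, x)
  node$track <- TRUE
  node
}

ag_value <- function(node) node$val

ag_backward <- function(tape, node) {
  if (length(node$val) != 1) stop("backward target must be scalar")
  node$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$track || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(NULL)
}

# ---- arithmetic -----------------------------------------------------------

ag_add <- function(tape, a, b) {
  ag_new(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ag_sub <- function(tape, a, b) {
  ag_new(tape, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ag_new(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ag_new(tape, av / bv, list(a, b),
         function(g) list(g / bv, -g * av / bv^2))
}

ag_neg <- function(tape, a) ag_new(tape, -a$val, list(a), function(g) list(-g))

ag_matmul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ag_new(tape, av %*% bv, list(a, b),
         function(g) list(g %*% t(bv), t(av) %*% g))
}

# add a 1 x k bias row to every row of an n x k matrix
ag_add_bias <- function(tape, a, bias) {
  ag_new(tape, sweep(a$val, 2, as.vector(bias$val), "+"), list(a, bias),
         function(g) list(g, matrix(colSums(g), 1)))
}

ag_scale_rows <- function(tape, a, w) {
  # multiply row i of a (n x k) by scalar w[i] (n x 1)
  av <- a$val; wv <- as.vector(w$val)
  ag_new(tape, av * wv, list(a, w), function(g) {
    list(g * wv, matrix(rowSums(g * av), ncol = 1))
  })
}

ag_sin <- function(tape, a) {
  av <- a$val
  ag_new(tape, sin(av), list(a), function(g) list(g * cos(av)))
}

ag_cos <- function(tape, a) {
  av <- a$val
  ag_new(tape, cos(av), list(a), function(g) list(-g * sin(av)))
}

ag_sqrt <- function(tape, a) {
  s <- sqrt(a$val)
  ag_new(tape, s, list(a), function(g) list(g / (2 * s)))
}

ag_exp <- function(tape, a) {
  e <- exp(a$val)
  ag_new(tape, e, list(a), function(g) list(g * e))
}

ag_leaky_relu <- function(tape, a, slope = 0.01) {
  av <- a$val
  ag_new(tape, ifelse(av > 0, av, slope * av), list(a),
         function(g) list(g * ifelse(av > 0, 1, slope)))
}

# ---- shape / indexing -----------------------------------------------------

ag_cbind <- function(tape, ...) {
  args <- list(...)
  widths <- vapply(args, function(a) ncol(a$val), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ag_new(tape, do.call(cbind, lapply(args, `[[`, "val")), args, function(g) {
    lapply(seq_along(args), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ag_rbind <- function(tape, ...) {
  args <- list(...)
  heights <- vapply(args, function(a) nrow(a$val), integer(1))
  ends <- cumsum(heights); starts <- ends - heights + 1L
  ag_new(tape, do.call(rbind, lapply(args, `[[`, "val")), args, function(g) {
    lapply(seq_along(args), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

ag_gather <- function(tape, a, idx) {
  av <- a$val
  ag_new(tape, av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    agg <- rowsum(g, group = idx)  # scatter-add of upstream rows
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ag_rowsum_cols <- function(tape, a) {
  # n x k -> n x 1 row sums
  av <- a$val
  ag_new(tape, matrix(rowSums(av), ncol = 1), list(a), function(g) {
    list(matrix(as.vector(g), nrow(av), ncol(av)))
  })
}

ag_sum <- function(tape, a) {
  av <- a$val
  ag_new(tape, sum(av), list(a),
         function(g) list(matrix(as.numeric(g), nrow(av), ncol(av))))
}

ag_segment_sum <- function(tape, a, seg, nseg) {
  av <- a$val
  out <- matrix(0, nseg, ncol(av))
  agg <- rowsum(av, group = seg)
  out[as.integer(rownames(agg)), ] <- agg
  ag_new(tape, out, list(a), function(g) list(g[seg, , drop = FALSE]))
}

ag_segment_mean <- function(tape, a, seg, nseg) {
  cnt <- tabulate(seg, nbins = nseg)
  cnt[cnt == 0] <- 1
  s <- ag_segment_sum(tape, a, seg, nseg)
  ag_new(tape, s$val / cnt, list(s), function(g) list(g / cnt))
}

ag_segment_max <- function(tape, a, seg, nseg) {
  av <- a$val
  out <- matrix(-Inf, nseg, ncol(av))
  arg <- matrix(NA_integer_, nseg, ncol(av))
  for (s in seq_len(nseg)) {
    rows <- which(seg == s)
    if (!length(rows)) { out[s, ] <- 0; next }
    block <- av[rows, , drop = FALSE]
    w <- apply(block, 2, which.max)
    arg[s, ] <- rows[w]
    out[s, ] <- block[cbind(w, seq_len(ncol(av)))]
  }
  ag_new(tape, out, list(a), function(g) {
    gi <- matrix(0, nrow(av), ncol(av))
    for (s in seq_len(nseg)) {
      ok <- which(!is.na(arg[s, ]))
      if (length(ok)) gi[cbind(arg[s, ok], ok)] <- gi[cbind(arg[s, ok], ok)] + g[s, ok]
    }
    list(gi)
  })
}

ag_layer_norm <- function(tape, a, eps = 1e-5) {
  av <- a$val
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  k <- ncol(av)
  ag_new(tape, y, list(a), function(g) {
    gm <- rowMeans(g)
    gym <- rowMeans(g * y)
    list((g - gm - y * gym) * inv)
  })
}

ag_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1, 1 - p), nrow(a$val)) / (1 - p)
  ag_new(tape, a$val * mask, list(a), function(g) list(g * mask))
}

ag_slice <- function(tape, a, i, j) {
  av <- a$val
  ag_new(tape, av[i, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[i, j] <- as.numeric(g)
    list(out)
  })
}

ag_t <- function(tape, a) {
  ag_new(tape, t(a$val), list(a), function(g) list(t(g)))
}

# ---- losses ---------------------------------------------------------------

# mean softmax cross-entropy over rows; labels are 1-based class indices
ag_softmax_xent <- function(tape, logits, labels) {
  lv <- logits$val
  m <- apply(lv, 1, max)
  e <- exp(lv - m)
  p <- e / rowSums(e)
  n <- nrow(lv)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), labels)], 1e-300)))
  ag_new(tape, loss, list(logits), function(g) {
    gl <- p
    gl[cbind(seq_len(n), labels)] <- gl[cbind(seq_len(n), labels)] - 1
    list(as.numeric(g) * gl / n)
  })
}

# mean smoothed L1 between prediction column and constant targets
ag_smooth_l1 <- function(tape, pred, target) {
  pv <- as.vector(pred$val)
  d <- pv - target
  ad <- abs(d)
  per <- ifelse(ad > 1, ad - 0.5, d^2 / 2)
  n <- length(d)
  ag_new(tape, mean(per), list(pred), function(g) {
    gd <- ifelse(ad > 1, sign(d), d)
    list(matrix(as.numeric(g) * gd / n, ncol = 1))
  })
}
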