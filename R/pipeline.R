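# Desk-scale training and evaluation: dataset splitting, mixed real/fake
# batch construction with generator alternation, Adam optimization over the
# autodiff tape, best-test-loss checkpoint selection, and the evaluation
# analyses (regression metrics, score distributions, correlations,
# quantile filtering).

#' Run configuration
#'
#' @param seed Master seed controlling the split, batch order, dropout
#'   masks and generator draws.
#' @param split Training fraction (default 0.8).
#' @param batch_size Minibatch size (default 32).
#' @param mix_prob Probability a fake sample comes from the Gaussian
#'   generator rather than the distortion generator (default 0.5).
#' @param c_dis Distortion scale for the distorted-crystal generator
#'   (default 0.1).
#' @param max_epochs Epoch cap (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early stop after this many non-improving epochs
#'   (default 20).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, split = 0.8, batch_size = 32L,
                       mix_prob = 0.5, c_dis = 0.1, max_epochs = 50L,
                       lr = 1e-3, patience = 20L) {
  stopifnot(split > 0, split < 1, mix_prob >= 0, mix_prob <= 1,
            batch_size >= 2, c_dis >= 0)
  structure(list(seed = as.integer(seed), split = split,
                 batch_size = as.integer(batch_size), mix_prob = mix_prob,
                 c_dis = c_dis, max_epochs = as.integer(max_epochs),
                 lr = lr, patience = as.integer(patience)),
            class = "run_config")
}

#' Deterministic train/test split
#'
#' Disjoint, exhaustive, and fully determined by the seed;
#' `|train| = round(split * n)` (80:20 by default).
#'
#' @param entries List (or vector) of samples.
#' @param config A [run_config()].
#' @return List with `train` and `test` index vectors.
#' @export
split_dataset <- function(entries, config = run_config()) {
  n <- length(entries)
  if (n < 2) stop("need at least two entries to split")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  perm <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(config$split * n)))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(weights)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mh <- state$m[[k]] / (1 - beta1^state$t)
    vh <- state$v[[k]] / (1 - beta2^state$t)
    weights[[k]] <- weights[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(weights = weights, state = state)
}

collect_grads <- function(param_nodes) {
  lapply(param_nodes, function(p) p$grad)
}

# ---- discriminator batches ------------------------------------------------

#' Precompute the generator pool for discriminator training
#'
#' Extracts crystal parameters and standardized conformers from a pool of
#' real crystals and fits the reduced-space Gaussian to them, so batches
#' can be synthesized cheaply.
#'
#' @param entries List of real [crystal_entry()] objects.
#' @param mols Optional featurized molecules (else featurized here).
#' @param gconfig A [graph_config()]; real supercells are prebuilt at this
#'   geometry so repeated batches do not rebuild them.
#' @return Object of class `discriminator_pool`.
#' @export
discriminator_pool <- function(entries, mols = NULL,
                               gconfig = graph_config()) {
  params <- lapply(entries, extract_crystal_params)
  confs <- lapply(seq_along(entries), function(i) {
    conf <- canonical_conformer(entries[[i]])
    if (is.null(mols)) {
      if (is.null(conf$atom_features)) conf <- featurize(conf,
                                                         volume_points = 2e4)
    } else {
      conf$atom_features <- mols[[i]]$atom_features
      conf$mol_features <- mols[[i]]$mol_features
      conf$mol_volume <- mols[[i]]$mol_volume
    }
    conf
  })
  Zs <- vapply(entries, `[[`, numeric(1), "Z")
  Vs <- vapply(confs, function(m) {
    if (is.null(m$mol_volume)) molecular_volume(m) else m$mol_volume
  }, numeric(1))
  stats <- fit_param_gaussian(params, Zs, Vs)
  supercells <- lapply(entries, function(e) {
    N <- gconfig$N
    while (N < 9 && !supercell_encloses_check(e, N, gconfig$r_c)) N <- N + 2
    build_supercell(e, N, gconfig$r_c)
  })
  structure(list(entries = entries, params = params, conformers = confs,
                 Z = Zs, V_mol = Vs, stats = stats,
                 supercells = supercells),
            class = "discriminator_pool")
}

#' Assemble a labeled real/fake discriminator batch
#'
#' Exactly half of the batch is real crystals drawn from the pool; the
#' other half is fakes, each synthesized by the Gaussian generator with
#' probability `mix_prob` and otherwise by the distortion generator at
#' `c_dis`, and rebuilt through [build_unit_cell()].
#'
#' @param pool A [discriminator_pool()].
#' @param config A [run_config()].
#' @param seed Batch seed (deterministic output).
#' @param batch_size Overrides the config batch size if given.
#' @return List with `entries`, `mols`, `labels` (1 real, 2 fake) and
#'   `generator` (`"real"`, `"gaussian"`, `"distorted"`).
#' @export
make_discriminator_batch <- function(pool, config = run_config(),
                                     seed = config$seed,
                                     batch_size = config$batch_size) {
  half <- batch_size %/% 2
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ridx <- sample.int(length(pool$entries), half, replace = TRUE)
  fidx <- sample.int(length(pool$entries), half, replace = TRUE)
  use_gauss <- stats::runif(half) < config$mix_prob
  entries <- vector("list", 2 * half)
  mols <- vector("list", 2 * half)
  gen <- character(2 * half)
  for (i in seq_len(half)) {
    entries[[i]] <- pool$supercells[[ridx[i]]]  # prebuilt; graphs are cheap
    mols[[i]] <- pool$conformers[[ridx[i]]]
    gen[i] <- "real"
  }
  for (i in seq_len(half)) {
    k <- fidx[i]
    conf <- pool$conformers[[k]]
    made <- NULL
    for (attempt in 1:5) {
      made <- tryCatch({
        if (use_gauss[i]) {
          ps <- sample_gaussian_crystals(pool$stats, conf,
                                         pool$params[[k]]$space_group, 1,
                                         seed = seed + 7L * i + attempt)[[1]]
        } else {
          ps <- distort_crystal(pool$params[[k]], pool$stats, pool$Z[k],
                                pool$V_mol[k], c_dis = config$c_dis,
                                seed = seed + 13L * i + attempt)
        }
        build_unit_cell(ps, conf, identifier = sprintf("fake_%d", i))
      }, error = function(e) NULL)
      if (!is.null(made)) break
    }
    if (is.null(made)) stop("fake-crystal generation failed repeatedly")
    entries[[half + i]] <- made
    mols[[half + i]] <- conf
    gen[half + i] <- if (use_gauss[i]) "gaussian" else "distorted"
  }
  list(entries = entries, mols = mols,
       labels = rep(c(1L, 2L), each = half), generator = gen)
}

# ---- training -------------------------------------------------------------

#' Train the packing-coefficient regressor
#'
#' Minimizes the smoothed L1 loss with Adam; logs per-epoch train/test
#' losses and returns the checkpoint with the lowest test loss.  Fully
#' reproducible under the configuration seed.
#'
#' @param model An `xtal_model` (density head).
#' @param mols List of featurized molecules.
#' @param labels Numeric packing-coefficient targets.
#' @param config A [run_config()].
#' @param gconfig A [graph_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best checkpoint), `history` (per-epoch data
#'   frame), `best_epoch`, and the split indices.
#' @export
train_density <- function(model, mols, labels, config = run_config(),
                          gconfig = graph_config(), verbose = FALSE) {
  if (model$config$head != "density") stop("model head is not 'density'")
  sp <- split_dataset(mols, config)
  test_batch <- molecule_batch(mols[sp$test], gconfig)
  test_y <- labels[sp$test]
  opt <- adam_state(model$weights)
  best <- list(loss = Inf, weights = model$weights, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     test_loss = numeric(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  since_best <- 0L
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample(sp$train)
    tr_losses <- numeric(0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      batch <- molecule_batch(mols[idx], gconfig)
      tape <- ag_tape()
      fw <- forward_core(tape, batch, model, training = TRUE)
      loss <- ag_smooth_l1(tape, fw$out, labels[idx])
      if (!is.finite(ag_value(loss))) stop("divergent (non-finite) loss")
      ag_backward(tape, loss)
      upd <- adam_step(model$weights, collect_grads(fw$params), opt,
                       config$lr)
      model$weights <- upd$weights; opt <- upd$state
      tr_losses <- c(tr_losses, ag_value(loss))
    }
    tape <- ag_tape()
    pred <- ag_value(forward_core(tape, test_batch, model)$out)
    te <- mean(smoothed_l1(as.vector(pred), test_y))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                   test_loss = te))
    if (verbose) {
      message(sprintf("epoch %d: train %.5f test %.5f", ep,
                      mean(tr_losses), te))
    }
    if (te < best$loss) {
      best <- list(loss = te, weights = model$weights, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  model$weights <- best$weights
  list(model = model, history = hist, best_epoch = best$epoch,
       split = sp)
}

#' Train the real-vs-fake crystal discriminator
#'
#' Cross-entropy training on equal real/fake batches with generator
#' alternation; checkpoint selection by best test loss on a fixed held-out
#' real/fake set.
#'
#' @param model An `xtal_model` (discriminator head).
#' @param pool A [discriminator_pool()] built from real crystals.
#' @param config A [run_config()].
#' @param gconfig A [graph_config()].
#' @param batches_per_epoch Number of fresh batches per epoch (default 8).
#' @param verbose Print per-epoch losses.
#' @return List with `model`, `history`, `best_epoch`, and the held-out
#'   `test` batch.
#' @export
train_discriminator <- function(model, pool, config = run_config(),
                                gconfig = graph_config(),
                                batches_per_epoch = 8L, verbose = FALSE) {
  if (model$config$head != "discriminator") {
    stop("model head is not 'discriminator'")
  }
  test_raw <- make_discriminator_batch(pool, config,
                                       seed = config$seed + 990000L)
  test_batch <- crystal_batch(test_raw$entries, gconfig,
                              mols = test_raw$mols)
  opt <- adam_state(model$weights)
  best <- list(loss = Inf, weights = model$weights, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     test_loss = numeric(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 2L)
  since_best <- 0L
  for (ep in seq_len(config$max_epochs)) {
    tr_losses <- numeric(0)
    for (b in seq_len(batches_per_epoch)) {
      raw <- make_discriminator_batch(pool, config,
                                      seed = config$seed + ep * 1000L + b)
      batch <- crystal_batch(raw$entries, gconfig, mols = raw$mols)
      tape <- ag_tape()
      fw <- forward_core(tape, batch, model, training = TRUE)
      loss <- ag_softmax_xent(tape, fw$out, raw$labels)
      if (!is.finite(ag_value(loss))) stop("divergent (non-finite) loss")
      ag_backward(tape, loss)
      upd <- adam_step(model$weights, collect_grads(fw$params), opt,
                       config$lr)
      model$weights <- upd$weights; opt <- upd$state
      tr_losses <- c(tr_losses, ag_value(loss))
    }
    tape <- ag_tape()
    out <- ag_value(forward_core(tape, test_batch, model)$out)
    te <- xent_numeric(out, test_raw$labels)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                   test_loss = te))
    if (verbose) {
      message(sprintf("epoch %d: train %.5f test %.5f", ep,
                      mean(tr_losses), te))
    }
    if (te < best$loss) {
      best <- list(loss = te, weights = model$weights, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  model$weights <- best$weights
  list(model = model, history = hist, best_epoch = best$epoch,
       test = test_raw)
}

xent_numeric <- function(logits, labels) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), labels)], 1e-300)))
}

#' Select the best checkpoint from a loss trace
#'
#' @param test_losses Numeric per-epoch test losses.
#' @return Index of the minimum (first on ties).
#' @export
best_checkpoint <- function(test_losses) which.min(test_losses)

# ---- evaluation -----------------------------------------------------------

#' Evaluate the density model
#'
#' Regression metrics on packing-coefficient predictions and on the derived
#' mass density (`rho = c_pack * M / (N_A V_mol)` per molecule): relative
#' MAE (mean of per-sample `|error| / target`, which is identical for
#' c_pack and density by construction), error standard deviation, Pearson
#' R, and the least-squares slope of prediction against target.
#'
#' @param model Trained density `xtal_model`.
#' @param mols Featurized molecules.
#' @param labels True packing coefficients.
#' @param gconfig A [graph_config()].
#' @return List of metrics for `c_pack` and `density`, plus predictions.
#' @export
evaluate_density <- function(model, mols, labels,
                             gconfig = graph_config()) {
  if (!length(mols)) stop("empty test set")
  pred <- forward_density(mols, model, gconfig)
  fac <- vapply(mols, function(m) {
    m$mol_features[["mass"]] / (0.6022140857 * m$mol_features[["volume"]])
  }, numeric(1))
  metrics <- function(p, y) {
    err <- p - y
    list(mae_rel = mean(abs(err) / y),
         mae = mean(abs(err)),
         err_sd = stats::sd(err),
         pearson_r = if (stats::sd(p) == 0) 0 else stats::cor(p, y),
         slope = if (stats::sd(y) == 0) NA_real_ else
           stats::cov(p, y) / stats::var(y))
  }
  list(c_pack = metrics(pred, labels),
       density = metrics(pred * fac, labels * fac),
       predictions = pred, targets = labels)
}

#' Evaluate the discriminator
#'
#' Score distributions per class, the loss-feature correlation table, and
#' the quantile-filter fraction of fakes falling below the real-score
#' quantile.
#'
#' @param model Trained discriminator `xtal_model`.
#' @param real,fake Lists of [crystal_entry()] (or supercells).
#' @param real_mols,fake_mols Optional featurized molecules.
#' @param gconfig A [graph_config()].
#' @param q Quantile level for the filter analysis (default 0.05).
#' @return List with per-class score tables, AUC, and the quantile-filter
#'   fraction.
#' @export
evaluate_discriminator <- function(model, real, fake, real_mols = NULL,
                                   fake_mols = NULL,
                                   gconfig = graph_config(), q = 0.05) {
  rs <- score_crystals(real, model, gconfig, mols = real_mols)
  fs <- score_crystals(fake, model, gconfig, mols = fake_mols)
  auc <- wilcox_auc(rs$score, fs$score)
  list(real = rs, fake = fs, auc = auc,
       quantile_fraction = quantile_filter(rs$score, fs$score, q))
}

# rank-based AUC: P(score_real > score_fake) + 0.5 P(tie)
wilcox_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
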