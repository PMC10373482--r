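# Losses and scores: smoothed L1 for the density regression, the softmax
# and stretched score for the discriminator, the geometric vdW overlap
# score, and the correlation / quantile evaluation helpers.

#' Smoothed L1 loss
#'
#' `|x - y| - 0.5` for `|x - y| > 1`, `(x - y)^2 / 2` below; continuous at
#' the breakpoint (both one-sided values are 0.5).
#'
#' @param x,y Numeric vectors (recycled).
#' @return Elementwise loss.
#' @export
smoothed_l1 <- function(x, y) {
  d <- abs(x - y)
  ifelse(d > 1, d - 0.5, d^2 / 2)
}

#' Softmax probability from a logit pair
#'
#' Overflow-safe `exp(l1) / (exp(l1) + exp(l2))`: the probability assigned
#' to the first (real) class.
#'
#' @param logits Length-2 numeric vector, or an `n x 2` matrix of rows.
#' @return Probability (vector) in `[0, 1]`.
#' @export
softmax_pair <- function(logits) {
  if (is.matrix(logits)) {
    stopifnot(ncol(logits) == 2)
    return(1 / (1 + exp(logits[, 2] - logits[, 1])))
  }
  stopifnot(length(logits) == 2)
  1 / (1 + exp(logits[2] - logits[1]))
}

# saturation bound: the log10 odds of the largest double strictly below 1
.stretch_saturation <- log10(2 / .Machine$double.eps - 1)

#' Stretched discriminator score
#'
#' A readability transform of the softmax output that spreads values near 0
#' and 1: the base-10 log-odds `log10(p / (1 - p))`, clipped at the odds of
#' the largest double-precision value strictly below 1 so the score
#' saturates near +/-16.  Strictly increasing, zero at `p = 0.5`, and
#' antisymmetric: `score(p) = -score(1 - p)`.
#'
#' @param p Softmax probability (vector), each in `[0, 1]`.
#' @return Stretched score.
#' @export
stretch_score <- function(p) {
  if (any(p < 0 | p > 1)) stop("softmax output must lie in [0, 1]")
  s <- log10(p) - log10(1 - p)
  pmin(pmax(s, -.stretch_saturation), .stretch_saturation)
}

#' Geometric vdW overlap score
#'
#' Enumerates intermolecular atom pairs between the canonical conformer and
#' its neighboring images within a 6 Angstrom range and scores the worst
#' van der Waals overlap: `min_n -log((r_n^vdW - r_n) / r_0)` over pairs
#' whose distance `r_n` is below the radius sum `r_n^vdW`, with the scale
#' `r_0 = 1` Angstrom.  With no overlapping pair the score diverges, so it
#' is clipped at 14; larger scores mean cleaner structures, and the score
#' strictly decreases as any overlap deepens.
#'
#' @param supercell A [build_supercell()] result.
#' @param pair_range Pair enumeration range in Angstrom (default 6).
#' @param r0 Overlap scale in Angstrom (default 1).
#' @param clip Saturation value (default 14).
#' @return Scalar score.
#' @export
vdw_score <- function(supercell, pair_range = 6, r0 = 1, clip = 14) {
  can <- which(supercell$labels == 0L)
  img <- which(supercell$labels == 1L)
  if (!length(img)) return(clip)
  radii <- vdw_radii(supercell$atomic_numbers)
  p <- pairs_within(supercell$coords[img, , drop = FALSE],
                    supercell$coords[can, , drop = FALSE], pair_range)
  if (!length(p$src)) return(clip)
  rsum <- radii[img[p$src]] + radii[can[p$tgt]]
  overlap <- rsum - p$dist
  if (all(overlap <= 0)) return(clip)
  min(clip, min(-log(overlap[overlap > 0] / r0)))
}

#' Size-normalized score
#'
#' Divides a per-crystal score by the molecule's atom count, removing the
#' systematic extensivity of sum-aggregated scores.
#'
#' @param score Numeric score(s).
#' @param n_atoms Atom count(s), >= 1.
#' @return Normalized score.
#' @export
size_normalize <- function(score, n_atoms) {
  if (any(n_atoms < 1)) stop("n_atoms must be at least 1")
  score / n_atoms
}

#' Pearson correlations between losses/scores and sample features
#'
#' One Pearson r per feature column, with the reporting rules applied: a
#' feature is retained only when `|r| >= 0.05` and its incidence (fraction
#' of samples with a nonzero value) is at least 5%.  Zero-variance features
#' have undefined r and are never retained.
#'
#' @param values Numeric vector (per-sample losses or scores).
#' @param features Data frame or matrix of per-sample features.
#' @param r_min Absolute correlation threshold (default 0.05).
#' @param incidence_min Incidence threshold (default 0.05).
#' @return Data frame: feature, pearson_r, incidence, retained.
#' @export
pearson_feature_correlations <- function(values, features, r_min = 0.05,
                                         incidence_min = 0.05) {
  features <- as.data.frame(features)
  if (nrow(features) != length(values)) stop("length mismatch")
  res <- lapply(names(features), function(nm) {
    f <- as.numeric(features[[nm]])
    inc <- mean(f != 0, na.rm = TRUE)
    r <- if (stats::sd(f, na.rm = TRUE) == 0 || stats::sd(values) == 0) {
      NA_real_
    } else stats::cor(values, f, use = "complete.obs")
    data.frame(feature = nm, pearson_r = r, incidence = inc,
               retained = !is.na(r) && abs(r) >= r_min && inc >= incidence_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Quantile-threshold filtering fraction
#'
#' Computes the empirical `q`-quantile (linear interpolation) of a
#' reference score distribution and returns the fraction of candidate
#' scores strictly below that threshold — the proportion of candidates a
#' quantile filter at level `q` would discard.
#'
#' @param test_scores Reference scores (e.g. held-out real crystals).
#' @param candidate_scores Scores of proposed structures.
#' @param q Quantile level in (0, 1) (default 0.05).
#' @return Fraction of candidates below the threshold.
#' @export
quantile_filter <- function(test_scores, candidate_scores, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0, 1)")
  if (!length(test_scores) || !length(candidate_scores)) {
    stop("score lists must be nonempty")
  }
  thr <- stats::quantile(test_scores, q, type = 7, names = FALSE)
  mean(candidate_scores < thr)
}

#' Tabulate discriminator scores for a set of crystals
#'
#' Convenience report: raw logits, softmax probability, stretched score,
#' vdW score and the size-normalized stretched score, one row per crystal.
#'
#' @param entries List of [crystal_entry()] objects.
#' @param model A discriminator `xtal_model`.
#' @param gconfig A [graph_config()].
#' @param mols Optional featurized molecules.
#' @return Data frame, one row per entry.
#' @export
score_crystals <- function(entries, model, gconfig = graph_config(),
                           mols = NULL) {
  logits <- forward_discriminator(entries, model, gconfig, mols = mols)
  p <- softmax_pair(logits)
  s <- stretch_score(p)
  vs <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    sc <- if (inherits(e, "supercell_structure")) e else
      build_supercell(e, gconfig$N, gconfig$r_c)
    vdw_score(sc)
  }, numeric(1))
  n_at <- vapply(entries, function(e) {
    if (inherits(e, "supercell_structure")) sum(e$labels == 0L) else
      length(e$molecule$atomic_numbers)
  }, numeric(1))
  data.frame(
    identifier = vapply(entries, function(e) e$identifier, ""),
    logit_real = logits[, 1], logit_fake = logits[, 2],
    p_real = p, score = s, vdw_score = vs,
    score_per_atom = size_normalize(s, n_at),
    stringsAsFactors = FALSE
  )
}
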