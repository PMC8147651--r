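#' Simulate a symmetric polypharmacy label tensor with planted structure
#'
#' Generates a binary drug-drug-effect label tensor whose positives follow a
#' smooth, feature-linked propensity, so that models and validation schemes
#' can be exercised without any external download. The generative model is:
#'
#' * drug latents \eqn{u_i \in R^r} and effect latents \eqn{v_k \in R^r},
#'   i.i.d. standard normal;
#' * a symmetric bilinear propensity
#'   \eqn{s_{ijk} = \sigma(\alpha\, u_i \cdot u_j / \sqrt r +
#'   (u_i \circ u_j)^\top W v_k)}, where \eqn{\circ} is the elementwise
#'   product — symmetric in the drug modes by construction. The pair-level
#'   term \eqn{\alpha\, u_i \cdot u_j} concentrates positives on interacting
#'   pairs (when two drugs interact, a larger set of effects tends to occur);
#' * labels: the `target_prevalence` quantile of the propensity over all
#'   canonical off-diagonal cells is the threshold (top cells are positive),
#'   so the realized prevalence is exact up to rounding one cell;
#' * mono-drug features: binary images \eqn{x_{im} = 1[(P u_i)_m > 0]} of the
#'   drug latents through a random projection \eqn{P}; each bit is replaced,
#'   with probability `feature_noise`, by an independent fair coin flip. At
#'   `feature_noise = 0` the features determine the latents' directions (the
#'   Gaussian drug kernel is informative); at `feature_noise = 1` they carry
#'   no signal at all.
#'
#' @param n_drugs,n_effects tensor dimensions.
#' @param latent_dim latent dimension \eqn{r} (default 8).
#' @param target_prevalence fraction of positive canonical triplets,
#'   in (0, 1); default 0.02, the prevalence of the reference
#'   pharmacovigilance benchmark.
#' @param feature_noise probability that a mono-feature bit is replaced by
#'   an independent Bernoulli(1/2) draw; in `[0, 1]`.
#' @param n_mono_features number of binary mono-effect features (default 64).
#' @param pair_effect weight \eqn{\alpha} of the pair-level propensity term
#'   (default 1).
#' @param seed integer seed; the same seed reproduces the outputs exactly.
#' @return a list of class `"polypharmacy_sim"`: `tensor` (a
#'   `"triplet_tensor"`), `features` (binary drug x mono-feature matrix),
#'   `propensity` (dense array of the continuous planted propensities, for
#'   oracle checks; symmetric, zero drug-diagonal) and `config`.
#' @examples
#' sim <- simulate_polypharmacy(n_drugs = 20, n_effects = 8, seed = 42)
#' positive_prevalence(sim$tensor)
#' @seealso [decagon_like()] for the benchmark-shaped preset.
#' @export
simulate_polypharmacy <- function(n_drugs, n_effects, latent_dim = 8,
                                  target_prevalence = 0.02,
                                  feature_noise = 0.05,
                                  n_mono_features = 64, pair_effect = 1,
                                  seed = 1) {
  cfg <- synth_config(n_drugs, n_effects, latent_dim, target_prevalence,
                      feature_noise, n_mono_features, pair_effect, seed)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  parts <- synth_propensity(cfg)
  np <- n_pairs(n_drugs)
  npos <- round(np * n_effects * target_prevalence)
  if (npos < 1L)
    stop("unreachable prevalence: fewer than one positive cell at this size")
  thr <- sort(parts$s, decreasing = TRUE)[npos]
  lab <- parts$s >= thr              # np x ne logical
  if (sum(lab) > npos) {             # ties at the threshold: keep the first
    extra <- which(parts$s == thr)
    lab[extra[seq_len(sum(lab) - npos)]] <- FALSE
  }
  finish_sim(cfg, parts, lab)
}

#' Benchmark-shaped synthetic preset
#'
#' A preset of [simulate_polypharmacy()] that reproduces, at a configurable
#' reduced scale, the two printed descriptive statistics of the reference
#' pharmacovigilance benchmark (645 drugs x 963 effects): 2% positive
#' triplet prevalence caused by about 70% of all drug pairs. An exact 70%
#' subset of pairs (the highest pair-level propensities, hence still
#' feature-linked) is designated interacting; each interacting pair is
#' guaranteed its highest-propensity effect and the remaining positive
#' budget is filled by global propensity rank within interacting pairs.
#' When the positive budget cannot cover the requested pair fraction
#' (possible at very small scale), coverage is capped at
#' `n_positives / n_pairs`.
#'
#' @inheritParams simulate_polypharmacy
#' @param target_pair_fraction fraction of pairs that interact (default 0.7).
#' @param ... further arguments to the base generator configuration.
#' @return as [simulate_polypharmacy()].
#' @examples
#' sim <- decagon_like(n_drugs = 40, n_effects = 50, seed = 1)
#' interacting_pair_fraction(sim$tensor)
#' @export
decagon_like <- function(n_drugs = 100, n_effects = 50,
                         target_prevalence = 0.02,
                         target_pair_fraction = 0.7, latent_dim = 8,
                         feature_noise = 0.05, n_mono_features = 64,
                         pair_effect = 1, seed = 1) {
  cfg <- synth_config(n_drugs, n_effects, latent_dim, target_prevalence,
                      feature_noise, n_mono_features, pair_effect, seed)
  if (target_pair_fraction <= 0 || target_pair_fraction > 1)
    stop("`target_pair_fraction` must be in (0, 1]")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  parts <- synth_propensity(cfg)
  np <- n_pairs(n_drugs)
  npos <- round(np * n_effects * target_prevalence)
  if (npos < 1L)
    stop("unreachable prevalence: fewer than one positive cell at this size")
  n_int <- min(round(np * target_pair_fraction), npos)
  int_pairs <- order(parts$g, decreasing = TRUE)[seq_len(n_int)]
  lab <- matrix(FALSE, np, n_effects)
  # guarantee each interacting pair its top effect
  top_eff <- max.col(parts$s[int_pairs, , drop = FALSE], ties.method = "first")
  lab[cbind(int_pairs, top_eff)] <- TRUE
  remaining <- npos - n_int
  if (remaining > 0L) {
    cand <- parts$s
    cand[-int_pairs, ] <- -Inf          # positives only on interacting pairs
    cand[lab] <- -Inf
    take <- order(cand, decreasing = TRUE)[seq_len(remaining)]
    lab[take] <- TRUE
  }
  finish_sim(cfg, parts, lab)
}

synth_config <- function(n_drugs, n_effects, latent_dim, target_prevalence,
                         feature_noise, n_mono_features, pair_effect, seed) {
  stopifnot(n_drugs >= 2, n_effects >= 1, latent_dim >= 1,
            n_mono_features >= 1)
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must be in (0, 1)")
  if (feature_noise < 0 || feature_noise > 1)
    stop("`feature_noise` must be in [0, 1]")
  list(n_drugs = as.integer(n_drugs), n_effects = as.integer(n_effects),
       latent_dim = as.integer(latent_dim),
       target_prevalence = target_prevalence, feature_noise = feature_noise,
       n_mono_features = as.integer(n_mono_features),
       pair_effect = pair_effect, seed = as.integer(seed))
}

## Latents, pair propensity g (np), cell propensity s (np x ne, on the
## probability scale), and the noisy binary mono-feature matrix.
synth_propensity <- function(cfg) {
  r <- cfg$latent_dim
  u <- matrix(stats::rnorm(cfg$n_drugs * r), cfg$n_drugs, r)
  v <- matrix(stats::rnorm(cfg$n_effects * r), cfg$n_effects, r)
  w <- matrix(stats::rnorm(r * r), r, r) / sqrt(r)
  pr <- all_pairs(cfg$n_drugs)
  up <- u[pr[, 1L], , drop = FALSE] * u[pr[, 2L], , drop = FALSE]
  g <- cfg$pair_effect * rowSums(u[pr[, 1L], , drop = FALSE] *
                                   u[pr[, 2L], , drop = FALSE]) / sqrt(r)
  z <- up %*% w %*% t(v) / sqrt(r)
  s <- stats::plogis(g + z)
  proj <- matrix(stats::rnorm(cfg$n_mono_features * r),
                 cfg$n_mono_features, r)
  x <- (u %*% t(proj) > 0) * 1
  if (cfg$feature_noise > 0) {
    noisy <- matrix(stats::runif(length(x)) < cfg$feature_noise, nrow(x))
    x[noisy] <- stats::rbinom(sum(noisy), 1L, 0.5)
  }
  list(u = u, v = v, pairs = pr, g = g, s = s, features = x)
}

finish_sim <- function(cfg, parts, lab) {
  drug_ids <- sprintf("d%03d", seq_len(cfg$n_drugs))
  effect_ids <- sprintf("e%03d", seq_len(cfg$n_effects))
  pos <- which(lab, arr.ind = TRUE)
  rec <- data.frame(drug_a = drug_ids[parts$pairs[pos[, 1L], 1L]],
                    drug_b = drug_ids[parts$pairs[pos[, 1L], 2L]],
                    effect = effect_ids[pos[, 2L]])
  tensor <- triplet_tensor(rec, drug_ids = drug_ids, effect_ids = effect_ids)
  prop <- array(0, c(cfg$n_drugs, cfg$n_drugs, cfg$n_effects),
                dimnames = list(drug_ids, drug_ids, effect_ids))
  for (k in seq_len(cfg$n_effects)) {
    m <- matrix(0, cfg$n_drugs, cfg$n_drugs)
    m[parts$pairs] <- parts$s[, k]
    prop[, , k] <- m + t(m)
  }
  features <- parts$features
  dimnames(features) <- list(drug_ids,
                             sprintf("m%03d", seq_len(cfg$n_mono_features)))
  structure(list(tensor = tensor, features = features, propensity = prop,
                 config = cfg),
            class = "polypharmacy_sim")
}

#' @export
print.polypharmacy_sim <- function(x, ...) {
  cat(sprintf("Synthetic polypharmacy data (seed %d)\n", x$config$seed))
  print(x$tensor)
  cat(sprintf("  mono features: %d (noise %.2f)\n",
              x$config$n_mono_features, x$config$feature_noise))
  invisible(x)
}
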