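#' Simulate a compound-to-expression world with a planted map
#'
#' Generates Bernoulli fingerprint bits and uniform \[0,1\] descriptor
#' values, then produces 978-gene signatures through a planted map
#' (linear, or a shallow tanh network) plus additive Gaussian noise. The
#' map coefficients are scaled so signature values have a differential-
#' expression-like spread (per-gene SD around 2 before noise). Used to
#' test whether the expression-generation model recovers a recoverable
#' structure-to-expression relationship.
#'
#' @param n_compounds Number of compounds.
#' @param n_fingerprint_bits,n_properties Feature widths (defaults give the
#'   50-feature planted world used throughout the recovery checks).
#' @param map `"linear"` or `"shallow"` (one hidden tanh layer).
#' @param noise_sd SD of the additive expression noise, in signature units.
#' @param seed Integer seed; the world is fully reproducible from it.
#' @return List with `fingerprints`, `properties`, `signatures` (matrices
#'   with compound rownames), `map` (the planted parameters) and `config`.
#' @export
simulate_expression_world <- function(n_compounds = 500L,
                                      n_fingerprint_bits = 32L,
                                      n_properties = 18L,
                                      map = c("linear", "shallow"),
                                      noise_sd = 0.5, seed = 7L) {
  map <- match.arg(map)
  stop_if(n_compounds < 1 || n_fingerprint_bits < 1 || n_properties < 1,
          "all counts must be > 0")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  set.seed(derive_seed(seed, "expr-world"))
  ids <- sprintf("C%05d", seq_len(n_compounds))
  fp <- matrix(stats::rbinom(n_compounds * n_fingerprint_bits, 1, 0.3),
               n_compounds, dimnames = list(ids, NULL))
  pr <- matrix(stats::runif(n_compounds * n_properties),
               n_compounds, dimnames = list(ids, NULL))
  x <- cbind(fp, pr)
  p <- ncol(x)
  genes <- sprintf("G%04d", seq_len(978L))
  feat_var <- c(rep(0.3 * 0.7, n_fingerprint_bits), rep(1 / 12, n_properties))
  if (map == "linear") {
    w_sd <- sqrt(4 / sum(feat_var))
    w <- matrix(stats::rnorm(p * 978L, 0, w_sd), p, 978L)
    signal <- x %*% w
    planted <- list(type = "linear", w = w)
  } else {
    hdim <- 32L
    w1 <- matrix(stats::rnorm(p * hdim, 0, sqrt(2 / p)), p, hdim)
    w2 <- matrix(stats::rnorm(hdim * 978L, 0, sqrt(2 / hdim)), hdim, 978L)
    signal <- tanh(scale(x %*% w1)) %*% w2
    signal <- signal * (2 / stats::sd(signal))
    planted <- list(type = "shallow", w1 = w1, w2 = w2)
  }
  noise <- matrix(stats::rnorm(n_compounds * 978L, 0, noise_sd),
                  n_compounds, 978L)
  signatures <- signal + noise
  dimnames(signatures) <- list(ids, genes)
  list(fingerprints = fp, properties = pr, signatures = signatures,
       signal = signal, map = planted,
       config = list(n_compounds = n_compounds,
                     n_fingerprint_bits = n_fingerprint_bits,
                     n_properties = n_properties, map = map,
                     noise_sd = noise_sd, seed = seed))
}

#' Simulate a DDI world with planted translating-embedding structure
#'
#' Samples true drug latents and, per side effect, a relation vector with
#' head/tail projections; scores every unordered drug pair with the
#' two-direction translating-embedding distance and labels the
#' lowest-scoring quantile (of size `positive_fraction`) positive for each
#' side effect. Drug expression signatures are a fixed random linear
#' embedding of the true latents, so the planted structure is recoverable
#' from the features. Optional symmetric label noise flips labels.
#'
#' @param n_drugs Number of drugs (>= 4).
#' @param n_side_effects Number of side effects.
#' @param latent_width,embedding_width Widths of the planted latents and
#'   relation space.
#' @param positive_fraction Fraction of pairs positive per side effect,
#'   in (0, 1).
#' @param label_noise Probability of flipping each pair's label.
#' @param seed Integer seed.
#' @return List with `triplets` (positives as a [triplet_dataset()]),
#'   `truth` (all pairs x side effects with true scores and labels),
#'   `expressions` (drugs x 978 matrix), and `params` (planted latents and
#'   side-effect spaces).
#' @export
simulate_ddi_world <- function(n_drugs = 60L, n_side_effects = 8L,
                               latent_width = 16L, embedding_width = 8L,
                               positive_fraction = 0.2, label_noise = 0,
                               seed = 7L) {
  stop_if(n_drugs < 4, "need at least 4 drugs")
  stop_if(positive_fraction <= 0 || positive_fraction >= 1,
          "positive_fraction must be in (0,1)")
  set.seed(derive_seed(seed, "ddi-world"))
  ids <- sprintf("D%03d", seq_len(n_drugs))
  z <- matrix(stats::rnorm(n_drugs * latent_width), n_drugs,
              dimnames = list(ids, NULL))
  a_embed <- matrix(stats::rnorm(978L * latent_width, 0, 1 / sqrt(latent_width)),
                    978L, latent_width)
  expressions <- z %*% t(a_embed)
  expressions <- expressions * (2 / stats::sd(expressions))
  dimnames(expressions) <- list(ids, sprintf("G%04d", seq_len(978L)))
  pairs <- t(utils::combn(n_drugs, 2))
  n_pairs <- nrow(pairs)
  m_pos <- round(positive_fraction * n_pairs)
  stop_if(m_pos < 1, "positive_fraction yields no positives per side effect")
  spaces <- vector("list", n_side_effects)
  truth <- vector("list", n_side_effects)
  se_ids <- sprintf("SE%02d", seq_len(n_side_effects))
  for (r in seq_len(n_side_effects)) {
    m_rh <- matrix(stats::rnorm(embedding_width * latent_width,
                                0, 1 / sqrt(latent_width)),
                   embedding_width, latent_width)
    m_rt <- matrix(stats::rnorm(embedding_width * latent_width,
                                0, 1 / sqrt(latent_width)),
                   embedding_width, latent_width)
    rv <- stats::rnorm(embedding_width)
    spaces[[r]] <- side_effect_space(m_rh, m_rt, rv)
    zh <- z[pairs[, 1], , drop = FALSE]
    zt <- z[pairs[, 2], , drop = FALSE]
    v1 <- sweep(zh %*% t(m_rh) - zt %*% t(m_rt), 2, rv, "+")
    v2 <- sweep(zt %*% t(m_rh) - zh %*% t(m_rt), 2, rv, "+")
    s <- sqrt(rowSums(v1^2)) + sqrt(rowSums(v2^2))
    lab <- integer(n_pairs)
    lab[order(s)[seq_len(m_pos)]] <- 1L
    if (label_noise > 0) {
      flip <- stats::runif(n_pairs) < label_noise
      lab[flip] <- 1L - lab[flip]
    }
    truth[[r]] <- data.frame(drug_i = ids[pairs[, 1]],
                             drug_j = ids[pairs[, 2]],
                             side_effect = se_ids[r],
                             score = s, label = lab,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  pos <- truth[truth$label == 1L, , drop = FALSE]
  names(spaces) <- se_ids
  list(
    triplets = triplet_dataset(pos$drug_i, pos$drug_j, pos$side_effect,
                               pos$label),
    truth = truth,
    expressions = expressions,
    params = list(latents = z, spaces = spaces, gene_embedding = a_embed),
    config = list(n_drugs = n_drugs, n_side_effects = n_side_effects,
                  latent_width = latent_width,
                  embedding_width = embedding_width,
                  positive_fraction = positive_fraction,
                  label_noise = label_noise, seed = seed)
  )
}
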