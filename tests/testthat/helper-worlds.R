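# Shared fixtures, built in code. Heavyweight objects are memoized so
# several test files can reuse one instance.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small DDI world with train/test splits and matched negatives.
tiny_ddi_data <- function(seed = 11L, n_drugs = 14L, n_se = 3L) {
  memo(paste0("ddi-data-", seed, "-", n_drugs, "-", n_se), {
    w <- simulate_ddi_world(n_drugs = n_drugs, n_side_effects = n_se,
                            positive_fraction = 0.25, seed = seed)
    sp <- split_triplets(w$triplets, "unseen_interaction",
                         test_fraction = 0.15, val_fraction = 0.05,
                         seed = seed)
    vocab <- rownames(w$expressions)
    neg_tr <- sample_negatives(sp$train, seed = seed + 1L, vocabulary = vocab,
                               exclude = w$triplets)
    neg_te <- sample_negatives(sp$test, seed = seed + 2L, vocabulary = vocab,
                               exclude = rbind(as.data.frame(w$triplets),
                                               as.data.frame(neg_tr)))
    list(world = w,
         train = rbind(as.data.frame(sp$train), as.data.frame(neg_tr)),
         test = rbind(as.data.frame(sp$test), as.data.frame(neg_te)))
  })
}

# Barely-trained full-width model (H = 978): cheap, used for API and
# interpretability contracts that do not need a converged fit.
tiny_ddi_model <- function() {
  memo("ddi-model-978", {
    d <- tiny_ddi_data()
    cfg <- ddi_model_config(latent_width = 978L, reduced_width = 16L,
                            embedding_width = 8L, epochs = 2L, seed = 5L)
    fit_ddi_model(d$train, d$world$expressions, cfg)
  })
}

# Compact trained model for behavioural checks.
small_trained_ddi_model <- function() {
  memo("ddi-model-small", {
    d <- tiny_ddi_data()
    cfg <- ddi_model_config(latent_width = 48L, reduced_width = 16L,
                            embedding_width = 8L, epochs = 150L,
                            lr_period = 75L, seed = 5L)
    fit_ddi_model(d$train, d$world$expressions, cfg)
  })
}

# A 1000-row unordered triplet dataset for split-protocol checks.
thousand_triplets <- function(seed = 3L) {
  memo("triplets-1000", {
    set.seed(seed)
    drugs <- sprintf("D%03d", 1:40)
    ses <- sprintf("SE%02d", 1:5)
    combos <- expand.grid(i = 1:39, j = 2:40, se = ses,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$i < combos$j, ]
    pick <- combos[sample.int(nrow(combos), 1000L), ]
    triplet_dataset(drugs[pick$i], drugs[pick$j], pick$se,
                    rep(1L, 1000L))
  })
}

# Brute-force ranking oracles, independent of the implementations under
# test: direct enumeration of positive-negative comparisons and of
# threshold-by-threshold confusion matrices.
auc_oracle <- function(scores, labels, lower_is_positive = TRUE) {
  s <- if (lower_is_positive) -scores else scores
  pos <- s[labels == 1]
  neg <- s[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

aupr_oracle <- function(scores, labels, lower_is_positive = TRUE) {
  s <- if (lower_is_positive) -scores else scores
  ths <- sort(unique(s), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  r_prev <- 0
  for (t in ths) {
    pred <- s >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

youden_oracle <- function(scores, labels, lower_is_positive = TRUE) {
  u <- sort(unique(scores))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  best_th <- NA_real_
  for (th in cands) {
    pred <- if (lower_is_positive) scores <= th else scores >= th
    j <- sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0) - 1
    if (j > best + 1e-12) {
      best <- j
      best_th <- th
    }
  }
  list(threshold = best_th, j = best)
}
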