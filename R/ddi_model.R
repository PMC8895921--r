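#' Gated linear unit
#'
#' Elementwise product of a payload vector with a sigmoid-activated gate:
#' `GLU(A, B) = A * sigmoid(B)`. The gate controls, per element, how much
#' of the payload propagates; here it encodes the influence of the
#' co-administered partner drug on each gene.
#'
#' @param a Payload vector (output of the previous layer).
#' @param b Gate input vector, same length.
#' @return Vector `a * sigmoid(b)`; every entry is bounded by `|a|`.
#' @export
glu_gate <- function(a, b) {
  stop_if(length(a) != length(b), "payload and gate lengths differ")
  a * sigmoid(b)
}

#' Side-effect embedding space
#'
#' Holds the relation vector and the head/tail projection matrices of one
#' side effect for the translating-embedding score.
#'
#' @param m_rh,m_rt Projection matrices (embedding width x drug width).
#' @param r Relation embedding vector (embedding width).
#' @return Object of class `"side_effect_space"`.
#' @export
side_effect_space <- function(m_rh, m_rt, r) {
  stop_if(!identical(dim(m_rh), dim(m_rt)), "projection shapes differ")
  stop_if(nrow(m_rh) != length(r), "relation vector width != projection rows")
  structure(list(m_rh = m_rh, m_rt = m_rt, r = r), class = "side_effect_space")
}

#' Translating-embedding score of a drug pair for one side effect
#'
#' Distance-style score
#' `S = ||M_rh z_h + r - M_rt z_t|| + ||M_rh z_t + r - M_rt z_h||`
#' (L2 norms). Both directions are summed because drug combinations carry
#' no directionality, making the score exactly symmetric in the pair.
#' Lower scores mean a more plausible interaction.
#'
#' @param z_h,z_t Drug representations (reduced latents).
#' @param space A [side_effect_space()].
#' @return Non-negative scalar.
#' @export
triplet_score <- function(z_h, z_t, space) {
  stop_if(!inherits(space, "side_effect_space"), "`space` must be a side_effect_space")
  stop_if(length(z_h) != ncol(space$m_rh) || length(z_t) != ncol(space$m_rh),
          "drug representation width != projection columns")
  v1 <- space$m_rh %*% z_h + space$r - space$m_rt %*% z_t
  v2 <- space$m_rh %*% z_t + space$r - space$m_rt %*% z_h
  sqrt(sum(v1^2)) + sqrt(sum(v2^2))
}

#' Margin ranking loss over matched positive/negative scores
#'
#' Default (`form = "pairwise"`): mean over matched (positive, negative)
#' pairs of `max(0, S_pos - S_neg + margin)`; zero exactly when every
#' negative scores at least `margin` above its matched positive.
#' `form = "aggregate"` instead applies a single hinge to the difference of
#' summed positive and summed negative scores.
#'
#' @param pos_scores,neg_scores Non-empty numeric vectors; for the pairwise
#'   form they must have equal length (elementwise matching).
#' @param margin Positive margin.
#' @param form `"pairwise"` or `"aggregate"`.
#' @return Non-negative scalar.
#' @export
margin_loss <- function(pos_scores, neg_scores, margin = 1,
                        form = c("pairwise", "aggregate")) {
  form <- match.arg(form)
  stop_if(length(pos_scores) == 0 || length(neg_scores) == 0,
          "score lists must be non-empty")
  stop_if(margin <= 0, "`margin` must be > 0")
  if (form == "pairwise") {
    stop_if(length(pos_scores) != length(neg_scores),
            "pairwise form needs matched score vectors of equal length")
    mean(pmax(0, pos_scores - neg_scores + margin))
  } else {
    max(0, sum(pos_scores) - sum(neg_scores) + margin)
  }
}

#' Configuration for the DDI prediction model
#'
#' @param latent_width Width H of the shared drug encoding and the gate.
#'   The default 978 keeps gate entries aligned to the landmark genes,
#'   which the interpretability analysis requires.
#' @param reduced_width Width D after dimension reduction.
#' @param embedding_width Width E of the side-effect embedding space.
#' @param margin Margin of the ranking loss.
#' @param gate `"pair"` (default; pair-conditional GLU gates) or `"open"`
#'   (gates forced to 1 — the ablation without the co-administration
#'   module).
#' @param score `"transe"` (translating-embedding score) or `"mlp"` (plain
#'   feed-forward classifier head — the ablation without the embedding
#'   module).
#' @param head_hidden Hidden width of the `"mlp"` ablation head.
#' @param loss_form `"pairwise"` or `"aggregate"`, see [margin_loss()].
#' @param activation Encoder/head activation, `"relu"` or `"tanh"`.
#' @param l2 L2 weight-decay coefficient.
#' @param epochs Full-batch training epochs.
#' @param lr_max,lr_min,lr_period Cosine-annealing schedule (in epochs).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `"ddi_model_config"`.
#' @export
ddi_model_config <- function(latent_width = 978L, reduced_width = 128L,
                             embedding_width = 64L, margin = 1,
                             gate = c("pair", "open"),
                             score = c("transe", "mlp"), head_hidden = 32L,
                             loss_form = c("pairwise", "aggregate"),
                             activation = "relu", l2 = 1e-5,
                             epochs = 300L, lr_max = 5e-3, lr_min = 1e-4,
                             lr_period = 100L, seed = 1L) {
  gate <- match.arg(gate)
  score <- match.arg(score)
  loss_form <- match.arg(loss_form)
  stop_if(margin <= 0, "`margin` must be > 0")
  stop_if(latent_width < 1 || reduced_width < 1 || embedding_width < 1,
          "all widths must be > 0")
  structure(as.list(environment()), class = "ddi_model_config")
}

ddi_init_params <- function(cfg, n_se, n_genes = 978L) {
  H <- cfg$latent_width; D <- cfg$reduced_width; E <- cfg$embedding_width
  gl <- function(nout, nin) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nout, nin)
  }
  p <- list(W1 = gl(H, n_genes), b1 = numeric(H),
            Wr = gl(D, H), br = numeric(D))
  if (cfg$gate == "pair") {
    p$Wgs <- gl(H, H)
    p$Wgp <- gl(H, H)
    p$bg <- numeric(H)
  }
  if (cfg$score == "transe") {
    for (r in seq_len(n_se)) {
      p[[paste0("Mh", r)]] <- gl(E, D)
      p[[paste0("Mt", r)]] <- gl(E, D)
      p[[paste0("rv", r)]] <- stats::rnorm(E, 0, 0.5)
    }
  } else {
    p$Wh <- gl(cfg$head_hidden, 2L * D)
    p$bh <- numeric(cfg$head_hidden)
    p$wo <- matrix(stats::rnorm(n_se * cfg$head_hidden, 0,
                                sqrt(2 / cfg$head_hidden)),
                   n_se, cfg$head_hidden)
    p$bo <- numeric(n_se)
  }
  p
}

# Scatter-accumulate rows of `d` onto `m` target rows indexed by `idx`.
acc_rows <- function(d, idx, m) {
  rs <- rowsum(d, idx)
  out <- matrix(0, m, ncol(d))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Forward pass over a batch of triplets. Drug encodings are computed once
# per drug and gates once per ordered drug pair, then gathered per triplet.
# hi, ti: drug indices; se: side-effect indices (into 1..n_se).
ddi_forward <- function(params, cfg, X, hi, ti, se, n_se, want_cache = FALSE) {
  act <- activation_fun(cfg$activation)
  pre <- sweep(X %*% t(params$W1), 2, params$b1, "+")
  Hd <- act$f(pre)
  okey <- paste(c(hi, ti), c(ti, hi))
  pairs_tab <- unique(data.frame(self = c(hi, ti), part = c(ti, hi)))
  pkey <- paste(pairs_tab$self, pairs_tab$part)
  pidx <- match(okey, pkey)
  B <- length(hi)
  pidx_h <- pidx[seq_len(B)]
  pidx_t <- pidx[B + seq_len(B)]
  Hs <- Hd[pairs_tab$self, , drop = FALSE]
  Hp <- Hd[pairs_tab$part, , drop = FALSE]
  if (cfg$gate == "pair") {
    U <- sweep(Hs %*% t(params$Wgs) + Hp %*% t(params$Wgp), 2, params$bg, "+")
    G <- sigmoid(U)
    A <- Hs * G
  } else {
    U <- NULL; G <- NULL
    A <- Hs
  }
  Zp <- sweep(A %*% t(params$Wr), 2, params$br, "+")
  Zh <- Zp[pidx_h, , drop = FALSE]
  Zt <- Zp[pidx_t, , drop = FALSE]
  S <- numeric(B)
  se_cache <- vector("list", n_se)
  if (cfg$score == "transe") {
    for (r in seq_len(n_se)) {
      I <- which(se == r)
      if (!length(I)) next
      Mh <- params[[paste0("Mh", r)]]
      Mt <- params[[paste0("Mt", r)]]
      rv <- params[[paste0("rv", r)]]
      V1 <- sweep(Zh[I, , drop = FALSE] %*% t(Mh) -
                    Zt[I, , drop = FALSE] %*% t(Mt), 2, rv, "+")
      V2 <- sweep(Zt[I, , drop = FALSE] %*% t(Mh) -
                    Zh[I, , drop = FALSE] %*% t(Mt), 2, rv, "+")
      n1 <- sqrt(rowSums(V1^2))
      n2 <- sqrt(rowSums(V2^2))
      S[I] <- n1 + n2
      if (want_cache) se_cache[[r]] <- list(I = I, V1 = V1, V2 = V2,
                                            n1 = n1, n2 = n2)
    }
  } else {
    C1 <- cbind(Zh, Zt)
    C2 <- cbind(Zt, Zh)
    P1 <- sweep(C1 %*% t(params$Wh), 2, params$bh, "+")
    P2 <- sweep(C2 %*% t(params$Wh), 2, params$bh, "+")
    A1 <- act$f(P1); A2 <- act$f(P2)
    wo_rows <- params$wo[se, , drop = FALSE]
    logit <- 0.5 * (rowSums(A1 * wo_rows) + rowSums(A2 * wo_rows)) +
      params$bo[se]
    S <- -logit
    if (want_cache) se_cache <- list(C1 = C1, C2 = C2, P1 = P1, P2 = P2,
                                     A1 = A1, A2 = A2)
  }
  out <- list(scores = S)
  if (want_cache) {
    out$cache <- list(pre = pre, Hd = Hd, pairs_tab = pairs_tab,
                      pidx_h = pidx_h, pidx_t = pidx_t, Hs = Hs, Hp = Hp,
                      U = U, G = G, A = A, Zp = Zp, Zh = Zh, Zt = Zt,
                      se_cache = se_cache)
  }
  out
}

# Backward pass: `coef` is dLoss/dScore per triplet. Returns gradients for
# every parameter (plus L2 terms on weight matrices).
ddi_backward <- function(params, cfg, X, hi, ti, se, n_se, fwd, coef) {
  act <- activation_fun(cfg$activation)
  cc <- fwd$cache
  B <- length(hi)
  D <- cfg$reduced_width
  g <- list()
  dZh <- matrix(0, B, D)
  dZt <- matrix(0, B, D)
  if (cfg$score == "transe") {
    for (r in seq_len(n_se)) {
      sc <- cc$se_cache[[r]]
      if (is.null(sc)) next
      I <- sc$I
      cI <- coef[I]
      u1 <- sc$V1 / pmax(sc$n1, 1e-12)
      u2 <- sc$V2 / pmax(sc$n2, 1e-12)
      Mh <- params[[paste0("Mh", r)]]
      Mt <- params[[paste0("Mt", r)]]
      cu1 <- cI * u1
      cu2 <- cI * u2
      dZh[I, ] <- dZh[I, ] + cu1 %*% Mh - cu2 %*% Mt
      dZt[I, ] <- dZt[I, ] + cu2 %*% Mh - cu1 %*% Mt
      g[[paste0("Mh", r)]] <- t(cu1) %*% cc$Zh[I, , drop = FALSE] +
        t(cu2) %*% cc$Zt[I, , drop = FALSE] + cfg$l2 * Mh
      g[[paste0("Mt", r)]] <- -(t(cu1) %*% cc$Zt[I, , drop = FALSE] +
                                  t(cu2) %*% cc$Zh[I, , drop = FALSE]) +
        cfg$l2 * Mt
      g[[paste0("rv", r)]] <- colSums(cu1 + cu2)
    }
    for (r in seq_len(n_se)) {
      for (nm in paste0(c("Mh", "Mt", "rv"), r)) {
        if (is.null(g[[nm]])) g[[nm]] <- params[[nm]] * 0
      }
    }
  } else {
    sc <- cc$se_cache
    dlogit <- -coef
    wo_rows <- params$wo[se, , drop = FALSE]
    dA1 <- 0.5 * dlogit * wo_rows
    dA2 <- 0.5 * dlogit * wo_rows
    dwo_all <- 0.5 * dlogit * (sc$A1 + sc$A2)
    g$wo <- acc_rows(dwo_all, se, n_se) + cfg$l2 * params$wo
    g$bo <- as.numeric(acc_rows(matrix(dlogit, ncol = 1), se, n_se))
    dP1 <- dA1 * act$df(sc$P1, sc$A1)
    dP2 <- dA2 * act$df(sc$P2, sc$A2)
    g$Wh <- t(dP1) %*% sc$C1 + t(dP2) %*% sc$C2 + cfg$l2 * params$Wh
    g$bh <- colSums(dP1) + colSums(dP2)
    dC1 <- dP1 %*% params$Wh
    dC2 <- dP2 %*% params$Wh
    dZh <- dC1[, seq_len(D), drop = FALSE] + dC2[, D + seq_len(D), drop = FALSE]
    dZt <- dC1[, D + seq_len(D), drop = FALSE] + dC2[, seq_len(D), drop = FALSE]
  }
  M <- nrow(cc$pairs_tab)
  dZp <- acc_rows(dZh, cc$pidx_h, M) + acc_rows(dZt, cc$pidx_t, M)
  g$Wr <- t(dZp) %*% cc$A + cfg$l2 * params$Wr
  g$br <- colSums(dZp)
  dA <- dZp %*% params$Wr
  n_drugs <- nrow(X)
  if (cfg$gate == "pair") {
    dHs <- dA * cc$G
    dG <- dA * cc$Hs
    dU <- dG * cc$G * (1 - cc$G)
    g$Wgs <- t(dU) %*% cc$Hs + cfg$l2 * params$Wgs
    g$Wgp <- t(dU) %*% cc$Hp + cfg$l2 * params$Wgp
    g$bg <- colSums(dU)
    dHs <- dHs + dU %*% params$Wgs
    dHp <- dU %*% params$Wgp
    dHd <- acc_rows(dHs, cc$pairs_tab$self, n_drugs) +
      acc_rows(dHp, cc$pairs_tab$part, n_drugs)
  } else {
    dHd <- acc_rows(dA, cc$pairs_tab$self, n_drugs)
  }
  dPre <- dHd * act$df(cc$pre, cc$Hd)
  g$W1 <- t(dPre) %*% X + cfg$l2 * params$W1
  g$b1 <- colSums(dPre)
  g
}

# Pairwise hinge loss and its per-triplet score coefficients for one epoch
# matching. pos_by_se/neg_by_se: lists of triplet indices per side effect.
ddi_hinge <- function(scores, pos_by_se, neg_by_se, margin, loss_form,
                      pairing_seed) {
  coef <- numeric(length(scores))
  total <- 0
  n_pairs <- 0L
  set.seed(pairing_seed)
  if (loss_form == "pairwise") {
    for (r in seq_along(pos_by_se)) {
      P <- pos_by_se[[r]]; N <- neg_by_se[[r]]
      if (!length(P) || !length(N)) next
      m <- min(length(P), length(N))
      P <- P[sample.int(length(P), m)]
      N <- N[sample.int(length(N), m)]
      h <- scores[P] - scores[N] + margin
      on <- h > 0
      total <- total + sum(h[on])
      n_pairs <- n_pairs + m
      coef[P[on]] <- coef[P[on]] + 1
      coef[N[on]] <- coef[N[on]] - 1
    }
    if (n_pairs > 0) {
      total <- total / n_pairs
      coef <- coef / n_pairs
    }
  } else {
    for (r in seq_along(pos_by_se)) {
      P <- pos_by_se[[r]]; N <- neg_by_se[[r]]
      if (!length(P) || !length(N)) next
      h <- sum(scores[P]) - sum(scores[N]) + margin
      if (h > 0) {
        total <- total + h
        coef[P] <- coef[P] + 1
        coef[N] <- coef[N] - 1
      }
    }
  }
  list(loss = total, coef = coef)
}

#' Fit the DDI prediction model
#'
#' Trains the pair-conditional gated encoder with a translating-embedding
#' score per side effect under a margin ranking loss. Each drug's
#' 978-gene expression signature is encoded by a shared dense layer; the
#' two encodings are gated by a GLU conditioned on the partner drug
#' (shared weights, self-first ordering, so swapping the pair swaps the
#' outputs exactly); a shared reduction layer yields the representations
#' scored against each side-effect space. Drugs never seen in training are
#' scored purely through their expression features, which is what enables
#' cold-start (one-/both-unseen) prediction.
#'
#' @param triplets A [triplet_dataset()] (or data frame with columns
#'   `drug_i`, `drug_j`, `side_effect`, `label` where label 1 = positive,
#'   0 = negative).
#' @param expressions Numeric matrix, drugs x 978 genes, rownames = drug
#'   ids covering every drug in `triplets`.
#' @param config A [ddi_model_config()].
#' @return Object of class `"ddi_model"`: fitted parameters, the
#'   side-effect vocabulary, gene names, config, and per-epoch `history`.
#' @export
fit_ddi_model <- function(triplets, expressions, config = ddi_model_config()) {
  stop_if(!inherits(config, "ddi_model_config"), "`config` must be a ddi_model_config")
  tr <- as.data.frame(triplets)
  stop_if(!all(c("drug_i", "drug_j", "side_effect", "label") %in% names(tr)),
          "triplets need columns drug_i, drug_j, side_effect, label")
  drugs <- rownames(expressions)
  missing <- setdiff(unique(c(tr$drug_i, tr$drug_j)), drugs)
  stop_if(length(missing) > 0, "drugs without expression features: ",
          paste(missing, collapse = ", "))
  stop_if(ncol(expressions) != 978L,
          "expressions must cover the 978 landmark genes")
  se_levels <- sort(unique(tr$side_effect))
  hi <- match(tr$drug_i, drugs)
  ti <- match(tr$drug_j, drugs)
  se <- match(tr$side_effect, se_levels)
  pos_by_se <- lapply(seq_along(se_levels),
                      function(r) which(se == r & tr$label == 1))
  neg_by_se <- lapply(seq_along(se_levels),
                      function(r) which(se == r & tr$label == 0))
  bad <- vapply(seq_along(se_levels), function(r) {
    length(pos_by_se[[r]]) == 0 || length(neg_by_se[[r]]) == 0
  }, logical(1))
  stop_if(any(bad), "side effects without both classes in training: ",
          paste(se_levels[bad], collapse = ", "))
  set.seed(derive_seed(config$seed, "ddi-init"))
  params <- ddi_init_params(config, length(se_levels), ncol(expressions))
  state <- adam_init(params)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_annealing_lr(epoch - 1L, config$lr_max, config$lr_min,
                              config$lr_period)
    fwd <- ddi_forward(params, config, expressions, hi, ti, se,
                       length(se_levels), want_cache = TRUE)
    hg <- ddi_hinge(fwd$scores, pos_by_se, neg_by_se, config$margin,
                    config$loss_form,
                    derive_seed(config$seed, paste0("pairing-", epoch)))
    grads <- ddi_backward(params, config, expressions, hi, ti, se,
                          length(se_levels), fwd, hg$coef)
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params
    state <- upd$state
    history$loss[epoch] <- hg$loss
  }
  fwd <- ddi_forward(params, config, expressions, hi, ti, se,
                     length(se_levels))
  structure(
    list(params = params, config = config, se_levels = se_levels,
         gene_names = colnames(expressions), history = history,
         train_pos_mean = mean(fwd$scores[tr$label == 1]),
         train_neg_mean = mean(fwd$scores[tr$label == 0])),
    class = "ddi_model"
  )
}

#' Score triplets with a fitted DDI model
#'
#' Lower scores indicate more plausible interactions. The score of
#' `(i, j, r)` equals the score of `(j, i, r)` exactly, by construction.
#' Side effects are closed-world (must be known to the model); drugs are
#' open-world through their expression features.
#'
#' @param object A fitted `"ddi_model"`.
#' @param triplets Data frame with columns `drug_i`, `drug_j`,
#'   `side_effect`.
#' @param expressions Expression matrix covering all drugs in `triplets`.
#' @param ... Unused.
#' @return Numeric vector of scores, one per triplet row.
#' @export
predict.ddi_model <- function(object, triplets, expressions, ...) {
  tr <- as.data.frame(triplets)
  drugs <- rownames(expressions)
  missing <- setdiff(unique(c(tr$drug_i, tr$drug_j)), drugs)
  stop_if(length(missing) > 0, "drugs without expression features: ",
          paste(missing, collapse = ", "))
  unknown <- setdiff(unique(tr$side_effect), object$se_levels)
  stop_if(length(unknown) > 0, "unknown side effect(s): ",
          paste(unknown, collapse = ", "))
  hi <- match(tr$drug_i, drugs)
  ti <- match(tr$drug_j, drugs)
  se <- match(tr$side_effect, object$se_levels)
  ddi_forward(object$params, object$config, expressions, hi, ti, se,
              length(object$se_levels))$scores
}

#' Encode one drug's expression signature (pre-gate)
#'
#' The shared first dense layer; independent of any partner drug.
#'
#' @param model A fitted `"ddi_model"`.
#' @param expression Length-978 numeric vector.
#' @return Latent vector of width H.
#' @export
encode_drug <- function(model, expression) {
  stop_if(length(expression) != 978L, "expression must have length 978")
  act <- activation_fun(model$config$activation)
  as.numeric(act$f(model$params$W1 %*% expression + model$params$b1))
}

#' Pair-conditional gating and reduction of two encoded drugs
#'
#' Computes the GLU gates `g_i = sigmoid(Wg [h_i; h_j])` (self-first,
#' shared weights) and the reduced representations
#' `z = Wr (h * g) + br`. Swapping the two drugs swaps the outputs
#' exactly.
#'
#' @param model A fitted `"ddi_model"`.
#' @param h_i,h_j Encoded latents from [encode_drug()].
#' @return List with `z_i`, `z_j`, `g_i`, `g_j`.
#' @export
coadminister <- function(model, h_i, h_j) {
  p <- model$params
  H <- model$config$latent_width
  stop_if(length(h_i) != H || length(h_j) != H, "latent width mismatch")
  if (model$config$gate == "pair") {
    g_i <- as.numeric(sigmoid(p$Wgs %*% h_i + p$Wgp %*% h_j + p$bg))
    g_j <- as.numeric(sigmoid(p$Wgs %*% h_j + p$Wgp %*% h_i + p$bg))
  } else {
    g_i <- g_j <- rep(1, H)
  }
  list(z_i = as.numeric(p$Wr %*% (h_i * g_i) + p$br),
       z_j = as.numeric(p$Wr %*% (h_j * g_j) + p$br),
       g_i = g_i, g_j = g_j)
}

#' Gene-level gate attention for a drug pair
#'
#' Returns the per-gene GLU gate values of both drugs in each other's
#' context. Requires the model's latent width to equal 978 so gate entries
#' align to the landmark-gene order.
#'
#' @param model A fitted `"ddi_model"` with `latent_width = 978`.
#' @param expressions Expression matrix containing both drugs.
#' @param drug_i,drug_j Drug ids (rownames of `expressions`).
#' @return List with named vectors `g_i` and `g_j` (length 978, entries in
#'   (0, 1)).
#' @export
gene_attention <- function(model, expressions, drug_i, drug_j) {
  stop_if(model$config$latent_width != 978L,
          "gene attention requires latent_width = 978 (gene-aligned gates)")
  stop_if(model$config$gate != "pair", "model was fitted without gates")
  stop_if(!all(c(drug_i, drug_j) %in% rownames(expressions)),
          "drugs absent from `expressions`")
  h_i <- encode_drug(model, expressions[drug_i, ])
  h_j <- encode_drug(model, expressions[drug_j, ])
  co <- coadminister(model, h_i, h_j)
  gn <- model$gene_names %||% paste0("G", seq_len(978))
  list(g_i = stats::setNames(co$g_i, gn), g_j = stats::setNames(co$g_j, gn))
}

#' Top-k attended genes
#'
#' @param attention Named per-gene attention vector (one element of
#'   [gene_attention()]'s result).
#' @param k Number of genes, `<= 978`.
#' @return Character vector of k gene names by descending attention, ties
#'   broken by gene order.
#' @export
top_attended_genes <- function(attention, k = 100L) {
  stop_if(k > length(attention), "k exceeds the number of genes")
  ord <- order(-attention, seq_along(attention))
  names(attention)[ord[seq_len(k)]]
}

#' Gated pre-reduction representation of a drug in a pair context
#'
#' `h_i * g_i`: the drug's latent representation as modulated by its
#' partner, before dimension reduction. This is the pair-dependent
#' "dynamic feature" exported for downstream clustering.
#'
#' @inheritParams gene_attention
#' @return Numeric vector of width H.
#' @export
pair_latent <- function(model, expressions, drug_i, drug_j) {
  stop_if(!all(c(drug_i, drug_j) %in% rownames(expressions)),
          "drugs absent from `expressions`")
  h_i <- encode_drug(model, expressions[drug_i, ])
  h_j <- encode_drug(model, expressions[drug_j, ])
  co <- coadminister(model, h_i, h_j)
  h_i * co$g_i
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("DDI prediction model (", x$config$score, " score, ",
      x$config$gate, " gates)\n", sep = "")
  cat("  side effects:", length(x$se_levels),
      "| widths H/D/E:", x$config$latent_width, "/",
      x$config$reduced_width, "/", x$config$embedding_width, "\n")
  cat(sprintf("  final loss: %.4f | train score means: pos %.3f / neg %.3f\n",
              utils::tail(x$history$loss, 1),
              x$train_pos_mean, x$train_neg_mean))
  invisible(x)
}

#' @export
summary.ddi_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.ddi_model <- function(object, ...) {
  object$params
}
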