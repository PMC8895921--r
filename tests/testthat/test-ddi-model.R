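test_that("GLU gate matches its closed forms and saturation limit", {
  expect_equal(glu_gate(c(2, -4), c(0, 0)), c(1, -2))
  expect_equal(glu_gate(c(1, 1), c(log(3), log(3))), c(0.75, 0.75))
  expect_equal(glu_gate(c(3, -2), c(1e4, 1e4)), c(3, -2))
  a <- rnorm(10); b <- rnorm(10)
  expect_true(all(abs(glu_gate(a, b)) <= abs(a)))
  expect_error(glu_gate(1:3, 1:2), "length")
})

test_that("translating-embedding score matches worked values and is symmetric", {
  id2 <- diag(2)
  sp0 <- side_effect_space(id2, id2, c(0, 0))
  expect_equal(triplet_score(c(1, 1), c(1, 1), sp0), 0)
  sp <- side_effect_space(id2, id2, c(1, 1))
  # ||(2,0)|| + ||(0,2)|| = 4
  expect_equal(triplet_score(c(1, 0), c(0, 1), sp), 4.0)
  set.seed(8)
  m1 <- matrix(rnorm(12), 3)
  m2 <- matrix(rnorm(12), 3)
  spr <- side_effect_space(m1, m2, rnorm(3))
  zh <- rnorm(4); zt <- rnorm(4)
  expect_equal(triplet_score(zh, zt, spr), triplet_score(zt, zh, spr))
  expect_gte(triplet_score(zh, zt, spr), 0)
  expect_error(triplet_score(rnorm(3), zt, spr), "width")
})

test_that("score is invariant under joint orthogonal rotation of the embedding space", {
  set.seed(14)
  e <- 5
  spr <- side_effect_space(matrix(rnorm(e * 4), e), matrix(rnorm(e * 4), e),
                           rnorm(e))
  q <- qr.Q(qr(matrix(rnorm(e * e), e)))
  rot <- side_effect_space(q %*% spr$m_rh, q %*% spr$m_rt,
                           as.numeric(q %*% spr$r))
  for (i in 1:5) {
    zh <- rnorm(4); zt <- rnorm(4)
    expect_equal(triplet_score(zh, zt, rot), triplet_score(zh, zt, spr))
  }
})

test_that("margin loss reproduces the hinge cases and its monotonicity", {
  expect_equal(margin_loss(1, 3, margin = 1), 0)
  expect_equal(margin_loss(2, 2, margin = 0.7), 0.7)
  expect_equal(margin_loss(3, 1, margin = 1), 3)
  expect_equal(margin_loss(c(1, 3), c(3, 1), margin = 1), 1.5)
  # aggregate (summed) form applies one hinge to the pooled scores
  expect_equal(margin_loss(c(1, 3), c(3, 1), margin = 1, form = "aggregate"), 1)
  # non-decreasing in positive scores, non-increasing in negative scores
  expect_lte(margin_loss(1, 2.5, margin = 1), margin_loss(1.5, 2.5, margin = 1))
  expect_lte(margin_loss(1.5, 3, margin = 1), margin_loss(1.5, 2.5, margin = 1))
  expect_error(margin_loss(numeric(0), 1), "non-empty")
  expect_error(margin_loss(c(1, 2), 3), "equal length")
})

test_that("analytic DDI gradients match finite differences in every configuration", {
  ns <- asNamespace("sigddi")
  set.seed(42)
  X <- matrix(rnorm(8 * 978), 8)
  hi <- c(1, 2, 3, 4, 5, 6); ti <- c(2, 3, 4, 5, 6, 7); se <- c(1, 1, 1, 2, 2, 2)
  pos_by_se <- list(c(1, 2), c(4, 5)); neg_by_se <- list(3, 6)
  eps <- 1e-6
  configs <- list(
    ddi_model_config(latent_width = 6, reduced_width = 4, embedding_width = 3,
                     activation = "tanh", l2 = 0, margin = 2),
    ddi_model_config(latent_width = 6, reduced_width = 4, embedding_width = 3,
                     activation = "tanh", l2 = 0, margin = 2, gate = "open"),
    ddi_model_config(latent_width = 6, reduced_width = 4, embedding_width = 3,
                     activation = "tanh", l2 = 0, margin = 2, score = "mlp"),
    ddi_model_config(latent_width = 6, reduced_width = 4, embedding_width = 3,
                     activation = "tanh", l2 = 0, margin = 2,
                     loss_form = "aggregate")
  )
  for (cfg in configs) {
    set.seed(9)
    params <- ns$ddi_init_params(cfg, 2L, 978L)
    lossfun <- function(p) {
      fwd <- ns$ddi_forward(p, cfg, X, hi, ti, se, 2L, want_cache = TRUE)
      ns$ddi_hinge(fwd$scores, pos_by_se, neg_by_se, cfg$margin,
                   cfg$loss_form, 555L)$loss
    }
    fwd <- ns$ddi_forward(params, cfg, X, hi, ti, se, 2L, want_cache = TRUE)
    hg <- ns$ddi_hinge(fwd$scores, pos_by_se, neg_by_se, cfg$margin,
                       cfg$loss_form, 555L)
    grads <- ns$ddi_backward(params, cfg, X, hi, ti, se, 2L, fwd, hg$coef)
    for (nm in names(params)) {
      for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
        expect_equal(grads[[nm]][k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("drug encoding is partner-independent and architectural contracts hold", {
  m <- tiny_ddi_model()
  X <- tiny_ddi_data()$world$expressions
  h1 <- encode_drug(m, X[1, ])
  expect_identical(h1, encode_drug(m, X[1, ]))
  expect_length(h1, 978)
  expect_error(encode_drug(m, X[1, 1:10]), "978")

  h2 <- encode_drug(m, X[2, ])
  h3 <- encode_drug(m, X[3, ])
  co12 <- coadminister(m, h1, h2)
  co21 <- coadminister(m, h2, h1)
  # swapping the pair swaps the outputs bitwise
  expect_identical(co12$z_i, co21$z_j)
  expect_identical(co12$g_i, co21$g_j)
  expect_true(all(co12$g_i >= 0 & co12$g_i <= 1))
  # strict interior openness, on a model whose gate logits stay moderate
  ms <- small_trained_ddi_model()
  hs1 <- encode_drug(ms, X[1, ])
  hs2 <- encode_drug(ms, X[2, ])
  gs <- coadminister(ms, hs1, hs2)$g_i
  expect_true(all(gs > 0 & gs < 1))
  # gates are pair-conditional: same drug, different partner
  co13 <- coadminister(m, h1, h3)
  expect_false(isTRUE(all.equal(co12$g_i, co13$g_i)))
})

test_that("predicted scores are exactly symmetric and cover unseen drugs", {
  m <- small_trained_ddi_model()
  d <- tiny_ddi_data()
  X <- d$world$expressions
  test <- d$test
  fwdS <- predict(m, test, X)
  rev <- data.frame(drug_i = test$drug_j, drug_j = test$drug_i,
                    side_effect = test$side_effect)
  expect_identical(fwdS, predict(m, rev, X))
  # batch and single-row scoring agree
  expect_equal(predict(m, test[3, ], X), fwdS[3])
  # a drug never seen in training scores finitely through its features
  Xnew <- rbind(X, NEWDRUG = rnorm(978))
  nov <- data.frame(drug_i = "NEWDRUG", drug_j = rownames(X)[1],
                    side_effect = test$side_effect[1])
  expect_true(is.finite(predict(m, nov, Xnew)))
  bad <- data.frame(drug_i = rownames(X)[1], drug_j = rownames(X)[2],
                    side_effect = "nonexistent")
  expect_error(predict(m, bad, X), "unknown side effect")
  expect_error(predict(m, nov, X), "without expression features")
})

test_that("training is reproducible, consistent with the loss bookkeeping, and separates classes", {
  d <- tiny_ddi_data()
  cfg <- ddi_model_config(latent_width = 32, reduced_width = 12,
                          embedding_width = 6, epochs = 8, seed = 77)
  f1 <- fit_ddi_model(d$train, d$world$expressions, cfg)
  f2 <- fit_ddi_model(d$train, d$world$expressions, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # trained model pushes positives below negatives on its training data
  m <- small_trained_ddi_model()
  expect_lt(m$train_pos_mean, m$train_neg_mean)
  # missing features are reported by drug id
  expect_error(fit_ddi_model(d$train, d$world$expressions[-1, ], cfg),
               rownames(d$world$expressions)[1])
})

test_that("the initial hinge loss is recomputable from scored triplets", {
  d <- tiny_ddi_data()
  cfg <- ddi_model_config(latent_width = 32, reduced_width = 12,
                          embedding_width = 6, epochs = 1,
                          lr_max = 0, lr_min = 0, seed = 31)
  f <- fit_ddi_model(d$train, d$world$expressions, cfg)
  # with lr = 0 the single epoch's loss is the loss of the initial
  # parameters, which we can recompute through the public scorer
  sc <- predict(f, d$train, d$world$expressions)
  ns <- asNamespace("sigddi")
  se_levels <- f$se_levels
  se <- match(d$train$side_effect, se_levels)
  pos_by_se <- lapply(seq_along(se_levels),
                      function(r) which(se == r & d$train$label == 1))
  neg_by_se <- lapply(seq_along(se_levels),
                      function(r) which(se == r & d$train$label == 0))
  hg <- ns$ddi_hinge(sc, pos_by_se, neg_by_se, cfg$margin, cfg$loss_form,
                     ns$derive_seed(cfg$seed, "pairing-1"))
  expect_equal(f$history$loss[1], hg$loss)
})

test_that("gene attention is gene-aligned, pair-dependent and top-k ordered", {
  m <- tiny_ddi_model()
  X <- tiny_ddi_data()$world$expressions
  ids <- rownames(X)
  att <- gene_attention(m, X, ids[1], ids[2])
  expect_length(att$g_i, 978)
  expect_true(all(att$g_i >= 0 & att$g_i <= 1))
  expect_named(att$g_i, colnames(X))
  att2 <- gene_attention(m, X, ids[1], ids[3])
  expect_false(isTRUE(all.equal(att$g_i, att2$g_i)))

  top <- top_attended_genes(att$g_i, k = 100)
  expect_length(top, 100)
  expect_equal(top[1], names(which.max(att$g_i)))
  expect_setequal(top_attended_genes(att$g_i, k = 978), names(att$g_i))
  expect_error(top_attended_genes(att$g_i, k = 979), "exceeds")
  # deterministic tie-break by gene order
  tied <- stats::setNames(rep(0.5, 978), colnames(X))
  expect_equal(top_attended_genes(tied, 3), colnames(X)[1:3])
})

test_that("pair latents vary with the partner and obey the zero-logit identity", {
  m <- tiny_ddi_model()
  X <- tiny_ddi_data()$world$expressions
  ids <- rownames(X)
  pl12 <- pair_latent(m, X, ids[1], ids[2])
  pl13 <- pair_latent(m, X, ids[1], ids[3])
  expect_length(pl12, 978)
  expect_false(isTRUE(all.equal(pl12, pl13)))
  # with all gate parameters zero the gate sits at sigmoid(0) = 1/2
  m0 <- m
  m0$params$Wgs[] <- 0
  m0$params$Wgp[] <- 0
  m0$params$bg[] <- 0
  h1 <- encode_drug(m0, X[ids[1], ])
  expect_equal(pair_latent(m0, X, ids[1], ids[2]), h1 / 2)
  expect_error(pair_latent(m, X, "ghost", ids[2]), "absent")
})

test_that("forcing the gates open reduces the model to an ungated scorer", {
  d <- tiny_ddi_data()
  cfg <- ddi_model_config(latent_width = 32, reduced_width = 12,
                          embedding_width = 6, epochs = 4, gate = "open",
                          seed = 13)
  f <- fit_ddi_model(d$train, d$world$expressions, cfg)
  X <- d$world$expressions
  h1 <- encode_drug(f, X[1, ])
  h2 <- encode_drug(f, X[2, ])
  co <- coadminister(f, h1, h2)
  expect_equal(co$g_i, rep(1, 32))
  # with unit gates the reduced latent no longer depends on the partner
  co3 <- coadminister(f, h1, encode_drug(f, X[3, ]))
  expect_identical(co$z_i, co3$z_i)
})
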