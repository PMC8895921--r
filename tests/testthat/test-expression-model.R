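test_that("MSE loss matches hand arithmetic and is permutation-invariant", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1.0)
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 5)), 4 / 3)
  set.seed(2)
  a <- matrix(rnorm(20), 4)
  b <- matrix(rnorm(20), 4)
  perm <- sample(5)
  expect_equal(mse_loss(a[, perm], b[, perm]), mse_loss(a, b))
  expect_error(mse_loss(1:3, 1:4), "shape")
})

test_that("cosine annealing hits its endpoints and restarts", {
  expect_equal(cosine_annealing_lr(0, 0.1, 0.001, 50), 0.1)
  expect_equal(cosine_annealing_lr(50, 0.1, 0.001, 50), 0.1)
  expect_equal(cosine_annealing_lr(25, 0.1, 0.001, 50), (0.1 + 0.001) / 2)
  expect_error(cosine_annealing_lr(1, 0.1, 0.001, 0), "period")
})

test_that("Pearson correlation matches closed forms and rejects degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  # frozen from the product-moment formula computed independently
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 5, 9)), 0.9647638,
               tolerance = 1e-6)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("analytic gradients of the two-branch network match finite differences", {
  ns <- asNamespace("sigddi")
  eps <- 1e-6
  for (bn in c(TRUE, FALSE)) {
    cfg <- expr_model_config(fingerprint_hidden = 5, property_hidden = 4,
                             l2 = 0.01, batch_norm = bn, activation = "tanh",
                             folds = 1, epochs = 1)
    set.seed(11)
    xf <- matrix(rbinom(40, 1, 0.5), 8)
    xp <- matrix(runif(24), 8, 3)
    y <- matrix(rnorm(8 * 7), 8)
    set.seed(12)
    params <- ns$expr_init_params(5, 3, 7, cfg)
    bns <- list(f = list(mean = numeric(5), var = rep(1, 5)),
                p = list(mean = numeric(4), var = rep(1, 4)))
    lossfun <- function(p) {
      fwd <- ns$expr_forward(p, xf, xp, cfg, bns, training = TRUE)
      mse_loss(fwd$y, y) +
        0.5 * cfg$l2 * (sum(p$Wf^2) + sum(p$Wp^2) + sum(p$Wo^2))
    }
    fwd <- ns$expr_forward(params, xf, xp, cfg, bns, training = TRUE)
    grads <- ns$expr_backward(params, xf, xp, y, fwd, cfg)
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

test_that("training is deterministic under a fixed seed and inert at lr = 0", {
  w <- simulate_expression_world(n_compounds = 40, noise_sd = 0.5, seed = 3)
  cfg <- expr_model_config(fingerprint_hidden = 8, property_hidden = 6,
                           epochs = 3, folds = 1, seed = 21)
  f1 <- fit_expression_model(w$fingerprints, w$properties, w$signatures, cfg)
  f2 <- fit_expression_model(w$fingerprints, w$properties, w$signatures, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)

  cfg0 <- expr_model_config(fingerprint_hidden = 8, property_hidden = 6,
                            epochs = 1, folds = 1, lr_max = 0, lr_min = 0,
                            seed = 21)
  f0 <- fit_expression_model(w$fingerprints, w$properties, w$signatures, cfg0)
  ns <- asNamespace("sigddi")
  set.seed(ns$derive_seed(21L, "init-final"))
  init <- ns$expr_init_params(ncol(w$fingerprints), ncol(w$properties),
                              978L, cfg0)
  expect_equal(f0$params, init)

  bad <- w$fingerprints
  bad[1, 1] <- NA
  expect_error(fit_expression_model(bad, w$properties, w$signatures, cfg),
               "NA")
})

test_that("prediction is 978-wide, batch-consistent and duplicate-consistent", {
  w <- simulate_expression_world(n_compounds = 30, noise_sd = 0, seed = 5)
  cfg <- expr_model_config(fingerprint_hidden = 8, property_hidden = 6,
                           epochs = 2, folds = 1, seed = 2)
  fit <- fit_expression_model(w$fingerprints, w$properties, w$signatures, cfg)
  pred <- predict(fit, w$fingerprints, w$properties)
  expect_equal(ncol(pred), 978)
  single <- predict(fit, w$fingerprints[3, ], w$properties[3, ])
  expect_equal(as.numeric(single), as.numeric(pred[3, ]))
  dup <- predict(fit, w$fingerprints[c(3, 3), ], w$properties[c(3, 3), ])
  expect_equal(dup[1, ], dup[2, ])
  expect_error(predict(fit, w$fingerprints[, -1], w$properties), "width")
})

test_that("cross-validation predicts each compound exactly once out-of-fold", {
  w <- simulate_expression_world(n_compounds = 36, noise_sd = 0.5, seed = 9)
  cfg <- expr_model_config(fingerprint_hidden = 8, property_hidden = 6,
                           epochs = 5, folds = 3, seed = 2)
  fit <- fit_expression_model(w$fingerprints, w$properties, w$signatures, cfg)
  expect_false(anyNA(fit$cv$predictions))
  expect_equal(dim(fit$cv$predictions), dim(w$signatures))
  expect_length(fit$cv$fold_history, 3)
  expect_true(is.finite(fit$cv$pearson))
})

test_that("the model recovers a noise-free planted linear map", {
  w <- simulate_expression_world(n_compounds = 500, noise_sd = 0, seed = 7)
  hold <- 1:50
  cfg <- expr_model_config(fingerprint_hidden = 64, property_hidden = 32,
                           epochs = 250, lr_period = 125, folds = 1, seed = 7)
  fit <- fit_expression_model(w$fingerprints[-hold, ], w$properties[-hold, ],
                              w$signatures[-hold, ], cfg)
  pred <- predict(fit, w$fingerprints[hold, ], w$properties[hold, ])
  r <- mean(vapply(seq_along(hold), function(i) {
    pearson_r(pred[i, ], w$signatures[hold[i], ])
  }, numeric(1)))
  expect_gte(r, 0.95)
})

test_that("held-out correlation degrades as expression noise grows", {
  rs <- vapply(c(0, 0.5, 2.0), function(ns_) {
    w <- simulate_expression_world(n_compounds = 200, noise_sd = ns_, seed = 7)
    hold <- 1:40
    cfg <- expr_model_config(fingerprint_hidden = 32, property_hidden = 16,
                             epochs = 60, lr_period = 30, folds = 1, seed = 7)
    fit <- fit_expression_model(w$fingerprints[-hold, ], w$properties[-hold, ],
                                w$signatures[-hold, ], cfg)
    pred <- predict(fit, w$fingerprints[hold, ], w$properties[hold, ])
    mean(vapply(seq_along(hold), function(i) {
      pearson_r(pred[i, ], w$signatures[hold[i], ])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(rs[1], rs[2])
  expect_gt(rs[2], rs[3])
})
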