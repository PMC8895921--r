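#' Mean squared error loss
#'
#' Average of squared differences over every element of the batch.
#'
#' @param y_pred,y_true Numeric vectors or matrices of identical shape.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(y_pred, y_true) {
  stop_if(length(y_pred) != length(y_true) ||
            !identical(dim(y_pred), dim(y_true)),
          "shape mismatch between y_pred and y_true")
  mean((y_pred - y_true)^2)
}

#' Cosine-annealing learning-rate schedule
#'
#' `lr(t) = lr_min + (lr_max - lr_min)/2 * (1 + cos(pi * (t mod T) / T))`,
#' restarting at every multiple of the period. Used to escape shallow local
#' minima during network training.
#'
#' @param step Zero-based step (epoch) index.
#' @param lr_max,lr_min Range of the schedule.
#' @param period Restart period T in steps, > 0.
#' @return Learning rate at `step`.
#' @export
cosine_annealing_lr <- function(step, lr_max = 1e-3, lr_min = 1e-5, period = 50L) {
  stop_if(period <= 0, "`period` must be > 0")
  stop_if(any(step < 0), "`step` must be >= 0")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * (step %% period) / period))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stop_if(length(x) != length(y), "length mismatch")
  stop_if(length(x) < 2, "need at least two observations")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "zero-variance input: correlation undefined")
  stats::cor(x, y)
}

#' Configuration for the expression-generation model
#'
#' @param fingerprint_hidden,property_hidden Widths of the two input
#'   branches (fingerprint and descriptor branch).
#' @param l2 L2 weight-decay coefficient.
#' @param batch_norm Apply batch normalization to branch pre-activations.
#' @param activation `"relu"` or `"tanh"`.
#' @param epochs,batch_size Training schedule.
#' @param lr_max,lr_min,lr_period Cosine-annealing parameters (period in
#'   epochs).
#' @param folds Cross-validation folds (1 disables CV).
#' @param metric `"per_compound"` (Pearson r across the 978 genes of each
#'   held-out compound, averaged over compounds) or `"per_gene"`.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A list of class `"expr_model_config"`.
#' @export
expr_model_config <- function(fingerprint_hidden = 512L, property_hidden = 64L,
                              l2 = 1e-4, batch_norm = TRUE,
                              activation = "relu",
                              epochs = 200L, batch_size = 64L,
                              lr_max = 1e-3, lr_min = 1e-5, lr_period = 50L,
                              folds = 10L, metric = "per_compound",
                              seed = 1L) {
  stop_if(fingerprint_hidden < 1 || property_hidden < 1, "branch widths must be > 0")
  stop_if(lr_min > lr_max, "lr_min must be <= lr_max")
  stop_if(epochs < 1, "epochs must be >= 1")
  stop_if(!metric %in% c("per_compound", "per_gene"), "unknown metric")
  structure(as.list(environment()), class = "expr_model_config")
}

expr_init_params <- function(n_fp, n_prop, n_genes, cfg) {
  d1 <- cfg$fingerprint_hidden
  d2 <- cfg$property_hidden
  gl <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nout, nin)
  }
  p <- list(
    Wf = gl(n_fp, d1), bf = numeric(d1),
    Wp = gl(n_prop, d2), bp = numeric(d2),
    Wo = gl(d1 + d2, n_genes), bo = numeric(n_genes)
  )
  if (cfg$batch_norm) {
    p$gf <- rep(1, d1); p$hf <- numeric(d1)
    p$gp <- rep(1, d2); p$hp <- numeric(d2)
  }
  p
}

bn_forward <- function(u, gamma, beta, running, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(u)
    va <- colMeans(sweep(u, 2, mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  xhat <- sweep(sweep(u, 2, mu), 2, sqrt(va + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, var = va, running = running)
}

bn_backward <- function(dout, cache, gamma, eps = 1e-5) {
  xhat <- cache$xhat
  istd <- 1 / sqrt(cache$var + eps)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  m1 <- matrix(colMeans(dout), nrow(dout), ncol(dout), byrow = TRUE)
  m2 <- matrix(colMeans(dout * xhat), nrow(dout), ncol(dout), byrow = TRUE)
  du <- sweep(dout - m1 - xhat * m2, 2, gamma * istd, "*")
  list(du = du, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass; returns prediction and, when training, the cache needed
# for the backward pass.
expr_forward <- function(params, xf, xp, cfg, bn_stats, training = FALSE) {
  act <- activation_fun(cfg$activation)
  uf <- sweep(xf %*% t(params$Wf), 2, params$bf, "+")
  up <- sweep(xp %*% t(params$Wp), 2, params$bp, "+")
  cf <- cp <- NULL
  if (cfg$batch_norm) {
    cf <- bn_forward(uf, params$gf, params$hf, bn_stats$f, training)
    cp <- bn_forward(up, params$gp, params$hp, bn_stats$p, training)
    bn_stats$f <- cf$running
    bn_stats$p <- cp$running
    af <- cf$out; ap <- cp$out
  } else {
    af <- uf; ap <- up
  }
  hf <- act$f(af); hp <- act$f(ap)
  h <- cbind(hf, hp)
  y <- sweep(h %*% t(params$Wo), 2, params$bo, "+")
  list(y = y, cache = list(uf = uf, up = up, af = af, ap = ap,
                           hf = hf, hp = hp, h = h, cf = cf, cp = cp),
       bn_stats = bn_stats)
}

expr_backward <- function(params, xf, xp, y_true, fwd, cfg) {
  act <- activation_fun(cfg$activation)
  n <- nrow(xf)
  cc <- fwd$cache
  dy <- 2 * (fwd$y - y_true) / length(y_true)
  g <- list()
  g$Wo <- t(dy) %*% cc$h + cfg$l2 * params$Wo
  g$bo <- colSums(dy)
  dh <- dy %*% params$Wo
  d1 <- ncol(cc$hf)
  dhf <- dh[, seq_len(d1), drop = FALSE]
  dhp <- dh[, -seq_len(d1), drop = FALSE]
  daf <- dhf * act$df(cc$af, cc$hf)
  dap <- dhp * act$df(cc$ap, cc$hp)
  if (cfg$batch_norm) {
    bf <- bn_backward(daf, cc$cf, params$gf)
    bp <- bn_backward(dap, cc$cp, params$gp)
    g$gf <- bf$dgamma; g$hf <- bf$dbeta
    g$gp <- bp$dgamma; g$hp <- bp$dbeta
    duf <- bf$du; dup <- bp$du
  } else {
    duf <- daf; dup <- dap
  }
  g$Wf <- t(duf) %*% xf + cfg$l2 * params$Wf
  g$bf <- colSums(duf)
  g$Wp <- t(dup) %*% xp + cfg$l2 * params$Wp
  g$bp <- colSums(dup)
  g
}

expr_train_once <- function(xf, xp, y, cfg, seed_salt, xf_val = NULL,
                            xp_val = NULL, y_val = NULL) {
  set.seed(derive_seed(cfg$seed, paste0("init-", seed_salt)))
  params <- expr_init_params(ncol(xf), ncol(xp), ncol(y), cfg)
  bn_stats <- list(
    f = list(mean = numeric(cfg$fingerprint_hidden),
             var = rep(1, cfg$fingerprint_hidden)),
    p = list(mean = numeric(cfg$property_hidden),
             var = rep(1, cfg$property_hidden))
  )
  state <- adam_init(params)
  n <- nrow(xf)
  history <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                        val_pearson = NA_real_)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_annealing_lr(epoch - 1L, cfg$lr_max, cfg$lr_min, cfg$lr_period)
    set.seed(derive_seed(cfg$seed, paste0("ep-", seed_salt, "-", epoch)))
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      fwd <- expr_forward(params, xf[idx, , drop = FALSE],
                          xp[idx, , drop = FALSE], cfg, bn_stats,
                          training = TRUE)
      bn_stats <- fwd$bn_stats
      grads <- expr_backward(params, xf[idx, , drop = FALSE],
                             xp[idx, , drop = FALSE],
                             y[idx, , drop = FALSE], fwd, cfg)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + mse_loss(fwd$y, y[idx, , drop = FALSE]) * length(idx)
    }
    history$loss[epoch] <- ep_loss / n
    if (!is.null(xf_val)) {
      pv <- expr_forward(params, xf_val, xp_val, cfg, bn_stats)$y
      history$val_pearson[epoch] <- mean_pearson(pv, y_val, cfg$metric)
    }
  }
  list(params = params, bn_stats = bn_stats, history = history)
}

# Aggregate Pearson correlation between predicted and true signature
# matrices, either per compound (rows) or per gene (columns).
mean_pearson <- function(pred, true, metric = "per_compound") {
  mar <- if (metric == "per_compound") 1 else 2
  rs <- vapply(seq_len(dim(pred)[mar]), function(i) {
    p <- if (mar == 1) pred[i, ] else pred[, i]
    t <- if (mar == 1) true[i, ] else true[, i]
    if (stats::sd(p) == 0 || stats::sd(t) == 0) return(NA_real_)
    stats::cor(p, t)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Fit the expression-generation model
#'
#' Trains a two-branch dense network mapping (Morgan fingerprint,
#' scaled descriptors) to a 978-gene differential-expression signature,
#' minimizing mean squared error with L2 regularization, optional batch
#' normalization and a cosine-annealing learning-rate schedule. With
#' `folds > 1` each compound is predicted exactly once out-of-fold and the
#' deployed model is then retrained on the full data set.
#'
#' @param fingerprints Binary matrix, compounds x fingerprint bits.
#' @param properties Numeric matrix in \[0,1\], compounds x descriptors.
#' @param signatures Numeric matrix, compounds x 978 genes.
#' @param config An [expr_model_config()].
#' @return Object of class `"expression_model"` with the fitted parameters,
#'   per-epoch history, and (when CV is on) out-of-fold predictions and the
#'   held-out correlation `cv$pearson`.
#' @export
fit_expression_model <- function(fingerprints, properties, signatures,
                                 config = expr_model_config()) {
  stop_if(!inherits(config, "expr_model_config"), "`config` must be an expr_model_config")
  stop_if(nrow(fingerprints) != nrow(signatures) ||
            nrow(properties) != nrow(signatures),
          "feature and signature row counts differ")
  stop_if(anyNA(fingerprints) || anyNA(properties) || anyNA(signatures),
          "NA values in inputs; clean features before training")
  stop_if(ncol(signatures) != 978L,
          "signatures must cover the 978 landmark genes, got ", ncol(signatures))
  n <- nrow(signatures)
  cv <- NULL
  if (config$folds > 1L) {
    stop_if(n < config$folds, "fewer compounds than folds")
    set.seed(derive_seed(config$seed, "cv-assign"))
    fold_id <- sample(rep_len(seq_len(config$folds), n))
    oof <- matrix(NA_real_, n, ncol(signatures),
                  dimnames = dimnames(signatures))
    fold_hist <- vector("list", config$folds)
    for (f in seq_len(config$folds)) {
      tr <- fold_id != f
      fit <- expr_train_once(fingerprints[tr, , drop = FALSE],
                             properties[tr, , drop = FALSE],
                             signatures[tr, , drop = FALSE],
                             config, seed_salt = paste0("fold", f),
                             xf_val = fingerprints[!tr, , drop = FALSE],
                             xp_val = properties[!tr, , drop = FALSE],
                             y_val = signatures[!tr, , drop = FALSE])
      oof[!tr, ] <- expr_forward(fit$params, fingerprints[!tr, , drop = FALSE],
                                 properties[!tr, , drop = FALSE],
                                 config, fit$bn_stats)$y
      fold_hist[[f]] <- fit$history
    }
    cv <- list(predictions = oof,
               pearson = mean_pearson(oof, signatures, config$metric),
               fold_history = fold_hist)
  }
  final <- expr_train_once(fingerprints, properties, signatures,
                           config, seed_salt = "final")
  structure(
    list(params = final$params, bn_stats = final$bn_stats,
         config = config, history = final$history, cv = cv,
         gene_names = colnames(signatures),
         n_fingerprint = ncol(fingerprints),
         n_properties = ncol(properties)),
    class = "expression_model"
  )
}

#' Predict expression signatures for new compounds
#'
#' @param object A fitted `"expression_model"`.
#' @param fingerprints,properties Feature matrices (or single vectors) with
#'   the widths the model was trained on.
#' @param ... Unused.
#' @return Matrix, compounds x 978.
#' @export
predict.expression_model <- function(object, fingerprints, properties, ...) {
  if (is.null(dim(fingerprints))) fingerprints <- matrix(fingerprints, 1)
  if (is.null(dim(properties))) properties <- matrix(properties, 1)
  stop_if(ncol(fingerprints) != object$n_fingerprint,
          "fingerprint width ", ncol(fingerprints), " != ", object$n_fingerprint)
  stop_if(ncol(properties) != object$n_properties,
          "property width ", ncol(properties), " != ", object$n_properties)
  y <- expr_forward(object$params, fingerprints, properties,
                    object$config, object$bn_stats)$y
  colnames(y) <- object$gene_names
  y
}

#' @export
print.expression_model <- function(x, ...) {
  cat("Expression-generation model\n")
  cat("  branches:", x$n_fingerprint, "->", x$config$fingerprint_hidden,
      "(fingerprint),", x$n_properties, "->", x$config$property_hidden,
      "(properties)\n")
  cat("  output: 978 landmark genes; epochs:", x$config$epochs, "\n")
  if (!is.null(x$cv)) {
    cat(sprintf("  held-out %s Pearson r: %.3f (%d-fold CV)\n",
                sub("_", "-", x$config$metric), x$cv$pearson, x$config$folds))
  }
  cat(sprintf("  final training loss: %.4f\n", utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.expression_model <- function(object, ...) {
  print(object)
  invisible(object)
}
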