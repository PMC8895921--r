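# Internal helpers shared across modules.

# Deterministic polynomial hash of a non-negative integer vector onto
# [0, 2^31 - 2]. Arithmetic stays below 2^53 so doubles are exact.
hash_ints <- function(x) {
  h <- 0
  for (v in x) {
    h <- (h * 131 + (v + 1)) %% 2147483647
  }
  h
}

hash_string <- function(s) {
  hash_ints(utf8ToInt(s))
}

# Derive a reproducible child seed from a base seed and a character salt.
derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) %% 65011 * 33013 + hash_string(salt)) %% 2147483647)
}

relu <- function(x) {
  x * (x > 0)
}

sigmoid <- function(x) {
  stats::plogis(x)
}

activation_fun <- function(name) {
  switch(name,
    relu = list(f = relu, df = function(pre, post) (pre > 0) * 1),
    tanh = list(f = tanh, df = function(pre, post) 1 - post^2),
    stop("unknown activation: ", name)
  )
}

# Adam optimizer over a named list of numeric arrays.
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  }
  list(
    m = lapply(params, zero_like),
    v = lapply(params, zero_like),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Canonical unordered-pair key used for split bookkeeping.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

triplet_key <- function(a, b, r) {
  paste(pair_key(a, b), r, sep = "\r")
}
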