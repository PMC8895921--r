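#' Construct a DDI triplet dataset
#'
#' A triplet is (drug_i, drug_j, side_effect, label) with the drug pair
#' unordered in meaning; pairs are stored in canonical (sorted) order.
#' Duplicate unordered triplets are collapsed and a triplet may not carry
#' both labels.
#'
#' @param drug_i,drug_j Character vectors of drug ids (`drug_i != drug_j`).
#' @param side_effect Character vector of side-effect ids.
#' @param label Integer vector, 1 = positive, 0 = negative.
#' @return Data frame of class `"triplet_dataset"`.
#' @export
triplet_dataset <- function(drug_i, drug_j, side_effect, label) {
  stop_if(any(drug_i == drug_j), "self-pairs (drug_i == drug_j) are not allowed")
  stop_if(!all(label %in% c(0L, 1L)), "label must be 0 or 1")
  a <- pmin(drug_i, drug_j)
  b <- pmax(drug_i, drug_j)
  df <- data.frame(drug_i = a, drug_j = b, side_effect = side_effect,
                   label = as.integer(label), stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  key <- triplet_key(df$drug_i, df$drug_j, df$side_effect)
  stop_if(anyDuplicated(key) > 0,
          "triplet(s) present with both labels: positives and negatives must be disjoint")
  rownames(df) <- NULL
  class(df) <- c("triplet_dataset", "data.frame")
  df
}

#' Read / write triplet tables
#'
#' TSV with header `drug_i`, `drug_j`, `side_effect`, `label`. On read,
#' records are canonicalized to unordered pairs; `(a, b)` / `(b, a)`
#' duplicates are collapsed with a warning. Malformed rows raise an error
#' naming the line.
#'
#' @param path File path.
#' @return A `"triplet_dataset"`.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_i", "drug_j", "side_effect", "label")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$drug_i) | is.na(df$drug_j) | is.na(df$side_effect) |
                 is.na(df$label) | !nzchar(df$drug_i) | !nzchar(df$drug_j) |
                 df$drug_i == df$drug_j | !df$label %in% c(0, 1))
  stop_if(length(bad) > 0, "malformed row(s) at line(s): ",
          paste(bad + 1L, collapse = ", "))
  a <- pmin(df$drug_i, df$drug_j)
  b <- pmax(df$drug_i, df$drug_j)
  key <- paste(a, b, df$side_effect, df$label)
  if (anyDuplicated(key) > 0) {
    warning(sum(duplicated(key)),
            " duplicate record(s) under unordered-pair semantics collapsed")
  }
  keep <- !duplicated(key)
  triplet_dataset(a[keep], b[keep], df$side_effect[keep], df$label[keep])
}

#' @rdname read_triplets
#' @param ds A `"triplet_dataset"`.
#' @export
write_triplets <- function(ds, path) {
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split triplets for the three cold-start evaluation regimes
#'
#' * `"unseen_interaction"`: the unordered triplets are partitioned
#'   test : train at `test_fraction` (default 9:1), then `val_fraction` of
#'   the training set is moved to validation. Test pairs are combinations
#'   of drugs seen in training.
#' * `"one_unseen"` / `"both_unseen"`: a fraction of the drug vocabulary is
#'   held out; test triplets contain exactly one (resp. both) held-out
#'   drug(s) and training contains none.
#'
#' The returned train/val/test sets are pairwise disjoint as unordered
#' triplets.
#'
#' @param ds A `"triplet_dataset"` (typically positives only; negatives are
#'   sampled per split afterwards with [sample_negatives()]).
#' @param regime One of `"unseen_interaction"`, `"one_unseen"`,
#'   `"both_unseen"`.
#' @param test_fraction Test share of triplets (unseen-interaction regime).
#' @param val_fraction Validation share of the training set.
#' @param drug_holdout_fraction Share of drugs held out (drug regimes).
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` (each a `"triplet_dataset"`)
#'   and, for the drug regimes, `held_out_drugs`.
#' @export
split_triplets <- function(ds, regime = c("unseen_interaction", "one_unseen",
                                          "both_unseen"),
                           test_fraction = 0.1, val_fraction = 0.01,
                           drug_holdout_fraction = 0.2, seed = 1L) {
  regime <- match.arg(regime)
  stop_if(test_fraction <= 0 || test_fraction >= 1, "test_fraction must be in (0,1)")
  stop_if(val_fraction <= 0 || val_fraction >= 1, "val_fraction must be in (0,1)")
  df <- as.data.frame(ds)
  n <- nrow(df)
  as_td <- function(d) {
    rownames(d) <- NULL
    class(d) <- c("triplet_dataset", "data.frame")
    d
  }
  if (regime == "unseen_interaction") {
    set.seed(derive_seed(seed, "split-ui"))
    n_test <- round(test_fraction * n)
    stop_if(n_test < 1 || n_test >= n, "dataset too small to split")
    test_idx <- sample.int(n, n_test)
    rest <- setdiff(seq_len(n), test_idx)
    n_val <- round(val_fraction * length(rest))
    stop_if(n_val < 1, "dataset too small for a validation set")
    val_idx <- rest[sample.int(length(rest), n_val)]
    train_idx <- setdiff(rest, val_idx)
    return(list(train = as_td(df[train_idx, ]), val = as_td(df[val_idx, ]),
                test = as_td(df[test_idx, ])))
  }
  vocab <- sort(unique(c(df$drug_i, df$drug_j)))
  set.seed(derive_seed(seed, "split-drugs"))
  n_held <- round(drug_holdout_fraction * length(vocab))
  if (n_held == 0) {
    warning("drug_holdout_fraction holds out no drugs; test set is empty")
  }
  held <- vocab[sample.int(length(vocab), n_held)]
  n_held_in <- (df$drug_i %in% held) + (df$drug_j %in% held)
  test_idx <- which(n_held_in == if (regime == "one_unseen") 1L else 2L)
  pool <- which(n_held_in == 0L)
  n_val <- max(1L, round(val_fraction * length(pool)))
  val_idx <- pool[sample.int(length(pool), n_val)]
  train_idx <- setdiff(pool, val_idx)
  train <- df[train_idx, , drop = FALSE]
  lost <- setdiff(unique(df$side_effect[df$label == 1]),
                  unique(train$side_effect[train$label == 1]))
  if (length(lost) > 0) {
    warning("side effect(s) without training positives after drug holdout: ",
            paste(lost, collapse = ", "))
  }
  list(train = as_td(train), val = as_td(df[val_idx, ]),
       test = as_td(df[test_idx, ]), held_out_drugs = held)
}

#' Sample negative triplets to match positives one-to-one
#'
#' For every positive `(d_i, d_j, r)` a corrupted partner `d_j'` is drawn
#' uniformly from the drug vocabulary so that `(d_i, d_j', r)` is not a
#' known positive, is not a self-pair, and does not duplicate another
#' sampled negative. The result has exactly as many negatives as there are
#' positives.
#'
#' @param positives A `"triplet_dataset"` of positive triplets.
#' @param seed Integer seed.
#' @param vocabulary Drug id vector to sample from (default: drugs in
#'   `positives`).
#' @param exclude Optional `"triplet_dataset"`(s) whose triplets must also
#'   be avoided (e.g. positives and negatives of other splits, to keep all
#'   sets exclusive).
#' @param max_attempts Resampling bound per positive before failing.
#' @return A `"triplet_dataset"` of label-0 triplets.
#' @export
sample_negatives <- function(positives, seed = 1L, vocabulary = NULL,
                             exclude = NULL, max_attempts = 1000L) {
  pos <- as.data.frame(positives)
  stop_if(nrow(pos) == 0, "no positives to corrupt")
  vocab <- vocabulary %||% sort(unique(c(pos$drug_i, pos$drug_j)))
  stop_if(length(vocab) <= 2, "drug vocabulary too small for negative sampling")
  forbidden <- triplet_key(pos$drug_i, pos$drug_j, pos$side_effect)
  if (!is.null(exclude)) {
    ex <- as.data.frame(exclude)
    forbidden <- c(forbidden, triplet_key(ex$drug_i, ex$drug_j, ex$side_effect))
  }
  forbidden <- unique(forbidden)
  set.seed(derive_seed(seed, "negatives"))
  out_i <- character(nrow(pos))
  out_j <- character(nrow(pos))
  taken <- character(0)
  for (k in seq_len(nrow(pos))) {
    r <- pos$side_effect[k]
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      # pairs are unordered, so the anchor kept fixed is drawn from the
      # pair; the partner is then corrupted
      d_i <- if (stats::runif(1) < 0.5) pos$drug_i[k] else pos$drug_j[k]
      d_new <- vocab[sample.int(length(vocab), 1L)]
      if (d_new == d_i) next
      key <- triplet_key(d_i, d_new, r)
      if (key %in% forbidden || key %in% taken) next
      taken <- c(taken, key)
      out_i[k] <- d_i
      out_j[k] <- d_new
      ok <- TRUE
      break
    }
    stop_if(!ok, "negative sampling failed for (", pos$drug_i[k], ", ", r,
            "): candidate partners exhausted after ", max_attempts, " attempts")
  }
  triplet_dataset(out_i, out_j, pos$side_effect, rep(0L, nrow(pos)))
}

#' Emit both orders of every unordered triplet
#'
#' Training-time augmentation reflecting that drug pairs carry no
#' directionality. Applying it twice is a no-op (the unordered set is
#' recovered first), and evaluation always de-duplicates back to unordered
#' triplets.
#'
#' @param ds A `"triplet_dataset"` or an already-augmented data frame.
#' @return Data frame with `2n` ordered records for `n` unordered
#'   triplets; labels preserved.
#' @export
add_reversed_pairs <- function(ds) {
  df <- as.data.frame(ds)
  a <- pmin(df$drug_i, df$drug_j)
  b <- pmax(df$drug_i, df$drug_j)
  key <- paste(a, b, df$side_effect, df$label)
  keep <- !duplicated(key)
  u <- data.frame(drug_i = a[keep], drug_j = b[keep],
                  side_effect = df$side_effect[keep],
                  label = df$label[keep], stringsAsFactors = FALSE)
  out <- rbind(u, data.frame(drug_i = u$drug_j, drug_j = u$drug_i,
                             side_effect = u$side_effect, label = u$label))
  rownames(out) <- NULL
  out
}

#' Drop rare side effects
#'
#' Retains side effects observed with at least `min_pairs` distinct
#' positive drug pairs, mirroring the preprocessing that removes uncommon
#' side effects. The retained set shrinks monotonically as the threshold
#' rises.
#'
#' @param ds A `"triplet_dataset"`.
#' @param min_pairs Minimum number of distinct positive pairs.
#' @return Filtered `"triplet_dataset"`.
#' @export
filter_side_effects <- function(ds, min_pairs = 500L) {
  df <- as.data.frame(ds)
  pos <- df[df$label == 1, , drop = FALSE]
  counts <- tapply(pair_key(pos$drug_i, pos$drug_j), pos$side_effect,
                   function(k) length(unique(k)))
  keep_se <- names(counts)[counts >= min_pairs]
  out <- df[df$side_effect %in% keep_se, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triplet_dataset", "data.frame")
  out
}
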