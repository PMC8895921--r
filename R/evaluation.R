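# Orient scores so that larger = more positive. Model scores are
# distances (lower = interacting), so ranking metrics negate them.
orient_scores <- function(scores, lower_is_positive) {
  if (lower_is_positive) -scores else scores
}

check_two_classes <- function(labels) {
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be 0/1")
  stop_if(length(unique(labels)) < 2,
          "both classes must be present to compute ranking metrics")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive is
#' ranked above a random negative; tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param lower_is_positive If `TRUE` (default) lower scores indicate the
#'   positive class, matching distance-style model output.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels, lower_is_positive = TRUE) {
  check_two_classes(labels)
  s <- orient_scores(scores, lower_is_positive)
  r <- rank(s)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): walking down the ranking,
#' precision is accumulated at every recall increment. Tied scores are
#' processed as one block.
#'
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(scores, labels, lower_is_positive = TRUE) {
  check_two_classes(labels)
  s <- orient_scores(scores, lower_is_positive)
  ord <- order(-s)
  s <- s[ord]
  y <- labels[ord]
  n_pos <- sum(y == 1)
  blocks <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  k <- seq_along(y)
  block_end <- !duplicated(blocks, fromLast = TRUE)
  tp_e <- tp[block_end]
  k_e <- k[block_end]
  recall <- tp_e / n_pos
  precision <- tp_e / k_e
  sum(diff(c(0, recall)) * precision)
}

#' Optimal classification threshold by Youden's J
#'
#' Scans the midpoints of consecutive sorted unique scores and returns the
#' threshold maximizing J = sensitivity + specificity - 1 (ties broken by
#' the lower threshold). With `lower_is_positive`, a triplet is predicted
#' positive when its score is at or below the threshold.
#'
#' @inheritParams auc_score
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
optimal_threshold <- function(scores, labels, lower_is_positive = TRUE) {
  check_two_classes(labels)
  u <- sort(unique(scores))
  cands <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  pos <- labels == 1
  best <- list(threshold = cands[1], sensitivity = 0, specificity = 0, j = -Inf)
  for (th in cands) {
    pred <- if (lower_is_positive) scores <= th else scores >= th
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (j > best$j) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec, j = j)
    }
  }
  if (length(u) == 1) {
    pred <- rep(TRUE, length(scores))
    best <- list(threshold = u, sensitivity = 1, specificity = 0, j = 0)
  }
  best
}

#' Per-side-effect ranking metrics and macro averages
#'
#' Computes AUC, AUPR, and threshold-based sensitivity/specificity/
#' precision within each side effect, then macro-averages with equal
#' weight per side effect. Side effects whose test triplets contain a
#' single class are excluded with a warning. Thresholds default to
#' Youden-optimal on the test scores; supply `val_scores`/`val_labels`
#' (e.g. from a validation split) to pick thresholds there instead.
#'
#' @param truth Data frame with columns `side_effect` and `label` (0/1),
#'   one row per scored triplet.
#' @param scores Numeric scores aligned with `truth` rows.
#' @param lower_is_positive See [auc_score()].
#' @param val_truth,val_scores Optional validation triplets and scores used
#'   only for threshold selection.
#' @return List with `per_side_effect` (data frame, one row per evaluable
#'   side effect) and `macro` (named list of macro-averaged metrics).
#' @export
per_side_effect_metrics <- function(truth, scores, lower_is_positive = TRUE,
                                    val_truth = NULL, val_scores = NULL) {
  stop_if(nrow(truth) != length(scores), "scores must align with truth rows")
  ses <- sort(unique(truth$side_effect))
  rows <- list()
  skipped <- character(0)
  for (se in ses) {
    idx <- truth$side_effect == se
    lab <- truth$label[idx]
    if (length(unique(lab)) < 2) {
      skipped <- c(skipped, se)
      next
    }
    sc <- scores[idx]
    if (!is.null(val_truth)) {
      vidx <- val_truth$side_effect == se
      th_src_scores <- val_scores[vidx]
      th_src_labels <- val_truth$label[vidx]
      if (length(unique(th_src_labels)) < 2) {
        th_src_scores <- sc
        th_src_labels <- lab
      }
    } else {
      th_src_scores <- sc
      th_src_labels <- lab
    }
    th <- optimal_threshold(th_src_scores, th_src_labels, lower_is_positive)
    pred <- if (lower_is_positive) sc <= th$threshold else sc >= th$threshold
    tp <- sum(pred & lab == 1)
    rows[[se]] <- data.frame(
      side_effect = se,
      auc = auc_score(sc, lab, lower_is_positive),
      aupr = aupr_score(sc, lab, lower_is_positive),
      sensitivity = tp / sum(lab == 1),
      specificity = sum(!pred & lab == 0) / sum(lab == 0),
      precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
      threshold = th$threshold,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0) {
    warning("side effect(s) with a single class excluded: ",
            paste(skipped, collapse = ", "))
  }
  stop_if(length(rows) == 0, "no side effect with both classes to evaluate")
  per_se <- do.call(rbind, rows)
  rownames(per_se) <- NULL
  macro <- lapply(per_se[c("auc", "aupr", "sensitivity", "specificity",
                           "precision")], mean, na.rm = TRUE)
  list(per_side_effect = per_se, macro = macro)
}

#' Label drug pairs by their count of predicted side effects
#'
#' External-validation rule: a pair is labeled positive when strictly more
#' than `cutoff` side effects are predicted positive for it (the cutoff
#' mirrors the mean number of side effects per interacting pair, ~65 in
#' the FAERS-derived data).
#'
#' @param predicted_positive Data frame of triplets predicted positive,
#'   with columns `drug_i`, `drug_j` (and any others, ignored).
#' @param cutoff Non-negative count threshold.
#' @param pairs Optional data frame of all pairs to report (zero counts
#'   included); defaults to the pairs present in `predicted_positive`.
#' @return Data frame with `drug_i`, `drug_j`, `n_side_effects`, `label`.
#' @export
label_pairs_by_count <- function(predicted_positive, cutoff = 65L,
                                 pairs = NULL) {
  stop_if(cutoff < 0, "`cutoff` must be >= 0")
  key <- pair_key(predicted_positive$drug_i, predicted_positive$drug_j)
  counts <- table(key)
  if (is.null(pairs)) {
    a <- pmin(predicted_positive$drug_i, predicted_positive$drug_j)
    b <- pmax(predicted_positive$drug_i, predicted_positive$drug_j)
    keep <- !duplicated(key)
    pairs <- data.frame(drug_i = a[keep], drug_j = b[keep],
                        stringsAsFactors = FALSE)
  }
  pk <- pair_key(pairs$drug_i, pairs$drug_j)
  n <- as.integer(counts[pk])
  n[is.na(n)] <- 0L
  data.frame(drug_i = pmin(pairs$drug_i, pairs$drug_j),
             drug_j = pmax(pairs$drug_i, pairs$drug_j),
             n_side_effects = n, label = as.integer(n > cutoff),
             stringsAsFactors = FALSE)
}

#' Mean number of side effects per interacting drug pair
#'
#' @param ds A `"triplet_dataset"`; only positive triplets are counted.
#' @return Positive triplet count divided by the number of distinct
#'   unordered pairs among them.
#' @export
mean_side_effects_per_pair <- function(ds) {
  df <- as.data.frame(ds)
  pos <- df[df$label == 1, , drop = FALSE]
  stop_if(nrow(pos) == 0, "no positive triplets")
  nrow(pos) / length(unique(pair_key(pos$drug_i, pos$drug_j)))
}

#' Permutation test for enrichment of confirmed predictions
#'
#' Draws `n_perm` random samples of `sample_size` elements (without
#' replacement within each draw) from the candidate pool, counts hits in
#' each, and reports `p = (1 + #\{null >= observed\}) / n_perm`, floored at
#' `1 / n_perm` and capped at 1. With 10,000 permutations an observation
#' exceeding every null draw yields p = 0.0001.
#'
#' @param observed_hits Observed hit count (integer).
#' @param pool Vector of candidate elements.
#' @param is_hit Logical vector aligned with `pool`, or a predicate
#'   function applied to sampled elements.
#' @param sample_size Elements drawn per permutation, `<= length(pool)`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `p_value`, `null` (the null hit counts) and
#'   `observed`.
#' @export
permutation_test <- function(observed_hits, pool, is_hit, sample_size,
                             n_perm = 10000L, seed = 1L) {
  stop_if(sample_size > length(pool), "sample_size exceeds the pool")
  if (is.function(is_hit)) {
    hit_vec <- vapply(pool, is_hit, logical(1))
  } else {
    stop_if(length(is_hit) != length(pool), "is_hit must align with pool")
    hit_vec <- as.logical(is_hit)
  }
  set.seed(derive_seed(seed, "perm"))
  null <- vapply(seq_len(n_perm), function(i) {
    sum(hit_vec[sample.int(length(pool), sample_size)])
  }, numeric(1))
  p <- (1 + sum(null >= observed_hits)) / n_perm
  list(p_value = min(1, max(p, 1 / n_perm)), null = null,
       observed = observed_hits)
}
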