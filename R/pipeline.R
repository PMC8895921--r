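#' Assemble a full pipeline run configuration
#'
#' One flat list wiring the synthetic worlds (or input files), the two
#' model configurations, the split regime and the evaluation together,
#' with a single global seed propagated to every stochastic stage.
#'
#' @param seed Global integer seed.
#' @param expression_world,ddi_world Argument lists for
#'   [simulate_expression_world()] / [simulate_ddi_world()] (their `seed`
#'   is filled from the global seed).
#' @param expr_config,ddi_config Model configurations; seeds filled from
#'   the global seed.
#' @param regime,test_fraction,val_fraction,drug_holdout_fraction Split
#'   parameters, see [split_triplets()].
#' @param out_dir Output directory for artifacts.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       expression_world = list(),
                       ddi_world = list(),
                       expr_config = expr_model_config(),
                       ddi_config = ddi_model_config(),
                       regime = "unseen_interaction",
                       test_fraction = 0.1, val_fraction = 0.01,
                       drug_holdout_fraction = 0.2,
                       out_dir = tempfile("sigddi_run_")) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Performs all schema and cross-field checks at once and returns every
#' finding, rather than stopping at the first.
#'
#' @param config A [run_config()].
#' @return Character vector of error messages (empty when valid).
#' @export
validate_run_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!inherits(config, "run_config")) {
    return("config must be created with run_config()")
  }
  ec <- config$expr_config
  if (!inherits(ec, "expr_model_config")) {
    add("expr_config must be an expr_model_config")
  } else if (ec$lr_min > ec$lr_max) {
    add("expr_config: lr_min exceeds lr_max")
  }
  dc <- config$ddi_config
  if (!inherits(dc, "ddi_model_config")) {
    add("ddi_config must be a ddi_model_config")
  } else {
    if (dc$margin <= 0) add("ddi_config: margin must be > 0")
    if (dc$lr_min > dc$lr_max) add("ddi_config: lr_min exceeds lr_max")
  }
  if (!config$regime %in% c("unseen_interaction", "one_unseen", "both_unseen")) {
    add(paste0("unknown regime: ", config$regime))
  }
  for (nm in c("test_fraction", "val_fraction")) {
    v <- config[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      add(paste0(nm, " must be in (0,1)"))
    }
  }
  ew <- config$expression_world
  if (!is.null(ew$noise_sd) && ew$noise_sd < 0) {
    add("expression_world: noise_sd must be >= 0")
  }
  dw <- config$ddi_world
  if (!is.null(dw$positive_fraction) &&
      (dw$positive_fraction <= 0 || dw$positive_fraction >= 1)) {
    add("ddi_world: positive_fraction must be in (0,1)")
  }
  errs
}

#' Run the end-to-end pipeline on synthetic worlds
#'
#' Simulates the expression and DDI worlds, trains the expression model,
#' splits the DDI triplets under the configured regime, samples matched
#' negatives per split, trains the DDI model, scores the test set and
#' writes per-side-effect metrics — every stage seeded from the global
#' seed, with all artifacts written as TSV/JSON and recorded in a
#' manifest (file digests included) so a rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted models, the evaluation report
#'   and the manifest; artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  errs <- validate_run_config(config)
  stop_if(length(errs) > 0, "invalid config:\n  ",
          paste(errs, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  ew_args <- config$expression_world
  ew_args$seed <- derive_seed(config$seed, "pipeline-expr-world")
  eworld <- do.call(simulate_expression_world, ew_args)
  write_signatures(eworld$signatures, out("expression_signatures.tsv"))

  ec <- config$expr_config
  ec$seed <- derive_seed(config$seed, "pipeline-expr-model")
  emodel <- fit_expression_model(eworld$fingerprints, eworld$properties,
                                 eworld$signatures, ec)

  dw_args <- config$ddi_world
  dw_args$seed <- derive_seed(config$seed, "pipeline-ddi-world")
  dworld <- do.call(simulate_ddi_world, dw_args)
  write_triplets(dworld$triplets, out("positive_triplets.tsv"))
  write_signatures(dworld$expressions, out("ddi_expressions.tsv"))

  split_seed <- derive_seed(config$seed, "pipeline-split")
  sp <- split_triplets(dworld$triplets, regime = config$regime,
                       test_fraction = config$test_fraction,
                       val_fraction = config$val_fraction,
                       drug_holdout_fraction = config$drug_holdout_fraction,
                       seed = split_seed)
  vocab <- rownames(dworld$expressions)
  all_pos <- dworld$triplets
  neg_train <- sample_negatives(sp$train, seed = derive_seed(config$seed, "neg-train"),
                                vocabulary = vocab, exclude = all_pos)
  neg_val <- sample_negatives(sp$val, seed = derive_seed(config$seed, "neg-val"),
                              vocabulary = vocab,
                              exclude = rbind(as.data.frame(all_pos),
                                              as.data.frame(neg_train)))
  neg_test <- sample_negatives(sp$test, seed = derive_seed(config$seed, "neg-test"),
                               vocabulary = vocab,
                               exclude = rbind(as.data.frame(all_pos),
                                               as.data.frame(neg_train),
                                               as.data.frame(neg_val)))
  train <- rbind(as.data.frame(sp$train), as.data.frame(neg_train))
  val <- rbind(as.data.frame(sp$val), as.data.frame(neg_val))
  test <- rbind(as.data.frame(sp$test), as.data.frame(neg_test))
  for (nm in c("train", "val", "test")) {
    utils::write.table(get(nm), out(paste0(nm, "_triplets.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  dc <- config$ddi_config
  dc$seed <- derive_seed(config$seed, "pipeline-ddi-model")
  dmodel <- fit_ddi_model(train, dworld$expressions, dc)

  test_scores <- predict(dmodel, test, dworld$expressions)
  val_scores <- predict(dmodel, val, dworld$expressions)
  scores_df <- cbind(test, score = test_scores)
  utils::write.table(scores_df, out("test_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- per_side_effect_metrics(test, test_scores,
                                    val_truth = val, val_scores = val_scores)
  utils::write.table(report$per_side_effect, out("per_side_effect_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  artifacts <- list.files(config$out_dir, pattern = "\\.tsv$")
  manifest <- list(
    seed = config$seed,
    regime = config$regime,
    n_compounds = nrow(eworld$signatures),
    n_drugs = nrow(dworld$expressions),
    n_train = nrow(train), n_val = nrow(val), n_test = nrow(test),
    expr_heldout_pearson = if (!is.null(emodel$cv)) emodel$cv$pearson else NA,
    macro = report$macro,
    digests = as.list(tools::md5sum(file.path(config$out_dir, artifacts)))
  )
  names(manifest$digests) <- artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(expression_model = emodel, ddi_model = dmodel,
                 report = report, manifest = manifest,
                 splits = list(train = train, val = val, test = test)))
}
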