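#' Pipeline configuration
#'
#' One flat configuration object for the build -> select -> train -> evaluate
#' orchestration. Inputs may be given as file paths (`fasta`, `pssm_dir`,
#' `fingerprints`, `interactions`) or as in-memory objects (`proteins`,
#' `pssms`, `drugs`, `interaction_table`); in-memory objects win.
#'
#' @param fasta,pssm_dir,fingerprints,interactions Input file paths
#'   (`pssm_dir` holds one `<protein_id>.pssm` per protein).
#' @param proteins,pssms,drugs,interaction_table In-memory equivalents.
#' @param mode Combination mode `"A"`, `"B"` or `"C"`.
#' @param neg_ratio Negatives per positive in pair assembly.
#' @param encoder An [encoder_config()].
#' @param selection List: `bins`, `max_rank` (IWSSR options), or `NULL` to
#'   skip selection.
#' @param rf List of [rotation_forest()] options.
#' @param evaluation List: `method` (`"split"` or `"cv"`), `train_fraction`,
#'   `k`.
#' @param seed Master integer seed.
#' @param out_dir Optional artifact directory (feature matrix CSV, selection
#'   JSON, model RDS, report JSON, ROC CSV).
#' @param verbose Log one line per stage.
#' @return A list of class `dti_config`.
#' @export
dti_config <- function(fasta = NULL, pssm_dir = NULL, fingerprints = NULL,
                       interactions = NULL, proteins = NULL, pssms = NULL,
                       drugs = NULL, interaction_table = NULL,
                       mode = "C", neg_ratio = 1,
                       encoder = encoder_config(),
                       selection = list(bins = 5L, max_rank = 100L),
                       rf = list(n_trees = 35L, subset_size = 3L,
                                 bootstrap_fraction = 0.75),
                       evaluation = list(method = "split",
                                         train_fraction = 0.9, k = 10L),
                       seed = 7L, out_dir = NULL, verbose = FALSE) {
  mode <- toupper(as.character(mode))
  if (!mode %in% c("A", "B", "C"))
    stop("unknown combination mode '", mode, "' (expected A, B or C)")
  if (!is.null(evaluation$method) &&
      !evaluation$method %in% c("split", "cv"))
    stop("evaluation method must be 'split' or 'cv'")
  for (p in c(fasta, fingerprints, interactions, pssm_dir))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(list(fasta = fasta, pssm_dir = pssm_dir,
                 fingerprints = fingerprints, interactions = interactions,
                 proteins = proteins, pssms = pssms, drugs = drugs,
                 interaction_table = interaction_table,
                 mode = mode, neg_ratio = neg_ratio, encoder = encoder,
                 selection = selection, rf = rf, evaluation = evaluation,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "dti_config")
}

.stage_log <- function(cfg, stage, ...) {
  if (cfg$verbose) message("[", stage, "] ", ...)
}

#' Run the full DTI prediction pipeline
#'
#' Stages, in order: (1) build the labeled pair feature matrix; (2) rank
#' features by symmetric uncertainty and run IWSSR selection; (3) fit the
#' Rotation Forest on the selected features; (4) evaluate. With the default
#' `"split"` protocol, a stratified 90/10 train/independent split is drawn,
#' selection and training happen on the 90% portion only, and the report
#' measures the held-out 10%. With `"cv"`, stratified k-fold
#' cross-validation nests selection and training inside each training fold.
#' Fully reproducible given the config seed.
#'
#' @param config A [dti_config()].
#' @return Object of class `dti_run`: `report` (a `dti_eval`), `selection`
#'   (an `iwssr`, or `NULL`), `model` (the final `rotation_forest`, split
#'   protocol only), `pairs` (the assembled `dti_pairs`), `config`, and any
#'   written artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dti_config"))
  cfg <- config
  t0 <- Sys.time()

  proteins <- cfg$proteins %||% read_fasta(cfg$fasta)
  drugs <- cfg$drugs %||% read_fingerprints(cfg$fingerprints)
  inter <- cfg$interaction_table %||% read_interactions(cfg$interactions,
                                                        quiet = !cfg$verbose)
  pssms <- cfg$pssms
  if (is.null(pssms) && !is.null(cfg$pssm_dir)) {
    files <- list.files(cfg$pssm_dir, pattern = "\\.pssm$",
                        full.names = TRUE)
    pssms <- lapply(files, read_pssm)
    names(pssms) <- sub("\\.pssm$", "", basename(files))
  }
  .stage_log(cfg, "inputs", length(proteins), " proteins, ", nrow(drugs),
             " drugs, ", nrow(inter), " interactions")

  pairs <- build_pairs(proteins, drugs, inter, mode = cfg$mode,
                       pssms = pssms, neg_ratio = cfg$neg_ratio,
                       seed = cfg$seed, config = cfg$encoder)
  .stage_log(cfg, "build", nrow(pairs$X), " pairs x ", ncol(pairs$X),
             " features (mode ", cfg$mode, ")")

  artifacts <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    artifacts$matrix <- file.path(cfg$out_dir, "feature_matrix.csv")
    write_feature_matrix(pairs, artifacts$matrix)
  }

  if (identical(cfg$evaluation$method %||% "split", "cv")) {
    report <- kfold_cv(pairs, k = cfg$evaluation$k %||% 10L,
                       seed = cfg$seed, selection = cfg$selection,
                       rf = cfg$rf)
    out <- structure(list(report = report, selection = NULL, model = NULL,
                          pairs = pairs, config = cfg,
                          artifacts = artifacts),
                     class = "dti_run")
    return(.finish_run(out, t0))
  }

  split <- independent_split(pairs,
                             train_fraction = cfg$evaluation$train_fraction %||% 0.9,
                             seed = cfg$seed)
  train <- split$train; indep <- split$independent
  cols <- seq_len(ncol(train$X))
  sel <- NULL
  if (!is.null(cfg$selection)) {
    sel <- iwssr_select(train$X, train$y,
                        bins = cfg$selection$bins %||% 5L,
                        max_rank = cfg$selection$max_rank,
                        seed = cfg$seed)
    cols <- sel$selected
    .stage_log(cfg, "select", length(cols), " features, wrapper accuracy ",
               round(sel$best_score, 4))
    if (cfg$verbose) print(utils::head(sel$trace, 10))
  }
  rf_opts <- cfg$rf
  if (!is.null(rf_opts$subset_size))
    rf_opts$subset_size <- min(rf_opts$subset_size, length(cols))
  model <- do.call(rotation_forest,
                   c(list(x = train$X[, cols, drop = FALSE], y = train$y,
                          seed = cfg$seed), rf_opts))
  .stage_log(cfg, "train", "rotation forest with ",
             model$config$n_trees, " trees on ", length(cols), " features")
  scores <- predict(model, indep$X[, cols, drop = FALSE], type = "prob")[, "1"]
  report <- evaluate_predictions(indep$y, scores)
  .stage_log(cfg, "eval", "independent Acc ",
             round(report$metrics[["Acc"]], 4), ", AUC ",
             round(report$auc, 4))

  out <- structure(list(report = report, selection = sel, model = model,
                        pairs = pairs, config = cfg, artifacts = artifacts),
                   class = "dti_run")
  .finish_run(out, t0)
}

.finish_run <- function(out, t0) {
  cfg <- out$config
  if (!is.null(cfg$out_dir)) {
    if (!is.null(out$selection)) {
      out$artifacts$selection <- file.path(cfg$out_dir, "selection.json")
      jsonlite::write_json(list(features = out$selection$feature_names,
                                su = unname(out$selection$su),
                                best_score = out$selection$best_score,
                                trace = out$selection$trace),
                           out$artifacts$selection, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    if (!is.null(out$model)) {
      out$artifacts$model <- file.path(cfg$out_dir, "model.rds")
      saveRDS(out$model, out$artifacts$model)
    }
    out$artifacts$report <- file.path(cfg$out_dir, "report.json")
    m <- out$report$metrics
    jsonlite::write_json(c(as.list(m), list(AUC = out$report$auc)),
                         out$artifacts$report, auto_unbox = TRUE, digits = NA)
    out$artifacts$roc <- file.path(cfg$out_dir, "roc.csv")
    utils::write.csv(out$report$roc_points, out$artifacts$roc,
                     row.names = FALSE)
  }
  out$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out
}

#' @export
print.dti_run <- function(x, ...) {
  cat("DTI pipeline run (mode ", x$config$mode, ", seed ", x$config$seed,
      ")\n", sep = "")
  if (!is.null(x$selection))
    cat("  selected features: ", length(x$selection$selected), "\n", sep = "")
  print(x$report)
  invisible(x)
}
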