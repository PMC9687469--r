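#' Load a labeled feature table from CSV
#'
#' Expects a header row, numeric feature columns and one label column
#' (default name `label`) with at most two distinct values. Non-numeric
#' feature cells are rejected with their row and column named.
#'
#' @param path CSV file path.
#' @param label_column name of the label column.
#' @return A [labeled_table()].
#' @export
load_table <- function(path, label_column = "label") {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': file does not exist", path),
         call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in '%s'", label_column, path),
         call. = FALSE)
  }
  labels <- df[[label_column]]
  feat_cols <- setdiff(names(df), label_column)
  feats <- matrix(NA_real_, nrow(df), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[feat_cols[j]]]))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric cell at row %d, column '%s': \"%s\"",
                   bad[1], feat_cols[j], df[[feat_cols[j]]][bad[1]]),
           call. = FALSE)
    }
    feats[, j] <- v
  }
  if (length(unique(labels)) > 2L) {
    stop(sprintf("label column '%s' has %d distinct values; expected 2",
                 label_column, length(unique(labels))), call. = FALSE)
  }
  labeled_table(feats, labels)
}

#' Load the Wisconsin diagnostic breast cancer dataset
#'
#' Reads the UCI ML Breast Cancer Wisconsin (Diagnostic) dataset — 569
#' samples, 30 real-valued cell-nucleus features, labels `malignant` /
#' `benign` — from the copy bundled with the local scikit-learn
#' installation (located once via the `python` on PATH). No network access
#' is needed, but a Python with scikit-learn must be available.
#'
#' @return A [labeled_table()] with 569 rows and 30 features.
#' @export
load_breast_cancer <- function() {
  path <- tryCatch(
    system2("python",
            c("-c", shQuote(paste0(
              "import sklearn.datasets, os; ",
              "print(os.path.join(os.path.dirname(sklearn.datasets.__file__),",
              " 'data', 'breast_cancer.csv'))"))),
            stdout = TRUE, stderr = FALSE),
    error = function(e) character(0), warning = function(w) character(0))
  if (length(path) == 0L || !file.exists(path[1])) {
    stop("could not locate scikit-learn's bundled breast cancer dataset; ",
         "is a python with scikit-learn on the PATH?", call. = FALSE)
  }
  header <- strsplit(readLines(path[1], n = 1L), ",")[[1]]
  target_names <- header[-(1:2)]  # c("malignant", "benign")
  raw <- read.csv(path[1], skip = 1L, header = FALSE)
  feats <- as.matrix(raw[, 1:30])
  base <- c("radius", "texture", "perimeter", "area", "smoothness",
            "compactness", "concavity", "concave points", "symmetry",
            "fractal dimension")
  colnames(feats) <- c(paste("mean", base), paste(base, "error"),
                       paste("worst", base))
  labeled_table(feats, target_names[raw[[31]] + 1L])
}

#' Experiment configuration for a PCA sweep
#'
#' Describes one end-to-end experiment: data source, train/test split, the
#' list of principal-component counts to sweep (a no-PCA baseline row is
#' always run first), training protocol and bookkeeping options.
#'
#' @param table a [labeled_table()], used directly.
#' @param input_path alternatively, a CSV to load with [load_table()].
#' @param synthetic alternatively, a [synthetic_spec()] to generate.
#' @param pca_components integer vector of component counts (may be empty
#'   for a baseline-only run).
#' @param train_fraction train share of the split (default 0.6, i.e. 3:2).
#' @param split_seed,init_seed seeds for the split and the parameter
#'   initialization (batch sampling is seeded by `train$seed`).
#' @param train a [train_config()].
#' @param embedding an [embedding_config()].
#' @param positive_label positive class for precision/recall (default:
#'   lexicographically second label).
#' @param stratified stratify the split (default TRUE).
#' @param fit_on_all fit standardization/PCA on the pooled data instead of
#'   the training split only (default FALSE; train-only avoids leakage).
#' @param init_scheme see [init_params()].
#' @param tie_class see [fidelity_classifier()].
#' @param output_dir when non-NULL, [run_sweep()] writes `metrics.csv`,
#'   `trace.csv`, `gram_train.csv`, `gram_test.csv`, `scatter.csv` and
#'   `run_meta.json` there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(table = NULL, input_path = NULL,
                              synthetic = NULL,
                              pca_components = c(30L, 16L, 8L, 4L, 2L),
                              train_fraction = 0.6, split_seed = 1L,
                              init_seed = 1L, train = train_config(),
                              embedding = embedding_config(),
                              positive_label = NULL, stratified = TRUE,
                              fit_on_all = FALSE, init_scheme = "normal",
                              tie_class = NULL, output_dir = NULL) {
  sources <- !vapply(list(table, input_path, synthetic), is.null, logical(1))
  if (sum(sources) != 1L) {
    stop("supply exactly one of `table`, `input_path`, `synthetic`",
         call. = FALSE)
  }
  pca_components <- vapply(pca_components, check_count, integer(1),
                           field = "pca_components")
  structure(list(table = table, input_path = input_path,
                 synthetic = synthetic, pca_components = pca_components,
                 train_fraction = train_fraction, split_seed = split_seed,
                 init_seed = init_seed, train = train, embedding = embedding,
                 positive_label = positive_label, stratified = stratified,
                 fit_on_all = fit_on_all, init_scheme = init_scheme,
                 tie_class = tie_class, output_dir = output_dir),
            class = "experiment_config")
}

# one split -> standardize -> (pca) -> init -> train -> evaluate run
run_one <- function(train_tab, test_tab, k, cfg) {
  fit_tab <- if (cfg$fit_on_all) {
    labeled_table(rbind(train_tab$features, test_tab$features),
                  c(train_tab$labels, test_tab$labels))
  } else {
    train_tab
  }
  std <- fit_standardizer(fit_tab)
  tr <- apply_standardizer(train_tab, std)
  te <- apply_standardizer(test_tab, std)
  used_pca <- !is.na(k)
  if (used_pca) {
    pca <- fit_pca(if (cfg$fit_on_all) apply_standardizer(fit_tab, std)
                   else tr, k)
    tr <- project_pca(tr, pca)
    te <- project_pca(te, pca)
  }
  init <- init_params(n_features(tr), seed = cfg$init_seed,
                      scheme = cfg$init_scheme, config = cfg$embedding)
  fit <- train_embedding(tr, init, cfg$train, cfg$embedding)
  rec <- evaluate_split(tr, te, fit$params, cfg$embedding,
                        positive_label = cfg$positive_label,
                        used_pca = used_pca, tie_class = cfg$tie_class)
  list(record = rec, fit = fit, train = tr, test = te)
}

#' Run a PCA sweep experiment
#'
#' Executes the full pipeline — split, standardize (fit on train), optional
#' PCA, random initialization, RMSProp training, evaluation — once without
#' PCA (the baseline row) and once per entry of `pca_components`, collecting
#' one metrics row each. With `output_dir` set, also writes the metrics
#' table (4 decimal places, published column order), per-row cost traces,
#' train/test Gram matrices and the (x1, x2) scatter coordinates of the
#' baseline row's trained model, and a run-metadata JSON recording every
#' seed and option.
#'
#' @param config an [experiment_config()].
#' @return A data.frame with one row per run (baseline first), columns as in
#'   [evaluate_split()].
#' @export
run_sweep <- function(config) {
  tab <- if (!is.null(config$table)) config$table
    else if (!is.null(config$input_path)) load_table(config$input_path)
    else generate_two_class_table(config$synthetic)
  bad <- config$pca_components[config$pca_components > n_features(tab)]
  if (length(bad) > 0L) {
    stop_param("pca_components",
               sprintf("entries must be <= n_features (%d); offending: %s",
                       n_features(tab), paste(bad, collapse = ", ")))
  }
  sp <- split_train_test(tab, config$train_fraction, config$split_seed,
                         stratified = config$stratified)

  ks <- c(NA_integer_, config$pca_components)
  rows <- vector("list", length(ks))
  runs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    runs[[i]] <- tryCatch(
      run_one(sp$train, sp$test, ks[i], config),
      error = function(e) {
        stop(sprintf("sweep entry %s failed: %s",
                     if (is.na(ks[i])) "baseline (no PCA)"
                     else paste0("k = ", ks[i]),
                     conditionMessage(e)), call. = FALSE)
      })
    rows[[i]] <- runs[[i]]$record
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  if (!is.null(config$output_dir)) {
    write_sweep_outputs(config, metrics, runs, ks)
  }
  metrics
}

write_sweep_outputs <- function(config, metrics, runs, ks) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  fmt <- data.frame(
    `No. of Features` = metrics$n_features_used,
    `Training Cost` = sprintf("%.4f", metrics$training_cost),
    `Test Cost` = sprintf("%.4f", metrics$test_cost),
    `Precision` = sprintf("%.4f", metrics$precision),
    `Recall` = sprintf("%.4f", metrics$recall),
    `F1-Score` = sprintf("%.4f", metrics$f1),
    check.names = FALSE
  )
  write.csv(fmt, out("metrics.csv"), row.names = FALSE)

  traces <- do.call(rbind, lapply(seq_along(runs), function(i) {
    costs <- runs[[i]]$fit$trace$costs
    data.frame(run = i, step = seq_along(costs) - 1L, batch_cost = costs)
  }))
  write.csv(traces, out("trace.csv"), row.names = FALSE)

  # Gram matrices and scatter coordinates from the baseline (no-PCA) run
  base <- runs[[1]]
  gtr <- gram_matrix(embed_table(base$train, base$fit$params,
                                 config$embedding))
  gte <- gram_matrix(embed_table(base$test, base$fit$params,
                                 config$embedding))
  write.csv(round(gtr, 6), out("gram_train.csv"), row.names = FALSE)
  write.csv(round(gte, 6), out("gram_test.csv"), row.names = FALSE)

  scatter <- do.call(rbind, lapply(c("train", "test"), function(split) {
    t <- base[[split]]
    x <- project_features(t$features, base$fit$params$weights)
    data.frame(sample = seq_len(nrow(x)), x1 = x[, 1], x2 = x[, 2],
               label = t$labels, split = split)
  }))
  write.csv(scatter, out("scatter.csv"), row.names = FALSE)

  meta <- list(
    pca_components = config$pca_components,
    train_fraction = config$train_fraction,
    split_seed = config$split_seed, init_seed = config$init_seed,
    batch_seed = config$train$seed,
    train_config = unclass(config$train),
    embedding = unclass(config$embedding),
    stratified = config$stratified, fit_on_all = config$fit_on_all,
    init_scheme = config$init_scheme,
    batch_mode = config$train$batch_mode,
    tie_class = if (is.null(config$tie_class)) "classB-default"
                else config$tie_class,
    positive_label = if (is.null(config$positive_label)) "second-level-default"
                     else config$positive_label
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             out("run_meta.json"))
  invisible(NULL)
}
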