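CLASS_LEVELS <- c("coding", "lncRNA")

#' Construct a labeled feature corpus
#'
#' Bundles transcript ids, a feature matrix and coding/lncRNA labels into
#' the unit that [stratified_split()] and [train_classifier()] consume.
#'
#' @param ids Character vector of transcript ids.
#' @param features Numeric matrix (rows = transcripts, columns =
#'   [feature_names()]-compatible).
#' @param labels Character/factor vector over `{"coding", "lncRNA"}`.
#' @param require_both_classes Demand both classes be present (needed for
#'   training; prediction-only corpora may be single-class).
#' @return An object of class `labeled_corpus`.
#' @export
labeled_corpus <- function(ids, features, labels, require_both_classes = TRUE) {
  labels <- as.character(labels)
  stopifnot(
    nrow(features) == length(labels),
    length(ids) == length(labels),
    all(labels %in% CLASS_LEVELS)
  )
  if (require_both_classes && length(unique(labels)) < 2L) {
    stop("corpus must contain both 'coding' and 'lncRNA' transcripts")
  }
  rownames(features) <- ids
  structure(
    list(ids = ids, features = features, labels = labels),
    class = "labeled_corpus"
  )
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(
    "labeled_corpus:", length(x$ids), "transcripts (",
    sum(x$labels == "coding"), "coding /",
    sum(x$labels == "lncRNA"), "lncRNA ),",
    ncol(x$features), "features\n"
  )
  invisible(x)
}

subset_corpus <- function(corpus, idx) {
  labeled_corpus(
    corpus$ids[idx], corpus$features[idx, , drop = FALSE],
    corpus$labels[idx],
    require_both_classes = FALSE
  )
}

#' Stratified train/test split
#'
#' Splits a corpus into train and test sets while maintaining the class
#' proportions. Per-class test counts are `round(class_n * test_fraction)`,
#' then adjusted (largest-remainder rule) so the total equals
#' `round(n * test_fraction)`. Reproducible for a fixed seed.
#'
#' @param corpus A [labeled_corpus].
#' @param test_fraction Fraction in (0, 1) placed in the test set.
#' @param seed Integer seed for the random membership draw.
#' @return List with elements `train` and `test`, both `labeled_corpus`
#'   (disjoint and exhaustive).
#' @export
stratified_split <- function(corpus, test_fraction = 0.2, seed = 1L) {
  stopifnot(
    inherits(corpus, "labeled_corpus"),
    test_fraction > 0, test_fraction < 1
  )
  tab <- table(factor(corpus$labels, CLASS_LEVELS))
  if (any(tab < 2L)) {
    stop("both classes need >= 2 members for a stratified split")
  }
  raw <- as.numeric(tab) * test_fraction
  cnt <- floor(raw + 0.5)
  target <- floor(sum(tab) * test_fraction + 0.5)
  excess <- target - sum(cnt)
  if (excess != 0) {
    rem <- raw - cnt
    ord <- order(if (excess > 0) -rem else rem)
    for (k in seq_len(abs(excess))) {
      i <- ord[(k - 1L) %% length(ord) + 1L]
      cnt[i] <- cnt[i] + sign(excess)
    }
  }
  cnt <- pmin(pmax(cnt, 0), as.numeric(tab))
  set.seed(seed)
  test_idx <- unlist(lapply(seq_along(tab), function(i) {
    pool <- which(corpus$labels == names(tab)[i])
    sample(pool, cnt[i])
  }), use.names = FALSE)
  list(
    train = subset_corpus(corpus, setdiff(seq_along(corpus$ids), test_idx)),
    test = subset_corpus(corpus, sort(test_idx))
  )
}

#' Train the gradient-boosted coding/lncRNA classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (XGBoost,
#' `binary:logistic`) on a labeled feature corpus, with lncRNA as the
#' positive class. The default ensemble has 500 trees; remaining
#' hyperparameters default to learning rate 0.1, maximum depth 6, subsample
#' 1.0, and are all recorded in the returned model. Training is
#' single-threaded by default so results are bit-reproducible for a fixed
#' seed; `nthread > 1` trades that guarantee for speed.
#'
#' @param corpus A [labeled_corpus] containing both classes.
#' @param n_rounds Number of boosting rounds (trees).
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @param subsample Row subsampling fraction.
#' @param seed Integer seed recorded in and passed to the booster.
#' @param nthread Training threads (1 = reproducible).
#' @param threshold Decision threshold on the lncRNA probability.
#' @param hexamer_table Optional [hexamer_table][train_hexamer_table] to
#'   bundle with the model so downstream featurization is self-contained.
#' @return An object of class `lnc_classifier`.
#' @export
train_classifier <- function(corpus, n_rounds = 500L, eta = 0.1,
                             max_depth = 6L, subsample = 1.0, seed = 1L,
                             nthread = 1L, threshold = 0.5,
                             hexamer_table = NULL) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (any(!is.finite(corpus$features))) {
    bad <- corpus$ids[rowSums(!is.finite(corpus$features)) > 0]
    stop(
      "non-finite feature values for: ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (length(unique(corpus$labels)) < 2L) {
    stop("training corpus must contain both classes")
  }
  y <- as.integer(corpus$labels == "lncRNA")
  params <- list(
    objective = "binary:logistic", eta = eta, max_depth = max_depth,
    subsample = subsample, nthread = nthread, seed = seed
  )
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(corpus$features, label = y),
    nrounds = n_rounds, verbose = 0
  )
  structure(
    list(
      booster = booster,
      n_rounds = as.integer(n_rounds),
      feature_names = colnames(corpus$features),
      params = params,
      seed = as.integer(seed),
      threshold = threshold,
      hexamer_table = hexamer_table
    ),
    class = "lnc_classifier"
  )
}

#' Predict lncRNA probability for feature rows
#'
#' Scores feature rows with a trained model. The matrix column names must
#' equal the model's recorded feature registry, in order; a mismatch is an
#' error, never a silent reordering.
#'
#' @param model An `lnc_classifier`.
#' @param features Numeric matrix with columns named as in the model.
#' @return Numeric vector of lncRNA probabilities in `[0, 1]`, named by
#'   rownames of `features`. The classification label is
#'   `score >= model$threshold`.
#' @export
predict_score <- function(model, features) {
  stopifnot(inherits(model, "lnc_classifier"))
  if (is.null(dim(features))) {
    features <- matrix(features,
      nrow = 1L,
      dimnames = list(NULL, names(features))
    )
  }
  if (!identical(colnames(features), model$feature_names)) {
    stop(
      "feature columns do not match the model's feature registry ",
      "(same names, same order, required)"
    )
  }
  if (nrow(features) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  p <- stats::predict(
    model$booster,
    xgboost::xgb.DMatrix(features)
  )
  stats::setNames(as.numeric(p), rownames(features))
}

#' Save / load a trained classifier
#'
#' The model is persisted as a single self-describing JSON file bundling the
#' serialized booster (base64), the feature registry, all training
#' parameters, the decision threshold, and the hexamer table (if bundled).
#'
#' @param model An `lnc_classifier`.
#' @param path File path.
#' @return `path` (writer) or an `lnc_classifier` (reader).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "lnc_classifier"))
  payload <- list(
    format = "lncsieve_classifier",
    version = 1L,
    booster_raw = jsonlite::base64_enc(xgboost::xgb.save.raw(model$booster)),
    n_rounds = model$n_rounds,
    feature_names = model$feature_names,
    params = model$params,
    seed = model$seed,
    threshold = model$threshold,
    hexamer = if (!is.null(model$hexamer_table)) {
      list(
        score = as.list(model$hexamer_table$score),
        pseudocount = model$hexamer_table$pseudocount
      )
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "lncsieve_classifier")) {
    stop("not a lncsieve classifier file: ", path)
  }
  ht <- NULL
  if (!is.null(payload$hexamer)) {
    ht <- structure(
      list(
        score = unlist(payload$hexamer$score)[ALL_HEXAMERS],
        pseudocount = payload$hexamer$pseudocount
      ),
      class = "hexamer_table"
    )
  }
  structure(
    list(
      booster = xgboost::xgb.load.raw(jsonlite::base64_dec(payload$booster_raw)),
      n_rounds = as.integer(payload$n_rounds),
      feature_names = payload$feature_names,
      params = as.list(payload$params),
      seed = as.integer(payload$seed),
      threshold = payload$threshold,
      hexamer_table = ht
    ),
    class = "lnc_classifier"
  )
}
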