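MODEL_FAMILIES <- c("logistic_regression", "linear_discriminant",
                    "k_nearest_neighbors", "decision_tree", "naive_bayes",
                    "support_vector", "random_forest")

#' ModelSpec: a classifier family with hyperparameters
#'
#' The random-forest defaults record the published hyperparameter block
#' verbatim: criterion "entropy", 200 trees, random_state 100,
#' min_samples_leaf 1, min_samples_split 2, bootstrap TRUE, max_features
#' "auto" (interpreted as sqrt of the feature count). The fitting backend
#' maps these onto the ranger implementation (see the methods vignette
#' for the mapping and its one deviation: ranger offers Gini-family split
#' rules only).
#'
#' @slot family one of `r paste(MODEL_FAMILIES, collapse=", ")`
#' @slot hyperparameters named list
#' @slot fingerprintVariant free tag (e.g. "morgan1024")
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(family = "character", hyperparameters = "list",
                 fingerprintVariant = "character"))

setValidity("ModelSpec", function(object) {
  if (!object@family %in% MODEL_FAMILIES)
    return(paste("unknown family", object@family))
  TRUE
})

#' @param family model family name
#' @param hyperparameters named list of family hyperparameters
#' @param fingerprintVariant tag recording the fingerprint the model is
#'   meant to consume
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(family, hyperparameters = list(),
                      fingerprintVariant = "morgan1024") {
  new("ModelSpec", family = family, hyperparameters = hyperparameters,
      fingerprintVariant = fingerprintVariant)
}

#' The default random-forest specification
#'
#' @return a [ModelSpec-class] with the published hyperparameters
#' @export
defaultRandomForestSpec <- function() {
  modelSpec("random_forest", list(
    criterion = "entropy", n_estimators = 200L, random_state = 100L,
    min_samples_leaf = 1L, min_samples_split = 2L, bootstrap = TRUE,
    max_features = "auto", max_depth = NULL, class_weight = NULL,
    min_impurity_decrease = 0, min_weight_fraction_leaf = 0,
    oob_score = FALSE, n_jobs = 1L))
}

#' Model specifications for the seven-family comparison
#'
#' @return named list of [ModelSpec-class] objects
#' @export
defaultModelSpecs <- function() {
  sp <- lapply(MODEL_FAMILIES, function(f)
    if (f == "random_forest") defaultRandomForestSpec() else modelSpec(f))
  names(sp) <- MODEL_FAMILIES
  sp
}

fitFamily <- function(spec, xTrain, yTrain, seed) {
  fam <- spec@family
  hp <- spec@hyperparameters
  keep <- which(apply(xTrain, 2, stats::var) > 0)
  xT <- xTrain[, keep, drop = FALSE]
  obj <- switch(fam,
    logistic_regression = glmnet::glmnet(
      xT, yTrain, family = "binomial", alpha = 0, lambda = 0.01),
    linear_discriminant = MASS::lda(xT, grouping = yTrain),
    k_nearest_neighbors = list(x = xT, y = yTrain,
                               k = if (!is.null(hp$k)) hp$k else 5L),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = yTrain, xT, check.names = FALSE),
      method = "class"),
    naive_bayes = e1071::naiveBayes(xT, yTrain),
    support_vector = e1071::svm(xT, yTrain, probability = TRUE),
    random_forest = {
      df <- data.frame(y = yTrain, xT, check.names = FALSE)
      nTrees <- if (!is.null(hp$n_estimators)) hp$n_estimators else 200L
      rfSeed <- if (!is.null(hp$random_state)) hp$random_state else seed
      ranger::ranger(y ~ ., data = df, num.trees = nTrees,
                     mtry = floor(sqrt(ncol(xT))),
                     min.node.size = if (!is.null(hp$min_samples_leaf))
                       hp$min_samples_leaf else 1L,
                     replace = !isFALSE(hp$bootstrap),
                     probability = TRUE, importance = "impurity",
                     seed = rfSeed, num.threads = 1L)
    },
    stop("unknown family"))
  list(family = fam, object = obj, keep = keep)
}

predictFamilyProb <- function(fit, xNew) {
  x <- xNew[, fit$keep, drop = FALSE]
  # probability of the positive ("targeted") class
  switch(fit$family,
    logistic_regression = {
      p <- stats::predict(fit$object, newx = x, type = "response")[, 1]
      1 - p  # glmnet models the second factor level
    },
    linear_discriminant =
      stats::predict(fit$object, x)$posterior[, "targeted"],
    k_nearest_neighbors = {
      pr <- class::knn(fit$object$x, x, fit$object$y, k = fit$object$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "targeted", p, 1 - p)
    },
    decision_tree = stats::predict(
      fit$object, newdata = data.frame(x, check.names = FALSE),
      type = "prob")[, "targeted"],
    naive_bayes = stats::predict(fit$object, x, type = "raw")[, "targeted"],
    support_vector = {
      pr <- stats::predict(fit$object, x, probability = TRUE)
      attr(pr, "probabilities")[, "targeted"]
    },
    random_forest = stats::predict(
      fit$object, data = data.frame(x, check.names = FALSE),
      num.threads = 1L)$predictions[, "targeted"])
}

aucOf <- function(labels, prob) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = prob, levels = c("non_targeted",
                                                    "targeted"),
    direction = "<", quiet = TRUE)))
}

#' Cross-validated comparison of classifier families
#'
#' Runs k-fold cross-validation on the training split for each model
#' specification, reporting the mean and standard deviation of accuracy
#' and ROC AUC over folds and the selection flag
#' `selected = (mean > 0.8) & (STD < 0.2)` applied to both metrics. A
#' family that fails to fit is recorded as failed, not dropped.
#'
#' @param dataset a split [ScreenDataset-class] (see [splitDataset()])
#' @param specs list of [ModelSpec-class] (default: all seven families)
#' @param k number of folds (uses the dataset's fold assignment when it
#'   has `k` folds, otherwise reassigns deterministically)
#' @param seed integer seed
#' @return data.frame with one row per spec: means, SDs, `selected`,
#'   `failed`
#' @export
compareModels <- function(dataset, specs = defaultModelSpecs(), k = 10L,
                          seed = 1L) {
  trainIx <- which(dataset@split == "train")
  if (!length(trainIx)) stop("dataset has no training split")
  if (k > length(trainIx)) stop("k exceeds training size")
  fold <- dataset@fold[trainIx]
  if (length(unique(stats::na.omit(fold))) != k) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    fold <- integer(length(trainIx))
    for (lab in levels(dataset@labels)) {
      ix <- which(dataset@labels[trainIx] == lab)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  }
  x <- dataset@features[trainIx, , drop = FALSE]
  y <- droplevels(dataset@labels[trainIx])
  foldRows <- list()
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    acc <- auc <- rep(NA_real_, k)
    failed <- FALSE
    for (f in seq_len(k)) {
      te <- fold == f
      res <- tryCatch({
        fit <- fitFamily(spec, x[!te, , drop = FALSE], y[!te], seed)
        p <- predictFamilyProb(fit, x[te, , drop = FALSE])
        list(acc = mean((p >= 0.5) == (y[te] == "targeted")),
             auc = aucOf(y[te], p))
      }, error = function(e) NULL)
      if (is.null(res)) { failed <- TRUE; break }
      acc[f] <- res$acc; auc[f] <- res$auc
      foldRows[[length(foldRows) + 1L]] <<- data.frame(
        family = spec@family, fold = f, accuracy = res$acc,
        roc_auc = res$auc)
    }
    meanAcc <- mean(acc); sdAcc <- stats::sd(acc)
    meanAuc <- mean(auc); sdAuc <- stats::sd(auc)
    selected <- !failed && meanAcc > 0.8 && sdAcc < 0.2 &&
      meanAuc > 0.8 && sdAuc < 0.2
    data.frame(family = spec@family, fingerprint = spec@fingerprintVariant,
               mean_accuracy = meanAcc, sd_accuracy = sdAcc,
               mean_roc_auc = meanAuc, sd_roc_auc = sdAuc,
               selected = selected, failed = failed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- do.call(rbind, foldRows)
  out
}

#' ScreenModel: a trained knowledge-based screening model
#'
#' @slot fit backend fit object plus retained-column index
#' @slot spec the [ModelSpec-class] trained
#' @slot manifest the feature manifest the model consumes
#' @slot nFeatures expected feature-vector length
#' @slot seed training seed
#' @slot trainScoreMedianPositive median training-set probability of the
#'   positive class (reference point for sanity checks)
#' @exportClass ScreenModel
setClass("ScreenModel",
  representation(fit = "list", spec = "ModelSpec", manifest = "data.frame",
                 nFeatures = "integer", seed = "integer",
                 trainScoreMedianPositive = "numeric"))

setMethod("show", "ScreenModel", function(object) {
  cat(sprintf("ScreenModel (%s), %d input features\n",
              object@spec@family, object@nFeatures))
})

#' Train the screening classifier
#'
#' Fits the specified family on the dataset's training split (the whole
#' dataset when no split is assigned). The returned artifact embeds the
#' feature manifest, the specification and the seed, so that a reloaded
#' model reproduces identical predictions.
#'
#' @param dataset a [ScreenDataset-class]
#' @param spec a [ModelSpec-class] (default: the published random forest)
#' @return a [ScreenModel-class]
#' @export
trainModel <- function(dataset, spec = defaultRandomForestSpec()) {
  ix <- if (all(is.na(dataset@split))) seq_len(nrow(dataset@features))
        else which(dataset@split == "train")
  x <- dataset@features[ix, , drop = FALSE]
  y <- droplevels(dataset@labels[ix])
  fit <- fitFamily(spec, x, y, dataset@seed)
  pTrain <- predictFamilyProb(fit, x)
  new("ScreenModel", fit = fit, spec = spec, manifest = dataset@manifest,
      nFeatures = ncol(x), seed = dataset@seed,
      trainScoreMedianPositive = stats::median(pTrain[y == "targeted"]))
}

#' Save / load a screening model artifact
#'
#' Single-file bundle embedding the manifest, specification and seed.
#'
#' @param model a [ScreenModel-class]
#' @param path file path
#' @return `loadScreenModel` returns the [ScreenModel-class]
#' @export
saveScreenModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveScreenModel
#' @export
loadScreenModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "ScreenModel"))
  model
}

#' Score candidate interactions with a trained model
#'
#' Featurizes candidates under the model's manifest (or accepts a
#' prebuilt feature matrix) and returns the probability that each
#' candidate is a true (`targeted`) interaction, ranked descending with
#' deterministic ties broken by `molecule_id`.
#'
#' @param model a [ScreenModel-class]
#' @param candidates data.frame with `rna_sequence`, `molecule_id`,
#'   `smiles` columns
#' @param features optional precomputed matrix (must match the model's
#'   feature count)
#' @param model0 energy model used for featurization
#' @return data.frame with `molecule_id`, `rna_sequence`, `probability`,
#'   `rank`
#' @export
predictScores <- function(model, candidates, features = NULL,
                          model0 = defaultEnergyModel()) {
  if (is.null(features))
    features <- featurizeRecords(candidates$rna_sequence, candidates$smiles,
                                 model@manifest, model0)
  if (ncol(features) != model@nFeatures)
    stop(sprintf("feature dimension %d does not match the model (%d)",
                 ncol(features), model@nFeatures))
  p <- predictFamilyProb(model@fit, features)
  out <- data.frame(molecule_id = candidates$molecule_id,
                    rna_sequence = candidates$rna_sequence,
                    probability = as.numeric(p))
  ord <- order(-out$probability, out$molecule_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Variable importances of a tree-ensemble screening model
#'
#' Normalized impurity importances (sum 1), with per-category (RNA vs
#' molecule fingerprint) aggregation and the count of features above a
#' threshold (default 0.001).
#'
#' @param model a [ScreenModel-class] trained with a tree-ensemble family
#' @param threshold importance threshold for the count report
#' @return list with `importance` (data.frame `feature`, `importance`,
#'   `category`, sorted), `category_share` (named numeric),
#'   `n_above_threshold`, `share_above_threshold`
#' @export
featureImportance <- function(model, threshold = 0.001) {
  if (model@spec@family != "random_forest")
    stop("feature importances require a tree-ensemble model")
  imp <- ranger::importance(model@fit$object)
  imp <- pmax(imp, 0)
  full <- setNames(numeric(model@nFeatures),
                   c(model@manifest$name,
                     paste0("fp_", seq_len(model@nFeatures -
                                             nrow(model@manifest)))))
  full[names(imp)] <- imp
  if (sum(full) > 0) full <- full / sum(full)
  cat1 <- ifelse(grepl("^fp_", names(full)), "molecule", "rna")
  df <- data.frame(feature = names(full), importance = as.numeric(full),
                   category = cat1)
  df <- df[order(-df$importance, df$feature), ]
  rownames(df) <- NULL
  share <- tapply(df$importance, df$category, sum)
  list(importance = df,
       category_share = c(rna = unname(share["rna"]),
                          molecule = unname(share["molecule"])),
       n_above_threshold = sum(df$importance > threshold),
       share_above_threshold = sum(df$importance[df$importance > threshold]))
}
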