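# a small planted-signal dataset shared across model tests
makePlantedDataset <- function(nPositive = 50, motifStrength = 1,
                               seed = 21) {
  cfg <- generatorConfig(nPositive = nPositive,
                         motifStrength = motifStrength, seed = seed)
  cur <- loadInteractionTable(generateInteractionTable(cfg)$table)
  splitDataset(buildDataset(cur$records, negRatio = 3, seed = seed),
               seed = seed)
}

test_that("the random-forest defaults record the published protocol", {
  spec <- defaultRandomForestSpec()
  hp <- spec@hyperparameters
  expect_equal(spec@family, "random_forest")
  expect_equal(hp$criterion, "entropy")
  expect_equal(hp$n_estimators, 200L)
  expect_equal(hp$random_state, 100L)
  expect_equal(hp$min_samples_leaf, 1L)
  expect_equal(hp$min_samples_split, 2L)
  expect_true(hp$bootstrap)
  expect_equal(hp$max_features, "auto")
  expect_null(hp$max_depth)
  expect_null(hp$class_weight)
  expect_equal(hp$min_impurity_decrease, 0)
  expect_false(hp$oob_score)
  expect_length(defaultModelSpecs(), 7L)
})

test_that("cross-validated comparison separates signal from permuted null", {
  ds <- makePlantedDataset(nPositive = 50, seed = 21)
  fast <- defaultModelSpecs()[c("decision_tree", "naive_bayes",
                                "random_forest")]
  cmp <- compareModels(ds, specs = fast, k = 10, seed = 21)
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$mean_accuracy > 0.8, na.rm = TRUE))
  expect_true(all(cmp$selected | cmp$failed))
  # the selection flag is definitional: recompute it from the fold table
  folds <- attr(cmp, "folds")
  expect_false(is.null(folds))
  for (fam in cmp$family) {
    ff <- folds[folds$family == fam, ]
    expect_equal(nrow(ff), 10L)
    sel <- mean(ff$accuracy) > 0.8 && sd(ff$accuracy) < 0.2 &&
      mean(ff$roc_auc) > 0.8 && sd(ff$roc_auc) < 0.2
    expect_equal(cmp$selected[cmp$family == fam],
                 sel && !cmp$failed[cmp$family == fam])
    expect_equal(cmp$mean_accuracy[cmp$family == fam], mean(ff$accuracy))
    expect_equal(cmp$sd_roc_auc[cmp$family == fam], sd(ff$roc_auc))
  }
  # permuted labels: chance-level AUC, nothing selected
  perm <- ds
  set.seed(99)
  perm@labels <- sample(perm@labels)
  perm@records$label <- as.character(perm@labels)
  cmpP <- compareModels(perm, specs = fast["random_forest"], k = 10,
                        seed = 21)
  expect_lt(abs(cmpP$mean_roc_auc - 0.5), 0.15)
  expect_false(any(cmpP$selected))
})

test_that("training, scoring and persistence are deterministic", {
  ds <- makePlantedDataset(nPositive = 50, seed = 22)
  model <- trainModel(ds)
  model2 <- trainModel(ds)
  te <- which(ds@split == "test")
  cand <- ds@records[te, ]
  s1 <- predictScores(model, cand, features = ds@features[te, , drop = FALSE])
  s2 <- predictScores(model2, cand, features = ds@features[te, , drop = FALSE])
  expect_identical(s1, s2)              # random_state honored
  expect_true(all(s1$probability >= 0 & s1$probability <= 1))
  expect_identical(s1$rank, seq_len(nrow(s1)))
  # save/load round trip reproduces identical probabilities
  path <- tempfile(fileext = ".rds")
  saveScreenModel(model, path)
  s3 <- predictScores(loadScreenModel(path), cand,
                      features = ds@features[te, , drop = FALSE])
  expect_identical(s1, s3)
  # positives score above negatives on held-out data; a candidate
  # identical to a training positive scores like a positive
  p <- s1$probability[match(cand$molecule_id[ds@labels[te] == "targeted"][1],
                            s1$molecule_id)]
  tr <- which(ds@split == "train" & ds@labels == "targeted")[1]
  pTrainPos <- predictScores(model, ds@records[tr, , drop = FALSE],
                             features = ds@features[tr, , drop = FALSE])
  expect_gt(pTrainPos$probability, 0.5)
  meanPos <- mean(s1$probability[match(
    cand$molecule_id[ds@labels[te] == "targeted"], s1$molecule_id)])
  expect_gt(meanPos, mean(s1$probability))
  # feature-dimension mismatch is refused
  expect_error(predictScores(model, cand,
                             features = ds@features[te, 1:100]),
               "dimension")
})

test_that("planted signal is learned and its features dominate importance", {
  cfg <- generatorConfig(nPositive = 100, motifStrength = 1, seed = 23)
  sim <- generateInteractionTable(cfg)
  cur <- loadInteractionTable(sim$table)
  ds <- splitDataset(buildDataset(cur$records, negRatio = 3, seed = 23),
                     seed = 23)
  model <- trainModel(ds)
  te <- which(ds@split == "test")
  p <- loopscreen:::predictFamilyProb(model@fit,
                                      ds@features[te, , drop = FALSE])
  expect_gt(mean((p >= 0.5) == (ds@labels[te] == "targeted")), 0.9)
  imp <- featureImportance(model)
  expect_equal(sum(imp$importance$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance$importance >= 0))
  expect_equal(sum(imp$category_share), 1, tolerance = 1e-9)
  top10 <- head(imp$importance$feature, 10)
  expect_gte(sum(top10 %in% sim$truth$informative_features), 6)
  expect_equal(imp$n_above_threshold,
               sum(imp$importance$importance > 0.001))
})

test_that("a single informative fingerprint bit dominates importances", {
  set.seed(33)
  n <- 120
  feat <- matrix(rbinom(n * 1250, 1, 0.2), n, 1250)
  colnames(feat) <- c(defaultFeatureManifest()$name, paste0("fp_", 1:1024))
  y <- feat[, "fp_7"]
  rec <- data.frame(rna_id = "r", rna_sequence = "ACGU",
                    molecule_id = sprintf("m%03d", seq_len(n)),
                    smiles = "CCO",
                    label = ifelse(y == 1, "targeted", "non_targeted"))
  ds <- new("ScreenDataset", records = rec, features = feat,
            labels = factor(rec$label,
                            levels = c("targeted", "non_targeted")),
            manifest = defaultFeatureManifest(),
            split = rep("train", n), fold = rep(NA_integer_, n),
            seed = 33L)
  model <- trainModel(ds)
  imp <- featureImportance(model)
  expect_equal(imp$importance$feature[1], "fp_7")
  expect_gt(imp$importance$importance[1],
            5 * imp$importance$importance[2])
  # importances require a tree ensemble
  dt <- trainModel(ds, modelSpec("decision_tree"))
  expect_error(featureImportance(dt), "tree-ensemble")
})
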