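## SVM-RFE feature ranking, minority-weighted gradient-boosted
## classification, and the pairwise-group evaluation protocol
## (stratified 70/30 split, fivefold CV on the training portion only).

## severity order: the more-stenosed group of a pair is the positive class
SEVERITY_ORDER <- c("severe", "mild-moderate", "CPNCA")

#' Classifier configuration
#'
#' @param w minority-class sample-weight coefficient (default 2.5).
#' @param testFraction held-out test fraction (default 0.30).
#' @param folds CV folds on the training portion (default 5).
#' @param repeats number of repeated stratified splits (default 10); the
#'   reported metrics are means over repeats.
#' @param k number of top-ranked features to retain, or `"cv"` (default)
#'   to choose k from `kGrid` by training-CV accuracy.
#' @param kGrid candidate k values for the CV choice.
#' @param depthGrid,nroundsGrid,eta gradient-boosting hyperparameter
#'   search space for the training-CV grid search.
#' @param seed integer seed controlling splits, folds and model fits.
#' @return List of class `classifierConfig`.
#' @export
classifierConfig <- function(w = 2.5, testFraction = 0.30, folds = 5L,
                             repeats = 10L, k = "cv",
                             kGrid = c(5L, 10L, 15L, 24L),
                             depthGrid = c(2L, 3L), nroundsGrid = c(50L, 150L),
                             eta = 0.1, seed = 1L) {
    stopifnot(w > 0, testFraction > 0, testFraction < 1, folds >= 2,
              repeats >= 1)
    structure(list(w = w, testFraction = testFraction,
                   folds = as.integer(folds), repeats = as.integer(repeats),
                   k = k, kGrid = as.integer(kGrid),
                   depthGrid = as.integer(depthGrid),
                   nroundsGrid = as.integer(nroundsGrid), eta = eta,
                   seed = as.integer(seed)),
              class = "classifierConfig")
}

#' SVM recursive feature elimination ranking
#'
#' Iteratively fits a linear max-margin classifier (cost-1 linear SVM) and
#' removes the feature with the smallest squared weight, one per
#' iteration; the last survivor has rank 1. Ties are broken by column
#' order (first tied column is removed). Features should be standardized
#' by the caller (training statistics only).
#'
#' @param X numeric matrix, subjects x features (standardized).
#' @param y binary labels (factor or coercible).
#' @return Named integer ranking (1 = most important); a permutation of
#'   `1:ncol(X)`.
#' @export
svmRfeRank <- function(X, y) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) stop("no features to rank")
    y <- factor(y)
    if (nlevels(y) != 2L) stop("svmRfeRank needs exactly two classes")
    p <- ncol(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
    ranking <- setNames(integer(p), colnames(X))
    remaining <- seq_len(p)
    while (length(remaining) > 1L) {
        fit <- e1071::svm(X[, remaining, drop = FALSE], y,
                          kernel = "linear", cost = 1, scale = FALSE)
        wvec <- as.vector(t(fit$coefs) %*% fit$SV)
        drop <- which.min(wvec^2)          # first minimum: column-order ties
        ranking[remaining[drop]] <- length(remaining)
        remaining <- remaining[-drop]
    }
    ranking[remaining] <- 1L
    ranking
}

## stratified split: returns logical test mask
stratifiedSplit <- function(y, testFraction, seed) {
    set.seed(seed)
    test <- rep(FALSE, length(y))
    for (g in unique(y)) {
        idx <- which(y == g)
        nTest <- max(1L, round(length(idx) * testFraction))
        test[sample(idx, nTest)] <- TRUE
    }
    test
}

## stratified fold assignment 1..folds
stratifiedFolds <- function(y, folds, seed) {
    set.seed(seed)
    fold <- integer(length(y))
    for (g in unique(y)) {
        idx <- sample(which(y == g))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
}

xgbFit <- function(X, y01, weights, depth, nrounds, eta) {
    dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y01, weight = weights)
    xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = depth,
                      eta = eta, nthread = 1),
        data = dm, nrounds = nrounds, verbose = 0)
}

#' Train the minority-weighted gradient-boosted model
#'
#' Binary gradient-boosted trees with per-sample weight `w` on the
#' minority class; tree depth and boosting rounds are chosen by stratified
#' fivefold cross-validation on the training data only (accuracy
#' criterion). Deterministic given data, config and seed.
#'
#' @param X training matrix, subjects x features.
#' @param y training labels (2 levels); the positive class is the first
#'   level of `factor(y, levels = ...)` as prepared by
#'   [runPairwiseTasks()], or the minority class when called directly.
#' @param cfg a [classifierConfig()].
#' @param positive label of the positive (more-stenosed) class; default:
#'   the rarer class.
#' @return List of class `weightedBoostModel` with the fitted booster,
#'   chosen hyperparameters and the positive-class label.
#' @export
trainWeightedModel <- function(X, y, cfg = classifierConfig(),
                               positive = NULL) {
    X <- as.matrix(X)
    y <- factor(y)
    if (nlevels(y) != 2L) stop("binary task required")
    if (is.null(positive)) positive <- names(which.min(table(y)))
    y01 <- as.integer(y == positive)
    minority <- names(which.min(table(y)))
    weights <- ifelse(y == minority, cfg$w, 1)

    grid <- expand.grid(depth = cfg$depthGrid, nrounds = cfg$nroundsGrid)
    fold <- stratifiedFolds(y, cfg$folds, seed = deriveSeed(cfg$seed, 17L))
    cvAcc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
        correct <- 0L
        for (fd in seq_len(cfg$folds)) {
            tr <- fold != fd
            if (length(unique(y01[tr])) < 2L) next
            fit <- xgbFit(X[tr, , drop = FALSE], y01[tr], weights[tr],
                          grid$depth[gi], grid$nrounds[gi], cfg$eta)
            pr <- predict(fit, X[!tr, , drop = FALSE])
            correct <- correct + sum((pr > 0.5) == (y01[!tr] == 1L))
        }
        cvAcc[gi] <- correct / length(y01)
    }
    best <- which.max(cvAcc)
    fit <- xgbFit(X, y01, weights, grid$depth[best], grid$nrounds[best],
                  cfg$eta)
    structure(list(booster = fit, positive = positive,
                   depth = grid$depth[best], nrounds = grid$nrounds[best],
                   eta = cfg$eta, w = cfg$w, cvAccuracy = cvAcc[best],
                   featureNames = colnames(X)),
              class = "weightedBoostModel")
}

#' @export
predict.weightedBoostModel <- function(object, newdata, ...) {
    predict(object$booster,
            as.matrix(newdata)[, object$featureNames, drop = FALSE])
}

#' Evaluate a fitted model on a disjoint test split
#'
#' Computes accuracy, F1 (the harmonic mean of sensitivity and precision),
#' sensitivity, specificity and AUC, with the more-stenosed group as the
#' positive class. Both test classes must be present.
#'
#' @param model a `weightedBoostModel`.
#' @param Xtest,ytest test features and labels.
#' @return List of class `classificationReport`: `metrics` (named numeric),
#'   `confusion` (2x2, predicted x truth), `positive`.
#' @export
evaluateModel <- function(model, Xtest, ytest) {
    evaluateScores(predict(model, Xtest), ytest, model$positive)
}

#' Evaluate predicted scores against test labels
#'
#' Score-level backend of [evaluateModel()]: thresholds the positive-class
#' scores at 0.5 for the confusion matrix and computes AUC from the raw
#' scores (constant scores give AUC 0.5).
#'
#' @param score numeric positive-class scores.
#' @param ytest test labels.
#' @param positive positive-class label.
#' @return A `classificationReport`.
#' @export
evaluateScores <- function(score, ytest, positive) {
    ytest <- factor(ytest)
    if (nlevels(droplevels(ytest)) < 2L)
        stop("test split missing a class: sensitivity/specificity undefined")
    truth <- as.integer(ytest == positive)
    pred <- as.integer(score > 0.5)
    auc <- if (length(unique(score)) == 1L) 0.5
           else as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                direction = "<", levels = c(0, 1))))
    metricsFromCounts(
        tp = sum(pred == 1 & truth == 1), fn = sum(pred == 0 & truth == 1),
        tn = sum(pred == 0 & truth == 0), fp = sum(pred == 1 & truth == 0),
        auc = auc, positive = positive)
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' `accuracy = (TP+TN)/n`; `sensitivity = TP/(TP+FN)`;
#' `specificity = TN/(TN+FP)`; `precision = TP/(TP+FP)`;
#' `F1 = 2 * sens * prec / (sens + prec)` (harmonic mean of sensitivity
#' and precision).
#'
#' @param tp,fn,tn,fp confusion counts (truth positive = more-stenosed
#'   group).
#' @param auc optional AUC to carry through (NA if not supplied).
#' @param positive positive-class label.
#' @return A `classificationReport` list.
#' @export
metricsFromCounts <- function(tp, fn, tn, fp, auc = NA_real_,
                              positive = "positive") {
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    f1 <- if (is.na(prec) || sens + prec == 0) NA_real_
          else 2 * sens * prec / (sens + prec)
    confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
        dimnames = list(predicted = c("pos", "neg"),
                        truth = c("pos", "neg")))
    structure(list(
        metrics = c(accuracy = (tp + tn) / (tp + fn + tn + fp), f1 = f1,
                    sensitivity = sens, specificity = spec, auc = auc),
        confusion = confusion, positive = positive),
        class = "classificationReport")
}

#' @export
print.classificationReport <- function(x, ...) {
    cat(sprintf("classificationReport (positive = %s)\n", x$positive))
    print(round(x$metrics, 4))
    invisible(x)
}

## z-score columns by training statistics
standardizeByTrain <- function(X, trainMask) {
    mu <- colMeans(X[trainMask, , drop = FALSE])
    sdv <- apply(X[trainMask, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Run the three pairwise-group classification tasks
#'
#' For each group pair (severe vs mild-moderate, severe vs CPNCA,
#' mild-moderate vs CPNCA): repeated stratified 70/30 splits; per split,
#' features are z-scored and NA-imputed with training statistics only,
#' SVM-RFE is run on the training portion, k is chosen by training CV
#' (or fixed), the weighted boosted model is fitted on the training
#' portion and evaluated on the held-out test split. No information from
#' the test split enters selection or tuning. The positive class is the
#' more-stenosed group of the pair.
#'
#' @param se feature `SummarizedExperiment` from [cohortFeatures()] (or
#'   features x subjects matrix with `labels`).
#' @param cfg a [classifierConfig()].
#' @param labels group labels when `se` is a matrix.
#' @param family feature family to use: `"all"` (default), `"entropy"`
#'   (the 24 XSampEn/XFuzzyEn/JDistEn features) or `"spectral"`.
#' @return Named list (one per task) of class `pairwiseTaskResult`:
#'   `metrics` (mean over repeats), `perRepeat` (repeats x 5 matrix),
#'   `selectedFeatures` (from the first repeat), `groups`, `positive`.
#'   Tasks with a group under 10 subjects are skipped with a warning.
#' @export
runPairwiseTasks <- function(se, cfg = classifierConfig(), labels = NULL,
                             family = c("all", "entropy", "spectral")) {
    family <- match.arg(family)
    if (is(se, "SummarizedExperiment")) {
        mat <- assay(se, "features")
        labels <- colData(se)$group
    } else mat <- as.matrix(se)
    stopifnot(!is.null(labels), ncol(mat) == length(labels))
    keep <- featureFamilyMask(rownames(mat), family)
    mat <- mat[keep, , drop = FALSE]
    X0 <- t(mat)                               # subjects x features
    labels <- as.character(labels)

    present <- intersect(SEVERITY_ORDER, unique(labels))
    if (length(present) < 2L) stop("need at least 2 groups")
    taskPairs <- utils::combn(present, 2, simplify = FALSE)
    out <- list()
    for (tp in taskPairs) {
        taskName <- paste(tp, collapse = " vs ")
        sel <- labels %in% tp
        ySub <- labels[sel]
        if (min(table(ySub)) < 10L) {
            warning(sprintf("task '%s' skipped: a group has < 10 subjects",
                            taskName))
            next
        }
        XSub <- X0[sel, , drop = FALSE]
        positive <- tp[which.min(match(tp, SEVERITY_ORDER))]
        perRepeat <- matrix(NA_real_, cfg$repeats, 5,
            dimnames = list(NULL, c("accuracy", "f1", "sensitivity",
                                    "specificity", "auc")))
        selected <- NULL
        for (rep in seq_len(cfg$repeats)) {
            splitSeed <- deriveSeed(cfg$seed, 100L + rep)
            testMask <- stratifiedSplit(ySub, cfg$testFraction, splitSeed)
            Xz <- standardizeByTrain(imputeByTrain(XSub, !testMask),
                                     !testMask)
            rk <- svmRfeRank(Xz[!testMask, , drop = FALSE],
                             ySub[!testMask])
            k <- chooseK(Xz[!testMask, , drop = FALSE], ySub[!testMask],
                         rk, cfg, positive, seed = splitSeed)
            feats <- names(sort(rk))[seq_len(k)]
            repCfg <- cfg; repCfg$seed <- splitSeed
            model <- trainWeightedModel(
                Xz[!testMask, feats, drop = FALSE], ySub[!testMask],
                repCfg, positive = positive)
            rept <- evaluateModel(model, Xz[testMask, feats, drop = FALSE],
                                  ySub[testMask])
            perRepeat[rep, ] <- rept$metrics
            if (is.null(selected)) selected <- feats
        }
        out[[taskName]] <- structure(
            list(metrics = colMeans(perRepeat), perRepeat = perRepeat,
                 selectedFeatures = selected, groups = tp,
                 positive = positive, family = family),
            class = "pairwiseTaskResult")
    }
    out
}

## impute NA cells using the training-subjects maximum per feature
imputeByTrain <- function(X, trainMask) {
    for (j in seq_len(ncol(X))) {
        miss <- is.na(X[, j])
        if (any(miss)) {
            mx <- suppressWarnings(max(X[trainMask & !miss, j]))
            if (!is.finite(mx)) mx <- 0
            X[miss, j] <- mx
        }
    }
    X
}

## choose k by training-data CV accuracy over cfg$kGrid
chooseK <- function(Xtr, ytr, ranking, cfg, positive, seed) {
    if (is.numeric(cfg$k)) return(min(cfg$k, ncol(Xtr)))
    kGrid <- unique(pmin(cfg$kGrid, ncol(Xtr)))
    if (length(kGrid) == 1L) return(kGrid)
    ord <- names(sort(ranking))
    fold <- stratifiedFolds(ytr, cfg$folds, seed = deriveSeed(seed, 29L))
    y01 <- as.integer(ytr == positive)
    minority <- names(which.min(table(ytr)))
    weights <- ifelse(ytr == minority, cfg$w, 1)
    acc <- numeric(length(kGrid))
    for (ki in seq_along(kGrid)) {
        feats <- ord[seq_len(kGrid[ki])]
        correct <- 0L
        for (fd in seq_len(cfg$folds)) {
            tr <- fold != fd
            if (length(unique(y01[tr])) < 2L) next
            fit <- xgbFit(Xtr[tr, feats, drop = FALSE], y01[tr],
                          weights[tr], cfg$depthGrid[1],
                          cfg$nroundsGrid[1], cfg$eta)
            pr <- predict(fit, Xtr[!tr, feats, drop = FALSE])
            correct <- correct + sum((pr > 0.5) == (y01[!tr] == 1L))
        }
        acc[ki] <- correct / length(y01)
    }
    kGrid[which.max(acc)]
}

#' @export
print.pairwiseTaskResult <- function(x, ...) {
    cat(sprintf("Task %s (positive = %s, family = %s)\n",
                paste(x$groups, collapse = " vs "), x$positive, x$family))
    print(round(x$metrics, 4))
    cat(sprintf("  %d selected features (first repeat): %s\n",
                length(x$selectedFeatures),
                paste(head(x$selectedFeatures, 6), collapse = ", ")))
    invisible(x)
}
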