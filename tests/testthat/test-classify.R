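test_that("SVM-RFE ranks a perfectly separating feature first", {
    set.seed(1)
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    X[, 4] <- ifelse(y == "a", -2, 2) + rnorm(n, sd = 0.1)
    X <- scale(X)
    rk <- svmRfeRank(X, y)
    expect_equal(unname(rk["f4"]), 1L)
    expect_setequal(rk, 1:10)
})

test_that("SVM-RFE is deterministic and breaks duplicate-column ties by order", {
    set.seed(2)
    y <- rep(c("a", "b"), each = 20)
    X <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    X[, 3] <- X[, 2]                      # exact duplicate
    rk1 <- svmRfeRank(X, y)
    rk2 <- svmRfeRank(X, y)
    expect_identical(rk1, rk2)
    expect_setequal(rk1, 1:4)
})

test_that("weighted model separates a linearly separable task and is reproducible", {
    set.seed(3)
    n <- 80
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    X[, 1] <- ifelse(y == "a", -3, 3)
    cfg <- classifierConfig(seed = 9)
    m1 <- trainWeightedModel(X, y, cfg, positive = "b")
    expect_true(all((predict(m1, X) > 0.5) == (y == "b")))
    m2 <- trainWeightedModel(X, y, cfg, positive = "b")
    expect_identical(predict(m1, X), predict(m2, X))
})

test_that("minority weighting does not reduce minority sensitivity on average", {
    sens <- sapply(c(1, 2.5), function(w) {
        mean(vapply(1:8, function(s) {
            set.seed(s)
            n1 <- 70; n2 <- 20          # imbalanced
            y <- c(rep("maj", n1), rep("min", n2))
            X <- matrix(rnorm((n1 + n2) * 4), n1 + n2, 4,
                        dimnames = list(NULL, paste0("f", 1:4)))
            X[, 1] <- X[, 1] + ifelse(y == "min", 1.2, 0)
            test <- c(seq_len(15), n1 + seq_len(5))
            cfg <- classifierConfig(w = w, seed = s, folds = 3,
                                    nroundsGrid = 50L, depthGrid = 2L)
            m <- trainWeightedModel(X[-test, ], y[-test], cfg,
                                    positive = "min")
            pr <- predict(m, X[test, ]) > 0.5
            mean(pr[y[test] == "min"])
        }, numeric(1)))
    })
    expect_gte(sens[2], sens[1] - 0.05)
})

test_that("metrics match the hand-computed confusion fixture", {
    ## TP=33, FN=2, TN=2, FP=9 -> accuracy 35/46, sensitivity 33/35
    r <- metricsFromCounts(tp = 33, fn = 2, tn = 2, fp = 9)
    expect_equal(unname(r$metrics["accuracy"]), 35 / 46, tolerance = 1e-12)
    expect_equal(round(unname(r$metrics["accuracy"]), 4), 0.7609)
    expect_equal(round(unname(r$metrics["sensitivity"]), 4), 0.9429)
    prec <- 33 / 42
    sens <- 33 / 35
    expect_equal(unname(r$metrics["f1"]), 2 * prec * sens / (prec + sens))
    expect_equal(sum(r$confusion), 46)
})

test_that("evaluateModel: perfect predictions give unit metrics, constant scores give AUC 0.5", {
    set.seed(4)
    y <- rep(c("a", "b"), each = 25)
    X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("f", 1:3)))
    X[, 1] <- ifelse(y == "b", 5, -5)
    cfg <- classifierConfig(seed = 1, folds = 3)
    m <- trainWeightedModel(X, y, cfg, positive = "b")
    r <- evaluateModel(m, X, y)
    expect_equal(unname(r$metrics[c("accuracy", "f1", "sensitivity",
                                    "specificity", "auc")]),
                 rep(1, 5))
    ## constant scores: AUC must be 0.5
    rc <- evaluateScores(rep(0.4, 50), y, positive = "b")
    expect_equal(unname(rc$metrics["auc"]), 0.5)
    expect_error(evaluateModel(m, X[y == "a", ], y[y == "a"]),
                 "missing a class")
})

test_that("pairwise tasks produce three reports with leakage-free selection", {
    cohort <- genCohort(smallConfig(n = 14, seed = 21), annotations = FALSE)
    se <- cohortFeatures(cohort)
    cfg <- classifierConfig(seed = 5, repeats = 2, kGrid = c(5L, 10L))
    tasks <- runPairwiseTasks(se, cfg, family = "entropy")
    expect_named(tasks, c("severe vs mild-moderate", "severe vs CPNCA",
                          "mild-moderate vs CPNCA"))
    for (t in tasks) {
        expect_true(all(t$metrics >= 0 & t$metrics <= 1))
        expect_true(all(t$selectedFeatures %in%
                        couplingFeatureNames(c("XS", "XF", "JD"))))
        expect_equal(t$positive,
                     t$groups[which.min(match(t$groups,
                        c("severe", "mild-moderate", "CPNCA")))])
    }
    ## selection is test-set independent: perturbing held-out rows leaves
    ## the train-statistics standardization and the ranking unchanged
    mat <- assay(se, "features")
    labels <- as.character(colData(se)$group)
    sel <- labels %in% c("severe", "CPNCA")
    X <- t(mat[featureFamilyMask(rownames(mat), "entropy"), sel])
    ySub <- labels[sel]
    testMask <- seq_along(ySub) %in% seq_len(8)
    X2 <- X
    X2[testMask, ] <- X2[testMask, ] * 100 + 7
    z1 <- cardiocoupling:::standardizeByTrain(X, !testMask)
    z2 <- cardiocoupling:::standardizeByTrain(X2, !testMask)
    expect_equal(z1[!testMask, ], z2[!testMask, ])
    rk1 <- svmRfeRank(z1[!testMask, ], ySub[!testMask])
    rk2 <- svmRfeRank(z2[!testMask, ], ySub[!testMask])
    expect_identical(rk1, rk2)
})

test_that("tiny groups are skipped with a warning", {
    cohort <- genCohort(smallConfig(n = 12, seed = 8), annotations = FALSE)
    se <- cohortFeatures(cohort)
    labs <- as.character(colData(se)$group)
    labs[labs == "CPNCA"][1:8] <- "severe"   # leaves 4 CPNCA subjects
    ## both CPNCA tasks emit a skip warning (4 subjects left in CPNCA)
    warns <- capture_warnings(
        tasks <- runPairwiseTasks(assay(se, "features"),
            classifierConfig(seed = 2, repeats = 1), labels = labs,
            family = "entropy"))
    expect_length(warns, 2L)
    expect_match(warns, "skipped", all = TRUE)
    expect_named(tasks, "severe vs mild-moderate")
})
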