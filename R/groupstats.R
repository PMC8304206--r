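## Statistical screening of coupling features across severity groups:
## per-group normality (Lilliefors-corrected Kolmogorov-Smirnov), omnibus
## one-way ANOVA or Kruskal-Wallis, pairwise post hoc tests with
## Bonferroni correction over the 3 pairwise comparisons per feature.

#' Choose the omnibus test for one feature
#'
#' ANOVA iff every group passes the Kolmogorov-Smirnov normality check at
#' `alpha`; otherwise Kruskal-Wallis. Because group means and SDs are
#' estimated, the Lilliefors-corrected KS test is used by default (the
#' plain KS test against a fitted Gaussian is anti-conservative); groups
#' too small for the Lilliefors test (n < 5) fail the normality check.
#'
#' @param values numeric feature values.
#' @param labels group labels (>= 2 groups, each n >= 3).
#' @param alpha normality significance level (default 0.05).
#' @param lilliefors use the Lilliefors correction (default TRUE); if
#'   FALSE a plain `ks.test` against the fitted Gaussian is used.
#' @return `"anova"` or `"kruskal"`, with attribute `normalityP` (named
#'   per-group p-values).
#' @export
chooseTest <- function(values, labels, alpha = 0.05, lilliefors = TRUE) {
    labels <- factor(labels)
    if (nlevels(labels) < 2L) stop("need at least 2 groups")
    ns <- table(labels)
    if (any(ns < 3L)) stop("every group needs n >= 3")
    ps <- vapply(levels(labels), function(g) {
        v <- values[labels == g]
        if (sd(v) == 0) return(0)
        if (lilliefors) {
            if (length(v) < 5L) return(0)
            nortest::lillie.test(v)$p.value
        } else {
            stats::ks.test(v, "pnorm", mean(v), sd(v))$p.value
        }
    }, numeric(1))
    test <- if (all(ps > alpha)) "anova" else "kruskal"
    attr(test, "normalityP") <- ps
    test
}

#' Compare coupling features across groups
#'
#' For every feature: omnibus test chosen by [chooseTest()], then the
#' three pairwise post hoc comparisons (t tests after ANOVA,
#' Mann-Whitney/Wilcoxon after Kruskal-Wallis) with Bonferroni correction
#' over the per-feature family of 3 comparisons
#' (`adjP = min(1, 3 * rawP)`). Significance stars follow the `* p < 0.05,
#' ** p < 0.01` convention. A constant feature is reported untestable
#' (`NA` p-values).
#'
#' @param se feature `SummarizedExperiment` from [cohortFeatures()], or a
#'   features x subjects matrix.
#' @param labels group labels (taken from `colData(se)$group` when `se` is
#'   a SummarizedExperiment).
#' @param alpha significance level (default 0.05).
#' @param lilliefors see [chooseTest()].
#' @return data.frame of class `statsReport`, one row per feature x
#'   pairwise comparison: `feature, test, omnibusP, comparison, rawP,
#'   adjP, significant, stars`.
#' @export
compareGroups <- function(se, labels = NULL, alpha = 0.05,
                          lilliefors = TRUE) {
    if (is(se, "SummarizedExperiment")) {
        mat <- assay(se, "features")
        if (is.null(labels)) labels <- colData(se)$group
    } else mat <- as.matrix(se)
    lvls <- intersect(GROUPS, unique(labels))
    labels <- if (length(lvls)) factor(labels, levels = lvls)
              else factor(labels)
    stopifnot(ncol(mat) == length(labels))
    mat <- imputeMissingFeatures(mat)
    lv <- levels(labels)
    pairsIdx <- utils::combn(lv, 2, simplify = FALSE)
    rows <- list()
    for (f in rownames(mat)) {
        v <- mat[f, ]
        if (sd(v) == 0) {
            for (pr in pairsIdx)
                rows[[length(rows) + 1L]] <- data.frame(
                    feature = f, test = "untestable", omnibusP = NA_real_,
                    comparison = paste(pr, collapse = " vs "),
                    rawP = NA_real_, adjP = NA_real_, significant = NA,
                    stars = "", stringsAsFactors = FALSE)
            next
        }
        test <- chooseTest(v, labels, alpha = alpha,
                           lilliefors = lilliefors)
        omni <- if (test == "anova")
            summary(aov(v ~ labels))[[1]][["Pr(>F)"]][1]
        else kruskal.test(v, labels)$p.value
        for (pr in pairsIdx) {
            sel <- labels %in% pr
            vp <- v[sel]; lp <- droplevels(labels[sel])
            raw <- if (test == "anova")
                t.test(vp ~ lp)$p.value
            else suppressWarnings(wilcox.test(vp ~ lp)$p.value)
            adj <- min(1, raw * length(pairsIdx))
            rows[[length(rows) + 1L]] <- data.frame(
                feature = f, test = as.character(test), omnibusP = omni,
                comparison = paste(pr, collapse = " vs "),
                rawP = raw, adjP = adj, significant = adj < alpha,
                stars = if (adj < 0.01) "**" else if (adj < alpha) "*"
                        else "", stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "alpha") <- alpha
    class(out) <- c("statsReport", class(out))
    out
}

#' Summarize significant features per pairwise comparison
#'
#' @param report a `statsReport` from [compareGroups()].
#' @return data.frame of significant feature/comparison rows, sorted by
#'   adjusted p.
#' @export
significanceSummary <- function(report) {
    sig <- report[!is.na(report$significant) & report$significant, ]
    sig[order(sig$adjP), ]
}

#' Write a stats report CSV
#' @param report a `statsReport`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeStatsReport <- function(report, path) {
    write.csv(as.data.frame(report), path, row.names = FALSE)
    invisible(path)
}
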