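# Confusion-matrix construction, the five performance metrics, and the
# end-to-end pipeline driver.

#' Cross-tabulate predictions against truth
#'
#' @param predicted per-sample predicted labels: the data.frame returned by
#'   [predict,RGLMModel-method], a two-column (`sample_id`, `label`)
#'   data.frame, or a named label vector.
#' @param truth true labels in any of the same forms.
#' @param positiveClass `"sarcoma"` (default) or `"healthy"`.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(predicted, truth, positiveClass = "sarcoma") {
  positiveClass <- match.arg(positiveClass, .CLASSES)
  if (is.data.frame(predicted) && all(c("sample_id", "label") %in%
                                      names(predicted)))
    predicted <- predicted[c("sample_id", "label")]
  pred <- .normalizeLabels(predicted)
  tru <- .normalizeLabels(truth)
  extraP <- setdiff(names(pred), names(tru))
  extraT <- setdiff(names(tru), names(pred))
  if (length(extraP) || length(extraT))
    stop("sample sets differ; only in predictions: ",
         paste(extraP, collapse = ", "), "; only in truth: ",
         paste(extraT, collapse = ", "), call. = FALSE)
  tru <- tru[names(pred)]
  isPosP <- as.character(pred) == positiveClass
  isPosT <- as.character(tru) == positiveClass
  new("ConfusionCounts",
      tp = as.numeric(sum(isPosP & isPosT)),
      fp = as.numeric(sum(isPosP & !isPosT)),
      tn = as.numeric(sum(!isPosP & !isPosT)),
      fn = as.numeric(sum(!isPosP & isPosT)),
      positiveClass = positiveClass)
}

#' Performance metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN). A metric
#' whose denominator is zero comes back `NA` and is listed under
#' `undefined` rather than erroring. Swapping the positive class swaps
#' sensitivity with specificity and PPV with NPV exactly.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricsReport-class].
#' @examples
#' cc <- new("ConfusionCounts", tp = 7, fp = 2, tn = 19, fn = 7,
#'           positiveClass = "healthy")
#' classifierMetrics(cc)
#' @export
classifierMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(accuracy = ratio(tp + tn, total),
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn))
  new("MetricsReport", counts = counts,
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, ppv = m$ppv, npv = m$npv,
      undefined = names(m)[vapply(m, is.na, logical(1))])
}

#' Run the full miRNA-pair pipeline
#'
#' Executes the whole analysis on an expression matrix and label table:
#' KNN imputation, abundance filtering, stratified 3:1 split, per-gene
#' t-test screen (training samples only), pair-indicator construction over
#' the candidate genes, near-constant pair removal and pair-level t-test
#' screen (training only), RGLM fit on the training samples, occurrence
#' thinning, and confusion-matrix evaluation on the training and internal
#' test partitions. An optional external cohort is imputed separately and
#' transformed with the training-derived gene-pair list only, then scored
#' with the same model.
#'
#' @param expr genes x samples log2 matrix (missing values allowed).
#' @param labels label table (data.frame `sample_id`, `label`) or named
#'   vector covering the columns of `expr`.
#' @param k KNN imputation neighbours (default 10).
#' @param abundanceThreshold,minFraction abundance filter (defaults 8, 0.5).
#' @param trainFraction per-class training share (default 0.75).
#' @param alpha screening significance level (default 0.05).
#' @param topGenes,topPairs screening caps (defaults 250, 80).
#' @param maxConstFraction near-constant pair cutoff (default 0.90).
#' @param config RGLM hyperparameters; its `seed` is overridden by `seed`.
#' @param thin run occurrence thinning (default TRUE).
#' @param thinTolerance acceptable out-of-bag accuracy drop (default 0.01).
#' @param seed master seed; the split and ensemble seeds derive from it.
#' @param externalExpr,externalLabels optional external cohort.
#' @param positiveClass class treated as positive in the reports (default
#'   `"sarcoma"`).
#' @param verbose log stage dimensions via `message()`.
#' @return list: `split`, `candidateGenes`, `candidatePairs` (oriented pair
#'   table), `model`, `thinned` (or NULL), `predictions` (per partition),
#'   `metrics` (a [MetricsReport-class] per partition).
#' @export
runPipeline <- function(expr, labels, k = 10, abundanceThreshold = 8,
                        minFraction = 0.5, trainFraction = 0.75,
                        alpha = 0.05, topGenes = 250, topPairs = 80,
                        maxConstFraction = 0.90, config = rglmConfig(),
                        thin = TRUE, thinTolerance = 0.01, seed = 1,
                        externalExpr = NULL, externalLabels = NULL,
                        positiveClass = "sarcoma", verbose = TRUE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  lab <- .normalizeLabels(labels, colnames(expr))
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max, 2L))

  say("impute: ", nrow(expr), " genes x ", ncol(expr), " samples, ",
      sum(is.na(expr)), " missing cells")
  imp <- knnImpute(expr, k = k)

  abd <- filterAbundant(imp, abundanceThreshold, minFraction)
  say("abundance filter: ", nrow(abd), " of ", nrow(imp), " genes retained")
  if (nrow(abd) < 2L)
    stop("pipeline stage 'filterAbundant': fewer than 2 abundant genes",
         call. = FALSE)

  split <- stratifiedSplit(lab, trainFraction, seed = seeds[1L])
  say("split: ", length(split@trainIds), " train / ",
      length(split@testIds), " test")

  gstats <- geneTTest(abd[, split@trainIds, drop = FALSE],
                      lab[split@trainIds])
  genes <- selectCandidateGenes(gstats, alpha, topGenes)
  say("gene screen: ", length(genes), " candidate genes")
  if (length(genes) < 2L)
    stop("pipeline stage 'selectCandidateGenes': fewer than 2 candidates",
         call. = FALSE)

  pm <- buildPairMatrix(abd, genes)
  say("pair build: ", length(pairIds(pm)), " pairs")
  pm <- filterNearConstant(pm, split@trainIds, maxConstFraction)
  say("near-constant filter: ", length(pairIds(pm)), " pairs retained")
  cand <- selectCandidatePairs(pm, lab, split@trainIds, alpha, topPairs)
  say("pair screen: ", length(pairIds(cand)), " candidate pairs")
  if (length(pairIds(cand)) == 0L)
    stop("pipeline stage 'selectCandidatePairs': no pair survived screening",
         call. = FALSE)

  config$seed <- seeds[2L]
  model <- fitRGLM(cand[, split@trainIds], lab[split@trainIds], config)
  say("RGLM: out-of-bag accuracy ", format(model@oobAccuracy, digits = 4))

  final <- model
  thinned <- NULL
  if (thin) {
    thinned <- thinRGLM(model, cand[, split@trainIds], lab[split@trainIds],
                        thinTolerance)
    say("thinning: ", length(thinned@retainedFeatures),
        " features at occurrence cutoff ", thinned@occurrenceCutoff)
    final <- thinned
  }

  predictions <- list(train = predict(final, cand[, split@trainIds]),
                      test = predict(final, cand[, split@testIds]))
  metrics <- list(
    train = classifierMetrics(confusionCounts(predictions$train,
                                              lab[split@trainIds],
                                              positiveClass)),
    test = classifierMetrics(confusionCounts(predictions$test,
                                             lab[split@testIds],
                                             positiveClass)))
  say("internal test accuracy: ", .pct1(metrics$test@accuracy), "%")

  if (!is.null(externalExpr)) {
    if (is.null(externalLabels))
      stop("externalLabels required with externalExpr", call. = FALSE)
    extLab <- .normalizeLabels(externalLabels, colnames(externalExpr))
    extImp <- if (anyNA(externalExpr)) knnImpute(externalExpr, k = k)
              else externalExpr
    extPm <- .PairFeatureMatrix(pairInfo(cand),
                                .indicatorMatrix(pairInfo(cand), extImp))
    predictions$external <- predict(final, extPm)
    metrics$external <- classifierMetrics(
      confusionCounts(predictions$external, extLab, positiveClass))
    say("external accuracy: ", .pct1(metrics$external@accuracy), "%")
  }

  list(split = split, candidateGenes = genes, candidatePairs = pairInfo(cand),
       geneStats = gstats, model = model, thinned = thinned,
       predictions = predictions, metrics = metrics)
}
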