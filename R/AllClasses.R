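#' @import methods
NULL

#' Binary gene-pair feature matrix
#'
#' Rank-comparison ("top-scoring-pair" style) features: one row per ordered
#' gene pair (G1, G2), one column per sample, value 1 when the expression of
#' G1 is strictly below that of G2 within the sample, else 0. Because only
#' the within-sample ordering of the two genes enters, the features are
#' invariant under any strictly increasing per-sample intensity transform —
#' the property that makes them robust to batch and platform effects.
#'
#' @slot pairs data.frame with character columns `gene1`, `gene2` (the
#'   oriented pair members); row i describes row i of `values`.
#' @slot values numeric matrix of 0/1 indicators, pairs x samples; rownames
#'   are pair identifiers `"G1|G2"`, colnames are sample identifiers.
#'
#' @seealso [buildPairMatrix()], [computePublishedFeatures()]
#' @export
setClass("PairFeatureMatrix",
         slots = c(pairs = "data.frame", values = "matrix"))

setValidity("PairFeatureMatrix", function(object) {
  p <- object@pairs
  v <- object@values
  msg <- character(0)
  if (!all(c("gene1", "gene2") %in% names(p)))
    msg <- c(msg, "pairs must have columns gene1, gene2")
  else {
    if (any(p$gene1 == p$gene2))
      msg <- c(msg, "a gene cannot be paired with itself")
    ids <- paste(p$gene1, p$gene2, sep = "|")
    if (anyDuplicated(ids))
      msg <- c(msg, "duplicate pair identifiers")
    if (nrow(v) != nrow(p))
      msg <- c(msg, "values row count must match pairs")
    else if (nrow(v) > 0 && !identical(rownames(v), ids))
      msg <- c(msg, "rownames(values) must equal 'gene1|gene2'")
  }
  if (is.null(colnames(v)) && ncol(v) > 0)
    msg <- c(msg, "values must carry sample colnames")
  if (length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "values must be 0/1 indicators")
  if (length(msg)) msg else TRUE
})

.PairFeatureMatrix <- function(pairs, values) {
  rownames(values) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  new("PairFeatureMatrix",
      pairs = data.frame(gene1 = as.character(pairs$gene1),
                         gene2 = as.character(pairs$gene2),
                         stringsAsFactors = FALSE),
      values = values)
}

#' Stratified train/test split assignment
#'
#' @slot trainIds,testIds character vectors of sample identifiers (disjoint;
#'   union is the full labelled cohort).
#' @slot trainFraction per-class training proportion (3:1 split = 0.75).
#' @slot seed integer seed the assignment was drawn under.
#'
#' @seealso [stratifiedSplit()]
#' @export
setClass("SplitAssignment",
         slots = c(trainIds = "character", testIds = "character",
                   trainFraction = "numeric", seed = "numeric"))

setValidity("SplitAssignment", function(object) {
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test sets overlap")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  TRUE
})

#' Synthetic-cohort configuration
#'
#' Parameters of the serum-miRNA cohort emulator: a log2-intensity matrix with
#' an abundant stratum, class-shifted (differentially expressed) miRNAs,
#' planted gene pairs whose within-sample ordering flips between classes with
#' a controlled probability, and missing-at-random cells.
#'
#' @slot nHealthy,nSarcoma samples per class.
#' @slot nGenes total miRNAs; the first `nAbundant` form the abundant stratum
#'   (log2 mean above 8 by construction).
#' @slot nDifferential abundant miRNAs whose sarcoma mean is shifted by
#'   `effectSize` log2 units.
#' @slot effectSize class mean shift (log2 units) for differential miRNAs.
#' @slot noiseSd within-class per-gene standard deviation (log2 units).
#' @slot nPlantedPairs disjoint gene pairs (drawn from the abundant,
#'   non-differential stratum) whose rank order holds with probability
#'   `flipProb` within each class and points the opposite way in the other.
#' @slot flipProb orientation probability, in (0.5, 1].
#' @slot missingRate independent per-cell missingness probability, in [0, 1).
#' @slot seed integer randomness seed; identical config + seed gives
#'   bit-identical cohorts.
#'
#' @seealso [syntheticConfig()], [generateCohort()]
#' @export
setClass("SyntheticConfig",
         slots = c(nHealthy = "numeric", nSarcoma = "numeric",
                   nGenes = "numeric", nAbundant = "numeric",
                   nDifferential = "numeric", effectSize = "numeric",
                   noiseSd = "numeric", nPlantedPairs = "numeric",
                   flipProb = "numeric", missingRate = "numeric",
                   seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  cnt <- c(nHealthy = object@nHealthy, nSarcoma = object@nSarcoma,
           nGenes = object@nGenes, nAbundant = object@nAbundant,
           nDifferential = object@nDifferential,
           nPlantedPairs = object@nPlantedPairs)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (object@nAbundant > object@nGenes)
    msg <- c(msg, "nAbundant must not exceed nGenes")
  if (object@nDifferential > object@nAbundant)
    msg <- c(msg, "nDifferential must not exceed nAbundant")
  if (object@nDifferential + 2 * object@nPlantedPairs > object@nAbundant)
    msg <- c(msg,
             "need nDifferential + 2*nPlantedPairs <= nAbundant (planted pairs use dedicated abundant genes)")
  if (object@flipProb <= 0.5 || object@flipProb > 1)
    msg <- c(msg, "flipProb must lie in (0.5, 1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive")
  if (length(msg)) msg else TRUE
})

#' Random generalized linear model ensemble
#'
#' A bagged ensemble of forward-selected logistic regressions over binary
#' pair features. Each bag holds a bootstrap of the training samples and a
#' random feature subset; features are pre-filtered by a point-biserial
#' correlation test and entered by forward AIC search; the ensemble predicts
#' by majority vote (sarcoma = positive class throughout).
#'
#' @slot config hyperparameter list, see [rglmConfig()].
#' @slot bags list of per-bag fits (bootstrap ids, out-of-bag ids, candidate
#'   and selected features, coefficients on the log-odds scale, separation
#'   flag).
#' @slot occurrence named numeric: for each candidate feature, the number of
#'   bags whose final GLM includes it.
#' @slot oobAccuracy out-of-bag accuracy of the majority vote.
#' @slot featureIds candidate feature universe at fit time.
#' @slot classLevels `c("healthy", "sarcoma")`.
#'
#' @seealso [fitRGLM()], [thinRGLM()], [predict,RGLMModel-method]
#' @export
setClass("RGLMModel",
         slots = c(config = "list", bags = "list", occurrence = "numeric",
                   oobAccuracy = "numeric", featureIds = "character",
                   classLevels = "character"))

setValidity("RGLMModel", function(object) {
  msg <- character(0)
  if (length(object@bags) < 1L)
    msg <- c(msg, "model must hold at least one bag")
  occ <- object@occurrence
  if (length(occ) && (any(occ < 0) || any(occ > length(object@bags))))
    msg <- c(msg, "occurrence counts must lie in [0, nBags]")
  if (!identical(object@classLevels, .CLASSES))
    msg <- c(msg, "classLevels must be c('healthy', 'sarcoma')")
  if (length(msg)) msg else TRUE
})

#' Thinned RGLM ensemble
#'
#' The result of occurrence-based thinning: the ensemble refit on the
#' features that occurred most often across the member GLMs, using the same
#' bag structure, with the out-of-bag accuracy trace of every cutoff tried.
#'
#' @slot retainedFeatures features with occurrence >= `occurrenceCutoff`.
#' @slot occurrenceCutoff the accepted occurrence cutoff.
#' @slot thinTrace data.frame (cutoff, nFeatures, oobAccuracy, accepted).
#'
#' @seealso [thinRGLM()]
#' @export
setClass("ThinnedRGLM", contains = "RGLMModel",
         slots = c(retainedFeatures = "character",
                   occurrenceCutoff = "numeric", thinTrace = "data.frame"))

#' Confusion counts
#'
#' The 2x2 cross-tabulation of predicted against true class for a stated
#' positive class.
#'
#' @slot tp,fp,tn,fn nonnegative counts.
#' @slot positiveClass `"sarcoma"` or `"healthy"`.
#'
#' @seealso [confusionCounts()], [classifierMetrics()]
#' @export
setClass("ConfusionCounts",
         slots = c(tp = "numeric", fp = "numeric", tn = "numeric",
                   fn = "numeric", positiveClass = "character"))

setValidity("ConfusionCounts", function(object) {
  n <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(n < 0) || any(n != floor(n)))
    return("counts must be nonnegative integers")
  if (!object@positiveClass %in% .CLASSES)
    return("positiveClass must be 'healthy' or 'sarcoma'")
  TRUE
})

#' Classifier performance report
#'
#' Accuracy, sensitivity, specificity, PPV and NPV derived from a confusion
#' table. A metric whose denominator is zero is NA and listed in `undefined`
#' rather than raising an error.
#'
#' @slot counts the [ConfusionCounts-class] the metrics derive from.
#' @slot accuracy (TP+TN)/(TP+TN+FP+FN).
#' @slot sensitivity TP/(TP+FN).
#' @slot specificity TN/(TN+FP).
#' @slot ppv TP/(TP+FP).
#' @slot npv TN/(TN+FN).
#' @slot undefined names of metrics with zero denominators.
#'
#' @seealso [classifierMetrics()]
#' @export
setClass("MetricsReport",
         slots = c(counts = "ConfusionCounts", accuracy = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   ppv = "numeric", npv = "numeric", undefined = "character"))
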