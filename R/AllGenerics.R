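#' Accessors for package classes
#'
#' Small accessor generics in the Bioconductor idiom: use these rather than
#' reaching into slots.
#'
#' @param object a package object (see the class pages).
#' @return `pairIds`: character pair identifiers ("G1|G2"); `pairInfo`: the
#'   oriented pair table (gene1, gene2); `pairValues`: the 0/1 indicator
#'   matrix; `sampleIds`: character sample identifiers; `occurrence`: named
#'   per-feature bag-occurrence counts; `oobAccuracy`: out-of-bag accuracy;
#'   `trainIds`/`testIds`: the split members; `retainedFeatures`: features a
#'   thinned model keeps.
#'
#' @name accessors
#' @aliases pairIds pairInfo pairValues sampleIds occurrence oobAccuracy
#'   trainIds testIds retainedFeatures
NULL

#' @rdname accessors
#' @export
setGeneric("pairIds", function(object) standardGeneric("pairIds"))

#' @rdname accessors
#' @export
setGeneric("pairInfo", function(object) standardGeneric("pairInfo"))

#' @rdname accessors
#' @export
setGeneric("pairValues", function(object) standardGeneric("pairValues"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("occurrence", function(object) standardGeneric("occurrence"))

#' @rdname accessors
#' @export
setGeneric("oobAccuracy", function(object) standardGeneric("oobAccuracy"))

#' @rdname accessors
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))

#' @rdname accessors
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))

#' @rdname accessors
#' @export
setGeneric("retainedFeatures",
           function(object) standardGeneric("retainedFeatures"))

#' @rdname accessors
#' @export
setMethod("pairIds", "PairFeatureMatrix",
          function(object) rownames(object@values))

#' @rdname accessors
#' @export
setMethod("pairInfo", "PairFeatureMatrix", function(object) object@pairs)

#' @rdname accessors
#' @export
setMethod("pairValues", "PairFeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("sampleIds", "PairFeatureMatrix",
          function(object) colnames(object@values))

#' @rdname accessors
#' @export
setMethod("occurrence", "RGLMModel", function(object) object@occurrence)

#' @rdname accessors
#' @export
setMethod("oobAccuracy", "RGLMModel", function(object) object@oobAccuracy)

#' @rdname accessors
#' @export
setMethod("trainIds", "SplitAssignment", function(object) object@trainIds)

#' @rdname accessors
#' @export
setMethod("testIds", "SplitAssignment", function(object) object@testIds)

#' @rdname accessors
#' @export
setMethod("retainedFeatures", "ThinnedRGLM",
          function(object) object@retainedFeatures)

#' Subset a pair-feature matrix
#'
#' `x[i, j]` subsets pairs (by index or "G1|G2" identifier) and samples (by
#' index or sample identifier), returning a `PairFeatureMatrix`.
#'
#' @param x a [PairFeatureMatrix-class].
#' @param i pair indices or identifiers.
#' @param j sample indices or identifiers.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "PairFeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(i)) {
    idx <- match(i, rownames(x@values))
    if (anyNA(idx))
      stop("unknown pair id(s): ", paste(i[is.na(idx)], collapse = ", "),
           call. = FALSE)
    i <- idx
  }
  .PairFeatureMatrix(x@pairs[i, , drop = FALSE],
                     x@values[i, j, drop = FALSE])
})

setMethod("show", "PairFeatureMatrix", function(object) {
  cat("PairFeatureMatrix:", nrow(object@values), "gene pairs x",
      ncol(object@values), "samples\n")
  if (nrow(object@pairs)) {
    k <- utils::head(seq_len(nrow(object@pairs)), 3L)
    cat("  pairs:",
        paste(rownames(object@values)[k], collapse = ", "),
        if (nrow(object@pairs) > 3L) "..." else "", "\n")
  }
})

setMethod("show", "SplitAssignment", function(object) {
  cat("SplitAssignment: ", length(object@trainIds), " train / ",
      length(object@testIds), " test (trainFraction = ",
      object@trainFraction, ", seed = ", object@seed, ")\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nHealthy, "healthy +", object@nSarcoma,
      "sarcoma samples,", object@nGenes, "miRNAs\n")
  cat("  abundant:", object@nAbundant, " differential:", object@nDifferential,
      "(effect", object@effectSize, "log2)\n")
  cat("  planted pairs:", object@nPlantedPairs, "(flipProb",
      object@flipProb, ") noiseSd:", object@noiseSd,
      " missingRate:", object@missingRate, " seed:", object@seed, "\n")
})

setMethod("show", "RGLMModel", function(object) {
  cat("RGLMModel:", length(object@bags), "bags over",
      length(object@featureIds), "candidate features\n")
  cat("  out-of-bag accuracy:", format(object@oobAccuracy, digits = 4), "\n")
  occ <- sort(object@occurrence[object@occurrence > 0], decreasing = TRUE)
  if (length(occ))
    cat("  top occurrence:",
        paste(utils::head(names(occ), 3L), "(", utils::head(occ, 3L), ")",
              collapse = ", "), "\n")
})

setMethod("show", "ThinnedRGLM", function(object) {
  cat("ThinnedRGLM:", length(object@retainedFeatures),
      "retained features (occurrence cutoff", object@occurrenceCutoff, ")\n")
  cat("  out-of-bag accuracy:", format(object@oobAccuracy, digits = 4),
      "over", length(object@bags), "bags\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (positive class: ", object@positiveClass, ")\n",
      sep = "")
  cat("  TP =", object@tp, " FP =", object@fp, " TN =", object@tn,
      " FN =", object@fn, "\n")
})

setMethod("show", "MetricsReport", function(object) {
  show(object@counts)
  fmt <- function(x) if (is.na(x)) "undefined" else paste0(.pct1(x), "%")
  cat("  accuracy:    ", fmt(object@accuracy), "\n")
  cat("  specificity: ", fmt(object@specificity), "\n")
  cat("  sensitivity: ", fmt(object@sensitivity), "\n")
  cat("  PPV:         ", fmt(object@ppv), "\n")
  cat("  NPV:         ", fmt(object@npv), "\n")
})
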