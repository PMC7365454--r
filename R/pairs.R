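# Gene screening, rank-comparison pair features, and pair screening.

#' Per-gene two-sample t test
#'
#' Welch (default) or pooled-variance t test of each miRNA between healthy
#' and sarcoma samples. The reported `effect` is the difference in class
#' means (sarcoma minus healthy); screening ranks genes by its absolute
#' value. Genes with zero variance in both classes are flagged `degenerate`:
#' with equal class means they get t = 0, p = 1, effect = 0; with unequal
#' means the infinite-t Welch limit (p = 0) applies.
#'
#' @param x complete genes x samples matrix.
#' @param labels label table or named vector covering all samples of `x`.
#' @param var.equal use the pooled-variance test instead of Welch.
#' @return data.frame: `feature_id`, `t_stat`, `df`, `p_value`, `effect`,
#'   `degenerate`.
#' @seealso [selectCandidateGenes()]
#' @export
geneTTest <- function(x, labels, var.equal = FALSE) {
  .assertExpression(x, complete = TRUE)
  grp <- .normalizeLabels(labels, colnames(x))
  .rowTTest(x, grp, var.equal = var.equal)
}

#' Select candidate genes
#'
#' Among genes with `p_value < alpha`, keeps the `topN` with the largest
#' absolute effect (all of them when fewer qualify). Ties are broken by
#' ascending p value, then identifier, so selection is deterministic.
#'
#' @param stats output of [geneTTest()] (or [pairTTest()]).
#' @param alpha significance level (default 0.05).
#' @param topN effect-rank cap (default 250, the gene-screen cap).
#' @return character vector of selected identifiers, ranked.
#' @export
selectCandidateGenes <- function(stats, alpha = 0.05, topN = 250) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0L)
  .selectTop(stats, alpha, topN)
}

# Indicator matrix for an oriented pair table: 1 iff expr(gene1) < expr(gene2)
# within the sample, ties and reversals 0.
.indicatorMatrix <- function(pairs, x) {
  i1 <- match(pairs$gene1, rownames(x))
  i2 <- match(pairs$gene2, rownames(x))
  absent <- unique(c(pairs$gene1[is.na(i1)], pairs$gene2[is.na(i2)]))
  if (length(absent))
    stop("gene(s) absent from the expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  v <- (x[i1, , drop = FALSE] < x[i2, , drop = FALSE]) * 1
  dimnames(v) <- list(paste(pairs$gene1, pairs$gene2, sep = "|"), colnames(x))
  v
}

#' Build the gene-pair indicator matrix
#'
#' One binary feature per unordered combination of the candidate genes,
#' oriented with G1 = the lexicographically smaller identifier: the feature
#' is 1 in a sample iff expression(G1) < expression(G2) there (ties give 0).
#' k candidate genes yield k(k-1)/2 pairs — 250 genes give 31,125.
#'
#' @param x complete genes x samples matrix.
#' @param genes candidate gene identifiers (all present in `x`).
#' @return a [PairFeatureMatrix-class].
#' @examples
#' m <- matrix(c(1, 5, 2, 4, 3, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
#' pairValues(buildPairMatrix(m, c("gA", "gB", "gC")))
#' @export
buildPairMatrix <- function(x, genes) {
  .assertExpression(x, complete = TRUE)
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in candidate list", call. = FALSE)
  absent <- setdiff(genes, rownames(x))
  if (length(absent))
    stop("gene(s) absent from the expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(genes) < 2L)
    stop("need at least two genes to form pairs", call. = FALSE)
  g <- .lexSort(genes)
  cmb <- utils::combn(length(g), 2L)
  pairs <- data.frame(gene1 = g[cmb[1L, ]], gene2 = g[cmb[2L, ]],
                      stringsAsFactors = FALSE)
  .PairFeatureMatrix(pairs, .indicatorMatrix(pairs, x))
}

#' Pair features for the published panel
#'
#' Indicator features for the six published pairs, using the panel's printed
#' orientation (gene1 as G1). All nine panel miRNAs must be present.
#'
#' @param x complete genes x samples matrix.
#' @param panel oriented pair table; defaults to [publishedPanel()].
#' @return a [PairFeatureMatrix-class] with one row per panel pair.
#' @export
computePublishedFeatures <- function(x, panel = publishedPanel()) {
  .assertExpression(x, complete = TRUE)
  stopifnot(all(c("gene1", "gene2") %in% names(panel)))
  .PairFeatureMatrix(panel[c("gene1", "gene2")],
                     .indicatorMatrix(panel, x))
}

#' Remove near-constant pair features
#'
#' Drops pairs whose majority value (0 or 1) occupies strictly more than
#' `maxFraction` of the *training* samples: such pairs carry almost no
#' discriminating information. All sample columns are retained in the
#' output; only rows are dropped.
#'
#' @param features a [PairFeatureMatrix-class].
#' @param trainingIds training sample identifiers (subset of the columns).
#' @param maxFraction majority-fraction cutoff (default 0.90; a pair at
#'   exactly 90% is kept).
#' @return the row-filtered [PairFeatureMatrix-class].
#' @export
filterNearConstant <- function(features, trainingIds, maxFraction = 0.90) {
  stopifnot(is(features, "PairFeatureMatrix"))
  if (length(trainingIds) == 0L)
    stop("empty training set", call. = FALSE)
  miss <- setdiff(trainingIds, sampleIds(features))
  if (length(miss))
    stop("training sample(s) absent from features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- features@values[, trainingIds, drop = FALSE]
  f1 <- rowMeans(v)
  keep <- pmax(f1, 1 - f1) <= maxFraction
  features[which(keep), ]
}

#' Per-pair two-sample t test
#'
#' Two-sample t test of each binary pair indicator between classes over the
#' training samples. For a 0/1 feature the `effect` (class mean difference)
#' is the difference in indicator frequency between sarcoma and healthy.
#'
#' @param features a [PairFeatureMatrix-class].
#' @param labels label table or named vector.
#' @param trainingIds training sample identifiers.
#' @param var.equal pooled-variance test instead of Welch.
#' @return data.frame as in [geneTTest()], `feature_id` = "G1|G2".
#' @export
pairTTest <- function(features, labels, trainingIds = sampleIds(features),
                      var.equal = FALSE) {
  stopifnot(is(features, "PairFeatureMatrix"))
  miss <- setdiff(trainingIds, sampleIds(features))
  if (length(miss))
    stop("training sample(s) absent from features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- features@values[, trainingIds, drop = FALSE]
  grp <- .normalizeLabels(labels, trainingIds)
  .rowTTest(v, grp, var.equal = var.equal)
}

#' Select candidate pairs
#'
#' Screens pair features on the training samples: among pairs with
#' `p_value < alpha`, keeps the `topN` by absolute indicator-frequency
#' difference (same tie rule as the gene screen). All sample columns are
#' retained.
#'
#' @param features a (near-constant-filtered) [PairFeatureMatrix-class].
#' @param labels label table or named vector.
#' @param trainingIds training sample identifiers.
#' @param alpha significance level (default 0.05).
#' @param topN cap (default 80, the pair-screen cap).
#' @param var.equal pooled-variance test instead of Welch.
#' @return the row-subset [PairFeatureMatrix-class], rows in rank order.
#' @export
selectCandidatePairs <- function(features, labels,
                                 trainingIds = sampleIds(features),
                                 alpha = 0.05, topN = 80,
                                 var.equal = FALSE) {
  stats <- pairTTest(features, labels, trainingIds, var.equal = var.equal)
  features[.selectTop(stats, alpha, topN), ]
}
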