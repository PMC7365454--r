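# Imputation, abundance filtering, stratified splitting.

# Pairwise gene distances: root-mean-square difference over samples where
# both genes are observed (Euclidean scaled by the shared-sample count).
# Inf where two genes share no observed sample.
.geneDistances <- function(x) {
  O <- !is.na(x)
  X0 <- x
  X0[!O] <- 0
  shared <- tcrossprod(O * 1)
  cross <- tcrossprod(X0)
  sq <- tcrossprod(X0^2, O * 1)
  d2 <- sq + t(sq) - 2 * cross
  d2[d2 < 0] <- 0                      # numeric noise
  d <- sqrt(d2 / shared)
  d[shared == 0] <- Inf
  diag(d) <- Inf
  d
}

#' K-nearest-neighbour expression imputation
#'
#' Fills each missing cell (g, s) with the unweighted mean, at sample s, of
#' the k genes nearest to g. Gene-gene distance is the root-mean-square
#' expression difference over the samples where both genes are observed
#' (Euclidean distance rescaled by the number of shared samples); neighbours
#' missing at s are skipped. Observed cells are never altered, so imputing a
#' complete matrix is the identity. If all k neighbours are missing at s the
#' gene's own observed mean is used as a last resort.
#'
#' @param x genes x samples log2 expression matrix, `NA` for missing.
#' @param k neighbour count (default 10, the conventional expression-
#'   imputation default).
#' @return the completed matrix (no `NA`s).
#' @examples
#' m <- matrix(c(1, 2, 3, 1, NA, 3, 5, 6, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
#' knnImpute(m, k = 1)
#' @export
knnImpute <- function(x, k = 10) {
  .assertExpression(x)
  if (k < 1 || k != floor(k)) stop("k must be a positive integer",
                                   call. = FALSE)
  if (!anyNA(x)) return(x)
  nObs <- rowSums(!is.na(x))
  if (any(nObs == 0L))
    stop("gene(s) with no observed value: ",
         paste(rownames(x)[nObs == 0L], collapse = ", "), call. = FALSE)
  if (nrow(x) < k + 1L)
    stop("k = ", k, " exceeds the available neighbour pool (",
         nrow(x) - 1L, " genes)", call. = FALSE)
  d <- .geneDistances(x)
  out <- x
  for (g in which(rowSums(is.na(x)) > 0L)) {
    dg <- d[g, ]
    pool <- which(is.finite(dg))
    if (length(pool) < k)
      stop("k = ", k, " exceeds the neighbour pool of gene '",
           rownames(x)[g], "' (", length(pool), " comparable genes)",
           call. = FALSE)
    nb <- pool[order(dg[pool], rownames(x)[pool], method = "radix")][seq_len(k)]
    for (s in which(is.na(x[g, ]))) {
      vals <- x[nb, s]
      vals <- vals[!is.na(vals)]
      out[g, s] <- if (length(vals)) mean(vals) else
        mean(x[g, ], na.rm = TRUE)
    }
  }
  out
}

#' Filter to abundant miRNAs
#'
#' Keeps the genes whose log2 intensity is strictly above `threshold` in at
#' least `minFraction` of samples (the "expression higher than 8 in half of
#' the samples" rule: strict on the intensity, inclusive on the fraction).
#' Requires a complete (imputed) matrix; sample set and gene order are
#' preserved.
#'
#' @param x complete genes x samples matrix.
#' @param threshold log2 abundance threshold (default 8).
#' @param minFraction minimum fraction of samples above threshold
#'   (default 0.5).
#' @return the row-subset matrix.
#' @export
filterAbundant <- function(x, threshold = 8, minFraction = 0.5) {
  .assertExpression(x, complete = TRUE)
  keep <- rowMeans(x > threshold) >= minFraction
  x[keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Within each class, assigns `round-half-up(n_class * trainFraction)`
#' samples to training uniformly at random and the rest to test. With the
#' default 3:1 ratio this reproduces the 402 sarcoma + 275 healthy cohort's
#' partition into 508 training and 169 test samples. Deterministic under a
#' fixed seed.
#'
#' @param labels label table (data.frame `sample_id`, `label`) or named
#'   vector.
#' @param trainFraction per-class training proportion in (0, 1); default
#'   0.75.
#' @param seed integer seed.
#' @return a [SplitAssignment-class].
#' @examples
#' lab <- data.frame(sample_id = sprintf("s%03d", 1:677),
#'                   label = rep(c("sarcoma", "healthy"), c(402, 275)))
#' sp <- stratifiedSplit(lab, seed = 1)
#' length(trainIds(sp)); length(testIds(sp))
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.75, seed = 1) {
  lab <- .normalizeLabels(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1 ",
         "(both partitions must be non-empty)", call. = FALSE)
  counts <- table(lab)
  if (any(counts < 2L))
    stop("each class needs at least 2 samples; got ",
         paste(names(counts), counts, sep = " = ", collapse = ", "),
         call. = FALSE)
  .withSeed(seed, {
    train <- character(0)
    for (cl in levels(lab)) {
      ids <- names(lab)[lab == cl]
      nTrain <- .halfUp(length(ids) * trainFraction)
      if (nTrain == 0L || nTrain == length(ids))
        stop("trainFraction = ", trainFraction, " empties a partition for ",
             "class '", cl, "'", call. = FALSE)
      train <- c(train, sample(ids, nTrain))
    }
    new("SplitAssignment",
        trainIds = names(lab)[names(lab) %in% train],
        testIds = setdiff(names(lab), train),
        trainFraction = trainFraction, seed = seed)
  })
}
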