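# Fixtures built in code: tiny matrices, label tables, toy models.

toyExpression <- function(nGenes = 6, nSamples = 4, seed = 1,
                          missingCells = 0) {
  set.seed(seed)
  x <- matrix(round(runif(nGenes * nSamples, 5, 13), 4), nGenes, nSamples,
              dimnames = list(sprintf("miR-%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  if (missingCells > 0)
    x[sample(length(x), missingCells)] <- NA
  x
}

toyLabels <- function(nHealthy, nSarcoma, prefix = "s") {
  n <- nHealthy + nSarcoma
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             label = rep(c("healthy", "sarcoma"), c(nHealthy, nSarcoma)),
             stringsAsFactors = FALSE)
}

# labels aligned with a matrix's colnames
labelsFor <- function(x, labels) {
  stopifnot(ncol(x) == nrow(labels))
  labels$sample_id <- colnames(x)
  labels
}

randomConfusion <- function() {
  new("ConfusionCounts", tp = sample(0:30, 1), fp = sample(0:30, 1),
      tn = sample(0:30, 1), fn = sample(0:30, 1),
      positiveClass = sample(c("healthy", "sarcoma"), 1))
}

# hand-built ensemble over named features with given coefficient vectors
handModel <- function(bagCoefs, featureIds, voteThreshold = 0.5) {
  bags <- lapply(seq_along(bagCoefs), function(i) {
    cf <- bagCoefs[[i]]
    list(bagIndex = i, bagSeed = i, inBag = character(0),
         oobIds = character(0),
         candidateFeatures = featureIds,
         selectedFeatures = setdiff(names(cf), "(Intercept)"),
         coefficients = cf, separation = FALSE)
  })
  occ <- setNames(numeric(length(featureIds)), featureIds)
  for (b in bags) occ[b$selectedFeatures] <- occ[b$selectedFeatures] + 1
  new("RGLMModel",
      config = rglmConfig(nBags = length(bags),
                          voteThreshold = voteThreshold),
      bags = bags, occurrence = occ, oobAccuracy = NA_real_,
      featureIds = featureIds, classLevels = c("healthy", "sarcoma"))
}

# a small fitted ensemble for serialization / prediction tests
smallFittedModel <- function(seed = 7) {
  set.seed(seed)
  v <- matrix(rbinom(5 * 60, 1, 0.5), 5, 60,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:60)))
  lab <- setNames(ifelse(v[1, ] == 1, "sarcoma", "healthy"), colnames(v))
  lab[1:6] <- rev(lab[1:6])   # imperfect signal
  list(features = v, labels = lab,
       model = fitRGLM(v, lab, rglmConfig(nBags = 5, featuresPerBag = 1,
                                          corrKeep = 5, seed = seed)))
}

# strictly increasing random scalar transform on the whole real line
randomIncreasingTransform <- function() {
  a <- runif(1, 0.2, 3)
  b <- runif(1, 0, 5)
  m <- runif(1, 4, 14)
  s <- runif(1, 1, 4)
  off <- runif(1, -3, 3)
  function(v) a * v + b * pnorm((v - m) / s) + off
}
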