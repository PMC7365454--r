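# Independent brute-force oracles shared across test files.

# KNN imputation oracle: double loop over genes and samples, RMS distance
# over shared observed samples, unweighted k-mean skipping absent neighbours.
bruteKnnImpute <- function(x, k) {
  out <- x
  for (g in seq_len(nrow(x))) {
    missing <- which(is.na(x[g, ]))
    if (!length(missing)) next
    d <- rep(Inf, nrow(x))
    for (h in seq_len(nrow(x))) {
      if (h == g) next
      shared <- which(!is.na(x[g, ]) & !is.na(x[h, ]))
      if (length(shared))
        d[h] <- sqrt(sum((x[g, shared] - x[h, shared])^2) / length(shared))
    }
    nb <- order(d, rownames(x), method = "radix")[seq_len(k)]
    for (s in missing) {
      v <- x[nb, s]
      v <- v[!is.na(v)]
      out[g, s] <- if (length(v)) mean(v) else mean(x[g, ], na.rm = TRUE)
    }
  }
  out
}

# Exhaustive forward-stepwise logistic oracle over a small feature set: at
# each step fit every candidate addition with glm() and take the best AIC,
# stopping when no addition improves it.
bruteForwardStep <- function(X, y, maxTerms = ncol(X)) {
  selected <- character(0)
  repeat {
    cur <- if (length(selected))
      glm(reformulate(sprintf("`%s`", selected), response = "y"),
          family = binomial(), data = data.frame(y = y, X, check.names = FALSE))
    else glm(y ~ 1, family = binomial(), data = data.frame(y = y))
    rest <- setdiff(colnames(X), selected)
    if (!length(rest) || length(selected) >= maxTerms) return(cur)
    aics <- vapply(rest, function(f) {
      AIC(glm(reformulate(sprintf("`%s`", c(selected, f)), response = "y"),
              family = binomial(),
              data = data.frame(y = y, X, check.names = FALSE)))
    }, numeric(1))
    if (min(aics) >= AIC(cur)) return(cur)
    selected <- c(selected, rest[which.min(aics)])
  }
}

# Two informative binary features with known structure for stepwise tests.
twoFeatureProblem <- function(seed) {
  set.seed(seed)
  n <- 120
  y <- rep(0:1, each = n / 2)
  f1 <- ifelse(runif(n) < 0.78, y, 1 - y)       # strong, imperfect
  f2 <- ifelse(runif(n) < 0.68, y, 1 - y)       # weaker
  v <- rbind(pairA = f1, pairB = f2)
  colnames(v) <- paste0("s", seq_len(n))
  lab <- setNames(ifelse(y == 1, "sarcoma", "healthy"), colnames(v))
  list(v = v, y = y, lab = lab)
}
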