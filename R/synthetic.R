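# Synthetic serum-miRNA cohort generator: the statistical structure the
# pipeline assumes, with analytic handles for testing (planted rank-flipping
# pairs, known differential genes, controlled missingness).

#' Configure a synthetic cohort
#'
#' Builds a validated [SyntheticConfig-class]. Defaults describe the
#' package's standard strong-signal validation cohort: 150 samples per class,
#' 300 miRNAs of which 150 are abundant, 30 differential miRNAs shifted by
#' 1.5 log2 units, 10 planted pairs whose within-sample order holds with
#' probability 0.95 in each class (and points the opposite way in the other
#' class), per-gene noise SD of 1 log2 unit and 2% missing cells.
#'
#' @param nHealthy,nSarcoma samples per class.
#' @param nGenes,nAbundant,nDifferential,nPlantedPairs gene strata sizes;
#'   planted pairs consume `2 * nPlantedPairs` dedicated abundant,
#'   non-differential genes.
#' @param effectSize class mean shift (log2 units) of differential genes.
#' @param noiseSd within-class SD (log2 units).
#' @param flipProb orientation probability of planted pairs, in (0.5, 1].
#' @param missingRate per-cell missingness probability, in [0, 1).
#' @param seed integer seed.
#' @return a [SyntheticConfig-class].
#' @seealso [generateCohort()]
#' @export
syntheticConfig <- function(nHealthy = 150, nSarcoma = 150, nGenes = 300,
                            nAbundant = 150, nDifferential = 30,
                            effectSize = 1.5, noiseSd = 1,
                            nPlantedPairs = 10, flipProb = 0.95,
                            missingRate = 0.02, seed = 1) {
  new("SyntheticConfig", nHealthy = nHealthy, nSarcoma = nSarcoma,
      nGenes = nGenes, nAbundant = nAbundant, nDifferential = nDifferential,
      effectSize = effectSize, noiseSd = noiseSd,
      nPlantedPairs = nPlantedPairs, flipProb = flipProb,
      missingRate = missingRate, seed = seed)
}

#' Generate a synthetic serum-miRNA cohort
#'
#' Draws a log2 genes x samples intensity matrix with the structure the
#' pipeline screens for:
#'
#' * an abundant stratum (genes 1..nAbundant) with per-gene means drawn
#'   above the log2 abundance threshold of 8 (uniform on 9.5--13), the rest
#'   drawn on 5--7 so they fail the abundance filter;
#' * `nDifferential` abundant genes whose sarcoma mean is shifted upward by
#'   `effectSize`;
#' * `nPlantedPairs` disjoint pairs (A, B) of abundant genes sharing a
#'   per-sample latent level (base mean on 10.5--12.5 plus a common
#'   `N(0, (3*noiseSd)^2)` sample effect, emulating per-sample intensity
#'   variation), displaced by a latent offset
#'   `delta = sqrt(2) * noiseSd * qnorm(flipProb)` so that, with Gaussian
#'   noise, `P(A < B) = flipProb` within healthy samples and
#'   `P(B < A) = flipProb` within sarcoma samples — the rank order flips
#'   between classes with a directly controlled probability, while the
#'   shared level keeps the signal in the pair itself rather than in the
#'   individual members;
#' * independent Gaussian noise (`noiseSd`) and completely-at-random missing
#'   cells at `missingRate`, never leaving a gene fully missing.
#'
#' Identical config (including seed) gives a bit-identical cohort.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `expression` (matrix with `NA`s), `labels`
#'   (data.frame `sample_id`, `label`), and `truth` (list: `differentialGenes`,
#'   `plantedPairs` — a data.frame of oriented pairs with gene1 < gene2 in
#'   healthy samples — and `delta`, the latent offset used).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nHealthy = 20, nSarcoma = 20,
#'   nGenes = 40, nAbundant = 30, nDifferential = 5, nPlantedPairs = 3,
#'   seed = 7))
#' dim(cohort$expression)
#' cohort$truth$plantedPairs
#' @export
generateCohort <- function(config) {
  validObject(config)
  nH <- as.integer(config@nHealthy)
  nS <- as.integer(config@nSarcoma)
  nG <- as.integer(config@nGenes)
  nA <- as.integer(config@nAbundant)
  nD <- as.integer(config@nDifferential)
  nP <- as.integer(config@nPlantedPairs)
  n <- nH + nS
  if (n < 1L || nG < 1L)
    stop("cohort must have at least one sample and one gene", call. = FALSE)
  genes <- sprintf("syn-miR-%04d", seq_len(nG))
  samples <- c(sprintf("healthy-%03d", seq_len(nH)),
               sprintf("sarcoma-%03d", seq_len(nS)))
  isSarcoma <- rep(c(FALSE, TRUE), c(nH, nS))

  .withSeed(config@seed, {
    mu <- numeric(nG)
    if (nA > 0L) mu[seq_len(nA)] <- stats::runif(nA, 9.5, 13)
    if (nA < nG) mu[(nA + 1L):nG] <- stats::runif(nG - nA, 5, 7)

    diffGenes <- if (nD > 0L) genes[seq_len(nD)] else character(0)

    # planted pairs occupy dedicated abundant genes after the differential ones
    plantIdx <- if (nP > 0L) nD + seq_len(2L * nP) else integer(0)
    delta <- sqrt(2) * config@noiseSd * stats::qnorm(config@flipProb)
    planted <- data.frame(gene1 = character(0), gene2 = character(0),
                          stringsAsFactors = FALSE)
    # mean matrix: gene x sample
    M <- matrix(mu, nrow = nG, ncol = n)
    if (nD > 0L)
      M[seq_len(nD), isSarcoma] <- M[seq_len(nD), isSarcoma] + config@effectSize
    if (nP > 0L) {
      base <- stats::runif(nP, 10.5, 12.5)
      for (p in seq_len(nP)) {
        a <- plantIdx[2L * p - 1L]; b <- plantIdx[2L * p]
        # shared per-sample level: cancels inside the pair (the flip
        # probability stays exactly Phi(delta / (sd*sqrt(2)))) but spreads
        # comparisons of these genes against anything else, so planted
        # pairs are informative as pairs, not through their members
        lvl <- base[p] + stats::rnorm(n, sd = 3 * config@noiseSd)
        # healthy: A sits delta below B; sarcoma: the order flips
        M[a, ] <- lvl + ifelse(isSarcoma, +delta / 2, -delta / 2)
        M[b, ] <- lvl + ifelse(isSarcoma, -delta / 2, +delta / 2)
      }
      planted <- data.frame(gene1 = genes[plantIdx[seq(1L, 2L * nP, 2L)]],
                            gene2 = genes[plantIdx[seq(2L, 2L * nP, 2L)]],
                            stringsAsFactors = FALSE)
    }

    x <- M + matrix(stats::rnorm(nG * n, sd = config@noiseSd), nrow = nG)
    dimnames(x) <- list(genes, samples)

    if (config@missingRate > 0) {
      mask <- matrix(stats::runif(nG * n) < config@missingRate, nrow = nG)
      allGone <- rowSums(!mask) == 0L
      for (g in which(allGone)) mask[g, sample.int(n, 1L)] <- FALSE
      x[mask] <- NA_real_
    }

    list(expression = x,
         labels = data.frame(sample_id = samples,
                             label = ifelse(isSarcoma, "sarcoma", "healthy"),
                             stringsAsFactors = FALSE),
         truth = list(differentialGenes = diffGenes,
                      plantedPairs = planted,
                      delta = delta))
  })
}

#' Apply a strictly increasing per-sample intensity distortion
#'
#' Emulates cross-platform / batch intensity shifts: applies a strictly
#' increasing scalar transform cell-wise to the selected samples, leaving
#' missingness untouched. Since pair features depend only on within-sample
#' orderings, any such distortion leaves the downstream pair-feature matrix
#' (computed on complete data) unchanged — the rank-robustness rationale of
#' the pair representation. Monotonicity is verified on a dense grid spanning
#' the selected samples' observed range; a non-increasing transform is
#' rejected.
#'
#' @param x genes x samples expression matrix (may contain `NA`).
#' @param transform strictly increasing scalar function (vectorised over a
#'   numeric vector).
#' @param samples sample identifiers to distort (default: all).
#' @param gridSize grid points used for the monotonicity check.
#' @return distorted copy of `x`.
#' @examples
#' m <- matrix(1:6 + 0, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' applyMonotoneDistortion(m, function(v) 2 * v + 3)
#' @export
applyMonotoneDistortion <- function(x, transform, samples = colnames(x),
                                    gridSize = 257L) {
  .assertExpression(x)
  miss <- setdiff(samples, colnames(x))
  if (length(miss))
    stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sub <- x[, samples, drop = FALSE]
  rng <- range(sub, na.rm = TRUE)
  if (!all(is.finite(rng)))
    stop("selected samples hold no observed values", call. = FALSE)
  grid <- seq(rng[1L], rng[2L], length.out = gridSize)
  tg <- transform(grid)
  if (length(tg) != gridSize || any(!is.finite(tg)) || any(diff(tg) <= 0))
    stop("transform is not strictly increasing on the data's range",
         call. = FALSE)
  out <- x
  obs <- !is.na(sub)
  sub[obs] <- transform(sub[obs])
  out[, samples] <- sub
  out
}
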