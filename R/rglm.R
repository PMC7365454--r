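# Random generalized linear model ensemble: bagged forward-selected logistic
# GLMs over binary pair features, majority-vote prediction, out-of-bag
# accuracy and occurrence-based thinning. The ensemble logic is authored
# here; each member GLM is an ordinary stats::glm / stats::step fit.

#' RGLM hyperparameters
#'
#' @param nBags ensemble size (default 100).
#' @param featuresPerBag fraction of candidate features sampled (without
#'   replacement) into each bag, in (0, 1]; default 0.5.
#' @param corrKeep maximum features surviving the per-bag correlation
#'   filter; default 20.
#' @param corrAlpha significance level of the point-biserial correlation
#'   filter; default 0.05.
#' @param maxTerms maximum covariates the forward AIC search may admit;
#'   default 10.
#' @param voteThreshold vote fraction above which the ensemble calls
#'   sarcoma (a tied vote also calls sarcoma — the screening context favours
#'   sensitivity); default 0.5.
#' @param bootstrap bootstrap the in-bag samples (size n, with replacement).
#'   Disabling it (a testing hook) makes every bag see all samples and
#'   leaves no out-of-bag pool, so `oobAccuracy` becomes `NA`.
#' @param seed integer seed for the per-bag randomness stream.
#' @return validated hyperparameter list.
#' @seealso [fitRGLM()]
#' @export
rglmConfig <- function(nBags = 100, featuresPerBag = 0.5, corrKeep = 20,
                       corrAlpha = 0.05, maxTerms = 10, voteThreshold = 0.5,
                       bootstrap = TRUE, seed = 1) {
  stopifnot(nBags >= 1, nBags == floor(nBags),
            featuresPerBag > 0, featuresPerBag <= 1,
            corrKeep >= 1, corrAlpha > 0, corrAlpha < 1,
            maxTerms >= 1, voteThreshold > 0, voteThreshold < 1,
            is.logical(bootstrap))
  list(nBags = as.integer(nBags), featuresPerBag = featuresPerBag,
       corrKeep = as.integer(corrKeep), corrAlpha = corrAlpha,
       maxTerms = as.integer(maxTerms), voteThreshold = voteThreshold,
       bootstrap = isTRUE(bootstrap), seed = as.integer(seed))
}

.featureValues <- function(features) {
  if (is(features, "PairFeatureMatrix")) return(features@values)
  if (is.matrix(features) && is.numeric(features)) {
    if (is.null(rownames(features)) || is.null(colnames(features)))
      stop("feature matrix must carry feature rownames and sample colnames",
           call. = FALSE)
    return(features)
  }
  stop("features must be a PairFeatureMatrix or a features x samples matrix",
       call. = FALSE)
}

# Penalized logistic fit by IRLS (ridge on slopes, not the intercept);
# stabilizes bags whose selected features separate the classes completely.
.ridgeLogit <- function(X, y, lambda = 1, maxit = 100, tol = 1e-9) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    bNew <- drop(solve(crossprod(X1, X1 * w) + pen, crossprod(X1, w * z)))
    done <- max(abs(bNew - beta)) < tol
    beta <- bNew
    if (done) break
  }
  beta
}

# Deterministic per-bag fit given the bootstrap ids and candidate features:
# point-biserial correlation filter, then forward AIC logistic search.
.fitBagCore <- function(Fv, lab, inBagIds, candidate, config) {
  y <- as.integer(lab[inBagIds] == "sarcoma")
  interceptOnly <- function(separation = FALSE) {
    p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    list(selectedFeatures = character(0),
         coefficients = c("(Intercept)" = stats::qlogis(p0)),
         separation = separation)
  }
  if (stats::sd(y) == 0) return(interceptOnly())
  X <- t(Fv[candidate, inBagIds, drop = FALSE])
  ps <- vapply(seq_along(candidate), function(j) {
    xv <- X[, j]
    if (stats::sd(xv) == 0) return(NA_real_)
    stats::cor.test(xv, y)$p.value
  }, numeric(1))
  ok <- which(!is.na(ps) & ps < config$corrAlpha)
  if (length(ok) == 0L) return(interceptOnly())
  ord <- ok[order(ps[ok], candidate[ok], method = "radix")]
  keep <- candidate[utils::head(ord, config$corrKeep)]

  safe <- paste0("f", seq_along(keep))
  dat <- data.frame(y = y, X[, match(keep, candidate), drop = FALSE])
  names(dat) <- c("y", safe)
  fit0 <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  fit <- suppressWarnings(stats::step(
    fit0, scope = list(lower = ~1, upper = stats::reformulate(safe)),
    direction = "forward", steps = config$maxTerms, trace = 0))
  cf <- stats::coef(fit)
  selSafe <- setdiff(names(cf), "(Intercept)")
  selected <- keep[match(selSafe, safe)]
  coefs <- stats::setNames(as.numeric(cf), c("(Intercept)", selected))
  separation <- any(!is.finite(coefs)) || max(abs(coefs)) > 15
  if (separation && length(selected)) {
    Xs <- as.matrix(dat[selSafe])
    coefs <- stats::setNames(.ridgeLogit(Xs, y), c("(Intercept)", selected))
  }
  if (length(selected) == 0L) return(interceptOnly(separation))
  list(selectedFeatures = selected, coefficients = coefs,
       separation = separation)
}

#' Fit one bag of the ensemble
#'
#' Draws a bootstrap of the samples and a random feature subset, filters the
#' candidates by a two-sided point-biserial correlation test against the
#' class label on the in-bag samples (keeping the `corrKeep` smallest
#' p values below `corrAlpha`), then grows a logistic GLM by forward AIC
#' search from the intercept-only model, stopping when no term improves the
#' AIC or `maxTerms` is reached. Bags whose fit separates completely are
#' refit with a ridge penalty on the slopes and flagged.
#'
#' @param features [PairFeatureMatrix-class] or features x samples matrix
#'   (training samples).
#' @param labels label table or named vector.
#' @param config hyperparameters from [rglmConfig()].
#' @param bagIndex index of this bag in the ensemble.
#' @param bagSeed integer seed for this bag's draws.
#' @return list: `bagIndex`, `bagSeed`, `inBag` (bootstrap sample ids, with
#'   multiplicity), `oobIds`, `candidateFeatures`, `selectedFeatures`,
#'   `coefficients` (log-odds scale, sarcoma positive), `separation`.
#' @seealso [fitRGLM()]
#' @export
fitBag <- function(features, labels, config = rglmConfig(), bagIndex = 1L,
                   bagSeed = config$seed) {
  Fv <- .featureValues(features)
  lab <- .normalizeLabels(labels, colnames(Fv))
  ids <- colnames(Fv)
  featIds <- rownames(Fv)
  .withSeed(bagSeed, {
    inBag <- if (config$bootstrap)
      sample(ids, length(ids), replace = TRUE) else ids
    m <- max(1L, ceiling(config$featuresPerBag * length(featIds)))
    candidate <- if (m >= length(featIds)) .lexSort(featIds) else
      .lexSort(sample(featIds, m))
    core <- .fitBagCore(Fv, lab, inBag, candidate, config)
    c(list(bagIndex = as.integer(bagIndex), bagSeed = as.integer(bagSeed),
           inBag = inBag, oobIds = setdiff(ids, inBag),
           candidateFeatures = candidate),
      core)
  })
}

# Vote matrix: samples x bags, 1 = sarcoma vote (per-bag GLM probability
# above 1/2, i.e. positive log-odds).
.bagVotes <- function(bags, Fv) {
  n <- ncol(Fv)
  votes <- matrix(NA_integer_, n, length(bags),
                  dimnames = list(colnames(Fv), NULL))
  for (b in seq_along(bags)) {
    cf <- bags[[b]]$coefficients
    sel <- bags[[b]]$selectedFeatures
    eta <- rep.int(cf[["(Intercept)"]], n)
    if (length(sel))
      eta <- eta + drop(crossprod(Fv[sel, , drop = FALSE], cf[sel]))
    votes[, b] <- as.integer(eta > 0)
  }
  votes
}

.oobStats <- function(bags, Fv, lab, voteThreshold) {
  votes <- .bagVotes(bags, Fv)
  oobMask <- vapply(bags, function(b) colnames(Fv) %in% b$oobIds,
                    logical(ncol(Fv)))
  den <- rowSums(oobMask)
  if (all(den == 0)) return(NA_real_)
  num <- rowSums(votes * oobMask)
  vf <- num[den > 0] / den[den > 0]
  pred <- ifelse(vf >= voteThreshold, "sarcoma", "healthy")
  mean(pred == as.character(lab)[den > 0])
}

#' Fit the RGLM ensemble
#'
#' Fits `nBags` independent bags (see [fitBag()]) from a seeded stream,
#' aggregates per-feature occurrence counts (the number of final GLMs each
#' feature enters), and estimates out-of-bag accuracy: each training sample
#' is classified by majority vote over only the bags that held it out.
#' A bag that fails to fit is dropped with a warning; the fit aborts only if
#' every bag fails. Identical inputs and seed give a bit-identical model.
#'
#' @param features [PairFeatureMatrix-class] or features x samples matrix of
#'   the training samples.
#' @param labels label table or named vector.
#' @param config hyperparameters from [rglmConfig()].
#' @return an [RGLMModel-class].
#' @examples
#' set.seed(1)
#' v <- matrix(rbinom(300, 1, 0.5), 3, 100,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:100)))
#' lab <- setNames(ifelse(v[1, ] == 1, "sarcoma", "healthy"), colnames(v))
#' m <- fitRGLM(v, lab, rglmConfig(nBags = 5, featuresPerBag = 1, seed = 2))
#' occurrence(m)
#' @export
fitRGLM <- function(features, labels, config = rglmConfig()) {
  Fv <- .featureValues(features)
  lab <- .normalizeLabels(labels, colnames(Fv))
  if (any(table(lab) < 2L))
    stop("need at least 2 training samples per class", call. = FALSE)
  bagSeeds <- .withSeed(config$seed,
                        sample.int(.Machine$integer.max, config$nBags))
  bags <- vector("list", config$nBags)
  failed <- character(0)
  for (b in seq_len(config$nBags)) {
    bags[[b]] <- tryCatch(
      fitBag(Fv, lab, config, bagIndex = b, bagSeed = bagSeeds[b]),
      error = function(e) {
        failed <<- c(failed, paste0("bag ", b, ": ", conditionMessage(e)))
        NULL
      })
  }
  bags <- bags[!vapply(bags, is.null, logical(1))]
  if (length(failed))
    warning(length(failed), " bag(s) failed to fit: ",
            paste(utils::head(failed, 3L), collapse = "; "), call. = FALSE)
  if (length(bags) == 0L)
    stop("all bags failed to fit", call. = FALSE)
  occ <- stats::setNames(numeric(length(rownames(Fv))), rownames(Fv))
  for (bag in bags)
    occ[bag$selectedFeatures] <- occ[bag$selectedFeatures] + 1
  new("RGLMModel", config = config, bags = bags, occurrence = occ,
      oobAccuracy = .oobStats(bags, Fv, lab, config$voteThreshold),
      featureIds = rownames(Fv), classLevels = .CLASSES)
}

.requiredFeatures <- function(model) {
  unique(unlist(lapply(model@bags, `[[`, "selectedFeatures")))
}

#' Predict with an RGLM ensemble
#'
#' Each bag votes sarcoma iff its GLM probability exceeds 1/2; the vote
#' fraction is the share of sarcoma votes over all voting bags, and the
#' label is sarcoma iff the fraction reaches `voteThreshold` (a tie votes
#' sarcoma).
#'
#' @param object an [RGLMModel-class] or [ThinnedRGLM-class].
#' @param features [PairFeatureMatrix-class] or features x samples matrix
#'   containing every feature the model references.
#' @param ... ignored.
#' @return data.frame: `sample_id`, `vote_fraction`, `label`.
#' @export
setMethod("predict", "RGLMModel", function(object, features, ...) {
  Fv <- .featureValues(features)
  need <- .requiredFeatures(object)
  absent <- setdiff(need, rownames(Fv))
  if (length(absent))
    stop("feature(s) referenced by the model are absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  votes <- .bagVotes(object@bags, Fv)
  vf <- unname(rowMeans(votes))
  data.frame(sample_id = colnames(Fv), vote_fraction = vf,
             label = ifelse(vf >= object@config$voteThreshold,
                            "sarcoma", "healthy"),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Thin an RGLM ensemble by feature occurrence
#'
#' Candidate cutoffs are the distinct nonzero occurrence counts, largest
#' first (smallest feature set first). For each cutoff the ensemble is refit
#' restricted to the features occurring at least that often — identical bag
#' structure (same bootstrap draws, same candidate subsets intersected with
#' the retained set), so no new randomness — and its out-of-bag accuracy is
#' recorded. The first (smallest) feature set whose out-of-bag accuracy is
#' within `tolerance` of the full model's is returned; if none qualifies the
#' best-scoring cutoff is returned with a warning.
#'
#' @param model a fitted [RGLMModel-class].
#' @param features,labels the training data the model was fitted on.
#' @param tolerance maximum acceptable out-of-bag accuracy drop; default
#'   0.01 (one misclassification per 100 training samples).
#' @return a [ThinnedRGLM-class]; its `thinTrace` records every cutoff
#'   tried.
#' @seealso [fitRGLM()]
#' @export
thinRGLM <- function(model, features, labels, tolerance = 0.01) {
  stopifnot(is(model, "RGLMModel"))
  Fv <- .featureValues(features)
  lab <- .normalizeLabels(labels, colnames(Fv))
  occ <- model@occurrence
  cutoffs <- sort(unique(occ[occ > 0]), decreasing = TRUE)
  if (length(cutoffs) == 0L)
    stop("model selected no features; nothing to thin", call. = FALSE)
  refOob <- model@oobAccuracy
  if (is.na(refOob))
    stop("model has no out-of-bag accuracy (bootstrap disabled); ",
         "thinning needs an OOB reference", call. = FALSE)
  trace <- data.frame(cutoff = numeric(0), nFeatures = integer(0),
                      oobAccuracy = numeric(0), accepted = logical(0))
  best <- NULL
  for (cut in cutoffs) {
    retained <- names(occ)[occ >= cut]
    bags2 <- lapply(model@bags, function(b) {
      cand <- intersect(b$candidateFeatures, retained)
      core <- .fitBagCore(Fv, lab, b$inBag, cand, model@config)
      c(b[c("bagIndex", "bagSeed", "inBag", "oobIds")],
        list(candidateFeatures = cand), core)
    })
    oob2 <- .oobStats(bags2, Fv, lab, model@config$voteThreshold)
    ok <- oob2 >= refOob - tolerance
    trace <- rbind(trace, data.frame(cutoff = cut,
                                     nFeatures = length(retained),
                                     oobAccuracy = oob2, accepted = ok))
    cand <- list(cutoff = cut, retained = retained, bags = bags2, oob = oob2)
    if (is.null(best) || oob2 > best$oob) best <- cand
    if (ok) { best <- cand; break }
  }
  if (!trace$accepted[nrow(trace)])
    warning("no occurrence cutoff kept out-of-bag accuracy within ",
            tolerance, " of the full model; returning the best cutoff (",
            best$cutoff, ")", call. = FALSE)
  occ2 <- stats::setNames(numeric(length(model@featureIds)), model@featureIds)
  for (bag in best$bags)
    occ2[bag$selectedFeatures] <- occ2[bag$selectedFeatures] + 1
  new("ThinnedRGLM", config = model@config, bags = best$bags,
      occurrence = occ2, oobAccuracy = best$oob,
      featureIds = model@featureIds, classLevels = .CLASSES,
      retainedFeatures = best$retained, occurrenceCutoff = best$cutoff,
      thinTrace = trace)
}
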