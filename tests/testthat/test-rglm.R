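test_that("a single full bag reproduces the exhaustive forward-stepwise fit", {
  for (seed in c(5, 19, 57)) {
    prob <- twoFeatureProblem(seed)
    cfg <- rglmConfig(nBags = 1, featuresPerBag = 1, bootstrap = FALSE,
                      corrKeep = 2, seed = seed)
    bag <- fitBag(prob$v, prob$lab, cfg)
    oracle <- bruteForwardStep(t(prob$v), prob$y)
    oSel <- gsub("`", "", setdiff(names(coef(oracle)), "(Intercept)"))
    # correlation pre-filter may exclude a feature the oracle saw; only
    # compare when both features reach the stepwise stage
    ps <- vapply(rownames(prob$v),
                 function(f) cor.test(prob$v[f, ], prob$y)$p.value, 0)
    if (all(ps < 0.05)) {
      expect_setequal(bag$selectedFeatures, oSel)
      expect_equal(sort(bag$coefficients),
                   sort(setNames(as.numeric(coef(oracle)),
                                 gsub("`", "", names(coef(oracle))))),
                   tolerance = 1e-8)
    }
  }
})

test_that("a perfect predictor is selected and flagged as separating", {
  set.seed(8)
  n <- 40
  y <- rep(c("healthy", "sarcoma"), each = n / 2)
  v <- rbind(perfect = as.numeric(y == "sarcoma"),
             noise = rbinom(n, 1, 0.5))
  colnames(v) <- paste0("s", 1:n)
  bag <- fitBag(v, setNames(y, colnames(v)),
                rglmConfig(nBags = 1, featuresPerBag = 1, bootstrap = FALSE))
  expect_true("perfect" %in% bag$selectedFeatures)
  expect_true(bag$separation)
  # the ridge-stabilised refit still classifies the training data perfectly
  expect_true(all(is.finite(bag$coefficients)))
  eta <- bag$coefficients[["(Intercept)"]] +
    bag$coefficients[["perfect"]] * v["perfect", ]
  expect_identical(unname(eta > 0), y == "sarcoma")
})

test_that("label-independent features leave bags mostly empty and OOB near chance", {
  set.seed(71)
  n <- 60
  v <- matrix(rbinom(32 * n, 1, 0.5), 32, n,
              dimnames = list(sprintf("p%02d", 1:32), paste0("s", 1:n)))
  lab <- setNames(rep(c("healthy", "sarcoma"), c(25, 35)), colnames(v))
  m <- fitRGLM(v, lab, rglmConfig(nBags = 30, featuresPerBag = 0.5,
                                  corrKeep = 16, seed = 2))
  nSel <- vapply(m@bags, function(b) length(b$selectedFeatures), integer(1))
  # null bags admit at most the handful of chance-correlated features the
  # finite dataset realizes; some stay intercept-only
  expect_gt(mean(nSel == 0L), 0)
  expect_lt(mean(nSel), 4)
  expect_lt(abs(oobAccuracy(m) - 35 / 60), 0.12)
})

test_that("an ensemble of one bag predicts exactly as its member GLM", {
  prob <- twoFeatureProblem(23)
  cfg <- rglmConfig(nBags = 1, featuresPerBag = 1, bootstrap = FALSE,
                    seed = 23)
  m <- fitRGLM(prob$v, prob$lab, cfg)
  expect_identical(length(m@bags), 1L)
  pred <- predict(m, prob$v)
  cf <- m@bags[[1]]$coefficients
  sel <- m@bags[[1]]$selectedFeatures
  probs <- plogis(cf[["(Intercept)"]] +
                  drop(crossprod(prob$v[sel, , drop = FALSE], cf[sel])))
  expect_identical(pred$vote_fraction, unname(as.numeric(probs > 0.5)))
  expect_identical(pred$label,
                   unname(ifelse(probs > 0.5, "sarcoma", "healthy")))
})

test_that("fitting is bit-identical under a fixed seed", {
  prob <- twoFeatureProblem(31)
  set.seed(99)
  v <- rbind(prob$v,
             matrix(rbinom(6 * ncol(prob$v), 1, 0.5), 6,
                    dimnames = list(paste0("d", 1:6), colnames(prob$v))))
  cfg <- rglmConfig(nBags = 8, featuresPerBag = 0.5, seed = 13)
  m1 <- fitRGLM(v, prob$lab, cfg)
  m2 <- fitRGLM(v, prob$lab, cfg)
  expect_identical(m1@bags, m2@bags)
  expect_identical(occurrence(m1), occurrence(m2))
  expect_identical(predict(m1, v), predict(m2, v))
})

test_that("votes follow per-bag logistic probabilities, ties call sarcoma", {
  feats <- c("pA|pB", "pC|pD")
  v <- rbind(c(1, 0, 1, 0), c(0, 0, 1, 1)) * 1
  dimnames(v) <- list(feats, paste0("s", 1:4))
  m <- handModel(list(
    c("(Intercept)" = -1, "pA|pB" = 2),            # sarcoma iff feature 1
    c("(Intercept)" = 1, "pC|pD" = -2),            # sarcoma iff NOT feature 2
    c("(Intercept)" = 0.5)),                       # always sarcoma
    featureIds = feats)
  pred <- predict(m, v)
  # hand-computed votes: s1 (1,1,1)=1; s2 (0,1,1)=2/3; s3 (1,0,1)=2/3;
  # s4 (0,0,1)=1/3
  expect_equal(pred$vote_fraction, c(1, 2 / 3, 2 / 3, 1 / 3))
  expect_identical(pred$label, c("sarcoma", "sarcoma", "sarcoma", "healthy"))

  tie <- handModel(list(c("(Intercept)" = 1), c("(Intercept)" = -1)),
                   featureIds = feats)
  predTie <- predict(tie, v)
  expect_true(all(predTie$vote_fraction == 0.5))
  expect_true(all(predTie$label == "sarcoma"))

  expect_error(predict(m, v[1, , drop = FALSE]), "pC\\|pD")
})

test_that("thinning keeps the dominant feature set and honours the tolerance", {
  set.seed(47)
  n <- 80
  y <- rep(c("healthy", "sarcoma"), each = n / 2)
  strong <- ifelse(runif(n) < 0.97, as.numeric(y == "sarcoma"),
                   1 - as.numeric(y == "sarcoma"))
  v <- rbind(strong = strong,
             matrix(rbinom(7 * n, 1, 0.5), 7,
                    dimnames = list(paste0("d", 1:7), NULL)))
  colnames(v) <- paste0("s", 1:n)
  lab <- setNames(y, colnames(v))
  m <- fitRGLM(v, lab, rglmConfig(nBags = 15, featuresPerBag = 1,
                                  corrKeep = 8, seed = 3))
  occ <- occurrence(m)
  expect_identical(unname(occ["strong"]), 15)

  th <- thinRGLM(m, v, lab)
  expect_true("strong" %in% retainedFeatures(th))
  expect_gte(oobAccuracy(th), oobAccuracy(m) - 0.01)
  expect_true(all(th@thinTrace$cutoff == sort(th@thinTrace$cutoff,
                                              decreasing = TRUE)))

  # infinite tolerance: the first cutoff (most frequent features only) wins
  thInf <- thinRGLM(m, v, lab, tolerance = Inf)
  expect_identical(thInf@occurrenceCutoff, max(occ))
  expect_identical(retainedFeatures(thInf),
                   names(occ)[occ == max(occ)])
  expect_identical(nrow(thInf@thinTrace), 1L)
})

test_that("ensemble predictions survive model thinning bookkeeping", {
  fit <- smallFittedModel(3)
  th <- tryCatch(thinRGLM(fit$model, fit$features, fit$labels,
                          tolerance = Inf),
                 error = function(e) NULL)
  if (!is.null(th)) {
    pred <- predict(th, fit$features)
    expect_identical(nrow(pred), ncol(fit$features))
    expect_true(all(pred$label %in% c("healthy", "sarcoma")))
    needed <- unique(unlist(lapply(th@bags, `[[`, "selectedFeatures")))
    expect_true(all(needed %in% retainedFeatures(th)))
  }
})
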