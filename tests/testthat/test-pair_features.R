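test_that("gene t statistics match stats::t.test", {
  set.seed(41)
  for (sizes in list(c(3, 3), c(8, 5))) {
    x <- matrix(rnorm(5 * sum(sizes), 9), 5,
                dimnames = list(paste0("g", 1:5),
                                paste0("s", seq_len(sum(sizes)))))
    lab <- labelsFor(x, toyLabels(sizes[1], sizes[2]))
    grp <- lab$label == "sarcoma"
    for (ve in c(FALSE, TRUE)) {
      st <- geneTTest(x, lab, var.equal = ve)
      for (g in 1:5) {
        ref <- t.test(x[g, grp], x[g, !grp], var.equal = ve)
        expect_equal(st$t_stat[g], unname(ref$statistic), tolerance = 1e-10)
        expect_equal(st$p_value[g], ref$p.value, tolerance = 1e-10)
        expect_equal(st$df[g], unname(ref$parameter), tolerance = 1e-10)
        expect_equal(st$effect[g],
                     unname(ref$estimate[1] - ref$estimate[2]),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("identical class distributions give t = 0 and p = 1", {
  x <- matrix(rep(c(1, 2, 3), 2), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  st <- geneTTest(x, labelsFor(x, toyLabels(3, 3)))
  expect_identical(st$t_stat, 0)
  expect_identical(st$p_value, 1)
})

test_that("zero-variance degenerate genes are flagged, not crashed on", {
  x <- rbind(same = rep(5, 8), split = rep(c(1, 2), each = 4))
  colnames(x) <- paste0("s", 1:8)
  st <- geneTTest(x, labelsFor(x, toyLabels(4, 4)))
  expect_true(all(st$degenerate))
  expect_identical(st[st$feature_id == "same", ]$p_value, 1)
  expect_identical(st[st$feature_id == "same", ]$effect, 0)
  # constant-per-class but separated: the infinite-t limit, maximally
  # significant, effect preserved
  expect_identical(st[st$feature_id == "split", ]$p_value, 0)
  expect_identical(st[st$feature_id == "split", ]$effect, 1)
})

test_that("screening under a global null selects about alpha of genes", {
  set.seed(67)
  hits <- 0L
  total <- 0L
  for (rep in 1:10) {
    x <- matrix(rnorm(200 * 40), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:40)))
    st <- geneTTest(x, labelsFor(x, toyLabels(20, 20)))
    hits <- hits + sum(st$p_value < 0.05)
    total <- total + 200L
  }
  expect_lt(abs(hits / total - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("candidate gene selection caps, keeps and tie-breaks deterministically", {
  set.seed(3)
  st <- data.frame(feature_id = sprintf("g%03d", 1:400),
                   t_stat = 0, df = 10,
                   p_value = c(runif(300, 0, 0.049), runif(100, 0.06, 1)),
                   effect = rnorm(400), degenerate = FALSE)
  sel <- selectCandidateGenes(st, topN = 250)
  expect_identical(length(sel), 250L)
  expect_true(all(st$p_value[match(sel, st$feature_id)] < 0.05))
  # ranked by |effect| among the significant
  eff <- abs(st$effect[match(sel, st$feature_id)])
  expect_true(all(diff(eff) <= 0))
  expect_identical(selectCandidateGenes(st[1:100, ], topN = 250),
                   selectCandidateGenes(st[1:100, ], topN = 100))

  tie <- data.frame(feature_id = c("gB", "gA", "gC"), t_stat = 0, df = 10,
                    p_value = c(0.01, 0.01, 0.01),
                    effect = c(2, 2, 2), degenerate = FALSE)
  expect_identical(selectCandidateGenes(tie, topN = 2), c("gA", "gB"))
})

test_that("pair matrix applies the G1 < G2 rule with lexicographic orientation", {
  x <- rbind(gA = c(7.2, 8.1, 5.0), gB = c(8.1, 7.2, 5.0))
  colnames(x) <- paste0("s", 1:3)
  pm <- buildPairMatrix(x, c("gB", "gA"))   # orientation ignores input order
  expect_identical(pairIds(pm), "gA|gB")
  # gA < gB -> 1; reversed -> 0; tie -> 0
  expect_identical(as.vector(pairValues(pm)), c(1, 0, 0))
  expect_error(buildPairMatrix(x, c("gA", "gZ")), "gZ")
  expect_error(buildPairMatrix(x, c("gA", "gA")), "duplicate")
})

test_that("pair counts follow k(k-1)/2 and values match exhaustive comparison", {
  for (k in 2:8) {
    x <- toyExpression(k, 3, seed = k)
    expect_identical(length(pairIds(buildPairMatrix(x, rownames(x)))),
                     as.integer(choose(k, 2L)))
  }
  x <- toyExpression(4, 3, seed = 12)
  pm <- buildPairMatrix(x, rownames(x))
  g <- sort(rownames(x))
  for (i in 1:3) for (j in (i + 1):4) for (s in 1:3) {
    expect_identical(pairValues(pm)[paste(g[i], g[j], sep = "|"), s],
                     as.numeric(x[g[i], s] < x[g[j], s]))
  }
})

test_that("published-panel features follow the printed orientation", {
  panel <- publishedPanel()
  genes <- unique(c(panel$gene1, panel$gene2))
  set.seed(15)
  x <- matrix(runif(9 * 5, 5, 13), 9, 5,
              dimnames = list(genes, paste0("s", 1:5)))
  pf <- computePublishedFeatures(x)
  expect_identical(nrow(pairValues(pf)), 6L)
  expect_identical(pairValues(pf)["hsa-miR-378c|hsa-miR-380-5p", "s1"],
                   as.numeric(x["hsa-miR-378c", "s1"] < x["hsa-miR-380-5p", "s1"]))
  expect_error(computePublishedFeatures(x[-1, ]), "hsa-miR-378c")

  for (i in 1:5) {
    y <- applyMonotoneDistortion(x, randomIncreasingTransform())
    expect_identical(pairValues(computePublishedFeatures(y)), pairValues(pf))
  }
})

test_that("near-constant pair filter removes majority values above 90% strictly", {
  v <- matrix(0, 4, 100, dimnames = list(NULL, paste0("s", 1:100)))
  v[1, 1:95] <- 1     # 95% ones -> removed
  v[2, 1:90] <- 1     # exactly 90% -> retained
  v[3, 1:5] <- 1      # 95% zeros -> removed
  v[4, 1:50] <- 1     # balanced -> retained
  pairs <- data.frame(gene1 = paste0("a", 1:4), gene2 = paste0("b", 1:4))
  rownames(v) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  pm <- new("PairFeatureMatrix", pairs = pairs, values = v)
  kept <- filterNearConstant(pm, trainingIds = colnames(v))
  expect_identical(pairIds(kept), c("a2|b2", "a4|b4"))
  expect_identical(sampleIds(kept), colnames(v))
  expect_error(filterNearConstant(pm, trainingIds = character(0)), "empty")
})

test_that("engineered near-constant pairs are the exact removals, training-only", {
  set.seed(29)
  train <- paste0("s", 1:60)
  test <- paste0("t", 1:20)
  bad <- c(2, 5, 9)
  v <- matrix(rbinom(10 * 80, 1, 0.5), 10, 80,
              dimnames = list(NULL, c(train, test)))
  for (b in bad) v[b, train] <- rbinom(60, 1, 0.98)
  while (any(pmax(rowMeans(v[bad, train, drop = FALSE]),
                  1 - rowMeans(v[bad, train, drop = FALSE])) <= 0.9))
    for (b in bad) v[b, train] <- rbinom(60, 1, 0.98)
  # make test columns of the bad pairs balanced: the filter must ignore them
  for (b in bad) v[b, test] <- rep(c(0, 1), 10)
  pairs <- data.frame(gene1 = sprintf("a%02d", 1:10),
                      gene2 = sprintf("b%02d", 1:10))
  rownames(v) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  pm <- new("PairFeatureMatrix", pairs = pairs, values = v)
  kept <- filterNearConstant(pm, trainingIds = train)
  expect_identical(length(pairIds(kept)), 7L)
  expect_identical(pairIds(kept), pairIds(pm)[-bad])
})

test_that("pair screening keeps the strongest pairs and recovers planted signal", {
  co <- generateCohort(syntheticConfig(nHealthy = 60, nSarcoma = 60,
                                       nGenes = 40, nAbundant = 40,
                                       nDifferential = 0, nPlantedPairs = 5,
                                       flipProb = 0.95, missingRate = 0,
                                       seed = 33))
  pm <- buildPairMatrix(co$expression, rownames(co$expression))
  sel <- selectCandidatePairs(pm, co$labels, topN = 20)
  planted <- paste(co$truth$plantedPairs$gene1, co$truth$plantedPairs$gene2,
                   sep = "|")
  expect_true(all(planted %in% pairIds(sel)))
  # cap honoured; fewer significant than cap -> all returned
  expect_lte(length(pairIds(sel)), 20L)
  st <- pairTTest(pm, co$labels)
  nSig <- sum(st$p_value < 0.05)
  expect_identical(length(pairIds(selectCandidatePairs(pm, co$labels,
                                                       topN = 10000))),
                   nSig)
})

test_that("pair t test effect equals the indicator frequency difference", {
  set.seed(51)
  v <- matrix(rbinom(3 * 40, 1, 0.5), 3, 40,
              dimnames = list(NULL, paste0("s", 1:40)))
  pairs <- data.frame(gene1 = c("a", "b", "c"), gene2 = c("x", "y", "z"))
  rownames(v) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  pm <- new("PairFeatureMatrix", pairs = pairs, values = v)
  lab <- toyLabels(20, 20)
  lab$sample_id <- colnames(v)
  st <- pairTTest(pm, lab)
  grp <- lab$label == "sarcoma"
  expect_equal(st$effect,
               rowMeans(v[, grp]) - rowMeans(v[, !grp]), tolerance = 1e-12,
               ignore_attr = TRUE)
})
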