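# Internal helpers shared across modules.

# Round half away from zero (x >= 0 only); reproduces the 402*0.75 -> 302,
# 275*0.75 -> 206 partition arithmetic.
.halfUp <- function(x) floor(x + 0.5)

# Locale-independent lexicographic sort; used for every identifier tie-break.
.lexSort <- function(x) sort(x, method = "radix")

.lexOrder <- function(...) order(..., method = "radix")

# Percentage with one decimal, half-up (table formatting convention).
.pct1 <- function(x) .halfUp(1000 * x) / 10

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Validate a genes x samples expression matrix.
.assertExpression <- function(x, complete = FALSE,
                              what = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric genes x samples matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry miRNA rownames and sample colnames", call. = FALSE)
  dg <- rownames(x)[duplicated(rownames(x))]
  if (length(dg))
    stop("duplicate gene identifier(s): ", paste(unique(dg), collapse = ", "),
         call. = FALSE)
  ds <- colnames(x)[duplicated(colnames(x))]
  if (length(ds))
    stop("duplicate sample identifier(s): ", paste(unique(ds), collapse = ", "),
         call. = FALSE)
  if (any(is.infinite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (complete && anyNA(x))
    stop(what, " contains missing values; impute first (see knnImpute)",
         call. = FALSE)
  invisible(TRUE)
}

.CLASSES <- c("healthy", "sarcoma")

# Accept a label table (data.frame: sample_id, label) or a named vector and
# return a named factor with levels healthy < sarcoma, optionally aligned to
# `sampleIds`.
.normalizeLabels <- function(labels, sampleIds = NULL) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      stop("label table needs two columns: sample_id, label", call. = FALSE)
    v <- stats::setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
  } else {
    v <- stats::setNames(as.character(labels), names(labels))
  }
  if (is.null(names(v)) || anyNA(names(v)))
    stop("labels must carry sample identifiers", call. = FALSE)
  dup <- names(v)[duplicated(names(v))]
  if (length(dup))
    stop("duplicate sample identifier(s) in labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(v), .CLASSES)
  if (length(bad))
    stop("unknown label token(s): ", paste(bad, collapse = ", "),
         " (expected 'healthy' or 'sarcoma')", call. = FALSE)
  if (!is.null(sampleIds)) {
    miss <- setdiff(sampleIds, names(v))
    if (length(miss))
      stop("no label for sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[sampleIds]
  }
  stats::setNames(factor(v, levels = .CLASSES), names(v))
}

# Vectorised two-sample t over matrix rows (class 2 minus class 1 effect).
# Welch by default; pooled variance with var.equal = TRUE. Degenerate rows
# (zero variance in both classes) are flagged: equal means give t = 0 / p = 1,
# unequal means the +/-Inf Welch limit with p = 0.
.rowTTest <- function(X, grp, var.equal = FALSE) {
  grp <- factor(grp, levels = .CLASSES)
  i2 <- grp == "sarcoma"
  X1 <- X[, !i2, drop = FALSE]
  X2 <- X[, i2, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per class for a t test", call. = FALSE)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  if (var.equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2L, nrow(X))
  } else {
    a1 <- v1 / n1; a2 <- v2 / n2
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (n1 - 1L) + a2^2 / (n2 - 1L))
  }
  effect <- m2 - m1
  tt <- effect / sqrt(se2)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & effect == 0
    tt[eq] <- 0
    df[eq] <- n1 + n2 - 2L
    ne <- degenerate & effect != 0
    tt[ne] <- sign(effect[ne]) * Inf
    df[ne] <- n1 + n2 - 2L
  }
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[degenerate & effect == 0] <- 1
  data.frame(feature_id = rownames(X), t_stat = tt, df = df, p_value = p,
             effect = effect, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Shared top-n rule: among p < alpha, rank by |effect| descending, break ties
# by ascending p then identifier.
.selectTop <- function(stats, alpha, topN) {
  sig <- stats[stats$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(character(0))
  ord <- .lexOrder(-abs(sig$effect), sig$p_value, sig$feature_id)
  utils::head(sig$feature_id[ord], topN)
}
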