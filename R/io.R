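# Reading/writing expression and label tables, the published six-pair panel,
# and JSON model serialization.

.MISSING_TOKENS <- c("", "na", "nan")

.sep <- function(dialect) switch(match.arg(dialect, c("tsv", "csv")),
                                 tsv = "\t", csv = ",")

#' Read a miRNA expression table
#'
#' Parses a genes x samples text table of log2 intensities: first column =
#' miRNA identifiers, header row = sample identifiers. Empty cells, `NA`,
#' `NaN` (case-insensitive) mark missing values. Row and column order are
#' preserved; duplicate identifiers and non-numeric cells are rejected with
#' the offending coordinate.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return numeric matrix, genes x samples, `NA` for missing cells.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("miRNA\ts1\ts2", "miR-a\t8.1\tNA", "miR-b\t7.0\t9.2"), tf)
#' readExpression(tf)
#' @seealso [writeExpression()], [readLabels()]
#' @export
readExpression <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- .sep(dialect)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression table needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  genes <- as.character(raw[[1L]])
  samples <- colnames(raw)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample identifier(s) in header: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells <- trimws(cells)
  miss <- tolower(cells) %in% .MISSING_TOKENS | is.na(cells)
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !miss)
  if (length(bad)) {
    b <- bad[1L]
    i <- ((b - 1L) %% nrow(cells)) + 1L
    j <- ((b - 1L) %/% nrow(cells)) + 1L
    stop("non-numeric cell '", cells[b], "' at gene '", genes[i],
         "', sample '", samples[j], "'", call. = FALSE)
  }
  vals[miss] <- NA_real_
  x <- matrix(vals, nrow = length(genes),
              dimnames = list(genes, samples))
  .assertExpression(x, what = "parsed expression table")
  x
}

#' Write a miRNA expression table
#'
#' Inverse of [readExpression()]: genes in rows, samples in columns, `NA`
#' for missing cells. Numbers are written with 17 significant digits so that
#' the read/write round trip reproduces doubles bit-for-bit.
#'
#' @param x numeric genes x samples matrix.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param idColumn header of the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, dialect = c("tsv", "csv"),
                            idColumn = "miRNA") {
  .assertExpression(x)
  sep <- .sep(dialect)
  fmt <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  fmt[is.na(x)] <- "NA"
  lines <- c(paste(c(idColumn, colnames(x)), collapse = sep),
             paste(rownames(x), apply(fmt, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample label table
#'
#' Two-column table (header required): sample identifier, class label. Labels
#' must be `"healthy"` or `"sarcoma"`; anything else is rejected naming the
#' offending token.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return data.frame with columns `sample_id`, `label`.
#' @seealso [writeLabels()]
#' @export
readLabels <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = .sep(dialect), header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse label table: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0L)
    stop("label table is empty", call. = FALSE)
  lab <- .normalizeLabels(raw[, 1:2])
  data.frame(sample_id = names(lab), label = as.character(lab),
             stringsAsFactors = FALSE)
}

#' Write a sample label table
#'
#' @param labels data.frame (`sample_id`, `label`) or named label vector.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path, dialect = c("tsv", "csv")) {
  lab <- .normalizeLabels(labels)
  sep <- .sep(dialect)
  writeLines(c(paste("sample_id", "label", sep = sep),
               paste(names(lab), as.character(lab), sep = sep)), path)
  invisible(path)
}

#' The published six-pair serum miRNA panel
#'
#' The six oriented miRNA pairs of the published thinned RGLM sarcoma
#' classifier (nine distinct miRNAs). Only the pairs were published, not the
#' fitted coefficients, so applying the panel to new data requires retraining
#' on a labelled cohort; [computePublishedFeatures()] builds the panel's
#' indicator features with this printed orientation.
#'
#' @return data.frame with columns `pair` (1..6), `gene1`, `gene2`.
#' @examples
#' publishedPanel()
#' @export
publishedPanel <- function() {
  data.frame(
    pair = 1:6,
    gene1 = c("hsa-miR-378c", "hsa-miR-378c", "hsa-miR-383-3p",
              "hsa-miR-454-5p", "hsa-miR-4740-5p", "hsa-miR-5007-3p"),
    gene2 = c("hsa-miR-380-5p", "hsa-miR-499b-3p", "hsa-miR-571",
              "hsa-miR-571", "hsa-miR-5007-3p", "hsa-miR-518a-3p"),
    stringsAsFactors = FALSE)
}

.MODEL_FORMAT <- "sarcomiR-rglm"
.MODEL_VERSION <- 1L

.bagToList <- function(bag) {
  list(bagIndex = bag$bagIndex, bagSeed = bag$bagSeed,
       inBag = bag$inBag, oobIds = bag$oobIds,
       candidateFeatures = bag$candidateFeatures,
       selectedFeatures = bag$selectedFeatures,
       coefficients = as.list(bag$coefficients),
       separation = bag$separation)
}

.bagFromList <- function(l) {
  cf <- unlist(l$coefficients)
  list(bagIndex = l$bagIndex, bagSeed = l$bagSeed,
       inBag = as.character(l$inBag), oobIds = as.character(l$oobIds),
       candidateFeatures = as.character(l$candidateFeatures),
       selectedFeatures = as.character(l$selectedFeatures),
       coefficients = stats::setNames(as.numeric(cf), names(cf)),
       separation = isTRUE(l$separation))
}

#' Serialize / restore an RGLM model
#'
#' Models are stored as a single self-describing JSON document embedding the
#' hyperparameters, seed, bag structure and coefficients, so that
#' `loadModel(saveModel(m))` reproduces identical predictions on any feature
#' table.
#'
#' @param model a fitted [RGLMModel-class] or [ThinnedRGLM-class].
#' @param path JSON file path.
#' @return `saveModel`: `path`, invisibly; `loadModel`: the restored model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "RGLMModel"))
  doc <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
              class = class(model)[1L],
              config = model@config,
              featureIds = model@featureIds,
              classLevels = model@classLevels,
              occurrence = as.list(model@occurrence),
              oobAccuracy = model@oobAccuracy,
              bags = lapply(model@bags, .bagToList))
  if (is(model, "ThinnedRGLM")) {
    doc$retainedFeatures <- model@retainedFeatures
    doc$occurrenceCutoff <- model@occurrenceCutoff
    doc$thinTrace <- as.list(model@thinTrace)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot load model: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!identical(doc$format, .MODEL_FORMAT))
    stop("not a ", .MODEL_FORMAT, " model file", call. = FALSE)
  if (!identical(as.integer(doc$version), .MODEL_VERSION))
    stop("unsupported model version: ", doc$version, call. = FALSE)
  occ <- unlist(doc$occurrence)
  model <- new(if (identical(doc$class, "ThinnedRGLM")) "ThinnedRGLM"
               else "RGLMModel",
               config = lapply(doc$config, function(v)
                 if (is.list(v)) unlist(v) else v),
               bags = lapply(doc$bags, .bagFromList),
               occurrence = stats::setNames(as.numeric(occ), names(occ)),
               oobAccuracy = as.numeric(doc$oobAccuracy),
               featureIds = as.character(unlist(doc$featureIds)),
               classLevels = as.character(unlist(doc$classLevels)))
  if (is(model, "ThinnedRGLM")) {
    model@retainedFeatures <- as.character(unlist(doc$retainedFeatures))
    model@occurrenceCutoff <- as.numeric(doc$occurrenceCutoff)
    tt <- doc$thinTrace
    model@thinTrace <- if (is.null(tt)) data.frame() else
      as.data.frame(lapply(tt, unlist), stringsAsFactors = FALSE)
  }
  validObject(model)
  model
}
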