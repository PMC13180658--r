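#' @importClassesFrom Matrix Matrix
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats cor sd rnorm runif rbinom rpois quantile pchisq pt pnorm
#'   fisher.test chisq.test p.adjust glm binomial anova ks.test t.test
#'   complete.cases setNames var
#' @importFrom utils read.delim write.table head
NULL

#' @rdname variantKeys
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' Variant keys
#'
#' "chrom:pos:ref:alt" key strings identifying variants in a
#' [SumstatsTable-class], [GenotypeMatrix-class] or [LDMatrix-class].
#'
#' @param x object carrying a variant table.
#' @return character vector of keys.
#' @rdname variantKeys
#' @export
setMethod("variantKeys", "SumstatsTable", function(x) .variantKey(x@variants))

#' @rdname variantKeys
#' @export
setMethod("variantKeys", "GenotypeMatrix", function(x) .variantKey(x@variants))

#' @rdname variantKeys
#' @export
setMethod("variantKeys", "LDMatrix", function(x) .variantKey(x@variants))

.variantKey <- function(v)
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Variant table of an object
#' @param x object carrying per-variant rows.
#' @return data.frame of variant-level fields.
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname variantTable
#' @export
setMethod("variantTable", "SumstatsTable", function(x) x@variants)

#' @rdname variantTable
#' @export
setMethod("variantTable", "GenotypeMatrix", function(x) x@variants)

#' Dosage matrix accessor
#' @param x a [GenotypeMatrix-class].
#' @return samples x variants numeric matrix (NA = missing).
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' Sample identifiers
#' @param x a [GenotypeMatrix-class].
#' @return character vector.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' Accessibility counts accessor
#' @param x a [CellPeakMatrix-class].
#' @return sparse cells x peaks matrix.
#' @export
setGeneric("peakCounts", function(x) standardGeneric("peakCounts"))

#' @rdname peakCounts
#' @export
setMethod("peakCounts", "CellPeakMatrix", function(x) x@counts)

#' Peak intervals accessor
#' @param x a [CellPeakMatrix-class].
#' @return GRanges of peaks.
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname peakRanges
#' @export
setMethod("peakRanges", "CellPeakMatrix", function(x) x@peaks)

#' Cell barcodes accessor
#' @param x a [CellPeakMatrix-class].
#' @return character vector of barcodes.
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname barcodes
#' @export
setMethod("barcodes", "CellPeakMatrix", function(x) rownames(x@counts))

#' Cell type labels accessor
#' @param x a [CellPeakMatrix-class].
#' @return character vector of labels (length 0 when absent).
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CellPeakMatrix", function(x) x@cellType)

#' Graph adjacency accessor
#' @param x a [CellGraph-class].
#' @return binary symmetric sparse adjacency matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "CellGraph", function(x) x@adjacency)

#' Normalized Laplacian accessor
#' @param x a [CellGraph-class].
#' @return symmetric normalized Laplacian (sparse).
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))

#' @rdname laplacian
#' @export
setMethod("laplacian", "CellGraph", function(x) x@laplacian)

#' PRS feature array accessor
#' @param x a [CellPRSTensor-class].
#' @return numeric array, individuals x cells x grid points.
#' @export
setGeneric("prsScores", function(x) standardGeneric("prsScores"))

#' @rdname prsScores
#' @export
setMethod("prsScores", "CellPRSTensor", function(x) x@scores)

#' C+T parameter grid accessor
#' @param x a [CellPRSTensor-class].
#' @return data.frame with columns r2 and p.
#' @export
setGeneric("ctGrid", function(x) standardGeneric("ctGrid"))

#' @rdname ctGrid
#' @export
setMethod("ctGrid", "CellPRSTensor", function(x) x@grid)

#' Ensemble weight matrix accessor
#' @param x a [CellWeightEnsemble-class].
#' @return models x cells matrix of readout coefficients.
#' @export
setGeneric("cellWeights", function(x) standardGeneric("cellWeights"))

#' @rdname cellWeights
#' @export
setMethod("cellWeights", "CellWeightEnsemble", function(x) x@weights)

#' Model parameter accessor
#' @param x a [ScprsFit-class].
#' @return list with W0, w1, w2, beta, b, gamma.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname modelParams
#' @export
setMethod("modelParams", "ScprsFit", function(x) x@params)

setMethod("show", "SumstatsTable", function(object) {
  cat(sprintf("SumstatsTable: %d variants [source=%s, build=%s]\n",
              nrow(object@variants), object@source, object@build))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(object@dosages), ncol(object@dosages),
              100 * mean(is.na(object@dosages))))
})

setMethod("show", "CellPeakMatrix", function(object) {
  cat(sprintf("CellPeakMatrix: %d cells x %d peaks%s\n",
              nrow(object@counts), ncol(object@counts),
              if (length(object@cellType))
                sprintf(", %d cell types", length(unique(object@cellType)))
              else ""))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants, window %g kb, %s\n",
              nrow(object@r2), object@windowKb, object@source))
})

setMethod("show", "CellGraph", function(object) {
  cat(sprintf("CellGraph: %d cells, k=%d, %d undirected edges\n",
              nrow(object@adjacency), object@k,
              as.integer(sum(object@adjacency) / 2)))
})

setMethod("show", "CellPRSTensor", function(object) {
  d <- dim(object@scores)
  cat(sprintf("CellPRSTensor: %d individuals x %d cells x %d grid points%s\n",
              d[1], d[2], d[3],
              if (object@normalized) " (normalized)" else ""))
})

setMethod("show", "ScprsFit", function(object) {
  cat(sprintf("ScprsFit: T=%d, task=%s, %d epochs, val metric=%.4f\n",
              object@config$T, object@config$task,
              length(object@lossTrace), object@valMetric))
})

setMethod("show", "CellWeightEnsemble", function(object) {
  cat(sprintf("CellWeightEnsemble: %d models x %d cells\n",
              nrow(object@weights), ncol(object@weights)))
})
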