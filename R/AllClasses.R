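#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib grnperturb, .registration = TRUE
NULL

#' Signed directed gene regulatory network topology
#'
#' A `GRNTopology` holds an ordered set of gene names and a signed directed
#' edge list (`+1` activation, `-1` inhibition). Node order is fixed at
#' construction and defines the index assignment used by every downstream
#' matrix, state vector and output.
#'
#' @slot nodes character vector of unique gene names, in index order.
#' @slot edges data.frame with columns `source`, `target` (gene names) and
#'   `sign` (integer, `+1` or `-1`); at most one edge per ordered pair.
#'
#' @seealso [readTopo()], [interactionMatrix()], [groupBetweenness()]
#' @export
setClass("GRNTopology",
         representation(nodes = "character", edges = "data.frame"))

setValidity("GRNTopology", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (anyDuplicated(nd)) msgs <- c(msgs, "duplicate node names")
  if (!all(c("source", "target", "sign") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns source, target, sign")
  else {
    if (!all(ed$source %in% nd) || !all(ed$target %in% nd))
      msgs <- c(msgs, "edge endpoint not among declared nodes")
    if (!all(ed$sign %in% c(-1L, 1L)))
      msgs <- c(msgs, "edge sign must be +1 or -1")
    if (anyDuplicated(paste(ed$source, ed$target, sep = "\r")))
      msgs <- c(msgs, "duplicate (source, target) edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GRNTopology
#'
#' @param nodes character vector of gene names (index order). If missing, the
#'   union of edge endpoints in first-appearance order is used.
#' @param edges data.frame with columns `source`, `target`, `sign`.
#' @return A [GRNTopology-class] object.
#' @examples
#' tp <- GRNTopology(edges = data.frame(source = "A", target = "B", sign = 1L))
#' geneNames(tp)
#' @export
GRNTopology <- function(nodes = NULL, edges = data.frame(source = character(),
                                                         target = character(),
                                                         sign = integer())) {
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (is.null(nodes)) {
    nodes <- unique(as.character(t(cbind(edges$source, edges$target))))
  }
  new("GRNTopology", nodes = as.character(nodes),
      edges = edges[, c("source", "target", "sign"), drop = FALSE])
}

setMethod("show", "GRNTopology", function(object) {
  cat(sprintf("GRNTopology with %d nodes and %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (length(object@nodes))
    cat("  nodes:", paste(utils::head(object@nodes, 8), collapse = ", "),
        if (length(object@nodes) > 8) "..." else "", "\n")
})

#' @rdname GRNTopology
#' @param x,object a `GRNTopology`.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname GRNTopology
#' @export
setMethod("geneNames", "GRNTopology", function(x) x@nodes)

#' @rdname GRNTopology
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname GRNTopology
#' @export
setMethod("edgeTable", "GRNTopology", function(x) x@edges)

#' @rdname GRNTopology
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))

#' @rdname GRNTopology
#' @export
setMethod("numGenes", "GRNTopology", function(x) length(x@nodes))

#' Ensemble of randomized-parameter ODE steady states
#'
#' `GRNStateEnsemble` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with genes in rows and
#' discovered steady states in columns. Assay `"raw"` holds steady-state
#' expression on the natural scale and `"processed"` the log1p-transformed,
#' per-gene standardized values used for clustering, PCA and KNN
#' classification. `colData` carries `model_id`, `state_id` and (after
#' clustering) the `label` column with `"E"`/`"M"` calls. `metadata` stores
#' the per-model parameter sets, the shared preprocessing transform, the
#' clustering summary and the generating [ensembleConfig()].
#'
#' @seealso [simulateEnsemble()], [bistableModels()], [stateLabels()]
#' @export
setClass("GRNStateEnsemble", contains = "SummarizedExperiment")

#' @rdname GRNStateEnsemble-class
#' @param x a `GRNStateEnsemble`.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname GRNStateEnsemble-class
#' @export
setMethod("stateLabels", "GRNStateEnsemble", function(x) {
  lb <- SummarizedExperiment::colData(x)$label
  if (is.null(lb)) stop("ensemble has not been clustered yet")
  lb
})

#' @rdname GRNStateEnsemble-class
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname GRNStateEnsemble-class
#' @export
setMethod("modelParams", "GRNStateEnsemble",
          function(x) S4Vectors::metadata(x)$params)

#' @rdname GRNStateEnsemble-class
#' @export
setGeneric("stateTransform", function(x) standardGeneric("stateTransform"))

#' @rdname GRNStateEnsemble-class
#' @export
setMethod("stateTransform", "GRNStateEnsemble",
          function(x) S4Vectors::metadata(x)$transform)

setMethod("show", "GRNStateEnsemble", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("GRNStateEnsemble: %d genes x %d steady states from %d models\n",
              nrow(object), ncol(object),
              length(unique(cd$model_id))))
  if (!is.null(cd$label)) {
    tb <- table(cd$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})
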