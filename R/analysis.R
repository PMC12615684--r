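#' Reshape a per-signal efficacy table into a symmetric matrix
#'
#' Entry (i, j), i != j, holds the pair signal's efficacy; the diagonal holds
#' the singleton efficacies. The table must contain every 1- and 2-gene
#' signal of the topology exactly once.
#'
#' @param table data.frame with columns `gene_1`, `gene_2` (NA for
#'   singletons) and an efficacy column.
#' @param topology a [GRNTopology-class].
#' @param valueColumn name of the efficacy column.
#' @return symmetric N x N numeric matrix with gene dimnames.
#' @export
efficacyMatrix <- function(table, topology, valueColumn = "emt_percent") {
  nd <- geneNames(topology)
  key <- function(a, b) {
    b[is.na(b)] <- a[is.na(b)]
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  have <- key(table$gene_1, table$gene_2)
  if (anyDuplicated(have)) stop("signal listed more than once")
  want <- unlist(lapply(enumerateSignals(topology),
                        function(sg) key(sg[1], sg[length(sg)])))
  missing <- setdiff(want, have)
  if (length(missing))
    stop("efficacy table incomplete; missing signal(s): ",
         paste(gsub("\r", "+", utils::head(missing, 10)), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  M <- matrix(0, length(nd), length(nd), dimnames = list(nd, nd))
  g2 <- ifelse(is.na(table$gene_2), table$gene_1, table$gene_2)
  i <- match(table$gene_1, nd); j <- match(g2, nd)
  M[cbind(i, j)] <- table[[valueColumn]]
  M[cbind(j, i)] <- table[[valueColumn]]
  M
}

#' Inverse of [efficacyMatrix()]
#'
#' @param M symmetric efficacy matrix.
#' @param topology a [GRNTopology-class].
#' @param valueColumn name for the efficacy column.
#' @return per-signal data.frame in [enumerateSignals()] order.
#' @export
efficacyTable <- function(M, topology, valueColumn = "emt_percent") {
  sigs <- enumerateSignals(topology)
  rows <- lapply(sigs, function(sg) {
    v <- if (length(sg) == 1) M[sg, sg] else M[sg[1], sg[2]]
    df <- data.frame(gene_1 = sg[1],
                     gene_2 = if (length(sg) > 1) sg[2] else NA)
    df[[valueColumn]] <- v
    df
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation between aligned per-signal values
#'
#' Average ranks are used for ties; invariant under strictly monotone
#' transforms of either argument.
#'
#' @param x,y numeric vectors over the same signals; if both are named, the
#'   names must match as sets and `y` is aligned to `x`.
#' @return Spearman correlation coefficient.
#' @export
rankCorrelation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("misaligned signal keys")
    y <- y[names(x)]
  } else if (length(x) != length(y)) stop("misaligned signal vectors")
  if (length(x) < 3) stop("need at least 3 signals")
  stats::cor(x, y, method = "spearman")
}

#' Principal components of the processed steady states
#'
#' PCA on the log1p-standardized state matrix; the returned object can
#' project new states or trajectories (after the same preprocessing
#' transform) into the fitted space.
#'
#' @param processed processed state matrix (states in rows, genes columns).
#' @return list of class `grnPCA` with `loadings` (genes x PCs), `scores`,
#'   `sdev`, `center`.
#' @export
pcaProjection <- function(processed) {
  if (nrow(processed) < 2) stop("need at least 2 states")
  pc <- stats::prcomp(processed, center = TRUE, scale. = FALSE)
  structure(list(loadings = pc$rotation, scores = pc$x, sdev = pc$sdev,
                 center = pc$center, fit = pc),
            class = "grnPCA")
}

#' Project processed states into a fitted PCA space
#'
#' @param pca a [pcaProjection()] result.
#' @param processed matrix (rows = states/time points) on the processed
#'   scale.
#' @return matrix of PC coordinates.
#' @export
projectStates <- function(pca, processed) {
  if (is.null(dim(processed))) processed <- matrix(processed, 1,
                                                   length(processed))
  stats::predict(pca$fit, newdata = processed)
}

#' Summarize a trajectory by E- and M-associated gene groups
#'
#' At each sampled time, reports the mean processed expression over the
#' +1-scored (epithelial) and -1-scored (mesenchymal) genes; clamped genes
#' are excluded from the group means and reported individually.
#'
#' @param trajectory time x genes matrix (raw scale) with gene colnames.
#' @param annotation named score vector.
#' @param clampedGenes genes clamped during the run, reported separately.
#' @param transform optional preprocessing transform ([preprocessStates()]);
#'   if `NULL` the raw values are summarized.
#' @param time optional time vector for the output.
#' @return data.frame with `time`, `e_mean`, `m_mean` and one column per
#'   clamped gene.
#' @export
trajectorySummary <- function(trajectory, annotation, clampedGenes = character(0),
                              transform = NULL, time = NULL) {
  if (!is.null(transform)) trajectory <- applyTransform(trajectory, transform)
  genes <- colnames(trajectory)
  free <- setdiff(genes, clampedGenes)
  eg <- free[annotation[free] > 0]
  mg <- free[annotation[free] < 0]
  if (is.null(time)) time <- seq_len(nrow(trajectory)) - 1
  out <- data.frame(time = time)
  if (length(eg)) out$e_mean <- rowMeans(trajectory[, eg, drop = FALSE])
  else warning("no epithelial-scored genes; e_mean omitted")
  if (length(mg)) out$m_mean <- rowMeans(trajectory[, mg, drop = FALSE])
  else warning("no mesenchymal-scored genes; m_mean omitted")
  for (g in clampedGenes) out[[g]] <- trajectory[, g]
  out
}
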