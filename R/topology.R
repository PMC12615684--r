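#' Read a `.topo` network file
#'
#' Parses the whitespace-separated three-column topology format used
#' throughout the RACIPE ecosystem: an optional header line
#' `Source Target Type` followed by rows `GENE_A GENE_B {1|2}` where type 1
#' is activation and 2 inhibition. Node order is assigned by first appearance
#' in the file and fixes every downstream index.
#'
#' @param path path to a `.topo` file.
#' @return A [GRNTopology-class].
#' @examples
#' f <- tempfile(fileext = ".topo")
#' writeLines(c("Source Target Type", "A B 2", "B A 2"), f)
#' readTopo(f)
#' @export
readTopo <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) &&
      grepl("^\\s*source\\s+target\\s+type\\s*$", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  src <- tgt <- character(length(lines))
  sgn <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 3L)
      stop(sprintf("malformed topology row at line %d: expected 3 fields, got %d",
                   i + 1L, length(f)))
    ty <- suppressWarnings(as.integer(f[3]))
    if (is.na(ty) || !ty %in% c(1L, 2L))
      stop(sprintf("invalid interaction type '%s' at line %d: must be 1 or 2",
                   f[3], i + 1L))
    src[i] <- f[1]; tgt[i] <- f[2]
    sgn[i] <- if (ty == 1L) 1L else -1L
  }
  if (anyDuplicated(paste(src, tgt, sep = "\r"))) {
    d <- which(duplicated(paste(src, tgt, sep = "\r")))[1]
    stop(sprintf("duplicate edge %s -> %s", src[d], tgt[d]))
  }
  nodes <- unique(as.character(t(cbind(src, tgt))))
  GRNTopology(nodes = nodes,
              edges = data.frame(source = src, target = tgt, sign = sgn,
                                 stringsAsFactors = FALSE))
}

#' Write a topology to a `.topo` file
#'
#' @param topology a [GRNTopology-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTopo <- function(topology, path) {
  ed <- edgeTable(topology)
  lines <- c("Source Target Type",
             sprintf("%s %s %d", ed$source, ed$target,
                     ifelse(ed$sign > 0, 1L, 2L)))
  writeLines(lines, path)
  invisible(path)
}

#' Signed interaction matrix
#'
#' Returns the N x N matrix J with `J[i, j]` the influence of node j on node
#' i: `+1` for an activating edge j -> i, `-1` for inhibition, 0 otherwise.
#'
#' @param topology a [GRNTopology-class].
#' @return integer matrix with dimnames set to the gene names.
#' @export
interactionMatrix <- function(topology) {
  nd <- geneNames(topology)
  ed <- edgeTable(topology)
  J <- matrix(0L, length(nd), length(nd), dimnames = list(nd, nd))
  if (nrow(ed))
    J[cbind(match(ed$target, nd), match(ed$source, nd))] <- ed$sign
  J
}

# BFS shortest-path counting on an unweighted directed adjacency list.
# Returns integer distances (NA = unreachable) and path counts from s.
.bfsCounts <- function(adj, s, n) {
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Group betweenness centrality
#'
#' Sums, over all ordered pairs of nodes outside `group`, the fraction of
#' shortest directed paths between them that pass through at least one group
#' member. The graph is treated as directed and unweighted with edge signs
#' ignored; endpoints are excluded from the group credit and no normalization
#' is applied, so for a singleton group on a DAG chain the value is a path
#' count.
#'
#' @param topology a [GRNTopology-class].
#' @param group character vector of gene names (non-empty, subset of nodes).
#' @return a single non-negative number.
#' @examples
#' tp <- GRNTopology(edges = data.frame(source = c("A", "B"),
#'                                      target = c("B", "C"), sign = 1L))
#' groupBetweenness(tp, "B") # the single A->C shortest path passes through B
#' @export
groupBetweenness <- function(topology, group) {
  nd <- geneNames(topology)
  if (length(group) == 0) stop("group must be non-empty")
  unknown <- setdiff(group, nd)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  n <- length(nd)
  gidx <- match(unique(group), nd)
  ed <- edgeTable(topology)
  adj <- rep(list(integer(0)), n)
  if (nrow(ed)) {
    si <- match(ed$source, nd); ti <- match(ed$target, nd)
    for (e in seq_along(si)) adj[[si[e]]] <- c(adj[[si[e]]], ti[e])
  }
  adjSub <- adj
  for (g in gidx) adjSub[[g]] <- integer(0)
  others <- setdiff(seq_len(n), gidx)
  total <- 0
  for (s in others) {
    full <- .bfsCounts(adj, s, n)
    sub <- .bfsCounts(adjSub, s, n)
    # paths leaving s via a group member are absent in the masked graph only
    # if they pass *through* the group; s itself is never masked, but edges
    # into group members are intact, so drop targets in the group.
    for (t in others) {
      if (t == s || is.na(full$dist[t])) next
      avoid <- if (!is.na(sub$dist[t]) && sub$dist[t] == full$dist[t])
        sub$sigma[t] else 0
      total <- total + (full$sigma[t] - avoid) / full$sigma[t]
    }
  }
  total
}

#' Read or write a node annotation table
#'
#' The annotation assigns each gene an integer phenotype score: `+1` for
#' epithelial markers, `-1` for mesenchymal markers, 0 for unscored genes.
#' The file format is two whitespace-separated columns `gene score`.
#'
#' @param path path to the annotation file.
#' @param topology optional [GRNTopology-class]; if given, the annotation is
#'   expanded (with zeros) and ordered to cover every node.
#' @return named integer vector of scores.
#' @export
readAnnotation <- function(path, topology = NULL) {
  tb <- utils::read.table(path, header = FALSE, col.names = c("gene", "score"),
                          stringsAsFactors = FALSE)
  if (!all(tb$score %in% c(-1L, 0L, 1L)))
    stop("annotation scores must be in {-1, 0, 1}")
  ann <- stats::setNames(as.integer(tb$score), tb$gene)
  if (!is.null(topology)) {
    unknown <- setdiff(names(ann), geneNames(topology))
    if (length(unknown))
      stop("annotation gene(s) not in topology: ", paste(unknown, collapse = ", "))
    full <- stats::setNames(integer(numGenes(topology)), geneNames(topology))
    full[names(ann)] <- ann
    ann <- full
  }
  ann
}

#' @rdname readAnnotation
#' @param annotation named integer score vector.
#' @export
writeAnnotation <- function(annotation, path) {
  utils::write.table(data.frame(gene = names(annotation),
                                score = as.integer(annotation)),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
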