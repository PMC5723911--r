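# Adjacency graph and ICAR precision structure for the BYM intercept.

#' Construct a SpatialGraph
#'
#' @param regionIds character vector of region identifiers (any order;
#'   duplicates removed, then sorted lexicographically).
#' @param edges two-column matrix or data.frame of region-id pairs, or a
#'   zero-row matrix for an edgeless graph. Pairs are symmetrized and
#'   deduplicated; self-loops are an error.
#' @return a [SpatialGraph-class].
#' @examples
#' g <- spatialGraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' nRegions(g)
#' @export
spatialGraph <- function(regionIds, edges = matrix(character(), 0L, 2L)) {
  ids <- sort(unique(as.character(regionIds)))
  edges <- as.matrix(edges)
  if (nrow(edges) && ncol(edges) != 2L)
    stop("edges must have exactly two columns")
  if (nrow(edges)) {
    a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
    if (any(a == b))
      stop("self-loop: region '", a[which(a == b)[1L]], "' paired with itself")
    unknown <- setdiff(c(a, b), ids)
    if (length(unknown))
      stop("edge endpoint not a known region: ", unknown[1L])
    i <- match(a, ids); j <- match(b, ids)
    lo <- pmin(i, j); hi <- pmax(i, j)
    keep <- !duplicated(paste(lo, hi))
    em <- cbind(lo[keep], hi[keep])
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  } else {
    em <- matrix(integer(), 0L, 2L)
  }
  storage.mode(em) <- "integer"
  new("SpatialGraph", regionIds = ids, edges = em)
}

#' Read a region adjacency file
#'
#' Plain-text format: one edge per line, two whitespace-separated region ids;
#' `#` starts a comment; an optional line `REGIONS: id1 id2 ...` enumerates
#' regions (used to declare isolated regions with no edges).
#'
#' @param path path to the adjacency file.
#' @return a [SpatialGraph-class] with deduplicated, symmetrized edges over
#'   the sorted union of all mentioned region ids.
#' @export
readAdjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  extra <- character()
  pairs <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (grepl("^REGIONS:", ln)) {
      extra <- c(extra, strsplit(trimws(sub("^REGIONS:", "", ln)), "[[:space:]]+")[[1L]])
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) != 2L)
      stop("line ", k, ": expected two region tokens, got ", length(tok))
    if (tok[1L] == tok[2L])
      stop("line ", k, ": self-loop on region '", tok[1L], "'")
    pairs[[length(pairs) + 1L]] <- tok
  }
  em <- if (length(pairs)) do.call(rbind, pairs) else matrix(character(), 0L, 2L)
  spatialGraph(c(extra, as.vector(em)), em)
}

#' Write a graph in the adjacency file format
#'
#' @param graph a [SpatialGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAdjacency <- function(graph, path) {
  ids <- regionIds(graph)
  em <- graphEdges(graph)
  deg <- tabulate(c(em), length(ids))
  out <- character()
  iso <- ids[deg == 0L]
  if (length(iso)) out <- paste("REGIONS:", paste(iso, collapse = " "))
  if (nrow(em)) out <- c(out, paste(ids[em[, 1L]], ids[em[, 2L]]))
  writeLines(out, path)
  invisible(path)
}

#' Rook-contiguity lattice graph
#'
#' Grid of `rows` x `cols` regions with horizontal and vertical neighbours;
#' a convenient stand-in for an administrative contiguity map in tests and
#' synthetic data.
#'
#' @param rows,cols positive grid dimensions.
#' @return a [SpatialGraph-class] with `rows * cols` regions and
#'   `rows*(cols-1) + cols*(rows-1)` edges.
#' @export
latticeGraph <- function(rows, cols) {
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  lab <- function(r, c) sprintf("R%02d_%02d", r, c)
  ids <- as.vector(outer(seq_len(rows), seq_len(cols), lab))
  e <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) e[[length(e) + 1L]] <- c(lab(r, c), lab(r, c + 1L))
    if (r < rows) e[[length(e) + 1L]] <- c(lab(r, c), lab(r + 1L, c))
  }
  em <- if (length(e)) do.call(rbind, e) else matrix(character(), 0L, 2L)
  spatialGraph(ids, em)
}

#' Connected components by breadth-first traversal
#' @noRd
.graphComponents <- function(n, edges) {
  comp <- integer(n)
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nbrs[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' Build the ICAR precision structure of a graph
#'
#' Returns the intrinsic CAR precision matrix Q with `Q[i,i] = degree(i)` and
#' `Q[i,j] = -1` for neighbours, together with the connected components of
#' the graph. Q is singular: its null space is spanned by the component
#' indicator vectors, so `rank(Q) = n - #components` and each component
#' carries its own sum-to-zero constraint on the structured effect.
#'
#' @param graph a [SpatialGraph-class].
#' @return an [ICARStructure-class].
#' @export
icarStructure <- function(graph) {
  stopifnot(is(graph, "SpatialGraph"))
  ids <- regionIds(graph)
  n <- length(ids)
  em <- graphEdges(graph)
  Q <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(em))) {
    i <- em[k, 1L]; j <- em[k, 2L]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1
    Q[j, j] <- Q[j, j] + 1
  }
  comp <- .graphComponents(n, em)
  names(comp) <- ids
  new("ICARStructure", precision = Q, components = comp,
      rank = n - length(unique(comp)))
}

#' ICAR quadratic form
#'
#' Computes `t(u) %*% Q %*% u`, which for the ICAR precision equals the sum
#' of squared differences between neighbouring regions -- the kernel of the
#' ICAR log density. Invariant to adding a constant within any connected
#' component.
#'
#' @param structure an [ICARStructure-class].
#' @param u numeric vector of region effects, length `nRegions`.
#' @return nonnegative scalar.
#' @export
icarQuadraticForm <- function(structure, u) {
  stopifnot(is(structure, "ICARStructure"))
  n <- nrow(structure@precision)
  if (length(u) != n)
    stop("length(u) = ", length(u), " but graph has ", n, " regions")
  drop(crossprod(u, structure@precision %*% u))
}

setMethod("regionIds", "SpatialGraph", function(x) x@regionIds)
setMethod("nRegions", "SpatialGraph", function(x) length(x@regionIds))
setMethod("graphEdges", "SpatialGraph", function(x) x@edges)
setMethod("regionIds", "ICARStructure", function(x) rownames(x@precision))
setMethod("nRegions", "ICARStructure", function(x) nrow(x@precision))
setMethod("icarPrecision", "ICARStructure", function(x) x@precision)
setMethod("icarComponents", "ICARStructure", function(x) x@components)
setMethod("icarRank", "ICARStructure", function(x) x@rank)

setMethod("show", "SpatialGraph", function(object) {
  cat("SpatialGraph with", length(object@regionIds), "regions and",
      nrow(object@edges), "edges\n")
  cat("  regions:", paste(head(object@regionIds, 5L), collapse = ", "),
      if (length(object@regionIds) > 5L) "..." else "", "\n")
})

setMethod("show", "ICARStructure", function(object) {
  cat("ICARStructure:", nrow(object@precision), "regions,",
      length(unique(object@components)), "connected component(s), rank",
      object@rank, "\n")
})
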