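#' Area adjacency graph
#'
#' An undirected simple graph over area identifiers, the contract for all
#' spatial structure in the package. Nodes keep a stable order; edges are
#' stored as sorted unordered pairs with duplicates and self-loops rejected.
#'
#' @param nodes Character vector of area ids (unique, non-empty).
#' @param edges Two-column character matrix (or data.frame) of node pairs;
#'   may have zero rows (a graph of islands).
#' @return An object of class `adjacency_graph` with elements `nodes`
#'   (character) and `edges` (2-column character matrix).
#' @export
adjacency_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  if (length(nodes) < 1L) stop("graph needs at least one node", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  mode(edges) <- "character"
  if (nrow(edges) > 0L) {
    if (!all(edges %in% nodes)) {
      bad <- unique(edges[!(edges %in% nodes)])
      stop("edge endpoints not in node set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed", call. = FALSE)
    # canonical order within pair, then drop duplicates
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "adjacency_graph")
}

#' @method print adjacency_graph
#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d areas, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(graph_components(x)))))
  invisible(x)
}

# igraph handle sharing the package's node order
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  g
}

#' Connected components of an adjacency graph
#'
#' @param graph An [adjacency_graph()].
#' @return Integer vector of component labels (1-based), named by node, in
#'   node order. Isolated nodes get their own component.
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(as_igraph(graph))$membership
  stats::setNames(as.integer(comp), graph$nodes)
}

#' Node degrees
#' @param graph An [adjacency_graph()].
#' @return Named integer vector in node order.
#' @export
graph_degree <- function(graph) {
  d <- integer(length(graph$nodes))
  names(d) <- graph$nodes
  if (nrow(graph$edges) > 0L) {
    tab <- table(c(graph$edges[, 1], graph$edges[, 2]))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Read / write an adjacency edge list
#'
#' The file format is one `AREA_ID_1<TAB>AREA_ID_2` pair per line, undirected,
#' `#` comments allowed. Isolated areas can be declared as a line with a
#' single id (so islands survive a round trip).
#'
#' @param path File path.
#' @param graph An [adjacency_graph()] (for writing).
#' @return `read_adjacency()` returns an [adjacency_graph()];
#'   `write_adjacency()` returns `path` invisibly.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  singles <- vapply(parts, length, 1L) == 1L
  pairs <- do.call(rbind, parts[!singles])
  if (is.null(pairs)) pairs <- matrix(character(0), ncol = 2)
  nodes <- unique(c(t(pairs), unlist(parts[singles])))
  adjacency_graph(sort(nodes), pairs)
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# adjacency edge list: AREA_ID_1<TAB>AREA_ID_2 (undirected)", con)
  if (nrow(graph$edges) > 0L) {
    writeLines(paste(graph$edges[, 1], graph$edges[, 2], sep = "\t"), con)
  }
  isolated <- graph$nodes[graph_degree(graph) == 0L]
  if (length(isolated)) writeLines(isolated, con)
  invisible(path)
}

#' ICAR spatial structure with BYM2 scaling factors
#'
#' Builds the intrinsic conditional autoregressive (ICAR) precision matrix
#' \eqn{Q} of a graph — degree on the diagonal, \eqn{-1} for each neighbour
#' pair — together with its connected components and, per component, the
#' BYM2 scaling factor \eqn{s}: the geometric mean of the diagonal of the
#' generalised inverse of \eqn{Q} restricted to the component's sum-to-zero
#' subspace. Dividing the structured effect by \eqn{\sqrt{s}} gives it unit
#' typical marginal variance, which is what makes the BYM2 mixing parameter
#' \eqn{\rho} interpretable as a variance proportion.
#'
#' Islands (components of size 1) have no ICAR distribution: their scaling
#' factor is recorded as `NA` and downstream code fixes their structured
#' effect at zero so they contribute through the unstructured term only.
#'
#' @param graph An [adjacency_graph()].
#' @return An object of class `icar_structure`: list with `graph`,
#'   `precision` (sparse symmetric `Matrix`, node order), `components`
#'   (integer labels per node), `scaling` (numeric per component, `NA` for
#'   islands), `s_area` (per-node scaling factor), `is_island` (logical per
#'   node).
#' @export
build_icar_structure <- function(graph) {
  n <- length(graph$nodes)
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges[, 1], graph$nodes)
    j <- match(graph$edges[, 2], graph$nodes)
    deg <- tabulate(c(i, j), nbins = n)
    Q <- Matrix::sparseMatrix(
      i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
      x = c(rep(-1, 2 * length(i)), deg), dims = c(n, n),
      dimnames = list(graph$nodes, graph$nodes)
    )
  } else {
    Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n),
                              dimnames = list(graph$nodes, graph$nodes))
  }
  comp <- graph_components(graph)
  ncomp <- max(comp)
  scaling <- rep(NA_real_, ncomp)
  for (c in seq_len(ncomp)) {
    idx <- which(comp == c)
    if (length(idx) >= 2L) {
      scaling[c] <- scaling_factor_component(as.matrix(Q[idx, idx,
                                                         drop = FALSE]))
    }
  }
  is_island <- comp %in% which(is.na(scaling))
  structure(
    list(graph = graph, precision = Q, components = comp,
         scaling = scaling, s_area = scaling[comp],
         is_island = stats::setNames(is_island, graph$nodes)),
    class = "icar_structure"
  )
}

# Geometric-mean scaling factor of one connected component's ICAR precision.
# The generalised inverse is taken on the sum-to-zero subspace: eigenvalues of
# Q_c are inverted except the single (theoretical) zero eigenvalue whose
# eigenvector is constant.
scaling_factor_component <- function(Qc) {
  m <- nrow(Qc)
  eig <- eigen(Qc, symmetric = TRUE)
  vals <- eig$values
  # the last eigenvalue is the structural zero (connected component)
  inv <- c(1 / vals[seq_len(m - 1L)], 0)
  d <- rowSums((eig$vectors^2) %*% diag(inv, m))
  exp(mean(log(d)))
}

#' BYM2 scaling factors of an ICAR structure
#'
#' @param structure An [build_icar_structure()] result.
#' @return Named numeric vector, one scaling factor per connected component
#'   of size >= 2; islands are omitted.
#' @export
compute_scaling_factor <- function(structure) {
  stopifnot(inherits(structure, "icar_structure"))
  s <- structure$scaling
  names(s) <- paste0("component", seq_along(s))
  s[!is.na(s)]
}

#' @method print icar_structure
#' @export
print.icar_structure <- function(x, ...) {
  sizes <- table(x$components)
  cat(sprintf("<icar_structure> %d areas, %d component(s)\n",
              length(x$graph$nodes), length(sizes)))
  for (c in seq_along(x$scaling)) {
    if (is.na(x$scaling[c])) {
      cat(sprintf("  component %d: island (structured effect fixed at 0)\n", c))
    } else {
      cat(sprintf("  component %d: %d areas, scaling factor s = %.6f\n",
                  c, sizes[[c]], x$scaling[c]))
    }
  }
  invisible(x)
}

#' Write a plain-text summary of an ICAR structure
#' @param structure An `icar_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_summary <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sizes <- table(structure$components)
  writeLines(sprintf("areas\t%d", length(structure$graph$nodes)), con)
  writeLines(sprintf("edges\t%d", nrow(structure$graph$edges)), con)
  writeLines(sprintf("components\t%d", length(sizes)), con)
  for (c in seq_along(structure$scaling)) {
    writeLines(sprintf("component\t%d\tsize\t%d\tscaling_factor\t%s",
                       c, sizes[[c]],
                       ifelse(is.na(structure$scaling[c]), "island",
                              format(structure$scaling[c], digits = 10))), con)
  }
  invisible(path)
}
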