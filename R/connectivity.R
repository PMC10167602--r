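#' Validate a functional connectivity matrix
#'
#' A connectivity matrix is a square symmetric matrix of correlation-like
#' weights in [-1, 1] with unit diagonal, row/column names giving region ids.
#'
#' @param weights numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @return the validated matrix of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(weights, tol = 1e-10) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square")
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("connectivity matrix must carry region ids as dimnames")
  if (!identical(rownames(weights), colnames(weights)))
    stop("row and column region ids must match")
  if (max(abs(weights - t(weights))) > tol)
    stop("connectivity matrix asymmetric beyond tolerance ", tol)
  if (max(abs(diag(weights) - 1)) > tol)
    stop("connectivity matrix diagonal must be 1")
  if (any(weights < -1 - tol | weights > 1 + tol))
    stop("connectivity weights must lie in [-1, 1]")
  class(weights) <- c("connectivity_matrix", class(weights))
  weights
}

#' Read a connectivity matrix from a delimited file
#'
#' Expects a square numeric table with a header row and first column of
#' region ids. If a catalog is given, rows/columns are reordered to catalog
#' order (all regions must be known).
#'
#' @param path TSV file.
#' @param catalog optional \code{\link{region_catalog}}.
#' @param sep delimiter.
#' @return a \code{connectivity_matrix}.
#' @export
read_connectivity <- function(path, catalog = NULL, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (!is.null(catalog)) {
    unknown <- setdiff(rownames(m), catalog$region_id)
    if (length(unknown))
      stop("connectivity regions unknown to catalog: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    ord <- intersect(catalog$region_id, rownames(m))
    m <- m[ord, ord, drop = FALSE]
  }
  connectivity_matrix(m)
}

#' Write a connectivity matrix to a delimited file
#' @param conn a \code{connectivity_matrix}.
#' @param path output path.
#' @param sep delimiter.
#' @export
write_connectivity <- function(conn, path, sep = "\t") {
  df <- data.frame(region_id = rownames(conn),
                   as.data.frame(unclass(conn), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert connectivity weights to path-length distances
#'
#' Stronger functional connectivity is interpreted as shorter path length:
#' each positive weight w contributes an edge of length 1/max(w, eps);
#' nonpositive weights carry no edge. Pairwise region-to-region distances are
#' all-pairs shortest paths over this weighted graph (Dijkstra, via igraph),
#' with zero diagonal. Disconnected pairs get distance \code{Inf} with a
#' warning.
#'
#' @param conn a \code{\link{connectivity_matrix}}.
#' @param eps floor applied to positive weights before inversion.
#' @return symmetric numeric distance matrix with the same dimnames.
#' @export
connectivity_to_distance <- function(conn, eps = 1e-6) {
  w <- unclass(conn)
  len <- ifelse(w > 0, 1 / pmax(w, eps), 0) # 0 = no edge for igraph adjacency
  diag(len) <- 0
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  d <- d[rownames(w), rownames(w)]
  if (any(is.infinite(d)))
    warning("connectivity graph is disconnected; some distances are Inf")
  d
}
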