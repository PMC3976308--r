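#' Read a weighted network from a text file
#'
#' Two plain-text formats are supported. `"dense"`: a whitespace- or
#' comma-delimited `n x n` numeric matrix, row order defining node order.
#' `"edgelist"`: three columns `node_i node_j weight` with 0-based node ids;
#' each undirected edge appears once.
#'
#' @param path file to read.
#' @param format `"dense"` or `"edgelist"`.
#' @param module_labels_path optional one-column file of integer module labels
#'   aligned to node order.
#' @return A [weighted_network()].
#' @export
read_network <- function(path, format = c("dense", "edgelist"),
                         module_labels_path = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(k) {
      x <- strsplit(trimws(lines[k]), "[,[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(x))
      if (any(is.na(v)))
        stop("non-numeric entry in dense matrix at line ", k)
      v
    })
    n <- length(rows)
    if (any(lengths(rows) != n))
      stop("dense matrix is not square: ", n, " rows but line ",
           which(lengths(rows) != n)[1], " has ",
           lengths(rows)[lengths(rows) != n][1], " entries")
    W <- do.call(rbind, rows)
    asym <- which(abs(W - t(W)) > 1e-12 * max(1, max(abs(W))), arr.ind = TRUE)
    if (nrow(asym) > 0)
      stop("dense matrix is not symmetric: entry [", asym[1, 1], ",",
           asym[1, 2], "] differs from its transpose")
  } else {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) != 3)
      stop("edge list must have exactly 3 columns (node_i, node_j, weight)")
    i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]])
    w <- as.numeric(tab[[3]])
    bad <- which(i == j)
    if (length(bad) > 0)
      stop("self-loop in edge list at line ", bad[1])
    bad <- which(w < 0)
    if (length(bad) > 0)
      stop("negative weight in edge list at line ", bad[1])
    if (any(i < 0 | j < 0))
      stop("edge-list node ids must be 0-based non-negative integers")
    n <- max(i, j) + 1L
    W <- matrix(0, n, n)
    W[cbind(i + 1L, j + 1L)] <- w
    W[cbind(j + 1L, i + 1L)] <- w
  }
  labels <- NULL
  if (!is.null(module_labels_path))
    labels <- as.integer(readLines(module_labels_path))
  weighted_network(W, module_labels = labels)
}

#' Write a weighted network to a text file
#'
#' Weights are printed with 17 significant digits so that
#' `read_network(write_network(net))` reproduces them exactly.
#'
#' @param net a [weighted_network()].
#' @param path output file.
#' @param format `"dense"` or `"edgelist"` (see [read_network()]).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("dense", "edgelist")) {
  stopifnot(inherits(net, "weighted_network"))
  format <- match.arg(format)
  if (format == "dense") {
    lines <- apply(net$weights, 1, function(row)
      paste(formatC(row, format = "g", digits = 17), collapse = " "))
    writeLines(lines, path)
  } else {
    el <- network_edges(net)
    writeLines(sprintf("%d\t%d\t%s", el$from, el$to,
                       formatC(el$weight, format = "g", digits = 17)), path)
  }
  invisible(path)
}
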