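#' Read an expression matrix from tab-separated text
#'
#' Expects one header row and one leading ID column; either orientation is
#' accepted and the result is always returned in the canonical samples x genes
#' layout. Values are used as-is (inputs are assumed already normalised, e.g.
#' RMA scale); any missing or non-numeric cell is an error that names the
#' offending row and column.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes_in_rows"` (genes x samples on disk) or
#'   `"samples_in_rows"`.
#' @return Numeric matrix, samples in rows, genes in columns, both dimensions
#'   named.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort_bad_arg(paste0("file not found: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2 || nrow(raw) < 1) {
    abort_bad_arg("expression file needs an ID column plus at least one data column")
  }
  ids <- raw[[1]]
  body <- raw[-1]
  if (anyDuplicated(ids) > 0) {
    abort_bad_arg(paste0("duplicate row IDs in ", path, ": ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(body)) > 0) {
    abort_bad_arg(paste0("duplicate column IDs in ", path))
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(body),
                dimnames = list(ids, names(body)))
  for (j in seq_along(body)) {
    cell <- trimws(body[[j]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) | cell == "")
    if (length(bad) > 0) {
      abort_bad_arg(sprintf(
        "non-numeric or empty cell at row '%s', column '%s' in %s",
        ids[bad[1]], names(body)[j], path
      ))
    }
    mat[, j] <- val
  }
  if (orientation == "genes_in_rows") mat <- t(mat)
  if (nrow(mat) < 2) abort_bad_arg("need at least 2 samples")
  mat
}

#' Write an expression matrix as tab-separated text
#'
#' Values are printed at full precision (17 significant digits), so a
#' write-read round trip reproduces the matrix exactly.
#'
#' @param expr Samples x genes numeric matrix with dimnames.
#' @param path Output path.
#' @param orientation On-disk layout; see [read_expression()].
#' @export
write_expression <- function(expr, path,
                             orientation = c("genes_in_rows",
                                             "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes_in_rows") t(expr) else expr
  df <- data.frame(id = rownames(m), format(m, digits = 17, trim = TRUE,
                                            scientific = FALSE),
                   check.names = FALSE)
  names(df)[1] <- if (orientation == "genes_in_rows") "gene" else "sample"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list with optional per-gene weights
#'
#' One gene ID per line; an optional tab-separated second column carries a
#' nonnegative weight (missing weights default to 1). File order is preserved.
#'
#' @param path Path to the list file.
#' @return Tibble with columns `gene` and `weight`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_bad_arg(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, function(x) trimws(x[1]), character(1))
  weights <- vapply(parts, function(x) {
    if (length(x) < 2 || !nzchar(trimws(x[2]))) return(1)
    w <- suppressWarnings(as.numeric(x[2]))
    if (is.na(w)) abort_bad_arg(paste0("non-numeric weight for gene ", x[1]))
    w
  }, numeric(1))
  if (any(weights < 0)) {
    abort_bad_arg(paste0("negative weight for gene: ",
                         paste(genes[weights < 0], collapse = ", ")))
  }
  if (anyDuplicated(genes) > 0) {
    abort_bad_arg("duplicate gene IDs in list")
  }
  tibble::tibble(gene = genes, weight = weights)
}

validate_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  needed <- c("regulator", "target", "layer", "importance")
  if (!all(needed %in% names(edges))) {
    abort_bad_arg("edge list needs columns regulator, target, layer, importance")
  }
  if (anyDuplicated(edges[c("regulator", "target")]) > 0) {
    abort_bad_arg("duplicate (regulator, target) pairs in edge list")
  }
  if (nrow(edges) > 0 && (any(edges$importance < 0) || any(edges$layer < 1))) {
    abort_bad_arg("edge importance must be >= 0 and layer >= 1")
  }
  edges[needed]
}

#' Write a network edge list as 4-column TSV
#'
#' Columns `regulator`, `target`, `layer`, `importance`; rows sorted by layer
#' descending, importance descending, then regulator and target ID so equal
#' scores always serialise in the same order.
#'
#' @param edges Data frame with columns `regulator`, `target`, `layer`,
#'   `importance`.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  edges <- validate_edges(edges)
  edges <- dplyr::arrange(edges, dplyr::desc(.data$layer),
                          dplyr::desc(.data$importance), .data$regulator,
                          .data$target)
  out <- edges
  out$importance <- format(out$importance, digits = 17, trim = TRUE,
                           scientific = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to the 4-column TSV.
#' @return Tibble with columns `regulator`, `target`, `layer`, `importance`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort_bad_arg(paste0("file not found: ", path))
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer",
                                  "numeric"))
  validate_edges(df)
}

#' Export a hierarchical network for visualisation
#'
#' Nodes carry their layer index (bottom pathway layer = 0) and edges their
#' importance score. GraphML goes through igraph; DOT is written directly with
#' one subgraph rank per layer so standard tooling draws the hierarchy.
#'
#' @param hgrn An `hgrn` from [build_hgrn()].
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_network <- function(hgrn, path, format = c("graphml", "dot")) {
  if (!inherits(hgrn, "hgrn")) abort_bad_arg("`hgrn` must be an hgrn object")
  format <- match.arg(format)
  nodes <- tibble::tibble(
    name = unlist(hgrn$layers),
    layer = rep(seq_along(hgrn$layers) - 1L,
                lengths(hgrn$layers))
  )
  edges <- validate_edges(hgrn$edges)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[c("regulator", "target", "layer", "importance")],
      directed = TRUE, vertices = nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c("digraph hgrn {", "  rankdir=TB;")
    for (lv in rev(sort(unique(nodes$layer)))) {
      members <- nodes$name[nodes$layer == lv]
      lines <- c(lines, sprintf(
        "  { rank=same; %s }",
        paste(sprintf("\"%s\" [layer=%d];", members, lv), collapse = " ")
      ))
    }
    if (nrow(edges) > 0) {
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [importance=%s];",
        edges$regulator, edges$target,
        format(edges$importance, digits = 10, trim = TRUE)
      ))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}
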