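# Minimal ASCII VTU (VTK XML unstructured grid) writer and reader, for
# exchanging meshes and cell fields with external viewers.

#' Write an ASCII VTU unstructured-grid file
#'
#' @param path Output path (`.vtu`).
#' @param points N x 3 coordinate matrix.
#' @param cells List of 1-based node-index vectors.
#' @param types Integer VTK cell types (10 = tetrahedron, 5 = triangle).
#' @param cell_data Named list of numeric/integer vectors, one value per
#'   cell.
#' @param point_data Named list of numeric vectors, one value per point.
#' @return Invisibly, `path`.
#' @export
write_vtu <- function(path, points, cells, types,
                      cell_data = list(), point_data = list()) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  np <- nrow(points); nc <- length(cells)
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("<UnstructuredGrid>")
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc))
  w("<Points>")
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(points, 1, num), con)
  w("</DataArray>")
  w("</Points>")
  w("<Cells>")
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(vapply(cells, function(cl) paste(cl - 1L, collapse = " "),
                    character(1)), con)
  w("</DataArray>")
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(cumsum(lengths(cells)), collapse = " "))
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(as.integer(types), collapse = " "))
  w("</DataArray>")
  w("</Cells>")
  emit_data <- function(data, n, tag) {
    w(sprintf("<%s>", tag))
    for (nm in names(data)) {
      x <- data[[nm]]
      if (length(x) != n)
        stop("field '", nm, "' has length ", length(x), ", expected ", n)
      tp <- if (is.integer(x)) "Int32" else "Float64"
      w(sprintf('<DataArray type="%s" Name="%s" format="ascii">', tp, nm))
      w(num(x))
      w("</DataArray>")
    }
    w(sprintf("</%s>", tag))
  }
  if (length(cell_data)) emit_data(cell_data, nc, "CellData")
  if (length(point_data)) emit_data(point_data, np, "PointData")
  w("</Piece>")
  w("</UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

#' Read an ASCII VTU unstructured-grid file
#'
#' Supports the subset produced by [write_vtu()] (ascii format arrays).
#'
#' @param path Path to a `.vtu` file.
#' @return List with `points`, `cells` (1-based), `types`, `cell_data`,
#'   `point_data`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  nums <- function(node) {
    as.numeric(strsplit(trimws(paste(xml2::xml_text(node), collapse = " ")),
                        "[[:space:]]+")[[1]])
  }
  pts <- nums(xml2::xml_find_first(piece, "./Points/DataArray"))
  points <- matrix(pts, ncol = 3, byrow = TRUE)
  arr <- function(name)
    nums(xml2::xml_find_first(
      piece, sprintf("./Cells/DataArray[@Name='%s']", name)))
  conn <- as.integer(arr("connectivity")) + 1L
  offs <- as.integer(arr("offsets"))
  types <- as.integer(arr("types"))
  starts <- c(1L, utils::head(offs, -1) + 1L)
  cells <- mapply(function(s, e) conn[s:e], starts, offs, SIMPLIFY = FALSE)
  get_fields <- function(tag) {
    nodes <- xml2::xml_find_all(piece, sprintf("./%s/DataArray", tag))
    out <- lapply(nodes, nums)
    names(out) <- xml2::xml_attr(nodes, "Name")
    out
  }
  list(points = points, cells = cells, types = types,
       cell_data = get_fields("CellData"),
       point_data = get_fields("PointData"))
}
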