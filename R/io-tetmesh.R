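# Tetrahedral-mesh file formats: legacy VTK unstructured grid (ASCII),
# Gmsh MSH 2.2 (ASCII) and TetGen .node/.ele pairs.

.labelCodes <- function(labels) {
  lv <- unique(labels)
  list(codes = match(labels, lv), levels = lv)
}

#' Write a tetrahedral mesh
#'
#' Formats: \code{"vtk"} (legacy ASCII unstructured grid with the tissue
#' label as integer cell data), \code{"msh"} (Gmsh 2.2 ASCII, label as the
#' physical/elementary tag) and \code{"node_ele"} (TetGen-style .node/.ele
#' pair with a region attribute; indices 1-based per TetGen convention).
#' Degenerate elements (non-positive volume) abort the write.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param path output file; for \code{node_ele} the common stem of the
#'   \code{.node}/\code{.ele} pair.
#' @param format \code{"vtk"}, \code{"msh"} or \code{"node_ele"}.
#' @return the main output path, invisibly.
#' @export
writeTetMesh <- function(mesh, path, format = c("vtk", "msh", "node_ele")) {
  format <- match.arg(format)
  N <- mesh@nodes
  E <- mesh@elements
  if (nrow(E) == 0) stop("refusing to write an empty mesh")
  sv <- .tetSignedVolumes(N, E)
  if (any(sv <= 0))
    stop("degenerate (zero-volume) element at index ",
         paste(utils::head(which(sv <= 0), 5), collapse = ", "))
  lc <- .labelCodes(mesh@labels)
  if (format == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 paste("headmesher tet mesh; labels:",
                       paste(sprintf("%d=%s", seq_along(lc$levels), lc$levels),
                             collapse = " ")),
                 "ASCII", "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d double", nrow(N))), con)
    writeLines(sprintf("%.17g %.17g %.17g", N[, 1], N[, 2], N[, 3]), con)
    writeLines(sprintf("CELLS %d %d", nrow(E), nrow(E) * 5), con)
    writeLines(sprintf("4 %d %d %d %d", E[, 1] - 1L, E[, 2] - 1L,
                       E[, 3] - 1L, E[, 4] - 1L), con)
    writeLines(sprintf("CELL_TYPES %d", nrow(E)), con)
    writeLines(rep("10", nrow(E)), con)
    writeLines(c(sprintf("CELL_DATA %d", nrow(E)),
                 "SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(lc$codes), con)
  } else if (format == "msh") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
                 "$PhysicalNames", as.character(length(lc$levels)),
                 sprintf("3 %d \"%s\"", seq_along(lc$levels), lc$levels),
                 "$EndPhysicalNames", "$Nodes", as.character(nrow(N))), con)
    writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(N)), N[, 1],
                       N[, 2], N[, 3]), con)
    writeLines(c("$EndNodes", "$Elements", as.character(nrow(E))), con)
    writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(E)),
                       lc$codes, lc$codes, E[, 1], E[, 2], E[, 3], E[, 4]),
               con)
    writeLines("$EndElements", con)
  } else {
    stem <- sub("\\.(node|ele)$", "", path)
    nodef <- paste0(stem, ".node")
    elef <- paste0(stem, ".ele")
    con <- file(nodef, "w")
    writeLines(sprintf("%d 3 0 0", nrow(N)), con)
    writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(N)), N[, 1],
                       N[, 2], N[, 3]), con)
    close(con)
    con <- file(elef, "w")
    writeLines(sprintf("%d 4 1", nrow(E)), con)
    writeLines(sprintf("%d %d %d %d %d %d", seq_len(nrow(E)), E[, 1],
                       E[, 2], E[, 3], E[, 4], lc$codes), con)
    writeLines(paste("#", paste(sprintf("%d=%s", seq_along(lc$levels),
                                        lc$levels), collapse = " ")), con)
    close(con)
    path <- nodef
  }
  invisible(path)
}

#' Read a tetrahedral mesh written by \code{\link{writeTetMesh}}
#'
#' @param path input file (or the .node file of a pair).
#' @param format \code{"vtk"}, \code{"msh"} or \code{"node_ele"}.
#' @return A \linkS4class{TetMesh}.
#' @export
readTetMesh <- function(path, format = c("vtk", "msh", "node_ele")) {
  format <- match.arg(format)
  if (format == "vtk") {
    lines <- readLines(path)
    ip <- grep("^POINTS", lines)
    np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    N <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
    ic <- grep("^CELLS", lines)
    nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
    Em <- matrix(scan(text = lines[(ic + 1):(ic + nc)], quiet = TRUE),
                 ncol = 5, byrow = TRUE)[, 2:5, drop = FALSE] + 1L
    isc <- grep("^LOOKUP_TABLE", lines)[1]
    codes <- scan(text = lines[(isc + 1):(isc + nc)], quiet = TRUE)
    lvl_line <- grep("labels:", lines, value = TRUE)
    levels <- NULL
    if (length(lvl_line)) {
      toks <- regmatches(lvl_line, gregexpr("[0-9]+=[^ ]+", lvl_line))[[1]]
      levels <- sub("^[0-9]+=", "", toks)
    }
    labels <- if (is.null(levels)) as.character(codes) else levels[codes]
    TetMesh(N, Em, labels)
  } else if (format == "msh") {
    lines <- readLines(path)
    inode <- grep("^\\$Nodes$", lines)
    nn <- as.integer(lines[inode + 1])
    N <- matrix(scan(text = lines[(inode + 2):(inode + 1 + nn)],
                     quiet = TRUE), ncol = 4, byrow = TRUE)[, 2:4,
                                                            drop = FALSE]
    iel <- grep("^\\$Elements$", lines)
    ne <- as.integer(lines[iel + 1])
    Em <- matrix(scan(text = lines[(iel + 2):(iel + 1 + ne)], quiet = TRUE),
                 ncol = 9, byrow = TRUE)
    labels <- as.character(Em[, 4])
    ipn <- grep("^\\$PhysicalNames$", lines)
    if (length(ipn)) {
      npn <- as.integer(lines[ipn + 1])
      pn <- lines[(ipn + 2):(ipn + 1 + npn)]
      ids <- as.integer(sub("^\\S+\\s+(\\S+)\\s+.*$", "\\1", pn))
      nms <- sub('^.*"(.*)".*$', "\\1", pn)
      labels <- nms[match(Em[, 4], ids)]
    }
    TetMesh(N, Em[, 6:9, drop = FALSE], labels)
  } else {
    stem <- sub("\\.(node|ele)$", "", path)
    nl <- readLines(paste0(stem, ".node"))
    nn <- as.integer(strsplit(trimws(nl[1]), "\\s+")[[1]][1])
    N <- matrix(scan(text = nl[2:(1 + nn)], quiet = TRUE), ncol = 4,
                byrow = TRUE)[, 2:4, drop = FALSE]
    el <- readLines(paste0(stem, ".ele"))
    el <- el[!grepl("^\\s*#", el)]
    ne <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]][1])
    Em <- matrix(scan(text = el[2:(1 + ne)], quiet = TRUE), ncol = 6,
                 byrow = TRUE)
    # recover label names from the trailing comment if present
    cmt <- grep("^\\s*#", readLines(paste0(stem, ".ele")), value = TRUE)
    labels <- as.character(Em[, 6])
    if (length(cmt)) {
      toks <- regmatches(cmt[1], gregexpr("[0-9]+=[^ ]+", cmt[1]))[[1]]
      if (length(toks)) {
        lv <- sub("^[0-9]+=", "", toks)
        labels <- lv[Em[, 6]]
      }
    }
    TetMesh(N, Em[, 2:5, drop = FALSE], labels)
  }
}
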