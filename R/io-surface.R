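# Triangle-surface file formats: OFF (ASCII), PLY and STL (binary
# little-endian, with ASCII read support).

#' Write a triangle surface to OFF, PLY or STL
#'
#' OFF is written in ASCII at full double precision (17 significant digits);
#' PLY and STL are written binary little-endian, so coordinates survive
#' bit-faithfully (STL demotes to the format's 32-bit floats).  Writing an
#' open surface to STL triggers a warning (STL consumers assume solids) but
#' the file is still produced.
#'
#' @param surface a \linkS4class{TriSurface}.
#' @param path output file.
#' @param format \code{"off"}, \code{"ply"} or \code{"stl"}; default from the
#'   file extension.
#' @return the path, invisibly.
#' @export
writeSurface <- function(surface, path,
                         format = c("auto", "off", "ply", "stl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("off", "ply", "stl"))
    stop("unknown surface format: ", format)
  V <- surface@vertices
  F <- surface@faces
  if (nrow(V) == 0 || nrow(F) == 0) stop("refusing to write an empty surface")
  if (format == "stl" && !isClosedSurface(surface))
    warning("surface is not closed; STL written anyway")
  if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(V), nrow(F)), con)
    writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
               con)
  } else if (format == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format binary_little_endian 1.0",
             sprintf("comment tissue %s", surface@tag),
             sprintf("element vertex %d", nrow(V)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(F)),
             "property list uchar int vertex_indices", "end_header")
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(V)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("headmesher", surface@tag)))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    a <- V[F[, 1], , drop = FALSE]
    b <- V[F[, 2], , drop = FALSE]
    c_ <- V[F[, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c_[i, ])), con, size = 4,
               endian = "little")
      writeBin(as.integer(0L), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a triangle surface from OFF, PLY or STL
#'
#' @param path input file.
#' @param format format override; default from the extension.
#' @param tag tissue tag to attach.
#' @return A \linkS4class{TriSurface}.
#' @export
readSurface <- function(path, format = c("auto", "off", "ply", "stl"),
                        tag = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  switch(format,
         off = .readOFF(path, tag),
         ply = .readPLY(path, tag),
         stl = .readSTL(path, tag),
         stop("unknown surface format: ", format))
}

.readOFF <- function(path, tag) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!identical(trimws(lines[1]), "OFF")) stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vals <- scan(text = lines[3:(2 + nv)], quiet = TRUE)
  V <- matrix(vals, ncol = 3, byrow = TRUE)
  fvals <- scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE)
  Fm <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (!all(Fm[, 1] == 3)) stop("only triangle OFF files are supported")
  TriSurface(V, Fm[, 2:4] + 1L, tag = tag)
}

.readPLY <- function(path, tag) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readBinLine(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200) stop("PLY header not terminated")
  }
  if (!identical(hdr[1], "ply")) stop("not a PLY file")
  binary <- any(grepl("^format binary_little_endian", hdr))
  ascii <- any(grepl("^format ascii", hdr))
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  dbl <- grepl("double", vprops[1])
  if (binary) {
    V <- matrix(readBin(con, "numeric", n = 3 * nv, size = if (dbl) 8 else 4,
                        endian = "little"), ncol = 3, byrow = TRUE)
    Fm <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop("only triangle PLY files are supported")
      Fm[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    }
  } else if (ascii) {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vals <- scan(text = rest[seq_len(nv)], quiet = TRUE)
    V <- matrix(vals, ncol = length(vprops), byrow = TRUE)[, 1:3, drop = FALSE]
    fvals <- scan(text = rest[nv + seq_len(nf)], quiet = TRUE)
    Fm <- matrix(fvals, ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE]
  } else {
    stop("unsupported PLY encoding")
  }
  TriSurface(V, Fm + 1L, tag = tag)
}

readBinLine <- function(con) {
  out <- raw()
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0 || ch == as.raw(10)) break
    out <- c(out, ch)
  }
  trimws(rawToChar(out))
}

.readSTL <- function(path, tag) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80)
  if (grepl("^solid", trimws(rawToChar(header[1:5])))) {
    close(con)
    on.exit()
    return(.readSTLAscii(path, tag))
  }
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tris <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    tris[3 * i - 2, ] <- rec[4:6]
    tris[3 * i - 1, ] <- rec[7:9]
    tris[3 * i, ] <- rec[10:12]
    readBin(con, "integer", n = 1, size = 2, endian = "little")
  }
  .weldTriangleSoup(tris, tag)
}

.readSTLAscii <- function(path, tag) {
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  vals <- scan(text = gsub("vertex", "", vlines), quiet = TRUE)
  tris <- matrix(vals, ncol = 3, byrow = TRUE)
  .weldTriangleSoup(tris, tag)
}

# STL stores a triangle soup; weld identical coordinates back into
# shared vertices.
.weldTriangleSoup <- function(tris, tag) {
  key <- apply(tris, 1, function(p) paste(sprintf("%.9g", p), collapse = ","))
  idx <- match(key, unique(key))
  V <- tris[!duplicated(key), , drop = FALSE]
  Fm <- matrix(idx, ncol = 3, byrow = TRUE)
  TriSurface(V, Fm, tag = tag)
}
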