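# Stanford PLY reading and writing.
#
# Photogrammetry tools emit both ASCII and binary PLY with heterogeneous
# vertex properties (normals, colors, quality); the reader accepts any
# scalar vertex properties and extracts x/y/z, and accepts list-typed face
# properties with arbitrary index types. Only triangular faces are kept.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_vals <- function(raw, type, n, endian) {
  sz <- .ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(raw, "double", n = n, size = sz, endian = endian)
  } else if (type %in% c("uchar", "uint8", "ushort", "uint16")) {
    readBin(raw, "integer", n = n, size = sz, signed = FALSE, endian = endian)
  } else if (type %in% c("uint", "uint32")) {
    v <- readBin(raw, "integer", n = n, size = 4L, endian = endian)
    v <- as.double(v)
    v[v < 0] <- v[v < 0] + 2^32
    v
  } else {
    readBin(raw, "integer", n = n, size = sz, signed = TRUE, endian = endian)
  }
}

.ply_parse_header <- function(lines) {
  if (length(lines) < 2L || trimws(lines[1]) != "ply")
    stop("format error: not a PLY file (missing 'ply' magic)")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("format error: property before element")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               value_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, value_type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt)) stop("format error: PLY header lacks a format line")
  if (!fmt %in% c("ascii", "binary_little_endian", "binary_big_endian"))
    stop("format error: unsupported PLY format '", fmt, "'")
  list(format = fmt, elements = elements)
}

.ply_decode_scalar_element <- function(raw, offset, el, endian) {
  sizes <- vapply(el$props, function(p) .ply_type_size[[p$value_type]], 1L)
  rec <- sum(sizes)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  out <- vector("list", length(el$props))
  names(out) <- vapply(el$props, `[[`, "", "name")
  starts <- offset + seq(0L, by = rec, length.out = el$count)
  for (k in seq_along(el$props)) {
    sz <- sizes[k]
    idx <- rep(starts + offs[k], each = sz) + seq_len(sz)
    out[[k]] <- .ply_read_vals(raw[idx], el$props[[k]]$value_type,
                               el$count, endian)
  }
  list(data = out, consumed = rec * el$count)
}

.ply_decode_face_element <- function(raw, offset, el, endian) {
  p <- el$props[[1]]
  if (!p$list) stop("format error: face element lacks a list property")
  csz <- .ply_type_size[[p$count_type]]
  isz <- .ply_type_size[[p$value_type]]
  n <- el$count
  # fast path: constant list length (triangulated meshes)
  k1 <- .ply_read_vals(raw[offset + seq_len(csz)], p$count_type, 1L, endian)
  rec <- csz + k1 * isz
  if (offset + rec * n <= length(raw)) {
    starts <- offset + seq(0L, by = rec, length.out = n)
    cidx <- rep(starts, each = csz) + seq_len(csz)
    counts <- .ply_read_vals(raw[cidx], p$count_type, n, endian)
    if (all(counts == k1)) {
      vidx <- rep(starts + csz, each = k1 * isz) + seq_len(k1 * isz)
      vals <- .ply_read_vals(raw[vidx], p$value_type, n * k1, endian)
      return(list(indices = matrix(vals, ncol = k1, byrow = TRUE),
                  consumed = rec * n))
    }
  }
  # general path: variable list lengths
  pos <- offset
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cnt <- .ply_read_vals(raw[pos + seq_len(csz)], p$count_type, 1L, endian)
    pos <- pos + csz
    rows[[i]] <- .ply_read_vals(raw[pos + seq_len(cnt * isz)],
                                p$value_type, cnt, endian)
    pos <- pos + cnt * isz
  }
  lens <- lengths(rows)
  keep <- lens == 3L
  list(indices = do.call(rbind, rows[keep]), consumed = pos - offset)
}

#' Read a PLY surface model
#'
#' Reads ASCII and binary (little- or big-endian) Stanford PLY files and
#' returns a [surfaceMesh()]. Coordinates are taken verbatim; the model's
#' units and scale are preserved.
#'
#' @param path path to a PLY file containing vertex and face elements.
#' @return A `SurfaceMesh`.
#' @export
readSurfaceModel <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  # header ends at the first newline after "end_header"; locate it on the
  # raw bytes (the binary payload may contain nul bytes)
  hdr_at <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(hdr_at) == 0L) stop("format error: PLY header not terminated")
  nl <- hdr_at[1] + 10L
  while (nl <= length(raw) && raw[nl] != as.raw(0x0a)) nl <- nl + 1L
  if (nl > length(raw)) stop("format error: PLY header not terminated")
  hdr_end <- nl
  header <- .ply_parse_header(
    strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\r?\n")[[1]])
  vel <- header$elements[["vertex"]]
  fel <- header$elements[["face"]]
  if (is.null(vel) || vel$count < 4L)
    stop("format error: PLY has fewer than 4 vertices")
  if (is.null(fel) || fel$count < 1L)
    stop("format error: PLY has no faces (point cloud only)")

  if (header$format == "ascii") {
    body <- strsplit(rawToChar(raw[(hdr_end + 1L):length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    # elements appear in declaration order
    order_names <- names(header$elements)
    pos <- 0L
    verts <- NULL; faceidx <- NULL
    for (nm in order_names) {
      el <- header$elements[[nm]]
      lines <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (nm == "vertex") {
        vals <- scan(text = lines, what = numeric(), quiet = TRUE)
        m <- matrix(vals, nrow = el$count, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        verts <- m
      } else if (nm == "face") {
        toks <- strsplit(trimws(lines), "[[:space:]]+")
        keep <- vapply(toks, function(t) as.integer(t[1]) == 3L, TRUE)
        faceidx <- do.call(rbind, lapply(toks[keep], function(t)
          as.integer(t[2:4])))
      }
    }
  } else {
    endian <- if (header$format == "binary_little_endian") "little" else "big"
    pos <- hdr_end
    verts <- NULL; faceidx <- NULL
    for (nm in names(header$elements)) {
      el <- header$elements[[nm]]
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        dec <- .ply_decode_face_element(raw, pos, el, endian)
        if (nm == "face") faceidx <- dec$indices
        pos <- pos + dec$consumed
      } else {
        dec <- .ply_decode_scalar_element(raw, pos, el, endian)
        if (nm == "vertex") {
          verts <- do.call(cbind, dec$data)
          colnames(verts) <- names(dec$data)
        }
        pos <- pos + dec$consumed
      }
    }
  }
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(verts)))
    stop("format error: vertex element lacks x/y/z properties")
  if (is.null(faceidx) || nrow(faceidx) < 1L)
    stop("format error: PLY has no triangular faces")
  surfaceMesh(verts[, need, drop = FALSE], faceidx + 1L, source_path = path)
}

#' Write a surface mesh to PLY
#'
#' @param mesh a `SurfaceMesh`.
#' @param path output file.
#' @param format `"binary_little_endian"` (default) or `"ascii"`. Coordinates
#'   are stored as 64-bit floats in both dialects so that a read/write
#'   round trip is lossless.
#' @return `path`, invisibly.
#' @export
writeSurfaceModel <- function(mesh, path,
                              format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  stopifnot(is_surface_mesh(mesh))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    "comment trackline fitted model",
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    vtxt <- apply(mesh$vertices, 1, function(v)
      paste(sprintf("%.17g", v), collapse = " "))
    ftxt <- apply(mesh$faces - 1L, 1, function(f)
      paste(c("3", f), collapse = " "))
    writeLines(c(vtxt, ftxt), con, sep = "\n")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    # interleave the per-face count byte with the 12 index bytes in one pass
    idx_raw <- writeBin(as.vector(t(mesh$faces - 1L)), raw(),
                        size = 4, endian = "little")
    rec <- rbind(matrix(as.raw(3L), nrow = 1L, ncol = nf),
                 matrix(idx_raw, nrow = 12L))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
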