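# Mesh readers/writers: STL (ASCII + binary), PLY (ASCII), OBJ (geometry).
# STL stores duplicated vertices per facet; reading welds them at 1e-6 mm.

#' Read a triangle mesh
#'
#' Supports STL (binary and ASCII; facet vertices are welded at 1e-6 mm),
#' ASCII PLY (a vertex-only PLY yields a point-cloud-only mesh with zero
#' faces), and OBJ (geometry only; polygonal faces are fan-triangulated).
#' Degenerate zero-area faces are flagged in `$diagnostics$degenerate_faces`.
#'
#' @param path mesh file; extension decides the format.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    stop(sprintf("format error in %s: empty file", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply_mesh(path),
         obj = read_obj(path),
         stop(sprintf("unsupported mesh format '%s' (expected STL/PLY/OBJ)", ext),
              call. = FALSE))
}

#' Write a triangle mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output file; extension picks the format (`.stl`, `.ply`,
#'   `.obj`).
#' @param binary for STL, write the binary layout (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply_mesh(mesh, path),
         obj = write_obj(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", ext), call. = FALSE))
  invisible(path)
}

# --- STL --------------------------------------------------------------------

stl_is_binary <- function(path) {
  size <- file.size(path)
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary iff the facet count matches the file size exactly
  !is.na(n) && n >= 0 && size == 84 + 50 * as.double(n)
}

read_stl <- function(path) {
  tri <- if (stl_is_binary(path)) {
    size <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", 50 * n)
    m <- matrix(raw, nrow = 50)
    coords <- matrix(readBin(as.raw(m[13:48, ]), "double", size = 4, n = 9 * n,
                             endian = "little"), ncol = 9, byrow = TRUE)
    coords
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop(sprintf("format error in %s: expected triples of 'vertex' lines, found %d",
                   path, length(vl)), call. = FALSE)
    }
    vals <- lapply(seq_along(vl), function(i) {
      x <- suppressWarnings(as.numeric(strsplit(trimws(vl[i]), "\\s+")[[1]][-1]))
      if (length(x) != 3 || any(is.na(x))) {
        stop(sprintf("format error in %s: bad vertex line '%s'", path,
                     trimws(vl[i])), call. = FALSE)
      }
      x
    })
    matrix(unlist(vals), ncol = 9, byrow = TRUE)
  }
  weld_triangle_soup(tri)
}

# coords: n x 9 (three vertices per facet); weld duplicates at 1e-6 mm
weld_triangle_soup <- function(coords) {
  pts <- t(matrix(t(coords), nrow = 3))
  key <- apply(round(pts / 1e-6), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  nrm <- face_normals(V, F)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2],
                       nrm[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- V[F[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  nrm <- face_normals(V, F)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(c(nrm[i, ], V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ])),
             con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# --- PLY (ASCII) ------------------------------------------------------------

parse_ply_header <- function(lines) {
  if (length(lines) < 2 || trimws(lines[1]) != "ply") {
    stop("format error: not a PLY file (missing 'ply' magic)", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("format error: PLY missing end_header", call. = FALSE)
  elements <- list()
  cur <- NULL
  for (ln in trimws(lines[2:(end - 1)])) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = character(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props <- c(cur$props, tok[length(tok)])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(elements = elements, data_start = end + 1L)
}

read_ply_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- parse_ply_header(lines)
  ve <- hd$elements[["vertex"]]
  if (is.null(ve)) stop(sprintf("format error in %s: PLY has no vertex element", path),
                        call. = FALSE)
  body <- lines[hd$data_start:length(lines)]
  if (length(body) < ve$count) {
    stop(sprintf("format error in %s: truncated PLY (expected %d vertex rows)",
                 path, ve$count), call. = FALSE)
  }
  vrows <- body[seq_len(ve$count)]
  vals <- strsplit(trimws(vrows), "\\s+")
  nv <- length(ve$props)
  vm <- matrix(suppressWarnings(as.numeric(unlist(vals))), ncol = nv, byrow = TRUE)
  if (any(is.na(vm))) {
    stop(sprintf("format error in %s: non-numeric vertex data", path), call. = FALSE)
  }
  xyz_cols <- match(c("x", "y", "z"), ve$props)
  if (any(is.na(xyz_cols))) {
    stop(sprintf("format error in %s: PLY vertex lacks x/y/z properties", path),
         call. = FALSE)
  }
  verts <- vm[, xyz_cols, drop = FALSE]
  fe <- hd$elements[["face"]]
  faces <- matrix(integer(0), 0, 3)
  if (!is.null(fe) && fe$count > 0) {
    frows <- body[ve$count + seq_len(fe$count)]
    fl <- lapply(strsplit(trimws(frows), "\\s+"), as.integer)
    tris <- list()
    for (i in seq_along(fl)) {
      k <- fl[[i]][1]
      idx <- fl[[i]][1 + seq_len(k)] + 1L # PLY is 0-based
      if (any(is.na(idx))) {
        stop(sprintf("format error in %s: bad face row %d", path, i), call. = FALSE)
      }
      for (j in seq_len(k - 2L)) {
        tris[[length(tris) + 1L]] <- c(idx[1], idx[j + 1L], idx[j + 2L])
      }
    }
    faces <- do.call(rbind, tris)
  }
  nrm_cols <- match(c("nx", "ny", "nz"), ve$props)
  mesh <- tri_mesh(verts, faces)
  if (!any(is.na(nrm_cols))) {
    attr(mesh, "normals") <- vm[, nrm_cols, drop = FALSE]
  }
  mesh
}

write_ply_mesh <- function(mesh, path, normals = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (!is.null(normals)) {
    hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- if (is.null(normals)) V else cbind(V, normals)
  writeLines(apply(vm, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             con)
  if (nrow(F) > 0) {
    writeLines(apply(F - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")), con)
  }
}

# --- OBJ (geometry only) ----------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (length(vl) == 0) {
    stop(sprintf("format error in %s: OBJ has no vertices", path), call. = FALSE)
  }
  verts <- t(vapply(lines[vl], function(ln) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4]))
    if (any(is.na(x))) {
      stop(sprintf("format error in %s: bad vertex line '%s'", path, ln),
           call. = FALSE)
    }
    x
  }, numeric(3), USE.NAMES = FALSE))
  tris <- list()
  for (ln in lines[fl]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1L))
    if (any(is.na(idx)) || length(idx) < 3) {
      stop(sprintf("format error in %s: bad face line '%s'", path, ln), call. = FALSE)
    }
    for (j in seq_len(length(idx) - 2L)) {
      tris[[length(tris) + 1L]] <- c(idx[1], idx[j + 1L], idx[j + 2L])
    }
  }
  tri_mesh(verts, if (length(tris)) do.call(rbind, tris) else matrix(integer(0), 0, 3))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L, function(r) {
    paste("v", paste(sprintf("%.10g", r), collapse = " "))
  }), con)
  if (nrow(mesh$faces) > 0) {
    writeLines(apply(mesh$faces, 1L, function(r) {
      paste("f", paste(r, collapse = " "))
    }), con)
  }
}
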