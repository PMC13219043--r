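# Point-list, landmark and transform file I/O. Coordinate files are
# millimetres by convention; `units = "m"` converts metres on read (x1000),
# never guessed from magnitudes.

#' Read a point cloud from XYZ/CSV/PLY
#'
#' Text point lists have one point per line with 3 columns (x y z) or 6
#' (x y z nx ny nz); the separator may be comma or whitespace and a header
#' row is auto-detected (non-numeric first row). Normals are re-normalised
#' to unit length, with a warning when any row is off by more than 1e-3.
#'
#' @param path input file (`.xyz`, `.csv`, `.txt`, or ASCII `.ply`).
#' @param units `"mm"` (default) or `"m"` (converted to mm on read).
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, units = c("mm", "m")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    mesh <- read_ply_mesh(path)
    pts <- mesh$vertices
    nrm <- attr(mesh, "normals")
  } else {
    parsed <- parse_point_table(path)
    pts <- parsed[, 1:3, drop = FALSE]
    nrm <- if (ncol(parsed) >= 6) parsed[, 4:6, drop = FALSE] else NULL
  }
  if (units == "m") pts <- pts * 1000
  if (!is.null(nrm)) {
    nn <- sqrt(rowSums(nrm^2))
    if (any(nn == 0)) stop("zero-length normal in input", call. = FALSE)
    if (any(abs(nn - 1) > 1e-3)) {
      warning("normals deviate from unit length by more than 1e-3; re-normalised")
    }
    nrm <- nrm / nn
  }
  point_cloud(pts, normals = nrm)
}

parse_point_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop(sprintf("parse error in %s: file has no data rows", path), call. = FALSE)
  }
  split_row <- function(ln) strsplit(trimws(ln), "\\s*,\\s*|\\s+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  start <- if (any(is.na(first))) 2L else 1L # header auto-detect
  if (start > length(lines)) {
    stop(sprintf("parse error in %s: only a header row present", path), call. = FALSE)
  }
  rows <- lapply(start:length(lines), function(i) {
    vals <- suppressWarnings(as.numeric(split_row(lines[i])))
    if (!(length(vals) %in% c(3L, 6L)) || any(is.na(vals))) {
      stop(sprintf("parse error in %s at line %d: expected 3 or 6 numeric fields",
                   path, i), call. = FALSE)
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- start - 1L + which(ncols != ncols[1])[1]
    stop(sprintf("parse error in %s at line %d: ragged row (mixed 3- and 6-column)",
                 path, bad), call. = FALSE)
  }
  matrix(unlist(rows), ncol = ncols[1], byrow = TRUE)
}

#' Write a point cloud
#'
#' `.csv` writes a header `x,y,z[,nx,ny,nz]`; `.xyz`/`.txt` write bare
#' space-separated rows; `.ply` writes an ASCII PLY with zero faces. Floats
#' round-trip through [read_point_cloud()] within 1e-6 mm.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  ext <- tolower(tools::file_ext(path))
  m <- if (is.null(cloud$normals)) cloud$points else cbind(cloud$points, cloud$normals)
  if (ext == "ply") {
    write_ply_mesh(tri_mesh(cloud$points, matrix(integer(0), 0, 3)), path,
                   normals = cloud$normals)
  } else if (ext == "csv") {
    hdr <- if (ncol(m) == 6) "x,y,z,nx,ny,nz" else "x,y,z"
    writeLines(c(hdr, apply(m, 1L, function(r) {
      paste(sprintf("%.10g", r), collapse = ",")
    })), path)
  } else {
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")),
               path)
  }
  invisible(path)
}

#' Read paired coarse-registration landmarks
#'
#' CSV with columns `name, frame, x, y, z` where `frame` is `source`
#' (patient/tracker space) or `target` (CT space). Every name must appear in
#' both frames; pairs return in name-sorted order.
#'
#' @param path landmark CSV.
#' @return List `name` (sorted), `source` and `target` (N x 3 matrices, mm).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "frame", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(sprintf("landmark file must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(df$frame %in% c("source", "target"))) {
    stop("landmark frame column must be 'source' or 'target'", call. = FALSE)
  }
  src <- df[df$frame == "source", ]
  tgt <- df[df$frame == "target", ]
  missing_tgt <- setdiff(src$name, tgt$name)
  missing_src <- setdiff(tgt$name, src$name)
  if (length(missing_tgt) || length(missing_src)) {
    parts <- c(
      if (length(missing_tgt)) sprintf("missing target side for: %s",
                                       paste(missing_tgt, collapse = ", ")),
      if (length(missing_src)) sprintf("missing source side for: %s",
                                       paste(missing_src, collapse = ", ")))
    stop(paste("unpaired landmarks -", paste(parts, collapse = "; ")), call. = FALSE)
  }
  nm <- sort(unique(src$name))
  if (length(nm) < 3L) {
    stop(sprintf("need at least 3 landmark pairs, got %d", length(nm)), call. = FALSE)
  }
  list(name = nm,
       source = as.matrix(src[match(nm, src$name), c("x", "y", "z")]),
       target = as.matrix(tgt[match(nm, tgt$name), c("x", "y", "z")]))
}

#' Write paired landmarks
#' @param landmarks list with `name`, `source`, `target` as from
#'   [read_landmarks()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- rbind(
    data.frame(name = landmarks$name, frame = "source",
               x = landmarks$source[, 1], y = landmarks$source[, 2],
               z = landmarks$source[, 3]),
    data.frame(name = landmarks$name, frame = "target",
               x = landmarks$target[, 1], y = landmarks$target[, 2],
               z = landmarks$target[, 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write rigid transforms
#'
#' `.txt` holds the 4x4 homogeneous matrix, row-major, one row per line;
#' `.json` holds `{rotation: [9, row-major], translation: [3], units: "mm"}`.
#'
#' @param A a [rigid_transform()].
#' @param path file path; extension decides the format.
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(A, path) {
  stopifnot(inherits(A, "rigid_transform"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(rotation = as.numeric(t(A$R)),
                              translation = A$t, units = "mm"),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    M <- as_homogeneous(A)
    writeLines(apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               path)
  }
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$rotation) || length(obj$rotation) != 9) {
      stop("transform JSON needs a 9-element row-major 'rotation'", call. = FALSE)
    }
    rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                    as.numeric(obj$translation))
  } else {
    rows <- lapply(readLines(path, warn = FALSE)[1:4], function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    from_homogeneous(do.call(rbind, rows))
  }
}
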