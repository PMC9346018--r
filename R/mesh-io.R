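# Surface mesh I/O: STL (ascii + binary), PLY (ascii, with a per-vertex
# `region` property), OFF, plus a JSON sidecar for named landmarks.

#' Write a surface mesh to file
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format `"stl"`, `"stl_binary"`, `"ply"` or `"off"`; default guessed
#'   from the file extension (`.stl` writes ascii STL).
#' @details PLY preserves the per-vertex region label as an integer vertex
#'   property `region` (0 = bone, 1 = cartilage). STL and OFF cannot carry
#'   vertex attributes; labels are dropped with a warning.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- format %||% guess_format(path)
  if (!dir.exists(dirname(path))) pf_stop("parent directory does not exist: ", dirname(path))
  switch(format,
    stl = write_stl_ascii(mesh, path),
    stl_binary = write_stl_binary(mesh, path),
    ply = write_ply(mesh, path),
    off = write_off(mesh, path),
    pf_stop("unknown mesh format: ", format)
  )
  invisible(path)
}

#' Read a surface mesh from file
#'
#' @param path input file; STL (ascii or binary, autodetected), PLY or OFF.
#' @param format optional override, as in [write_mesh()].
#' @param side side flag to attach (`"right"` default; not stored by the
#'   formats themselves).
#' @return a `surface_mesh`. For PLY files written by [write_mesh()] the
#'   region labels are restored; otherwise all vertices are labeled bone.
#' @export
read_mesh <- function(path, format = NULL, side = "right") {
  if (!file.exists(path)) pf_stop("file does not exist: ", path)
  format <- format %||% guess_format(path)
  switch(format,
    stl = ,
    stl_binary = read_stl(path, side),
    ply = read_ply(path, side),
    off = read_off(path, side),
    pf_stop("unknown mesh format: ", format)
  )
}

#' @noRd
guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply", "off")) ext else
    pf_stop("cannot guess mesh format from extension: ", path)
}

#' @noRd
warn_labels_dropped <- function(mesh, format) {
  if (any(mesh$region == "cartilage")) {
    warning(sprintf("%s cannot store vertex region labels; cartilage labels dropped",
                    toupper(format)), call. = FALSE)
  }
}

#' @noRd
write_stl_ascii <- function(mesh, path) {
  warn_labels_dropped(mesh, "stl")
  n <- triangle_normals(mesh)
  tr <- mesh$triangles; v <- mesh$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid patellofem", con)
  fmt <- paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "  endloop\n endfacet")
  a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  lines <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                   a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                   cc[, 1], cc[, 2], cc[, 3])
  writeLines(lines, con)
  writeLines("endsolid patellofem", con)
}

#' @noRd
write_stl_binary <- function(mesh, path) {
  warn_labels_dropped(mesh, "stl")
  n <- triangle_normals(mesh)
  tr <- mesh$triangles; v <- mesh$vertices
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
  dat <- cbind(n, v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ])
  for (i in seq_len(nrow(tr))) {
    writeBin(as.numeric(dat[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

# merge duplicated vertices produced by facet-soup formats (STL)
#' @noRd
weld_vertices <- function(verts, tris, digits = 6) {
  key <- apply(round(verts, digits), 1, paste, collapse = "_")
  uid <- match(key, unique(key))
  keep <- !duplicated(uid)
  list(vertices = verts[keep, , drop = FALSE],
       triangles = matrix(uid[tris], ncol = 3))
}

#' @noRd
read_stl <- function(path, side) {
  # binary autodetect: ascii files start with "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path, side) else read_stl_binary(path, side)
}

#' @noRd
read_stl_ascii <- function(path, side) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0) {
    pf_stop("malformed ascii STL (vertex count ", length(vl),
            " not a multiple of 3): ", path)
  }
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    if (length(p) != 4) pf_stop("malformed STL vertex record: '", paste(p, collapse = " "), "'")
    as.numeric(p[2:4])
  }))
  tris <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  w <- weld_vertices(nums, tris)
  surface_mesh(w$vertices, w$triangles, side = side)
}

#' @noRd
read_stl_binary <- function(path, side) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", size = 4, endian = "little")
  if (!length(nt) || nt <= 0) pf_stop("malformed binary STL header: ", path)
  verts <- matrix(0, nt * 3, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) pf_stop("truncated binary STL at facet ", i, ": ", path)
    readBin(con, "integer", size = 2, endian = "little")
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  tris <- matrix(seq_len(nt * 3), ncol = 3, byrow = TRUE)
  w <- weld_vertices(verts, tris)
  surface_mesh(w$vertices, w$triangles, side = side)
}

#' @noRd
write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment patellofem surface mesh",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    "property int region",
    sprintf("element face %d", nrow(tr)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  lab <- as.integer(mesh$region == "cartilage")
  writeLines(sprintf("%.10g %.10g %.10g %d", v[, 1], v[, 2], v[, 3], lab), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
}

#' @noRd
read_ply <- function(path, side) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") pf_stop("not a PLY file: ", path)
  hd_end <- match("end_header", trimws(lines))
  if (is.na(hd_end)) pf_stop("malformed PLY: no end_header in ", path)
  header <- trimws(lines[seq_len(hd_end)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  if (!length(nv) || !length(nf)) pf_stop("malformed PLY header in ", path)
  vprops <- character(0)
  in_vert <- FALSE
  for (h in header) {
    if (startsWith(h, "element vertex")) { in_vert <- TRUE; next }
    if (startsWith(h, "element")) in_vert <- FALSE
    if (in_vert && startsWith(h, "property")) {
      vprops <- c(vprops, utils::tail(strsplit(h, "\\s+")[[1]], 1))
    }
  }
  vlines <- lines[(hd_end + 1):(hd_end + nv)]
  vdat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  if (ncol(vdat) < length(vprops)) pf_stop("malformed PLY vertex records in ", path)
  colnames(vdat)[seq_along(vprops)] <- vprops
  region <- if ("region" %in% vprops) {
    ifelse(vdat[, "region"] > 0, "cartilage", "bone")
  } else NULL
  flines <- lines[(hd_end + nv + 1):(hd_end + nv + nf)]
  fdat <- lapply(strsplit(trimws(flines), "\\s+"), as.integer)
  bad <- which(vapply(fdat, function(p) p[1] != 3L, logical(1)))
  if (length(bad)) pf_stop("PLY face ", bad[1], " is not a triangle in ", path)
  tris <- do.call(rbind, lapply(fdat, function(p) p[2:4] + 1L))
  surface_mesh(vdat[, c("x", "y", "z")], tris, region, side = side)
}

#' @noRd
write_off <- function(mesh, path) {
  warn_labels_dropped(mesh, "off")
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(tr))), con)
  writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
}

#' @noRd
read_off <- function(path, side) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || lines[1] != "OFF") pf_stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vdat <- do.call(rbind, lapply(strsplit(lines[3:(2 + nv)], "\\s+"), as.numeric))
  fdat <- lapply(strsplit(lines[(3 + nv):(2 + nv + nf)], "\\s+"), as.integer)
  bad <- which(vapply(fdat, function(p) p[1] != 3L, logical(1)))
  if (length(bad)) {
    pf_stop("OFF face ", bad[1], " has ", fdat[[bad[1]]][1],
            " vertices; only triangles are supported: ", path)
  }
  tris <- do.call(rbind, lapply(fdat, function(p) p[2:4] + 1L))
  surface_mesh(vdat[, 1:3], tris, side = side)
}

#' Write named landmarks to a JSON sidecar
#'
#' @param landmarks named list; each entry a length-3 point or an n x 3
#'   polyline matrix.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(p) {
    if (is.matrix(p)) unname(apply(p, 1, function(r) unname(as.numeric(r)), simplify = FALSE))
    else unname(as.numeric(p))
  }), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a landmarks JSON sidecar
#' @param path path written by [write_landmarks()].
#' @return named list of points / polyline matrices.
#' @export
read_landmarks <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) if (is.matrix(p)) p else as.numeric(p))
}
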