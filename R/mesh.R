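#' Triangulated tooth-root surface
#'
#' A light container for a closed triangle mesh of a root surface (dentine
#' core or cementum envelope) together with the anatomical frame needed to
#' partition it: the apex landmark, the axial coordinate of the
#' cemento-enamel junction (CEJ) ring, the apex-to-cervix axis and a unit
#' vector pointing to the buccal side. Coordinates are in millimetres.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside.
#' @param apex_point Coordinates of the root apex.
#' @param cej_height Axial coordinate (projection on `axis`) of the CEJ
#'   ring, or `NA` for crownless roots whose CEJ is not preserved.
#' @param axis Unit vector from apex towards cervix.
#' @param buccal_reference Unit vector orthogonal to `axis` pointing
#'   buccally (`<`); mesial is at +90 degrees about the axis, lingual
#'   (`>`) opposite, distal at -90 degrees.
#' @return An object of class `root_mesh`.
#' @export
root_mesh <- function(vertices, faces, apex_point = NULL, cej_height = NA,
                      axis = c(0, 0, 1), buccal_reference = c(1, 0, 0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("`vertices` must be n x 3")
  if (ncol(faces) != 3) stop("`faces` must be m x 3")
  if (nrow(vertices) == 0 || nrow(faces) == 0) stop("empty mesh")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  axis <- unitv(axis)
  b <- buccal_reference - sum(buccal_reference * axis) * axis
  structure(list(vertices = vertices, faces = faces,
                 apex_point = apex_point,
                 cej_height = cej_height, axis = axis,
                 buccal_reference = unitv(b)),
            class = "root_mesh")
}

#' @export
print.root_mesh <- function(x, ...) {
  cat(sprintf("root_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$apex_point))
    cat(sprintf("  apex at (%.2f, %.2f, %.2f) mm, CEJ height %s mm\n",
                x$apex_point[1], x$apex_point[2], x$apex_point[3],
                if (is.na(x$cej_height)) "not preserved"
                else sprintf("%.2f", x$cej_height)))
  invisible(x)
}

# Angle-weighted per-vertex normals (outward for an outward-oriented mesh).
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  fn <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  for (k in 1:3) {
    idx <- f[, k]
    for (d in 1:3) n[, d] <- n[, d] + tabulate_add(idx, fn[, d], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-15] <- 1
  n / len
}

# Sum `w` into bins `idx` of length n (sparse accumulation).
tabulate_add <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Vertex adjacency as a list of integer vectors (from triangle edges).
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices))))
}

# Each undirected edge of a closed manifold triangle mesh borders exactly
# two faces.
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Signed volume (positive for outward orientation).
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Read and write triangle meshes (ASCII PLY and OBJ)
#'
#' Minimal readers/writers for the two interchange formats used by the
#' package. PLY files may carry one per-vertex scalar as a `quality`
#' property, used to store thickness maps on the cementum surface.
#' Landmarks and the anatomical frame travel in a YAML sidecar (see
#' [write_mesh_sidecar()]).
#'
#' @param mesh A `root_mesh`.
#' @param path File path.
#' @param quality Optional numeric per-vertex scalar (e.g. thickness, um).
#' @return `read_ply()`/`read_obj()` return a `root_mesh` (with a
#'   `quality` attribute if present); writers return `path` invisibly.
#' @export
write_ply <- function(mesh, path, quality = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  has_q <- !is.null(quality)
  if (has_q) stopifnot(length(quality) == nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               if (has_q) "property float quality",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- if (has_q) cbind(v, quality) else v
  writeLines(apply(format(vm, trim = TRUE, digits = 9, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", lines)
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vprops <- grep("^property (float|double)", header, value = TRUE)
  has_q <- any(grepl("quality", vprops))
  vl <- lines[endh + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, "[[:space:]]+"))),
               nrow = nv, byrow = TRUE)
  fl <- lines[endh + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(fl, "[[:space:]]+"))),
               nrow = nf, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular face in PLY")
  mesh <- root_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L)
  if (has_q) attr(mesh, "quality") <- vm[, 4]
  mesh
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vm <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " +"))),
               ncol = 3, byrow = TRUE)
  ftok <- strsplit(sub("^f ", "", fl), " +")
  fm <- t(vapply(ftok, function(tk) as.integer(sub("/.*", "", tk[1:3])),
                 integer(3)))
  root_mesh(vm, fm)
}

#' @rdname write_ply
#' @export
write_mesh_sidecar <- function(mesh, path) {
  yaml::write_yaml(list(
    apex_point = as.numeric(mesh$apex_point),
    cej_height = if (is.na(mesh$cej_height)) NULL else mesh$cej_height,
    axis = as.numeric(mesh$axis),
    buccal_reference = as.numeric(mesh$buccal_reference)), path)
  invisible(path)
}

#' @rdname write_ply
#' @param sidecar Optional path to a YAML sidecar with `apex_point`,
#'   `cej_height`, `axis` and `buccal_reference`.
#' @export
read_root_mesh <- function(path, sidecar = NULL) {
  ext <- tolower(sub(".*\\.", "", path))
  mesh <- switch(ext, ply = read_ply(path), obj = read_obj(path),
                 stop("unsupported mesh format: ", ext))
  if (!is.null(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    mesh <- root_mesh(mesh$vertices, mesh$faces,
                      apex_point = unlist(sc$apex_point),
                      cej_height = sc$cej_height %||% NA,
                      axis = unlist(sc$axis),
                      buccal_reference = unlist(sc$buccal_reference))
  }
  mesh
}

# Loop-style midpoint subdivision (positions only: each triangle split in
# four through edge midpoints). Used to test refinement invariance.
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                        cbind(f[, 3], f[, 1])))
  keys <- ekey(edges[, 1], edges[, 2])
  ord <- !duplicated(keys)
  edges <- edges[ord, , drop = FALSE]
  keys <- keys[ord]
  mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
  midx <- setNames(nrow(v) + seq_len(nrow(mid)), keys)
  m12 <- midx[ekey(f[, 1], f[, 2])]
  m23 <- midx[ekey(f[, 2], f[, 3])]
  m31 <- midx[ekey(f[, 3], f[, 1])]
  nf <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  root_mesh(rbind(v, mid), nf, apex_point = mesh$apex_point,
            cej_height = mesh$cej_height, axis = mesh$axis,
            buccal_reference = mesh$buccal_reference)
}
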