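# Minimal ASCII mesh readers (OBJ, STL, PLY) and triangle-mesh geometry.
# No mesh-processing package ships with this stack, and the package only
# needs plain triangle soups with consistent winding, so the readers are
# deliberately small: text formats only, triangles only (quads in OBJ/PLY
# are fan-triangulated).

#' Read a triangulated mesh from an ASCII OBJ, STL, or PLY file
#'
#' @param path file path; format inferred from the extension.
#' @return List with \code{vertices} (n x 3, mm) and \code{faces}
#'   (m x 3 integer, 1-based, counterclockwise seen from outside).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 obj = read_obj(path),
                 stl = read_stl_ascii(path),
                 ply = read_ply_ascii(path),
                 stop("unsupported mesh format: ", ext,
                      " (expected obj, stl, or ply)"))
  if (nrow(mesh$faces) == 0) stop("mesh has no faces: ", path)
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- list()
  for (ln in fl) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, "", 1))
    idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
    for (k in seq_len(length(idx) - 2))      # fan-triangulate polygons
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1])))
    stop("binary STL is not supported; export as ASCII STL")
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                               function(x) as.numeric(x[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  # weld duplicate corner vertices so edge/volume bookkeeping works
  key <- apply(round(xyz, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1]) != "ply") stop("not a PLY file")
  if (!any(grepl("format ascii", lines))) stop("binary PLY is not supported")
  endh <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*element vertex ", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face ", "",
                       grep("element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]),
                                          "[[:space:]]+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  for (ln in body[nv + seq_len(nf)]) {
    tok <- as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    idx <- tok[2:(1 + tok[1])] + 1L          # PLY indices are 0-based
    for (k in seq_len(length(idx) - 2))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Write a mesh as ASCII OBJ
#' @param mesh list with \code{vertices} and \code{faces}.
#' @param path output file path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

# --- triangle geometry ------------------------------------------------------

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_centers <- function(mesh) {
  fc <- face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

# unnormalized normals follow the winding order; norm = 2 * area
face_normals_raw <- function(mesh) {
  fc <- face_corners(mesh)
  cross3(fc$b - fc$a, fc$c - fc$a)
}

face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_normals_raw(mesh)^2))
}

face_unit_normals <- function(mesh) {
  n <- face_normals_raw(mesh)
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("mesh contains degenerate (zero-area) triangles")
  n / len
}

# signed volume by the divergence theorem; positive when normals point outward
mesh_signed_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

# centroid of the enclosed solid (valid for closed meshes)
mesh_volume_centroid <- function(mesh) {
  fc <- face_corners(mesh)
  w <- rowSums(fc$a * cross3(fc$b, fc$c)) / 6     # signed tetra volumes
  v <- sum(w)
  if (abs(v) < 1e-12) stop("mesh encloses no volume")
  colSums(w * (fc$a + fc$b + fc$c) / 4) / v
}

mesh_area_centroid <- function(mesh) {
  a <- face_areas(mesh)
  colSums(a * face_centers(mesh)) / sum(a)
}

# a closed 2-manifold has every edge shared by exactly two faces
mesh_is_closed <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# largest pairwise distance between mesh vertices, chunked to bound memory
max_pairwise_distance <- function(points, chunk = 512L) {
  points <- rbind3(points)
  n <- nrow(points)
  if (n < 2) stop("need at least two points")
  sq <- rowSums(points^2)
  best <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(points[idx, , drop = FALSE],
                                                   points)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
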