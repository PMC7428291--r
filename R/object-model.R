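# Rigid objects: posed triangle meshes with mass properties, plus the
# candidate contact points (triangle centers) on their accessible surface.
#
# Frame convention (fixed package-wide): x rightward, y away from the
# participant, z up, table plane z = 0, lengths in mm, masses in g.

# default per-cube masses, calibrated so that 10 wood cubes total 97 g and
# 5 wood + 5 brass cubes total 716 g
.cube_masses <- c(wood = 9.7, brass = 133.5)

new_rigid_object <- function(vertices, faces, face_part, part_masses,
                             mass, com_local, centroid_local, pose, source) {
  stopifnot(mass > 0)
  obj <- structure(list(
    vertices = vertices,          # object frame, mm
    faces = faces,
    face_part = face_part,        # which part (cube / component) owns a face
    part_masses = part_masses,    # g
    mass = mass,                  # g
    com_local = com_local,        # object frame, mm
    centroid_local = centroid_local,
    pose = pose,
    d_max = max_pairwise_distance(vertices),
    source = source), class = "rigid_object")
  bb_lo <- apply(vertices, 2, min); bb_hi <- apply(vertices, 2, max)
  if (any(com_local < bb_lo - 1e-6) || any(com_local > bb_hi + 1e-6))
    stop("center of mass falls outside the mesh bounding box")
  obj
}

#' Build a polycube object
#'
#' Constructs a watertight triangulated mesh from unit cubes placed on an
#' integer grid, the stimulus family used for the grasping experiments the
#' model was developed on: compounds of 2.5 cm cubes made of beech wood
#' (9.7 g per cube) and/or brass (133.5 g per cube), so that ten wooden
#' cubes total 97 g and a five wood / five brass compound totals 716 g.
#' Interior faces shared by adjacent cubes are removed; each exposed square
#' face is subdivided into \code{triangles_per_face} triangles.
#'
#' @param cube_coords k x 3 integer matrix of distinct grid positions.
#' @param materials character vector ("wood"/"brass"), length 1 or k.
#' @param cube_edge cube edge length, mm.
#' @param triangles_per_face triangles per exposed cube face; must be
#'   \code{2 * s^2} for integer s (2, 8, 32, 128, ...). 128 reproduces the
#'   original stimulus meshes; 2 or 8 are fast modes for testing.
#' @param cube_masses named numeric, mass per cube of each material, g.
#' @param pose \code{rigid_transform} placing the object in the participant
#'   frame.
#' @return A \code{rigid_object}.
#' @export
build_polycube <- function(cube_coords, materials = "wood", cube_edge = 25,
                           triangles_per_face = 128,
                           cube_masses = .cube_masses,
                           pose = rigid_transform()) {
  g <- rbind3(cube_coords)
  if (max(abs(g - round(g))) > 1e-9) stop("cube_coords must be integers")
  g <- round(g)
  k <- nrow(g)
  key <- apply(g, 1, paste, collapse = ",")
  if (anyDuplicated(key)) stop("overlapping cube coordinates")
  materials <- rep_len(materials, k)
  if (!all(materials %in% names(cube_masses)))
    stop("unknown material; expected one of: ",
         paste(names(cube_masses), collapse = ", "))
  stopifnot(cube_edge > 0)
  s <- sqrt(triangles_per_face / 2)
  if (s != round(s)) stop("triangles_per_face must be 2*s^2 (2, 8, 32, 128, ...)")
  s <- as.integer(s)

  if (!polycube_connected(g))
    warning("cube layout is not face-connected; building it anyway")

  occupied <- new.env(parent = emptyenv())
  for (kk in key) assign(kk, TRUE, envir = occupied)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  # per direction: grid offset of the face plane corner, and in-plane axes
  # u, v chosen so that u x v is the outward normal
  face_frames <- list(
    list(o = c(1, 0, 0), u = c(0, 1, 0), v = c(0, 0, 1)),  # +x
    list(o = c(0, 0, 0), u = c(0, 0, 1), v = c(0, 1, 0)),  # -x
    list(o = c(0, 1, 0), u = c(0, 0, 1), v = c(1, 0, 0)),  # +y
    list(o = c(0, 0, 0), u = c(1, 0, 0), v = c(0, 0, 1)),  # -y
    list(o = c(0, 0, 1), u = c(1, 0, 0), v = c(0, 1, 0)),  # +z
    list(o = c(0, 0, 0), u = c(0, 1, 0), v = c(1, 0, 0)))  # -z

  vkey <- character(0); verts <- list(); faces <- list(); face_part <- integer(0)
  vindex <- new.env(parent = emptyenv())
  get_vertex <- function(p) {
    kk <- paste(round(p, 6), collapse = ",")
    id <- vindex[[kk]]
    if (is.null(id)) {
      id <- length(verts) + 1L
      verts[[id]] <<- p
      vindex[[kk]] <- id
    }
    id
  }
  for (ci in seq_len(k)) {
    for (di in 1:6) {
      nb <- paste(g[ci, ] + dirs[di, ], collapse = ",")
      if (!is.null(occupied[[nb]])) next            # interior shared face
      fr <- face_frames[[di]]
      origin <- (g[ci, ] + fr$o) * cube_edge
      # (s+1)^2 grid points on this face
      ids <- matrix(0L, s + 1, s + 1)
      for (i in 0:s) for (j in 0:s)
        ids[i + 1, j + 1] <- get_vertex(origin + (i / s) * cube_edge * fr$u +
                                          (j / s) * cube_edge * fr$v)
      for (i in 1:s) for (j in 1:s) {
        p00 <- ids[i, j]; p10 <- ids[i + 1, j]
        p11 <- ids[i + 1, j + 1]; p01 <- ids[i, j + 1]
        faces[[length(faces) + 1L]] <- c(p00, p10, p11)
        faces[[length(faces) + 1L]] <- c(p00, p11, p01)
        face_part <- c(face_part, ci, ci)
      }
    }
  }
  vertices <- do.call(rbind, verts)
  faces <- do.call(rbind, faces)
  m <- cube_masses[materials]
  centers <- (g + 0.5) * cube_edge
  obj <- new_rigid_object(
    vertices = vertices, faces = faces, face_part = face_part,
    part_masses = stats::setNames(as.numeric(m), materials),
    mass = sum(m),
    com_local = colSums(m * centers) / sum(m),
    centroid_local = colMeans(centers),
    pose = pose,
    source = list(kind = "polycube", cube_coords = g, materials = materials,
                  cube_edge = cube_edge, triangles_per_face = triangles_per_face))
  obj
}

polycube_connected <- function(g) {
  k <- nrow(g)
  if (k <= 1) return(TRUE)
  # BFS over face adjacency (Manhattan distance 1)
  adj <- as.matrix(stats::dist(g, method = "manhattan")) == 1
  seen <- logical(k); frontier <- 1L; seen[1] <- TRUE
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Load a rigid object from a mesh file
#'
#' Reads an ASCII OBJ/STL/PLY mesh and integrates mass and center of mass
#' from the enclosed volume at uniform density. Meshes whose normals point
#' inward (negative signed volume) are re-wound; open meshes fall back to
#' the area-weighted surface centroid with a warning.
#'
#' @param path mesh file path.
#' @param density uniform material density, g/mm^3 (beech wood is about
#'   6.5e-4, brass about 8.5e-3).
#' @param pose \code{rigid_transform} into the participant frame.
#' @return A \code{rigid_object}.
#' @export
load_mesh <- function(path, density, pose = rigid_transform()) {
  if (length(density) != 1 || !is.finite(density) || density <= 0)
    stop("density must be a single positive value in g/mm^3")
  mesh <- read_mesh(path)
  closed <- mesh_is_closed(mesh)
  vol <- mesh_signed_volume(mesh)
  if (closed && vol < 0) {      # inward winding: flip
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
    vol <- -vol
  }
  if (closed) {
    com <- mesh_volume_centroid(mesh)
  } else {
    warning("mesh is not closed; center of mass approximated by the ",
            "area-weighted surface centroid")
    com <- mesh_area_centroid(mesh)
  }
  mass <- abs(vol) * density
  if (mass <= 0) stop("mesh encloses no volume; cannot assign a mass")
  new_rigid_object(
    vertices = mesh$vertices, faces = mesh$faces,
    face_part = rep(1L, nrow(mesh$faces)),
    part_masses = c(uniform = mass),
    mass = mass, com_local = com,
    centroid_local = if (closed) mesh_volume_centroid(mesh) else com,
    pose = pose,
    source = list(kind = "mesh", path = path, density = density,
                  closed = closed))
}

#' @export
print.rigid_object <- function(x, ...) {
  cat(sprintf("rigid object (%s): %d vertices, %d faces\n",
              x$source$kind, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  mass %.4g g | CoM (participant frame) [%s] mm | D_max %.4g mm\n",
              x$mass, paste(format(round(object_com(x), 2)), collapse = ", "),
              x$d_max))
  invisible(x)
}

#' Replace the pose of a rigid object
#' @param obj \code{rigid_object}.
#' @param pose \code{rigid_transform}.
#' @return The object with the new pose.
#' @export
set_pose <- function(obj, pose) {
  stopifnot(inherits(obj, "rigid_object"), inherits(pose, "rigid_transform"))
  obj$pose <- pose
  obj
}

#' Mesh of a rigid object in the participant frame
#' @param obj \code{rigid_object}.
#' @return List with posed \code{vertices} and \code{faces}.
#' @export
posed_mesh <- function(obj) {
  list(vertices = transform_points(obj$pose, obj$vertices), faces = obj$faces)
}

#' Center of mass in the participant frame
#' @param obj \code{rigid_object}.
#' @return Length-3 vector, mm.
#' @export
object_com <- function(obj) transform_points(obj$pose, obj$com_local)

#' Geometric centroid (uniform-density CoM) in the participant frame
#' @param obj \code{rigid_object}.
#' @return Length-3 vector, mm.
#' @export
object_centroid <- function(obj) transform_points(obj$pose, obj$centroid_local)

#' Enumerate candidate contact points on the accessible surface
#'
#' Candidate contacts are the centers of mesh triangles, in the participant
#' frame. Faces resting on the table (all three vertices within
#' \code{table_tol} of \code{table_z}) are inaccessible and excluded.
#' Optionally retains a seeded uniform random subset of the candidates, the
#' mesh-subsampling perturbation of the model.
#'
#' @param obj \code{rigid_object}.
#' @param table_z table plane height, mm.
#' @param subsample_pct percentage of candidates to retain, in (0, 100].
#' @param seed integer seed for the subsample draw (required when
#'   \code{subsample_pct < 100}).
#' @param table_tol tolerance for table contact, mm.
#' @return A \code{candidate_set}: positions, outward unit normals, areas,
#'   parent face indices.
#' @export
candidate_contacts <- function(obj, table_z = 0, subsample_pct = 100,
                               seed = NULL, table_tol = 1) {
  stopifnot(subsample_pct > 0, subsample_pct <= 100)
  pm <- posed_mesh(obj)
  z <- matrix(pm$vertices[t(pm$faces), 3], nrow = 3)   # 3 x nfaces corner z
  on_table <- colSums(abs(z - table_z) <= table_tol) == 3
  keep <- which(!on_table)
  if (!length(keep)) stop("no accessible faces above the table plane")
  if (subsample_pct < 100) {
    n_keep <- max(1L, round(length(keep) * subsample_pct / 100))
    keep <- sort(with_seed(seed, sample(keep, n_keep)))
  }
  sub <- list(vertices = pm$vertices, faces = pm$faces[keep, , drop = FALSE])
  structure(list(
    positions = face_centers(sub),
    normals = face_unit_normals(sub),
    areas = face_areas(sub),
    parent_face = keep,
    table_z = table_z,
    n = length(keep)), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set: %d accessible contact points (table z = %g mm)\n",
              x$n, x$table_z))
  invisible(x)
}

#' Mean distance from each candidate to its nearest neighbour
#'
#' The surface sampling density diagnostic used when judging how much mesh
#' subsampling the model tolerates.
#' @param cands \code{candidate_set}.
#' @return Mean nearest-neighbour spacing, mm.
#' @export
candidate_spacing <- function(cands) {
  d <- as.matrix(stats::dist(cands$positions))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# run expr with a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# --- plain-text object / pose files ----------------------------------------

#' Read a polycube layout file
#'
#' One cube per line: \code{ix iy iz material}; \code{#} starts a comment.
#' @param path layout file.
#' @return List with \code{cube_coords} (k x 3 integer) and \code{materials}.
#' @export
read_polycube_layout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(tok, length, 1L) != 4)
  if (length(bad))
    stop("malformed layout line(s): ", paste(bad, collapse = ", "),
         " (expected 'ix iy iz material')")
  coords <- do.call(rbind, lapply(tok, function(x) as.integer(x[1:3])))
  list(cube_coords = coords,
       materials = vapply(tok, `[`, "", 4))
}

#' Material assignment schemes for 10-cube compound objects
#'
#' Reproduces the three heavy-object material configurations: cubes
#' alternating between wood and brass along the layout order, or bipartite
#' with one connected half brass (optionally inverted).
#' @param n_cubes number of cubes.
#' @param scheme one of "wood", "alternating", "bipartite",
#'   "bipartite_inverted".
#' @return Character vector of materials along the layout order.
#' @export
polycube_materials <- function(n_cubes,
                               scheme = c("wood", "alternating", "bipartite",
                                          "bipartite_inverted")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         wood = rep("wood", n_cubes),
         alternating = rep_len(c("wood", "brass"), n_cubes),
         bipartite = c(rep("wood", ceiling(n_cubes / 2)),
                       rep("brass", floor(n_cubes / 2))),
         bipartite_inverted = c(rep("brass", ceiling(n_cubes / 2)),
                                rep("wood", floor(n_cubes / 2))))
}

#' Read a pose file (4 x 4 homogeneous matrix, row-major text)
#' @param path pose file.
#' @return \code{rigid_transform}.
#' @export
read_pose <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!identical(dim(m), c(4L, 4L))) stop("pose file must hold a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write a pose file
#' @param tf \code{rigid_transform}.
#' @param path output path.
#' @export
write_pose <- function(tf, path) {
  m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
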