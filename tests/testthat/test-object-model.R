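test_that("polycube mass and CoM match closed-form cube sums", {
  # 10 wooden cubes: the light stimulus, 97 g
  expect_equal(fx_L()$mass, 97, tolerance = 1e-12)
  # 5 wood + 5 brass: the heavy stimulus, 716 g
  expect_equal(fx_L_heavy()$mass, 716, tolerance = 1e-12)
  # wooden domino: CoM at the shared-face center by symmetry
  dom <- fx_domino()
  expect_equal(dom$mass, 19.4, tolerance = 1e-12)
  expect_equal(unname(object_com(dom)), c(25, 12.5, 12.5), tolerance = 1e-9)
  # closed-form CoM of the heavy bipartite L
  lay <- polycube_shape("L")
  m <- c(9.7, 133.5)[(polycube_materials(10, "bipartite") == "brass") + 1]
  centers <- (lay$cube_coords + 0.5) * 25
  expect_equal(unname(object_com(fx_L_heavy())),
               unname(colSums(m * centers) / sum(m)), tolerance = 1e-9)
})

test_that("per-cube masses agree with the familiarization cuboids within 4%", {
  # a 12.5 x 2.5 x 2.5 cm rod is five cubes; the printed rod masses imply
  # 10 g per wood cube and 134 g per brass cube
  rod <- matrix(c(0:4, rep(0, 10)), ncol = 3)
  wood_rod <- build_polycube(rod, "wood", triangles_per_face = 2)
  brass_rod <- build_polycube(rod, "brass", triangles_per_face = 2)
  expect_lt(abs(wood_rod$mass - 50) / 50, 0.04)
  expect_lt(abs(brass_rod$mass - 670) / 670, 0.04)
})

test_that("polycube meshes are watertight with outward normals", {
  for (obj in list(fx_L(), fx_domino())) {
    mesh <- list(vertices = obj$vertices, faces = obj$faces)
    expect_true(graspsel:::mesh_is_closed(mesh))
    vol <- graspsel:::mesh_signed_volume(mesh)
    expect_equal(vol, nrow(obj$source$cube_coords) * 25^3, tolerance = 1e-9)
    # solid centroid from the surface integral equals the cube-sum centroid
    expect_equal(unname(graspsel:::mesh_volume_centroid(mesh)),
                 unname(obj$centroid_local), tolerance = 1e-9)
  }
})

test_that("polycube layouts are validated", {
  expect_error(build_polycube(rbind(c(0, 0, 0), c(0, 0, 0)), "wood",
                              triangles_per_face = 2), "overlap")
  expect_warning(build_polycube(rbind(c(0, 0, 0), c(2, 0, 0)), "wood",
                                triangles_per_face = 2), "face-connected")
  expect_error(build_polycube(c(0, 0, 0), "marble", triangles_per_face = 2),
               "material")
  expect_error(build_polycube(c(0, 0, 0), "wood", triangles_per_face = 3),
               "2\\*s\\^2")
})

test_that("mass properties are pose-invariant and CoM transforms covariantly", {
  obj <- fx_L()
  pose <- rigid_transform(rotation_about("z", 55), c(40, 120, 0))
  posed <- set_pose(obj, pose)
  expect_identical(posed$mass, obj$mass)
  expect_identical(posed$d_max, obj$d_max)
  expect_equal(unname(object_com(posed)),
               unname(transform_points(pose, object_com(obj))),
               tolerance = 1e-9)
  # candidate geometry: pairwise distances invariant, normals co-rotate
  c0 <- candidate_contacts(obj, table_z = -1e9)   # keep all faces
  c1 <- candidate_contacts(posed, table_z = -1e9)
  expect_equal(as.matrix(dist(c1$positions)), as.matrix(dist(c0$positions)),
               tolerance = 1e-9)
  expect_equal(c1$normals, transform_points(pose, c0$normals, vector = TRUE),
               tolerance = 1e-9)
})

test_that("mesh loading integrates mass and CoM from the enclosed volume", {
  dir <- withr::local_tempdir()
  cube <- build_polycube(c(0, 0, 0), "wood", triangles_per_face = 2)
  path <- file.path(dir, "cube.obj")
  write_obj(list(vertices = cube$vertices, faces = cube$faces), path)
  rho <- 6.5e-4
  obj <- load_mesh(path, density = rho)
  expect_equal(unname(object_com(obj)), c(12.5, 12.5, 12.5), tolerance = 1e-6)
  expect_equal(obj$mass, rho * 25^3, tolerance = 1e-9)
  # scaling law: x2 in size means x8 mass, x2 extent
  big <- list(vertices = cube$vertices * 2, faces = cube$faces)
  path2 <- file.path(dir, "cube2.obj")
  write_obj(big, path2)
  obj2 <- load_mesh(path2, density = rho)
  expect_equal(obj2$mass / obj$mass, 8, tolerance = 1e-9)
  expect_equal(obj2$d_max / obj$d_max, 2, tolerance = 1e-9)
  expect_error(load_mesh(path, density = 0), "density")
})

test_that("open meshes fall back to the surface centroid with a warning", {
  dir <- withr::local_tempdir()
  cube <- build_polycube(c(0, 0, 0), "wood", triangles_per_face = 2)
  open_mesh <- list(vertices = cube$vertices,
                    faces = cube$faces[-(1:2), ])    # remove one square
  path <- file.path(dir, "open.obj")
  write_obj(open_mesh, path)
  expect_warning(obj <- load_mesh(path, density = 6.5e-4), "not closed")
  expect_equal(unname(graspsel:::mesh_area_centroid(open_mesh)),
               unname(obj$com_local), tolerance = 1e-9)
})

test_that("mesh readers agree across OBJ, STL, and PLY", {
  dir <- withr::local_tempdir()
  dom <- fx_domino()
  mesh <- list(vertices = dom$vertices, faces = dom$faces)
  obj_path <- file.path(dir, "m.obj")
  write_obj(mesh, obj_path)
  # ASCII STL
  stl_path <- file.path(dir, "m.stl")
  fc <- lapply(1:3, function(k) mesh$vertices[mesh$faces[, k], , drop = FALSE])
  stl <- c("solid m",
           unlist(lapply(seq_len(nrow(mesh$faces)), function(f) c(
             "facet normal 0 0 0", "outer loop",
             sprintf("vertex %.9g %.9g %.9g",
                     c(fc[[1]][f, 1], fc[[2]][f, 1], fc[[3]][f, 1]),
                     c(fc[[1]][f, 2], fc[[2]][f, 2], fc[[3]][f, 2]),
                     c(fc[[1]][f, 3], fc[[2]][f, 3], fc[[3]][f, 3])),
             "endloop", "endfacet"))),
           "endsolid m")
  writeLines(stl, stl_path)
  # ASCII PLY
  ply_path <- file.path(dir, "m.ply")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)),
             ply_path)
  for (p in c(obj_path, stl_path, ply_path)) {
    m <- read_mesh(p)
    expect_equal(graspsel:::mesh_signed_volume(m), 2 * 25^3, tolerance = 1e-6)
    expect_equal(sort(graspsel:::face_areas(m)), sort(graspsel:::face_areas(mesh)),
                 tolerance = 1e-6)
  }
})

test_that("candidate contacts exclude table faces and honor subsampling", {
  cube <- build_polycube(c(0, 0, 0), "wood", triangles_per_face = 2)
  cands <- candidate_contacts(cube)
  # resting cube: 5 of 6 faces accessible, 2 triangles each
  expect_identical(cands$n, 10L)
  expect_true(all(cands$positions[, 3] > 1))
  # every accessible candidate's face has a vertex strictly above the table
  zmax <- apply(matrix(cube$vertices[t(cube$faces[cands$parent_face, ]), 3],
                       nrow = 3), 2, max)
  expect_true(all(zmax > 0))
  expect_true(all(abs(sqrt(rowSums(cands$normals^2)) - 1) < 1e-9))
  # triangle centers are the corner means
  fc <- graspsel:::face_centers(list(vertices = cube$vertices,
                                     faces = cube$faces[cands$parent_face, ]))
  expect_equal(cands$positions, fc, tolerance = 1e-12)
  # subsampling: half the candidates, reproducibly
  big <- fx_cands("L")
  half <- candidate_contacts(fx_L(), subsample_pct = 50, seed = 7)
  expect_identical(half$n, as.integer(round(big$n / 2)))
  expect_identical(half$parent_face,
                   candidate_contacts(fx_L(), subsample_pct = 50,
                                      seed = 7)$parent_face)
  # a tolerance swallowing the whole object leaves nothing accessible
  expect_error(candidate_contacts(cube, table_tol = 1000), "accessible")
})

test_that("sparse subsampling spreads candidates beyond 4 mm", {
  # at experiment-3 mesh scale (thousands of triangles), retaining < 5% of
  # candidates leaves mean nearest-neighbour spacing above 4 mm
  obj <- build_polycube(polycube_shape("L")$cube_coords, "wood",
                        triangles_per_face = 128)
  cands <- candidate_contacts(obj, subsample_pct = 5, seed = 2)
  expect_gt(candidate_spacing(cands), 4)
  # at full resolution the surface is sampled much more densely
  full <- candidate_contacts(obj)
  expect_lt(candidate_spacing(full), 4)
})

test_that("layout and pose files round-trip", {
  dir <- withr::local_tempdir()
  lay <- polycube_shape("U")
  expect_identical(nrow(lay$cube_coords), 10L)
  pose <- rigid_transform(rotation_about("z", 90), c(10, 20, 0))
  path <- file.path(dir, "pose.txt")
  write_pose(pose, path)
  back <- read_pose(path)
  expect_equal(back$rotation, pose$rotation, tolerance = 1e-12)
  expect_equal(back$translation, pose$translation, tolerance = 1e-12)
  expect_error(read_polycube_layout(textConnection("1 2 wood")))
})
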