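# Shared fixtures, built once per run and cached. All geometry is generated
# in code; coarse polycube meshes (2 or 8 triangles per face) keep the
# manifold small enough for exhaustive oracles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# standing L, 10 wooden cubes, moderate mesh: the workhorse object
fx_L <- function(tpf = 8) {
  fixture(paste0("L", tpf), function() {
    lay <- polycube_shape("L")
    build_polycube(lay$cube_coords, lay$materials, triangles_per_face = tpf)
  })
}

fx_L_heavy <- function(tpf = 8) {
  fixture(paste0("Lheavy", tpf), function() {
    lay <- polycube_shape("L")
    build_polycube(lay$cube_coords, polycube_materials(10, "bipartite"),
                   triangles_per_face = tpf)
  })
}

# 2-cube domino at coarse resolution: 16 accessible candidates
fx_domino <- function() {
  fixture("domino", function() {
    build_polycube(rbind(c(0, 0, 0), c(1, 0, 0)), "wood",
                   triangles_per_face = 2)
  })
}

fx_cands <- function(obj_name = c("L", "Lheavy", "domino"), tpf = 8) {
  obj_name <- match.arg(obj_name)
  key <- paste0("cands_", obj_name, tpf)
  fixture(key, function() {
    obj <- switch(obj_name, L = fx_L(tpf), Lheavy = fx_L_heavy(tpf),
                  domino = fx_domino())
    candidate_contacts(obj)
  })
}

fx_maps <- function(obj_name = c("L", "Lheavy"), tpf = 8) {
  obj_name <- match.arg(obj_name)
  key <- paste0("maps_", obj_name, tpf)
  fixture(key, function() {
    obj <- if (obj_name == "L") fx_L(tpf) else fx_L_heavy(tpf)
    suppressMessages(penalty_stack(fx_cands(obj_name, tpf), obj))
  })
}

# hand-built candidate set (positions + unit normals), for scalar examples
manual_cands <- function(positions, normals) {
  positions <- matrix(positions, ncol = 3, byrow = TRUE)
  normals <- matrix(normals, ncol = 3, byrow = TRUE)
  normals <- normals / sqrt(rowSums(normals^2))
  structure(list(positions = positions, normals = normals,
                 areas = rep(1, nrow(positions)),
                 parent_face = seq_len(nrow(positions)),
                 table_z = 0, n = nrow(positions)),
            class = "candidate_set")
}
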