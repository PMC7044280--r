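test_that("parameter validation rejects degenerate geometries", {
  expect_error(geometry_params(target_edge = 0), "positive")
  expect_error(geometry_params(perturb_amplitude = 2), "10%")
  expect_error(geometry_params(centrale_semi = c(8, 4.5, 1.5)), "narrower")
  expect_error(geometry_params(facet_fraction = 0), "facet_fraction")
})

test_that("unfused meshes have 3 bodies and all nine region labels", {
  m <- generate_carpal_set(coarse_params(seed = 4), "unfused")
  expect_length(m$bodies, 3L)
  expect_setequal(unique(m$tri_region), carpal_regions())
  expect_setequal(names(m$bodies), c("scaphoid", "centrale", "capitate"))
})

test_that("fusion merges scaphoid and centrale and removes their interface", {
  m <- generate_carpal_set(coarse_params(seed = 4), "fused")
  expect_length(m$bodies, 2L)
  expect_false("contact_scaphoid_centrale" %in% m$tri_region)
  expect_true(all(c("contact_scaphoid_capitate",
                    "contact_centrale_capitate") %in% m$tri_region))
  expect_error(build_contact_interface(m, "contact_scaphoid_centrale"),
               "absent")
})

test_that("generation is deterministic in (params, seed, variant)", {
  p <- coarse_params(seed = 99)
  expect_identical(generate_carpal_set(p, "unfused"),
                   generate_carpal_set(p, "unfused"))
  p2 <- coarse_params(seed = 100)
  expect_false(identical(generate_carpal_set(p, "unfused"),
                         generate_carpal_set(p2, "unfused")))
})

test_that("every body surface is closed and all tets have positive volume", {
  for (variant in c("unfused", "fused")) {
    m <- generate_carpal_set(coarse_params(seed = 2), variant)
    expect_true(all(carpofem:::tet_volumes(m$nodes, m$tets) > 0))
    for (b in m$bodies) {
      tr <- m$tris[m$tri_body == b, , drop = FALSE]
      ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
      key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
      expect_true(all(table(key) == 2L))    # watertight: each edge twice
    }
  }
})

test_that("labelled triangle areas partition each body's surface exactly", {
  m <- generate_carpal_set(coarse_params(seed = 8), "unfused")
  areas <- carpofem:::tri_normals(m$nodes, m$tris)$area
  for (b in m$bodies) {
    tot <- sum(areas[m$tri_body == b])
    by_region <- tapply(areas[m$tri_body == b],
                        m$tri_region[m$tri_body == b], sum)
    expect_equal(sum(by_region), tot, tolerance = 1e-12)
  }
})

test_that("fused body volume matches scaphoid + centrale within 5%", {
  p <- coarse_params(seed = 12)
  mu <- generate_carpal_set(p, "unfused")
  mf <- generate_carpal_set(p, "fused")
  vu <- carpofem:::tet_volumes(mu$nodes, mu$tets)
  vf <- carpofem:::tet_volumes(mf$nodes, mf$tets)
  v_sc <- sum(vu[mu$tet_body == mu$bodies["scaphoid"]])
  v_ce <- sum(vu[mu$tet_body == mu$bodies["centrale"]])
  v_f <- sum(vf[mf$tet_body == mf$bodies["scaphoid_centrale"]])
  expect_lt(abs(v_f - (v_sc + v_ce)) / v_f, 0.05)
})

test_that("contact interfaces pair exactly the coincident nodes", {
  m <- generate_carpal_set(coarse_params(seed = 5), "unfused")
  for (lbl in c("contact_scaphoid_capitate", "contact_scaphoid_centrale",
                "contact_centrale_capitate")) {
    ci <- build_contact_interface(m, lbl)
    # paired coordinates coincide
    d <- m$nodes[ci$pairs[, 1], ] - m$nodes[ci$pairs[, 2], ]
    expect_lt(max(abs(d)), 1e-6)
    # unit normals
    expect_equal(sqrt(rowSums(ci$normals^2)), rep(1, nrow(ci$normals)),
                 tolerance = 1e-12)
    # brute force: all-pairs nearest neighbour over the two node sets
    sel <- m$tri_region == lbl
    bodies <- sort(unique(m$tri_body[sel]))
    na <- sort(unique(as.vector(m$tris[sel & m$tri_body == bodies[1], ])))
    nb <- sort(unique(as.vector(m$tris[sel & m$tri_body == bodies[2], ])))
    dall <- as.matrix(stats::dist(m$nodes[c(na, nb), ]))
    cross <- dall[seq_along(na), length(na) + seq_along(nb), drop = FALSE]
    brute <- cbind(na, nb[apply(cross, 1, which.min)])
    expect_true(all(cross[cbind(seq_along(na),
                                match(ci$pairs[, 2], nb))] < 1e-6))
    expect_equal(unname(ci$pairs[, 1]), na)
    expect_equal(sort(ci$pairs[, 2]), sort(brute[, 2]))
    expect_false(anyDuplicated(ci$pairs[, 2]) > 0)
  }
})

test_that("a fabricated 2-triangle conforming patch yields 4 node pairs", {
  # two square patches (two triangles, four nodes) on coincident planes
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mesh <- list(nodes = nodes,
               tris = rbind(c(1, 2, 3), c(1, 3, 4), c(5, 7, 6), c(5, 8, 7)),
               tri_body = c(1L, 1L, 2L, 2L),
               tri_region = rep("contact_scaphoid_capitate", 4))
  ci <- build_contact_interface(mesh, "contact_scaphoid_capitate")
  expect_equal(nrow(ci$pairs), 4L)
  expect_equal(unname(ci$pairs[, 2] - ci$pairs[, 1]), rep(4L, 4))
})

test_that("mesh quality reports volume CV and flags quasi-ideal meshes", {
  # identical Kuhn tets from a uniform grid: CV exactly 0
  g <- seq(0, 2, by = 1)
  b <- carpofem:::block_mesh(g, g, g)
  q <- mesh_quality(list(nodes = b$nodes,
                         tets = carpofem:::orient_tets(b$nodes, b$tets)))
  expect_equal(q$volume_cv, 0)
  expect_true(q$qim)
  expect_equal(q$n_elements, 48L)
  # two tets with volumes 1 and 3: population CV = 0.5
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 6),
                 c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 2))
  two <- list(nodes = nodes, tets = rbind(1:4, 5:8))
  expect_equal(mesh_quality(two)$volume_cv, 0.5)
  # degenerate element is an error
  bad <- list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
              tets = matrix(1:4, 1))
  expect_error(mesh_quality(bad), "volume")
  expect_error(mesh_quality(list(nodes = nodes,
                                 tets = matrix(integer(0), 0, 4))),
               "no tetrahedra")
})

test_that("carpal meshes at the default edge length are quasi-ideal", {
  m <- generate_carpal_set(coarse_params(seed = 3), "unfused")
  q <- mesh_quality(m)
  expect_true(q$qim)
  expect_gt(q$volume_cv, 0)        # perturbed, hence non-uniform
  expect_gt(q$min_dihedral_deg, 10)
  expect_lt(q$max_dihedral_deg, 170)
})
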