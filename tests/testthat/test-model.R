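test_that("total load reproduces the published species loads exactly", {
  expect_equal(compute_total_load(77.9), 152.79)
  expect_equal(compute_total_load(9.5), 18.63)
  expect_equal(compute_total_load(0), 0)
  expect_error(compute_total_load(-1), "non-negative")
  expect_error(compute_total_load(50, fraction = 1.2), "fraction")
})

test_that("load case direction follows the tilt rotation", {
  lc0 <- make_load_case(59.7, tilt_deg = 0)
  expect_identical(lc0$direction, c(0, 0, -1))
  lc5 <- make_load_case(59.7, tilt_deg = 5)
  expect_equal(sum(lc5$direction * lc0$direction), 0.996195,
               tolerance = 5e-7)
  expect_equal(sqrt(sum(lc5$direction^2)), 1, tolerance = 1e-12)
  expect_error(make_load_case(59.7, tilt_deg = 95), "tilt")
  expect_error(make_load_case(59.7, partition = "magic"), "unknown")
  expect_error(make_load_case(59.7, partition = c(0.7, 0.7)), "summing")
})

test_that("ligament strands reproduce the total rigidity by composition", {
  mu <- generate_carpal_set(coarse_params(seed = 6), "unfused")
  mf <- generate_carpal_set(coarse_params(seed = 6), "fused")

  direct <- distribute_ligament_springs(mf, ligament_spec(40, 8, "direct"))
  expect_equal(nrow(direct$springs), 8L)
  expect_true(all(direct$springs$k == 5))
  expect_equal(reduce_spring_set(direct), 40, tolerance = 1e-12)

  serial1 <- distribute_ligament_springs(mu, ligament_spec(40, 1, "serial"))
  expect_equal(nrow(serial1$springs), 2L)
  expect_true(all(serial1$springs$k == 80))
  expect_equal(reduce_spring_set(serial1), 40, tolerance = 1e-12)

  single <- distribute_ligament_springs(mf, ligament_spec(40, 1, "direct"))
  expect_equal(single$springs$k, 40)

  for (n in c(3, 8, 13)) {
    ss <- distribute_ligament_springs(mu, ligament_spec(37.5, n, "serial"))
    expect_equal(reduce_spring_set(ss), 37.5, tolerance = 1e-9 * 37.5)
  }
  # serial topology needs the centrale patch, absent from fused meshes
  expect_error(distribute_ligament_springs(mf, ligament_spec(40, 4, "serial")),
               "absent")
})

test_that("foundation springs partition the patch stiffness by area", {
  m <- generate_carpal_set(coarse_params(seed = 6), "unfused")
  for (patch in c("lat_scaphoid_lunate", "lat_capitate_hamate",
                  "lat_capitate_trapezoid")) {
    fs <- build_foundation_springs(m, patch, 20.5)
    expect_equal(sum(fs$grounded$k), 20.5, tolerance = 1e-9 * 20.5)
    expect_true(all(fs$grounded$k > 0))
    # stiffness shares equal brute-force tributary areas
    sel <- m$tri_patch == patch
    tris <- m$tris[sel, , drop = FALSE]
    ar <- carpofem:::tri_normals(m$nodes, tris)$area
    trib <- tapply(rep(ar / 3, 3), as.vector(tris), sum)
    trib <- trib[match(fs$grounded$node, as.integer(names(trib)))]
    expect_equal(fs$grounded$k / sum(fs$grounded$k),
                 as.numeric(trib / sum(trib)), tolerance = 1e-12)
  }
  expect_error(build_foundation_springs(m, "no_such_patch"), "absent")
  expect_error(build_foundation_springs(m, "lat_capitate_hamate", 0),
               "positive")
})

test_that("assembled load vector resultant equals F times direction", {
  m <- generate_carpal_set(coarse_params(seed = 7), "unfused")
  for (tilt in c(0, 5)) {
    lc <- make_load_case(77.9, tilt_deg = tilt)
    sys <- assemble_model(m, material_set(), ligament_spec(40, 4, "serial"),
                          default_boundary(m), lc)
    resultant <- colSums(matrix(sys$f, ncol = 3, byrow = TRUE))
    expect_equal(resultant, lc$F * lc$direction, tolerance = 1e-9 * lc$F)
  }
  # a 60:40 split leaves the resultant unchanged
  lc2 <- make_load_case(77.9, partition = c(0.6, 0.4))
  sys2 <- assemble_model(m, material_set(), NULL, default_boundary(m), lc2)
  expect_equal(colSums(matrix(sys2$f, ncol = 3, byrow = TRUE)),
               lc2$F * lc2$direction, tolerance = 1e-9 * lc2$F)
})

test_that("stiffness is symmetric and fixed DOFs sit on the right bodies", {
  for (variant in c("unfused", "fused")) {
    m <- generate_carpal_set(coarse_params(seed = 7), variant)
    sys <- assemble_model(m, material_set(),
                          ligament_spec(40, 4, if (variant == "fused")
                            "direct" else "serial"),
                          default_boundary(m), make_load_case(59.7))
    asym <- max(abs(sys$K - Matrix::t(sys$K))) / max(abs(sys$K))
    expect_lt(asym, 1e-10)
    fix_nodes <- unique((sys$fixed_dofs - 1L) %/% 3L + 1L)
    fb <- sort(unique(m$node_body[fix_nodes]))
    if (variant == "unfused") {
      expect_equal(fb, unname(m$bodies[c("centrale", "capitate")]))
    } else {
      expect_equal(fb, unname(m$bodies[c("scaphoid_centrale", "capitate")]))
    }
  }
})

test_that("an unconstrained single elastic body has exactly 6 rigid modes", {
  g <- seq(0, 2, length.out = 3)
  b <- carpofem:::block_mesh(g, g, g)
  tets <- carpofem:::orient_tets(b$nodes, b$tets)
  tr <- carpofem:::tet_triplets(b$nodes, tets, 100, 0.25)
  n <- 3 * nrow(b$nodes)
  K <- as.matrix(Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                      dims = c(n, n)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
})

test_that("fused and unfused assemblies share everything but topology", {
  p <- coarse_params(seed = 10)
  cfg <- coarse_config()
  ru <- solve_carpal_model(cfg, 59.7, "unfused", 0, seed = 10)
  rf <- solve_carpal_model(cfg, 59.7, "fused", 0, seed = 10)
  expect_identical(ru$system$load_case$F, rf$system$load_case$F)
  expect_identical(ru$system$materials, rf$system$materials)
  expect_equal(sum(ru$system$grounded$k), sum(rf$system$grounded$k),
               tolerance = 1e-12)
})
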