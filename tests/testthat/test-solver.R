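test_that("tet stiffness is symmetric with exactly six zero-energy modes", {
  set.seed(1)
  for (r in 1:5) {
    co <- matrix(stats::runif(12, -2, 2), 4, 3)
    v <- carpofem:::tet_volumes(co, matrix(1:4, 1))
    if (v < 0) co <- co[c(2, 1, 3, 4), ]
    if (abs(v) < 1e-3) next
    K <- tet_stiffness(co, 1000, 0.3)
    expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
    expect_gt(min(ev), -1e-9 * max(ev))     # positive semidefinite
  }
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(tet_stiffness(flat, 1000, 0.3), "degenerate")
})

test_that("membrane stiffness scales with thickness and kills rigid modes", {
  co <- rbind(c(0, 0, 0), c(2, 0, 1), c(0, 2, 0.5))
  K1 <- membrane_stiffness(co, 100, 0.3, 0.5)
  K2 <- membrane_stiffness(co, 100, 0.3, 1.0)
  expect_equal(2 * K1, K2, tolerance = 1e-12)
  expect_lt(max(abs(K1 %*% rep(c(1, -2, 3), 3))), 1e-10)
  # uniaxial in-plane stretch, nu = 0: strain energy = E t eps^2 A / 2
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Km <- membrane_stiffness(tri, 200, 0, 0.5)
  eps <- 0.01
  u <- as.vector(t(cbind(eps * tri[, 1], 0, 0)))
  expect_equal(as.numeric(0.5 * t(u) %*% Km %*% u),
               0.5 * 200 * 0.5 * eps^2 * 0.5, tolerance = 1e-12)
  expect_error(membrane_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                  100, 0.3, 1), "zero-area")
})

test_that("constant-strain patch test: uniaxial bar matches sigma L / E", {
  bar <- carpofem:::uniaxial_bar_fixture(n = 2)
  expect_equal(bar$tip, bar$expected, tolerance = 1e-10)
  eq <- check_equilibrium(bar$sys, bar$disp)
  expect_lt(eq$rel_error, 1e-8)
})

test_that("a grounded spring deflects by F / k", {
  spr <- carpofem:::spring_fixture(k = 40, F = 20)
  expect_equal(spr$u, 0.5, tolerance = 1e-12)
})

test_that("cantilever tip deflection converges monotonically to PL^3/3EI", {
  tips <- vapply(list(c(10, 2), c(20, 4), c(40, 8)), function(m)
    carpofem:::cantilever_fixture(n_len = m[1], n_th = m[2])$tip, numeric(1))
  expect_true(all(diff(tips) > 0))          # stiffness decreases on refining
  expect_true(all(tips < 0.2012))           # bounded by the elasticity limit
})

test_that("zero load produces identically zero displacement", {
  m <- generate_carpal_set(coarse_params(seed = 3), "unfused")
  sys <- assemble_model(m, material_set(), NULL, default_boundary(m), NULL)
  disp <- solve_linear(sys)
  expect_equal(max(abs(disp$u)), 0)
})

test_that("sparse solution matches a dense direct solve on a small model", {
  g <- seq(0, 4, length.out = 3)
  b <- carpofem:::block_mesh(g, g, g)    # 27 nodes, 81 DOFs
  tets <- carpofem:::orient_tets(b$nodes, b$tets)
  tr <- carpofem:::tet_triplets(b$nodes, tets, 500, 0.3)
  n <- 3 * nrow(b$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  bot <- which(abs(b$nodes[, 3]) < 1e-9)
  fixed <- c(carpofem:::dof_of(bot, 1L), carpofem:::dof_of(bot, 2L),
             carpofem:::dof_of(bot, 3L))
  set.seed(5)
  f <- numeric(n)
  topn <- which(abs(b$nodes[, 3] - 4) < 1e-9)
  f[carpofem:::dof_of(topn, 3L)] <- stats::runif(length(topn), -1, 1)
  sys <- structure(list(K = K, f = f, fixed_dofs = fixed, ties = NULL,
                        grounded = NULL, ndof = n, nnode = nrow(b$nodes)),
                   class = "linear_system")
  red <- apply_constraints(sys)
  u_sparse <- solve_linear(red)$u_dof
  u_dense <- numeric(n)
  u_dense[red$masters] <- solve(as.matrix(red$K), red$f)
  expect_equal(u_sparse, u_dense, tolerance = 1e-10)
})

test_that("ties forbid normal gaps but leave tangential sliding free", {
  m <- generate_carpal_set(coarse_params(seed = 9), "unfused")
  cfg <- coarse_config()
  res <- solve_carpal_model(cfg, 77.9, "unfused", 0, seed = 9)
  sys <- res$system
  u <- res$disp$u
  nrm <- cbind(sys$ties$nx, sys$ties$ny, sys$ties$nz)
  rel <- u[sys$ties$node_a, , drop = FALSE] - u[sys$ties$node_b, , drop = FALSE]
  gap <- abs(rowSums(rel * nrm))
  expect_lt(max(gap), 1e-10)
  slip <- sqrt(rowSums((rel - rowSums(rel * nrm) * nrm)^2))
  expect_gt(max(slip), 1e-6)               # sliding is genuinely free
})

test_that("the reduced stiffness of a supported two-body model is SPD", {
  # two stacked single-hex blocks tied across the interface
  g <- c(0, 1)
  lo <- carpofem:::block_mesh(g, g, g)
  hi <- carpofem:::block_mesh(g, g, c(1, 2))
  nodes <- rbind(lo$nodes, hi$nodes)
  tets <- rbind(carpofem:::orient_tets(lo$nodes, lo$tets),
                carpofem:::orient_tets(hi$nodes, hi$tets) + nrow(lo$nodes))
  tr <- carpofem:::tet_triplets(nodes, tets, 100, 0.3)
  n <- 3 * nrow(nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  bot <- which(abs(nodes[, 3]) < 1e-9 & seq_len(nrow(nodes)) <= 8)
  fixed <- as.vector(vapply(1:3, function(a)
    carpofem:::dof_of(bot, a), integer(length(bot))))
  ia <- which(abs(nodes[, 3] - 1) < 1e-9 & seq_len(nrow(nodes)) <= 8)
  ib <- 8L + which(abs(hi$nodes[, 3] - 1) < 1e-9)
  key <- function(i) paste(round(nodes[i, 1], 8), round(nodes[i, 2], 8))
  ib <- ib[match(key(ia), key(ib))]
  ties <- data.frame(node_a = ia, node_b = ib, nx = 0, ny = 0, nz = 1)
  sys <- structure(list(K = K, f = numeric(n), fixed_dofs = fixed,
                        ties = ties, grounded = NULL, ndof = n,
                        nnode = nrow(nodes)), class = "linear_system")
  red <- apply_constraints(sys)
  # upper body is held only through the normal ties: x/y rigid modes remain,
  # so add weak grounded springs as the lateral restraint would
  ev <- eigen(as.matrix(red$K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(sum(ev < 1e-8 * max(ev)), 0)   # sliding modes are free
  # with both tangential DOFs of the upper block restrained it becomes SPD
  extra <- c(carpofem:::dof_of(ib, 1L), carpofem:::dof_of(ib, 2L))
  sys2 <- sys; sys2$fixed_dofs <- c(fixed, extra)
  red2 <- apply_constraints(sys2)
  ev2 <- eigen(as.matrix(red2$K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev2), 0)
})

test_that("every carpal solve satisfies global equilibrium", {
  cfg <- coarse_config()
  for (variant in c("unfused", "fused")) {
    res <- solve_carpal_model(cfg, 170.4, variant, 5, seed = 3)
    expect_lt(res$diag$equilibrium_error, 1e-8)
    expect_lt(res$diag$residual, 1e-8)
  }
})

test_that("a floating (unsupported) model raises a singularity error", {
  g <- seq(0, 1, length.out = 2)
  b <- carpofem:::block_mesh(g, g, g)
  tets <- carpofem:::orient_tets(b$nodes, b$tets)
  tr <- carpofem:::tet_triplets(b$nodes, tets, 100, 0.3)
  n <- 3 * nrow(b$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  f <- numeric(n); f[3] <- 1
  sys <- structure(list(K = K, f = f, fixed_dofs = integer(0), ties = NULL,
                        grounded = NULL, ndof = n, nnode = nrow(b$nodes)),
                   class = "linear_system")
  expect_error(solve_linear(sys), "singular")
})
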