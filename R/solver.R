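# Linear-static FE core: element stiffness, constraint elimination, solve.
# Unit system mm-N-MPa: moduli in MPa, lengths mm, forces N, stiffness N/mm.

lame <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

dof_of <- function(node, axis) 3L * (node - 1L) + axis

#' Stiffness matrix of a constant-strain tetrahedron
#'
#' Linear (4-node) tetrahedral element for isotropic linear elasticity,
#' used for the cancellous bone volume. Returns the 12 x 12 symmetric
#' positive-semidefinite stiffness in global coordinates with DOF order
#' (node1 x,y,z, node2 x,y,z, ...).
#'
#' @param coords 4 x 3 matrix of node coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 12 x 12 numeric matrix (N/mm).
#' @export
tet_stiffness <- function(coords, E, nu) {
  trip <- tet_triplets(coords[1:4, , drop = FALSE],
                       matrix(1:4, 1), E, nu, local = TRUE)
  K <- matrix(0, 12, 12)
  K[cbind(trip$i, trip$j)] <- trip$x
  K
}

# vectorised triplets for all tets; local=TRUE numbers DOFs 1..12 per element
tet_triplets <- function(nodes, tets, E, nu, local = FALSE) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  crossv <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- crossv(e2, e3)
  det <- rowSums(e1 * c23)              # 6V
  if (any(det <= 0)) stop("degenerate or inverted tetrahedron")
  V <- det / 6
  g <- vector("list", 4)                # shape-function gradients
  g[[2]] <- c23 / det
  g[[3]] <- crossv(e3, e1) / det
  g[[4]] <- crossv(e1, e2) / det
  g[[1]] <- -(g[[2]] + g[[3]] + g[[4]])
  lm <- lame(E, nu)
  ne <- nrow(tets)
  ii <- jj <- integer(0); xx <- numeric(0)
  out_i <- vector("list", 144); out_j <- vector("list", 144)
  out_x <- vector("list", 144); ctr <- 0L
  for (a in 1:4) for (b in 1:4) {
    gab <- rowSums(g[[a]] * g[[b]])
    for (al in 1:3) for (be in 1:3) {
      val <- V * (lm$lambda * g[[a]][, al] * g[[b]][, be] +
                  lm$mu * g[[a]][, be] * g[[b]][, al] +
                  (al == be) * lm$mu * gab)
      ctr <- ctr + 1L
      if (local) {
        out_i[[ctr]] <- rep.int(3L * (a - 1L) + al, ne)
        out_j[[ctr]] <- rep.int(3L * (b - 1L) + be, ne)
      } else {
        out_i[[ctr]] <- dof_of(tets[, a], al)
        out_j[[ctr]] <- dof_of(tets[, b], be)
      }
      out_x[[ctr]] <- val
    }
  }
  list(i = unlist(out_i), j = unlist(out_j), x = unlist(out_x),
       volumes = V)
}

#' Stiffness matrix of a constant-strain membrane triangle
#'
#' Plane-stress constant-strain triangle embedded in 3D, used for the
#' cortical-bone and cartilage surface layers. Membrane only (no bending):
#' the layers are thin and continuously bonded to the underlying solid, so
#' in-plane stiffness dominates. Returns the 9 x 9 global stiffness with
#' DOF order (node1 x,y,z, ...); out-of-plane drilling/normal motion
#' carries no stiffness.
#'
#' @param coords 3 x 3 matrix of node coordinates (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param thickness Layer thickness (mm); stiffness scales linearly in it.
#' @return 9 x 9 numeric matrix (N/mm).
#' @export
membrane_stiffness <- function(coords, E, nu, thickness) {
  trip <- membrane_triplets(coords[1:3, , drop = FALSE], matrix(1:3, 1),
                            E, nu, thickness, local = TRUE)
  K <- matrix(0, 9, 9)
  K[cbind(trip$i, trip$j)] <- trip$x
  K
}

membrane_triplets <- function(nodes, tris, E, nu, thickness, local = FALSE) {
  p1 <- nodes[tris[, 1], , drop = FALSE]
  u <- nodes[tris[, 2], , drop = FALSE] - p1
  v <- nodes[tris[, 3], , drop = FALSE] - p1
  nz <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  a2 <- sqrt(rowSums(nz^2))             # 2A
  if (any(a2 <= 0)) stop("zero-area membrane triangle")
  A <- a2 / 2
  le1 <- sqrt(rowSums(u^2))
  ex <- u / le1
  ez <- nz / a2
  ey <- cbind(ez[, 2] * ex[, 3] - ez[, 3] * ex[, 2],
              ez[, 3] * ex[, 1] - ez[, 1] * ex[, 3],
              ez[, 1] * ex[, 2] - ez[, 2] * ex[, 1])
  # local planar coordinates of the three nodes
  x1 <- 0; y1 <- 0
  x2 <- le1; y2 <- 0
  x3 <- rowSums(v * ex); y3 <- rowSums(v * ey)
  # CST coefficients b_i = dN_i/dx, c_i = dN_i/dy
  bb <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  d11 <- E / (1 - nu^2); d12 <- nu * d11; d33 <- E / (2 * (1 + nu))
  tA <- thickness * A
  ne <- nrow(tris)
  out_i <- vector("list", 81); out_j <- vector("list", 81)
  out_x <- vector("list", 81); ctr <- 0L
  for (a in 1:3) for (b in 1:3) {
    k11 <- tA * (bb[, a] * d11 * bb[, b] + cc[, a] * d33 * cc[, b])
    k12 <- tA * (bb[, a] * d12 * cc[, b] + cc[, a] * d33 * bb[, b])
    k21 <- tA * (cc[, a] * d12 * bb[, b] + bb[, a] * d33 * cc[, b])
    k22 <- tA * (cc[, a] * d11 * cc[, b] + bb[, a] * d33 * bb[, b])
    for (al in 1:3) for (be in 1:3) {
      val <- k11 * ex[, al] * ex[, be] + k12 * ex[, al] * ey[, be] +
             k21 * ey[, al] * ex[, be] + k22 * ey[, al] * ey[, be]
      ctr <- ctr + 1L
      if (local) {
        out_i[[ctr]] <- rep.int(3L * (a - 1L) + al, ne)
        out_j[[ctr]] <- rep.int(3L * (b - 1L) + be, ne)
      } else {
        out_i[[ctr]] <- dof_of(tris[, a], al)
        out_j[[ctr]] <- dof_of(tris[, b], be)
      }
      out_x[[ctr]] <- val
    }
  }
  list(i = unlist(out_i), j = unlist(out_j), x = unlist(out_x), areas = A)
}

# triplets for axial two-node springs (k N/mm along the chord)
spring_triplets <- function(nodes, springs) {
  if (is.null(springs) || nrow(springs) == 0)
    return(list(i = integer(0), j = integer(0), x = numeric(0)))
  a <- springs$node_a; b <- springs$node_b; k <- springs$k
  d <- nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0)) stop("zero-length ligament spring")
  d <- d / len
  ii <- jj <- vector("list", 36); xx <- vector("list", 36); ctr <- 0L
  ends <- list(a, b)
  for (ea in 1:2) for (eb in 1:2) {
    sgn <- if (ea == eb) 1 else -1
    for (al in 1:3) for (be in 1:3) {
      ctr <- ctr + 1L
      ii[[ctr]] <- dof_of(ends[[ea]], al)
      jj[[ctr]] <- dof_of(ends[[eb]], be)
      xx[[ctr]] <- sgn * k * d[, al] * d[, be]
    }
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

# triplets for grounded springs acting along a fixed direction per node
grounded_triplets <- function(grounded) {
  if (is.null(grounded) || nrow(grounded) == 0)
    return(list(i = integer(0), j = integer(0), x = numeric(0)))
  ii <- jj <- vector("list", 9); xx <- vector("list", 9); ctr <- 0L
  d <- as.matrix(grounded[, c("dx", "dy", "dz")])
  for (al in 1:3) for (be in 1:3) {
    ctr <- ctr + 1L
    ii[[ctr]] <- dof_of(grounded$node, al)
    jj[[ctr]] <- dof_of(grounded$node, be)
    xx[[ctr]] <- grounded$k * d[, al] * d[, be]
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

#' Eliminate fixed and tie constraints from a linear system
#'
#' Applies zero-displacement supports and non-separation contact ties by
#' master-slave elimination: each tie enforces `(u_A - u_B) . n = 0`
#' (no normal gap) while leaving tangential relative sliding free. The
#' elimination builds a sparse null-space basis `T` such that `u = T q`,
#' keeping the reduced stiffness symmetric positive definite for any
#' properly supported model. Constraints that become redundant after
#' substitution (e.g. at nodes shared by two interfaces) are detected and
#' dropped; a tie with a degenerate normal is an error.
#'
#' @param system A `linear_system` from [assemble_model()].
#' @return A `reduced_system`: reduced stiffness and load, the basis `T`,
#'   master DOF indices, and the originating system.
#' @export
apply_constraints <- function(system) {
  ndof <- system$ndof
  is_elim <- logical(ndof)
  expr_dofs <- vector("list", ndof)
  expr_coefs <- vector("list", ndof)
  order_elim <- integer(0)

  fixed <- unique(system$fixed_dofs)
  is_elim[fixed] <- TRUE
  for (d in fixed) {
    expr_dofs[[d]] <- integer(0)
    expr_coefs[[d]] <- numeric(0)
  }
  order_elim <- fixed

  substitute_expr <- function(dofs, coefs) {
    while (length(dofs) && any(is_elim[dofs])) {
      nd <- integer(0); nc <- numeric(0)
      for (q in seq_along(dofs)) {
        d <- dofs[q]
        if (is_elim[d]) {
          nd <- c(nd, expr_dofs[[d]])
          nc <- c(nc, coefs[q] * expr_coefs[[d]])
        } else {
          nd <- c(nd, d); nc <- c(nc, coefs[q])
        }
      }
      coefs <- as.numeric(rowsum(nc, nd))
      dofs <- sort(unique(nd))
      keep <- abs(coefs) > 1e-13
      dofs <- dofs[keep]; coefs <- coefs[keep]
    }
    list(dofs = dofs, coefs = coefs)
  }

  ties <- system$ties
  if (!is.null(ties) && nrow(ties) > 0) {
    for (r in seq_len(nrow(ties))) {
      n <- c(ties$nx[r], ties$ny[r], ties$nz[r])
      dofs <- c(dof_of(ties$node_a[r], 1:3), dof_of(ties$node_b[r], 1:3))
      coefs <- c(n, -n)
      keep <- abs(coefs) > 1e-13
      s <- substitute_expr(dofs[keep], coefs[keep])
      if (!length(s$dofs)) next             # redundant after substitution
      piv <- which.max(abs(s$coefs))
      if (abs(s$coefs[piv]) < 1e-10)
        stop("degenerate tie constraint (near-zero normal component)")
      d <- s$dofs[piv]
      expr_dofs[[d]] <- s$dofs[-piv]
      expr_coefs[[d]] <- -s$coefs[-piv] / s$coefs[piv]
      is_elim[d] <- TRUE
      order_elim <- c(order_elim, d)
    }
  }

  # back-substitute so every elimination expression uses master DOFs only
  for (d in rev(order_elim)) {
    dofs <- expr_dofs[[d]]
    if (!length(dofs) || !any(is_elim[dofs])) next
    s <- substitute_expr(dofs, expr_coefs[[d]])
    expr_dofs[[d]] <- s$dofs
    expr_coefs[[d]] <- s$coefs
  }

  masters <- which(!is_elim)
  col_of <- integer(ndof)
  col_of[masters] <- seq_along(masters)
  ed <- unlist(expr_dofs[order_elim])
  ti <- c(masters, rep.int(order_elim,
                           vapply(expr_dofs[order_elim], length, integer(1))))
  tj <- c(col_of[masters], col_of[ed])
  tx <- c(rep(1, length(masters)), unlist(expr_coefs[order_elim]))
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(ndof, length(masters)))
  K_red <- Matrix::forceSymmetric(Matrix::crossprod(T, system$K %*% T))
  f_red <- as.numeric(Matrix::crossprod(T, system$f))
  structure(list(K = K_red, f = f_red, T = T, masters = masters,
                 n_constraints = ndof - length(masters),
                 system = system),
            class = "reduced_system")
}

#' Solve a reduced linear-static system
#'
#' Sparse Cholesky factorisation of the constrained stiffness, with the
#' displacement field mapped back to all nodes through the constraint
#' basis, support reactions recovered at fixed DOFs, and the relative
#' residual checked against `tol`.
#'
#' @param reduced A `reduced_system` from [apply_constraints()], or a
#'   `linear_system` (constraints are applied first).
#' @param tol Maximum admissible relative residual.
#' @return A `displacement_field`: per-node displacements (mm), reactions
#'   at fixed DOFs (N), solver residual, and DOF counts.
#' @export
solve_linear <- function(reduced, tol = 1e-8) {
  if (inherits(reduced, "linear_system")) reduced <- apply_constraints(reduced)
  K <- reduced$K; f <- reduced$f
  if (length(f) == 0L) {
    u_full <- numeric(reduced$system$ndof)
  } else {
    ch <- tryCatch(suppressWarnings(Matrix::Cholesky(K, LDL = FALSE,
                                                     perm = TRUE)),
                   error = function(e)
                     stop("singular reduced system (unconstrained ",
                          "rigid-body mode or disconnected part): ",
                          conditionMessage(e)))
    q <- as.numeric(Matrix::solve(ch, f))
    r <- as.numeric(K %*% q) - f
    fn <- sqrt(sum(f^2))
    res <- if (fn > 0) sqrt(sum(r^2)) / fn else sqrt(sum(r^2))
    if (res > tol) {
      dq <- as.numeric(Matrix::solve(ch, -r))      # one refinement step
      q <- q + dq
      r <- as.numeric(K %*% q) - f
      res <- if (fn > 0) sqrt(sum(r^2)) / fn else sqrt(sum(r^2))
      if (res > tol) stop("solver residual ", format(res), " exceeds ", tol)
    }
    u_full <- as.numeric(reduced$T %*% q)
  }
  sys <- reduced$system
  resid_full <- as.numeric(sys$K %*% u_full) - sys$f
  fixed <- unique(sys$fixed_dofs)
  reactions <- resid_full[fixed]
  res <- if (length(f)) res else 0
  structure(list(
    u = matrix(u_full, ncol = 3, byrow = TRUE),
    u_dof = u_full,
    reactions = reactions, fixed_dofs = fixed,
    residual = res,
    ndof = sys$ndof, n_reduced = length(f)),
    class = "displacement_field")
}

#' Check global force equilibrium of a solved model
#'
#' Sums the applied loads, the reactions at fixed supports and the forces
#' exerted by the grounded foundation springs; a correct solve balances
#' them to numerical precision in every axis.
#'
#' @param system The `linear_system` that was solved.
#' @param disp The corresponding `displacement_field`.
#' @return List with per-axis `applied`, `reactions`, `foundation` force
#'   sums and the relative imbalance `rel_error`.
#' @export
check_equilibrium <- function(system, disp) {
  fmat <- matrix(system$f, ncol = 3, byrow = TRUE)
  applied <- colSums(fmat)
  # support DOFs: fixed supports plus contact-tie nodes (a tie adjoining a
  # fixed region transmits reaction force into the fixture)
  sup <- unique(system$fixed_dofs)
  if (!is.null(system$ties) && nrow(system$ties))
    sup <- unique(c(sup,
                    dof_of(rep(system$ties$node_a, each = 3L), 1:3),
                    dof_of(rep(system$ties$node_b, each = 3L), 1:3)))
  r_full <- as.numeric(system$K %*% disp$u_dof) - system$f
  rx <- numeric(3)
  ax <- (sup - 1L) %% 3L + 1L
  for (k in 1:3) rx[k] <- sum(r_full[sup[ax == k]])
  found <- numeric(3)
  g <- system$grounded
  if (!is.null(g) && nrow(g)) {
    d <- as.matrix(g[, c("dx", "dy", "dz")])
    un <- disp$u[g$node, , drop = FALSE]
    fmag <- -g$k * rowSums(d * un)
    found <- colSums(fmag * d)
  }
  tot <- applied + rx + found
  scale <- max(sqrt(sum(applied^2)), 1e-12)
  list(applied = applied, reactions = rx, foundation = found,
       rel_error = sqrt(sum(tot^2)) / scale)
}
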