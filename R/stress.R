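# Stress recovery and mesh-weighted statistics (MWAM / MWM) per bone.

#' Recover element stresses from a displacement field
#'
#' Constitutive stress per element: constant-strain recovery on the
#' cancellous tetrahedra and on both membrane layers (cortical bone,
#' cartilage) of every boundary triangle. Element weights are volume for
#' solids and area times thickness for membranes, the sizes used by the
#' mesh-weighted statistics. Rigid-body displacement fields recover zero
#' stress.
#'
#' @param mesh A `carpal_mesh`.
#' @param materials A [material_set()].
#' @param disp A `displacement_field` (or an `ndof` displacement vector).
#' @return A `stress_field` data frame: six tensor components (MPa,
#'   order xx, yy, zz, xy, yz, zx), `weight`, `body`, `tissue`.
#' @export
recover_stress <- function(mesh, materials, disp) {
  u <- if (inherits(disp, "displacement_field")) disp$u_dof
       else as.numeric(disp)
  if (length(u) != 3L * nrow(mesh$nodes))
    stop("displacement field length does not match the mesh DOFs")
  um <- matrix(u, ncol = 3, byrow = TRUE)

  tet_sigma <- function(nodes, tets, E, nu) {
    p1 <- nodes[tets[, 1], , drop = FALSE]
    e1 <- nodes[tets[, 2], , drop = FALSE] - p1
    e2 <- nodes[tets[, 3], , drop = FALSE] - p1
    e3 <- nodes[tets[, 4], , drop = FALSE] - p1
    crossv <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
    c23 <- crossv(e2, e3)
    det <- rowSums(e1 * c23)
    g <- vector("list", 4)
    g[[2]] <- c23 / det
    g[[3]] <- crossv(e3, e1) / det
    g[[4]] <- crossv(e1, e2) / det
    g[[1]] <- -(g[[2]] + g[[3]] + g[[4]])
    gradu <- array(0, c(nrow(tets), 3, 3))     # du_beta / dx_alpha
    for (a in 1:4) {
      ua <- um[tets[, a], , drop = FALSE]
      for (al in 1:3) for (be in 1:3)
        gradu[, al, be] <- gradu[, al, be] + g[[a]][, al] * ua[, be]
    }
    lm <- lame(E, nu)
    tr <- gradu[, 1, 1] + gradu[, 2, 2] + gradu[, 3, 3]
    sig <- cbind(xx = lm$lambda * tr + 2 * lm$mu * gradu[, 1, 1],
                 yy = lm$lambda * tr + 2 * lm$mu * gradu[, 2, 2],
                 zz = lm$lambda * tr + 2 * lm$mu * gradu[, 3, 3],
                 xy = lm$mu * (gradu[, 1, 2] + gradu[, 2, 1]),
                 yz = lm$mu * (gradu[, 2, 3] + gradu[, 3, 2]),
                 zx = lm$mu * (gradu[, 3, 1] + gradu[, 1, 3]))
    list(sigma = sig, weight = det / 6)
  }

  mem_sigma <- function(nodes, tris, E, nu, thickness) {
    p1 <- nodes[tris[, 1], , drop = FALSE]
    uu <- nodes[tris[, 2], , drop = FALSE] - p1
    vv <- nodes[tris[, 3], , drop = FALSE] - p1
    nz <- cbind(uu[, 2] * vv[, 3] - uu[, 3] * vv[, 2],
                uu[, 3] * vv[, 1] - uu[, 1] * vv[, 3],
                uu[, 1] * vv[, 2] - uu[, 2] * vv[, 1])
    a2 <- sqrt(rowSums(nz^2))
    le1 <- sqrt(rowSums(uu^2))
    ex <- uu / le1
    ez <- nz / a2
    ey <- cbind(ez[, 2] * ex[, 3] - ez[, 3] * ex[, 2],
                ez[, 3] * ex[, 1] - ez[, 1] * ex[, 3],
                ez[, 1] * ex[, 2] - ez[, 2] * ex[, 1])
    x2 <- le1; x3 <- rowSums(vv * ex); y3 <- rowSums(vv * ey)
    bb <- cbind(0 - y3, y3 - 0, rep(0, nrow(tris))) / a2
    cc <- cbind(x3 - x2, 0 - x3, x2 - 0) / a2
    # local in-plane displacements per node
    eps <- matrix(0, nrow(tris), 3)            # exx, eyy, gxy (local)
    for (a in 1:3) {
      ua <- um[tris[, a], , drop = FALSE]
      ul <- rowSums(ua * ex); vl <- rowSums(ua * ey)
      eps[, 1] <- eps[, 1] + bb[, a] * ul
      eps[, 2] <- eps[, 2] + cc[, a] * vl
      eps[, 3] <- eps[, 3] + cc[, a] * ul + bb[, a] * vl
    }
    d11 <- E / (1 - nu^2); d12 <- nu * d11; d33 <- E / (2 * (1 + nu))
    sl <- cbind(d11 * eps[, 1] + d12 * eps[, 2],
                d12 * eps[, 1] + d11 * eps[, 2],
                d33 * eps[, 3])
    # rotate the plane-stress tensor to global components
    sig <- cbind(
      xx = sl[, 1] * ex[, 1]^2 + sl[, 2] * ey[, 1]^2 +
        2 * sl[, 3] * ex[, 1] * ey[, 1],
      yy = sl[, 1] * ex[, 2]^2 + sl[, 2] * ey[, 2]^2 +
        2 * sl[, 3] * ex[, 2] * ey[, 2],
      zz = sl[, 1] * ex[, 3]^2 + sl[, 2] * ey[, 3]^2 +
        2 * sl[, 3] * ex[, 3] * ey[, 3],
      xy = sl[, 1] * ex[, 1] * ex[, 2] + sl[, 2] * ey[, 1] * ey[, 2] +
        sl[, 3] * (ex[, 1] * ey[, 2] + ey[, 1] * ex[, 2]),
      yz = sl[, 1] * ex[, 2] * ex[, 3] + sl[, 2] * ey[, 2] * ey[, 3] +
        sl[, 3] * (ex[, 2] * ey[, 3] + ey[, 2] * ex[, 3]),
      zx = sl[, 1] * ex[, 3] * ex[, 1] + sl[, 2] * ey[, 3] * ey[, 1] +
        sl[, 3] * (ex[, 3] * ey[, 1] + ey[, 3] * ex[, 1]))
    list(sigma = sig, weight = thickness * a2 / 2)
  }

  ts <- tet_sigma(mesh$nodes, mesh$tets,
                  materials$cancellous_E, materials$cancellous_nu)
  cs <- mem_sigma(mesh$nodes, mesh$tris, materials$cortical_E,
                  materials$cortical_nu, materials$cortical_thickness)
  gs <- mem_sigma(mesh$nodes, mesh$tris, materials$cartilage_E,
                  materials$cartilage_nu, materials$cartilage_thickness)

  out <- rbind(
    data.frame(ts$sigma, weight = ts$weight, body = mesh$tet_body,
               tissue = "cancellous"),
    data.frame(cs$sigma, weight = cs$weight, body = mesh$tri_body,
               tissue = "cortical"),
    data.frame(gs$sigma, weight = gs$weight, body = mesh$tri_body,
               tissue = "cartilage"))
  class(out) <- c("stress_field", "data.frame")
  out
}

#' von Mises equivalent stress
#'
#' `sqrt(0.5 * ((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2) +
#' 3 * (sxy^2 + syz^2 + szx^2))`, the scalar intensity of the deviatoric
#' stress; invariant under rotations of the tensor.
#'
#' @param tensor Numeric vector of 6 components (xx, yy, zz, xy, yz, zx)
#'   or an n x 6 matrix / `stress_field`.
#' @return Scalar or vector of von Mises stresses (MPa).
#' @export
von_mises <- function(tensor) {
  if (inherits(tensor, "stress_field"))
    tensor <- as.matrix(tensor[, c("xx", "yy", "zz", "xy", "yz", "zx")])
  if (is.null(dim(tensor))) tensor <- matrix(tensor, 1)
  if (any(!is.finite(tensor))) stop("non-finite stress components")
  s <- tensor
  v <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                   (s[, 3] - s[, 1])^2) +
            3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  as.numeric(v)
}

check_wv <- function(values, weights) {
  if (length(values) == 0L) stop("empty sample")
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
}

#' Mesh-weighted arithmetic mean
#'
#' `sum(v * w) / sum(w)`: the arithmetic mean of element values weighted
#' by element size, correcting for the non-uniform element sizes of a
#' quasi-ideal mesh.
#'
#' @param values Element values (e.g. von Mises stress, MPa).
#' @param weights Positive element weights (volume, or area x thickness).
#' @return Scalar weighted mean.
#' @export
mwam <- function(values, weights = rep(1, length(values))) {
  check_wv(values, weights)
  sum(values * weights) / sum(weights)
}

# weighted quantile: smallest value whose cumulative weight reaches q*total
weighted_quantile <- function(values, weights, q) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= q * cw[length(cw)])[1]]
}

#' Mesh-weighted median
#'
#' The smallest element value whose cumulative weight reaches half of the
#' total weight; reduces to the sample median for equal weights (lower
#' median for even counts).
#'
#' @inheritParams mwam
#' @return Scalar weighted median.
#' @export
mwm <- function(values, weights = rep(1, length(values))) {
  check_wv(values, weights)
  weighted_quantile(values, weights, 0.5)
}

#' Per-bone mesh-weighted summary of a stress field
#'
#' Computes, per body, the mesh-weighted statistics of the von Mises
#' stress over bone tissue (cancellous + cortical elements pooled;
#' cartilage excluded): MWAM, MWM, weighted median and quartiles
#' (cumulative-weight rule at 1/4, 1/2, 3/4), min and max (the whisker
#' definition used by the boxplot summaries), element count and total weight.
#'
#' @param field A `stress_field` from [recover_stress()].
#' @param mesh The originating `carpal_mesh` (for body names); optional.
#' @param bodies Integer body ids to summarise; default all in `field`.
#' @return Data frame, one row per body, class `stress_summary`.
#' @export
stress_summary <- function(field, mesh = NULL, bodies = NULL) {
  bone <- field[field$tissue != "cartilage", , drop = FALSE]
  if (is.null(bodies)) bodies <- sort(unique(bone$body))
  rows <- lapply(bodies, function(b) {
    fb <- bone[bone$body == b, , drop = FALSE]
    if (nrow(fb) == 0L) stop("unknown body id ", b, " in stress field")
    v <- von_mises(as.matrix(fb[, c("xx", "yy", "zz", "xy", "yz", "zx")]))
    w <- fb$weight
    data.frame(body = b,
               body_name = if (!is.null(mesh))
                 names(mesh$bodies)[match(b, mesh$bodies)] else NA_character_,
               mwam = mwam(v, w), mwm = mwm(v, w),
               median = weighted_quantile(v, w, 0.5),
               q25 = weighted_quantile(v, w, 0.25),
               q75 = weighted_quantile(v, w, 0.75),
               min = min(v), max = max(v),
               n_elements = length(v), total_weight = sum(w))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stress_summary", "data.frame")
  out
}

#' Export a solved model's fields to VTU and CSV
#'
#' Writes an ASCII VTU unstructured-grid file with the tetrahedra and
#' membrane triangles and cell data `von_mises`, `body_id`, `tissue`
#' (0 cancellous, 1 cortical, 2 cartilage), plus a CSV of the per-bone
#' summaries if given.
#'
#' @param mesh A `carpal_mesh`.
#' @param field A `stress_field` for this mesh.
#' @param summaries Optional `stress_summary` (or any data frame).
#' @param path Output path ending in `.vtu`.
#' @return Invisibly, the paths written.
#' @export
export_fields <- function(mesh, field, summaries = NULL, path) {
  if (!grepl("\\.vtu$", path)) stop("unsupported output extension (need .vtu)")
  ntet <- nrow(mesh$tets); ntri <- nrow(mesh$tris)
  # order must match recover_stress: tets, cortical tris, cartilage tris
  cells <- c(split(mesh$tets, row(mesh$tets)),
             rep(split(mesh$tris, row(mesh$tris)), 2))
  types <- c(rep(10L, ntet), rep(5L, 2 * ntri))
  vm <- von_mises(field)
  tiss <- match(field$tissue, c("cancellous", "cortical", "cartilage")) - 1L
  write_vtu(path, mesh$nodes,
            cells = cells, types = types,
            cell_data = list(von_mises = vm,
                             body_id = as.integer(field$body),
                             tissue = tiss,
                             weight = field$weight))
  paths <- path
  if (!is.null(summaries)) {
    csv <- sub("\\.vtu$", "_summary.csv", path)
    utils::write.csv(summaries, csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  invisible(paths)
}
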