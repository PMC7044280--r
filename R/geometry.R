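# Synthetic carpal geometry: seeded, parametric stand-ins for CT-derived
# scaphoid / os centrale / capitate surfaces, meshed with labelled facets.

#' Surface region labels used by carpal meshes
#'
#' The nine roles a boundary triangle can play in a carpal model:
#' loaded articular facets (`radial_facet` on the scaphoid, `lunate_facet`
#' on the capitate), distal fixation (`distal_fixed`), elastic lateral
#' restraints (`lateral_restraint`), ligament attachment patches
#' (`ligament_attach`), the three inter-bone contact patches, and `free`.
#'
#' @return Character vector of the nine region labels.
#' @export
carpal_regions <- function() {
  c("radial_facet", "lunate_facet", "distal_fixed", "lateral_restraint",
    "ligament_attach", "contact_scaphoid_capitate",
    "contact_scaphoid_centrale", "contact_centrale_capitate", "free")
}

#' Parameters for the synthetic carpal geometry generator
#'
#' Defines the simplified three-bone complex: per-bone semi-axes (half
#' extents, mm), the cartilage gap recessing the unfused scaphoid-centrale
#' step face, facet extents as fractions of the host face, the target
#' tetrahedron edge length, and the seeded free-surface perturbation that
#' stands in for individual anatomical shape variation.
#'
#' Default semi-axes give bones of hominoid carpal scale (capitate
#' 14 x 12 x 12 mm, scaphoid 14 x 9 x 8 mm, centrale 5 x 9 x 3 mm).
#' `scale` multiplies every length (semi-axes, gap, edge length,
#' perturbation) so species-sized variants keep comparable element counts.
#'
#' @param scaphoid_semi,centrale_semi,capitate_semi Numeric length-3
#'   semi-axes (x, y, z) in mm.
#' @param cartilage_gap Inter-bone clearance (mm) applied to the unfused
#'   scaphoid-centrale step interface.
#' @param facet_fraction Central fraction of a host face occupied by the
#'   loaded/fixed/restrained facets.
#' @param ligament_fraction Fraction of the centrale extents setting the
#'   ligament attachment patch size.
#' @param target_edge Target tetrahedron edge length (mm).
#' @param perturb_amplitude Amplitude (mm) of the smooth seeded free-surface
#'   perturbation; must stay below 10% of the smallest semi-axis.
#' @param seed Integer seed; fully determines the generated mesh.
#' @param scale Isotropic geometric scale factor.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(scaphoid_semi = c(7, 4.5, 4),
                            centrale_semi = c(2.5, 4.5, 1.5),
                            capitate_semi = c(7, 6, 6),
                            cartilage_gap = 0.25,
                            facet_fraction = 0.8,
                            ligament_fraction = 0.5,
                            articular_slope = 0.4,
                            target_edge = 1.0,
                            perturb_amplitude = 0.12,
                            seed = 1L,
                            scale = 1.0) {
  p <- list(scaphoid_semi = as.numeric(scaphoid_semi),
            centrale_semi = as.numeric(centrale_semi),
            capitate_semi = as.numeric(capitate_semi),
            cartilage_gap = cartilage_gap,
            facet_fraction = facet_fraction,
            ligament_fraction = ligament_fraction,
            articular_slope = articular_slope,
            target_edge = target_edge,
            perturb_amplitude = perturb_amplitude,
            seed = as.integer(seed),
            scale = scale)
  lens <- c(p$scaphoid_semi, p$centrale_semi, p$capitate_semi,
            p$cartilage_gap, p$target_edge, p$scale)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometry lengths must be positive and finite")
  if (p$perturb_amplitude < 0)
    stop("perturb_amplitude must be >= 0")
  if (p$perturb_amplitude >= 0.1 * min(p$scaphoid_semi, p$centrale_semi,
                                       p$capitate_semi))
    stop("perturb_amplitude must be below 10% of the smallest semi-axis")
  if (p$facet_fraction <= 0 || p$facet_fraction > 1)
    stop("facet_fraction must be in (0, 1]")
  if (p$articular_slope < 0 || p$articular_slope >= 1)
    stop("articular_slope must be in [0, 1)")
  # layout constraints of the three-bone complex
  if (2 * p$centrale_semi[1] >= 2 * p$capitate_semi[1])
    stop("centrale must be narrower (x) than the capitate")
  if (p$centrale_semi[3] >= p$scaphoid_semi[3])
    stop("centrale must be shorter (z) than the scaphoid")
  if (abs(p$scaphoid_semi[2] - p$centrale_semi[2]) > 1e-12)
    stop("scaphoid and centrale y semi-axes must match")
  if (p$scaphoid_semi[2] >= p$capitate_semi[2])
    stop("capitate must be wider (y) than the scaphoid")
  if (abs(p$scaphoid_semi[1] - p$capitate_semi[1]) > 1e-12)
    stop("scaphoid and capitate x semi-axes must match")
  if (is.na(p$seed)) stop("seed is mandatory")
  class(p) <- "geometry_params"
  p
}

# grid with spacing as close as possible to h, exact endpoints
grid_seq <- function(a, b, h) {
  n <- max(1L, as.integer(round((b - a) / h)))
  seq(a, b, length.out = n + 1L)
}

# Kuhn (Freudenthal) 6-tet decomposition of a structured hex grid.
# Conforming across cells and across blocks sharing grid planes.
block_mesh <- function(xg, yg, zg) {
  nx <- length(xg); ny <- length(yg); nz <- length(zg)
  nodes <- cbind(rep(xg, times = ny * nz),
                 rep(rep(yg, each = nx), times = nz),
                 rep(zg, each = nx * ny))
  idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  corner <- function(dx, dy, dz) idx(ci + dx, cj + dy, ck + dz)
  # unit vectors per axis as corner offsets; path permutations of (x,y,z)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  off <- function(mask) corner(bitwAnd(mask, 1L) > 0,
                               bitwAnd(mask, 2L) > 0,
                               bitwAnd(mask, 4L) > 0)
  axis_bit <- c(1L, 2L, 4L)
  tets <- vector("list", 6L)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    m1 <- axis_bit[p[1]]
    m2 <- m1 + axis_bit[p[2]]
    tets[[t]] <- cbind(off(0L), off(m1), off(m2), off(7L))
  }
  tets <- do.call(rbind, tets)
  list(nodes = nodes, tets = tets)
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
   a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
   a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# fix tet orientation so all volumes are positive
orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(1, 2)] <- tets[neg, c(2, 1)]
  tets
}

node_key <- function(nodes, digits = 7) {
  paste(round(nodes[, 1], digits), round(nodes[, 2], digits),
        round(nodes[, 3], digits), sep = "|")
}

# concatenate blocks into one body, merging coincident nodes
merge_blocks <- function(blocks) {
  nodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  offs <- cumsum(c(0L, vapply(blocks, function(b) nrow(b$nodes),
                              integer(1))))
  tets <- do.call(rbind, lapply(seq_along(blocks), function(i)
    blocks[[i]]$tets + offs[i]))
  key <- node_key(nodes)
  first <- !duplicated(key)
  remap <- match(key, key[first])
  nodes <- nodes[first, , drop = FALSE]
  tets[] <- remap[tets]
  list(nodes = nodes, tets = tets)
}

# boundary faces of a tet set: faces used by exactly one tet, oriented outward
boundary_faces <- function(nodes, tets) {
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
             tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  srt <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
               pmax(f[, 1], f[, 2], f[, 3]))
  mid <- f[, 1] + f[, 2] + f[, 3] - srt[, 1] - srt[, 2]
  key <- paste(srt[, 1], mid, srt[, 2])
  tab <- table(key)
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

tri_normals <- function(nodes, tris) {
  u <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  v <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  list(unit = n / len, area = len / 2)
}

tri_centroids <- function(nodes, tris) {
  (nodes[tris[, 1], , drop = FALSE] + nodes[tris[, 2], , drop = FALSE] +
     nodes[tris[, 3], , drop = FALSE]) / 3
}

# smooth seeded perturbation field (sum of three random plane waves)
perturb_field <- function(pts, amp, wavelength) {
  k <- matrix(stats::runif(9, -1, 1), 3, 3)
  k <- 2 * pi * k / sqrt(rowSums(k^2)) / wavelength
  phase <- stats::runif(3, 0, 2 * pi)
  w <- stats::runif(3, 0.5, 1)
  s <- (w[1] * sin(pts %*% k[1, ] + phase[1]) +
        w[2] * sin(pts %*% k[2, ] + phase[2]) +
        w[3] * sin(pts %*% k[3, ] + phase[3])) / sum(w)
  amp * as.numeric(s)
}

#' Generate a fused or unfused synthetic carpal mesh
#'
#' Builds the simplified scaphoid / os centrale / capitate complex as
#' labelled tetrahedral bodies. The capitate forms the distal base; the
#' small centrale sits on its ulnar-distal corner; the scaphoid is a
#' stepped body resting on both, so compressive load entering the
#' scaphoid's radial facet passes partly through the centrale - the load
#' path whose interruption the fused morphology removes. The fused variant
#' merges scaphoid and centrale into one body, deleting their mutual
#' interface; all other regions, including both contacts with the
#' capitate, are identical between variants.
#'
#' Opposing contact patches are node-coincident by construction (shared
#' structured grid planes), so non-separation contact can be imposed as
#' linear node-pair constraints. A seeded smooth perturbation is applied
#' along the outward normal of purely free surface nodes, standing in for
#' individual shape variation without touching any labelled facet.
#'
#' @param params A [geometry_params()] object.
#' @param variant `"fused"` or `"unfused"`.
#' @return A `carpal_mesh`: node coordinates (mm), tetrahedra with body
#'   ids, labelled boundary triangles (region and patch ids), the variant
#'   tag, and the body name/id map.
#' @export
generate_carpal_set <- function(params, variant = c("unfused", "fused")) {
  variant <- match.arg(variant)
  if (!inherits(params, "geometry_params"))
    params <- do.call(geometry_params, params)
  p <- params
  s <- p$scale
  sc <- 2 * p$scaphoid_semi * s
  ce <- 2 * p$centrale_semi * s
  cap <- 2 * p$capitate_semi * s
  h <- p$target_edge * s
  gap <- p$cartilage_gap * s
  amp <- p$perturb_amplitude * s

  Lx <- cap[1]; Ly <- cap[2]; Lz <- cap[3]
  xsplit <- Lx - ce[1]           # radial/ulnar split of the proximal row
  zstep <- Lz + ce[3]            # top of the centrale
  ztop <- Lz + sc[3]             # radial facet plane
  ys <- sc[2]                    # proximal-row depth

  xg1 <- grid_seq(0, xsplit, h)
  xg2 <- grid_seq(xsplit, Lx, h)
  xg_cap <- c(xg1, xg2[-1])
  yg_s <- grid_seq(0, ys, h)
  yg_cap <- c(yg_s, grid_seq(ys, Ly, h)[-1])
  zg_cap <- grid_seq(0, Lz, h)
  zg_ce <- grid_seq(Lz, zstep, h)
  zg_up <- grid_seq(zstep, ztop, h)
  zg_s1 <- c(zg_ce, zg_up[-1])

  b_s1 <- block_mesh(xg1, yg_s, zg_s1)
  b_s2 <- block_mesh(xg2, yg_s, zg_up)
  b_ce <- block_mesh(xg2, yg_s, zg_ce)
  b_cap <- block_mesh(xg_cap, yg_cap, zg_cap)

  if (variant == "unfused") {
    bodies <- c(scaphoid = 1L, centrale = 2L, capitate = 3L)
    parts <- list(merge_blocks(list(b_s1, b_s2)), b_ce, b_cap)
  } else {
    bodies <- c(scaphoid_centrale = 1L, capitate = 2L)
    parts <- list(merge_blocks(list(b_s1, b_s2, b_ce)), b_cap)
  }

  nodes <- do.call(rbind, lapply(parts, `[[`, "nodes"))
  offs <- cumsum(c(0L, vapply(parts, function(b) nrow(b$nodes), integer(1))))
  tets <- do.call(rbind, lapply(seq_along(parts), function(i)
    parts[[i]]$tets + offs[i]))
  tet_body <- rep.int(bodies, vapply(parts, function(b) nrow(b$tets),
                                     integer(1)))
  node_body <- rep.int(bodies, diff(offs))
  tets <- orient_tets(nodes, tets)

  tris <- NULL; tri_body <- NULL
  for (bi in seq_along(bodies)) {
    bf <- boundary_faces(nodes, tets[tet_body == bodies[bi], , drop = FALSE])
    tris <- rbind(tris, bf)
    tri_body <- c(tri_body, rep.int(bodies[bi], nrow(bf)))
  }

  # classify boundary triangles on the unperturbed geometry
  cen <- tri_centroids(nodes, tris)
  nrm <- tri_normals(nodes, tris)$unit
  eps <- 1e-7 * max(Lx, Ly, ztop)
  on_plane <- function(axis, value, sign) {
    abs(cen[, axis] - value) < eps & sign * nrm[, axis] > 0.9
  }
  central <- function(axis, lo, hi, frac = p$facet_fraction) {
    abs(cen[, axis] - (lo + hi) / 2) <= frac * (hi - lo) / 2
  }
  within <- function(axis, lo, hi) cen[, axis] > lo - eps & cen[, axis] < hi + eps
  is_prox <- tri_body == bodies[1]            # scaphoid (or fused body)
  is_ce <- if (variant == "unfused") tri_body == bodies["centrale"] else rep(FALSE, nrow(tris))
  is_cap <- tri_body == bodies[length(bodies)]
  prox_part <- is_prox & cen[, 3] < zstep + eps   # centrale-height portion
  region <- rep("free", nrow(tris))
  patch <- rep("free", nrow(tris))
  setr <- function(sel, reg, pat = reg) {
    region[sel] <<- reg
    patch[sel] <<- pat
  }
  # loaded facets
  setr(is_prox & on_plane(3, ztop, +1) & central(1, 0, Lx) & central(2, 0, ys),
       "radial_facet")
  setr(is_cap & on_plane(3, Lz, +1) & within(2, ys, Ly) & central(2, ys, Ly) &
         central(1, 0, Lx), "lunate_facet")
  # contacts (horizontal planes; proximal side keeps y inside the row)
  sel_sc_cap_a <- is_prox & on_plane(3, Lz, -1) & within(1, 0, xsplit)
  sel_sc_cap_b <- is_cap & on_plane(3, Lz, +1) & within(1, 0, xsplit) &
    within(2, 0, ys)
  setr(sel_sc_cap_a | sel_sc_cap_b, "contact_scaphoid_capitate")
  sel_ce_cap_a <- (if (variant == "unfused") is_ce else is_prox) &
    on_plane(3, Lz, -1) & within(1, xsplit, Lx)
  sel_ce_cap_b <- is_cap & on_plane(3, Lz, +1) & within(1, xsplit, Lx) &
    within(2, 0, ys)
  setr(sel_ce_cap_a | sel_ce_cap_b, "contact_centrale_capitate")
  if (variant == "unfused") {
    sel_sc_ce_a <- is_prox & on_plane(3, zstep, -1) & within(1, xsplit, Lx)
    sel_sc_ce_b <- is_ce & on_plane(3, zstep, +1)
    setr(sel_sc_ce_a | sel_sc_ce_b, "contact_scaphoid_centrale")
  }
  # distal fixation: capitate base plus the trapezoid/trapezium facet on the
  # centrale (centrale-portion of the fused body)
  setr(is_cap & on_plane(3, 0, -1) & central(1, 0, Lx) & central(2, 0, Ly),
       "distal_fixed", "fix_capitate_mc3")
  sel_fix_ce <- (if (variant == "unfused") is_ce else prox_part) &
    on_plane(1, Lx, +1) & central(3, Lz, zstep) & central(2, 0, ys)
  setr(sel_fix_ce, "distal_fixed", "fix_centrale_trapezoid")
  # lateral elastic restraints: lunate side of the scaphoid, hamate and
  # trapezoid sides of the capitate
  setr(is_prox & on_plane(2, ys, +1) & central(1, 0, Lx) & central(3, Lz, ztop),
       "lateral_restraint", "lat_scaphoid_lunate")
  setr(is_cap & on_plane(1, Lx, +1) & central(2, 0, Ly) & central(3, 0, Lz),
       "lateral_restraint", "lat_capitate_hamate")
  setr(is_cap & on_plane(1, 0, -1) & central(2, 0, Ly) & central(3, 0, Lz),
       "lateral_restraint", "lat_capitate_trapezoid")
  # ligament attachment patches on the palmar (y = 0) faces
  lw <- p$ligament_fraction * ce[1]
  lh <- p$ligament_fraction * ce[3]
  on_palmar <- on_plane(2, 0, -1)
  setr(is_prox & on_palmar & within(1, xsplit - lw, xsplit) &
         within(3, zstep, zstep + lh), "ligament_attach", "lig_scaphoid")
  if (variant == "unfused") {
    xm <- (xsplit + Lx) / 2; zm <- (Lz + zstep) / 2
    setr(is_ce & on_palmar & within(1, xm - lw / 2, xm + lw / 2) &
           within(3, zm - lh / 2, zm + lh / 2), "ligament_attach",
         "lig_centrale")
  }
  setr(is_cap & on_palmar & within(1, xsplit, xsplit + lw) &
         within(3, Lz - lh, Lz), "ligament_attach", "lig_capitate")

  # recess the unfused centrale's radial face to open the cartilage gap,
  # keeping contact-plane edge nodes in place
  if (variant == "unfused") {
    ni <- which(node_body == bodies["centrale"] &
                  abs(nodes[, 1] - xsplit) < eps &
                  nodes[, 3] > Lz + eps & nodes[, 3] < zstep - eps)
    nodes[ni, 1] <- nodes[ni, 1] + gap
  }

  # incline the articular planes: a volume-preserving shear of the whole
  # lattice (z += slope * x) tilts every contact plane relative to the
  # proximodistal load axis, so sliding joints must shed their tangential
  # load share into ligaments and restraints while fused interfaces carry
  # it directly - the load-transfer contrast under study
  if (p$articular_slope > 0)
    nodes[, 3] <- nodes[, 3] + p$articular_slope * nodes[, 1]

  # seeded smooth perturbation of purely-free surface nodes
  if (amp > 0) {
    free_nodes <- setdiff(unique(as.vector(tris[region == "free", ])),
                          unique(as.vector(tris[region != "free", ])))
    if (length(free_nodes)) {
      nn <- tri_normals(nodes, tris)
      # area-weighted node normals accumulated over all three triangle corners
      acc <- matrix(0, nrow(nodes), 3)
      for (c_i in 1:3) {
        ti <- tris[, c_i]
        for (k in 1:3) {
          sums <- rowsum(nn$unit[, k] * nn$area, group = ti)
          acc[as.integer(rownames(sums)), k] <-
            acc[as.integer(rownames(sums)), k] + sums[, 1]
        }
      }
      nlen <- sqrt(rowSums(acc^2))
      ok <- free_nodes[nlen[free_nodes] > 0]
      dirs <- acc[ok, , drop = FALSE] / nlen[ok]
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
      set.seed(p$seed)
      d <- perturb_field(nodes[ok, , drop = FALSE], amp,
                         wavelength = max(Lx, ztop) / 2)
      nodes[ok, ] <- nodes[ok, , drop = FALSE] + d * dirs
    }
  }

  if (any(tet_volumes(nodes, tets) <= 0))
    stop("geometry error: degenerate (non-positive volume) tetrahedra after ",
         "surface perturbation; reduce perturb_amplitude or refine the mesh")

  structure(list(nodes = nodes, tets = tets, tet_body = unname(tet_body),
                 node_body = unname(node_body),
                 tris = tris, tri_body = unname(tri_body),
                 tri_region = region, tri_patch = patch,
                 variant = variant, bodies = bodies, params = p),
            class = "carpal_mesh")
}

#' @export
print.carpal_mesh <- function(x, ...) {
  cat("carpal_mesh (", x$variant, "): ",
      length(x$bodies), " bodies, ",
      nrow(x$nodes), " nodes, ", nrow(x$tets), " tetrahedra, ",
      nrow(x$tris), " boundary triangles\n", sep = "")
  cat("bodies:", paste(names(x$bodies), collapse = ", "), "\n")
  tb <- table(x$tri_region)
  cat("regions:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the node-pair interface of a contact patch
#'
#' Pairs the coincident nodes of the two sides of a conforming contact
#' patch and attaches the outward unit normal of the first-named body,
#' ready to be imposed as non-separation (normal tie, tangential sliding)
#' constraints.
#'
#' @param mesh A `carpal_mesh`.
#' @param patch_label One of the `contact_*` region labels.
#' @param tol Coincidence tolerance (mm).
#' @return A `contact_interface`: `pairs` (node index of body A, node index
#'   of body B), unit `normals` per pair, and the patch label.
#' @export
build_contact_interface <- function(mesh, patch_label, tol = 1e-6) {
  sel <- mesh$tri_region == patch_label
  if (!any(sel))
    stop("contact patch '", patch_label, "' is absent from this mesh")
  bodies <- sort(unique(mesh$tri_body[sel]))
  if (length(bodies) != 2L)
    stop("contact patch '", patch_label, "' must lie on exactly two bodies")
  tris_a <- mesh$tris[sel & mesh$tri_body == bodies[1], , drop = FALSE]
  tris_b <- mesh$tris[sel & mesh$tri_body == bodies[2], , drop = FALSE]
  na <- sort(unique(as.vector(tris_a)))
  nb <- sort(unique(as.vector(tris_b)))
  key <- function(i) paste(round(mesh$nodes[i, 1] / tol) * tol,
                           round(mesh$nodes[i, 2] / tol) * tol,
                           round(mesh$nodes[i, 3] / tol) * tol)
  m <- match(key(na), key(nb))
  if (anyNA(m) || anyDuplicated(m))
    stop("contact patch '", patch_label,
         "' is non-conforming: unmatched or duplicated nodes across bodies")
  pairs <- cbind(A = na, B = nb[m])
  # area-weighted outward normal of body A at each paired node
  nn <- tri_normals(mesh$nodes, tris_a)
  acc <- matrix(0, length(na), 3)
  gi <- match(as.vector(tris_a), na)
  for (k in 1:3) {
    sums <- rowsum(rep(nn$unit[, k] * nn$area, 3), gi)
    acc[as.integer(rownames(sums)), k] <- sums[, 1]
  }
  normals <- acc / sqrt(rowSums(acc^2))
  structure(list(pairs = pairs, normals = normals, patch = patch_label,
                 bodies = bodies),
            class = "contact_interface")
}

#' Mesh quality statistics and quasi-ideal-mesh flag
#'
#' Element-size statistics over the tetrahedra of a carpal mesh: element
#' count, coefficient of variation of element volume, and the dihedral
#' angle range. A quasi-ideal mesh (QIM) is a non-uniform mesh whose
#' elements are nearly but not exactly equal in size; the flag is set when
#' the volume CV falls below `cv_threshold`.
#'
#' @param mesh A `carpal_mesh` (or any list with `nodes` and `tets`).
#' @param cv_threshold Volume CV below which the mesh counts as quasi-ideal.
#' @return A `quality_report` list: `n_elements`, `volume_cv`,
#'   `min_dihedral_deg`, `max_dihedral_deg`, `qim`.
#' @export
mesh_quality <- function(mesh, cv_threshold = 0.75) {
  if (is.null(mesh$tets) || nrow(mesh$tets) == 0L)
    stop("mesh has no tetrahedra")
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) stop("mesh contains non-positive-volume tetrahedra")
  cv <- sqrt(mean((v - mean(v))^2)) / mean(v)     # population CV
  # dihedral angles: between the four face normals of each tet
  n1 <- tri_normals(mesh$nodes, mesh$tets[, c(2, 3, 4), drop = FALSE])$unit
  n2 <- tri_normals(mesh$nodes, mesh$tets[, c(1, 4, 3), drop = FALSE])$unit
  n3 <- tri_normals(mesh$nodes, mesh$tets[, c(1, 2, 4), drop = FALSE])$unit
  n4 <- tri_normals(mesh$nodes, mesh$tets[, c(1, 3, 2), drop = FALSE])$unit
  dihed <- function(a, b) {
    d <- pmin(1, pmax(-1, -rowSums(a * b)))
    acos(d) * 180 / pi
  }
  ang <- cbind(dihed(n1, n2), dihed(n1, n3), dihed(n1, n4),
               dihed(n2, n3), dihed(n2, n4), dihed(n3, n4))
  structure(list(n_elements = nrow(mesh$tets), volume_cv = cv,
                 min_dihedral_deg = min(ang), max_dihedral_deg = max(ang),
                 qim = cv < cv_threshold, cv_threshold = cv_threshold),
            class = "quality_report")
}

# total area of each body's boundary, by region (used by tests and loads)
region_areas <- function(mesh) {
  a <- tri_normals(mesh$nodes, mesh$tris)$area
  stats::aggregate(a, list(body = mesh$tri_body, region = mesh$tri_region),
                   sum)
}
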