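# Model setup: materials, load case, ligament and foundation springs, and
# assembly of the complete constrained linear system for a carpal mesh.

#' Material parameter set for the carpal model
#'
#' Homogeneous linear-elastic properties: cortical bone 10000 MPa / 0.22,
#' cancellous bone 500 MPa / 0.30, articular cartilage 7 MPa / 0.30.
#' Cortical bone and cartilage are thin layers carried by surface
#' membranes; their constant thicknesses (mm) are part of the set.
#'
#' @param cortical_E,cortical_nu Cortical bone modulus (MPa) and ratio.
#' @param cancellous_E,cancellous_nu Cancellous bone modulus and ratio.
#' @param cartilage_E,cartilage_nu Cartilage modulus and ratio.
#' @param cortical_thickness Cortical shell thickness (mm).
#' @param cartilage_thickness Cartilage layer thickness (mm).
#' @return A `material_set` list.
#' @export
material_set <- function(cortical_E = 10000, cortical_nu = 0.22,
                         cancellous_E = 500, cancellous_nu = 0.30,
                         cartilage_E = 7, cartilage_nu = 0.30,
                         cortical_thickness = 1.0,
                         cartilage_thickness = 0.55) {
  m <- list(cortical_E = cortical_E, cortical_nu = cortical_nu,
            cancellous_E = cancellous_E, cancellous_nu = cancellous_nu,
            cartilage_E = cartilage_E, cartilage_nu = cartilage_nu,
            cortical_thickness = cortical_thickness,
            cartilage_thickness = cartilage_thickness)
  if (any(c(m$cortical_E, m$cancellous_E, m$cartilage_E) <= 0))
    stop("all Young moduli must be positive")
  nus <- c(m$cortical_nu, m$cancellous_nu, m$cartilage_nu)
  if (any(nus < 0 | nus >= 0.5))
    stop("Poisson ratios must lie in [0, 0.5)")
  if (any(c(m$cortical_thickness, m$cartilage_thickness) <= 0))
    stop("layer thicknesses must be positive")
  class(m) <- "material_set"
  m
}

#' Ligament specification
#'
#' A single inter-carpal ligament of total axial rigidity `total` (N/mm,
#' default 40 as for the palmar scaphocapitate ligament), realised as
#' `n_strands` parallel spring strands distributed over the attachment
#' patches. Topology is `"direct"` (scaphoid to capitate, fused models) or
#' `"serial"` (scaphoid through centrale to capitate, unfused models); a
#' serial strand is two segments of doubled stiffness so its series
#' combination equals the strand share.
#'
#' @param total Total ligament rigidity (N/mm).
#' @param n_strands Number of parallel strands (>= 1).
#' @param topology `"direct"` or `"serial"`.
#' @return A `ligament_spec` list.
#' @export
ligament_spec <- function(total = 40, n_strands = 8,
                          topology = c("serial", "direct")) {
  topology <- match.arg(topology)
  if (total <= 0) stop("total ligament rigidity must be positive")
  if (n_strands < 1) stop("at least one strand is required")
  structure(list(total = total, n_strands = as.integer(n_strands),
                 topology = topology), class = "ligament_spec")
}

#' Total knuckle-walking load from body mass
#'
#' The applied load is a fixed fraction of body weight: hominoid forelimbs
#' carry roughly 40% of body weight in terrestrial quadrupedalism, i.e.
#' 20% per forelimb, so `F = fraction * mass * g`. Standard gravity
#' 9.80665 m s^-2 is the default. The result is reported to 0.01 N.
#'
#' @param mass Body mass (kg), non-negative.
#' @param fraction Load fraction of body weight in (0, 1); default 0.2.
#' @param g Gravitational acceleration (m s^-2).
#' @return Total load in N, rounded to 0.01 N.
#' @export
compute_total_load <- function(mass, fraction = 0.2, g = 9.80665) {
  if (any(mass < 0)) stop("body mass must be non-negative")
  if (fraction <= 0 || fraction >= 1) stop("load fraction must be in (0, 1)")
  if (g <= 0) stop("g must be positive")
  round(fraction * mass * g, 2)
}

#' Construct a load case
#'
#' The load acts along the proximodistal axis (compression, -z in mesh
#' coordinates), optionally tilted by `tilt_deg` about an in-plane axis,
#' and is partitioned between the radial facet of the scaphoid and the
#' lunate facet of the capitate.
#'
#' @param mass Body mass (kg).
#' @param fraction Load fraction; default 0.2.
#' @param g Gravitational acceleration (m s^-2).
#' @param tilt_deg Tilt angle in degrees, in `[0, 90)`.
#' @param partition `"area"` (proportional to facet areas) or a numeric
#'   length-2 vector of shares (radial, lunate) summing to 1.
#' @param tilt_axis In-plane rotation axis, `"x"` or `"y"`.
#' @return A `load_case` with total force `F` (N) and unit `direction`.
#' @export
make_load_case <- function(mass, fraction = 0.2, g = 9.80665, tilt_deg = 0,
                           partition = "area", tilt_axis = c("y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  if (tilt_deg < 0 || tilt_deg >= 90) stop("tilt angle must be in [0, 90)")
  if (is.character(partition)) {
    if (!identical(partition, "area"))
      stop("unknown partition rule: ", partition)
  } else {
    partition <- as.numeric(partition)
    if (length(partition) != 2 || any(partition < 0) ||
        abs(sum(partition) - 1) > 1e-12)
      stop("numeric partition must be two non-negative shares summing to 1")
  }
  F <- compute_total_load(mass, fraction, g)
  t <- tilt_deg * pi / 180
  base <- c(0, 0, -1)
  direction <- if (tilt_axis == "y") {
    c(-sin(t), 0, -cos(t))          # rotation about +y applied to -z
  } else {
    c(0, sin(t), -cos(t))
  }
  structure(list(mass = mass, fraction = fraction, g = g, F = F,
                 direction = direction, base_axis = base,
                 tilt_deg = tilt_deg, tilt_axis = tilt_axis,
                 partition = partition), class = "load_case")
}

# nodes of a patch with tributary areas (one third of each incident
# triangle's area) and area-weighted outward normals
patch_nodes <- function(mesh, sel) {
  tris <- mesh$tris[sel, , drop = FALSE]
  if (nrow(tris) == 0L) return(NULL)
  nn <- tri_normals(mesh$nodes, tris)
  ids <- sort(unique(as.vector(tris)))
  gi <- match(as.vector(tris), ids)
  w <- as.numeric(rowsum(rep(nn$area / 3, 3), gi))
  acc <- matrix(0, length(ids), 3)
  for (k in 1:3) {
    s <- rowsum(rep(nn$unit[, k] * nn$area, 3), gi)
    acc[as.integer(rownames(s)), k] <- s[, 1]
  }
  normals <- acc / sqrt(rowSums(acc^2))
  list(nodes = ids, weight = w, normals = normals, area = sum(nn$area))
}

#' Distribute a ligament over parallel spring strands
#'
#' Realises a [ligament_spec()] on a carpal mesh as discrete linear spring
#' elements between ligament attachment patches. Direct topology places
#' `n` strands of stiffness `total/n` from the scaphoid patch to the
#' capitate patch; serial topology routes each strand through the centrale
#' as two segments of stiffness `2*total/n`, so every strand's series
#' combination is `total/n` and the parallel aggregate equals `total`.
#'
#' @param mesh A `carpal_mesh`.
#' @param spec A [ligament_spec()]; topology must match the mesh variant
#'   (serial needs a centrale attachment patch).
#' @return A `spring_set`: data frame `springs` with `node_a`, `node_b`,
#'   `k` (N/mm), `strand`, `segment`, and an empty `grounded` table.
#' @export
distribute_ligament_springs <- function(mesh, spec) {
  stopifnot(inherits(spec, "ligament_spec"))
  get_patch <- function(id) {
    pn <- patch_nodes(mesh, mesh$tri_patch == id)
    if (is.null(pn))
      stop("ligament attachment patch '", id, "' is absent from this mesh")
    pn
  }
  pick <- function(pn, n) {
    ids <- pn$nodes
    ord <- order(mesh$nodes[ids, 1], mesh$nodes[ids, 3], mesh$nodes[ids, 2])
    ids <- ids[ord]
    ids[round(seq(1, length(ids), length.out = n))]
  }
  n <- spec$n_strands
  a <- pick(get_patch("lig_scaphoid"), n)
  b <- pick(get_patch("lig_capitate"), n)
  if (spec$topology == "direct") {
    springs <- data.frame(node_a = a, node_b = b, k = spec$total / n,
                          strand = seq_len(n), segment = 1L)
  } else {
    m <- pick(get_patch("lig_centrale"), n)
    springs <- rbind(
      data.frame(node_a = a, node_b = m, k = 2 * spec$total / n,
                 strand = seq_len(n), segment = 1L),
      data.frame(node_a = m, node_b = b, k = 2 * spec$total / n,
                 strand = seq_len(n), segment = 2L))
  }
  structure(list(springs = springs,
                 grounded = data.frame(node = integer(0), dx = numeric(0),
                                       dy = numeric(0), dz = numeric(0),
                                       k = numeric(0)),
                 spec = spec),
            class = "spring_set")
}

#' Build grounded foundation springs on a restraint patch
#'
#' Represents the compliant support of a neighbouring carpal (lunate,
#' hamate, trapezoid) as grounded springs acting along the patch outward
#' normal at every patch node, with the total stiffness partitioned by
#' tributary area so the sum equals `total_stiffness` exactly.
#'
#' @param mesh A `carpal_mesh`.
#' @param patch Patch id (e.g. `"lat_scaphoid_lunate"`).
#' @param total_stiffness Total lateral stiffness (N/mm), default 20.5.
#' @return A `spring_set` with only the `grounded` table filled.
#' @export
build_foundation_springs <- function(mesh, patch, total_stiffness = 20.5) {
  if (total_stiffness <= 0) stop("foundation stiffness must be positive")
  pn <- patch_nodes(mesh, mesh$tri_patch == patch)
  if (is.null(pn)) stop("foundation patch '", patch, "' is absent")
  if (pn$area <= 0) stop("foundation patch '", patch, "' has zero area")
  k <- total_stiffness * pn$weight / sum(pn$weight)
  structure(list(springs = data.frame(node_a = integer(0),
                                      node_b = integer(0), k = numeric(0),
                                      strand = integer(0),
                                      segment = integer(0)),
                 grounded = data.frame(node = pn$nodes,
                                       dx = pn$normals[, 1],
                                       dy = pn$normals[, 2],
                                       dz = pn$normals[, 3], k = k),
                 patch = patch),
            class = "spring_set")
}

#' Boundary specification
#'
#' Fixed (zero-displacement) patches, elastic foundation patches with
#' their total lateral stiffnesses, and the non-separation contact
#' interfaces of the model.
#'
#' @param fixed_patches Character vector of patch ids held fixed.
#' @param foundation Named numeric vector: patch id -> total stiffness
#'   (N/mm); defaults to 20.5 per lateral restraint patch.
#' @param contacts List of `contact_interface` objects.
#' @return A `boundary_spec` list.
#' @export
boundary_spec <- function(fixed_patches, foundation, contacts = list()) {
  if (length(fixed_patches) < 1) stop("at least one fixed patch is required")
  if (any(foundation <= 0)) stop("foundation stiffnesses must be positive")
  structure(list(fixed_patches = fixed_patches, foundation = foundation,
                 contacts = contacts), class = "boundary_spec")
}

#' Default boundary specification for a carpal mesh
#'
#' Fixes the distal facets (capitate base at the third metacarpal and the
#' centrale facet at the trapezoid/trapezium), restrains every lateral
#' patch with 20.5 N/mm, and ties all contact patches present in the mesh.
#'
#' @param mesh A `carpal_mesh`.
#' @param lateral_stiffness Total stiffness per lateral restraint patch.
#' @return A `boundary_spec`.
#' @export
default_boundary <- function(mesh, lateral_stiffness = 20.5) {
  fixed <- unique(mesh$tri_patch[mesh$tri_region == "distal_fixed"])
  lat <- unique(mesh$tri_patch[mesh$tri_region == "lateral_restraint"])
  foundation <- stats::setNames(rep(lateral_stiffness, length(lat)), lat)
  labels <- intersect(c("contact_scaphoid_capitate",
                        "contact_scaphoid_centrale",
                        "contact_centrale_capitate"),
                      unique(mesh$tri_region))
  contacts <- lapply(labels, function(l) build_contact_interface(mesh, l))
  boundary_spec(fixed, foundation, contacts)
}

# accumulate values into a vector at (possibly repeated) indices
accumulate_at <- function(x, idx, val) {
  s <- rowsum(val, idx)
  at <- as.integer(rownames(s))
  x[at] <- x[at] + s[, 1]
  x
}

#' Assemble the constrained linear system for a carpal model
#'
#' Builds the global symmetric stiffness from the cancellous tetrahedra,
#' the cortical and cartilage membrane layers sharing the nodes of every
#' boundary triangle (full DOF coupling of shell and solid), the ligament
#' strand springs and the grounded foundation springs; assembles the load
#' vector on the radial and lunate facets with the load-case partition;
#' collects fixed DOFs on the distal patches and one normal-tie constraint
#' per contact node pair.
#'
#' @param mesh A `carpal_mesh`.
#' @param materials A [material_set()].
#' @param ligaments A [ligament_spec()] or `NULL` for no ligament.
#' @param boundary A [boundary_spec()]; default [default_boundary()].
#' @param load_case A [make_load_case()] result.
#' @return A `linear_system`.
#' @export
assemble_model <- function(mesh, materials = material_set(),
                           ligaments = NULL, boundary = NULL,
                           load_case = NULL) {
  if (is.null(boundary)) boundary <- default_boundary(mesh)
  nnode <- nrow(mesh$nodes)
  ndof <- 3L * nnode

  tt <- tet_triplets(mesh$nodes, mesh$tets,
                     materials$cancellous_E, materials$cancellous_nu)
  mc <- membrane_triplets(mesh$nodes, mesh$tris, materials$cortical_E,
                          materials$cortical_nu,
                          materials$cortical_thickness)
  mg <- membrane_triplets(mesh$nodes, mesh$tris, materials$cartilage_E,
                          materials$cartilage_nu,
                          materials$cartilage_thickness)

  springs <- NULL
  if (!is.null(ligaments)) {
    if (inherits(ligaments, "ligament_spec"))
      ligaments <- distribute_ligament_springs(mesh, ligaments)
    springs <- ligaments$springs
  }
  grounded <- NULL
  for (pid in names(boundary$foundation)) {
    fs <- build_foundation_springs(mesh, pid, boundary$foundation[[pid]])
    grounded <- rbind(grounded, fs$grounded)
  }
  st <- spring_triplets(mesh$nodes, springs)
  gt <- grounded_triplets(grounded)

  K <- Matrix::sparseMatrix(i = c(tt$i, mc$i, mg$i, st$i, gt$i),
                            j = c(tt$j, mc$j, mg$j, st$j, gt$j),
                            x = c(tt$x, mc$x, mg$x, st$x, gt$x),
                            dims = c(ndof, ndof))

  # loads on the radial (scaphoid) and lunate (capitate) facets
  f <- numeric(ndof)
  if (!is.null(load_case)) {
    pr <- patch_nodes(mesh, mesh$tri_region == "radial_facet")
    pl <- patch_nodes(mesh, mesh$tri_region == "lunate_facet")
    if (is.null(pr) || is.null(pl))
      stop("loaded facets (radial_facet, lunate_facet) must be present")
    shares <- if (is.character(load_case$partition)) {
      c(pr$area, pl$area) / (pr$area + pl$area)
    } else load_case$partition
    for (pi in 1:2) {
      pn <- list(pr, pl)[[pi]]
      fn <- load_case$F * shares[pi] * pn$weight / sum(pn$weight)
      for (ax in 1:3)
        f <- accumulate_at(f, dof_of(pn$nodes, ax),
                           fn * load_case$direction[ax])
    }
  }

  fix_sel <- mesh$tri_patch %in% boundary$fixed_patches
  if (!any(fix_sel)) stop("no fixed patch present in the mesh")
  fix_nodes <- sort(unique(as.vector(mesh$tris[fix_sel, ])))
  fixed_dofs <- as.integer(t(outer(fix_nodes, 1:3, dof_of)))

  ties <- NULL
  for (ci in boundary$contacts) {
    ties <- rbind(ties, data.frame(node_a = ci$pairs[, 1],
                                   node_b = ci$pairs[, 2],
                                   nx = ci$normals[, 1],
                                   ny = ci$normals[, 2],
                                   nz = ci$normals[, 3],
                                   patch = ci$patch))
  }

  structure(list(K = K, f = f, fixed_dofs = fixed_dofs, ties = ties,
                 grounded = grounded, springs = springs,
                 ndof = ndof, nnode = nnode,
                 mesh = mesh, materials = materials,
                 load_case = load_case, boundary = boundary,
                 element_volumes = tt$volumes,
                 membrane_areas = mc$areas),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat("linear_system: ", x$ndof, " DOFs, ",
      length(unique(x$fixed_dofs)), " fixed, ",
      if (is.null(x$ties)) 0L else nrow(x$ties), " contact ties, ",
      if (is.null(x$springs)) 0L else nrow(x$springs), " ligament springs, ",
      if (is.null(x$grounded)) 0L else nrow(x$grounded),
      " foundation springs\n", sep = "")
  invisible(x)
}
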