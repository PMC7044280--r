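# Orchestration of the full fused-vs-unfused study: species x variant x
# load angle, from seeded geometry to the comparison report.

#' Study configuration
#'
#' Declares the full experiment. Defaults follow the study conditions:
#' five hominoid species with their body masses (kg), both morphological
#' variants, load angle 0 (a 5 degree tilt is the sensitivity setting),
#' 20% body-weight load, 40 N/mm ligament, 20.5 N/mm lateral restraints.
#' Species share one geometry template; they differ in load magnitude, an
#' isometric size factor `(mass / ref_mass)^(1/3)`, and the seeded
#' surface perturbation drawn from a per-species sub-seed.
#'
#' @param species Data frame with `name` and `mass` (kg).
#' @param variants Character subset of `c("fused", "unfused")`.
#' @param angles Numeric load tilt angles (degrees).
#' @param geometry Named list of [geometry_params()] overrides.
#' @param materials A [material_set()].
#' @param ligament_total,ligament_strands Ligament rigidity (N/mm) and
#'   parallel strand count.
#' @param lateral_stiffness Foundation stiffness per restraint patch.
#' @param load_fraction Fraction of body weight applied.
#' @param g Gravitational acceleration (m s^-2).
#' @param partition Load partition rule (see [make_load_case()]).
#' @param tilt_axis Axis of the tilt rotation.
#' @param ref_mass Reference mass (kg) for the isometric size factor.
#' @param seed Master seed (mandatory); per-combination sub-seeds are
#'   derived as `(seed + 104729 * species_index) mod 2147483647`.
#' @param outdir Output directory, or `NULL` for no file output.
#' @return A `study_config` list.
#' @export
study_config <- function(species = data.frame(
                           name = c("H. sapiens", "G. gorilla",
                                    "P. troglodytes", "P. abelii", "H. lar"),
                           mass = c(72.1, 170.4, 59.7, 77.9, 9.5)),
                         variants = c("fused", "unfused"),
                         angles = 0,
                         geometry = list(),
                         materials = material_set(),
                         ligament_total = 40, ligament_strands = 8,
                         lateral_stiffness = 20.5,
                         load_fraction = 0.2, g = 9.80665,
                         partition = "area", tilt_axis = "y",
                         ref_mass = 59.7,
                         seed = 1L, outdir = NULL) {
  if (any(species$mass <= 0)) stop("body masses must be positive")
  if (is.null(seed) || is.na(seed)) stop("a master seed is mandatory")
  variants <- match.arg(variants, c("fused", "unfused"), several.ok = TRUE)
  structure(list(species = species, variants = variants, angles = angles,
                 geometry = geometry, materials = materials,
                 ligament_total = ligament_total,
                 ligament_strands = ligament_strands,
                 lateral_stiffness = lateral_stiffness,
                 load_fraction = load_fraction, g = g,
                 partition = partition, tilt_axis = tilt_axis,
                 ref_mass = ref_mass,
                 seed = as.integer(seed), outdir = outdir),
            class = "study_config")
}

derive_seed <- function(master, index) {
  s <- (as.numeric(master) + 104729 * index) %% 2147483647
  as.integer(max(1, s))
}

#' Load a study configuration from a YAML file
#'
#' Reads the `study:`, `geometry:`, `materials:`, `ligaments:`,
#' `boundary:` and `load:` sections (all optional except the seed, which
#' must appear under `study:`) into a [study_config()].
#'
#' @param path Path to the YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- y$study %||% list()
  args <- list()
  if (!is.null(st$species))
    args$species <- data.frame(
      name = vapply(st$species, `[[`, character(1), "name"),
      mass = vapply(st$species, function(s) as.numeric(s$mass), numeric(1)))
  for (nm in c("variants", "angles", "seed", "outdir", "ref_mass"))
    if (!is.null(st[[nm]])) args[[nm]] <- st[[nm]]
  if (!is.null(y$geometry)) args$geometry <- y$geometry
  if (!is.null(y$materials)) args$materials <- do.call(material_set, y$materials)
  lg <- y$ligaments
  if (!is.null(lg$total)) args$ligament_total <- lg$total
  if (!is.null(lg$n_strands)) args$ligament_strands <- lg$n_strands
  bd <- y$boundary
  if (!is.null(bd$lateral_stiffness))
    args$lateral_stiffness <- bd$lateral_stiffness
  ld <- y$load
  for (map in list(c("load_fraction", "fraction"), c("g", "g"),
                   c("partition", "partition"), c("tilt_axis", "tilt_axis")))
    if (!is.null(ld[[map[2]]])) args[[map[1]]] <- ld[[map[2]]]
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve one carpal model combination
#'
#' Generates the seeded geometry, assembles the full constrained system,
#' solves it, recovers stress and returns per-bone summaries together
#' with solver diagnostics.
#'
#' @param config A [study_config()].
#' @param mass Body mass (kg) for the load case.
#' @param variant `"fused"` or `"unfused"`.
#' @param angle Load tilt (degrees).
#' @param seed Geometry seed for this model.
#' @param scale Isometric size factor.
#' @return List: `mesh`, `system`, `disp`, `field`, `summary`, `diag`.
#' @export
solve_carpal_model <- function(config, mass, variant, angle, seed,
                               scale = 1) {
  gargs <- config$geometry
  gargs$seed <- seed
  gargs$scale <- scale * (gargs$scale %||% 1)
  params <- do.call(geometry_params, gargs)
  mesh <- generate_carpal_set(params, variant)
  materials <- config$materials
  # cortical shell thickness scales isometrically with bone size; the
  # cartilage layer is held at its constant thickness for every species
  materials$cortical_thickness <- materials$cortical_thickness * scale
  lig <- ligament_spec(config$ligament_total, config$ligament_strands,
                       topology = if (variant == "fused") "direct"
                                  else "serial")
  boundary <- default_boundary(mesh, config$lateral_stiffness)
  lc <- make_load_case(mass, config$load_fraction, config$g,
                       tilt_deg = angle, partition = config$partition,
                       tilt_axis = config$tilt_axis)
  t0 <- proc.time()[3]
  sys <- assemble_model(mesh, materials, lig, boundary, lc)
  t1 <- proc.time()[3]
  disp <- solve_linear(sys)
  t2 <- proc.time()[3]
  eq <- check_equilibrium(sys, disp)
  field <- recover_stress(mesh, materials, disp)
  summ <- stress_summary(field, mesh)
  diag <- data.frame(variant = variant, angle = angle, seed = seed,
                     n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets),
                     ndof = sys$ndof,
                     n_fixed = length(unique(sys$fixed_dofs)),
                     n_ties = if (is.null(sys$ties)) 0L else nrow(sys$ties),
                     residual = disp$residual,
                     equilibrium_error = eq$rel_error,
                     t_assemble = t1 - t0, t_solve = t2 - t1)
  list(mesh = mesh, system = sys, disp = disp, field = field,
       summary = summ, diag = diag)
}

#' Run the full fused-vs-unfused study
#'
#' For every species x variant x angle combination: generate the seeded
#' geometry, assemble and solve the model, and summarise per-bone von
#' Mises stress; then compare fused against unfused MWAM per bone and
#' angle with a pooled Shapiro-Wilk check and Welch's t-test. When
#' `config$outdir` is set, writes `summaries.csv`, `comparisons.csv`,
#' `study.log`, `config.resolved.yaml` and per-model VTU stress fields.
#'
#' @param config A [study_config()].
#' @param write_fields Write per-model VTU files when an output directory
#'   is configured.
#' @return A `study_report`: `summaries`, `samples`, `comparisons`,
#'   `diagnostics`, and the resolved `config`.
#' @export
run_study <- function(config = study_config(), write_fields = TRUE) {
  outdir <- config$outdir
  logf <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(outdir, "study.log")
    cat("study started ", format(Sys.time()), "\n", file = logf)
  }
  log_line <- function(...) {
    if (!is.null(logf)) cat(..., "\n", file = logf, append = TRUE)
  }
  summaries <- NULL; diagnostics <- NULL
  for (si in seq_len(nrow(config$species))) {
    sp <- config$species$name[si]
    mass <- config$species$mass[si]
    seed <- derive_seed(config$seed, si)
    scale <- (mass / config$ref_mass)^(1 / 3)
    for (variant in config$variants) {
      for (angle in config$angles) {
        res <- tryCatch(
          solve_carpal_model(config, mass, variant, angle, seed, scale),
          error = function(e)
            stop("study failed at (", sp, ", ", variant, ", ", angle,
                 " deg): ", conditionMessage(e)))
        s <- res$summary
        s <- data.frame(species = sp, variant = variant, angle_deg = angle,
                        body = s$body_name, s[, !(names(s) %in%
                          c("body", "body_name")), drop = FALSE])
        summaries <- rbind(summaries, s)
        d <- cbind(species = sp, res$diag)
        diagnostics <- rbind(diagnostics, d)
        log_line(sprintf(
          "%s %s %g deg: %d dofs, %d ties, residual %.2e, equilibrium %.2e",
          sp, variant, angle, res$diag$ndof, res$diag$n_ties,
          res$diag$residual, res$diag$equilibrium_error))
        if (!is.null(outdir) && write_fields) {
          fn <- file.path(outdir, sprintf("%s_%s_%gdeg.vtu",
                                          gsub("[^A-Za-z0-9]+", "_", sp),
                                          variant, angle))
          export_fields(res$mesh, res$field, path = fn)
        }
      }
    }
  }
  samples <- study_samples(summaries)
  comparisons <- NULL
  # the pooled normality check needs at least 3 values (2+ species)
  if (all(c("fused", "unfused") %in% config$variants) &&
      nrow(config$species) >= 2) {
    for (angle in config$angles)
      for (bone in c("scaphoid", "capitate"))
        comparisons <- rbind(comparisons,
                             compare_fused_unfused(samples, bone, angle))
  }
  report <- structure(list(summaries = summaries, samples = samples,
                           comparisons = comparisons,
                           diagnostics = diagnostics, config = config),
                      class = "study_report")
  if (!is.null(outdir)) {
    utils::write.csv(summaries, file.path(outdir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                       row.names = FALSE)
    cfg <- config
    cfg$materials <- unclass(cfg$materials)
    cfg$species <- lapply(seq_len(nrow(config$species)), function(i)
      list(name = config$species$name[i], mass = config$species$mass[i]))
    yaml::write_yaml(lapply(unclass(cfg), function(x)
      if (is.data.frame(x)) as.list(x) else x),
      file.path(outdir, "config.resolved.yaml"))
    log_line("study finished ", format(Sys.time()))
  }
  report
}

# long summary table -> tidy (species, bone, variant, angle, mwam) records;
# the fused scaphoid_centrale body stands for the scaphoid
study_samples <- function(summaries) {
  bone <- ifelse(summaries$body == "scaphoid_centrale", "scaphoid",
                 summaries$body)
  data.frame(species = summaries$species, bone = bone,
             variant = summaries$variant, angle = summaries$angle_deg,
             mwam = summaries$mwam)
}

#' Welch comparison of two load angles
#'
#' Sensitivity check: per bone, Welch's t-test between the pooled (both
#' variants) MWAM samples obtained under two load angles.
#'
#' @param report A `study_report` whose config included both angles.
#' @param angle_a,angle_b The two angles to compare (degrees).
#' @param bones Bones to test.
#' @return Data frame, one row per bone: `t`, `df`, `p`.
#' @export
sensitivity_compare <- function(report, angle_a = 0, angle_b = 5,
                                bones = c("scaphoid", "capitate")) {
  s <- report$samples
  if (!all(c(angle_a, angle_b) %in% s$angle))
    stop("both angles must be present in the report")
  out <- NULL
  for (bone in bones) {
    xa <- s$mwam[s$bone == bone & s$angle == angle_a]
    xb <- s$mwam[s$bone == bone & s$angle == angle_b]
    wt <- welch_t(xa, xb)
    out <- rbind(out, data.frame(bone = bone, angle_a = angle_a,
                                 angle_b = angle_b, t = wt$t, df = wt$df,
                                 p = wt$p))
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report: ", length(unique(x$summaries$species)), " species x ",
      length(unique(x$summaries$variant)), " variants x ",
      length(unique(x$summaries$angle_deg)), " angles\n", sep = "")
  if (!is.null(x$comparisons)) {
    cat("fused vs unfused (Welch):\n")
    print(x$comparisons[, c("bone", "angle", "mean_fused", "mean_unfused",
                            "t", "df", "p_t")], row.names = FALSE)
  }
  invisible(x)
}

#' Run the verification fixtures
#'
#' Desk-scale analytical checks of the mechanical core: the constant
#' strain patch test (uniaxial bar, sigma L / E), a grounded spring
#' (F / k), cantilever tip deflection against the Euler-Bernoulli closed
#' form, and von Mises rotation invariance.
#'
#' @param refine Cantilever mesh refinement (elements through the
#'   thickness); 12 is the level at which the tip deflection sits within
#'   5% of the closed form.
#' @return Data frame of checks: `value`, `expected`, `rel_error`, `pass`.
#' @export
verification_suite <- function(refine = 12) {
  checks <- NULL
  add <- function(name, value, expected, tol) {
    rel <- abs(value - expected) / max(abs(expected), 1e-300)
    checks <<- rbind(checks, data.frame(check = name, value = value,
                                        expected = expected,
                                        rel_error = rel, pass = rel <= tol))
  }
  bar <- uniaxial_bar_fixture(n = 4)
  add("uniaxial_bar_tip_mm", bar$tip, bar$expected, 1e-8)
  spr <- spring_fixture()
  add("grounded_spring_mm", spr$u, spr$expected, 1e-12)
  ct <- cantilever_fixture(n_len = 5 * refine, n_th = refine)
  add("cantilever_tip_mm", ct$tip, ct$expected, 0.05)
  s <- c(3, -1, 2, 0.5, -0.25, 1)
  R <- rotation_matrix(c(1, 2, 3) / sqrt(14), 0.7)
  add("von_mises_rotation", von_mises(rotate_tensor(s, R)), von_mises(s),
      1e-10)
  checks
}

# --- analytic fixtures used by verification and the test-suite ---------

uniaxial_bar_fixture <- function(n = 4, L = 10, E = 500, nu = 0, sigma = 1) {
  g <- seq(0, L, length.out = n + 1)
  b <- block_mesh(g, g, g)
  tets <- orient_tets(b$nodes, b$tets)
  nn <- nrow(b$nodes)
  tr <- tet_triplets(b$nodes, tets, E, nu)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(3 * nn, 3 * nn))
  bf <- boundary_faces(b$nodes, tets)
  cen <- tri_centroids(b$nodes, bf)
  top <- bf[abs(cen[, 3] - L) < 1e-9, , drop = FALSE]
  ar <- tri_normals(b$nodes, top)$area
  f <- numeric(3 * nn)
  f <- accumulate_at(f, dof_of(as.vector(top), 3L), rep(sigma * ar / 3, 3))
  bot <- which(abs(b$nodes[, 3]) < 1e-9)
  fixed <- c(dof_of(bot, 1L), dof_of(bot, 2L), dof_of(bot, 3L))
  sys <- structure(list(K = K, f = f, fixed_dofs = fixed, ties = NULL,
                        grounded = NULL, ndof = 3 * nn, nnode = nn),
                   class = "linear_system")
  disp <- solve_linear(sys)
  topn <- which(abs(b$nodes[, 3] - L) < 1e-9)
  list(tip = mean(disp$u[topn, 3]), expected = sigma * L / E,
       sys = sys, disp = disp, nodes = b$nodes, tets = tets)
}

spring_fixture <- function(k = 40, F = 20) {
  K <- Matrix::sparseMatrix(i = 1:6, j = 1:6, x = c(rep(1, 5), k),
                            dims = c(6, 6))
  f <- numeric(6); f[6] <- F
  sys <- structure(list(K = K, f = f, fixed_dofs = 1:3, ties = NULL,
                        grounded = NULL, ndof = 6L, nnode = 2L),
                   class = "linear_system")
  disp <- solve_linear(sys)
  list(u = disp$u[2, 3], expected = F / k)
}

cantilever_fixture <- function(n_len = 40, n_th = 8, L = 20, b = 2, h = 2,
                               E = 10000, P = 1) {
  xg <- seq(0, L, length.out = n_len + 1)
  yg <- seq(0, b, length.out = n_th + 1)
  zg <- seq(0, h, length.out = n_th + 1)
  bm <- block_mesh(xg, yg, zg)
  tets <- orient_tets(bm$nodes, bm$tets)
  nn <- nrow(bm$nodes)
  tr <- tet_triplets(bm$nodes, tets, E, 0)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(3 * nn, 3 * nn))
  tipn <- which(abs(bm$nodes[, 1] - L) < 1e-9)
  f <- numeric(3 * nn)
  f[dof_of(tipn, 3L)] <- -P / length(tipn)
  root <- which(abs(bm$nodes[, 1]) < 1e-9)
  fixed <- c(dof_of(root, 1L), dof_of(root, 2L), dof_of(root, 3L))
  sys <- structure(list(K = K, f = f, fixed_dofs = fixed, ties = NULL,
                        grounded = NULL, ndof = 3 * nn, nnode = nn),
                   class = "linear_system")
  disp <- solve_linear(sys)
  I <- b * h^3 / 12
  list(tip = -mean(disp$u[tipn, 3]), expected = P * L^3 / (3 * E * I))
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  C <- 1 - c
  matrix(c(c + a[1]^2 * C, a[1] * a[2] * C - a[3] * s,
           a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, c + a[2]^2 * C,
           a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s,
           c + a[3]^2 * C), 3, 3, byrow = TRUE)
}

rotate_tensor <- function(s6, R) {
  S <- matrix(c(s6[1], s6[4], s6[6],
                s6[4], s6[2], s6[5],
                s6[6], s6[5], s6[3]), 3, 3)
  Sp <- R %*% S %*% t(R)
  c(Sp[1, 1], Sp[2, 2], Sp[3, 3], Sp[1, 2], Sp[2, 3], Sp[3, 1])
}
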