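# Synthetic heart-torso anatomy: two truncated half-ellipsoid ventricles
# (thick LV, thin RV crescent) inside an elliptic-cylinder torso with lungs,
# liver, spine and blood pools, meshed on a graded rectilinear tet grid.

#' Geometry parameters of the synthetic anatomy
#'
#' All lengths in cm. The default is a compact adult-like torso with the
#' biventricular unit placed left-anterior, the left lung adjoining the LV
#' epicardium, the liver under the apex and the spine posterior; +z points
#' from apex towards base, -y is anterior.
#'
#' @param ... named overrides (see defaults in the function body).
#' @return named list of geometry parameters.
#' @export
geometry_params <- function(...) {
  g <- list(
    torso_rx = 8, torso_ry = 6.2, torso_zlo = -9, torso_zhi = 7,
    heart_center = c(1.2, -0.6), base_z = 1.0,
    lv_semi = c(2.1, 2.1, 4.0), lv_wall = 1.0,
    rv_offset = -0.9, rv_semi = c(2.9, 1.9, 3.7), rv_wall = 0.5,
    lung_left_center = c(5.0, 0.3, 0.5), lung_left_semi = c(2.7, 3.6, 6.5),
    lung_right_center = c(-4.6, 0.3, 0.8), lung_right_semi = c(2.9, 3.7, 6.2),
    liver_center = c(-2.5, 0.3, -5.6), liver_semi = c(4.2, 3.6, 3.2),
    spine_center = c(0, 4.7), spine_radius = 1.3,
    h_fine = 0.2, h_coarse = 0.8, jitter = 0.1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(g))
  if (length(bad)) stop("unknown geometry parameter(s): ",
                        paste(bad, collapse = ", "))
  g[names(ov)] <- ov
  g
}

in_ellipsoid <- function(p, center, semi) {
  ((p[, 1] - center[1]) / semi[1])^2 + ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2 <= 1
}

check_geometry <- function(g) {
  num <- unlist(g[c("torso_rx", "torso_ry", "lv_semi", "lv_wall",
                    "rv_semi", "rv_wall", "lung_left_semi", "lung_right_semi",
                    "liver_semi", "spine_radius", "h_fine", "h_coarse")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("infeasible geometry: all extents, wall thicknesses and mesh ",
         "targets must be positive")
  if (g$lv_wall >= min(g$lv_semi))
    stop("infeasible geometry: LV wall thickness (", g$lv_wall,
         " cm) is not smaller than the LV outer semi-axes")
  if (g$rv_wall >= min(g$rv_semi))
    stop("infeasible geometry: RV wall thickness (", g$rv_wall,
         " cm) is not smaller than the RV outer semi-axes")
  hx <- g$heart_center[1]
  if (abs(hx) + g$lv_semi[1] >= g$torso_rx ||
      abs(g$heart_center[2]) + g$lv_semi[2] >= g$torso_ry)
    stop("infeasible geometry: ventricles do not fit inside the torso")
  if (g$torso_zlo >= g$base_z - g$lv_semi[3])
    stop("infeasible geometry: torso floor above the ventricular apex")
  invisible(g)
}

# region label per centroid; also returns lv/rv wall tag for myocardium
label_regions <- function(ctr, g) {
  hc <- c(g$heart_center, g$base_z)
  lv_out <- in_ellipsoid(ctr, hc, g$lv_semi)
  lv_in <- in_ellipsoid(ctr, hc, g$lv_semi - g$lv_wall)
  rvc <- c(hc[1] + g$rv_offset, hc[2], g$base_z)
  rv_out <- in_ellipsoid(ctr, rvc, g$rv_semi)
  # cavity ellipsoid chosen so the free wall is rv_wall thick on the far side
  rv_cav_c <- c(rvc[1] + g$rv_wall / 10, rvc[2], g$base_z)
  rv_in <- in_ellipsoid(ctr, rv_cav_c, g$rv_semi - g$rv_wall)
  sub_base <- ctr[, 3] <= g$base_z
  myo_lv <- sub_base & lv_out & !lv_in
  myo_rv <- sub_base & rv_out & !lv_out & !rv_in
  blood <- sub_base & ((lv_in & lv_out) | (rv_in & rv_out & !lv_out))
  lungs <- in_ellipsoid(ctr, g$lung_left_center, g$lung_left_semi) |
    in_ellipsoid(ctr, g$lung_right_center, g$lung_right_semi)
  liver <- in_ellipsoid(ctr, g$liver_center, g$liver_semi)
  spine <- (ctr[, 1] - g$spine_center[1])^2 +
    (ctr[, 2] - g$spine_center[2])^2 <= g$spine_radius^2
  region <- rep("torso_bulk", nrow(ctr))
  region[spine] <- "spine"
  region[liver] <- "liver"
  region[lungs] <- "lungs"
  region[blood] <- "blood"
  region[myo_lv | myo_rv] <- "myocardium"
  wall <- rep(NA_character_, nrow(ctr))
  wall[myo_lv] <- "lv"
  wall[myo_rv] <- "rv"
  list(region = region, wall = wall)
}

# absorb tiny disconnected label islands into the dominant neighbor label
absorb_islands <- function(tets, region, wall) {
  myo <- region == "myocardium"
  comp <- tet_components_cpp(tets, myo)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp[comp > 0L])
    main <- which.max(sizes)
    stray <- which(comp > 0L & comp != main)
    if (length(stray) > 0.02 * sum(myo))
      stop("myocardium splits into large disconnected components; ",
           "refine the mesh or adjust the geometry")
    region[stray] <- "torso_bulk"
    wall[stray] <- NA_character_
  }
  list(region = region, wall = wall)
}

#' Generate a synthetic labeled heart-torso anatomy
#'
#' Builds a graded rectilinear tetrahedral mesh of an elliptic-cylinder torso
#' and labels every tetrahedron as one of myocardium, blood, lungs, liver,
#' spine or torso_bulk from implicit geometry. The node lattice is jittered
#' (deterministically from \code{seed}) to break grid symmetry.
#'
#' @param geometry list from \code{\link{geometry_params}}.
#' @param seed integer generation seed.
#' @return an object of class \code{anatomy_model} with fields \code{nodes}
#'   (n x 3, cm), \code{tets} (m x 4, 1-based), \code{region} (per tet),
#'   \code{wall} (\code{"lv"}/\code{"rv"} per myocardial tet), extracted
#'   heart/torso surfaces and the myocardial node index set.
#' @export
build_anatomy <- function(geometry = geometry_params(), seed = 0L) {
  g <- check_geometry(geometry)
  hc <- g$heart_center
  fb <- list( # focus box around the heart, meshed at h_fine
    x = c(hc[1] + g$rv_offset - g$rv_semi[1] - 0.3, hc[1] + g$lv_semi[1] + 0.3),
    y = c(hc[2] - g$lv_semi[2] - 0.3, hc[2] + g$lv_semi[2] + 0.3),
    z = c(g$base_z - g$lv_semi[3] - 0.3, g$base_z + 0.3)
  )
  xs <- grid_lines(-g$torso_rx, g$torso_rx, fb$x[1], fb$x[2], g$h_fine, g$h_coarse)
  ys <- grid_lines(-g$torso_ry, g$torso_ry, fb$y[1], fb$y[2], g$h_fine, g$h_coarse)
  zs <- grid_lines(g$torso_zlo, g$torso_zhi, fb$z[1], fb$z[2], g$h_fine, g$h_coarse)
  gr <- grid_tets(xs, ys, zs)
  nodes <- gr$nodes
  if (g$jitter > 0) {
    # jitter interior lattice nodes by a fraction of the local spacing
    sp <- function(v) { d <- diff(v); pmin(c(d[1], d), c(d, d[length(d)])) }
    hx <- sp(xs)[match(nodes[, 1], xs)]
    hy <- sp(ys)[match(nodes[, 2], ys)]
    hz <- sp(zs)[match(nodes[, 3], zs)]
    nodes <- with_seed(seed, {
      n <- nrow(nodes)
      jit <- matrix(runif(3 * n, -1, 1), n, 3) * cbind(hx, hy, hz) * g$jitter
      unname(nodes + jit)
    })
  }
  ctr <- tet_centroids(nodes, gr$tets)
  inside <- (ctr[, 1] / g$torso_rx)^2 + (ctr[, 2] / g$torso_ry)^2 <= 1 &
    ctr[, 3] >= g$torso_zlo & ctr[, 3] <= g$torso_zhi
  cm <- compact_mesh(nodes, gr$tets, inside)
  lab <- label_regions(tet_centroids(cm$nodes, cm$tets), g)
  lab <- absorb_islands(cm$tets, lab$region, lab$wall)
  region <- lab$region
  missing <- setdiff(REGIONS, unique(region))
  if (length(missing))
    stop("generated anatomy lacks region(s): ", paste(missing, collapse = ", "))
  surfaces <- anatomy_surfaces(cm$tets, region)
  myo_nodes <- sort(unique(as.vector(
    cm$tets[region == "myocardium", , drop = FALSE])))
  structure(list(
    nodes = cm$nodes, tets = cm$tets, region = region, wall = lab$wall,
    surfaces = surfaces, myo_nodes = myo_nodes, geometry = g,
    generation_seed = as.integer(seed),
    mesh_hash = mesh_hash(cm$nodes, cm$tets)
  ), class = "anatomy_model")
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat("anatomy_model:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  print(table(x$region))
  invisible(x)
}

#' Rectangular myocardial bar (calibration mesh)
#'
#' A thin all-myocardium bar used for conduction-velocity calibration and
#' solver verification; no bath, uniform fibers.
#'
#' @param length,width,height bar extents in cm.
#' @param h target edge length in cm.
#' @return an \code{anatomy_model} whose tets are all myocardium.
#' @export
build_bar_anatomy <- function(length = 2, width = 0.1, height = 0.1, h = 0.02) {
  stopifnot(length > 0, width > 0, height > 0, h > 0)
  xs <- seq(0, length, by = h)
  ys <- seq(0, width, by = h)
  zs <- seq(0, height, by = h)
  gr <- grid_tets(xs, ys, zs)
  region <- rep("myocardium", nrow(gr$tets))
  surfaces <- anatomy_surfaces(gr$tets, region)
  structure(list(
    nodes = gr$nodes, tets = gr$tets, region = region,
    wall = rep("lv", nrow(gr$tets)),
    surfaces = surfaces, myo_nodes = seq_len(nrow(gr$nodes)),
    geometry = list(bar = c(length, width, height), h_fine = h),
    generation_seed = 0L, mesh_hash = mesh_hash(gr$nodes, gr$tets)
  ), class = "anatomy_model")
}

# isotropic Laplace solve on the myocardial sub-mesh with Dirichlet data
laplace_dirichlet <- function(anatomy, fixed_idx, fixed_val) {
  myo <- anatomy$region == "myocardium"
  m <- sum(myo)
  tensors <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = nrow(anatomy$tets)),
                    ncol = 6)
  asm <- fem_assemble_cpp(anatomy$nodes, anatomy$tets, tensors, myo)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = rep(nrow(anatomy$nodes), 2))
  mn <- anatomy$myo_nodes
  K <- K[mn, mn, drop = FALSE]
  loc <- match(fixed_idx, mn)
  if (anyNA(loc)) stop("Dirichlet nodes outside the myocardium")
  free <- setdiff(seq_along(mn), loc)
  u <- numeric(length(mn))
  u[loc] <- fixed_val
  rhs <- -K[free, loc, drop = FALSE] %*% u[loc]
  u[free] <- as.vector(Matrix::solve(
    Matrix::forceSymmetric(K[free, free, drop = FALSE]), rhs))
  u
}

#' Apicobasal and transmural anatomical coordinates
#'
#' Solves two Laplace-Dirichlet problems on the myocardial sub-mesh:
#' the transmural depth d (0 on the endocardium, identified as
#' myocardium-blood interfaces, 1 on the epicardium, identified as
#' myocardium-to-torso/lung/liver interfaces and exterior walls) and the
#' normalized apicobasal coordinate z (0 on an apical cap, 1 on the base
#' plane).
#'
#' @param anatomy an \code{anatomy_model}.
#' @param apex_cap thickness (cm) of the apical node cap clamped to z = 0.
#' @return object of class \code{anatomical_coords}: lists \code{z_apicobasal}
#'   and \code{d_transmural} aligned with \code{anatomy$myo_nodes}, plus the
#'   endo/epi node sets.
#' @export
compute_anatomical_coords <- function(anatomy, apex_cap = 0.45) {
  faces <- anatomy$surfaces$faces
  myo <- anatomy$region == "myocardium"
  lab <- function(t) ifelse(t == 0L, "outside", anatomy$region[pmax(t, 1L)])
  l1 <- lab(faces[, 4]); l2 <- lab(faces[, 5])
  myo_face <- (l1 == "myocardium") | (l2 == "myocardium")
  other <- ifelse(l1 == "myocardium", l2, l1)
  endo_f <- myo_face & other == "blood"
  epi_f <- myo_face & other %in% c("lungs", "liver", "spine", "torso_bulk",
                                   "outside")
  if (!any(endo_f)) stop("no endocardial surface found (myocardium is ",
                         "nowhere adjacent to blood)")
  endo_nodes <- sort(unique(as.vector(faces[endo_f, 1:3])))
  epi_nodes <- setdiff(sort(unique(as.vector(faces[epi_f, 1:3]))), endo_nodes)
  d <- laplace_dirichlet(anatomy,
                         c(endo_nodes, epi_nodes),
                         c(rep(0, length(endo_nodes)), rep(1, length(epi_nodes))))
  mn <- anatomy$myo_nodes
  zc <- anatomy$nodes[mn, 3]
  zmin <- min(zc); zmax <- max(zc)
  apex_nodes <- mn[zc <= zmin + apex_cap]
  base_nodes <- setdiff(mn[zc >= zmax - 0.15], apex_nodes)
  if (!length(base_nodes)) base_nodes <- mn[which.max(zc)]
  z <- laplace_dirichlet(anatomy,
                         c(apex_nodes, base_nodes),
                         c(rep(0, length(apex_nodes)), rep(1, length(base_nodes))))
  clamp <- function(v) pmin(1, pmax(0, v))
  structure(list(z_apicobasal = clamp(z), d_transmural = clamp(d),
                 myo_nodes = mn, endo_nodes = endo_nodes,
                 epi_nodes = epi_nodes),
            class = "anatomical_coords")
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Rule-based myofiber field
#'
#' Fibers lie in the plane tangent to the wall (orthogonal to the transmural
#' gradient) and rotate linearly with transmural depth from
#' \code{helix_endo_deg} on the endocardium to \code{helix_epi_deg} on the
#' epicardium, measured against the circumferential direction.
#'
#' @param anatomy an \code{anatomy_model}.
#' @param coords matching \code{anatomical_coords}.
#' @param helix_endo_deg,helix_epi_deg helix angles in degrees, in (-90, 90).
#' @param axis long-axis unit vector (apex to base).
#' @return object of class \code{fiber_field}: unit fiber per myocardial tet.
#' @export
assign_fibers <- function(anatomy, coords, helix_endo_deg = 60,
                          helix_epi_deg = -60, axis = c(0, 0, 1)) {
  if (abs(helix_endo_deg) >= 90 || abs(helix_epi_deg) >= 90)
    stop("helix angles must lie in (-90, 90) degrees")
  axis <- axis / sqrt(sum(axis^2))
  myo_tets <- which(anatomy$region == "myocardium")
  dfull <- numeric(nrow(anatomy$nodes))
  dfull[coords$myo_nodes] <- coords$d_transmural
  gall <- tet_gradient_cpp(anatomy$nodes, anatomy$tets, dfull)
  gt <- gall[myo_tets, , drop = FALSE]
  # recover a smooth gradient: volume-weighted average at nodes, then back
  # to tets (raw P1 gradients vanish on tets whose nodes all sit on one
  # Dirichlet surface)
  tt <- anatomy$tets[myo_tets, , drop = FALSE]
  vol <- tet_volumes(anatomy$nodes, tt)
  nn <- nrow(anatomy$nodes)
  for (pass in 1:3) {
    acc <- matrix(0, nn, 3)
    wacc <- numeric(nn)
    for (k in 1:4) {
      idx <- tt[, k]
      for (dcomp in 1:3)
        acc[, dcomp] <- acc[, dcomp] +
          unname(tapply_add(gt[, dcomp] * vol, idx, nn))
      wacc <- wacc + unname(tapply_add(vol, idx, nn))
    }
    gnode <- acc / pmax(wacc, 1e-300)
    gt <- (gnode[tt[, 1], ] + gnode[tt[, 2], ] + gnode[tt[, 3], ] +
             gnode[tt[, 4], ]) / 4
    if (all(sqrt(rowSums(gt^2)) >= 1e-6)) break
  }
  gn <- sqrt(rowSums(gt^2))
  bad <- which(gn < 1e-6)
  if (length(bad))
    stop("degenerate transmural gradient in ", length(bad),
         " myocardial element(s): ",
         paste(head(myo_tets[bad], 10), collapse = ", "))
  et <- gt / gn
  # apicobasal tangent: long axis projected onto the wall-tangent plane
  proj <- et %*% axis
  el <- -sweep(et, 1, as.vector(proj), "*")
  el[, 1] <- el[, 1] + axis[1]
  el[, 2] <- el[, 2] + axis[2]
  el[, 3] <- el[, 3] + axis[3]
  eln <- sqrt(rowSums(el^2))
  flat <- eln < 1e-6
  if (any(flat)) { # wall normal parallel to the axis (apex cap): pick any tangent
    alt <- cbind(-et[flat, 2], et[flat, 1], 0)
    altn <- sqrt(rowSums(alt^2))
    alt[altn < 1e-6, ] <- matrix(c(1, 0, 0), sum(altn < 1e-6), 3, byrow = TRUE)
    el[flat, ] <- alt
    eln[flat] <- sqrt(rowSums(el[flat, , drop = FALSE]^2))
  }
  el <- el / eln
  ec <- cbind(et[, 2] * el[, 3] - et[, 3] * el[, 2],
              et[, 3] * el[, 1] - et[, 1] * el[, 3],
              et[, 1] * el[, 2] - et[, 2] * el[, 1])
  ec <- normalize_rows(ec)
  dtet <- rowMeans(matrix(dfull[anatomy$tets[myo_tets, ]], ncol = 4))
  ang <- (helix_endo_deg + (helix_epi_deg - helix_endo_deg) * dtet) * pi / 180
  fib <- normalize_rows(ec * cos(ang) + el * sin(ang))
  structure(list(fiber = fib, myo_tets = myo_tets,
                 helix = c(endo = helix_endo_deg, epi = helix_epi_deg)),
            class = "fiber_field")
}

#' Uniform fiber field (for bars and verification meshes)
#' @param anatomy an \code{anatomy_model}.
#' @param direction fiber direction (normalized internally).
#' @return a \code{fiber_field}.
#' @export
uniform_fiber_field <- function(anatomy, direction = c(1, 0, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  myo_tets <- which(anatomy$region == "myocardium")
  structure(list(
    fiber = matrix(direction, length(myo_tets), 3, byrow = TRUE),
    myo_tets = myo_tets, helix = c(endo = 0, epi = 0)
  ), class = "fiber_field")
}


tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  abs(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# sparse scatter-add of x into bins 1..n
tapply_add <- function(x, bins, n) {
  out <- numeric(n)
  s <- rowsum(x, bins)
  out[as.integer(rownames(s))] <- s
  out
}
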