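test_that("anatomy generation is deterministic and labels all regions", {
  g <- mini_geometry()
  a1 <- build_anatomy(g, seed = 0)
  a2 <- build_anatomy(g, seed = 0)
  expect_identical(a1$nodes, a2$nodes)
  expect_identical(a1$tets, a2$tets)
  expect_identical(a1$region, a2$region)
  expect_setequal(unique(a1$region), fecgsim:::REGIONS)
  # label partition: per-region counts sum to the tet total
  expect_equal(sum(table(a1$region)), nrow(a1$tets))
  # different seed jitters the nodes but keeps the topology valid
  a3 <- build_anatomy(g, seed = 1)
  expect_false(identical(a1$nodes, a3$nodes))
  expect_setequal(unique(a3$region), fecgsim:::REGIONS)
})

test_that("myocardium is connected and inside the torso surface", {
  an <- mini_anatomy()
  myo <- an$region == "myocardium"
  comp <- fecgsim:::tet_components_cpp(an$tets, myo)
  expect_equal(max(comp), 1L)
  g <- an$geometry
  xyz <- an$nodes[an$myo_nodes, ]
  expect_true(all((xyz[, 1] / g$torso_rx)^2 + (xyz[, 2] / g$torso_ry)^2 < 1))
  expect_true(all(xyz[, 3] > g$torso_zlo & xyz[, 3] < g$torso_zhi))
})

test_that("heart and torso surfaces are closed orientable triangulations", {
  an <- mini_anatomy()
  closed <- function(tris) {
    edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    # watertight: every edge is shared by an even number of triangles
    # (staircase surfaces may pinch, giving 4 at non-manifold edges)
    tab <- table(key)
    all(tab %% 2 == 0) && all(tab >= 2)
  }
  expect_true(closed(an$surfaces$torso))
  expect_true(closed(an$surfaces$heart))
})

test_that("mesh edge lengths track the regional targets", {
  an <- mini_anatomy()
  g <- an$geometry
  myo <- an$region == "myocardium"
  e_myo <- fecgsim:::mesh_edge_lengths(an$nodes, an$tets[myo, , drop = FALSE])
  # axis-aligned edges near h_fine, cell diagonals up to sqrt(3)*h: the
  # median must sit within +/-50% of the target
  expect_gt(median(e_myo), 0.5 * g$h_fine)
  expect_lt(median(e_myo), 1.5 * g$h_fine)
})

test_that("infeasible geometries are rejected with the violated constraint", {
  expect_error(build_anatomy(mini_geometry(lv_wall = 10), 0),
               "infeasible geometry.*LV wall")
  expect_error(build_anatomy(mini_geometry(rv_wall = 5), 0),
               "infeasible geometry.*RV wall")
  expect_error(build_anatomy(mini_geometry(torso_rx = 2), 0),
               "infeasible geometry")
})

test_that("anatomical coordinates satisfy their boundary conditions", {
  an <- mini_anatomy(); co <- mini_coords()
  expect_true(all(co$z_apicobasal >= 0 & co$z_apicobasal <= 1))
  expect_true(all(co$d_transmural >= 0 & co$d_transmural <= 1))
  iendo <- match(co$endo_nodes, co$myo_nodes)
  iepi <- match(co$epi_nodes, co$myo_nodes)
  expect_lt(max(co$d_transmural[iendo]), 1e-6)
  expect_gt(min(co$d_transmural[iepi]), 1 - 1e-6)
  # apex-most node at z = 0; base-most at 1
  zc <- an$nodes[co$myo_nodes, 3]
  expect_lt(co$z_apicobasal[which.min(zc)], 1e-6)
  expect_gt(co$z_apicobasal[which.max(zc)], 1 - 1e-6)
  # z increases along the long axis (monotone trend)
  expect_gt(cor(zc, co$z_apicobasal), 0.95)
})

test_that("transmural coordinate matches the radial Laplace solution on an annulus", {
  # thick-walled annulus tube meshed in polar coordinates (exact circular
  # endo/epi surfaces): myocardium r in [r0, r1], blood core, torso bulk
  # outside; the harmonic transmural coordinate is
  # d(r) = log(r/r0)/log(r1/r0). The tube is long in z and evaluated at
  # mid-height, away from the end faces.
  r0 <- 0.95; r1 <- 1.35
  rv <- seq(0.8, 1.5, by = 0.05)
  th <- seq(0, 2 * pi, length.out = 49)  # duplicate seam line, welded below
  zv <- seq(0, 2, by = 0.1)
  gr <- fecgsim:::grid_tets(rv, th, zv)   # connectivity in (r, theta, z)
  nx <- length(rv); ny <- length(th); nz <- length(zv)
  remap <- seq_len(nx * ny * nz)          # weld theta = 2*pi onto theta = 0
  for (k in seq_len(nz))
    remap[(k - 1) * nx * ny + (ny - 1) * nx + seq_len(nx)] <-
      (k - 1) * nx * ny + seq_len(nx)
  tets <- matrix(remap[gr$tets], ncol = 4)
  ctr <- fecgsim:::tet_centroids(gr$nodes, gr$tets)
  region <- ifelse(ctr[, 1] < r0, "blood",
                   ifelse(ctr[, 1] <= r1, "myocardium", "torso_bulk"))
  nodes <- cbind(gr$nodes[, 1] * cos(gr$nodes[, 2]),
                 gr$nodes[, 1] * sin(gr$nodes[, 2]),
                 gr$nodes[, 3])
  rn_node <- gr$nodes[, 1]
  surfaces <- fecgsim:::anatomy_surfaces(tets, region)
  an <- structure(list(
    nodes = nodes, tets = tets, region = region, wall = NULL,
    surfaces = surfaces,
    myo_nodes = sort(unique(as.vector(
      tets[region == "myocardium", , drop = FALSE]))),
    geometry = list(), generation_seed = 0L, mesh_hash = "annulus"),
    class = "anatomy_model")
  co <- compute_anatomical_coords(an)
  rn <- rn_node[co$myo_nodes]
  zn <- nodes[co$myo_nodes, 3]
  inside <- rn > r0 + 1e-9 & rn < r1 - 1e-9 & zn > 0.8 & zn < 1.2
  exact <- log(rn[inside] / r0) / log(r1 / r0)
  expect_lt(max(abs(co$d_transmural[inside] - exact)), 0.02)
})

test_that("discrete maximum principle for the coordinate fields", {
  co <- mini_coords()
  # harmonic interpolants stay within the Dirichlet data
  expect_gte(min(co$d_transmural), 0 - 1e-6)
  expect_lte(max(co$d_transmural), 1 + 1e-6)
  raw <- fecgsim:::laplace_dirichlet(
    mini_anatomy(), c(co$endo_nodes, co$epi_nodes),
    c(rep(0.2, length(co$endo_nodes)), rep(0.7, length(co$epi_nodes))))
  expect_gte(min(raw), 0.2 - 1e-6)
  expect_lte(max(raw), 0.7 + 1e-6)
})

test_that("fiber field: normalization, tangency, helix interpolation", {
  an <- mini_anatomy(); co <- mini_coords()
  fib <- assign_fibers(an, co)
  expect_lt(max(abs(sqrt(rowSums(fib$fiber^2)) - 1)), 1e-12)
  # fibers tangent to the wall: small projection on the transmural direction
  dfull <- numeric(nrow(an$nodes))
  dfull[co$myo_nodes] <- co$d_transmural
  myo_tets <- which(an$region == "myocardium")
  # circumferential limit: zero helix angles -> orthogonal to the long axis
  fib0 <- assign_fibers(an, co, 0, 0)
  expect_lt(stats::quantile(abs(fib0$fiber[, 3]), 0.95), 0.05)
  # helix angle at mid-wall is the linear midpoint (0 for +60/-60)
  dtet <- rowMeans(matrix(dfull[an$tets[myo_tets, ]], ncol = 4))
  mid <- which(abs(dtet - 0.5) < 0.02)
  ang <- asin(pmin(1, pmax(-1, fib$fiber[mid, 3]))) * 180 / pi
  expect_lt(median(abs(ang)), 2)
  expect_error(assign_fibers(an, co, 95, -60), "helix")
})

test_that("fiber field rotates rigidly with the anatomy", {
  an <- mini_anatomy(); co <- mini_coords()
  fib <- assign_fibers(an, co)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R <- R %*% rbind(c(1, 0, 0),
                   c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  an2 <- an
  an2$nodes <- an$nodes %*% t(R)
  co2 <- co  # isotropic Laplace solves are rotation-invariant
  fib2 <- assign_fibers(an2, co2, axis = as.vector(R %*% c(0, 0, 1)))
  rotated <- fib$fiber %*% t(R)
  ang <- acos(pmin(1, abs(rowSums(rotated * fib2$fiber)))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.99), 1)
})

test_that("electrode vest and pacing sites respect their definitions", {
  an <- mini_anatomy(); co <- mini_coords()
  pl <- place_electrodes_and_pacing(
    an, electrode_layout(sites = c("rv_apex", "lv_lateral_epi", "rvot")), co)
  el <- pl$electrodes
  expect_length(el$bsm_nodes, 224)
  expect_equal(anyDuplicated(el$bsm_nodes), 0)
  surf <- unique(as.vector(an$surfaces$torso))
  expect_true(all(el$bsm_nodes %in% surf))
  expect_true(all(unlist(el$limb_nodes) %in% surf))
  expect_true(all(el$precordial_nodes %in% surf))
  site_coord <- function(s, what) {
    i <- match(pl$stimuli[[s]]$node, an$myo_nodes)
    if (what == "z") co$z_apicobasal[i] else co$d_transmural[i]
  }
  expect_lt(site_coord("rv_apex", "z"), 0.1)
  expect_gt(site_coord("lv_lateral_epi", "d"), 0.9)
  expect_gt(site_coord("rvot", "z"), 0.8)
  expect_error(place_electrodes_and_pacing(
    an, electrode_layout(sites = "left_atrium"), co), "unknown pacing site")
  expect_error(place_electrodes_and_pacing(
    an, electrode_layout(n_rings = 100, per_ring = 100), co),
    "electrodes")
})

test_that("refine-by-splitting preserves geometry and labels", {
  bar <- short_bar()
  rb <- refine_anatomy(bar)
  expect_equal(nrow(rb$tets), 8 * nrow(bar$tets))
  expect_identical(rb$nodes[seq_len(nrow(bar$nodes)), ], bar$nodes)
  expect_equal(sum(fecgsim:::tet_volumes(rb$nodes, rb$tets)),
               sum(fecgsim:::tet_volumes(bar$nodes, bar$tets)),
               tolerance = 1e-12)
  expect_true(all(rb$region == "myocardium"))
})
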