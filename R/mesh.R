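# Rectilinear tetrahedral meshing utilities. Grids are graded (fine inside a
# focus box, coarsening geometrically outside) and carved into six Kuhn
# tetrahedra per hexahedral cell, which is conforming across cells.

REGIONS <- c("myocardium", "blood", "lungs", "liver", "spine", "torso_bulk")

# 1-D grid: spacing h_fine on [flo, fhi], growing geometrically (ratio 1.4)
# up to h_coarse towards lo and hi.
grid_lines <- function(lo, hi, flo, fhi, h_fine, h_coarse, ratio = 1.4) {
  stopifnot(lo < flo, fhi < hi, h_fine > 0, h_coarse >= h_fine)
  mid <- seq(flo, fhi, length.out = max(2L, ceiling((fhi - flo) / h_fine) + 1L))
  grow <- function(from, bound, dir) {
    out <- numeric(0)
    h <- h_fine
    x <- from
    while ((bound - x) * dir > 1e-9) {
      h <- min(h * ratio, h_coarse, abs(bound - x))
      x <- x + dir * h
      out <- c(out, x)
    }
    if (length(out)) out[length(out)] <- bound
    out
  }
  sort(unique(c(grow(flo, lo, -1), mid, grow(fhi, hi, +1))))
}

# Tetrahedralize the full rectilinear grid; returns nodes and 6*m tets.
# Kuhn split along the (0,0,0)-(1,1,1) cell diagonal, identical in every
# cell so shared faces match.
grid_tets <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  id <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  v <- function(dx, dy, dz) id(ci + dx, cj + dy, ck + dz)
  c000 <- v(0L,0L,0L); c100 <- v(1L,0L,0L); c010 <- v(0L,1L,0L)
  c110 <- v(1L,1L,0L); c001 <- v(0L,0L,1L); c101 <- v(1L,0L,1L)
  c011 <- v(0L,1L,1L); c111 <- v(1L,1L,1L)
  # six path tetrahedra sharing diagonal c000-c111
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c110, c010, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c011, c001, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c101, c100, c111)
  )
  dimnames(tets) <- NULL
  list(nodes = nodes, tets = tets)
}

# drop unreferenced nodes, remap tet indices
compact_mesh <- function(nodes, tets, keep_tets) {
  tets <- tets[keep_tets, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  tets[] <- remap[tets]
  list(nodes = nodes[used, , drop = FALSE], tets = tets, used = used)
}

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
   nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

mesh_edge_lengths <- function(nodes, tets) {
  pairs <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  unlist(lapply(seq_len(nrow(pairs)), function(r) {
    a <- tets[, pairs[r, 1]]; b <- tets[, pairs[r, 2]]
    sqrt(rowSums((nodes[a, , drop = FALSE] - nodes[b, , drop = FALSE])^2))
  }))
}

# faces of the mesh with adjacent tets (from C++); cached per call site
mesh_faces <- function(tets) mesh_faces_cpp(tets)

# boundary triangles of a tet subset, and interface triangles between a
# subset and everything else
subset_surface <- function(faces, in_subset) {
  t1 <- faces[, 4]; t2 <- faces[, 5]
  a <- in_subset[t1]
  b <- ifelse(t2 == 0L, FALSE, in_subset[pmax(t2, 1L)])
  sel <- (a & !b) | (!a & b)
  faces[sel, 1:3, drop = FALSE]
}

#' Uniformly refine a labeled tetrahedral mesh by splitting
#'
#' Each tetrahedron is split into eight children (refine-by-splitting);
#' per-tet attributes (region labels, fibers) are inherited from the parent.
#' Parent nodes keep their indices, so coarse-mesh nodal traces can be
#' compared directly against refined-mesh traces.
#'
#' @param anatomy an \code{anatomy_model}.
#' @return a refined \code{anatomy_model}.
#' @export
refine_anatomy <- function(anatomy) {
  r <- refine_tets_cpp(anatomy$nodes, anatomy$tets)
  out <- anatomy
  out$nodes <- r$nodes
  out$tets <- r$tets
  out$region <- anatomy$region[r$parent]
  if (!is.null(anatomy$wall)) out$wall <- anatomy$wall[r$parent]
  out$surfaces <- anatomy_surfaces(out$tets, out$region)
  out$myo_nodes <- sort(unique(as.vector(
    out$tets[out$region == "myocardium", , drop = FALSE])))
  out$refined_from <- anatomy$mesh_hash
  out$mesh_hash <- mesh_hash(out$nodes, out$tets)
  out
}

mesh_hash <- function(nodes, tets) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(c(as.vector(nodes), as.double(tets)), f)
  unname(tools::md5sum(f))
}

anatomy_surfaces <- function(tets, region) {
  faces <- mesh_faces(tets)
  myo <- region == "myocardium"
  list(
    heart = subset_surface(faces, myo),
    torso = faces[faces[, 5] == 0L, 1:3, drop = FALSE],
    faces = faces
  )
}
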