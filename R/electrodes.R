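# Electrode vests and focal pacing sites on the synthetic anatomy.

#' Electrode vest layout specification
#'
#' The default layout is a regular grid over the whole torso circumference:
#' \code{n_rings} rings of \code{per_ring} electrodes (default 14 x 16 = 224
#' unipolar leads), plus the three limb electrodes (RA, LA, LL) and the six
#' precordial positions V1-V6 on the anterior chest.
#'
#' @param n_rings,per_ring vest grid dimensions.
#' @param sites pacing site names among \code{"rv_apex"},
#'   \code{"lv_lateral_epi"}, \code{"rvot"}.
#' @param custom_sites optional list of 3-vectors (cm) for custom pacing
#'   points.
#' @return layout list.
#' @export
electrode_layout <- function(n_rings = 14, per_ring = 16,
                             sites = "rv_apex", custom_sites = list()) {
  list(name = "vest_grid", n_rings = n_rings, per_ring = per_ring,
       sites = sites, custom_sites = custom_sites)
}

# nearest unused node among candidates, deterministic
snap_nodes <- function(targets, node_xyz, cand) {
  out <- integer(nrow(targets))
  used <- logical(length(cand))
  for (k in seq_len(nrow(targets))) {
    d2 <- (node_xyz[cand, 1] - targets[k, 1])^2 +
      (node_xyz[cand, 2] - targets[k, 2])^2 +
      (node_xyz[cand, 3] - targets[k, 3])^2
    d2[used] <- Inf
    j <- which.min(d2)
    used[j] <- TRUE
    out[k] <- cand[j]
  }
  out
}

#' Place the electrode vest and pacing sites
#'
#' Electrodes are snapped to the nearest (unused) torso-surface node; pacing
#' centers snap to the myocardial node matching the named site: rv_apex is
#' the lowest node of the RV wall, lv_lateral_epi an epicardial node of the
#' lateral LV, rvot a basal anterior RV node.
#'
#' @param anatomy an \code{anatomy_model} from \code{\link{build_anatomy}}.
#' @param layout_spec from \code{\link{electrode_layout}}.
#' @param coords optional precomputed \code{anatomical_coords} (computed on
#'   demand otherwise).
#' @return list with \code{electrodes} (class \code{electrode_array}) and
#'   \code{stimuli} (list of \code{\link{stimulus_region}}).
#' @export
place_electrodes_and_pacing <- function(anatomy, layout_spec = electrode_layout(),
                                        coords = NULL) {
  g <- anatomy$geometry
  if (is.null(g$torso_rx)) stop("electrode placement needs a torso anatomy")
  surf_nodes <- sort(unique(as.vector(anatomy$surfaces$torso)))
  nb <- layout_spec$n_rings * layout_spec$per_ring
  if (nb + 9 > length(surf_nodes))
    stop("requested ", nb, " electrodes but the torso surface has only ",
         length(surf_nodes), " nodes")
  on_torso <- function(theta, z)  # theta = 0 anterior, increasing to patient left
    cbind(g$torso_rx * sin(theta), -g$torso_ry * cos(theta), z)
  zr <- seq(g$torso_zlo + 1.2, g$torso_zhi - 1.2,
            length.out = layout_spec$n_rings)
  th <- seq(0, 2 * pi, length.out = layout_spec$per_ring + 1)[-1]
  targets <- on_torso(rep(th, times = layout_spec$n_rings),
                      rep(zr, each = layout_spec$per_ring))
  aux <- rbind(
    RA = on_torso(-1.1, g$torso_zhi - 0.6),
    LA = on_torso(1.1, g$torso_zhi - 0.6),
    LL = on_torso(0.9, g$torso_zlo + 0.6),
    V1 = on_torso(-0.18, 0.6), V2 = on_torso(0.10, 0.6),
    V3 = on_torso(0.28, 0.0), V4 = on_torso(0.45, -0.6),
    V5 = on_torso(0.75, -0.6), V6 = on_torso(1.05, -0.6))
  all_nodes <- snap_nodes(rbind(targets, aux), anatomy$nodes, surf_nodes)
  bsm <- all_nodes[seq_len(nb)]
  names(bsm) <- paste0("e", seq_len(nb))
  auxn <- all_nodes[nb + 1:9]
  electrodes <- structure(list(
    bsm_nodes = bsm,
    limb_nodes = list(RA = auxn[1], LA = auxn[2], LL = auxn[3]),
    precordial_nodes = stats::setNames(auxn[4:9], paste0("V", 1:6)),
    layout = layout_spec$name
  ), class = "electrode_array")

  sites <- layout_spec$sites
  known <- c("rv_apex", "lv_lateral_epi", "rvot")
  bad <- setdiff(sites, known)
  if (length(bad)) stop("unknown pacing site(s): ", paste(bad, collapse = ", "))
  stimuli <- list()
  if (length(sites) || length(layout_spec$custom_sites)) {
    if (is.null(coords)) coords <- compute_anatomical_coords(anatomy)
    mn <- anatomy$myo_nodes
    xyz <- anatomy$nodes
    rv_nodes <- sort(unique(as.vector(
      anatomy$tets[which(anatomy$region == "myocardium" &
                           !is.na(anatomy$wall) & anatomy$wall == "rv"), ,
                   drop = FALSE])))
    for (s in sites) {
      node <- switch(s,
        rv_apex = rv_nodes[which.min(xyz[rv_nodes, 3])],
        lv_lateral_epi = {
          epi <- mn[coords$d_transmural >= 0.95 &
                      coords$z_apicobasal >= 0.3 &
                      coords$z_apicobasal <= 0.8]
          epi[which.max(xyz[epi, 1])]
        },
        rvot = {
          ant <- rv_nodes[xyz[rv_nodes, 2] < anatomy$geometry$heart_center[2]]
          if (!length(ant)) ant <- rv_nodes
          ant[which.max(xyz[ant, 3])]
        })
      stimuli[[s]] <- stimulus_region(xyz[node, ])
      stimuli[[s]]$site <- s
      stimuli[[s]]$node <- node
    }
    for (k in seq_along(layout_spec$custom_sites)) {
      pt <- layout_spec$custom_sites[[k]]
      d2 <- (xyz[mn, 1] - pt[1])^2 + (xyz[mn, 2] - pt[2])^2 +
        (xyz[mn, 3] - pt[3])^2
      node <- mn[which.min(d2)]
      nm <- paste0("custom", k)
      stimuli[[nm]] <- stimulus_region(xyz[node, ])
      stimuli[[nm]]$site <- nm
      stimuli[[nm]]$node <- node
    }
  }
  list(electrodes = electrodes, stimuli = stimuli, coords = coords)
}
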