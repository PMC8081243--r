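# Text-format round-tripping: VTU (ASCII XML unstructured grid) for meshes
# and surface maps, CSV for lead signals and simulation results, JSON for
# electrodes, biomarkers and manifests. External files use 0-based node
# indexing (the VTU convention); in-memory R objects are 1-based.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Export an anatomy (with optional fields) to VTU
#'
#' Writes an ASCII XML unstructured-grid file with the integer cell field
#' \code{region} (1 = myocardium ... 6 = torso_bulk), optional vector cell
#' field \code{fiber} and optional point fields \code{z_apicobasal},
#' \code{d_transmural} (NaN outside the myocardium).
#'
#' @param anatomy an \code{anatomy_model}.
#' @param path output file.
#' @param coords optional \code{anatomical_coords}.
#' @param fibers optional \code{fiber_field}.
#' @param extra_point_fields,extra_cell_fields optional named lists of
#'   numeric vectors.
#' @export
write_anatomy_vtu <- function(anatomy, path, coords = NULL, fibers = NULL,
                              extra_point_fields = list(),
                              extra_cell_fields = list()) {
  n <- nrow(anatomy$nodes); m <- nrow(anatomy$tets)
  da <- function(name, x, type = "Float64", ncomp = 1)
    paste0('<DataArray type="', type, '" Name="', name,
           '" NumberOfComponents="', ncomp, '" format="ascii">\n',
           paste(if (type == "Float64") fmt_num(x) else as.integer(x),
                 collapse = " "),
           "\n</DataArray>")
  pts <- paste0('<DataArray type="Float64" NumberOfComponents="3" ',
                'format="ascii">\n',
                paste(fmt_num(as.vector(t(anatomy$nodes))), collapse = " "),
                "\n</DataArray>")
  cell_fields <- c(
    list(region = da("region", match(anatomy$region, REGIONS), "Int32")),
    if (!is.null(fibers)) {
      fib_full <- matrix(0, m, 3)
      fib_full[fibers$myo_tets, ] <- fibers$fiber
      list(fiber = da("fiber", as.vector(t(fib_full)), ncomp = 3))
    },
    lapply(names(extra_cell_fields), function(nm)
      da(nm, extra_cell_fields[[nm]]))
  )
  point_fields <- c(
    if (!is.null(coords)) {
      z <- rep(NaN, n); d <- rep(NaN, n)
      z[coords$myo_nodes] <- coords$z_apicobasal
      d[coords$myo_nodes] <- coords$d_transmural
      list(da("z_apicobasal", z), da("d_transmural", d))
    },
    lapply(names(extra_point_fields), function(nm)
      da(nm, extra_point_fields[[nm]]))
  )
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    '<Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">\n',
    "<Points>\n", pts, "\n</Points>\n",
    "<Cells>\n",
    '<DataArray type="Int32" Name="connectivity" format="ascii">\n',
    paste(as.vector(t(anatomy$tets)) - 1L, collapse = " "),
    "\n</DataArray>\n",
    '<DataArray type="Int32" Name="offsets" format="ascii">\n',
    paste(seq_len(m) * 4L, collapse = " "), "\n</DataArray>\n",
    '<DataArray type="UInt8" Name="types" format="ascii">\n',
    paste(rep(10L, m), collapse = " "), "\n</DataArray>\n",
    "</Cells>\n",
    "<CellData>\n", paste(unlist(cell_fields), collapse = "\n"),
    "\n</CellData>\n",
    "<PointData>\n", paste(unlist(point_fields), collapse = "\n"),
    "\n</PointData>\n",
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read an anatomy written by \code{\link{write_anatomy_vtu}}
#' @param path VTU file.
#' @return an \code{anatomy_model} (surfaces and node sets are rebuilt).
#' @export
read_anatomy_vtu <- function(path) {
  doc <- xml2::read_xml(path, options = c("NOBLANKS", "HUGE"))
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(piece)) stop("malformed VTU: no <Piece> element in ", path)
  get_da <- function(xp) {
    node <- xml2::xml_find_first(doc, xp)
    if (is.na(node)) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  nodes <- matrix(get_da(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- get_da(".//Cells/DataArray[@Name='connectivity']")
  tets <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
  region_code <- get_da(".//CellData/DataArray[@Name='region']")
  if (is.null(region_code)) stop("malformed VTU: missing region cell field")
  region <- REGIONS[as.integer(region_code)]
  surfaces <- anatomy_surfaces(tets, region)
  myo_nodes <- sort(unique(as.vector(tets[region == "myocardium", ,
                                          drop = FALSE])))
  structure(list(nodes = nodes, tets = tets, region = region,
                 wall = NULL, surfaces = surfaces, myo_nodes = myo_nodes,
                 geometry = list(imported_from = path),
                 generation_seed = NA_integer_,
                 mesh_hash = mesh_hash(nodes, tets)),
            class = "anatomy_model")
}

#' Write a surface scalar map (e.g. a regional RED map) to VTU
#' @param anatomy source \code{anatomy_model}.
#' @param map a \code{regional_map}.
#' @param path output file.
#' @export
write_regional_map_vtu <- function(anatomy, map, path) {
  tris <- if (map$surface == "heart") anatomy$surfaces$heart
          else anatomy$surfaces$torso
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(anatomy$nodes)); remap[used] <- seq_along(used)
  vals <- rep(NaN, length(used))
  vals[remap[map$nodes]] <- map$local_red
  disp <- rep(NaN, length(used))
  disp[remap[map$nodes]] <- map$display
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    '<Piece NumberOfPoints="', length(used), '" NumberOfCells="',
    nrow(tris), '">\n',
    "<Points>\n",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    paste(fmt_num(as.vector(t(anatomy$nodes[used, , drop = FALSE]))),
          collapse = " "),
    "\n</DataArray>\n</Points>\n<Cells>\n",
    '<DataArray type="Int32" Name="connectivity" format="ascii">\n',
    paste(remap[as.vector(t(tris))] - 1L, collapse = " "),
    "\n</DataArray>\n",
    '<DataArray type="Int32" Name="offsets" format="ascii">\n',
    paste(seq_len(nrow(tris)) * 3L, collapse = " "), "\n</DataArray>\n",
    '<DataArray type="UInt8" Name="types" format="ascii">\n',
    paste(rep(5L, nrow(tris)), collapse = " "), "\n</DataArray>\n</Cells>\n",
    "<PointData>\n",
    '<DataArray type="Float64" Name="local_red" NumberOfComponents="1" ',
    'format="ascii">\n', paste(fmt_num(vals), collapse = " "),
    "\n</DataArray>\n",
    '<DataArray type="Float64" Name="display" NumberOfComponents="1" ',
    'format="ascii">\n', paste(fmt_num(disp), collapse = " "),
    "\n</DataArray>\n</PointData>\n",
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Write lead signals to CSV (one column per lead)
#' @param leads a \code{lead_signals}.
#' @param path output file.
#' @param digits decimal places (documented precision of the format).
#' @export
write_leads_csv <- function(leads, path, digits = 6) {
  m <- t(rbind(leads$bsm, leads$leads12))
  df <- data.frame(t_ms = leads$times, round(m, digits), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read lead signals written by \code{\link{write_leads_csv}}
#' @param path CSV file.
#' @return a \code{lead_signals} (without electrode metadata).
#' @export
read_leads_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)[-1]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(m) <- nm
  std <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  structure(list(times = df$t_ms,
                 bsm = m[!rownames(m) %in% std, , drop = FALSE],
                 leads12 = m[rownames(m) %in% std, , drop = FALSE],
                 electrodes = NULL),
            class = "lead_signals")
}

#' Export electrodes and pacing sites to JSON (0-based node indices)
#' @param placement output of \code{\link{place_electrodes_and_pacing}}.
#' @param anatomy the \code{anatomy_model} used for placement.
#' @param path output file.
#' @export
write_electrodes_json <- function(placement, anatomy, path) {
  el <- placement$electrodes
  node_entry <- function(idx) list(node = unname(idx) - 1L,
                                   xyz = unname(anatomy$nodes[idx, ]))
  out <- list(
    indexing = "0-based",
    bsm = lapply(seq_along(el$bsm_nodes), function(k)
      c(list(label = names(el$bsm_nodes)[k]), node_entry(el$bsm_nodes[k]))),
    limb = lapply(el$limb_nodes, node_entry),
    precordial = lapply(seq_along(el$precordial_nodes), function(k)
      c(list(label = names(el$precordial_nodes)[k]),
        node_entry(el$precordial_nodes[k]))),
    pacing = lapply(placement$stimuli, function(s)
      list(site = s$site, center = s$center, radius = s$radius,
           onset = s$onset, duration = s$duration, amplitude = s$amplitude))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Persist a simulation result as CSV + JSON metadata
#' @param result a \code{simulation_result}.
#' @param dir output directory (created).
#' @export
write_simulation_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    format(m, digits = 17, scientific = TRUE, trim = TRUE),
    file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  wm(result$Vm, "Vm.csv")
  wm(result$phi_e, "phi_e.csv")
  wm(result$phi_b, "phi_b.csv")
  meta <- result[c("times", "myo_nodes", "dt_pde", "dt_ode", "mesh_hash",
                   "wct_applied", "ionic_model", "heart_surface_nodes",
                   "torso_surface_nodes")]
  meta$params <- unclass(result$params)
  meta$stimuli <- lapply(result$stimuli, unclass)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a simulation result written by \code{\link{write_simulation_result}}
#' @param dir directory.
#' @return a \code{simulation_result}.
#' @export
read_simulation_result <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  Vm <- unname(rm_("Vm.csv"))
  res <- list(times = meta$times, Vm = Vm,
              phi_e = unname(rm_("phi_e.csv")),
              phi_b = unname(rm_("phi_b.csv")),
              myo_nodes = meta$myo_nodes,
              stimuli = lapply(meta$stimuli, function(s)
                structure(s, class = "stimulus_region")),
              dt_pde = meta$dt_pde, dt_ode = meta$dt_ode,
              params = do.call(parameter_set, as.list(meta$params)),
              mesh_hash = meta$mesh_hash,
              heart_surface_nodes = meta$heart_surface_nodes,
              torso_surface_nodes = meta$torso_surface_nodes,
              wct_applied = meta$wct_applied, ionic_model = meta$ionic_model)
  structure(res, class = "simulation_result")
}
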