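# Configuration handling and the end-to-end pipeline: anatomy ->
# conductivity -> simulation -> signals -> biomarkers -> sweeps, with a
# provenance manifest.

CONFIG_SCHEMA <- list(
  anatomy = c("geometry", "seed"),
  parameters = c("C_m", "beta", "sigma", "alpha", "epsilon", "sigma_b",
                 "anisotropy_ratio", "H_TR", "H_AB", "sigma_lungs",
                 "sigma_blood", "sigma_spine", "sigma_liver"),
  protocol = c("pacing_site", "duration_ms", "dt_pde", "dt_ode",
               "stim_amplitude", "phi_update_every"),
  sweep = c("parameters", "range_kind", "n_points", "duration_ms"),
  output = c("dir", "formats")
)

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' @param path config file; format chosen by extension (.yaml/.yml/.json).
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg config list.
#' @export
validate_run_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(CONFIG_SCHEMA)) {
    if (is.null(cfg[[sec]])) next
    extra <- setdiff(names(cfg[[sec]]), CONFIG_SCHEMA[[sec]])
    if (length(extra)) stop("unknown config key(s) in section '", sec, "': ",
                            paste(extra, collapse = ", "))
  }
  if (!is.null(cfg$anatomy$geometry)) {
    known <- names(geometry_params())
    extra <- setdiff(names(cfg$anatomy$geometry), known)
    if (length(extra)) stop("unknown config key(s) in anatomy.geometry: ",
                            paste(extra, collapse = ", "))
  }
  cfg
}

file_hash <- function(path) unname(tools::md5sum(path))

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  file_hash(f)
}

#' Run the configured pipeline end to end
#'
#' Stages: synthetic anatomy, anatomical coordinates and fibers, electrode
#' and pacing placement, reference bidomain simulation, lead derivation and
#' biomarkers, optional one-at-a-time sweeps with rankings and regional
#' maps. Writes artifacts (VTU/CSV/JSON) plus a run manifest with content
#' hashes of inputs and outputs, and returns the manifest.
#'
#' @param config path to a YAML/JSON config or a config list.
#' @return manifest list (also written to \code{output.dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  outdir <- cfg$output$dir %||% "fecgsim-run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, config_hash = object_hash(cfg),
                   stages = list(), status = "running",
                   package_version = as.character(utils::packageVersion("fecgsim")))
  t_all <- proc.time()[3]
  stage <- function(name, fn) {
    t0 <- proc.time()[3]
    res <- tryCatch(fn(), error = function(e) e)
    entry <- list(seconds = round(proc.time()[3] - t0, 2))
    if (inherits(res, "error")) {
      entry$status <- "failed"
      entry$message <- conditionMessage(res)
      manifest$stages[[name]] <<- entry
      manifest$status <<- paste0("failed at stage ", name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    entry$status <- "ok"
    if (!is.null(attr(res, "hash"))) entry$hash <- attr(res, "hash")
    manifest$stages[[name]] <<- entry
    res
  }
  on.exit({
    manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  })

  geo <- do.call(geometry_params, as.list(cfg$anatomy$geometry %||% list()))
  seed <- cfg$anatomy$seed %||% 0L
  params <- do.call(parameter_set, as.list(cfg$parameters %||% list()))
  anatomy <- stage("anatomy", function() {
    a <- build_anatomy(geo, seed)
    attr(a, "hash") <- a$mesh_hash
    a
  })
  coords <- stage("coordinates", function() compute_anatomical_coords(anatomy))
  fibers <- stage("fibers", function() assign_fibers(anatomy, coords))
  site <- cfg$protocol$pacing_site %||% "rv_apex"
  placement <- stage("electrodes", function() {
    pl <- place_electrodes_and_pacing(anatomy,
                                      electrode_layout(sites = site), coords)
    f <- file.path(outdir, "electrodes.json")
    write_electrodes_json(pl, anatomy, f)
    attr(pl, "hash") <- file_hash(f)
    pl
  })
  stage("anatomy_export", function() {
    f <- file.path(outdir, "anatomy.vtu")
    write_anatomy_vtu(anatomy, f, coords, fibers)
    structure(f, hash = file_hash(f))
  })
  sim <- stage("simulation", function() {
    stim <- placement$stimuli
    if (!is.null(cfg$protocol$stim_amplitude))
      stim <- lapply(stim, function(s) {
        s$amplitude <- cfg$protocol$stim_amplitude
        s
      })
    tf <- build_tensor_field(anatomy, fibers, params)
    sys <- assemble_system(anatomy, tf, params)
    ion <- ionic_assignment(anatomy, coords, params)
    res <- run_simulation(sys, ion, stim,
                          cfg$protocol$duration_ms %||% 500,
                          dt_pde = cfg$protocol$dt_pde %||% 0.1,
                          dt_ode = cfg$protocol$dt_ode %||% 0.02,
                          electrodes = placement$electrodes,
                          phi_update_every = cfg$protocol$phi_update_every %||% 1L)
    attr(res, "hash") <- object_hash(res[c("times", "Vm", "phi_b")])
    res
  })
  leads <- stage("signals", function() {
    ld <- derive_leads(sim, placement$electrodes)
    f <- file.path(outdir, "leads.csv")
    write_leads_csv(ld, f)
    attr(ld, "hash") <- file_hash(f)
    ld
  })
  stage("biomarkers", function() {
    bm <- biomarker_table(sim, leads)
    f <- file.path(outdir, "biomarkers.json")
    jsonlite::write_json(unclass(bm), f, auto_unbox = TRUE, digits = NA)
    structure(f, hash = file_hash(f))
  })
  if (!is.null(cfg$sweep)) {
    sweeps <- stage("sweeps", function() {
      sw <- lapply(cfg$sweep$parameters, function(pn)
        run_oat_sweep(anatomy, params, pn,
                      range_kind = cfg$sweep$range_kind %||% "physiological",
                      n_points = cfg$sweep$n_points %||% 5,
                      pacing_site = site,
                      duration_ms = cfg$sweep$duration_ms %||%
                        (cfg$protocol$duration_ms %||% 500)))
      names(sw) <- cfg$sweep$parameters
      f <- file.path(outdir, "sweeps.json")
      jsonlite::write_json(lapply(sw, function(s)
        s[c("parameter", "range_kind", "values", "delta", "max_red",
            "argmax", "spans", "status")]),
        f, auto_unbox = TRUE, digits = NA, force = TRUE)
      attr(sw, "hash") <- file_hash(f)
      sw
    })
    stage("ranking", function() {
      rk <- rank_parameters(sweeps, "bsm")
      f <- file.path(outdir, "ranking.csv")
      write.csv(rk, f, row.names = FALSE)
      structure(f, hash = file_hash(f))
    })
  }
  manifest$status <- "ok"
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
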