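#' Build configuration for the full construction pipeline
#'
#' One object holds every stage parameter; [run_pipeline()] logs the fully
#' resolved configuration, and [write_config()] / [read_config()] round-trip
#' it losslessly as JSON.
#'
#' @param cif path to a unit-cell CIF; `NULL` uses the packaged magnetite.
#' @param facets facet string `"hkl:gamma,..."` (default `"100:1.0,111:1.15"`,
#'   the cube-dominant, corner-truncating default).
#' @param diameter_nm core face-to-face diameter (nm).
#' @param n_chains chains to graft (count mode; `NULL` with `density` set
#'   switches to density mode).
#' @param density grafting density (chains/nm^2) for density mode.
#' @param chain_length_nm target chain length (nm).
#' @param lipids_per_leaflet DPPC count per leaflet.
#' @param area_per_lipid nm^2 per lipid.
#' @param gap_A initial particle-to-phosphate-plane distance (A).
#' @param seed master seed for every stochastic choice.
#' @param include_membrane build and assemble the bilayer stage.
#' @param solvate_system fill the assembled box with water (the slow stage;
#'   off by default at desk scale — see the methods vignette).
#' @param frozen_core if `TRUE` the oxide core contributes no internal bonds.
#' @param out_dir if non-`NULL`, write PDB/GRO/topology artifacts there.
#' @return a `build_config` list.
#' @export
build_config <- function(cif = NULL, facets = "100:1.0,111:1.15",
                         diameter_nm = 3, n_chains = 64, density = NULL,
                         chain_length_nm = 6.5, lipids_per_leaflet = 489,
                         area_per_lipid = 0.63, gap_A = 5, seed = 1,
                         include_membrane = TRUE, solvate_system = FALSE,
                         frozen_core = FALSE, out_dir = NULL) {
  cfg <- list(cif = cif, facets = facets, diameter_nm = diameter_nm,
              n_chains = n_chains, density = density,
              chain_length_nm = chain_length_nm,
              lipids_per_leaflet = lipids_per_leaflet,
              area_per_lipid = area_per_lipid, gap_A = gap_A, seed = seed,
              include_membrane = include_membrane,
              solvate_system = solvate_system, frozen_core = frozen_core,
              out_dir = out_dir)
  class(cfg) <- "build_config"
  cfg
}

#' @export
print.build_config <- function(x, ...) {
  cat("# nanoforge build config\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, if (is.null(v)) "NULL" else paste(v, collapse = ",")))
  }
  invisible(x)
}

#' @rdname build_config
#' @param config a `build_config`.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname build_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(build_config, cfg[!vapply(cfg, is.null, TRUE)])
}

#' Run the full construction pipeline
#'
#' Executes core carving, site selection, chain grafting, topology
#' enumeration and (optionally) bilayer assembly in order, collecting a
#' build report. Any stage failure is rethrown with the stage name and the
#' resolved configuration.
#'
#' @param config from [build_config()].
#' @param verbose log stage progress to stderr.
#' @return object of class `nanoforge_build`: list with `config`, `cell`,
#'   `core`, `shape`, `sites`, `chain`, `np`, `topology`, `bilayer`,
#'   `system` (the latter two `NULL` unless the membrane stage ran), and
#'   `report` (tibble of build metrics).
#' @examples
#' \dontrun{
#' build <- run_pipeline(build_config())
#' glance(build)
#' }
#' @export
run_pipeline <- function(config = build_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message("[nanoforge] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "\n  config: ", paste(names(config), unlist(lapply(config, function(v)
             if (is.null(v)) "NULL" else paste(v, collapse = ","))),
             sep = "=", collapse = " "), call. = FALSE)
    })
  }
  say("resolved config: seed=", config$seed, " facets=", config$facets,
      " diameter=", config$diameter_nm, " nm")

  cell <- stage("core", {
    if (is.null(config$cif)) magnetite_cell() else read_cif(config$cif)
  })
  facets <- stage("core", parse_facets(config$facets))
  core <- stage("core", carve_core(cell, facets, config$diameter_nm * 10,
                                   verbose = verbose))
  shape <- attr(core, "shape")
  say("core: ", nrow(core), " atoms")

  n_request <- config$n_chains
  # rank extra candidates beyond the request so grafting can substitute
  # hemmed-in sites; farthest-point ordering is prefix-stable, so the first
  # n_want entries equal the plain n_want selection
  sites_all <- stage("sites", {
    n_want <- if (is.null(n_request))
      round(config$density * shape$area / 100) else n_request
    cls <- classify_fe_sites(core)
    surf <- detect_surface_atoms(core, shape, skin = 3.0)
    n_cand <- nrow(dplyr::inner_join(surf, cls[!is.na(cls$bulk_class) &
                                                 cls$bulk_class == "octahedral", ],
                                     by = "atom_id"))
    pool <- min(n_cand, n_want + max(16, ceiling(n_want / 2)))
    list(sel = select_graft_sites(core, n_chains = pool, seed = config$seed),
         n_want = n_want)
  })
  n_want <- sites_all$n_want
  if (nrow(sites_all$sel) < n_want) {
    stop("stage 'sites' failed: only ", nrow(sites_all$sel),
         " graft candidates for ", n_want, " requested chains", call. = FALSE)
  }
  sites <- sites_all$sel[seq_len(n_want), ]
  alternates <- if (nrow(sites_all$sel) > n_want)
    sites_all$sel[(n_want + 1):nrow(sites_all$sel), ] else NULL
  say("sites: ", n_want, " of ", nrow(sites_all$sel), " ranked candidates")

  chain <- stage("chains", build_chain_geometry(
    target_length = config$chain_length_nm))
  np <- stage("chains", attach_chains(core, sites, chain,
                                      alternates = alternates))
  say("chains: ", n_want, " grafted (", attr(np, "n_substituted"),
      " substituted), ", nrow(np), " atoms")

  topo <- stage("topology", {
    bonds <- system_bonds(np, frozen_core = config$frozen_core)
    assign_charges(np, enumerate_topology(np, bonds))
  })
  say("topology: ", nrow(topo$bonds), " bonds, ", nrow(topo$angles),
      " angles, ", nrow(topo$dihedrals), " dihedrals")

  bilayer <- NULL; system <- NULL
  if (isTRUE(config$include_membrane)) {
    bilayer <- stage("membrane", build_bilayer(
      config$lipids_per_leaflet, area_per_lipid = config$area_per_lipid))
    say("membrane: ", attr(bilayer, "n_per_leaflet"), " lipids per leaflet")
    system <- stage("assembly", assemble_system(
      np, bilayer, gap = config$gap_A,
      solvate_system = isTRUE(config$solvate_system)))
    say("assembly: ", nrow(system$structure), " atoms, gap ",
        sprintf("%.2f", system$gap_realized), " A")
  }

  realized_len <- attr(chain, "length_nm")
  area_nm2 <- shape$area / 100
  report <- tibble::tibble(
    metric = c("core_atoms", "core_extent_nm", "n_chains",
               "grafting_density_per_nm2", "chain_length_nm",
               "chain_residues", "np_atoms", "net_charge_e",
               "lipids_per_leaflet", "system_atoms", "gap_A"),
    value = c(sum(np$resname == "CRY"),
              core_extent_nm(core),
              n_want,
              n_want / area_nm2,
              realized_len,
              nrow(attr(chain, "sequence")),
              nrow(np),
              topo$net_charge,
              if (is.null(bilayer)) NA_real_ else attr(bilayer, "n_per_leaflet"),
              if (is.null(system)) NA_real_ else nrow(system$structure),
              if (is.null(system)) NA_real_ else system$gap_realized))

  out <- structure(list(config = config, cell = cell, core = core,
                        shape = shape, sites = sites, chain = chain, np = np,
                        topology = topo, bilayer = bilayer, system = system,
                        report = report), class = "nanoforge_build")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stage("write", write_system(
      np, topo,
      gro = file.path(config$out_dir, "mag_ara.gro"),
      pdb = file.path(config$out_dir, "mag_ara.pdb"),
      top = file.path(config$out_dir, "mag_ara.top")))
    if (!is.null(system)) {
      stage("write", write_gro(system$structure,
                               file.path(config$out_dir, "system.gro")))
    }
    stage("write", write_config(config, file.path(config$out_dir, "config.json")))
    say("artifacts written to ", config$out_dir)
  }
  out
}

#' Face-to-face extent of a carved core along the dominant facet normal (nm)
#'
#' Measured on the atom coordinates: the span of their projections onto the
#' lowest-energy facet normal of the generating shape.
#'
#' @param core carved structure with a `"shape"` attribute.
#' @return extent in nm.
#' @export
core_extent_nm <- function(core) {
  shape <- attr(core, "shape")
  n <- shape$normals[which.min(shape$gamma), ]
  proj <- coords(core[core$resname == "CRY", ]) %*% n
  (max(proj) - min(proj)) / 10
}

#' @export
print.nanoforge_build <- function(x, ...) {
  cat("# nanoforge build\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-26s %s\n", r$metric[i],
                ifelse(is.na(r$value[i]), "-", signif(r$value[i], 6))))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `nanoforge_build`.
#' @param ... unused.
#' @return `tidy()`: the report as a tibble (`metric`, `value`);
#'   `glance()`: one-row tibble of the headline metrics.
#' @export
tidy.nanoforge_build <- function(x, ...) x$report

#' @rdname run_pipeline
#' @export
glance.nanoforge_build <- function(x, ...) {
  r <- stats::setNames(x$report$value, x$report$metric)
  tibble::tibble(n_chains = r[["n_chains"]],
                 chain_length_nm = r[["chain_length_nm"]],
                 core_extent_nm = r[["core_extent_nm"]],
                 grafting_density_per_nm2 = r[["grafting_density_per_nm2"]],
                 np_atoms = r[["np_atoms"]],
                 net_charge_e = r[["net_charge_e"]],
                 lipids_per_leaflet = r[["lipids_per_leaflet"]],
                 gap_A = r[["gap_A"]])
}
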