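# File writers: deterministic CSV tables, legacy-ASCII VTK field series,
# and a YAML run manifest that round-trips to the same configuration.

#' Write a mesh (with optional per-element fields) as legacy ASCII VTK
#'
#' Legacy VTK unstructured-grid format, chosen because it is plain text and
#' diff-able; loads in ParaView/VisIt and with meshio.
#'
#' @param mesh an [axisym_mesh][build_mesh()]; node coordinates are written
#'   as (r, z, 0).
#' @param path output file.
#' @param cell_data named list of per-element numeric vectors.
#' @param displacements optional 2n displacement vector (r, z interleaved)
#'   written as point data.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), displacements = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("staplecomp axisymmetric tissue mesh (r z 0)")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  w("CELLS %d %d", ne, 5L * ne)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L,
                     mesh$elems[, 2] - 1L, mesh$elems[, 3] - 1L,
                     mesh$elems[, 4] - 1L), con)
  w("CELL_TYPES %d", ne)
  writeLines(rep("9", ne), con)
  if (length(cell_data)) {
    w("CELL_DATA %d", ne)
    for (nm in names(cell_data)) {
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  if (!is.null(displacements)) {
    w("POINT_DATA %d", n)
    w("VECTORS displacement double")
    writeLines(sprintf("%.9g %.9g 0",
                       displacements[seq(1, 2 * n, by = 2)],
                       displacements[seq(2, 2 * n, by = 2)]), con)
  }
  invisible(path)
}

#' Write the outputs of a solved run
#'
#' Writes, with deterministic names and byte-identical reruns:
#' `layer_stats.csv` (step, d, ratio, per-layer max/mean von Mises, force),
#' `band_fractions.csv` (the per-step volumetric band statistic and state),
#' `safety_table.csv`, `manifest.yaml` (config echo + seed), and - when a
#' mesh is supplied - a `field_step<k>.vtk` series of per-element von Mises
#' and volume fields.
#'
#' @param results list of `step_result`s.
#' @param cfg a [load_config()] configuration (for the manifest and
#'   thresholds).
#' @param dir output directory (created if missing).
#' @param mesh optional [axisym_mesh][build_mesh()] for VTK output.
#' @param vtk_steps which steps to write as VTK (default: final step only).
#' @return manifest list, invisibly; files are written under `dir`.
#' @export
write_outputs <- function(results, cfg, dir, mesh = NULL,
                          vtk_steps = length(results)) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  stack <- cfg$objects$stack
  thr <- cfg$objects$thr
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  wcsv(sweep_layer_stats(results, stack), "layer_stats.csv")
  wcsv(sweep_band_series(results, thr, stack), "band_fractions.csv")
  st <- safety_table(results, thr, stack)
  wcsv(st$table, "safety_table.csv")
  if (!is.null(mesh)) {
    for (k in vtk_steps) {
      r <- results[[k]]
      write_vtk(mesh, file.path(dir, sprintf("field_step%03d.vtk", k)),
                cell_data = list(von_mises = r$vm, volume = r$vol_cur))
    }
  }
  manifest <- list(package = "staplecomp",
                   config = config_echo(cfg),
                   seed = cfg$seed,
                   n_steps = length(results))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
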