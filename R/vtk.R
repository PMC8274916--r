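#' Export field snapshots as a legacy-VTK polyline series
#'
#' Writes one ASCII legacy `.vtk` file per stored snapshot (points along
#' the radius, all nodal fields as point data), numbered in time order, so
#' the series can be loaded directly into standard VTK viewers.
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_result_vtk <- function(result, dir, prefix = "snapshot") {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(result$snapshots)) {
    sn <- result$snapshots[[i]]
    n <- length(sn$r)
    f <- file.path(dir, sprintf("%s_%04d.vtk", prefix, i - 1L))
    con <- file(f, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("radial fields at t = %.6e s", sn$time),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", n)), con)
    writeLines(sprintf("%.9e 0 0", sn$r), con)
    writeLines(c(sprintf("LINES 1 %d", n + 1L),
                 paste(c(n, seq_len(n) - 1L), collapse = " "),
                 sprintf("POINT_DATA %d", n)), con)
    for (fld in setdiff(names(sn), c("time", "r"))) {
      writeLines(c(sprintf("SCALARS %s double 1", fld),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9e", sn[[fld]]), con)
    }
    close(con)
    files <- c(files, f)
  }
  invisible(files)
}
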