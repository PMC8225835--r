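# Configuration files, lossless JSON snapshots, VTK export and run
# directories. All outputs are plain text.

#' Write / read a run configuration
#'
#' JSON with one key per [default_params()] field plus an optional
#' `scenario` name. Unknown keys are an error on read.
#'
#' @param params an `ep_params`.
#' @param path file path.
#' @param scenario optional scenario name stored alongside the parameters.
#' @return `write_config`: the path, invisibly. `read_config`: list with
#'   `params` (`ep_params`) and `scenario` (or NULL).
#' @export
write_config <- function(params, path, scenario = NULL) {
  x <- unclass(params)
  if (!is.null(scenario)) x$scenario <- scenario
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- x$scenario
  x$scenario <- NULL
  known <- names(default_params())
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (f in c("N_div", "M1", "M2", "derm_layers", "seed"))
    if (!is.null(x[[f]])) x[[f]] <- as.integer(x[[f]])
  list(params = do.call(default_params, x), scenario = scenario)
}

SNAPSHOT_VERSION <- 1L

#' Snapshot a state to JSON and restore it
#'
#' Lossless round-trip of the whole simulation state: particle and cell
#' tables, membrane mesh with rest lengths, clock, parameters, event log and
#' the RNG stream, written with 17 significant digits. `read_state_json()`
#' restores the RNG stream so a resumed run continues the same realisation.
#'
#' @param state an `ep_state`.
#' @param path file path (.json).
#' @return `write_state_json`: the path, invisibly; `read_state_json`: the
#'   restored `ep_state`.
#' @export
write_state_json <- function(state, path) {
  seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  cells <- state$cells
  # JSON has no Inf: fields that can hold it travel as %.17g strings
  cells$div_left <- sprintf("%.17g", cells$div_left)
  cells$next_div <- sprintf("%.17g", cells$next_div)
  x <- list(
    version = SNAPSHOT_VERSION,
    t = state$t,
    params = unclass(state$params),
    derm = list(pos = state$derm$pos, mobile = state$derm$mobile),
    mem = state$mem,
    cells = cells,
    next_id = state$next_id,
    events = list(divisions = state$events$divisions,
                  cornifications = state$events$cornifications,
                  removals = state$events$removals,
                  delaminations = state$events$delaminations,
                  discarded_doses = state$events$discarded_doses),
    random_seed = seed
  )
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = I(17),
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_state_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("snapshot read error: ",
                                         conditionMessage(e)))
  if (is.null(x$version) || x$version != SNAPSHOT_VERSION)
    stop("snapshot version mismatch")
  st <- new.env(parent = emptyenv())
  st$t <- x$t
  st$params <- structure(as.list(x$params), class = "ep_params")
  st$params$N_div <- as.integer(st$params$N_div)
  st$derm <- list(pos = matrix(x$derm$pos, ncol = 3),
                  mobile = as.logical(x$derm$mobile))
  st$mem <- list(pos = matrix(x$mem$pos, ncol = 3),
                 edges = matrix(as.integer(x$mem$edges), ncol = 2),
                 l0 = as.numeric(x$mem$l0),
                 hinges = matrix(as.integer(x$mem$hinges), ncol = 4),
                 triangles = matrix(as.integer(x$mem$triangles), ncol = 3))
  cl <- x$cells
  cl$pos <- matrix(cl$pos, ncol = 3)
  cl$id <- as.integer(cl$id)
  cl$lineage <- as.integer(cl$lineage)
  cl$type <- as.integer(cl$type)
  cl$abnormal <- as.logical(cl$abnormal)
  cl$attached <- as.logical(cl$attached)
  cl$born_div <- as.logical(cl$born_div)
  for (f in c("div_left", "next_div", "w", "a", "c", "Ca", "S", "L_in",
              "L_out", "D", "t_birth", "t_corn"))
    cl[[f]] <- as.numeric(cl[[f]])
  st$cells <- cl
  st$next_id <- as.integer(x$next_id)
  st$events <- new.env(parent = emptyenv())
  fix_ev <- function(l) lapply(l, function(m) matrix(m, ncol = ncol(m)))
  st$events$divisions <- lapply(x$events$divisions, as.matrix)
  st$events$cornifications <- lapply(x$events$cornifications, as.matrix)
  st$events$removals <- lapply(x$events$removals, as.matrix)
  st$events$delaminations <- lapply(x$events$delaminations, as.matrix)
  st$events$discarded_doses <- as.integer(x$events$discarded_doses)
  if (!is.null(x$random_seed) && length(x$random_seed))
    assign(".Random.seed", as.integer(x$random_seed), envir = globalenv())
  class(st) <- "ep_state"
  st
}

#' Export a state for visualisation (legacy ASCII VTK)
#'
#' Writes `<prefix>_membrane.vtk` (the basement membrane as a triangulated
#' polydata surface with vertical displacement as point data) and
#' `<prefix>_cells.vtk` (cell centres as points with type, differentiation
#' state, released-lipid ratio and semi-axes as point data).
#'
#' @param state an `ep_state`.
#' @param prefix path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
write_vtk <- function(state, prefix) {
  mem_path <- paste0(prefix, "_membrane.vtk")
  mp <- state$mem$pos
  tri <- state$mem$triangles - 1L
  con <- file(mem_path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "epidermsim basement membrane",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mp))), con)
  writeLines(sprintf("%.6g %.6g %.6g", mp[, 1], mp[, 2], mp[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri), 4L * nrow(tri)), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1], tri[, 2], tri[, 3]), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(mp)),
               "SCALARS displacement float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", mp[, 3] - min(mp[, 3])), con)
  close(con)

  cell_path <- paste0(prefix, "_cells.vtk")
  cl <- state$cells
  n <- length(cl$id)
  con <- file(cell_path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "epidermsim cells", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6g %.6g %.6g", cl$pos[, 1], cl$pos[, 2],
                     cl$pos[, 3]), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  scalars <- list(type = cl$type, w = cl$w,
                  lipid_ratio = cl$L_out / state$params$L_max,
                  a = cl$a, c = cl$c,
                  abnormal = as.numeric(cl$abnormal))
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6g", scalars[[nm]]), con)
  }
  close(con)
  invisible(c(mem_path, cell_path))
}

#' Write a self-describing run directory
#'
#' Resolved configuration (every effective parameter), metrics time-series
#' CSV, event-log CSVs, final snapshot JSON and VTK export.
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(result$scenario$params, file.path(dir, "config.json"),
               scenario = result$scenario$name)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (nm in names(result$events))
    utils::write.csv(result$events[[nm]],
                     file.path(dir, paste0("events_", nm, ".csv")),
                     row.names = FALSE)
  write_state_json(result$state, file.path(dir, "final_state.json"))
  write_vtk(result$state, file.path(dir, "final"))
  invisible(dir)
}
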