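# Scenario presets and the in-silico experiments: homeostasis, reduced cell
# supply, supply sweep, dermal stiffening, corn formation.

#' Scenario presets
#'
#' Named presets bundling parameter overrides and a default duration:
#' \describe{
#'   \item{homeostasis}{`(N_div, T_div) = (14, 4.0)`, 200 µm box, 280 days.}
#'   \item{reduced_supply}{`(N_div, T_div) = (8, 4.4)`: smaller division
#'     budget, longer period — the destabilised regime.}
#'   \item{stiff_dermis}{homeostasis with the dermal-dermal adhesion
#'     multiplied by 4.}
#'   \item{corn}{homeostasis on a 2x-wider box with the most central stem
#'     cell flagged abnormal: its descendants divide twice as fast in the
#'     basal layer and differentiate twice as fast above it.}
#'   \item{fixture_small}{150 µm box, 60 days: the fast desk-scale fixture
#'     showing all qualitative behaviours.}
#' }
#'
#' @param name preset name.
#' @param ... parameter overrides applied on top of the preset.
#' @param days optional duration override (days).
#' @return An `ep_scenario` list: `name`, `params`, `days`.
#' @export
#' @examples
#' sc <- scenario_params("homeostasis", seed = 7)
#' sc$params$N_div
scenario_params <- function(name = c("homeostasis", "reduced_supply",
                                     "stiff_dermis", "corn",
                                     "fixture_small"),
                            ..., days = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    homeostasis = list(ov = list(N_div = 14L, T_div = 4.0), days = 280),
    reduced_supply = list(ov = list(N_div = 8L, T_div = 4.4), days = 280),
    stiff_dermis = list(ov = list(N_div = 14L, T_div = 4.0,
                                  stiffness_mult = 4), days = 280),
    corn = list(ov = list(N_div = 14L, T_div = 4.0, Lx = 300, Ly = 300,
                          M1 = 6L, M2 = 6L), days = 140),
    fixture_small = list(ov = list(N_div = 14L, T_div = 4.0, Lx = 150,
                                   Ly = 150, M1 = 3L, M2 = 3L), days = 60)
  )
  ov <- utils::modifyList(preset$ov, list(...))
  structure(list(name = name, params = do.call(default_params, ov),
                 days = if (is.null(days)) preset$days else days),
            class = "ep_scenario")
}

# flag the stem cell closest to the domain centre as the abnormal lineage
flag_abnormal_stem <- function(state) {
  cl <- state$cells
  stems <- which(cl$type == 1L)
  if (!length(stems)) stop("corn run: no stem cell to flag abnormal")
  p <- state$params
  d2 <- (cl$pos[stems, 1] - p$Lx / 2)^2 + (cl$pos[stems, 2] - p$Ly / 2)^2
  cl$abnormal[stems[which.min(d2)]] <- TRUE
  state$cells <- cl
  invisible(state)
}

#' Run a scenario preset
#'
#' Builds the initial state (corn scenarios get their central stem flagged
#' abnormal), simulates for the scenario duration, and optionally writes a
#' self-describing run directory: resolved configuration, metrics CSV, event
#' CSVs, final snapshot and VTK export. Deterministic given the seed.
#'
#' @param scenario an `ep_scenario` from [scenario_params()] or a preset
#'   name (extra arguments in `...` are forwarded as overrides).
#' @param ... overrides when `scenario` is a name.
#' @param days duration override (days).
#' @param out_dir optional output directory.
#' @param sample_every metrics cadence (days).
#' @param progress print progress.
#' @return list: `scenario`, `state` (final), `metrics`, `events`,
#'   `summary` (turnover statistics and time-averaged metrics over the last
#'   half of the run).
#' @export
run_scenario <- function(scenario, ..., days = NULL, out_dir = NULL,
                         sample_every = 0.07, progress = FALSE) {
  if (is.character(scenario))
    scenario <- scenario_params(scenario, ..., days = days)
  else if (!is.null(days)) scenario$days <- days
  state <- build_initial_state(scenario$params)
  if (scenario$name == "corn") flag_abnormal_stem(state)
  metrics <- run_simulation(state, scenario$days, sample_every,
                            progress = progress)
  events <- event_log(state)
  burn <- scenario$days / 2
  summary <- list(
    turnover = turnover_stats(events$removals, from = burn),
    averages = time_average(metrics, burn_in = burn)
  )
  res <- list(scenario = scenario, state = state, metrics = metrics,
              events = events, summary = summary)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

#' Parameter sweep over the cell-supply plane
#'
#' One (scaled-down) run per `(N_div, T_div)` grid point; reports the
#' time-averaged layer metrics over the stationary window. Failures of
#' individual grid cells are caught and marked, not propagated.
#'
#' @param N_div_values,T_div_values grid axes.
#' @param days duration per run; `burn_in` start of the averaging window.
#' @param burn_in start of the averaging window (days).
#' @param ... shared parameter overrides (e.g. a smaller domain).
#' @param sample_every metrics cadence (days).
#' @return data.frame, one row per grid point: time-averaged `H`, `G/H`,
#'   `E/H` per layer, lipid ratio, deficient-cell count, basal statistics;
#'   `failed` flags aborted runs.
#' @export
run_sweep <- function(N_div_values, T_div_values, days = 120, burn_in = 60,
                      ..., sample_every = 0.25) {
  stopifnot(length(N_div_values) >= 1, length(T_div_values) >= 1)
  grid <- expand.grid(N_div = N_div_values, T_div = T_div_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    res <- tryCatch({
      p <- default_params(N_div = as.integer(grid$N_div[k]),
                          T_div = grid$T_div[k], ...)
      st <- build_initial_state(p)
      m <- run_simulation(st, days, sample_every)
      av <- time_average(m, burn_in)
      data.frame(N_div = grid$N_div[k], T_div = grid$T_div[k],
                 H_gran = av[["H_gran"]],
                 GH_gran = av[["G_gran"]] / av[["H_gran"]],
                 EH_gran = av[["E_gran"]] / av[["H_gran"]],
                 H_corn = av[["H_corn"]],
                 GH_corn = av[["G_corn"]] / av[["H_corn"]],
                 EH_corn = av[["E_corn"]] / av[["H_corn"]],
                 lipid_ratio = av[["lipid_ratio"]],
                 n_deficient = av[["n_deficient"]],
                 div_per_day = av[["div_per_day"]],
                 n_basal = av[["n_basal"]],
                 n_proliferative = av[["n_proliferative"]],
                 failed = FALSE)
    }, error = function(e) {
      data.frame(N_div = grid$N_div[k], T_div = grid$T_div[k],
                 H_gran = NA, GH_gran = NA, EH_gran = NA, H_corn = NA,
                 GH_corn = NA, EH_corn = NA, lipid_ratio = NA,
                 n_deficient = NA, div_per_day = NA, n_basal = NA,
                 n_proliferative = NA, failed = TRUE)
    })
    res
  })
  do.call(rbind, rows)
}

# ray-casting point-in-polygon (polygon as two-column matrix, open ring)
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Corn lesion report
#'
#' Quantifies the lesion of a corn run on the current state. The lesion
#' footprint is the convex hull (in x, y) of the abnormal-lineage basal
#' cells. Reported: the intrusion depth of the cornified layer (non-lesional
#' mean lower boundary minus its minimum above the footprint, on a fine
#' tile grid), the membrane mean height inside versus outside the footprint,
#' and the fraction of intruding cornified cells (those below the
#' non-lesional lower boundary inside the footprint) that descend from the
#' abnormal stem. The per-tile lower boundary is the 10th percentile of the
#' cornified cell-centre heights: isolated cells dangling below the bulk
#' (the dispersion `G` counts those separately) would otherwise dominate
#' the minimum and mask the lesion.
#'
#' @param state final `ep_state` of a corn run.
#' @param tile tile size (µm) for the lower-boundary grid.
#' @return list: `intrusion_depth` (µm), `mem_height_lesion`,
#'   `mem_height_outside` (µm), `frac_intruding_abnormal`, `footprint`
#'   (hull vertices), `n_abnormal_basal`.
#' @export
corn_report <- function(state, tile = 25) {
  cl <- state$cells
  p <- state$params
  ab_basal <- which(cl$abnormal & cl$attached)
  if (!length(ab_basal)) stop("corn report: no abnormal basal cells")
  hx <- cl$pos[ab_basal, 1]; hy <- cl$pos[ab_basal, 2]
  hull <- grDevices::chull(hx, hy)
  poly <- cbind(hx[hull], hy[hull])

  grid <- subregion_grid(p$Lx, p$Ly, max(2, round(p$Lx / tile)),
                         max(2, round(p$Ly / tile)))
  corn <- which(cl$type == 5L)
  zlow <- matrix(NA_real_, grid$M1, grid$M2)
  if (length(corn)) {
    ij <- tile_index(cl$pos[corn, 1], cl$pos[corn, 2], grid)
    key <- (ij[, 2] - 1L) * grid$M1 + ij[, 1]
    # robust per-tile lower boundary of the cornified *layer*
    zl <- tapply(cl$pos[corn, 3], key, stats::quantile, probs = 0.1,
                 names = FALSE)
    zlow[as.integer(names(zl))] <- zl
  }
  centers <- expand.grid(x = (seq_len(grid$M1) - 0.5) * grid$dx,
                         y = (seq_len(grid$M2) - 0.5) * grid$dy)
  lesional_tile <- in_polygon(centers$x, centers$y, poly)
  z_out <- mean(zlow[!lesional_tile], na.rm = TRUE)
  z_les_min <- suppressWarnings(min(zlow[lesional_tile], na.rm = TRUE))
  intrusion <- if (is.finite(z_les_min)) z_out - z_les_min else NA_real_

  mem_in <- in_polygon(state$mem$pos[, 1], state$mem$pos[, 2], poly)
  intr <- corn[in_polygon(cl$pos[corn, 1], cl$pos[corn, 2], poly) &
                 cl$pos[corn, 3] < z_out]
  list(intrusion_depth = intrusion,
       mem_height_lesion = mean(state$mem$pos[mem_in, 3]),
       mem_height_outside = mean(state$mem$pos[!mem_in, 3]),
       frac_intruding_abnormal = if (length(intr))
         mean(cl$abnormal[intr]) else NA_real_,
       n_intruding = length(intr),
       footprint = poly,
       n_abnormal_basal = length(ab_basal))
}

#' Run the corn experiment
#'
#' [run_scenario()] on the corn preset plus the lesion report. With
#' `div_factor_abnormal = diff_factor_abnormal = 1` the flagged stem behaves
#' normally (null control).
#'
#' @param ... overrides forwarded to [scenario_params()].
#' @param days duration (days).
#' @param out_dir optional output directory.
#' @return list as [run_scenario()] plus `lesion`.
#' @export
run_corn <- function(..., days = NULL, out_dir = NULL) {
  res <- run_scenario("corn", ..., days = days, out_dir = out_dir)
  res$lesion <- corn_report(res$state)
  res
}
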