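# Layer-quality morphometrics on a subregion grid, lipid and basal-layer
# diagnostics, membrane deformation amplitude and turnover statistics.

#' Subregion grid
#'
#' Divides the domain `[0, Lx) x [0, Ly)` into `M1 x M2` tiles of size
#' `Δx = Lx/M1`, `Δy = Ly/M2`, tile `(i, j)` covering the half-open box
#' `[(i-1)Δx, iΔx) x [(j-1)Δy, jΔy)`, so every cell centre lands in exactly
#' one tile.
#'
#' @param Lx,Ly domain size (µm); `M1`, `M2` tile counts.
#' @param M1,M2 number of tiles in x and y.
#' @return An `ep_grid` list (Lx, Ly, M1, M2, dx, dy).
#' @export
subregion_grid <- function(Lx, Ly, M1, M2) {
  stopifnot(M1 >= 1, M2 >= 1, Lx > 0, Ly > 0)
  structure(list(Lx = Lx, Ly = Ly, M1 = as.integer(M1), M2 = as.integer(M2),
                 dx = Lx / M1, dy = Ly / M2), class = "ep_grid")
}

tile_index <- function(x, y, grid) {
  i <- pmin(grid$M1, floor((x %% grid$Lx) / grid$dx) + 1L)
  j <- pmin(grid$M2, floor((y %% grid$Ly) / grid$dy) + 1L)
  cbind(i, j)
}

#' Per-tile layer thickness
#'
#' `H_ij = 4 π R^3 n_ij / (3 Δx Δy)`: the volume of the layer's cells in the
#' tile — counted with the undifferentiated radius `R`, ignoring flattening —
#' divided by the tile area.
#'
#' @param x,y cell-centre coordinates of the layer's cells (µm).
#' @param grid an `ep_grid`.
#' @param R undifferentiated cell radius (µm).
#' @return M1 x M2 matrix of thicknesses (µm); 0 for empty tiles.
#' @export
thickness_grid <- function(x, y, grid, R) {
  n_ij <- matrix(0, grid$M1, grid$M2)
  if (length(x)) {
    ij <- tile_index(x, y, grid)
    for (k in seq_along(x)) n_ij[ij[k, 1], ij[k, 2]] <-
        n_ij[ij[k, 1], ij[k, 2]] + 1
  }
  4 * pi * R^3 * n_ij / (3 * grid$dx * grid$dy)
}

#' Per-tile vertical dispersion
#'
#' `G_ij = z_max - z_min - H_ij` over the layer's cell centres in the tile:
#' the vertical spread not accounted for by the bulk thickness (isolated
#' cells far from the bulk make it large). Undefined (NA) for empty tiles;
#' those are excluded from the layer mean.
#'
#' @param x,y,z cell-centre coordinates of the layer's cells.
#' @param grid an `ep_grid`.
#' @param H_ij matrix from [thickness_grid()].
#' @return M1 x M2 matrix; NA where the tile holds no cell.
#' @export
dispersion_grid <- function(x, y, z, grid, H_ij) {
  G <- matrix(NA_real_, grid$M1, grid$M2)
  if (length(x)) {
    ij <- tile_index(x, y, grid)
    key <- (ij[, 2] - 1L) * grid$M1 + ij[, 1]
    zmax <- tapply(z, key, max)
    zmin <- tapply(z, key, min)
    k <- as.integer(names(zmax))
    G[k] <- zmax - zmin - H_ij[k]
  }
  G
}

#' Layer means of the tile matrices
#'
#' Arithmetic means over the `M1 x M2` tiles. Empty tiles contribute
#' `H_ij = 0` to the thickness mean but are excluded from the dispersion
#' mean (`G_ij` is undefined without extremes).
#'
#' @param H_ij,G_ij matrices from [thickness_grid()] / [dispersion_grid()].
#' @return list(H, G).
#' @export
layer_means <- function(H_ij, G_ij) {
  list(H = mean(H_ij), G = if (all(is.na(G_ij))) NA_real_
       else mean(G_ij, na.rm = TRUE))
}

#' Spatial variation of the thickness
#'
#' Population standard deviation of the tile thicknesses:
#' `E = sqrt(mean((H - H_ij)^2))`.
#'
#' @param H_ij thickness matrix.
#' @return scalar E (µm).
#' @export
spatial_variation <- function(H_ij) {
  sqrt(mean((mean(H_ij) - H_ij)^2))
}

#' Lipid statistics of the cornified layer
#'
#' Mean released-lipid ratio `L_out / L_max` over cornified cells and the
#' count of lipid-deficient cells (strictly below 50% of the maximum).
#'
#' @param L_out released lipid of the cornified cells.
#' @param L_max lipid cap.
#' @return list(ratio, n_deficient); ratio is NA with no cornified cells.
#' @export
lipid_stats <- function(L_out, L_max) {
  if (!length(L_out)) return(list(ratio = NA_real_, n_deficient = 0L))
  r <- L_out / L_max
  list(ratio = mean(r), n_deficient = sum(r < 0.5))
}

#' Basal-layer diagnostics
#'
#' Division frequency (events per day over a trailing window), the number of
#' basal (attached) cells and the number of proliferative cells (attached
#' with a remaining division budget; stem cells count). In homeostasis the
#' frequency is close to `n_proliferative / T_div`.
#'
#' @param div_times times of division events (days).
#' @param attached logical vector over living cells.
#' @param div_left remaining divisions (Inf for stem).
#' @param window averaging window (days), ending at `t_now`; must be > 0.
#' @param t_now current time.
#' @return list(div_per_day, n_basal, n_proliferative).
#' @export
basal_stats <- function(div_times, attached, div_left, window, t_now) {
  if (window <= 0) stop("basal_stats: empty window")
  nev <- sum(div_times > t_now - window & div_times <= t_now)
  list(div_per_day = nev / window,
       n_basal = sum(attached),
       n_proliferative = sum(attached & div_left > 0))
}

#' Membrane deformation amplitude
#'
#' Difference between the maximum and minimum vertical displacement of the
#' membrane particles.
#'
#' @param mem_pos membrane particle positions (n x 3) or an `ep_state`.
#' @return amplitude (µm).
#' @export
membrane_amplitude <- function(mem_pos) {
  if (inherits(mem_pos, "ep_state")) mem_pos <- mem_pos$mem$pos
  max(mem_pos[, 3]) - min(mem_pos[, 3])
}

#' Turnover statistics from the event log
#'
#' Mean time from basal birth to desquamation (over division-born removed
#' cells, i.e. excluding the seeded founders) and mean time from
#' cornification to desquamation, over removals inside a time window.
#'
#' @param removals removals data.frame from [event_log()].
#' @param from,to window of removal times (days) to include.
#' @return list(turnover, corn_lag, n_turnover, n_lag): means in days and
#'   the number of removals behind each.
#' @export
turnover_stats <- function(removals, from = 0, to = Inf) {
  r <- removals[removals$time >= from & removals$time <= to, , drop = FALSE]
  born <- r[r$born_div > 0, , drop = FALSE]
  corn <- r[!is.na(r$t_corn), , drop = FALSE]
  list(turnover = if (nrow(born)) mean(born$time - born$t_birth) else NA_real_,
       corn_lag = if (nrow(corn)) mean(corn$time - corn$t_corn) else NA_real_,
       n_turnover = nrow(born), n_lag = nrow(corn))
}

#' Snapshot layer metrics
#'
#' One row of every evaluation measure of a state: thickness `H`, dispersion
#' `G` and spatial variation `E` for the granular and cornified layers on
#' the `M1 x M2` subregion grid, lipid statistics, basal-layer diagnostics
#' and the membrane deformation amplitude.
#'
#' @param state an `ep_state`.
#' @param window trailing window (days) for the division frequency.
#' @return one-row data.frame.
#' @export
layer_metrics <- function(state, window = 7) {
  p <- state$params
  cl <- state$cells
  grid <- subregion_grid(p$Lx, p$Ly, p$M1, p$M2)
  one_layer <- function(code) {
    sel <- cl$type == code
    H_ij <- thickness_grid(cl$pos[sel, 1], cl$pos[sel, 2], grid, p$R)
    G_ij <- dispersion_grid(cl$pos[sel, 1], cl$pos[sel, 2], cl$pos[sel, 3],
                            grid, H_ij)
    m <- layer_means(H_ij, G_ij)
    c(H = m$H, G = m$G, E = spatial_variation(H_ij))
  }
  gr <- one_layer(4L)
  co <- one_layer(5L)
  ls <- lipid_stats(cl$L_out[cl$type == 5L], p$L_max)
  div_times <- if (length(state$events$divisions))
    do.call(rbind, state$events$divisions)[, 1] else numeric(0)
  bs <- basal_stats(div_times, cl$attached, cl$div_left,
                    window = min(window, max(state$t, 1e-6)), t_now = state$t)
  data.frame(t = state$t,
             H_gran = gr[["H"]], G_gran = gr[["G"]], E_gran = gr[["E"]],
             H_corn = co[["H"]], G_corn = co[["G"]], E_corn = co[["E"]],
             lipid_ratio = ls$ratio, n_deficient = ls$n_deficient,
             div_per_day = bs$div_per_day, n_basal = bs$n_basal,
             n_proliferative = bs$n_proliferative,
             mem_amplitude = membrane_amplitude(state$mem$pos),
             n_cells = length(cl$id))
}

#' Time-average of a metric series over a stationary window
#'
#' Averages the requested columns of a metrics time series over
#' `t >= burn_in`, the convention used for all regime comparisons (the
#' transient is excluded).
#'
#' @param metrics data.frame from [run_simulation()].
#' @param burn_in start of the stationary window (days).
#' @param cols columns to average (default: all numeric except `t`).
#' @return named numeric vector of time averages.
#' @export
time_average <- function(metrics, burn_in, cols = NULL) {
  m <- metrics[metrics$t >= burn_in, , drop = FALSE]
  if (!nrow(m)) stop("time_average: no samples after the burn-in")
  if (is.null(cols)) cols <- setdiff(names(m)[vapply(m, is.numeric,
                                                     logical(1))], "t")
  vapply(m[cols], mean, numeric(1), na.rm = TRUE)
}
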