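# Pairwise and membrane mechanics, and the overdamped Euler step.

#' Central pair force between two particles
#'
#' Piecewise force along the separation vector: linear repulsion
#' `k_rep (r_eq - r)` below the rest separation, a quadratic attraction well
#' `-k_adh (r - r_eq)(r_cut - r)/(r_cut - r_eq)^2` between `r_eq` and `r_cut`
#' (zero at both ends, peak attraction `k_adh/4` at the midpoint), zero
#' beyond the cutoff.
#'
#' @param pos_i,pos_j 3-vectors (µm); minimal-image convention is the
#'   caller's responsibility.
#' @param r_eq rest separation; `r_cut > r_eq > 0`.
#' @param k_rep,k_adh repulsion and adhesion coefficients.
#' @param r_cut interaction cutoff.
#' @return Force 3-vector acting on particle i.
#' @export
#' @examples
#' pair_force(c(0, 0, 0), c(10, 0, 0), r_eq = 10, k_rep = 1, k_adh = 1,
#'            r_cut = 13)  # zero at rest separation
pair_force <- function(pos_i, pos_j, r_eq, k_rep, k_adh, r_cut) {
  stopifnot(r_cut > r_eq, r_eq > 0)
  d <- pos_i - pos_j
  r <- sqrt(sum(d^2))
  if (r == 0) stop("coincident positions: pair force direction undefined")
  f <- if (r < r_eq) {
    k_rep * (r_eq - r)
  } else if (r < r_cut) {
    -k_adh * (r - r_eq) * (r_cut - r) / (r_cut - r_eq)^2
  } else 0
  f * d / r
}

#' Effective separation of two spheroidal cells
#'
#' The z-component of the separation is rescaled by the mean
#' equatorial-to-polar ratio of the two cells before taking the norm, so
#' flattened cells interact at a shorter vertical range. Reduces to the
#' Euclidean distance for spheres.
#'
#' @param dx,dy,dz separation components (µm, minimal image).
#' @param a_i,c_i,a_j,c_j equatorial and polar semi-axes of the two cells.
#' @return Effective scalar separation (vectorised).
#' @export
effective_separation <- function(dx, dy, dz, a_i, c_i, a_j, c_j) {
  s <- 0.5 * (a_i / c_i + a_j / c_j)
  sqrt(dx^2 + dy^2 + (s * dz)^2)
}

#' Elastic forces of the basement membrane
#'
#' Negative gradient of
#' `E = sum_edges k_stretch (l - l0)^2 / 2 + sum_hinges k_bend (1 - cos θ)`
#' with θ the dihedral deviation from flat. A flat mesh at its rest lengths
#' carries zero energy and zero force.
#'
#' @param mesh membrane mesh list with `pos`, `edges`, `l0`, `hinges` (as in
#'   `ep_state$mem`).
#' @param k_stretch,k_bend elastic moduli.
#' @param Lx,Ly periodic box size.
#' @return list with `force` (n x 3 matrix) and `energy` (scalar).
#' @export
membrane_elastic_forces <- function(mesh, k_stretch, k_bend, Lx, Ly) {
  ep_membrane_forces_cpp(mesh$pos, mesh$edges, mesh$l0, mesh$hinges,
                         k_stretch, k_bend, Lx, Ly)
}

#' Basal adhesion force of one cell to the membrane
#'
#' Pull-only linear spring toward the nearest membrane particle, zero at the
#' contact distance `R`; stem cells use `k_stem`, TA cells `k_TA`
#' (`k_stem > k_TA`: differential adhesion). Detachment of TA cells beyond
#' `R + d_detach` is handled by [step_state()].
#'
#' @param cell_pos 3-vector.
#' @param mem_pos membrane particle positions (n x 3).
#' @param k spring constant (`k_stem` or `k_TA`).
#' @param R contact distance (cell radius).
#' @param Lx,Ly periodic box size.
#' @return list(force = 3-vector on the cell, dist = distance to the nearest
#'   membrane particle, nearest = its row index).
#' @export
adhesion_to_membrane <- function(cell_pos, mem_pos, k, R, Lx, Ly) {
  dx <- cell_pos[1] - mem_pos[, 1]; dx <- dx - Lx * round(dx / Lx)
  dy <- cell_pos[2] - mem_pos[, 2]; dy <- dy - Ly * round(dy / Ly)
  dz <- cell_pos[3] - mem_pos[, 3]
  r2 <- dx^2 + dy^2 + dz^2
  j <- which.min(r2)
  d <- sqrt(r2[j])
  f <- if (d > R) -k * (d - R) * c(dx[j], dy[j], dz[j]) / d else c(0, 0, 0)
  list(force = f, dist = d, nearest = j)
}

# parameter list handed to the C++ kernel
force_par <- function(p) {
  list(Lx = p$Lx, Ly = p$Ly, k_rep = p$k_rep, k_adh_cell = p$k_adh_cell,
       k_adh_derm_eff = p$k_adh_derm * p$stiffness_mult,
       k_adh_derm_mem = p$k_adh_mem,
       k_stem = p$k_stem, k_TA = p$k_TA,
       k_stretch = p$k_stretch, k_bend = p$k_bend,
       derm_req = p$derm_spacing, derm_rcut = 1.3 * p$derm_spacing,
       dm_req = p$derm_spacing / 2, dm_rcut = p$derm_spacing / 2 + 5,
       rcut_factor = p$rcut_factor, R = p$R,
       derm_radius = p$derm_spacing / 2)
}

#' Compute all forces of a state
#'
#' One evaluation of every mechanical interaction: dermal-dermal and
#' dermal-membrane adhesive pair forces (with the dermal stiffening
#' multiplier on dermal-dermal adhesion), membrane stretching and bending,
#' spheroid cell-cell forces at the effective separation, steric repulsion of
#' cells against membrane and dermis, and basal adhesion springs. Internal
#' pair forces obey Newton's third law; immobile dermal particles get zero
#' force.
#'
#' @param state an `ep_state`.
#' @param want_energy also accumulate the total mechanical energy.
#' @return list: `f_derm`, `f_mem`, `f_cell` (n x 3 matrices), `mem_dist`
#'   (distance of each attached cell to its nearest membrane particle, NA for
#'   detached cells), `pairs` (cell-neighbour index pairs used as the
#'   signalling graph), `energy`.
#' @export
compute_forces <- function(state, want_energy = FALSE) {
  cl <- state$cells
  ep_forces_cpp(state$derm$pos, state$derm$mobile,
                state$mem$pos, state$mem$edges, state$mem$l0,
                state$mem$hinges,
                cl$pos, cl$a, cl$c, cl$attached, cl$type == 1L,
                force_par(state$params), want_energy)
}

#' Total mechanical energy of a state
#'
#' Sum of all pair potentials, membrane elastic energy and basal adhesion
#' spring energy. Under pure overdamped relaxation (no division, signalling
#' or removal events) this is non-increasing for `dt` below the stability
#' bound.
#'
#' @param state an `ep_state`.
#' @return scalar energy.
#' @export
total_energy <- function(state) compute_forces(state, want_energy = TRUE)$energy

wrap_xy <- function(pos, Lx, Ly) {
  pos[, 1] <- pos[, 1] %% Lx
  pos[, 2] <- pos[, 2] %% Ly
  pos
}

#' Advance the mechanics by one Euler step
#'
#' Overdamped explicit Euler `x <- x + F dt` (damping 1) for dermal
#' particles, membrane particles and cells, with periodic wrapping in x and
#' y. This is the pure mechanics update used by the full scheduler
#' [step_simulation()]; it performs no lifecycle or signalling events.
#'
#' @param state an `ep_state`, modified in place.
#' @param dt step (days); must not exceed [dt_stability_bound()].
#' @param forces optional precomputed result of [compute_forces()].
#' @return The force list (invisibly), including `mem_dist` and `pairs` for
#'   the caller.
#' @export
step_state <- function(state, dt, forces = NULL) {
  p <- state$params
  if (dt > dt_stability_bound(p) * (1 + 1e-9))
    stop("dt exceeds the mechanics stability bound")
  if (is.null(forces)) forces <- compute_forces(state)
  state$derm$pos <- wrap_xy(state$derm$pos + dt * forces$f_derm, p$Lx, p$Ly)
  state$mem$pos <- wrap_xy(state$mem$pos + dt * forces$f_mem, p$Lx, p$Ly)
  if (length(state$cells$id))
    state$cells$pos <- wrap_xy(state$cells$pos + dt * forces$f_cell,
                               p$Lx, p$Ly)
  if (!all(is.finite(state$derm$pos)))
    stop("integration error: non-finite dermal particle position")
  if (!all(is.finite(state$mem$pos)))
    stop("integration error: non-finite membrane particle position")
  if (length(state$cells$id) && !all(is.finite(state$cells$pos)))
    stop("integration error: non-finite cell position")
  state$t <- state$t + dt
  invisible(forces)
}
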