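# Calcium and stimulant dynamics on the cell-neighbour graph, lipid
# production/release, and corneodesmosome-controlled desquamation.

#' Cell neighbour graph
#'
#' Pairs of cells whose effective separation is below the interaction cutoff
#' (`rcut_factor * (a_i + a_j)`); the same adjacency that carries the
#' cell-cell forces. Symmetric, no self edges; rebuilt every step by the
#' scheduler.
#'
#' @param state an `ep_state`.
#' @return two-column integer matrix of row-index pairs.
#' @export
neighbor_pairs <- function(state) compute_forces(state)$pairs

#' One explicit step of field exchange and decay
#'
#' Graph-Laplacian exchange with linear decay:
#' `v_i <- v_i + dt (D sum_j (v_j - v_i) - lambda v_i)`. With `lambda = 0`
#' the graph diffusion conserves the total mass exactly; non-negativity is
#' preserved for `dt` below the explicit-scheme bound `1/(D deg_max +
#' lambda)`.
#'
#' @param v field values per cell.
#' @param pairs two-column matrix of neighbour index pairs.
#' @param dt time step (days).
#' @param D exchange rate (1/day); `lambda` decay rate (1/day).
#' @param lambda decay rate (1/day).
#' @return Updated field vector.
#' @export
graph_diffusion_step <- function(v, pairs, dt, D, lambda) {
  n <- length(v)
  deg_max <- if (nrow(pairs)) max(tabulate(c(pairs[, 1], pairs[, 2]), n)) else 0
  if (dt * (D * deg_max + lambda) > 1)
    stop("dt above the explicit diffusion stability bound")
  lap <- ep_graph_sum_cpp(v, pairs[, 1], pairs[, 2], n)
  v + dt * (D * lap - lambda * v)
}

#' Calcium release at cornification
#'
#' A fixed dose `Q_Ca` is split equally among the cornifying cell's living
#' (non-cornified) graph neighbours; the total added calcium is exactly
#' `Q_Ca` per event. With no eligible neighbour the dose is discarded and
#' counted in `state$events$discarded_doses`.
#'
#' @param state an `ep_state`, modified in place.
#' @param idx row indices of cells that just cornified.
#' @param pairs neighbour pairs (from the current step's force evaluation).
#' @return invisibly, the number of discarded doses this call.
#' @export
cornification_release <- function(state, idx, pairs) {
  if (!length(idx)) return(invisible(0L))
  cl <- state$cells
  Q <- state$params$Q_Ca
  discarded <- 0L
  for (i in idx) {
    nb <- c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])
    nb <- nb[cl$type[nb] != 5L]  # living neighbours (suprabasal side and basal)
    if (!length(nb)) {
      discarded <- discarded + 1L
      next
    }
    cl$Ca[nb] <- cl$Ca[nb] + Q / length(nb)
  }
  if (discarded) {
    state$events$discarded_doses <- state$events$discarded_doses + discarded
    warning(sprintf("%d calcium dose(s) discarded: cornified cell without living neighbours", discarded))
  }
  state$cells <- cl
  invisible(discarded)
}

#' Lipid production and release
#'
#' Granular cells accumulate internal lipid at rate `p_lip`, capped so
#' `L_in + L_out <= L_max`. When a cell's calcium exceeds `Ca_threshold` —
#' which typically happens when a neighbour cornifies and sends its dose —
#' the entire internal store transfers to the released pool in one shot.
#' Cells that never receive the calcium trigger keep their store internal
#' and count as lipid-deficient once cornified.
#'
#' @param type integer type codes.
#' @param Ca calcium per cell.
#' @param L_in,L_out internal and released lipid.
#' @param dt time step (days).
#' @param p_lip production rate (1/day); `L_max` cap; `Ca_threshold` release
#'   trigger.
#' @param L_max lipid cap.
#' @param Ca_threshold calcium release trigger.
#' @param force_release logical vector: force the transfer regardless of
#'   calcium (not used by the default scheduler).
#' @return list(L_in, L_out).
#' @export
lipid_update <- function(type, Ca, L_in, L_out, dt, p_lip, L_max,
                         Ca_threshold, force_release = FALSE) {
  gran <- type == 4L
  L_in[gran] <- pmin(L_in[gran] + p_lip * dt, L_max - L_out[gran])
  rel <- (Ca > Ca_threshold | force_release) & L_in > 0
  L_out[rel] <- L_out[rel] + L_in[rel]
  L_in[rel] <- 0
  list(L_in = L_in, L_out = L_out)
}

#' Corneodesmosome decay and desquamation
#'
#' Cornified cells' junction integrity decays as `D <- D exp(-dt/tau_desq)`.
#' A cornified cell is removed (desquamates) once `D < D_th` and it is
#' surface-exposed: no other cell centre lies above it within one lateral
#' (equatorial) radius. Removals are logged with birth and cornification
#' timestamps.
#'
#' @param state an `ep_state`, modified in place.
#' @param dt time step (days).
#' @return invisibly, ids of the removed cells.
#' @export
desquamation_update <- function(state, dt) {
  cl <- state$cells
  p <- state$params
  corn <- cl$type == 5L
  if (!any(corn)) return(invisible(integer(0)))
  cl$D[corn] <- cl$D[corn] * exp(-dt / p$tau_desq)
  state$cells <- cl
  cand <- which(corn & cl$D < p$D_th)
  if (!length(cand)) return(invisible(integer(0)))
  exposed <- ep_exposed_cpp(cl$pos, cl$a, cand, p$Lx, p$Ly)
  rem <- cand[exposed]
  if (!length(rem)) return(invisible(integer(0)))
  state$events$removals[[length(state$events$removals) + 1L]] <-
    cbind(state$t, cl$id[rem], cl$t_birth[rem], cl$t_corn[rem],
          as.numeric(cl$born_div[rem]), cl$lineage[rem],
          as.numeric(cl$abnormal[rem]))
  remove_and_append(state, rem)
  invisible(cl$id[rem])
}
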