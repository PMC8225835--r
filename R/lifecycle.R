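# Cell division, delamination-triggered differentiation, type assignment
# and shape flattening.

#' Draw the next division time
#'
#' The cycle is stochastic around the deterministic period `T_div`: the
#' waiting time is `T_div * X` with `X` lognormal with mean 1 and coefficient
#' of variation `cycle_cv` (`cycle_cv = 0` gives exactly `T_div`). Cells of
#' the abnormal (corn) lineage divide `div_factor` times faster, i.e. their
#' period is `T_div / div_factor`.
#'
#' @param t_now current time (days).
#' @param T_div division period (days).
#' @param cycle_cv coefficient of variation of the lognormal jitter.
#' @param abnormal logical vector; TRUE for corn-lineage cells.
#' @param div_factor speed-up factor of the abnormal lineage (default 2).
#' @return Vector of next division times (days). Vectorised over
#'   `abnormal`; draws come from the active RNG stream.
#' @export
schedule_division_time <- function(t_now, T_div, cycle_cv, abnormal = FALSE,
                                   div_factor = 2) {
  n <- length(abnormal)
  x <- if (cycle_cv > 0) {
    sdl <- sqrt(log(1 + cycle_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)
  period <- ifelse(abnormal, T_div / div_factor, T_div)
  t_now + period * x
}

#' Divide one basal cell
#'
#' Asymmetric stem division (one stem + one TA daughter with a fresh budget
#' of `N_div` divisions, so the stem count per niche is conserved) or
#' symmetric TA division (two TA daughters, each with one division fewer
#' than the mother). Daughters are placed at `± div_offset/2` along a random
#' horizontal direction, inherit the mother's lineage root, abnormality flag
#' and half of her calcium and stimulant (mass-conserving), and are
#' rescheduled. The mother is replaced; the event is logged.
#'
#' @param state an `ep_state`, modified in place.
#' @param idx row indices (into the cell table) of the mothers; all must be
#'   attached and proliferative.
#' @return ids of the daughters (invisibly).
#' @export
divide_cells <- function(state, idx) {
  cl <- state$cells
  p <- state$params
  if (any(!cl$attached[idx] | !(cl$type[idx] %in% c(1L, 2L)) |
          cl$div_left[idx] <= 0))
    stop("divide: cell is not attached and proliferative")
  n_new <- 2L * length(idx)
  phi <- stats::runif(length(idx), 0, 2 * pi)
  ux <- cos(phi); uy <- sin(phi)
  off <- p$div_offset / 2
  ids <- state$next_id - 1L + seq_len(n_new)
  state$next_id <- state$next_id + n_new

  d1 <- seq_along(idx) * 2L - 1L
  d2 <- seq_along(idx) * 2L
  pos <- matrix(0, n_new, 3)
  pos[d1, ] <- cl$pos[idx, , drop = FALSE] + off * cbind(ux, uy, 0)
  pos[d2, ] <- cl$pos[idx, , drop = FALSE] - off * cbind(ux, uy, 0)
  pos <- wrap_xy(pos, p$Lx, p$Ly)

  m_stem <- cl$type[idx] == 1L
  type <- integer(n_new)
  type[d1] <- ifelse(m_stem, 1L, 2L)
  type[d2] <- 2L
  div_left <- numeric(n_new)
  div_left[d1] <- ifelse(m_stem, Inf, cl$div_left[idx] - 1)
  div_left[d2] <- ifelse(m_stem, as.numeric(p$N_div), cl$div_left[idx] - 1)
  abnormal <- rep(cl$abnormal[idx], each = 2L)
  next_div <- schedule_division_time(state$t, p$T_div, p$cycle_cv,
                                     abnormal, p$div_factor_abnormal)

  new <- list(
    id = ids,
    lineage = rep(cl$lineage[idx], each = 2L),
    abnormal = abnormal,
    pos = pos,
    type = type,
    attached = rep(TRUE, n_new),
    div_left = div_left,
    next_div = next_div,
    w = numeric(n_new), a = rep(p$R, n_new), c = rep(p$R, n_new),
    Ca = rep(cl$Ca[idx] / 2, each = 2L),
    S = rep(cl$S[idx] / 2, each = 2L),
    L_in = numeric(n_new), L_out = numeric(n_new), D = rep(1, n_new),
    t_birth = rep(state$t, n_new), t_corn = rep(NA_real_, n_new),
    born_div = rep(TRUE, n_new)
  )
  state$events$divisions[[length(state$events$divisions) + 1L]] <-
    cbind(state$t, cl$id[idx], ids[d1], ids[d2], cl$type[idx],
          cl$pos[idx, 1], cl$pos[idx, 2], cl$pos[idx, 3])
  remove_and_append(state, idx, new)
  invisible(ids)
}

# drop rows `idx` from the cell table and append the `new` block (may be NULL)
remove_and_append <- function(state, idx, new = NULL) {
  cl <- state$cells
  keep <- if (length(idx)) -idx else TRUE
  for (f in names(cl)) {
    v <- if (f == "pos") cl$pos[keep, , drop = FALSE] else cl[[f]][keep]
    if (!is.null(new))
      v <- if (f == "pos") rbind(v, new$pos) else c(v, new[[f]])
    cl[[f]] <- v
  }
  state$cells <- cl
  invisible(state)
}

#' Delaminate detached TA cells
#'
#' A TA cell whose membrane bond was lost (mechanics pushed it beyond the
#' detachment distance) is regarded as differentiated: it becomes spinous,
#' its differentiation state starts evolving from `w = 0`, and it never
#' divides again. Irreversible; stem cells never delaminate.
#'
#' @param state an `ep_state`, modified in place.
#' @param idx row indices of detached TA cells (must currently be attached
#'   TA cells — the caller decides detachment).
#' @return invisibly, the ids delaminated.
#' @export
delaminate_cells <- function(state, idx) {
  if (!length(idx)) return(invisible(integer(0)))
  cl <- state$cells
  if (any(cl$type[idx] != 2L))
    stop("delaminate: only TA cells can delaminate")
  cl$attached[idx] <- FALSE
  cl$type[idx] <- 3L
  cl$w[idx] <- 0
  cl$next_div[idx] <- Inf
  state$cells <- cl
  state$events$delaminations[[length(state$events$delaminations) + 1L]] <-
    cbind(state$t, cl$id[idx])
  invisible(cl$id[idx])
}

#' Advance the differentiation state
#'
#' `w` grows at the baseline speed `alpha`, accelerated linearly by the local
#' calcium and stimulant levels:
#' `w <- w + alpha_eff (1 + beta_Ca Ca + beta_S S) dt`, with
#' `alpha_eff = diff_factor * alpha` for the abnormal (corn) lineage.
#' Applies to differentiated, living cells (spinous, granular); cornified
#' cells stop advancing. `w` is non-decreasing.
#'
#' @param w current state values (>= 0).
#' @param Ca,S local calcium and stimulant levels (>= 0).
#' @param dt time step (days).
#' @param alpha baseline speed; `beta_Ca`, `beta_S` acceleration
#'   coefficients.
#' @param beta_Ca,beta_S acceleration coefficients.
#' @param abnormal logical; corn-lineage flag.
#' @param diff_factor abnormal-lineage speed-up (default 2).
#' @return Updated `w` vector.
#' @export
advance_differentiation <- function(w, Ca, S, dt, alpha, beta_Ca, beta_S,
                                    abnormal = FALSE, diff_factor = 2) {
  if (any(w < 0) || any(Ca < 0) || any(S < 0))
    stop("advance_differentiation: negative input")
  a_eff <- ifelse(abnormal, diff_factor * alpha, alpha)
  w + a_eff * (1 + beta_Ca * Ca + beta_S * S) * dt
}

#' Cell type from the differentiation state
#'
#' Half-open intervals: spinous for `w < w1`, granular for `w1 <= w < w2`,
#' cornified for `w >= w2`. The first crossing of `w2` is the cornification
#' event (timestamped and signalled by the scheduler).
#'
#' @param w state values (>= 0).
#' @param w1,w2 thresholds, `w2 > w1 > 0`.
#' @return Integer codes (3 spinous, 4 granular, 5 cornified); see
#'   [cell_type_label()].
#' @export
assign_type <- function(w, w1, w2) {
  ifelse(w >= w2, 5L, ifelse(w >= w1, 4L, 3L))
}

#' Spheroid semi-axes from the differentiation state
#'
#' Flattening: the aspect ratio `q = c/a` falls linearly in `w` from 1
#' (sphere) at `w = 0` to `q_min` at `w = w2` and stays there; the semi-axes
#' solve `a^2 c = R^3` (volume conservation) with `c = q a`.
#'
#' @param w state values.
#' @param w2 cornification threshold.
#' @param R undifferentiated radius.
#' @param q_min terminal aspect ratio (default 0.25).
#' @return list(a, c) of semi-axes (µm).
#' @export
cell_shape <- function(w, w2, R, q_min = 0.25) {
  q <- 1 - (1 - q_min) * pmin(w, w2) / w2
  a <- R * q^(-1 / 3)
  list(a = a, c = a * q)
}
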