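# Full scheduler: mechanics step + lifecycle + signalling + desquamation.

#' Advance the full model by one time step
#'
#' One step of the coupled model, in this order: (1) overdamped mechanics
#' update of all particle species; (2) calcium/stimulant exchange, decay and
#' cornified-cell secretion on the neighbour graph; (3) differentiation
#' advance of suprabasal cells with type transitions — a first crossing of
#' `w2` stamps the cornification time, arms the corneodesmosome and releases
#' the calcium dose onto the living suprabasal neighbours; (4) lipid
#' production in granular cells and calcium-triggered release (a
#' neighbour's cornification dose is the typical trigger); (5) flattening;
#' (6) delamination of TA cells pushed beyond the detachment distance;
#' (7) scheduled basal divisions; (8) corneodesmosome decay and
#' desquamation.
#'
#' @param state an `ep_state`, modified in place.
#' @param dt time step (days); defaults to `params$dt`.
#' @return invisibly, the state.
#' @export
step_simulation <- function(state, dt = state$params$dt) {
  p <- state$params
  forces <- compute_forces(state)
  step_state(state, dt, forces)
  cl <- state$cells
  n <- length(cl$id)
  if (n == 0L) return(invisible(state))
  pairs <- forces$pairs

  # (2) fields on the neighbour graph
  cl$Ca <- graph_diffusion_step(cl$Ca, pairs, dt, p$D_Ca, p$lambda_Ca)
  S <- graph_diffusion_step(cl$S, pairs, dt, p$D_S, p$lambda_S)
  if (nrow(pairs)) {
    corn1 <- cl$type[pairs[, 1]] == 5L
    corn2 <- cl$type[pairs[, 2]] == 5L
    src <- tabulate(c(pairs[corn1, 2], pairs[corn2, 1]), n)
    S <- S + p$s_rate * dt * src
  }
  cl$S <- S

  # (3) differentiation and type transitions
  dif <- cl$type %in% c(3L, 4L)
  if (any(dif)) {
    cl$w[dif] <- advance_differentiation(cl$w[dif], cl$Ca[dif], cl$S[dif],
                                         dt, p$alpha, p$beta_Ca, p$beta_S,
                                         cl$abnormal[dif],
                                         p$diff_factor_abnormal)
    new_type <- assign_type(cl$w[dif], p$w1, p$w2)
    cornified_now <- which(dif)[new_type == 5L & cl$type[dif] != 5L]
    cl$type[dif] <- new_type
    if (length(cornified_now)) {
      cl$t_corn[cornified_now] <- state$t
      cl$D[cornified_now] <- 1
      state$events$cornifications[[
        length(state$events$cornifications) + 1L]] <-
        cbind(state$t, cl$id[cornified_now])
      state$cells <- cl
      suppressWarnings(cornification_release(state, cornified_now, pairs))
      cl <- state$cells
    }
  }

  # (4) lipids: granular production; release is purely calcium-triggered
  # (the dose a cornifying neighbour sends is the typical trigger)
  lp <- lipid_update(cl$type, cl$Ca, cl$L_in, cl$L_out, dt, p$p_lip,
                     p$L_max, p$Ca_lip_threshold)
  cl$L_in <- lp$L_in
  cl$L_out <- lp$L_out

  # (5) flattening
  sh <- cell_shape(cl$w, p$w2, p$R, p$q_min)
  cl$a <- sh$a
  cl$c <- sh$c
  state$cells <- cl

  # (6) detachment -> delamination (TA only; stems never detach)
  det <- which(cl$attached & cl$type == 2L &
                 (forces$mem_dist - p$R) > p$d_detach)
  delaminate_cells(state, det)

  # (7) scheduled divisions while attached and proliferative
  cl <- state$cells
  due <- which(cl$attached & cl$type %in% c(1L, 2L) & cl$div_left > 0 &
                 state$t >= cl$next_div)
  if (length(due)) divide_cells(state, due)

  # (8) desquamation
  desquamation_update(state, dt)
  invisible(state)
}

#' Run the simulation for a given duration
#'
#' Steps the model with the configured `dt` and samples [layer_metrics()]
#' at a fixed cadence. Deterministic given the state's seed.
#'
#' @param state an `ep_state`, modified in place.
#' @param days duration to simulate (days).
#' @param sample_every metrics sampling interval (days; default 0.07, i.e.
#'   4001 samples over a 280-day run).
#' @param window trailing window (days) for the division-frequency metric.
#' @param progress print a progress line every simulated 10 days.
#' @return data.frame of metric samples (one row per sample).
#' @export
run_simulation <- function(state, days, sample_every = 0.07, window = 7,
                           progress = FALSE) {
  p <- state$params
  n_steps <- ceiling(days / p$dt - 1e-9)
  t_end <- state$t + days
  next_sample <- state$t + sample_every
  out <- vector("list", ceiling(days / sample_every) + 1L)
  k <- 0L
  for (s in seq_len(n_steps)) {
    dt <- min(p$dt, t_end - state$t)
    if (dt <= 1e-12) break
    step_simulation(state, dt)
    if (state$t + 1e-9 >= next_sample) {
      k <- k + 1L
      out[[k]] <- layer_metrics(state, window)
      next_sample <- next_sample + sample_every
      if (progress && k %% max(1L, round(10 / sample_every)) == 0L)
        message(sprintf("t = %.1f d, %d cells", state$t,
                        length(state$cells$id)))
    }
  }
  do.call(rbind, out[seq_len(k)])
}
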