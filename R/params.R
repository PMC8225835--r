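#' Default model parameters
#'
#' Returns the full parameter set of the epidermis model as an `ep_params`
#' object. Lengths are in micrometres (the undifferentiated cell radius
#' `R = 5` sets the 10 µm cell-diameter anchor), times in days. The defaults
#' are the calibrated homeostasis regime `(N_div, T_div) = (14, 4.0)`; the
#' desquamation timescale `tau_desq` is calibrated so that the mean lag from
#' cornification to shedding is 14 days, which together with the basal and
#' suprabasal transit puts the whole-epidermis turnover near 28 days.
#'
#' @param ... named overrides of any default field. Unknown names are an
#'   error.
#' @return An `ep_params` object (named list).
#' @details Key fields:
#' \describe{
#'   \item{N_div, T_div}{maximum number of TA-cell divisions and the cell
#'     division period (days).}
#'   \item{R}{undifferentiated cell radius (µm).}
#'   \item{tau_desq, D_th}{corneodesmosome decay timescale (days) and removal
#'     threshold on the integrity variable `D` in \[0, 1\].}
#'   \item{Lx, Ly, M1, M2}{lateral domain size (µm) and the subregion grid
#'     used by the layer metrics.}
#'   \item{k_rep, k_adh_cell, k_adh_derm, k_adh_mem, k_stem, k_TA}{force
#'     coefficients (µm/day at unit strain): repulsion, cell-cell adhesion,
#'     dermal-dermal adhesion, membrane-dermis adhesion and the basal
#'     adhesion springs; `stiffness_mult` scales the dermal-dermal adhesion
#'     to model a stiffened dermis.}
#'   \item{k_stretch, k_bend}{membrane stretching and bending moduli.}
#'   \item{w1, w2}{differentiation-state thresholds for the spinous/granular
#'     and granular/cornified transitions.}
#'   \item{alpha, beta_Ca, beta_S}{baseline differentiation speed (state
#'     units/day) and its acceleration per unit calcium / stimulant.}
#'   \item{lambda_Ca, lambda_S, D_Ca, D_S}{field decay rates (1/day) and
#'     neighbour-graph exchange rates (1/day); the stimulant decays more
#'     slowly, making it longer-ranged than calcium.}
#'   \item{Q_Ca, s_rate, Ca_lip_threshold}{calcium dose released at
#'     cornification, continuous stimulant secretion rate per cornified
#'     neighbour, and the calcium level that triggers lipid release.}
#'   \item{p_lip, L_max}{lipid production rate (1/day) and cap.}
#'   \item{cycle_cv}{coefficient of variation of the lognormal cell-cycle
#'     jitter.}
#'   \item{dt}{integration step (days); must satisfy [dt_stability_bound()].}
#'   \item{div_factor_abnormal, diff_factor_abnormal}{corn-lesion modifiers:
#'     descendants of the abnormal stem cell divide and differentiate this
#'     many times faster (2 reproduces the lesion, 1 is the null control).}
#' }
#' @export
#' @examples
#' p <- default_params(Lx = 100, Ly = 100)
#' validate_params(p)
default_params <- function(...) {
  p <- list(
    # supply
    N_div = 14L, T_div = 4.0, cycle_cv = 0.2,
    # geometry / units
    R = 5, Lx = 200, Ly = 200, M1 = 4L, M2 = 4L,
    derm_spacing = 10, derm_layers = 4L, mem_spacing = 5,
    stem_spacing = 50, q_min = 0.25,
    # mechanics
    k_rep = 25, k_adh_cell = 5, k_adh_derm = 3, k_adh_mem = 30,
    stiffness_mult = 1,
    k_stem = 15, k_TA = 6, k_stretch = 15, k_bend = 5,
    rcut_factor = 1.3, d_detach = 3,
    div_offset = 0.5,
    # differentiation
    w1 = 1, w2 = 2, alpha = 0.05, beta_S = 4, beta_Ca = 5,
    # fields
    lambda_Ca = 0.8, lambda_S = 0.25, D_Ca = 1, D_S = 1,
    Q_Ca = 3, s_rate = 0.12,
    # lipids
    p_lip = 0.3, L_max = 1, Ca_lip_threshold = 0.25,
    # desquamation (calibrated; ~14 / ln(1/D_th) minus exposure queueing)
    tau_desq = 5.5, D_th = 0.1,
    # abnormal (corn) lineage factors
    div_factor_abnormal = 2, diff_factor_abnormal = 2,
    # integration
    dt = 0.008, seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "ep_params")
}

#' Largest stable integration step
#'
#' Conservative explicit-Euler stability bound for the overdamped dynamics,
#' `dt_max = gamma / (4 k_max)` with damping `gamma = 1` and `k_max` the
#' largest effective stiffness among the repulsion, membrane stretching,
#' basal adhesion springs and the slopes of the adhesion wells (including the
#' dermal stiffening multiplier).
#'
#' @param params an `ep_params` object.
#' @return upper bound on `dt` in days.
#' @export
dt_stability_bound <- function(params) {
  p <- params
  well_cell <- p$k_adh_cell / (2 * p$R * (p$rcut_factor - 1))
  well_derm <- p$k_adh_derm * p$stiffness_mult / (0.3 * p$derm_spacing)
  well_mem <- p$k_adh_mem / 5
  k_max <- max(p$k_rep, p$k_stretch, p$k_stem, p$k_TA,
               p$k_bend / p$mem_spacing^2, well_cell, well_derm, well_mem)
  1 / (4 * k_max)
}

#' Validate model parameters
#'
#' Checks every invariant of the parameter set and reports violations rather
#' than throwing: positivity of periods, radii, rates and moduli, ordering of
#' the differentiation thresholds, grid sizes, and the integration-step
#' stability bound.
#'
#' @param params an `ep_params` object (or plain named list).
#' @return Character vector of violations, each naming the offending field;
#'   `character(0)` when all invariants hold.
#' @export
validate_params <- function(params) {
  p <- params
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(p$N_div >= 0, "N_div: must be >= 0")
  chk(p$T_div > 0, "T_div: must be > 0")
  chk(p$R > 0, "R: must be > 0")
  chk(p$tau_desq > 0, "tau_desq: must be > 0")
  chk(p$D_th > 0 && p$D_th < 1, "D_th: must be in (0, 1)")
  chk(p$Lx > 0 && p$Ly > 0, "Lx/Ly: must be > 0")
  chk(p$M1 >= 1 && p$M2 >= 1, "M1/M2: must be >= 1")
  for (f in c("k_rep", "k_adh_cell", "k_adh_derm", "k_adh_mem",
              "k_stem", "k_TA",
              "k_stretch", "k_bend", "alpha", "beta_Ca", "beta_S",
              "lambda_Ca", "lambda_S", "D_Ca", "D_S", "Q_Ca", "s_rate",
              "p_lip", "cycle_cv"))
    chk(p[[f]] >= 0, paste0(f, ": must be >= 0"))
  chk(p$w1 > 0 && p$w2 > p$w1, "w1/w2: need w2 > w1 > 0")
  chk(p$stiffness_mult > 0, "stiffness_mult: must be > 0")
  chk(p$L_max > 0, "L_max: must be > 0")
  chk(p$q_min > 0 && p$q_min <= 1, "q_min: must be in (0, 1]")
  chk(p$rcut_factor > 1, "rcut_factor: must be > 1")
  chk(p$dt > 0, "dt: must be > 0")
  if (p$dt > 0 && p$T_div > 0 && p$R > 0 && p$rcut_factor > 1)
    chk(p$dt <= dt_stability_bound(p),
        sprintf("dt: exceeds the stability bound %.4g", dt_stability_bound(p)))
  chk(p$div_factor_abnormal > 0, "div_factor_abnormal: must be > 0")
  chk(p$diff_factor_abnormal > 0, "diff_factor_abnormal: must be > 0")
  v
}

#' @export
print.ep_params <- function(x, ...) {
  cat("<ep_params>\n")
  cat(sprintf("  supply: N_div = %d, T_div = %.2f d (cv %.2f)\n",
              x$N_div, x$T_div, x$cycle_cv))
  cat(sprintf("  domain: %.0f x %.0f um, grid %d x %d, R = %.1f um\n",
              x$Lx, x$Ly, x$M1, x$M2, x$R))
  cat(sprintf("  desquamation: tau = %.3f d, threshold %.2f\n",
              x$tau_desq, x$D_th))
  cat(sprintf("  dermis stiffness multiplier: %.1f\n", x$stiffness_mult))
  cat(sprintf("  dt = %.4g d (bound %.4g)\n", x$dt, dt_stability_bound(x)))
  invisible(x)
}

# cell type codes used throughout the cell table
CELL_TYPES <- c("stem", "TA", "spinous", "granular", "cornified")

#' Cell type labels
#'
#' Integer codes 1..5 map to stem, TA, spinous, granular, cornified.
#' @param code integer vector of type codes.
#' @return character vector of labels.
#' @export
cell_type_label <- function(code) CELL_TYPES[code]
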