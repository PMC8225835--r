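# Construction of the initial world: flat dermal slab, flat triangular
# membrane at z = 0, basal monolayer of stem/TA cells attached to it.

# Periodic triangular lattice in the Lx x Ly box. Returns positions and, if
# with_mesh, edges (with rest lengths), hinges (a,b,c,d; triangles (a,b,c)
# and (b,a,d)) and triangles. Row count is forced even so the offset rows
# tile periodically in y.
tri_lattice <- function(Lx, Ly, spacing, z = 0, with_mesh = FALSE) {
  nx <- max(3L, as.integer(round(Lx / spacing)))
  hx <- Lx / nx
  ny <- max(4L, as.integer(round(Ly / (hx * sqrt(3) / 2))))
  if (ny %% 2L == 1L) ny <- ny + 1L
  hy <- Ly / ny
  ij <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  pos <- unname(cbind((ij$i + 0.5 * (ij$j %% 2L)) * hx,
                      ij$j * hy,
                      rep(z, nrow(ij))))
  if (!with_mesh)
    return(list(pos = pos, nx = nx, ny = ny))

  idx <- function(i, j) ((j %% ny) * nx + (i %% nx)) + 1L
  tris <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (j in 0:(ny - 1L)) {
    odd <- j %% 2L == 1L
    for (i in 0:(nx - 1L)) {
      if (!odd) {
        t1 <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
        t2 <- c(idx(i, j), idx(i, j + 1L), idx(i - 1L, j + 1L))
      } else {
        t1 <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
        t2 <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      }
      tris[k + 1L, ] <- t1
      tris[k + 2L, ] <- t2
      k <- k + 2L
    }
  }
  # unique edges and the (<= 2) triangles adjacent to each
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  t_of <- rep(seq_len(nrow(tris)), 3L)
  keys <- ekey(e_all[, 1], e_all[, 2])
  first <- !duplicated(keys)
  edges <- cbind(pmin(e_all[first, 1], e_all[first, 2]),
                 pmax(e_all[first, 1], e_all[first, 2]))
  adj <- split(t_of, keys)  # named by key, alphabetical
  edge_keys <- keys[first]

  mi <- function(d, L) d - L * round(d / L)
  evec <- function(a, b) cbind(mi(pos[b, 1] - pos[a, 1], Lx),
                               mi(pos[b, 2] - pos[a, 2], Ly),
                               pos[b, 3] - pos[a, 3])
  l0 <- sqrt(rowSums(evec(edges[, 1], edges[, 2])^2))

  hinges <- matrix(0L, 0L, 4L)
  hl <- vector("list", length(edge_keys))
  for (m in seq_along(edge_keys)) {
    ts <- adj[[edge_keys[m]]]
    if (length(ts) != 2L) next
    a <- edges[m, 1]; b <- edges[m, 2]
    opp <- function(tr) setdiff(tris[tr, ], c(a, b))
    cc <- opp(ts[1]); dd <- opp(ts[2])
    # orient so cc lies to the left of a -> b in the flat mesh
    ab <- evec(a, b); ac <- evec(a, cc)
    if (ab[1] * ac[2] - ab[2] * ac[1] < 0) { tmp <- cc; cc <- dd; dd <- tmp }
    hl[[m]] <- c(a, b, cc, dd)
  }
  hinges <- do.call(rbind, hl[!vapply(hl, is.null, logical(1))])
  storage.mode(hinges) <- "integer"
  storage.mode(edges) <- "integer"
  list(pos = pos, nx = nx, ny = ny, edges = edges, l0 = l0,
       hinges = hinges, triangles = tris)
}

#' Build the initial simulation state
#'
#' Constructs the cold-start world: a flat dermal slab of adhesive particles
#' on a close-packed lattice below `z = 0` (the deepest layer immobile), a
#' flat triangular-lattice basement membrane at `z = 0` at elastic rest (zero
#' stretching and bending energy), and a basal monolayer of cells attached to
#' the membrane. Stem cells sit on a regular square sub-lattice with spacing
#' `stem_spacing`; every other basal cell is a TA cell with
#' `divisions_left = N_div`. All cells start undifferentiated: `w = 0`,
#' `Ca = S = 0`, no lipids, spherical shape `a = c = R`. The RNG is seeded
#' from `params$seed`, making construction (and any subsequent simulation)
#' deterministic.
#'
#' @param params an `ep_params` object; must pass [validate_params()].
#' @return An `ep_state` environment with fields `t` (days), `params`,
#'   `derm`, `mem`, `cells`, `events` and `next_id`.
#' @export
#' @examples
#' st <- build_initial_state(default_params(Lx = 60, Ly = 60))
#' st
build_initial_state <- function(params) {
  v <- validate_params(params)
  if (length(v)) stop("invalid params: ", paste(v, collapse = "; "))
  p <- params
  set.seed(p$seed)

  # dermis: derm_layers close-packed triangular layers, alternate offset
  dz <- p$derm_spacing * sqrt(2 / 3)
  derm_pos <- NULL
  mobile <- NULL
  for (l in 0:(p$derm_layers - 1L)) {
    lay <- tri_lattice(p$Lx, p$Ly, p$derm_spacing,
                       z = -p$derm_spacing / 2 - l * dz)$pos
    if (l %% 2L == 1L) {
      lay[, 1] <- (lay[, 1] + p$Lx / (2 * round(p$Lx / p$derm_spacing))) %% p$Lx
      lay[, 2] <- (lay[, 2] + p$derm_spacing / (2 * sqrt(3))) %% p$Ly
    }
    derm_pos <- rbind(derm_pos, lay)
    mobile <- c(mobile, rep(l < p$derm_layers - 1L, nrow(lay)))
  }

  mesh <- tri_lattice(p$Lx, p$Ly, p$mem_spacing, z = 0, with_mesh = TRUE)

  # basal monolayer on a square lattice at contact height z = R
  ncx <- as.integer(round(p$Lx / (2 * p$R)))
  ncy <- as.integer(round(p$Ly / (2 * p$R)))
  if (ncx < 1L || ncy < 1L)
    stop("domain too small to host a basal monolayer")
  hcx <- p$Lx / ncx; hcy <- p$Ly / ncy
  gc_ <- expand.grid(i = 0:(ncx - 1L), j = 0:(ncy - 1L))
  cx <- (gc_$i + 0.5) * hcx
  cy <- (gc_$j + 0.5) * hcy
  n <- length(cx)

  # stem sub-lattice: nearest basal site to each stem grid point
  nsx <- max(1L, as.integer(round(p$Lx / p$stem_spacing)))
  nsy <- max(1L, as.integer(round(p$Ly / p$stem_spacing)))
  sg <- expand.grid(sx = (seq_len(nsx) - 0.5) * p$Lx / nsx,
                    sy = (seq_len(nsy) - 0.5) * p$Ly / nsy)
  stem_idx <- unique(vapply(seq_len(nrow(sg)), function(k) {
    dxs <- abs(cx - sg$sx[k]); dxs <- pmin(dxs, p$Lx - dxs)
    dys <- abs(cy - sg$sy[k]); dys <- pmin(dys, p$Ly - dys)
    which.min(dxs^2 + dys^2)
  }, integer(1)))
  if (length(stem_idx) < 1L)
    stop("domain too small to host one stem cell")

  type <- rep(2L, n)          # TA
  type[stem_idx] <- 1L        # stem
  cells <- list(
    id = seq_len(n),
    lineage = seq_len(n),
    abnormal = rep(FALSE, n),
    pos = unname(cbind(cx, cy, rep(p$R, n))),
    type = type,
    attached = rep(TRUE, n),
    div_left = ifelse(type == 1L, Inf, as.numeric(p$N_div)),
    # uniform phase over one period desynchronises the first wave
    next_div = stats::runif(n) * p$T_div,
    w = rep(0, n), a = rep(p$R, n), c = rep(p$R, n),
    Ca = rep(0, n), S = rep(0, n),
    L_in = rep(0, n), L_out = rep(0, n), D = rep(1, n),
    t_birth = rep(0, n), t_corn = rep(NA_real_, n),
    born_div = rep(FALSE, n)
  )

  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$params <- p
  st$derm <- list(pos = derm_pos, mobile = mobile)
  st$mem <- list(pos = mesh$pos, edges = mesh$edges, l0 = mesh$l0,
                 hinges = mesh$hinges, triangles = mesh$triangles)
  st$cells <- cells
  st$next_id <- n + 1L
  st$events <- new.env(parent = emptyenv())
  st$events$divisions <- list()
  st$events$cornifications <- list()
  st$events$removals <- list()
  st$events$delaminations <- list()
  st$events$discarded_doses <- 0L
  class(st) <- "ep_state"
  st
}

#' @export
print.ep_state <- function(x, ...) {
  tb <- table(factor(cell_type_label(x$cells$type), levels = CELL_TYPES))
  cat(sprintf("<ep_state> t = %.2f d, %d cells (%s)\n", x$t,
              length(x$cells$id),
              paste(names(tb), tb, sep = ":", collapse = ", ")))
  cat(sprintf("  dermis %d particles, membrane %d particles / %d edges\n",
              nrow(x$derm$pos), nrow(x$mem$pos), nrow(x$mem$edges)))
  invisible(x)
}

#' Cell table of a state
#'
#' @param state an `ep_state`.
#' @return data.frame with one row per living cell (id, lineage, abnormal,
#'   position, type, attachment, division budget, differentiation state `w`,
#'   semi-axes, calcium, stimulant, lipids, corneodesmosome integrity,
#'   timestamps).
#' @export
cells_df <- function(state) {
  cl <- state$cells
  data.frame(id = cl$id, lineage = cl$lineage, abnormal = cl$abnormal,
             x = cl$pos[, 1], y = cl$pos[, 2], z = cl$pos[, 3],
             type = cell_type_label(cl$type), attached = cl$attached,
             div_left = cl$div_left, next_div = cl$next_div, w = cl$w,
             a = cl$a, c = cl$c, Ca = cl$Ca, S = cl$S,
             L_in = cl$L_in, L_out = cl$L_out, D = cl$D,
             t_birth = cl$t_birth, t_corn = cl$t_corn,
             born_div = cl$born_div)
}

# event log accessors -------------------------------------------------------

#' Event log as data frames
#'
#' @param state an `ep_state`.
#' @return list of data.frames: `divisions` (time, mother, daughters, mother
#'   type, position), `cornifications` (time, id), `removals` (time, id,
#'   t_birth, t_corn, born_div, lineage, abnormal), `delaminations`.
#' @export
event_log <- function(state) {
  bind <- function(l, cols) {
    if (!length(l)) {
      df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
      names(df) <- cols
      return(df)
    }
    df <- as.data.frame(do.call(rbind, l))
    names(df) <- cols
    df
  }
  list(
    divisions = bind(state$events$divisions,
                     c("time", "mother", "d1", "d2", "mother_type",
                       "x", "y", "z")),
    cornifications = bind(state$events$cornifications, c("time", "id")),
    removals = bind(state$events$removals,
                    c("time", "id", "t_birth", "t_corn", "born_div",
                      "lineage", "abnormal")),
    delaminations = bind(state$events$delaminations, c("time", "id"))
  )
}
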