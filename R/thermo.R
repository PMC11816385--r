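# Closed-form liquidus branches and eutectic location.
#
# Branch equations (per-branch compound with fraction x, Tm in K, dHm in
# J/mol, R = 8.31446):
#   ideal:          1/T = 1/Tm - R log(x) / dHm
#   Bragg-Williams: T   = [1 + (zw/dHm) (1-x)^2] / [1/Tm - (R/dHm) log(x)]
# The BW numerator can turn non-positive for strongly negative zw; such
# points are nonphysical and are reported as NA, never as a negative
# temperature.

.check_x <- function(x, allow_one = TRUE, what = "x") {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop(sprintf("'%s' must be numeric without NA", what), call. = FALSE)
  }
  hi_bad <- if (allow_one) x > 1 else x >= 1
  bad <- x <= 0 | hi_bad
  if (any(bad)) {
    stop(sprintf("molar fraction '%s' out of %s: %s", what,
                 if (allow_one) "(0, 1]" else "(0, 1)",
                 paste(format(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# vectorized BW branch temperature in plain arguments; NA where the
# numerator of the closed form is <= 0 (nonphysical); the x = 1 limit is
# the pure melting temperature analytically (avoids 1/(1/Tm) rounding)
.bw_t <- function(tm, dhm, zw, x) {
  num <- 1 + (zw / dhm) * (1 - x)^2
  den <- 1 / tm - (.R_GAS / dhm) * log(x)
  tt <- num / den
  tt[num <= 0] <- NA_real_
  tt[x == 1] <- tm
  tt
}

#' Ideal (Schroeder-van Laar) liquidus branch temperature
#'
#' Temperature at which a liquid mixture containing molar fraction `x` of
#' `compound` is in equilibrium with the pure solid, for an ideal solution
#' (zero mixing enthalpy): `1/T = 1/Tm - R log(x) / dHm`. The depression of
#' the melting point is purely entropic; `T <= Tm` with equality iff
#' `x = 1`. Assumes the enthalpy of melting is temperature-independent
#' (zero heat-capacity change on melting).
#'
#' @param compound A [pure_compound()].
#' @param x Molar fraction of `compound` in the liquid, in (0, 1].
#'   Vectorized.
#'
#' @return Equilibrium temperature(s), K.
#' @examples
#' reg <- bw_compounds()
#' ideal_branch_temperature(compound(reg, "Menthol"), x = c(1, 0.5))
#' @export
ideal_branch_temperature <- function(compound, x) {
  stopifnot(inherits(compound, "pure_compound"))
  .check_x(x, allow_one = TRUE)
  tt <- 1 / (1 / compound$tm - .R_GAS * log(x) / compound$dhm)
  tt[x == 1] <- compound$tm   # analytic limit, exact
  tt
}

#' Bragg-Williams liquidus branch temperature
#'
#' Temperature of the solid-liquid equilibrium branch of one compound of a
#' Bragg-Williams mixture, in closed form:
#' `T = [1 + (zw/dHm) (1-x)^2] / [1/Tm - (R/dHm) log(x)]`,
#' where `x` is the molar fraction of the *branch* compound (for the
#' B branch pass `x = 1 - x_a`), and `Tm`, `dHm` are that compound's
#' melting data. With `zw = 0` this reduces exactly to
#' [ideal_branch_temperature()].
#'
#' For strongly negative `zw` the numerator can reach zero or below; such
#' compositions have no physical equilibrium temperature on that branch and
#' `NA` is returned there.
#'
#' @param model A [bw_model()].
#' @param x Molar fraction of the branch compound, in (0, 1]. Vectorized.
#' @param branch `"a"` or `"b"`: which compound's branch.
#'
#' @return Equilibrium temperature(s), K; `NA` where the branch is
#'   nonphysical.
#' @examples
#' reg <- bw_compounds()
#' m <- bw_model(binary_pair(compound(reg, "Menthol"),
#'                           compound(reg, "Lauric acid")), zw = -5000)
#' bw_branch_temperature(m, x = 0.5, branch = "a")
#' @export
bw_branch_temperature <- function(model, x, branch = c("a", "b")) {
  stopifnot(inherits(model, "bw_model"))
  branch <- match.arg(branch)
  .check_x(x, allow_one = TRUE)
  cmp <- model$pair[[branch]]
  .bw_t(cmp$tm, cmp$dhm, model$zw, x)
}

#' Partial molar mixing enthalpy of compound A
#'
#' The Bragg-Williams excess (partial molar) enthalpy of mixing for
#' compound A at molar fraction `x`: `(1 - x)^2 * zw`. It vanishes in pure
#' A (`x = 1`) and equals `zw` at infinite dilution (`x = 0`).
#'
#' @param model A [bw_model()].
#' @param x Molar fraction of A, in \[0, 1\]. Vectorized.
#'
#' @return Partial molar mixing enthalpy, J/mol.
#' @export
excess_mixing_enthalpy <- function(model, x) {
  stopifnot(inherits(model, "bw_model"))
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop("'x' must lie in [0, 1]", call. = FALSE)
  }
  (1 - x)^2 * model$zw
}

#' Construct the liquidus curve of a Bragg-Williams mixture
#'
#' Evaluates both solid-liquid equilibrium branches on a grid of interior
#' molar fractions `x_i = i/(n_grid + 1)`, i = 1..n_grid (the endpoints are
#' excluded: the entropic log term is singular at x = 0, and the branch
#' limits at the endpoints are the pure-compound melting temperatures,
#' known analytically). At each composition the liquidus is the higher of
#' the two branch temperatures — the mixture is fully liquid only above
#' both equilibrium conditions; a branch that is nonphysical at a point
#' simply cannot be the liquidus there.
#'
#' @param model A [bw_model()].
#' @param n_grid Number of interior grid points (>= 2); default 1000.
#'
#' @return An object of class `liquidus_curve`: a data frame with columns
#'   `x_a`, `t_branch_a`, `t_branch_b`, `t_liquidus` (K) and
#'   `limiting_branch` (`"a"` or `"b"`), with the generating model attached
#'   as attribute `model`.
#' @examples
#' reg <- bw_compounds()
#' m <- bw_model(binary_pair(compound(reg, "Menthol"),
#'                           compound(reg, "Lauric acid")), zw = -8000)
#' head(liquidus_curve(m, n_grid = 9))
#' @export
liquidus_curve <- function(model, n_grid = 1000) {
  stopifnot(inherits(model, "bw_model"))
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 2) {
    stop("'n_grid' must be >= 2", call. = FALSE)
  }
  n_grid <- as.integer(n_grid)
  x <- seq_len(n_grid) / (n_grid + 1)
  ta <- bw_branch_temperature(model, x, "a")
  tb <- bw_branch_temperature(model, 1 - x, "b")
  both_na <- is.na(ta) & is.na(tb)
  if (any(both_na)) {
    stop(sprintf("both branches nonphysical at x_a = %s for zw = %g J/mol",
                 format(x[which(both_na)[1]]), model$zw), call. = FALSE)
  }
  tl <- pmax(ta, tb, na.rm = TRUE)
  limiting <- ifelse(is.na(tb) | (!is.na(ta) & ta >= tb), "a", "b")
  out <- data.frame(x_a = x, t_branch_a = ta, t_branch_b = tb,
                    t_liquidus = tl, limiting_branch = limiting,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  class(out) <- c("liquidus_curve", "data.frame")
  out
}

#' @export
print.liquidus_curve <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("<liquidus_curve> %s / %s, zw = %g kJ/mol, %d grid points\n",
              m$pair$a$name, m$pair$b$name, m$zw / 1000, nrow(x)))
  i <- which.min(x$t_liquidus)
  cat(sprintf("  liquidus minimum: %.2f K at x_a = %.4f\n",
              x$t_liquidus[i], x$x_a[i]))
  invisible(x)
}

#' Plot a liquidus curve
#'
#' Base-graphics phase-diagram plot: both branches, the liquidus, and
#' optionally experimental points.
#'
#' @param x A `liquidus_curve`.
#' @param data Optional [sle_dataset()] to overlay.
#' @param ... Passed to [plot()].
#' @importFrom graphics lines points
#' @export
plot.liquidus_curve <- function(x, data = NULL, ...) {
  m <- attr(x, "model")
  ylim <- range(x$t_liquidus, x$t_branch_a, x$t_branch_b,
                if (!is.null(data)) data$points$t, na.rm = TRUE)
  plot(x$x_a, x$t_liquidus, type = "l", lwd = 2, ylim = ylim,
       xlab = sprintf("molar fraction of %s", m$pair$a$name),
       ylab = "T (K)", ...)
  lines(x$x_a, x$t_branch_a, lty = 2, col = "grey40")
  lines(x$x_a, x$t_branch_b, lty = 3, col = "grey40")
  if (!is.null(data)) points(data$points$x_a, data$points$t, pch = 19,
                             col = "darkgreen")
  invisible(x)
}

#' Locate the eutectic point
#'
#' Finds the minimum of the liquidus: first on the interior grid, then —
#' when the two branches cross inside (0, 1) — refines the crossing
#' `T_A(x) = T_B(x)` by bisection on the (continuous, locally monotone)
#' branch difference until the temperature gap is below `tol`. If one
#' branch dominates everywhere on the grid (no crossing), the
#' boundary-adjacent grid minimum is returned with
#' `branch_crossing = FALSE`.
#'
#' @param model A [bw_model()].
#' @param n_grid Interior grid size for the initial scan; default 1000.
#' @param tol Temperature tolerance of the bisection refinement, K.
#'
#' @return An object of class `eutectic_point`: list with `x` (molar
#'   fraction of A), `t` (K) and `branch_crossing` (logical).
#' @examples
#' reg <- bw_compounds()
#' m <- bw_model(binary_pair(compound(reg, "Menthol"),
#'                           compound(reg, "Thymol")), zw = 0)
#' eutectic_point(m)
#' @export
eutectic_point <- function(model, n_grid = 1000, tol = 1e-6) {
  curve <- liquidus_curve(model, n_grid)
  i <- which.min(curve$t_liquidus)
  x0 <- curve$x_a[i]
  t0 <- curve$t_liquidus[i]
  diff_fun <- function(x) {
    bw_branch_temperature(model, x, "a") -
      bw_branch_temperature(model, 1 - x, "b")
  }
  # bracket a sign change of T_A - T_B around the grid minimum
  d <- curve$t_branch_a - curve$t_branch_b
  sgn <- sign(d)
  cross <- which(!is.na(sgn[-1]) & !is.na(sgn[-length(sgn)]) &
                   sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) == 0L) {
    return(structure(list(x = x0, t = t0, branch_crossing = FALSE),
                     class = "eutectic_point"))
  }
  # the crossing nearest the grid minimum is the eutectic
  j <- cross[which.min(abs(curve$x_a[cross] - x0))]
  lo <- curve$x_a[j]; hi <- curve$x_a[j + 1]
  flo <- d[j]
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- diff_fun(mid)
    if (is.na(fm) || abs(fm) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  structure(list(x = mid, t = bw_branch_temperature(model, mid, "a"),
                 branch_crossing = TRUE),
            class = "eutectic_point")
}

#' @export
print.eutectic_point <- function(x, ...) {
  cat(sprintf("<eutectic_point> x_a = %.5f, T = %.3f K%s\n", x$x, x$t,
              if (!x$branch_crossing) " (no branch crossing; grid minimum)"
              else ""))
  invisible(x)
}
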