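# Estimation of zw from melting-point data and propagation of
# uncertainties. The per-point estimator inverts the closed-form branch
# equation algebraically:
#   zw = [dHm (T/Tm - 1) - R T log(x)] / (1 - x)^2        (branch compound)
# computed for both branches; the numerically smaller of the two is chosen
# (the larger one would imply, for the other compound, an equilibrium
# temperature above the measured one). The grid fit scans candidate zw
# values and minimizes the average absolute deviation (AAD) between the
# model liquidus (branch maximum at each measured composition) and the
# measured temperatures.

# points usable for estimation: strictly interior, away from the
# (1-x)^-2 singularities
.interior_idx <- function(x, eps = 1e-6) {
  which(x > eps & x < 1 - eps)
}

# branch-equation inversion in plain arguments; vectorized
.zw_from_point <- function(tm, dhm, x, t) {
  (dhm * (t / tm - 1) - .R_GAS * t * log(x)) / (1 - x)^2
}

#' Estimate zw from a single melting point
#'
#' Inverts the Bragg-Williams branch equation at one measured point
#' `(x_a, t)`: `zw = [dHm (T/Tm - 1) - R T log(x)] / (1 - x)^2`, evaluated
#' once with compound A's data at `x_a` and once with compound B's data at
#' `1 - x_a`. The numerically smaller (more negative) of the two is the
#' chosen estimate: the larger one would place the other compound's branch
#' above the measured melting temperature, contradicting the measurement
#' being on the liquidus.
#'
#' @param pair A [binary_pair()].
#' @param x_a Molar fraction of compound A, strictly inside (0, 1).
#' @param t Measured melting (liquidus) temperature, K.
#'
#' @return A list with `zw_a`, `zw_b` and `zw_chosen`, all J/mol.
#' @examples
#' reg <- bw_compounds()
#' pair <- binary_pair(compound(reg, "Menthol"), compound(reg, "Lauric acid"))
#' t <- bw_branch_temperature(bw_model(pair, -10000), x = 0.3, branch = "a")
#' estimate_zw_from_point(pair, x_a = 0.3, t = t)
#' @export
estimate_zw_from_point <- function(pair, x_a, t) {
  stopifnot(inherits(pair, "binary_pair"))
  .check_x(x_a, allow_one = FALSE, what = "x_a")
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    stop("'t' must be a positive temperature in K", call. = FALSE)
  }
  zw_a <- .zw_from_point(pair$a$tm, pair$a$dhm, x_a, t)
  zw_b <- .zw_from_point(pair$b$tm, pair$b$dhm, 1 - x_a, t)
  list(zw_a = zw_a, zw_b = zw_b, zw_chosen = pmin(zw_a, zw_b))
}

#' Average absolute deviation of a model from a dataset
#'
#' Mean over the dataset's interior points of the absolute difference
#' between the model liquidus temperature (branch maximum, evaluated
#' directly at each measured composition) and the measured temperature.
#' Boundary points (within 1e-6 of x = 0 or 1) are excluded with a
#' warning.
#'
#' @param dataset An [sle_dataset()].
#' @param model A [bw_model()] for the same pair.
#'
#' @return AAD in K.
#' @export
aad <- function(dataset, model) {
  stopifnot(inherits(dataset, "sle_dataset"), inherits(model, "bw_model"))
  pts <- dataset$points
  idx <- .interior_idx(pts$x_a)
  if (length(idx) < nrow(pts)) {
    warning(sprintf("%d boundary point(s) excluded from AAD",
                    nrow(pts) - length(idx)), call. = FALSE)
  }
  if (length(idx) == 0L) stop("no interior points in dataset", call. = FALSE)
  tmod <- .liquidus_at(model, pts$x_a[idx])
  if (anyNA(tmod)) {
    stop(sprintf("model nonphysical (both branches) at some data compositions for zw = %g J/mol",
                 model$zw), call. = FALSE)
  }
  mean(abs(tmod - pts$t[idx]))
}

# liquidus (branch maximum) at arbitrary compositions; NA only where both
# branches are nonphysical
.liquidus_at <- function(model, x_a) {
  ta <- bw_branch_temperature(model, x_a, "a")
  tb <- bw_branch_temperature(model, 1 - x_a, "b")
  ifelse(is.na(ta) & is.na(tb), NA_real_, pmax(ta, tb, na.rm = TRUE))
}

#' Fit zw by grid search over candidate values
#'
#' Scans candidate `zw` values on a regular grid and minimizes the average
#' absolute deviation (AAD) between the model liquidus and the measured
#' temperatures; the default grid spans -100 to 100 kJ/mol in steps of
#' 0.1 kJ/mol. The model temperature at each measured composition is the
#' higher of the two branch temperatures, evaluated directly at that
#' composition (no interpolation from a display grid). Ties are broken
#' toward the smallest `|zw|` (parsimony toward the ideal model). Because
#' the default grid contains `zw = 0`, the fitted AAD can never exceed the
#' ideal-solution AAD.
#'
#' An optional golden-section refinement of the continuous objective
#' around the grid optimum is available but off by default, so the
#' default protocol is exactly the grid scan.
#'
#' @param dataset An [sle_dataset()] with at least one interior point.
#' @param grid_min,grid_max,step Grid specification, J/mol. Defaults
#'   -1e5, 1e5, 100 (i.e. -100..100 kJ/mol by 0.1).
#' @param refine If `TRUE`, polish the optimum by golden-section search
#'   within one grid step of the best candidate.
#'
#' @return An object of class `zw_fit`: list with `zw` (J/mol), `aad_bw`,
#'   `aad_ideal` (K), `grid` (min, max, step; J/mol), `n_points_used`,
#'   `refined`, and the input `pair`.
#' @examples
#' reg <- bw_compounds()
#' pair <- binary_pair(compound(reg, "Menthol"), compound(reg, "Lauric acid"))
#' spec <- synthetic_spec(pair, zw_true = -8000, n_points = 11,
#'                        noise_sd = 0, seed = 1)
#' fit_zw_grid(generate_dataset(spec))
#' @export
fit_zw_grid <- function(dataset, grid_min = -1e5, grid_max = 1e5,
                        step = 100, refine = FALSE) {
  stopifnot(inherits(dataset, "sle_dataset"))
  if (!(grid_min < grid_max) || step <= 0) {
    stop("need grid_min < grid_max and step > 0", call. = FALSE)
  }
  pts <- dataset$points
  idx <- .interior_idx(pts$x_a)
  if (length(idx) < nrow(pts)) {
    warning(sprintf("%d boundary point(s) excluded from the fit",
                    nrow(pts) - length(idx)), call. = FALSE)
  }
  if (length(idx) == 0L) {
    stop("dataset has no interior points usable for fitting", call. = FALSE)
  }
  x <- pts$x_a[idx]
  tobs <- pts$t[idx]
  zw_grid <- seq(grid_min, grid_max, by = step)
  pair <- dataset$pair
  obj <- .aad_over_grid(pair, zw_grid, x, tobs)
  if (all(!is.finite(obj))) {
    stop(sprintf("all candidate zw in [%g, %g] J/mol are nonphysical at some data composition",
                 grid_min, grid_max), call. = FALSE)
  }
  best <- min(obj, na.rm = TRUE)
  cand <- which(obj <= best)        # ties broken toward smallest |zw|
  zbest <- zw_grid[cand[which.min(abs(zw_grid[cand]))]]
  refined <- FALSE
  if (refine) {
    o <- stats::optimize(function(z) .aad_over_grid(pair, z, x, tobs),
                         interval = c(zbest - step, zbest + step))
    if (is.finite(o$objective) && o$objective <= best) {
      zbest <- o$minimum
      best <- o$objective
      refined <- TRUE
    }
  }
  aad_ideal <- mean(abs(.liquidus_at(bw_model(pair, 0), x) - tobs))
  structure(list(zw = zbest, aad_bw = best, aad_ideal = aad_ideal,
                 grid = c(min = grid_min, max = grid_max, step = step),
                 n_points_used = length(idx), refined = refined,
                 pair = pair),
            class = "zw_fit")
}

# AAD objective for a vector of candidate zw values (vectorized over both
# candidates and data points); Inf where a candidate is nonphysical on
# both branches at any data composition
.aad_over_grid <- function(pair, zw_grid, x, tobs) {
  ca <- pair$a; cb <- pair$b
  # branch temperatures as (n_candidates x n_points) matrices
  na_ <- 1 + outer(zw_grid / ca$dhm, (1 - x)^2)
  da <- 1 / ca$tm - (.R_GAS / ca$dhm) * log(x)
  ta <- sweep(na_, 2, da, "/")
  ta[na_ <= 0] <- NA_real_
  nb_ <- 1 + outer(zw_grid / cb$dhm, x^2)
  db <- 1 / cb$tm - (.R_GAS / cb$dhm) * log(1 - x)
  tb <- sweep(nb_, 2, db, "/")
  tb[nb_ <= 0] <- NA_real_
  tl <- pmax(ta, tb, na.rm = TRUE)
  tl[is.na(ta) & is.na(tb)] <- NA_real_
  res <- abs(sweep(tl, 2, tobs, "-"))
  out <- rowMeans(res)
  out[apply(is.na(res), 1L, any)] <- Inf
  out
}

#' @export
print.zw_fit <- function(x, ...) {
  cat(sprintf("<zw_fit> %s / %s\n", x$pair$a$name, x$pair$b$name))
  cat(sprintf("  zw        = %.4g kJ/mol%s\n", x$zw / 1000,
              if (x$refined) " (refined)" else ""))
  cat(sprintf("  AAD (BW)  = %.3f K\n  AAD (id)  = %.3f K\n",
              x$aad_bw, x$aad_ideal))
  cat(sprintf("  grid      = [%g, %g] kJ/mol, step %g; %d point(s) used\n",
              x$grid[["min"]] / 1000, x$grid[["max"]] / 1000,
              x$grid[["step"]] / 1000, x$n_points_used))
  invisible(x)
}

# resolve the branch an error formula should use: the branch whose
# inversion is chosen at this point by the smaller-zw rule
.resolve_branch <- function(pair, x_a, t, branch) {
  if (branch != "auto") return(branch)
  est <- estimate_zw_from_point(pair, x_a, t)
  if (est$zw_a <= est$zw_b) "a" else "b"
}

.branch_args <- function(pair, x_a, branch) {
  if (branch == "a") list(cmp = pair$a, x = x_a)
  else list(cmp = pair$b, x = 1 - x_a)
}

#' Propagated uncertainty of a per-point zw estimate
#'
#' Analytic propagation of a single error source through the per-point
#' inversion ([estimate_zw_from_point()]); each formula is the exact
#' partial derivative of the inversion with respect to the perturbed
#' quantity, evaluated at the measured temperature:
#'
#' * `zw_error_from_temperature`: error `dT` in the measured melting
#'   temperature — `[dHm/Tm - R log(x)] / (1-x)^2 * dT`;
#' * `zw_error_from_enthalpy`: error `dH` in the pure compound's enthalpy
#'   of melting — `|T/Tm - 1| / (1-x)^2 * dH`;
#' * `zw_error_from_tm`: error `dTm` in the pure compound's melting
#'   temperature — `dHm T / Tm^2 / (1-x)^2 * dTm`.
#'
#' Here `x`, `Tm`, `dHm` belong to the branch compound (`x = 1 - x_a` on
#' the B branch). All three diverge as `(1-x)^-2` near the pure ends of
#' the composition range: points close to `x_a` of 0 or 1 carry very
#' large parameter uncertainty. The value is returned as computed — large
#' near the boundary, never clipped.
#'
#' @param pair A [binary_pair()].
#' @param x_a Molar fraction of compound A at the measured point, (0, 1).
#' @param t Measured melting temperature, K.
#' @param dT,dH,dTm Perturbation magnitude: K for temperatures, J/mol for
#'   the enthalpy.
#' @param branch `"auto"` (default; the branch selected by the smaller-zw
#'   rule at this point), `"a"`, or `"b"`.
#'
#' @return Propagated uncertainty in `zw`, J/mol (non-negative).
#' @name zw_errors
#' @examples
#' reg <- bw_compounds()
#' pair <- binary_pair(compound(reg, "Thymol"), compound(reg, "Camphor"))
#' zw_error_from_temperature(pair, x_a = 0.5, t = 290, dT = 5)
NULL

#' @rdname zw_errors
#' @export
zw_error_from_temperature <- function(pair, x_a, t, dT, branch = "auto") {
  stopifnot(inherits(pair, "binary_pair"), dT > 0)
  .check_x(x_a, allow_one = FALSE, what = "x_a")
  branch <- .resolve_branch(pair, x_a, t, branch)
  ba <- .branch_args(pair, x_a, branch)
  abs((ba$cmp$dhm / ba$cmp$tm - .R_GAS * log(ba$x)) / (1 - ba$x)^2) * dT
}

#' @rdname zw_errors
#' @export
zw_error_from_enthalpy <- function(pair, x_a, t, dH, branch = "auto") {
  stopifnot(inherits(pair, "binary_pair"), dH > 0)
  .check_x(x_a, allow_one = FALSE, what = "x_a")
  branch <- .resolve_branch(pair, x_a, t, branch)
  ba <- .branch_args(pair, x_a, branch)
  abs(t / ba$cmp$tm - 1) / (1 - ba$x)^2 * dH
}

#' @rdname zw_errors
#' @export
zw_error_from_tm <- function(pair, x_a, t, dTm, branch = "auto") {
  stopifnot(inherits(pair, "binary_pair"), dTm > 0)
  .check_x(x_a, allow_one = FALSE, what = "x_a")
  branch <- .resolve_branch(pair, x_a, t, branch)
  ba <- .branch_args(pair, x_a, branch)
  ba$cmp$dhm * t / ba$cmp$tm^2 / (1 - ba$x)^2 * dTm
}

#' Sensitivity of the liquidus temperature to zw
#'
#' First-order change of a branch temperature under a perturbation `dzw`
#' of the interaction parameter: `(1-x)^2 / dHm * T_id(x) * dzw`, where
#' `T_id` is the ideal branch temperature of the branch compound. Unlike
#' the parameter-error formulas this is bounded for every interior
#' composition — the liquidus itself has no singular sensitivity — which
#' is why fitting all available points reduces the temperature error even
#' when individual per-point `zw` estimates are poor.
#'
#' @param model A [bw_model()].
#' @param x Molar fraction of the branch compound, (0, 1).
#' @param dzw Perturbation of `zw`, J/mol.
#' @param branch `"a"` (default) or `"b"`.
#'
#' @return First-order temperature change, K.
#' @export
curve_sensitivity <- function(model, x, dzw, branch = c("a", "b")) {
  stopifnot(inherits(model, "bw_model"))
  branch <- match.arg(branch)
  .check_x(x, allow_one = FALSE)
  cmp <- model$pair[[branch]]
  tid <- ideal_branch_temperature(cmp, x)
  (1 - x)^2 / cmp$dhm * tid * dzw
}

#' Inverse-variance weighted mean of zw estimates
#'
#' Combines per-point estimates with weights `1/err^2`:
#' `mean = sum(zw/err^2) / sum(1/err^2)`, with uncertainty
#' `1/sqrt(sum(1/err^2))` (the standard error of the inverse-variance
#' weighted mean). Estimates with infinite error get zero weight and drop
#' out.
#'
#' @param zw Per-point estimates, J/mol.
#' @param err Their positive uncertainties, J/mol (`Inf` allowed).
#'
#' @return List with `mean` and `err`, J/mol.
#' @examples
#' weighted_mean_zw(c(-10000, -20000), c(1000, 2000))
#' @export
weighted_mean_zw <- function(zw, err) {
  if (length(zw) != length(err) || length(zw) == 0L) {
    stop("'zw' and 'err' must be non-empty and of equal length", call. = FALSE)
  }
  if (any(is.na(zw)) || any(is.na(err)) || any(err <= 0)) {
    stop("uncertainties must be positive (Inf allowed); no NAs", call. = FALSE)
  }
  w <- 1 / err^2
  if (sum(w) == 0) {
    stop("all estimates have infinite uncertainty; weighted mean undefined",
         call. = FALSE)
  }
  list(mean = sum(zw * w) / sum(w), err = 1 / sqrt(sum(w)))
}

#' Per-point zw estimates with propagated error bars
#'
#' Applies [estimate_zw_from_point()] to every interior point of a
#' dataset, attaches a propagated uncertainty from one stated error
#' source, and forms the inverse-variance weighted mean. Defaults follow
#' common analysis assumptions for melting data: 5 K on the measured
#' temperature, 5 kJ/mol on the enthalpy of melting, 5 K on the
#' pure-compound melting temperature. Boundary points (within 1e-6 of
#' x = 0 or 1) are excluded with a warning.
#'
#' @param dataset An [sle_dataset()].
#' @param error_source One of `"temperature"`, `"enthalpy"`, `"tm"`: which
#'   uncertainty is propagated into the per-point error bars.
#' @param dT,dH,dTm Perturbation magnitudes (K, J/mol, K).
#'
#' @return An object of class `zw_point_estimates`: a data frame with
#'   columns `x_a`, `t`, `zw_a`, `zw_b`, `zw_chosen`, `branch`, `err`
#'   (J/mol), plus attributes `weighted_mean`, `weighted_mean_err`,
#'   `error_source` and `pair`.
#' @examples
#' reg <- bw_compounds()
#' pair <- binary_pair(compound(reg, "Thymol"), compound(reg, "Camphor"))
#' ds <- generate_dataset(synthetic_spec(pair, zw_true = -25000,
#'                                       n_points = 9, noise_sd = 0, seed = 3))
#' zw_point_estimates(ds)
#' @export
zw_point_estimates <- function(dataset,
                               error_source = c("temperature", "enthalpy", "tm"),
                               dT = 5, dH = 5000, dTm = 5) {
  stopifnot(inherits(dataset, "sle_dataset"))
  error_source <- match.arg(error_source)
  pts <- dataset$points
  idx <- .interior_idx(pts$x_a)
  if (length(idx) < nrow(pts)) {
    warning(sprintf("%d boundary point(s) excluded from per-point estimation",
                    nrow(pts) - length(idx)), call. = FALSE)
  }
  if (length(idx) == 0L) {
    stop("dataset has no interior points usable for estimation",
         call. = FALSE)
  }
  pair <- dataset$pair
  x <- pts$x_a[idx]; t <- pts$t[idx]
  est <- estimate_zw_from_point(pair, x, t)
  branch <- ifelse(est$zw_a <= est$zw_b, "a", "b")
  err_fun <- switch(error_source,
    temperature = function(i) zw_error_from_temperature(pair, x[i], t[i],
                                                        dT, branch[i]),
    enthalpy    = function(i) zw_error_from_enthalpy(pair, x[i], t[i],
                                                     dH, branch[i]),
    tm          = function(i) zw_error_from_tm(pair, x[i], t[i],
                                               dTm, branch[i]))
  err <- vapply(seq_along(x), err_fun, numeric(1))
  wm <- weighted_mean_zw(est$zw_chosen, err)
  out <- data.frame(x_a = x, t = t, zw_a = est$zw_a, zw_b = est$zw_b,
                    zw_chosen = est$zw_chosen, branch = branch, err = err,
                    stringsAsFactors = FALSE)
  attr(out, "weighted_mean") <- wm$mean
  attr(out, "weighted_mean_err") <- wm$err
  attr(out, "error_source") <- error_source
  attr(out, "pair") <- pair
  class(out) <- c("zw_point_estimates", "data.frame")
  out
}

#' @export
print.zw_point_estimates <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("<zw_point_estimates> %s / %s, %d point(s), error source: %s\n",
              pair$a$name, pair$b$name, nrow(x), attr(x, "error_source")))
  df <- data.frame(x_a = round(x$x_a, 4),
                   t_K = round(x$t, 2),
                   zw_kJ = round(x$zw_chosen / 1000, 3),
                   branch = x$branch,
                   err_kJ = round(x$err / 1000, 3))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  weighted mean zw = %.3f +/- %.3f kJ/mol\n",
              attr(x, "weighted_mean") / 1000,
              attr(x, "weighted_mean_err") / 1000))
  invisible(x)
}
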