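# CSV readers/writers and the structured fit report.
#
# File conventions: comma-separated, '.' decimal, UTF-8, '#' comment lines
# allowed; temperatures in K and enthalpies/zw in kJ/mol (converted to
# J/mol on read). Readers validate loudly with the offending line number;
# nothing is silently coerced.

# read a CSV keeping track of the original line number of every data row
.read_csv_lines <- function(source, required, optional = character(0)) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("empty file: ", source, call. = FALSE)
  line_no <- which(keep)
  df <- utils::read.csv(text = paste(lines[keep], collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) %s in %s (found: %s)",
                 paste(missing_cols, collapse = ", "), source,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    stop(sprintf("unexpected column(s) %s in %s",
                 paste(extra, collapse = ", "), source), call. = FALSE)
  }
  attr(df, "line_no") <- line_no[-1]   # data rows (header is row 1)
  df
}

.as_num_col <- function(df, col, source) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !(is.na(raw) | raw == ""))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                 raw[bad[1]], col, attr(df, "line_no")[bad[1]], source),
         call. = FALSE)
  }
  val
}

#' Read a pure-compound table
#'
#' Reads a CSV with header `name,tm_K,dhm_kJ_per_mol` into a
#' [compound_registry()]. Enthalpies are converted from kJ/mol to J/mol.
#' Comment lines starting with `#` are ignored. Malformed rows (missing
#' columns, non-numeric or non-positive values, duplicate names) raise an
#' error naming the offending line.
#'
#' @param source Path to the CSV file (or a connection).
#'
#' @return A [compound_registry()].
#' @examples
#' reg <- read_compounds(system.file("extdata", "pure_compounds.csv",
#'                                   package = "bwsle"))
#' compound(reg, "menthol")
#' @export
read_compounds <- function(source) {
  df <- .read_csv_lines(source, required = c("name", "tm_K", "dhm_kJ_per_mol"))
  if (nrow(df) == 0L) return(compound_registry(list()))
  tm <- .as_num_col(df, "tm_K", source)
  dhm <- .as_num_col(df, "dhm_kJ_per_mol", source)
  ln <- attr(df, "line_no")
  compounds <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    compounds[[i]] <- tryCatch(
      pure_compound(df$name[i], tm[i], dhm[i] * 1000),
      error = function(e) {
        stop(sprintf("line %d of %s: %s", ln[i], source, conditionMessage(e)),
             call. = FALSE)
      })
  }
  tryCatch(compound_registry(compounds), error = function(e) {
    stop(sprintf("%s: %s", source, conditionMessage(e)), call. = FALSE)
  })
}

#' Solid-liquid equilibrium dataset
#'
#' Melting points `(x_a, T)` of a binary mixture, with an optional
#' temperature uncertainty per point. Points at or within 1e-6 of the
#' composition boundaries are stored but excluded (with a warning) from
#' estimation, where the `(1-x)^-2` factors diverge.
#'
#' @param pair A [binary_pair()].
#' @param x_a Molar fractions of compound A, in \[0, 1\].
#' @param t Measured melting temperatures, K (> 0).
#' @param t_err Optional temperature uncertainties, K (`NA` allowed).
#'
#' @return An object of class `sle_dataset`: list with `pair` and a data
#'   frame `points` (`x_a`, `t`, `t_err`) in input order.
#' @export
sle_dataset <- function(pair, x_a, t, t_err = NULL) {
  stopifnot(inherits(pair, "binary_pair"))
  if (length(x_a) != length(t)) {
    stop("'x_a' and 't' must have equal length", call. = FALSE)
  }
  if (!is.numeric(x_a) || anyNA(x_a) || any(x_a < 0 | x_a > 1)) {
    stop("'x_a' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    stop("'t' must be positive (K)", call. = FALSE)
  }
  if (is.null(t_err)) t_err <- rep(NA_real_, length(x_a))
  if (length(t_err) != length(x_a)) {
    stop("'t_err' must match 'x_a' in length", call. = FALSE)
  }
  structure(list(pair = pair,
                 points = data.frame(x_a = as.numeric(x_a),
                                     t = as.numeric(t),
                                     t_err = as.numeric(t_err))),
            class = "sle_dataset")
}

#' @export
print.sle_dataset <- function(x, ...) {
  cat(sprintf("<sle_dataset> %s / %s, %d point(s)\n",
              x$pair$a$name, x$pair$b$name, nrow(x$points)))
  print.data.frame(utils::head(x$points, 10), row.names = FALSE)
  if (nrow(x$points) > 10) cat(sprintf("  ... %d more\n", nrow(x$points) - 10))
  invisible(x)
}

#' Read a solid-liquid equilibrium dataset
#'
#' Reads a CSV with header `x_a,T_K` and optional `T_err_K` into an
#' [sle_dataset()] for the given pair, preserving file order. Compositions
#' outside \[0, 1\] or non-positive temperatures raise an error naming the
#' line; boundary points load but are excluded from estimation later.
#'
#' @param source Path to the CSV file.
#' @param pair A [binary_pair()] the points refer to (`x_a` is the molar
#'   fraction of `pair$a`).
#'
#' @return An [sle_dataset()].
#' @export
read_sle_dataset <- function(source, pair) {
  df <- .read_csv_lines(source, required = c("x_a", "T_K"),
                        optional = "T_err_K")
  x <- .as_num_col(df, "x_a", source)
  t <- .as_num_col(df, "T_K", source)
  terr <- if ("T_err_K" %in% names(df)) .as_num_col(df, "T_err_K", source)
          else NULL
  ln <- attr(df, "line_no")
  bad <- which(x < 0 | x > 1)
  if (length(bad)) {
    stop(sprintf("x_a = %s out of [0, 1] at line %d of %s",
                 format(x[bad[1]]), ln[bad[1]], source), call. = FALSE)
  }
  bad <- which(t <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive temperature %s K at line %d of %s",
                 format(t[bad[1]]), ln[bad[1]], source), call. = FALSE)
  }
  sle_dataset(pair, x, t, terr)
}

#' Write a solid-liquid equilibrium dataset
#'
#' Writes the dataset's points as CSV (`x_a,T_K` plus `T_err_K` when any
#' uncertainty is present), round-trippable through [read_sle_dataset()]
#' at full precision.
#'
#' @param dataset An [sle_dataset()].
#' @param path Destination path.
#'
#' @return `path`, invisibly.
#' @export
write_sle_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sle_dataset"))
  pts <- dataset$points
  df <- data.frame(x_a = format(pts$x_a, digits = 17, trim = TRUE),
                   T_K = format(pts$t, digits = 17, trim = TRUE))
  if (any(!is.na(pts$t_err))) {
    df$T_err_K <- ifelse(is.na(pts$t_err), "",
                         format(pts$t_err, digits = 17, trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report and liquidus curve export
#'
#' Writes two files under `dir`:
#'
#' * `fit_report.json` — machine-readable report: the pair, `zw` in
#'   kJ/mol, `aad_bw_K`, `aad_ideal_K`, the search grid (kJ/mol), the
#'   number of points used, and (when `estimates` is supplied) the
#'   per-point table with propagated errors and the weighted mean;
#' * `liquidus_curve.csv` — columns
#'   `x_a,T_branch_a_K,T_branch_b_K,T_liquidus_K,limiting_branch`.
#'
#' @param result A [fit_zw_grid()] result.
#' @param curve A [liquidus_curve()].
#' @param estimates Optional [zw_point_estimates()].
#' @param dir Destination directory (created if missing).
#'
#' @return Named character vector of the files written, invisibly.
#' @export
write_fit_report <- function(result, curve, estimates = NULL, dir = ".") {
  stopifnot(inherits(result, "zw_fit"), inherits(curve, "liquidus_curve"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- list(
    pair = list(a = result$pair$a$name, b = result$pair$b$name),
    zw_kJ_per_mol = result$zw / 1000,
    aad_bw_K = result$aad_bw,
    aad_ideal_K = result$aad_ideal,
    grid_kJ_per_mol = list(min = result$grid[["min"]] / 1000,
                           max = result$grid[["max"]] / 1000,
                           step = result$grid[["step"]] / 1000),
    n_points_used = result$n_points_used,
    refined = result$refined
  )
  if (!is.null(estimates)) {
    stopifnot(inherits(estimates, "zw_point_estimates"))
    report$per_point <- list(
      error_source = attr(estimates, "error_source"),
      points = data.frame(
        x_a = estimates$x_a, t_K = estimates$t,
        zw_a_kJ_per_mol = estimates$zw_a / 1000,
        zw_b_kJ_per_mol = estimates$zw_b / 1000,
        zw_chosen_kJ_per_mol = estimates$zw_chosen / 1000,
        branch = estimates$branch,
        err_kJ_per_mol = estimates$err / 1000),
      weighted_mean_kJ_per_mol = attr(estimates, "weighted_mean") / 1000,
      weighted_mean_err_kJ_per_mol = attr(estimates, "weighted_mean_err") / 1000
    )
  }
  report_path <- file.path(dir, "fit_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  curve_path <- file.path(dir, "liquidus_curve.csv")
  write_liquidus_csv(curve, curve_path)
  invisible(c(report = report_path, curve = curve_path))
}

#' Write a liquidus curve as CSV
#'
#' @param curve A [liquidus_curve()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_liquidus_csv <- function(curve, path) {
  stopifnot(inherits(curve, "liquidus_curve"))
  df <- data.frame(x_a = curve$x_a,
                   T_branch_a_K = curve$t_branch_a,
                   T_branch_b_K = curve$t_branch_b,
                   T_liquidus_K = curve$t_liquidus,
                   limiting_branch = curve$limiting_branch)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
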