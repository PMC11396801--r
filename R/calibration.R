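#' Fit standard curves from dilution series
#'
#' Estimates per-primer amplification efficiency from a serial-dilution
#' experiment. For a `base`-fold series, dilution level `i` (0 = undiluted)
#' corresponds to log10 relative concentration `-i * log10(base)`; ordinary
#' least squares of Ct on log10 concentration gives the slope `k`, and
#' efficiency is `E = 10^(-1/k) - 1` (so slope -3.3219 on a 5-fold series is
#' exactly 100%: perfect doubling chemistry). Replicate Ct values at a
#' dilution level enter the regression as individual points.
#'
#' @param dilution A data frame with columns `primer`, `level` (non-negative
#'   integer dilution step), `ct`. Additional replicate rows per level are
#'   allowed.
#' @param base Fold-change per dilution step (default 5, a 5-fold series).
#' @return A tibble of class `standard_curve` with one row per primer:
#'   `primer`, `slope` (cycles per log10 concentration), `intercept`,
#'   `r_squared` (squared Pearson correlation of the fit), `efficiency`
#'   (fraction; 1.0 = 100%), `efficiency_pct`, `n_points`, `n_levels`.
#'   A positive slope leaves `efficiency` as `NA` with a warning.
#' @examples
#' d <- tidyr::crossing(primer = "RPL13", level = 0:4) |>
#'   dplyr::mutate(ct = 18 + level * log2(5))   # perfect doubling
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(dilution, base = 5) {
  dilution <- tibble::as_tibble(dilution)
  need <- c("primer", "level", "ct")
  miss <- setdiff(need, names(dilution))
  if (length(miss) > 0) {
    stop("dilution table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(dilution$ct))) stop("all dilution-series Ct must be finite", call. = FALSE)
  stopifnot(base > 1)
  fit_one <- function(d) {
    lvls <- unique(d$level)
    if (length(lvls) < 3) {
      stop("primer '", d$primer[1], "': need >= 3 distinct dilution levels, got ",
           length(lvls), call. = FALSE)
    }
    log_conc <- -d$level * log10(base)
    if (stats::var(log_conc) == 0) stop("zero variance in concentration", call. = FALSE)
    fit <- stats::lm(d$ct ~ log_conc)
    k <- unname(stats::coef(fit)[2])
    r2 <- if (stats::var(d$ct) == 0) 1 else unname(stats::cor(log_conc, d$ct))^2
    eff <- if (is.na(k) || k >= 0) NA_real_ else 10^(-1 / k) - 1
    tibble::tibble(
      slope = k, intercept = unname(stats::coef(fit)[1]),
      r_squared = r2, efficiency = eff,
      n_points = nrow(d), n_levels = length(lvls)
    )
  }
  out <- dplyr::reframe(dplyr::group_by(dilution, .data$primer), fit_one(dplyr::pick(dplyr::everything())))
  out <- dplyr::mutate(dplyr::ungroup(out), efficiency_pct = 100 * .data$efficiency,
                       .after = "efficiency")
  if (any(is.na(out$efficiency))) {
    warning("positive or undefined slope for primer(s): ",
            paste(out$primer[is.na(out$efficiency)], collapse = ", "),
            "; efficiency undefined", call. = FALSE)
  }
  class(out) <- c("standard_curve", class(out))
  out
}

#' Primer quality control
#'
#' Applies the conventional acceptance rules for qPCR primers: amplification
#' efficiency within `[e_lo, e_hi]` (default 90--120%) and standard-curve
#' R-squared at least `r2_min` (default 0.99). Primers with undefined
#' efficiency fail automatically.
#'
#' @param curves A `standard_curve` tibble from [fit_standard_curve()], or any
#'   data frame with `primer`, `efficiency`, `r_squared` columns.
#' @param e_lo,e_hi Efficiency acceptance bounds as fractions.
#' @param r2_min Minimum R-squared.
#' @return The input with `qc_pass` (logical) and `qc_reasons` (character;
#'   `""` when passing, otherwise semicolon-separated rule violations).
#' @export
primer_qc <- function(curves, e_lo = 0.90, e_hi = 1.20, r2_min = 0.99) {
  curves <- tibble::as_tibble(curves)
  reasons <- purrr::map2_chr(curves$efficiency, curves$r_squared, function(e, r2) {
    out <- character()
    if (is.na(e)) {
      out <- c(out, "efficiency undefined (non-negative slope)")
    } else {
      if (e < e_lo) out <- c(out, sprintf("efficiency %.1f%% below %.0f%%", 100 * e, 100 * e_lo))
      if (e > e_hi) out <- c(out, sprintf("efficiency %.1f%% above %.0f%%", 100 * e, 100 * e_hi))
    }
    if (r2 < r2_min) out <- c(out, sprintf("R-squared %.4f below %.2f", r2, r2_min))
    paste(out, collapse = "; ")
  })
  dplyr::mutate(curves, qc_pass = reasons == "", qc_reasons = reasons)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    n_primers = nrow(x),
    min_efficiency = min(x$efficiency, na.rm = TRUE),
    max_efficiency = max(x$efficiency, na.rm = TRUE),
    min_r_squared = min(x$r_squared)
  )
}
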