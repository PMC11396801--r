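#' BestKeeper descriptive stability screening
#'
#' Screens candidate reference genes by the dispersion of their raw Ct values:
#' per gene, the arithmetic mean Ct, the sample standard deviation (SD, n-1
#' denominator) and the coefficient of variation (CV% = 100 * SD / mean).
#' Genes whose SD exceeds `sd_cutoff` (default 1 cycle) are flagged unstable
#' and unsuitable for normalization. Ranks are by ascending SD with CV% as
#' tiebreak. Flagged genes still receive ranks so that consensus aggregation
#' across methods remains possible; the flag is carried along.
#'
#' Optionally the analysis is completed with the BestKeeper index: the
#' geometric mean of the surviving candidates' Ct per sample, against which
#' each gene's Pearson correlation (and two-sided p-value) is reported.
#'
#' @param agg An aggregated Ct table (columns `gene`, `treatment`,
#'   `timepoint`, `ct`), restricted to the samples of interest.
#' @param sd_cutoff SD exclusion threshold in cycles; strictly greater than
#'   the cutoff flags the gene (SD exactly 1 is not flagged).
#' @param mad If `TRUE` use the mean absolute deviation about the arithmetic
#'   mean instead of the sample SD (the original tool's dispersion), default
#'   `FALSE`.
#' @param index If `TRUE` (default) compute per-gene correlations with the
#'   BestKeeper index over the unflagged candidates; skipped with a warning
#'   when fewer than 3 survive.
#' @return A tibble of class `bestkeeper_fit`: `gene`, `mean_ct`, `sd_ct`,
#'   `cv_pct`, `unstable`, `rank`, and when computed `index_r`, `index_p`.
#' @export
bestkeeper <- function(agg, sd_cutoff = 1, mad = FALSE, index = TRUE) {
  m <- ct_matrix(agg)
  if (ncol(m) < 2) stop("BestKeeper requires at least 2 samples", call. = FALSE)
  disp <- if (mad) {
    apply(m, 1, function(x) mean(abs(x - mean(x))))
  } else {
    apply(m, 1, stats::sd)
  }
  out <- tibble::tibble(
    gene = rownames(m),
    mean_ct = unname(rowMeans(m)),
    sd_ct = unname(disp),
    cv_pct = 100 * unname(disp) / unname(rowMeans(m))
  )
  # rank by SD, CV% breaking SD ties; genes tied on both share an average rank
  composite <- rank_ascending(out$sd_ct) + rank_ascending(out$cv_pct) / (10 * nrow(out))
  out <- dplyr::mutate(out,
    unstable = .data$sd_ct > sd_cutoff,
    rank = rank_ascending(composite)
  )
  if (index) {
    survivors <- out$gene[!out$unstable]
    if (length(survivors) < 3) {
      warning("fewer than 3 genes survive the SD filter; BestKeeper index skipped",
              call. = FALSE)
    } else {
      idx <- exp(colMeans(log(m[survivors, , drop = FALSE])))
      cors <- purrr::map(rownames(m), function(g) {
        ct <- suppressWarnings(stats::cor.test(m[g, ], idx))
        tibble::tibble(index_r = unname(ct$estimate), index_p = ct$p.value)
      })
      out <- dplyr::bind_cols(out, dplyr::bind_rows(cors))
    }
  }
  class(out) <- c("bestkeeper_fit", class(out))
  out
}

#' @export
tidy.bestkeeper_fit <- function(x, ...) tibble::as_tibble(unclass(x))
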