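#' Comparative delta-Ct stability analysis
#'
#' For every ordered pair of genes (g, h) the per-sample Ct difference
#' `Ct_g - Ct_h` is formed and its standard deviation over samples computed;
#' a gene's stability value is the mean of these pairwise SDs over all
#' partners. A gene whose expression tracks the rest of the panel has small
#' pairwise SDs throughout and hence a small mean SD; the gene with the
#' smallest value is the most stable. Ties share an average rank.
#'
#' @param agg An aggregated Ct table (columns `gene`, `treatment`,
#'   `timepoint`, `ct`), restricted to the samples of interest.
#' @return A tibble of class `delta_ct_fit`: `gene`, `mean_sd` (cycles),
#'   `rank`.
#' @export
delta_ct_stability <- function(agg) {
  m <- ct_matrix(agg)
  if (nrow(m) < 3) stop("delta-Ct stability requires at least 3 genes", call. = FALSE)
  if (ncol(m) < 2) stop("delta-Ct stability requires at least 2 samples", call. = FALSE)
  j <- nrow(m)
  sd_pair <- matrix(0, j, j)
  for (a in seq_len(j - 1)) {
    for (b in (a + 1):j) {
      sd_pair[a, b] <- sd_pair[b, a] <- stats::sd(m[a, ] - m[b, ])
    }
  }
  out <- tibble::tibble(
    gene = rownames(m),
    mean_sd = rowSums(sd_pair) / (j - 1)
  )
  out <- dplyr::mutate(out, rank = rank_ascending(.data$mean_sd))
  class(out) <- c("delta_ct_fit", class(out))
  out
}

#' @export
tidy.delta_ct_fit <- function(x, ...) tibble::as_tibble(unclass(x))
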