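#' Transform Ct values to relative quantities
#'
#' Converts aggregated Ct values to the relative quantities Q used by geNorm:
#' `Q = (1 + E)^(Ct_min - Ct)` per gene, so the best-expressed sample of each
#' gene has Q = 1 and all Q lie in (0, 1]. With the default efficiency E = 1
#' this is the familiar `Q = 2^-dCt` transform.
#'
#' @param agg An aggregated Ct table from [aggregate_replicates()] (columns
#'   `gene`, `treatment`, `timepoint`, `ct`), optionally pre-filtered to a
#'   treatment subset.
#' @param efficiency Either a single amplification efficiency (fraction,
#'   default 1 = perfect doubling) applied to all genes, or a data frame with
#'   columns `gene` and `efficiency`.
#' @return A tibble `gene`, `treatment`, `timepoint`, `q`. Errors if any
#'   gene has a missing Ct in the supplied rows: exclude genes or subsets
#'   first.
#' @export
relative_quantities <- function(agg, efficiency = 1) {
  agg <- tibble::as_tibble(agg)
  if (anyNA(agg$ct)) {
    bad <- unique(agg$gene[is.na(agg$ct)])
    stop("missing Ct for gene(s) ", paste(bad, collapse = ", "),
         "; drop these genes or restrict the subset before transforming", call. = FALSE)
  }
  eff_tbl <- efficiency_table(efficiency, unique(agg$gene))
  out <- dplyr::left_join(agg, eff_tbl, by = "gene")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$gene),
    q = (1 + .data$efficiency)^(min(.data$ct) - .data$ct)
  )
  dplyr::select(dplyr::ungroup(out), "gene", "treatment", "timepoint", "q")
}

# Normalise the efficiency argument to a per-gene lookup tibble.
efficiency_table <- function(efficiency, genes) {
  if (is.data.frame(efficiency)) {
    stopifnot(all(c("gene", "efficiency") %in% names(efficiency)))
    miss <- setdiff(genes, efficiency$gene)
    if (length(miss) > 0) {
      stop("no efficiency supplied for gene(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    tibble::as_tibble(efficiency)[, c("gene", "efficiency")]
  } else {
    stopifnot(is.numeric(efficiency), length(efficiency) == 1, efficiency > 0)
    tibble::tibble(gene = genes, efficiency = efficiency)
  }
}

# Internal: genes x samples matrix of Q values from an aggregated table.
q_matrix <- function(agg, efficiency = 1, subset = NULL) {
  m <- ct_matrix(agg, subset = subset)
  eff <- efficiency_table(efficiency, rownames(m))
  e <- eff$efficiency[match(rownames(m), eff$gene)]
  (1 + e)^(apply(m, 1, min) - m)
}
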