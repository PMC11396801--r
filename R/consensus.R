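#' Aggregate method ranks into a consensus ranking
#'
#' Combines per-gene ranks from several stability methods by their geometric
#' mean, the RefFinder-style comprehensive ranking. Methods are weighted
#' equally. Genes missing from any method are dropped with a warning; fully
#' disjoint gene sets are an error. Final ranks are assigned by ascending
#' geometric-mean rank with average-rank ties.
#'
#' @param ranks A data frame with columns `gene`, `method`, `rank` (long), or
#'   a named list of tibbles each with `gene` and `rank` columns (names become
#'   method labels).
#' @return A tibble of class `consensus_ranking`: `gene`, one `rank_<method>`
#'   column per method, `geomean_rank`, `final_rank`.
#' @examples
#' aggregate_ranks(tibble::tibble(
#'   gene = rep(c("A", "B"), 2),
#'   method = rep(c("genorm", "delta_ct"), each = 2),
#'   rank = c(1, 2, 1, 2)
#' ))
#' @export
aggregate_ranks <- function(ranks) {
  if (is.list(ranks) && !is.data.frame(ranks)) {
    stopifnot(!is.null(names(ranks)))
    ranks <- purrr::imap(ranks, function(x, nm) {
      tibble::tibble(gene = x$gene, method = nm, rank = x$rank)
    })
    ranks <- dplyr::bind_rows(ranks)
  }
  ranks <- tibble::as_tibble(ranks)
  stopifnot(all(c("gene", "method", "rank") %in% names(ranks)))
  methods <- unique(ranks$method)
  if (length(methods) < 2) stop("need ranks from at least 2 methods", call. = FALSE)

  common <- purrr::reduce(
    purrr::map(methods, function(m) unique(ranks$gene[ranks$method == m])),
    intersect
  )
  if (length(common) == 0) stop("methods share no genes; cannot aggregate", call. = FALSE)
  dropped <- setdiff(unique(ranks$gene), common)
  if (length(dropped) > 0) {
    warning("dropping gene(s) missing from some method(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  ranks <- dplyr::filter(ranks, .data$gene %in% common)

  wide <- tidyr::pivot_wider(ranks, id_cols = "gene", names_from = "method",
                             values_from = "rank", names_prefix = "rank_")
  rank_cols <- paste0("rank_", methods)
  gm <- exp(rowMeans(log(as.matrix(wide[, rank_cols]))))
  out <- dplyr::mutate(wide, geomean_rank = gm, final_rank = rank_ascending(gm))
  out <- dplyr::arrange(out, .data$final_rank, .data$gene)
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Pick the best reference-gene pair
#'
#' Returns the two top-ranked genes of a consensus ranking (the pairwise
#' variation analysis typically shows two reference genes suffice). Ties at
#' the boundary are broken by gene name, with a message.
#'
#' @param consensus A `consensus_ranking` from [aggregate_ranks()].
#' @return Character vector of two gene names, best first.
#' @export
best_pair <- function(consensus) {
  stopifnot(is.data.frame(consensus), nrow(consensus) >= 2)
  ord <- order(consensus$final_rank, consensus$gene)
  top <- consensus[ord, ]
  if (nrow(consensus) > 2 && top$final_rank[2] == top$final_rank[3]) {
    message("tie at rank 2 broken by gene name: ",
            paste(top$gene[top$final_rank == top$final_rank[2]], collapse = ", "))
  }
  top$gene[1:2]
}

#' Run all four stability methods and their consensus per treatment subset
#'
#' Convenience wrapper that runs geNorm, NormFinder, BestKeeper and the
#' comparative delta-Ct method on each requested treatment subset of an
#' aggregated Ct table, plus a pooled `"all"` subset, and aggregates their
#' ranks into a consensus per subset.
#'
#' @param agg An aggregated Ct table from [aggregate_replicates()].
#' @param subsets Character vector of treatment labels to analyse
#'   independently (default: every treatment present). The pooled analysis is
#'   added under the label `"all"` unless `pool = FALSE`.
#' @param pool Include the pooled all-samples analysis (default `TRUE`).
#' @param efficiency Per-gene efficiency for the geNorm Q transform, as in
#'   [relative_quantities()].
#' @param v_threshold,sd_cutoff Thresholds passed to [genorm()] and
#'   [bestkeeper()].
#' @return A list with
#'   \describe{
#'     \item{scores}{tibble `subset`, `method`, `gene`, `score`, `rank`,
#'       `unstable` (BestKeeper flag, `NA` elsewhere).}
#'     \item{consensus}{tibble `subset` + consensus columns.}
#'     \item{best_pair}{tibble `subset`, `gene1`, `gene2`.}
#'     \item{genorm_v}{tibble `subset`, `n`, `v`, `recommended_n`.}
#'   }
#' @export
rank_stability <- function(agg, subsets = NULL, pool = TRUE, efficiency = 1,
                           v_threshold = 0.15, sd_cutoff = 1) {
  agg <- tibble::as_tibble(agg)
  if (is.null(subsets)) subsets <- sort(unique(agg$treatment))
  labels <- c(subsets, if (pool) "all")
  per_subset <- purrr::map(labels, function(lab) {
    sub <- if (lab == "all") agg else dplyr::filter(agg, .data$treatment == lab)
    gn <- genorm(sub, efficiency = efficiency, v_threshold = v_threshold)
    nf <- normfinder(sub, groups = if (lab == "all") "treatment" else "none")
    bk <- bestkeeper(sub, sd_cutoff = sd_cutoff)
    dc <- delta_ct_stability(sub)
    scores <- dplyr::bind_rows(
      dplyr::transmute(gn$stability, method = "genorm", gene = .data$gene,
                       score = .data$m, rank = .data$rank, unstable = NA),
      dplyr::transmute(tibble::as_tibble(nf), method = "normfinder", gene = .data$gene,
                       score = .data$stability, rank = .data$rank, unstable = NA),
      dplyr::transmute(tibble::as_tibble(bk), method = "bestkeeper", gene = .data$gene,
                       score = .data$sd_ct, rank = .data$rank, unstable = .data$unstable),
      dplyr::transmute(tibble::as_tibble(dc), method = "delta_ct", gene = .data$gene,
                       score = .data$mean_sd, rank = .data$rank, unstable = NA)
    )
    cons <- aggregate_ranks(dplyr::select(scores, "gene", "method", "rank"))
    bp <- best_pair(cons)
    list(
      scores = dplyr::mutate(scores, subset = lab, .before = 1),
      consensus = dplyr::mutate(tibble::as_tibble(cons), subset = lab, .before = 1),
      best_pair = tibble::tibble(subset = lab, gene1 = bp[1], gene2 = bp[2]),
      genorm_v = dplyr::mutate(gn$pairwise_variation, subset = lab,
                               recommended_n = gn$recommended_n, .before = 1)
    )
  })
  list(
    scores = dplyr::bind_rows(purrr::map(per_subset, "scores")),
    consensus = dplyr::bind_rows(purrr::map(per_subset, "consensus")),
    best_pair = dplyr::bind_rows(purrr::map(per_subset, "best_pair")),
    genorm_v = dplyr::bind_rows(purrr::map(per_subset, "genorm_v"))
  )
}
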