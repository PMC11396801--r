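#' geNorm expression-stability analysis
#'
#' Implements the stepwise geNorm procedure. For genes j, k the pairwise
#' variation `V_jk` is the standard deviation over samples of the log2 ratio
#' of their relative quantities; a gene's expression-stability measure `M_j`
#' is the mean of its `V_jk` over all other candidates. The least stable gene
#' (highest M) is removed and M recomputed, until two genes remain; those two
#' cannot be resolved further and share average rank 1.5.
#'
#' The pairwise-variation curve `V(n/n+1)` compares normalization factors
#' (geometric means of relative quantities) built from the `n` and `n+1` most
#' stable genes; the smallest `n` with `V < v_threshold` (default 0.15) is the
#' recommended number of reference genes.
#'
#' @param agg An aggregated Ct table (see [aggregate_replicates()]), already
#'   restricted to the treatment subset of interest if desired.
#' @param efficiency Per-gene amplification efficiency as in
#'   [relative_quantities()]; default 1 (Q = 2^-dCt).
#' @param v_threshold Pairwise-variation threshold for the recommended number
#'   of reference genes.
#' @param stepwise If `TRUE` (default) each gene's reported M is the value at
#'   the round of its exclusion, matching the published stepwise charts;
#'   `FALSE` reports single-pass M over the full panel.
#' @return An object of class `genorm_fit`: a list with
#'   \describe{
#'     \item{stability}{tibble `gene`, `m`, `rank` (1 = most stable; final
#'       pair tied at 1.5), `excluded_round`.}
#'     \item{pairwise_variation}{tibble `n`, `v` for n = 2..J-1.}
#'     \item{recommended_n}{smallest n with `v < v_threshold`, or J with a
#'       warning when no V passes.}
#'     \item{order}{gene names from most to least stable.}
#'   }
#' @export
genorm <- function(agg, efficiency = 1, v_threshold = 0.15, stepwise = TRUE) {
  q <- q_matrix(agg, efficiency = efficiency)
  genorm_fit(q, v_threshold = v_threshold, stepwise = stepwise)
}

# Core geNorm on a genes x samples Q matrix.
genorm_fit <- function(q, v_threshold = 0.15, stepwise = TRUE) {
  j <- nrow(q)
  if (j < 3) stop("geNorm requires at least 3 genes", call. = FALSE)
  if (ncol(q) < 2) stop("geNorm requires at least 2 samples", call. = FALSE)

  single_pass <- genorm_m_values(q)

  keep <- rownames(q)
  excluded <- character(0)
  m_at_exclusion <- stats::setNames(numeric(j), rownames(q))
  round_of <- stats::setNames(integer(j), rownames(q))
  r <- 1L
  while (length(keep) > 2) {
    m <- genorm_m_values(q[keep, , drop = FALSE])
    # deterministic tie-break on gene name
    worst <- sort(names(m)[m == max(m)])[1]
    m_at_exclusion[worst] <- m[worst]
    round_of[worst] <- r
    excluded <- c(excluded, worst)
    keep <- setdiff(keep, worst)
    r <- r + 1L
  }
  final_m <- genorm_m_values(q[keep, , drop = FALSE])
  m_at_exclusion[keep] <- final_m
  round_of[keep] <- r

  order_stable <- c(sort(keep), rev(excluded))  # most -> least stable
  ranks <- stats::setNames(seq_len(j), order_stable)
  ranks[keep] <- 1.5  # final pair unresolved by geNorm

  genes <- rownames(q)
  stability <- tibble::tibble(
    gene = genes,
    m = if (stepwise) unname(m_at_exclusion[genes]) else unname(single_pass[genes]),
    rank = unname(ranks[genes]),
    excluded_round = unname(round_of[genes])
  )
  degenerate <- all(single_pass < 1e-12)
  if (degenerate) {
    warning("all pairwise variations are ~0 (genes are scalar multiples of one profile); ",
            "exclusion order is arbitrary", call. = FALSE)
  }

  v <- genorm_v_curve(q, order_stable)
  hit <- which(v$v < v_threshold)
  if (length(hit) > 0) {
    recommended_n <- v$n[hit[1]]
  } else {
    recommended_n <- j
    warning("no pairwise variation below ", v_threshold,
            "; all ", j, " genes may be needed", call. = FALSE)
  }

  structure(
    list(stability = stability, pairwise_variation = v,
         recommended_n = recommended_n, v_threshold = v_threshold,
         order = order_stable, degenerate = degenerate),
    class = "genorm_fit"
  )
}

# Single-pass M for every gene of a Q matrix: mean over partners of the
# sample-SD of pairwise log2 ratios.
genorm_m_values <- function(q) {
  lq <- log2(q)
  j <- nrow(q)
  if (j < 2) stop("need >= 2 genes for pairwise variation", call. = FALSE)
  v <- matrix(0, j, j)
  for (a in seq_len(j - 1)) {
    for (b in (a + 1):j) {
      v[a, b] <- v[b, a] <- stats::sd(lq[a, ] - lq[b, ])
    }
  }
  m <- rowSums(v) / (j - 1)
  stats::setNames(m, rownames(q))
}

# V(n/n+1) curve: SD over samples of log2(NF_n / NF_{n+1}), NF_n the geometric
# mean of Q over the n most stable genes.
genorm_v_curve <- function(q, order_stable) {
  j <- nrow(q)
  if (j < 3) stop("pairwise-variation curve needs at least 3 genes", call. = FALSE)
  nf_log2 <- function(n) colMeans(log2(q[order_stable[seq_len(n)], , drop = FALSE]))
  tibble::tibble(
    n = 2:(j - 1),
    v = purrr::map_dbl(2:(j - 1), function(n) stats::sd(nf_log2(n) - nf_log2(n + 1)))
  )
}

#' @export
tidy.genorm_fit <- function(x, ...) x$stability

#' @export
glance.genorm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    recommended_n = x$recommended_n,
    v_threshold = x$v_threshold,
    min_m = min(x$stability$m),
    best_pair = paste(x$order[1:2], collapse = "+"),
    degenerate = x$degenerate
  )
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability analysis (", nrow(x$stability), " genes)\n", sep = "")
  cat("Most stable pair:", paste(x$order[1:2], collapse = ", "), "\n")
  cat("Recommended number of reference genes:", x$recommended_n,
      sprintf("(V < %.2f rule)\n", x$v_threshold))
  print(dplyr::arrange(x$stability, .data$rank), n = 12)
  invisible(x)
}
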