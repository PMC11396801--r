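#' NormFinder-style stability analysis
#'
#' A model-based stability estimate that separates within-group (intragroup)
#' variation from systematic between-group (intergroup) bias, operating
#' directly on Ct values (already a log scale). Each sample column is first
#' centred by its cross-gene mean, removing sample-loading effects; the
#' centred residuals `w` carry each gene's deviation from the panel average.
#'
#' With a single group the stability value is simply the sample SD of `w`.
#' With grouping, each gene's per-group mean deviation `z` is shrunk towards
#' zero by an empirical-Bayes factor built from the between-group variance
#' component `gamma^2` (truncated at zero) and the group's sampling variance,
#' and the stability value combines the shrunken absolute bias with the
#' intragroup uncertainty. Lower values mean more stable expression. This is a
#' fixed, documented variant of the published estimator; agreement with the
#' original tool is at the rank level.
#'
#' @param agg An aggregated Ct table (columns `gene`, `treatment`,
#'   `timepoint`, `ct`), restricted to the samples of interest.
#' @param groups How samples are grouped for the intra/inter decomposition:
#'   `"treatment"` (default) groups by the treatment label, `"none"` uses the
#'   single-group estimator, or supply a data frame with columns `treatment`,
#'   `timepoint`, `group`.
#' @return A tibble of class `normfinder_fit`: `gene`, `stability`,
#'   `intragroup` (mean within-group SD of the centred residuals),
#'   `intergroup` (mean absolute shrunken group bias), `rank`.
#' @export
normfinder <- function(agg, groups = c("treatment", "none")) {
  m <- ct_matrix(agg)
  if (nrow(m) < 3) stop("NormFinder requires at least 3 genes", call. = FALSE)
  if (is.data.frame(groups)) {
    key <- tibble::tibble(sample = colnames(m)) |>
      tidyr::separate_wider_delim("sample", delim = ":", names = c("treatment", "timepoint"),
                                  cols_remove = FALSE) |>
      dplyr::mutate(timepoint = as.numeric(.data$timepoint))
    key <- dplyr::left_join(key, tibble::as_tibble(groups), by = c("treatment", "timepoint"))
    if (anyNA(key$group)) stop("group map does not cover all samples", call. = FALSE)
    grp <- key$group
  } else {
    groups <- rlang::arg_match(groups)
    grp <- if (groups == "none") rep("all", ncol(m)) else sub(":.*$", "", colnames(m))
  }
  out <- normfinder_fit(m, grp)
  class(out) <- c("normfinder_fit", class(out))
  out
}

# Core estimator on a genes x samples Ct matrix with a group label per sample.
normfinder_fit <- function(m, grp) {
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  w <- sweep(m, 2, colMeans(m))  # remove per-sample loading
  groups <- names(sizes)

  if (length(groups) == 1) {
    stab <- apply(w, 1, stats::sd)
    out <- tibble::tibble(gene = rownames(m), stability = unname(stab),
                          intragroup = unname(stab), intergroup = 0)
  } else {
    g_mean <- sapply(groups, function(g) rowMeans(w[, grp == g, drop = FALSE]))
    g_var <- sapply(groups, function(g) apply(w[, grp == g, drop = FALSE], 1, stats::var))
    n_g <- as.numeric(sizes[groups])
    z <- g_mean - rowMeans(g_mean)                       # gene x group bias
    samp_var <- sweep(g_var, 2, n_g, "/")                # var of z from sampling
    gamma2 <- max(0, stats::var(as.vector(z)) - mean(samp_var))
    denom <- gamma2 + samp_var
    shrink <- ifelse(denom == 0, 0, gamma2 / denom)  # degenerate: no variation at all
    z_tilde <- z * shrink
    per_group <- abs(z_tilde) + sqrt(samp_var + shrink * samp_var)
    out <- tibble::tibble(
      gene = rownames(m),
      stability = unname(rowMeans(per_group)),
      intragroup = unname(rowMeans(sqrt(g_var))),
      intergroup = unname(rowMeans(abs(z_tilde)))
    )
  }
  dplyr::mutate(out, rank = rank_ascending(.data$stability))
}

#' @export
tidy.normfinder_fit <- function(x, ...) tibble::as_tibble(unclass(x))
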