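#' Relative expression of a target gene by the comparative Ct method
#'
#' Computes per-replicate relative quantities of a target gene against one or
#' more reference genes with the 2^-ddCt method, calibrated to the 0 h sample
#' of each treatment (or another calibrator). For each replicate,
#' `dCt = Ct_target - mean(Ct_references)` (the arithmetic mean of reference
#' Ct is the geometric mean of their linear quantities, the usual
#' normalization-factor convention); `ddCt` subtracts the mean dCt over the
#' calibrator replicates of the same treatment, and `RQ = 2^-ddCt`.
#'
#' When per-gene efficiencies are supplied, the efficiency-corrected ratio is
#' used instead: `(1+E_target)^(mean_cal Ct_target - Ct_target)` divided by
#' the geometric mean over references of `(1+E_ref)^(mean_cal Ct_ref -
#' Ct_ref)`. With all efficiencies equal to 1 this reproduces 2^-ddCt exactly.
#'
#' @param ct A replicate-level Ct table (see [validate_ct()]).
#' @param target Target gene name (must not be among the references).
#' @param reference Character vector of one or more reference gene names.
#' @param calibrator_timepoint Timepoint (hours) of the calibrator condition
#'   within each treatment; default 0.
#' @param efficiency `NULL` (default, plain 2^-ddCt) or per-gene efficiencies
#'   as in [relative_quantities()].
#' @param treatments Optional subset of treatments to profile.
#' @return An object of class `expression_profile`: a list with
#'   \describe{
#'     \item{profile}{tibble `target`, `treatment`, `timepoint`, `rq_mean`,
#'       `rq_sem`, `n` (replicates used).}
#'     \item{replicates}{tibble with per-replicate `rq` and `log2_rq`, used by
#'       [timepoint_significance()].}
#'     \item{normalizer}{the reference gene set.}
#'   }
#'   Replicates with a missing target or reference Ct are dropped with a
#'   warning; a condition losing all replicates is an error.
#' @export
relative_expression <- function(ct, target, reference, calibrator_timepoint = 0,
                                efficiency = NULL, treatments = NULL) {
  ct <- validate_ct(ct)
  stopifnot(length(target) == 1, length(reference) >= 1)
  if (target %in% reference) stop("target gene cannot be one of its references", call. = FALSE)
  genes <- c(target, reference)
  miss <- setdiff(genes, unique(ct$gene))
  if (length(miss) > 0) stop("gene(s) not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- dplyr::filter(ct, .data$gene %in% genes)
  if (!is.null(treatments)) dat <- dplyr::filter(dat, .data$treatment %in% treatments)

  eff <- if (is.null(efficiency)) {
    tibble::tibble(gene = genes, efficiency = 1)
  } else {
    efficiency_table(efficiency, genes)
  }

  wide <- tidyr::pivot_wider(dat, id_cols = c("treatment", "timepoint", "replicate"),
                             names_from = "gene", values_from = "ct")
  complete <- stats::complete.cases(wide[, genes])
  if (any(!complete)) {
    warning(sum(!complete), " replicate(s) dropped for missing target/reference Ct",
            call. = FALSE)
    wide <- wide[complete, ]
  }

  # per-treatment calibrator means of each gene's Ct
  cal <- dplyr::filter(wide, .data$timepoint == calibrator_timepoint)
  if (nrow(cal) == 0) stop("no calibrator replicates at timepoint ", calibrator_timepoint, call. = FALSE)
  cal_means <- dplyr::summarise(dplyr::group_by(cal, .data$treatment),
                                dplyr::across(dplyr::all_of(genes), mean))
  missing_cal <- setdiff(unique(wide$treatment), cal_means$treatment)
  if (length(missing_cal) > 0) {
    stop("treatment(s) without calibrator replicates: ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }

  e_of <- function(g) eff$efficiency[match(g, eff$gene)]
  log2_factor <- function(g, ct_now, ct_cal) (ct_cal - ct_now) * log2(1 + e_of(g))
  cal_wide <- dplyr::rename_with(cal_means, function(x) paste0(".cal_", x), dplyr::all_of(genes))
  reps <- dplyr::left_join(wide, cal_wide, by = "treatment")
  ref_log2 <- rowMeans(do.call(cbind, lapply(reference, function(g) {
    log2_factor(g, reps[[g]], reps[[paste0(".cal_", g)]])
  })))
  tgt_log2 <- log2_factor(target, reps[[target]], reps[[paste0(".cal_", target)]])
  reps <- dplyr::transmute(reps,
    target = target, treatment = .data$treatment, timepoint = .data$timepoint,
    replicate = .data$replicate, log2_rq = tgt_log2 - ref_log2, rq = 2^.data$log2_rq
  )

  profile <- dplyr::summarise(
    dplyr::group_by(reps, .data$target, .data$treatment, .data$timepoint),
    rq_mean = mean(.data$rq),
    rq_sem = stats::sd(.data$rq) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  structure(
    list(profile = profile, replicates = reps,
         normalizer = reference, calibrator_timepoint = calibrator_timepoint),
    class = "expression_profile"
  )
}

#' Per-timepoint significance of expression changes
#'
#' Tests each (treatment, timepoint) of an expression profile against the
#' baseline timepoint with a two-sided independent-samples t-test on
#' per-replicate log2 relative quantities (fold changes are approximately
#' log-normal, so testing on the log scale is appropriate). The
#' pooled-variance (Student) test is the default: replicates at different
#' timepoints come from one protocol, and with typical 3-replicate groups the
#' Welch approximation is markedly conservative (true level ~0.03 at nominal
#' 0.05); Welch is available via `var_equal = FALSE`. Stars follow the usual
#' convention: `**` for p < 0.01, `*` for p < 0.05, none otherwise.
#'
#' @param fit An `expression_profile` from [relative_expression()].
#' @param baseline Baseline timepoint (default 0 h).
#' @param p_adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()]; default `"none"` (per-timepoint stars), `"BH"`
#'   available.
#' @param var_equal `TRUE` (default) for the pooled-variance t-test, `FALSE`
#'   for Welch.
#' @return The profile tibble with `p_value` and `stars` columns. Conditions
#'   with fewer than 2 replicates on either side get `NA` with a flag column
#'   `testable = FALSE`.
#' @export
timepoint_significance <- function(fit, baseline = 0, p_adjust = "none",
                                   var_equal = TRUE) {
  stopifnot(inherits(fit, "expression_profile"))
  reps <- fit$replicates
  prof <- fit$profile
  res <- purrr::pmap(list(prof$treatment, prof$timepoint), function(trt, tp) {
    x <- reps$log2_rq[reps$treatment == trt & reps$timepoint == tp]
    y <- reps$log2_rq[reps$treatment == trt & reps$timepoint == baseline]
    if (tp == baseline) return(tibble::tibble(p_value = NA_real_, testable = NA))
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(p_value = NA_real_, testable = FALSE))
    }
    # degenerate replicate sets: zero variance on both sides means the test
    # statistic is +/-Inf (different means) or 0 (equal means)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble::tibble(p_value = as.numeric(mean(x) == mean(y)), testable = TRUE))
    }
    p <- tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
                  error = function(e) as.numeric(isTRUE(all.equal(mean(x), mean(y)))))
    tibble::tibble(p_value = p, testable = TRUE)
  })
  out <- dplyr::bind_cols(prof, dplyr::bind_rows(res))
  tested <- !is.na(out$p_value)
  out$p_value[tested] <- stats::p.adjust(out$p_value[tested], method = p_adjust)
  out <- dplyr::mutate(out, stars = dplyr::case_when(
    is.na(.data$p_value) ~ "",
    .data$p_value < 0.01 ~ "**",
    .data$p_value < 0.05 ~ "*",
    TRUE ~ ""
  ))
  class(out) <- c("rq_profile", class(out))
  out
}

#' Concordance of expression profiles under different normalizers
#'
#' Compares the trajectories a target gene takes under different reference
#' gene choices: pairwise Pearson correlation of mean log2 relative
#' quantities over the shared (treatment, timepoint) grid, and whether the
#' peak (argmax) timepoint agrees within each treatment. Profile pairs whose
#' correlation falls below `min_cor` are flagged discordant — the signature
#' of normalizing by an unstable reference.
#'
#' @param profiles A named list of `expression_profile` objects for the same
#'   target over identical conditions.
#' @param min_cor Flagging threshold for the trajectory correlation
#'   (default 0.9).
#' @return A tibble: `profile_a`, `profile_b`, `cor_log2` (Pearson),
#'   `peak_agreement` (fraction of treatments with the same peak timepoint),
#'   `discordant`.
#' @export
normalizer_concordance <- function(profiles, min_cor = 0.9) {
  stopifnot(is.list(profiles), length(profiles) >= 2, !is.null(names(profiles)))
  grids <- purrr::map(profiles, function(p) {
    dplyr::arrange(p$profile, .data$treatment, .data$timepoint)[, c("treatment", "timepoint")]
  })
  same <- purrr::map_lgl(grids[-1], function(g) identical(g, grids[[1]]))
  if (!all(same)) stop("profiles cover different (treatment, timepoint) grids", call. = FALSE)

  traj <- purrr::map(profiles, function(p) {
    dplyr::arrange(p$profile, .data$treatment, .data$timepoint)
  })
  peak_of <- function(tr) {
    dplyr::summarise(dplyr::group_by(tr, .data$treatment),
                     peak = .data$timepoint[which.max(.data$rq_mean)])
  }
  pairs <- utils::combn(names(profiles), 2, simplify = FALSE)
  out <- purrr::map(pairs, function(pr) {
    a <- traj[[pr[1]]]; b <- traj[[pr[2]]]
    r <- stats::cor(log2(a$rq_mean), log2(b$rq_mean))
    pk <- dplyr::inner_join(peak_of(a), peak_of(b), by = "treatment", suffix = c("_a", "_b"))
    tibble::tibble(
      profile_a = pr[1], profile_b = pr[2], cor_log2 = r,
      peak_agreement = mean(pk$peak_a == pk$peak_b)
    )
  })
  dplyr::mutate(dplyr::bind_rows(out), discordant = .data$cor_log2 < min_cor)
}

#' @export
tidy.expression_profile <- function(x, ...) x$profile

#' @export
print.expression_profile <- function(x, ...) {
  cat("Relative expression of", x$profile$target[1],
      "normalized by", paste(x$normalizer, collapse = " + "),
      sprintf("(calibrator: %g h)\n", x$calibrator_timepoint))
  print(x$profile, n = 20)
  invisible(x)
}
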