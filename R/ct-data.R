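#' Read a table of raw Ct values
#'
#' Reads cycle-threshold (Ct) measurements from a delimited text file into the
#' canonical tidy layout used throughout the package: one row per
#' (gene, treatment, timepoint, replicate) observation.
#'
#' Two on-disk layouts are accepted. The long layout (canonical) has columns
#' `gene,treatment,timepoint,replicate,ct`. The wide layout has a first column
#' `gene` and one column per sample, headed `treatment:timepoint:replicate`.
#'
#' @param path Path to a delimited text file.
#' @param layout `"long"` (default) or `"wide"`.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with columns `gene` (character), `treatment` (character),
#'   `timepoint` (numeric, hours), `replicate` (integer), `ct` (numeric,
#'   cycles; `NA` for missing wells), validated by [validate_ct()]. Row order
#'   in the file does not affect the result: rows are sorted by gene,
#'   treatment, timepoint, replicate.
#' @seealso [write_ct_table()], [aggregate_replicates()], [screen_ct_range()]
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), delim = ",") {
  layout <- rlang::arg_match(layout)
  if (!file.exists(path)) {
    stop("Ct input file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  if (layout == "long") {
    need <- c("gene", "treatment", "timepoint", "replicate", "ct")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      stop("long Ct table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    tbl <- dplyr::select(raw, dplyr::all_of(need))
  } else {
    if (names(raw)[1] != "gene") {
      stop("wide Ct table must have 'gene' as its first column", call. = FALSE)
    }
    sample_cols <- names(raw)[-1]
    bad <- sample_cols[!grepl("^[^:]+:[^:]+:[^:]+$", sample_cols)]
    if (length(bad) > 0) {
      stop("wide sample headers must be 'treatment:timepoint:replicate'; offending: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
    tbl <- tidyr::pivot_longer(raw, -"gene", names_to = "sample", values_to = "ct")
    tbl <- tidyr::separate_wider_delim(tbl, "sample", delim = ":",
                                       names = c("treatment", "timepoint", "replicate"))
  }
  bad_ct <- which(!is.na(tbl$ct) & is.na(suppressWarnings(as.numeric(tbl$ct))))
  if (length(bad_ct) > 0) {
    stop("non-numeric Ct value '", tbl$ct[bad_ct[1]], "' at data row ", bad_ct[1], call. = FALSE)
  }
  tbl <- dplyr::mutate(tbl,
    timepoint = as.numeric(.data$timepoint),
    replicate = as.integer(.data$replicate),
    ct = as.numeric(.data$ct)
  )
  tbl <- dplyr::arrange(tbl, .data$gene, .data$treatment, .data$timepoint, .data$replicate)
  validate_ct(tbl)
}

#' Write a Ct table to disk
#'
#' Inverse of [read_ct_table()]; round-trips cell-for-cell.
#'
#' @param ct A tidy Ct table (see [validate_ct()]).
#' @param path Output file path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, layout = c("long", "wide")) {
  layout <- rlang::arg_match(layout)
  ct <- validate_ct(ct)
  if (layout == "long") {
    readr::write_csv(ct, path, progress = FALSE)
  } else {
    wide <- tidyr::pivot_wider(
      dplyr::mutate(ct, sample = paste(.data$treatment, .data$timepoint, .data$replicate, sep = ":")),
      id_cols = "gene", names_from = "sample", values_from = "ct"
    )
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate a tidy Ct table
#'
#' Checks the structural invariants every downstream algorithm relies on:
#' required columns present, no duplicated (gene, treatment, timepoint,
#' replicate) records, all non-missing Ct finite and in (0, 45], at least two
#' genes and two distinct samples.
#'
#' @param ct A data frame of replicate-level Ct values.
#' @return The input as a tibble, invisibly unchanged, or an error naming the
#'   first offending record.
#' @export
validate_ct <- function(ct) {
  ct <- tibble::as_tibble(ct)
  need <- c("gene", "treatment", "timepoint", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) {
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste(ct$gene, ct$treatment, ct$timepoint, ct$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    d <- ct[dup[1], ]
    stop(sprintf("duplicate Ct record for gene '%s', sample %s:%g:%d",
                 d$gene, d$treatment, d$timepoint, d$replicate), call. = FALSE)
  }
  ok <- is.na(ct$ct) | (is.finite(ct$ct) & ct$ct > 0 & ct$ct <= 45)
  if (!all(ok)) {
    d <- ct[which(!ok)[1], ]
    stop(sprintf("Ct value %s out of (0, 45] for gene '%s', sample %s:%g:%d",
                 format(d$ct), d$gene, d$treatment, d$timepoint, d$replicate), call. = FALSE)
  }
  if (any(ct$timepoint < 0, na.rm = TRUE)) {
    stop("negative timepoint in Ct table", call. = FALSE)
  }
  ct
}

#' Average biological replicates
#'
#' Collapses a replicate-level Ct table to one value per
#' (gene, treatment, timepoint): the arithmetic mean of the non-missing
#' replicate Ct values. The arithmetic mean is used (not a geometric mean)
#' because Ct is already a log-scale quantity. The replicate count, standard
#' deviation, and standard error of the mean (SD/sqrt(n)) are carried along
#' for reporting.
#'
#' Cells where some but not all replicates are missing are kept (flagged
#' `partial`); cells with no usable replicate are kept as `NA` with a warning,
#' so downstream subset/gene exclusion is explicit.
#'
#' @param ct A tidy replicate-level Ct table (see [validate_ct()]).
#' @return A tibble with columns `gene`, `treatment`, `timepoint`, `ct`
#'   (replicate mean), `ct_sd`, `ct_sem`, `n_reps`, `partial`. Idempotent:
#'   re-aggregating an aggregated table (as replicate 1) returns it unchanged.
#' @export
aggregate_replicates <- function(ct) {
  ct <- validate_ct(ct)
  agg <- dplyr::summarise(
    dplyr::group_by(ct, .data$gene, .data$treatment, .data$timepoint),
    n_total = dplyr::n(),
    n_reps = sum(!is.na(.data$ct)),
    ct_sd = stats::sd(.data$ct[!is.na(.data$ct)]),
    ct = ifelse(.data$n_reps > 0, mean(.data$ct, na.rm = TRUE), NA_real_),
    .groups = "drop"
  )
  agg <- dplyr::mutate(agg,
    ct_sem = .data$ct_sd / sqrt(.data$n_reps),
    partial = .data$n_reps < .data$n_total
  )
  empty <- dplyr::filter(agg, .data$n_reps == 0)
  if (nrow(empty) > 0) {
    warning(sprintf("%d cell(s) have no usable replicate (first: gene '%s', %s:%g)",
                    nrow(empty), empty$gene[1], empty$treatment[1], empty$timepoint[1]),
            call. = FALSE)
  }
  dplyr::select(agg, "gene", "treatment", "timepoint", "ct", "ct_sd", "ct_sem",
                "n_reps", "partial")
}

#' Screen Ct values against a plausibility band
#'
#' Reports every non-missing Ct outside `[lo, hi]`. Typical RT-qPCR templates
#' yield Ct values well inside 10--40 cycles; values outside that band usually
#' indicate failed wells or primer problems. The table itself is not modified.
#'
#' @param ct A tidy replicate-level Ct table.
#' @param lo,hi Band limits in cycles (`lo < hi`).
#' @return A tibble of violations with columns `gene`, `treatment`,
#'   `timepoint`, `replicate`, `ct`; zero rows when all values are in band.
#' @export
screen_ct_range <- function(ct, lo = 10, hi = 40) {
  stopifnot(lo < hi)
  ct <- validate_ct(ct)
  dplyr::filter(ct, !is.na(.data$ct) & (.data$ct < lo | .data$ct > hi))
}

# Internal: pivot an aggregated table (one row per gene x condition) into a
# genes x samples matrix, optionally restricted to one treatment subset.
# Genes with any missing cell in the subset are dropped with a warning.
ct_matrix <- function(agg, subset = NULL, drop_missing = TRUE) {
  if (!is.null(subset) && !identical(subset, "all")) {
    agg <- dplyr::filter(agg, .data$treatment %in% subset)
    if (nrow(agg) == 0) stop("no samples in subset: ", paste(subset, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::mutate(agg, sample = paste(.data$treatment, .data$timepoint, sep = ":")),
    id_cols = "gene", names_from = "sample", values_from = "ct"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (drop_missing && anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    warning("excluding gene(s) with missing aggregated cells: ",
            paste(bad, collapse = ", "), call. = FALSE)
    m <- m[!rownames(m) %in% bad, , drop = FALSE]
  }
  m
}

# Internal: average ranks ascending (1 = smallest = most stable)
rank_ascending <- function(x) rank(x, ties.method = "average")
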