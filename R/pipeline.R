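#' Read a pipeline run configuration
#'
#' Loads a YAML run configuration and fills defaults. Recognised keys:
#' `input` (`ct`: long CSV path, `dilution`: dilution CSV path, or `simulate`:
#' `TRUE` to generate the built-in study), `seed`, `subsets` (treatment
#' labels; default every treatment plus the pooled analysis), `thresholds`
#' (`v_threshold`, `sd_cutoff`, `e_lo`, `e_hi`, `r2_min`), `efficiency_mode`
#' (`"doubling"` or `"dilution"`), `normalizers` (list of
#' `{target, references}` entries), `calibrator_timepoint`, `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg A named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(
    input = list(ct = NULL, dilution = NULL, simulate = FALSE),
    seed = 1L,
    subsets = NULL,
    thresholds = list(v_threshold = 0.15, sd_cutoff = 1.0,
                      e_lo = 0.90, e_hi = 1.20, r2_min = 0.99),
    efficiency_mode = "doubling",
    normalizers = list(),
    calibrator_timepoint = 0,
    out_dir = "refstab-report"
  )
  cfg <- utils::modifyList(defaults, cfg)
  th <- cfg$thresholds
  if (any(unlist(th[c("v_threshold", "sd_cutoff", "e_lo", "e_hi", "r2_min")]) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (!isTRUE(cfg$input$simulate) && is.null(cfg$input$ct)) {
    stop("config needs input$ct or input$simulate: true", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full reference-gene selection and validation pipeline
#'
#' Executes the study workflow end to end: read (or simulate) replicate-level
#' Ct values, average biological replicates, optionally calibrate
#' amplification efficiencies from a dilution series, run the four stability
#' methods per treatment subset plus the pooled set, aggregate their ranks
#' into a consensus and pick the best reference pair, then profile the
#' configured target genes by 2^-ddCt with per-timepoint significance.
#' All tables are written as TSV under `out_dir` together with a provenance
#' record (config hash, seed, package version); a rerun with the same config
#' reproduces them byte for byte.
#'
#' @param cfg A `run_config` (see [read_run_config()]/[as_run_config()]) or a
#'   plain list coerced with [as_run_config()].
#' @return Invisibly, the run report: a list with `aggregated`, `curves`,
#'   `stability` (the [rank_stability()] output), `expression` (named list of
#'   significance-annotated profiles), `provenance`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds

  candidates <- cfg$candidates
  if (isTRUE(cfg$input$simulate)) {
    sim <- simulate_reference_study(seed = cfg$seed)
    ct <- sim$ct
    if (is.null(candidates)) {
      candidates <- sim$panel$genes$gene[sim$panel$genes$role != "target"]
    }
    if (length(cfg$normalizers) == 0) {
      cfg$normalizers <- list(
        list(target = "CS", references = sim$panel$stable_pair),
        list(target = "CS", references = sim$panel$unstable_gene)
      )
    }
  } else {
    ct <- read_ct_table(cfg$input$ct)
  }
  agg <- aggregate_replicates(ct)

  curves <- NULL
  eff <- 1
  if (!is.null(cfg$input$dilution)) {
    dil <- readr::read_csv(cfg$input$dilution, show_col_types = FALSE, progress = FALSE)
    curves <- primer_qc(fit_standard_curve(dil),
                        e_lo = th$e_lo, e_hi = th$e_hi, r2_min = th$r2_min)
    readr::write_tsv(tibble::as_tibble(curves), file.path(cfg$out_dir, "efficiency.tsv"),
                     progress = FALSE)
    if (identical(cfg$efficiency_mode, "dilution")) {
      eff <- dplyr::rename(curves[, c("primer", "efficiency")], gene = "primer")
    }
  }

  # candidate reference genes: configured explicitly, or everything that is
  # not being profiled as a target
  targets <- unique(purrr::map_chr(cfg$normalizers, "target"))
  if (is.null(candidates)) candidates <- setdiff(unique(agg$gene), targets)
  stab_agg <- dplyr::filter(agg, .data$gene %in% candidates)
  stab <- rank_stability(stab_agg, subsets = cfg$subsets,
                         efficiency = if (is.data.frame(eff)) {
                           dplyr::filter(eff, .data$gene %in% stab_agg$gene)
                         } else eff,
                         v_threshold = th$v_threshold, sd_cutoff = th$sd_cutoff)
  readr::write_tsv(stab$scores, file.path(cfg$out_dir, "stability_scores.tsv"), progress = FALSE)
  readr::write_tsv(stab$consensus, file.path(cfg$out_dir, "consensus.tsv"), progress = FALSE)
  readr::write_tsv(stab$best_pair, file.path(cfg$out_dir, "best_pair.tsv"), progress = FALSE)
  readr::write_tsv(stab$genorm_v, file.path(cfg$out_dir, "genorm_v.tsv"), progress = FALSE)

  expression <- list()
  for (nm in cfg$normalizers) {
    label <- paste0(nm$target, "_by_", paste(nm$references, collapse = "+"))
    prof <- relative_expression(ct, target = nm$target, reference = nm$references,
                                calibrator_timepoint = cfg$calibrator_timepoint,
                                efficiency = if (is.data.frame(eff)) eff else NULL)
    sig <- timepoint_significance(prof, baseline = cfg$calibrator_timepoint)
    readr::write_tsv(sig, file.path(cfg$out_dir, paste0("expression_", label, ".tsv")),
                     progress = FALSE)
    expression[[label]] <- sig
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("refstab")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    thresholds = th
  )
  yaml::write_yaml(provenance, file.path(cfg$out_dir, "provenance.yaml"))
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))

  invisible(list(aggregated = agg, curves = curves, stability = stab,
                 expression = expression, provenance = provenance))
}
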