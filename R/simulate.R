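#' Describe a qPCR study design
#'
#' Captures the experimental layout a synthetic Ct dataset should emulate:
#' treatments, the timepoint grid of each treatment, the number of biological
#' replicates, and a per-sample "loading" standard deviation modelling cDNA
#' input variation (a constant added to every gene of a sample — exactly the
#' nuisance reference-gene normalization exists to remove).
#'
#' The default mirrors a five-treatment abiotic-stress time course: hormone
#' elicitors (MeJA, EtH, SA) sampled at 0, 3, 6, 12, 24, 48 h and temperature
#' stresses (HighTem, LowTem) at 0, 6, 12, 24, 36, 48 h, three biological
#' replicates each.
#'
#' @param treatments Character vector of treatment labels.
#' @param timepoints Named list mapping each treatment to its timepoint grid
#'   (hours; must contain 0), or a single numeric vector used for all.
#' @param replicates Biological replicates per condition (default 3).
#' @param loading_sd SD (cycles) of the per-sample loading effect, default 0.3.
#' @return A list of class `qpcr_design`.
#' @export
qpcr_design <- function(treatments = c("MeJA", "EtH", "SA", "HighTem", "LowTem"),
                        timepoints = NULL, replicates = 3, loading_sd = 0.3) {
  hormone_grid <- c(0, 3, 6, 12, 24, 48)
  temp_grid <- c(0, 6, 12, 24, 36, 48)
  if (is.null(timepoints)) {
    timepoints <- lapply(treatments, function(t) {
      if (t %in% c("HighTem", "LowTem")) temp_grid else hormone_grid
    })
    names(timepoints) <- treatments
  } else if (is.numeric(timepoints)) {
    timepoints <- stats::setNames(rep(list(timepoints), length(treatments)), treatments)
  }
  stopifnot(setequal(names(timepoints), treatments), replicates >= 1, loading_sd >= 0)
  if (!all(vapply(timepoints, function(tp) 0 %in% tp, logical(1)))) {
    stop("every treatment's timepoint grid must contain 0", call. = FALSE)
  }
  structure(list(treatments = treatments, timepoints = timepoints,
                 replicates = as.integer(replicates), loading_sd = loading_sd),
            class = "qpcr_design")
}

#' Simulate a replicate-level Ct dataset with known ground truth
#'
#' Generates Ct values as `baseline + designed shift + loading + noise`:
#' a fixed per-gene baseline, a deterministic per-(gene, treatment, timepoint)
#' Ct shift encoding the designed biology, a per-sample loading constant
#' shared by all genes (`Normal(0, loading_sd^2)`), and independent Gaussian
#' replicate noise (`Normal(0, noise_sd_g^2)`). The same seed reproduces the
#' dataset bit for bit.
#'
#' @param design A [qpcr_design()].
#' @param genes A tibble with columns `gene`, `role` (one of `stable`,
#'   `group_biased`, `time_drifting`, `noisy`, `target`), `baseline` (cycles,
#'   conventionally 17--25), `noise_sd` (cycles), `amplitude` (cycles; peak
#'   designed shift for non-stable candidate roles, ignored for `stable` and
#'   `target`).
#' @param effects Optional tibble `gene`, `treatment`, `timepoint`, `shift`
#'   overriding or supplying designed shifts (required for `target` genes;
#'   a target's designed log2 fold change is `-shift`). Role-derived shifts
#'   are built automatically for `group_biased` (alternating per-treatment
#'   offset) and `time_drifting` (linear ramp to `amplitude` at the last
#'   timepoint).
#' @param seed Integer seed; required, for reproducibility.
#' @return A list with `ct` (tidy replicate-level Ct table) and `truth`
#'   (list: `roles` = the gene tibble, `trajectories` = tibble `gene`,
#'   `treatment`, `timepoint`, `shift`, `log2fc`).
#' @export
simulate_ct <- function(design, genes, effects = NULL, seed) {
  stopifnot(inherits(design, "qpcr_design"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  genes <- tibble::as_tibble(genes)
  need <- c("gene", "role", "baseline", "noise_sd")
  stopifnot(all(need %in% names(genes)))
  if (!"amplitude" %in% names(genes)) genes$amplitude <- 0
  roles_ok <- c("stable", "group_biased", "time_drifting", "noisy", "target")
  bad <- setdiff(unique(genes$role), roles_ok)
  if (length(bad) > 0) stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(genes$role == "stable" & genes$amplitude != 0)) {
    stop("stable genes must have amplitude 0", call. = FALSE)
  }
  if (any(genes$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  grid <- dplyr::bind_rows(purrr::imap(design$timepoints, function(tp, trt) {
    tibble::tibble(treatment = trt, timepoint = tp)
  }))

  shifts <- tidyr::crossing(gene = genes$gene, grid)
  shifts <- dplyr::left_join(shifts, genes[, c("gene", "role", "amplitude")], by = "gene")
  shifts <- dplyr::mutate(
    dplyr::group_by(shifts, .data$treatment),
    t_frac = .data$timepoint / max(.data$timepoint)
  )
  trt_sign <- stats::setNames(rep_len(c(1, -1), length(design$treatments)), design$treatments)
  shifts <- dplyr::mutate(dplyr::ungroup(shifts), shift = dplyr::case_when(
    .data$role == "time_drifting" ~ .data$amplitude * .data$t_frac,
    .data$role == "group_biased" ~ .data$amplitude * unname(trt_sign[.data$treatment]) / 2,
    TRUE ~ 0
  ))
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("gene", "treatment", "timepoint", "shift") %in% names(effects)))
    shifts <- dplyr::left_join(shifts, effects,
                               by = c("gene", "treatment", "timepoint"),
                               suffix = c("", ".given"))
    shifts <- dplyr::mutate(shifts,
      shift = dplyr::coalesce(.data$shift.given, .data$shift))
    shifts$shift.given <- NULL
  }
  no_fx <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(shifts, .data$gene, .data$role),
                     all_zero = all(.data$shift == 0), .groups = "drop"),
    .data$role == "target" & .data$all_zero
  )
  if (nrow(no_fx) > 0) {
    stop("target gene(s) without designed trajectory: ",
         paste(no_fx$gene, collapse = ", "), call. = FALSE)
  }

  set.seed(seed)
  samples <- tidyr::crossing(grid, replicate = seq_len(design$replicates))
  # scale standard draws so RNG consumption is independent of the SD values
  # (rnorm(n, 0, 0) consumes nothing, which would desynchronise streams)
  samples$loading <- stats::rnorm(nrow(samples)) * design$loading_sd
  ct <- tidyr::crossing(gene = genes$gene, samples)
  ct <- dplyr::left_join(ct, genes[, c("gene", "baseline", "noise_sd")], by = "gene")
  ct <- dplyr::left_join(ct, shifts[, c("gene", "treatment", "timepoint", "shift")],
                         by = c("gene", "treatment", "timepoint"))
  ct <- dplyr::arrange(ct, .data$gene, .data$treatment, .data$timepoint, .data$replicate)
  ct <- dplyr::mutate(ct,
    ct = .data$baseline + .data$shift + .data$loading +
      stats::rnorm(dplyr::n()) * .data$noise_sd)
  out_ct <- validate_ct(dplyr::select(ct, "gene", "treatment", "timepoint", "replicate", "ct"))

  traj <- dplyr::mutate(shifts[, c("gene", "role", "treatment", "timepoint", "shift")],
                        log2fc = ifelse(.data$role == "target", -.data$shift, NA_real_))
  list(ct = out_ct, truth = list(roles = genes, trajectories = traj))
}

#' Gene panel emulating a reference-gene screening study
#'
#' A ready-made 12-candidate + 14-target gene panel for [simulate_ct()],
#' modelled on reference-gene screening in a mogroside-producing cucurbit:
#' CDC6 and NCBP2 are designed stable (the truth the pipeline should
#' recover), PP2A is designed unstable (drifting `drift` cycles over each
#' time course), the remaining candidates carry intermediate treatment biases
#' or drifts, and the 14 mogroside-pathway targets (AACT ... EPH) follow
#' designed treatment-specific trajectories: under SA every target peaks at
#' 3 h and then declines sharply; under MeJA/EtH genes split into
#' up-then-down and down-then-up groups; the temperature treatments suppress
#' or transiently induce expression.
#'
#' @param drift Designed Ct drift of the unstable candidate (cycles over a
#'   time course), default 2 (at least 1.5 to be clearly unstable).
#' @param noise_sd Replicate noise SD in cycles for a typical gene,
#'   default 0.15.
#' @param targets Include the 14 target genes (default `TRUE`); `FALSE`
#'   gives the 12-candidate panel only.
#' @return A list with `genes` (gene-model tibble), `effects` (designed target
#'   trajectories as Ct shifts), `design` (a [qpcr_design()]), `stable_pair`,
#'   `unstable_gene`.
#' @export
reference_panel <- function(drift = 2, noise_sd = 0.15, targets = TRUE) {
  candidates <- tibble::tribble(
    ~gene,    ~role,           ~baseline, ~noise_sd, ~amplitude,
    "RPL13",  "group_biased",  20.5,      noise_sd,  0.6,
    "CDC6",   "stable",        23.8,      0.10,      0,
    "TIP41",  "group_biased",  22.0,      noise_sd,  0.5,
    "tubB2",  "time_drifting", 21.5,      noise_sd,  0.6,
    "tubB3",  "group_biased",  22.5,      noise_sd,  0.8,
    "GAPDH",  "time_drifting", 19.6,      noise_sd,  0.7,
    "tubA",   "group_biased",  21.0,      noise_sd,  0.6,
    "EF1a",   "time_drifting", 18.5,      noise_sd,  0.5,
    "NCBP2",  "stable",        22.3,      0.10,      0,
    "UBQC",   "group_biased",  20.0,      noise_sd,  0.5,
    "PP2A",   "time_drifting", 21.3,      2 * noise_sd, drift,
    "PCACO",  "time_drifting", 17.4,      2 * noise_sd, 1.2
  )
  design <- qpcr_design()

  # Explicit designed shifts for the non-stable candidates. Each gene gets a
  # distinct sign pattern over treatments (group_biased) or a distinct
  # direction/shape of drift (time_drifting): unstable genes that all moved
  # in lockstep would look mutually stable to the pairwise methods, which no
  # real panel of independently misbehaving genes does.
  trts <- design$treatments  # MeJA, EtH, SA, HighTem, LowTem
  bias_signs <- list(
    RPL13 = c(1, -1, 1, -1, 1),
    TIP41 = c(-1, 1, 1, -1, -1),
    tubB3 = c(-1, -1, 1, 1, 1),
    tubA  = c(1, 1, -1, 1, -1),
    UBQC  = c(1, -1, -1, 1, -1)
  )
  drift_shape <- list(  # direction and ramp exponent over the time course
    tubB2 = c(1, 1), GAPDH = c(-1, 1), EF1a = c(1, 0.5),
    PP2A = c(1, 1), PCACO = c(-1, 2)
  )
  grid <- dplyr::bind_rows(purrr::imap(design$timepoints, function(tp, trt) {
    tibble::tibble(treatment = trt, timepoint = tp)
  }))
  amp_of <- stats::setNames(candidates$amplitude, candidates$gene)
  cand_fx <- dplyr::bind_rows(c(
    purrr::imap(bias_signs, function(s, g) {
      dplyr::mutate(grid, gene = g,
                    shift = amp_of[[g]] / 2 * s[match(.data$treatment, trts)])
    }),
    purrr::imap(drift_shape, function(ds, g) {
      dplyr::mutate(dplyr::group_by(grid, .data$treatment), gene = g,
                    shift = ds[1] * amp_of[[g]] *
                      (.data$timepoint / max(.data$timepoint))^ds[2]) |>
        dplyr::ungroup()
    })
  ))[, c("gene", "treatment", "timepoint", "shift")]

  if (!targets) {
    return(list(genes = candidates, effects = cand_fx, design = design,
                stable_pair = c("CDC6", "NCBP2"), unstable_gene = "PP2A"))
  }

  target_names <- c("AACT", "HMGS", "HMGR", "MK", "PMK", "MVD", "IPI",
                    "GPS", "FPS", "SQS", "SQE", "CS", "CYP450", "EPH")
  target_genes <- tibble::tibble(
    gene = target_names, role = "target",
    baseline = seq(20, 24, length.out = length(target_names)),
    noise_sd = noise_sd, amplitude = 0
  )

  # designed log2 fold-change trajectories per treatment group of targets
  hormone_tp <- c(0, 3, 6, 12, 24, 48)
  temp_tp <- c(0, 6, 12, 24, 36, 48)
  up3_meja <- c("AACT", "MK", "IPI", "GPS", "MVD", "EPH", "SQS", "PMK")
  down_up_meja <- setdiff(target_names, up3_meja)
  dip_eth <- c("AACT", "HMGS", "HMGR", "IPI", "FPS", "SQS", "SQE", "CS", "CYP450")
  spike_eth <- setdiff(target_names, dip_eth)
  spike_high <- c("AACT", "IPI", "GPS", "SQE", "PMK")
  down_high <- setdiff(target_names, spike_high)

  traj <- function(genes, treatment, tp, log2fc) {
    tidyr::crossing(gene = genes, tibble::tibble(treatment = treatment,
                                                 timepoint = tp, log2fc = log2fc))
  }
  fx <- dplyr::bind_rows(
    traj(target_names, "SA", hormone_tp, c(0, 2, -0.5, -1, -1.5, -1)),
    traj(up3_meja, "MeJA", hormone_tp, c(0, 2, 1.5, 1, 1.2, 1)),
    traj(down_up_meja, "MeJA", hormone_tp, c(0, -1, -1.2, -0.8, 0, 0.8)),
    traj(dip_eth, "EtH", hormone_tp, c(0, -0.5, -1, -1.5, 1.5, 0.5)),
    traj(spike_eth, "EtH", hormone_tp, c(0, 1.5, 0.8, 0.3, 0, 0)),
    traj(setdiff(target_names, "MK"), "LowTem", temp_tp, c(0, 1.5, 2, 1, -0.5, 0)),
    traj("MK", "LowTem", temp_tp, c(0, -0.5, -1, -0.5, 0, 0.5)),
    traj(spike_high, "HighTem", temp_tp, c(0, 1, 0.2, 0, 0, 0)),
    traj(down_high, "HighTem", temp_tp, c(0, -1, -1.5, -2, -2, -2))
  )
  effects <- dplyr::bind_rows(
    cand_fx,
    dplyr::mutate(fx, shift = -.data$log2fc)[, c("gene", "treatment", "timepoint", "shift")]
  )

  list(genes = dplyr::bind_rows(candidates, target_genes), effects = effects,
       design = design, stable_pair = c("CDC6", "NCBP2"), unstable_gene = "PP2A")
}

#' Simulate the full reference-gene screening study
#'
#' One-call wrapper: [reference_panel()] simulated through [simulate_ct()].
#'
#' @param seed Integer seed.
#' @param ... Passed to [reference_panel()].
#' @return As [simulate_ct()], plus `panel` (the [reference_panel()] spec).
#' @export
simulate_reference_study <- function(seed, ...) {
  panel <- reference_panel(...)
  sim <- simulate_ct(panel$design, panel$genes, panel$effects, seed = seed)
  c(sim, list(panel = panel))
}

#' Simulate dilution series with known amplification efficiencies
#'
#' Generates standard-curve input with designed per-primer efficiency: at
#' dilution level i of a `base`-fold series the expected Ct is
#' `intercept + i * log10(base) / log10(1 + E)`, plus optional Gaussian noise.
#' [fit_standard_curve()] recovers E exactly in the noiseless case.
#'
#' @param efficiencies A data frame `primer`, `efficiency` (fractions), or a
#'   named numeric vector.
#' @param base Fold-step of the series (default 5).
#' @param levels Dilution levels (default 0:4).
#' @param replicates Technical replicates per level.
#' @param noise_sd Ct noise SD (default 0 = noiseless).
#' @param intercept Undiluted Ct (default 18).
#' @param seed Seed, required when `noise_sd > 0`.
#' @return A tibble `primer`, `level`, `ct`.
#' @export
simulate_dilution_series <- function(efficiencies, base = 5, levels = 0:4,
                                     replicates = 1, noise_sd = 0,
                                     intercept = 18, seed = NULL) {
  if (!is.data.frame(efficiencies)) {
    efficiencies <- tibble::tibble(primer = names(efficiencies),
                                   efficiency = unname(efficiencies))
  }
  stopifnot(all(c("primer", "efficiency") %in% names(efficiencies)),
            all(efficiencies$efficiency > 0))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    set.seed(seed)
  }
  out <- tidyr::crossing(efficiencies, level = levels, rep = seq_len(replicates))
  out <- dplyr::mutate(out,
    ct = intercept + .data$level * log10(base) / log10(1 + .data$efficiency) +
      if (noise_sd > 0) stats::rnorm(dplyr::n(), 0, noise_sd) else 0)
  dplyr::select(out, "primer", "level", "ct")
}
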