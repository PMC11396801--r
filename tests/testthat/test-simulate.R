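test_that("noiseless generation reproduces baseline + designed shifts exactly", {
  design <- qpcr_design(treatments = c("A", "B"), timepoints = c(0, 3, 6),
                        replicates = 2, loading_sd = 0)
  genes <- tibble::tibble(
    gene = c("s", "d"), role = c("stable", "time_drifting"),
    baseline = c(20, 22), noise_sd = 0, amplitude = c(0, 1.5)
  )
  sim <- simulate_ct(design, genes, seed = 1)
  s_rows <- dplyr::filter(sim$ct, gene == "s")
  expect_true(all(s_rows$ct == 20))
  d6 <- dplyr::filter(sim$ct, gene == "d", timepoint == 6)
  expect_true(all(d6$ct == 22 + 1.5))
  d3 <- dplyr::filter(sim$ct, gene == "d", timepoint == 3)
  expect_true(all(d3$ct == 22 + 1.5 * 0.5))
})

test_that("identical seeds give bitwise-identical tables, different seeds differ", {
  a <- simulate_reference_study(seed = 7)
  b <- simulate_reference_study(seed = 7)
  expect_identical(a$ct, b$ct)
  c <- simulate_reference_study(seed = 8)
  expect_false(identical(a$ct$ct, c$ct$ct))
})

test_that("the built-in panel matches the designed study dimensions and truth", {
  sim <- simulate_reference_study(seed = 4)
  expect_equal(length(unique(sim$ct$gene)), 26)
  expect_equal(nrow(sim$ct), 26 * 5 * 6 * 3)
  roles <- sim$truth$roles
  expect_setequal(roles$gene[roles$role == "stable"], c("CDC6", "NCBP2"))
  expect_equal(roles$amplitude[roles$gene == "PP2A"], 2)
  expect_gte(roles$amplitude[roles$gene == "PP2A"], 1.5)

  # hormone and temperature treatments use their two distinct grids
  tp <- dplyr::distinct(sim$ct, treatment, timepoint)
  expect_setequal(tp$timepoint[tp$treatment == "SA"], c(0, 3, 6, 12, 24, 48))
  expect_setequal(tp$timepoint[tp$treatment == "HighTem"], c(0, 6, 12, 24, 36, 48))

  # SA trajectories peak at 3 h by design
  traj <- dplyr::filter(sim$truth$trajectories, role == "target", treatment == "SA")
  peaks <- dplyr::summarise(dplyr::group_by(traj, gene),
                            peak = timepoint[which.max(log2fc)])
  expect_true(all(peaks$peak == 3))
})

test_that("replicate SDs converge to the designed noise SD", {
  design <- qpcr_design(treatments = "A", timepoints = 0, replicates = 1000,
                        loading_sd = 0)
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"), role = "stable",
                          baseline = 20, noise_sd = 0.15, amplitude = 0)
  sim <- simulate_ct(design, genes, seed = 99)
  sds <- dplyr::summarise(dplyr::group_by(sim$ct, gene), s = sd(ct))$s
  expect_true(all(abs(sds - 0.15) / 0.15 < 0.05))
})

test_that("dilution-series companion round-trips designed efficiencies", {
  effs <- tibble::tibble(primer = paste0("p", 1:4),
                         efficiency = c(0.9, 1.0, 1.026, 1.2))
  fit <- fit_standard_curve(simulate_dilution_series(effs))
  expect_equal(fit$efficiency[match(effs$primer, fit$primer)], effs$efficiency,
               tolerance = 1e-6)
})

test_that("loading effects do not change geNorm or delta-Ct orderings", {
  for (seed in 1:3) {
    panel <- reference_panel(targets = FALSE)
    quiet <- panel$design; quiet$loading_sd <- 0
    loud <- panel$design; loud$loading_sd <- 1.0
    agg_q <- aggregate_replicates(simulate_ct(quiet, panel$genes, panel$effects, seed = seed)$ct)
    agg_l <- aggregate_replicates(simulate_ct(loud, panel$genes, panel$effects, seed = seed)$ct)
    expect_equal(genorm(agg_l)$order, genorm(agg_q)$order)
    dq <- delta_ct_stability(agg_q); dl <- delta_ct_stability(agg_l)
    expect_equal(dl$rank[match(dq$gene, dl$gene)], dq$rank)
  }
})

test_that("invalid specifications are rejected", {
  design <- qpcr_design(treatments = "A", timepoints = c(0, 3))
  bad_role <- tibble::tibble(gene = "g", role = "wild", baseline = 20,
                             noise_sd = 0.1, amplitude = 0)
  expect_error(simulate_ct(design, bad_role, seed = 1), "unknown role")
  drifting_stable <- tibble::tibble(gene = "g", role = "stable", baseline = 20,
                                    noise_sd = 0.1, amplitude = 1)
  expect_error(simulate_ct(design, drifting_stable, seed = 1), "amplitude 0")
  target_no_fx <- tibble::tibble(gene = "g", role = "target", baseline = 20,
                                 noise_sd = 0.1, amplitude = 0)
  expect_error(simulate_ct(design, target_no_fx, seed = 1), "without designed trajectory")
  expect_error(qpcr_design(treatments = "A", timepoints = c(3, 6)), "contain 0")
  expect_error(simulate_ct(design, drifting_stable), "seed")
})
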