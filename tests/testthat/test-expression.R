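test_that("2^-ddCt closed forms: constants, single-cycle shift, common shifts", {
  # all genes constant: RQ = 1 everywhere
  ct <- make_ct(c("tgt", "ref1", "ref2"), timepoints = c(0, 3, 6),
                ct_fun = function(g, trt, tp, r) 20 + (g == "tgt") * 2)
  fit <- relative_expression(ct, "tgt", c("ref1", "ref2"))
  expect_equal(fit$profile$rq_mean, rep(1, 3))
  expect_equal(fit$profile$rq_sem, rep(0, 3))

  # target 1 cycle lower at 3 h: RQ = 2 there
  ct2 <- make_ct(c("tgt", "ref"), timepoints = c(0, 3),
                 ct_fun = function(g, trt, tp, r) 20 - (g == "tgt" & tp == 3))
  fit2 <- relative_expression(ct2, "tgt", "ref")
  expect_equal(fit2$profile$rq_mean[fit2$profile$timepoint == 3], 2)
  expect_equal(fit2$profile$rq_mean[fit2$profile$timepoint == 0], 1)

  # common +0.6 shift of target and both references cancels
  ct3 <- make_ct(c("tgt", "ref1", "ref2"), timepoints = c(0, 3),
                 ct_fun = function(g, trt, tp, r) 20 + (tp == 3) * 0.6)
  fit3 <- relative_expression(ct3, "tgt", c("ref1", "ref2"))
  expect_equal(fit3$profile$rq_mean, c(1, 1))
})

test_that("per-sample constant Ct shifts leave every RQ unchanged", {
  sim <- simulate_reference_study(seed = 5)
  fit0 <- relative_expression(sim$ct, "CS", c("CDC6", "NCBP2"))
  shifted <- dplyr::group_by(sim$ct, treatment, timepoint, replicate)
  shifted <- dplyr::ungroup(dplyr::mutate(shifted, ct = ct + dplyr::cur_group_id() * 0.1))
  fit1 <- relative_expression(shifted, "CS", c("CDC6", "NCBP2"))
  expect_equal(fit1$profile$rq_mean, fit0$profile$rq_mean, tolerance = 1e-9)
})

test_that("a reference with Ct identical to the target forces RQ = 1", {
  ct <- make_ct("tgt", timepoints = c(0, 3, 6),
                ct_fun = function(g, trt, tp, r) 20 - tp / 6 + 0.1 * r)
  twin <- dplyr::mutate(ct, gene = "twin")
  fit <- relative_expression(dplyr::bind_rows(ct, twin), "tgt", "twin")
  expect_equal(fit$profile$rq_mean, rep(1, 3))
})

test_that("efficiency-corrected mode with E = 1 reproduces plain 2^-ddCt", {
  sim <- simulate_reference_study(seed = 6)
  fit0 <- relative_expression(sim$ct, "CS", c("CDC6", "NCBP2"))
  eff <- tibble::tibble(gene = c("CS", "CDC6", "NCBP2"), efficiency = 1)
  fit1 <- relative_expression(sim$ct, "CS", c("CDC6", "NCBP2"), efficiency = eff)
  expect_equal(fit1$profile$rq_mean, fit0$profile$rq_mean, tolerance = 1e-12)
  expect_error(relative_expression(sim$ct, "CS", "CS"), "cannot be one of its references")
})

test_that("significance stars follow the t-test on log2 RQ", {
  # identical replicate sets at both timepoints: no evidence, no star
  ct <- make_ct(c("tgt", "ref"), timepoints = c(0, 3),
                ct_fun = function(g, trt, tp, r) 20 + 0.2 * r)
  sig <- timepoint_significance(relative_expression(ct, "tgt", "ref"))
  expect_equal(sig$stars[sig$timepoint == 3], "")

  # 6-cycle separation with tiny variance: p ~ 0, two stars
  ct2 <- make_ct(c("tgt", "ref"), timepoints = c(0, 3),
                 ct_fun = function(g, trt, tp, r)
                   20 - (g == "tgt" & tp == 3) * 6 + 0.01 * r)
  sig2 <- timepoint_significance(relative_expression(ct2, "tgt", "ref"))
  expect_equal(sig2$stars[sig2$timepoint == 3], "**")
  expect_lt(sig2$p_value[sig2$timepoint == 3], 1e-4)

  # single replicate: not testable
  ct3 <- make_ct(c("tgt", "ref"), timepoints = c(0, 3), replicates = 1,
                 ct_fun = function(g, trt, tp, r) 20)
  sig3 <- timepoint_significance(relative_expression(ct3, "tgt", "ref"))
  expect_false(sig3$testable[sig3$timepoint == 3])
  expect_equal(sig3$stars[sig3$timepoint == 3], "")
})

test_that("null simulations reject at close to the nominal 5% rate", {
  # each "treatment" is an independent null trial: no designed effect, 3 reps
  set.seed(101)
  n_trials <- 400
  ct <- make_ct(c("tgt", "ref"), treatments = paste0("trial", seq_len(n_trials)),
                timepoints = c(0, 3),
                ct_fun = function(g, trt, tp, r) 20)
  ct$ct[ct$gene == "tgt"] <- 20 + rnorm(sum(ct$gene == "tgt"), 0, 0.25)
  sig <- timepoint_significance(relative_expression(ct, "tgt", "ref"))
  rejections <- sum(sig$p_value < 0.05, na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), n_trials, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("concordance separates stable normalizers from an unstable one", {
  sim <- simulate_reference_study(seed = 9)
  stable <- relative_expression(sim$ct, "AACT", c("CDC6", "NCBP2"))
  stable2 <- relative_expression(sim$ct, "AACT", "CDC6")
  drifty <- relative_expression(sim$ct, "AACT", "PP2A")

  conc <- normalizer_concordance(list(pair = stable, single = stable2, unstable = drifty))
  self <- normalizer_concordance(list(a = stable, b = stable))
  expect_equal(self$cor_log2, 1)
  expect_equal(self$peak_agreement, 1)

  r_stable <- conc$cor_log2[conc$profile_a == "pair" & conc$profile_b == "single"]
  expect_gt(r_stable, 0.95)

  # the drifting reference moves the designed HighTem peak (6 h) to late times
  peak_of <- function(p, trt) {
    d <- dplyr::filter(p$profile, treatment == trt)
    d$timepoint[which.max(d$rq_mean)]
  }
  expect_equal(peak_of(stable, "HighTem"), 6)
  expect_false(peak_of(drifty, "HighTem") == 6)

  grid_mismatch <- relative_expression(sim$ct, "AACT", "CDC6", treatments = "SA")
  expect_error(normalizer_concordance(list(a = stable, b = grid_mismatch)), "grids")
})
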