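test_that("relative quantities: powers of (1+E) with max 1 per gene", {
  agg <- tibble::tibble(gene = "g", treatment = "A", timepoint = c(0, 3, 6),
                        ct = c(20, 21, 22))
  expect_equal(relative_quantities(agg)$q, c(1, 0.5, 0.25))

  agg2 <- dplyr::mutate(agg, ct = 20)
  expect_equal(relative_quantities(agg2)$q, c(1, 1, 1))

  agg3 <- tibble::tibble(gene = "g", treatment = "A", timepoint = c(0, 3),
                         ct = c(20, 21))
  q3 <- relative_quantities(agg3, efficiency = tibble::tibble(gene = "g", efficiency = 0.9))
  expect_equal(q3$q, c(1, 1 / 1.9))

  expect_error(relative_quantities(dplyr::mutate(agg, ct = c(20, NA, 22))), "missing Ct")
})

test_that("constant-offset genes survive geNorm with zero pairwise variation", {
  # genes 1,2 differ by a constant Ct offset; gene 3 varies independently
  m <- rbind(g1 = c(20, 21, 22, 20.5),
             g2 = c(22, 23, 24, 22.5),
             g3 = c(20, 24, 18, 23))
  colnames(m) <- paste0("A:", 1:4)
  fit <- suppressWarnings(genorm(ct_matrix_to_agg(m)))
  expect_setequal(fit$order[1:2], c("g1", "g2"))
  expect_equal(fit$stability$m[fit$stability$gene %in% c("g1", "g2")], c(0, 0))
  expect_equal(fit$stability$rank[fit$stability$gene %in% c("g1", "g2")], c(1.5, 1.5))
})

test_that("stepwise M matches the brute-force oracle at every exclusion round", {
  for (seed in 1:5) {
    m <- random_ct_matrix(6, 12, seed = seed)
    agg <- ct_matrix_to_agg(m)
    fit <- suppressWarnings(genorm(agg))
    q <- 2^(apply(m, 1, min) - m)
    oracle <- oracle_genorm_stepwise(q)
    expect_equal(fit$stability$m, unname(oracle$m[fit$stability$gene]),
                 tolerance = 1e-9)
    expect_setequal(fit$order[1:2], oracle$final_pair)
  }
})

test_that("pairwise-variation curve matches geometric-mean recomputation", {
  for (seed in 6:8) {
    m <- random_ct_matrix(6, 12, seed = seed)
    fit <- suppressWarnings(genorm(ct_matrix_to_agg(m)))
    q <- 2^(apply(m, 1, min) - m)
    expect_equal(fit$pairwise_variation$v, unname(oracle_v_curve(q, fit$order)),
                 tolerance = 1e-9)
  }
})

test_that("scalar-multiple profiles are degenerate: all M = 0, V = 0, n = 2", {
  base <- c(20, 21.5, 19, 22, 20.5)
  m <- rbind(g1 = base, g2 = base + 1, g3 = base + 2, g4 = base - 0.5)
  colnames(m) <- paste0("A:", 1:5)
  expect_warning(fit <- genorm(ct_matrix_to_agg(m)), "scalar multiples")
  expect_equal(fit$stability$m, rep(0, 4))
  expect_equal(fit$pairwise_variation$v, rep(0, 2))
  expect_equal(fit$recommended_n, 2)
})

test_that("the V < 0.15 rule fires exactly at the boundary", {
  # g1 = g2, g3 = g1 shifted by delta_s cycles: V_2 = sd(delta)/3
  make_v_fixture <- function(target_v) {
    delta <- c(0, 3 * target_v * sqrt(2))  # sd over 2 samples = 3 * target_v
    m <- rbind(g1 = c(20, 21), g2 = c(22, 23), g3 = c(20, 21) + delta)
    colnames(m) <- paste0("A:", 1:2)
    ct_matrix_to_agg(m)
  }
  below <- genorm(make_v_fixture(0.149))
  expect_equal(below$pairwise_variation$v, 0.149, tolerance = 1e-9)
  expect_equal(below$recommended_n, 2)

  expect_warning(above <- genorm(make_v_fixture(0.151)), "no pairwise variation below")
  expect_equal(above$pairwise_variation$v, 0.151, tolerance = 1e-9)
  expect_equal(above$recommended_n, 3)
})

test_that("per-sample loading constants do not change geNorm results", {
  m <- random_ct_matrix(6, 10, seed = 11)
  fit0 <- suppressWarnings(genorm(ct_matrix_to_agg(m)))
  loading <- seq(-1, 1, length.out = 10)
  fit1 <- suppressWarnings(genorm(ct_matrix_to_agg(sweep(m, 2, loading, "+"))))
  expect_equal(fit1$stability$m, fit0$stability$m, tolerance = 1e-9)
  expect_equal(fit1$order, fit0$order)
  expect_equal(fit1$pairwise_variation$v, fit0$pairwise_variation$v, tolerance = 1e-9)
})

test_that("geNorm output is invariant to gene and sample permutations", {
  m <- random_ct_matrix(5, 8, seed = 12)
  fit0 <- suppressWarnings(genorm(ct_matrix_to_agg(m)))
  set.seed(1)
  perm <- ct_matrix_to_agg(m[sample(nrow(m)), sample(ncol(m))])
  fit1 <- suppressWarnings(genorm(perm))
  s0 <- dplyr::arrange(fit0$stability, gene)
  s1 <- dplyr::arrange(fit1$stability, gene)
  expect_equal(s1$m, s0$m, tolerance = 1e-12)
  expect_equal(s1$rank, s0$rank)
  expect_equal(fit1$order, fit0$order)
})

test_that("small panels are rejected with clear errors", {
  m <- random_ct_matrix(2, 4, seed = 1)
  expect_error(genorm(ct_matrix_to_agg(m)), "at least 3 genes")
})
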