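# Independent brute-force re-derivations of the stability statistics, written
# against the formulas directly (explicit loops, no shared code with R/).

# sample SD without stats::sd, from the definition
.sd_def <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# geNorm M of every gene of a Q matrix, single pass
oracle_genorm_m <- function(q) {
  genes <- rownames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    vs <- c()
    for (k in setdiff(genes, j)) {
      a <- log2(q[j, ] / q[k, ])
      vs <- c(vs, .sd_def(a))
    }
    m[j] <- mean(vs)
  }
  m
}

# geNorm stepwise exclusion from scratch; returns per-gene M at exclusion
oracle_genorm_stepwise <- function(q) {
  keep <- rownames(q)
  m_out <- numeric(nrow(q))
  names(m_out) <- rownames(q)
  while (length(keep) > 2) {
    m <- oracle_genorm_m(q[keep, , drop = FALSE])
    worst <- sort(names(m)[m == max(m)])[1]
    m_out[worst] <- m[worst]
    keep <- setdiff(keep, worst)
  }
  m_final <- oracle_genorm_m(q[keep, , drop = FALSE])
  m_out[keep] <- m_final
  list(m = m_out, final_pair = keep)
}

# V(n/n+1) from geometric means, given a most-to-least-stable gene order
oracle_v_curve <- function(q, ord) {
  nf <- function(n, s) prod(q[ord[1:n], s])^(1 / n)
  sapply(2:(nrow(q) - 1), function(n) {
    ratio <- sapply(colnames(q), function(s) log2(nf(n, s) / nf(n + 1, s)))
    .sd_def(ratio)
  })
}

# delta-Ct mean pairwise SD per gene of a Ct matrix
oracle_delta_ct <- function(m) {
  genes <- rownames(m)
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    sds <- c()
    for (h in setdiff(genes, g)) {
      sds <- c(sds, .sd_def(m[g, ] - m[h, ]))
    }
    out[g] <- mean(sds)
  }
  out
}

# BestKeeper SD and CV% per gene
oracle_bestkeeper <- function(m) {
  t(apply(m, 1, function(x) {
    c(sd = .sd_def(x), cv = 100 * .sd_def(x) / mean(x))
  }))
}

# geometric mean of a rank matrix (genes x methods) by product and root
oracle_geomean <- function(r) {
  apply(r, 1, function(x) prod(x)^(1 / length(x)))
}

# random genes x samples Ct matrix in the typical 17-25 band
random_ct_matrix <- function(genes = 6, samples = 12, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(genes * samples, 17, 25), genes, samples)
  rownames(m) <- paste0("g", seq_len(genes))
  colnames(m) <- paste0("T", rep(1:2, length.out = samples), ":",
                        seq_len(samples))
  m
}

# wrap a genes x samples Ct matrix as an aggregated tidy table
ct_matrix_to_agg <- function(m) {
  tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    treatment = rep(sub(":.*$", "", colnames(m)), each = nrow(m)),
    timepoint = rep(as.numeric(sub("^.*:", "", colnames(m))), each = nrow(m)),
    ct = as.vector(m)
  )
}

# small replicate-level Ct table builder
make_ct <- function(genes, treatments = "A", timepoints = c(0, 3), replicates = 3,
                    ct_fun = function(g, trt, tp, r) 20) {
  grid <- tidyr::crossing(gene = genes, treatment = treatments,
                          timepoint = timepoints, replicate = seq_len(replicates))
  dplyr::mutate(grid, ct = purrr::pmap_dbl(
    list(gene, treatment, timepoint, replicate), ct_fun))
}
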