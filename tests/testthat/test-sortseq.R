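# shared synthetic experiment
gen1 <- generate_counts(counts_sim_spec(seed = 1))

test_that("plate normalization scales every plate to the deepest median", {
  # two plates with per-cell-total medians 2000 and 4000
  counts <- rbind(Cldn5 = c(2000, 2000, 4000, 4000),
                  Pdgfrb = c(0, 0, 0, 0))
  cells <- tibble::tibble(barcode = c("a", "b", "a", "b"),
                          plate_id = c("p1", "p1", "p2", "p2"),
                          genotype = "control")
  x <- counts_matrix(counts, cells)
  nx <- normalize_plates(x)
  expect_true(nx$normalized)
  tot <- cell_totals(nx)
  expect_equal(as.vector(tapply(tot, nx$cells$plate_id, stats::median)),
               c(4000, 4000))
  expect_equal(unname(tot[nx$cells$plate_id == "p1"] /
                        cell_totals(x)[nx$cells$plate_id == "p1"]),
               c(2, 2))
  # single plate: identity
  x1 <- toy_counts(c(1500, 2500, 3500))
  n1 <- normalize_plates(x1)
  expect_equal(unname(cell_totals(n1)), c(1500, 2500, 3500))
  # plate of all-zero cells errors, naming the plate
  z <- counts_matrix(rbind(Cldn5 = c(5, 0), Pdgfrb = c(0, 0)),
                     tibble::tibble(barcode = c("a", "b"),
                                    plate_id = c("p1", "pz"),
                                    genotype = "control"))
  expect_error(normalize_plates(z), "pz")
})

test_that("generated plate effects are removed to numerical precision", {
  norm <- normalize_plates(gen1$counts)
  tot <- cell_totals(norm)
  med <- tapply(tot[tot > 0], norm$cells$plate_id[tot > 0], stats::median)
  expect_equal(max(med) / min(med), 1, tolerance = 1e-9)
})

test_that("QC boundaries are inclusive on UMI and strict on mito", {
  x <- normalize_plates(toy_counts(c(999, 1000, 8000, 8001, 2000, 2000),
                                   mito_counts = c(0, 0, 0, 0, 200, 199)))
  qc <- qc_filter(x)
  # totals 999 / 1000 / 8000 / 8001
  expect_equal(qc$qc$pass[1:4], c(FALSE, TRUE, TRUE, FALSE))
  # mito exactly 10.0% fails (strict <); 9.95% passes
  expect_equal(qc$qc$mito_pct[5:6], c(10, 9.95))
  expect_equal(qc$qc$pass[5:6], c(FALSE, TRUE))
  expect_equal(ncol(qc$counts$counts), sum(qc$qc$pass))
  # un-normalized input is rejected (QC follows plate scaling)
  expect_error(qc_filter(toy_counts(2000)), "normalize")
  # unknown mito prefix: warning, mito_pct zero
  expect_warning(q2 <- qc_filter(normalize_plates(toy_counts(2000)),
                                 mito_prefix = "zzz-"), "zzz-")
  expect_equal(q2$qc$mito_pct, 0)
})

test_that("QC retains exactly the planted cell set", {
  norm <- normalize_plates(gen1$counts)
  qc <- qc_filter(norm)
  tr <- gen1$truth$cells
  expect_identical(qc$qc$cell, tr$cell)
  # planted high-mito cells fail the mito criterion, all others pass it
  expect_true(all(qc$qc$mito_pct[tr$mito_target > 0.1] >= 10))
  expect_true(all(qc$qc$mito_pct[tr$mito_target <= 0.1] < 10))
  # planted depth outliers fall outside the UMI window
  in_window <- qc$qc$total_umi >= 1000 & qc$qc$total_umi <= 8000
  expect_true(all(!in_window[tr$depth_class != "in_window"]))
  expect_true(all(in_window[tr$depth_class == "in_window"]))
})

test_that("QC is monotone in its thresholds", {
  norm <- normalize_plates(gen1$counts)
  base <- qc_filter(norm)$qc
  wider <- qc_filter(norm, umi_min = 500, umi_max = 10000,
                     mito_max = 20)$qc
  expect_true(all(wider$pass[base$pass]))
})

test_that("marker-rule cell typing implements the stated truth table", {
  counts <- rbind(Cldn5 = c(3, 0, 1, 0),
                  Pdgfrb = c(0, 2, 1, 0),
                  Other = c(10, 10, 10, 10))
  cells <- tibble::tibble(barcode = letters[1:4], plate_id = "p1",
                          genotype = "control")
  calls <- assign_cell_types(counts_matrix(counts, cells))
  expect_equal(calls$call, c("endothelial",  # Cldn5 > 0, Pdgfrb = 0
                             "pericyte",     # Pdgfrb > 0, Cldn5 = 0
                             "excluded",     # both markers
                             "excluded"))    # neither marker
  expect_error(assign_cell_types(counts_matrix(counts, cells),
                                 ec_marker = "Missing"), "Missing")
  # partition: every cell gets exactly one call
  norm <- normalize_plates(gen1$counts)
  kept <- qc_filter(norm)$counts
  ct <- assign_cell_types(kept)
  expect_equal(nrow(ct), ncol(kept$counts))
  expect_true(all(ct$call %in% c("endothelial", "pericyte", "excluded")))
})

test_that("log-normalization matches ln(1 + 1e4 x / total) and inverts", {
  counts <- rbind(Cldn5 = c(1, 5), Pdgfrb = c(0, 3),
                  G1 = c(9999, 4992))
  cells <- tibble::tibble(barcode = c("a", "b"), plate_id = "p1",
                          genotype = "control")
  x <- counts_matrix(counts, cells)
  e <- log_normalize(x)
  expect_equal(e["Cldn5", 1], log(2))       # count 1 of total 1e4
  expect_equal(e["Pdgfrb", 1], 0)           # zero count stays zero
  # algebraic round trip
  tot <- cell_totals(x)
  back <- sweep(expm1(e), 2, tot / 1e4, `*`)
  expect_equal(unname(back), unname(as.matrix(x$counts)[rownames(e), ]),
               tolerance = 1e-9)
  # z-scaling: per-gene mean 0, sd 1 for non-constant genes
  z <- z_scale(e)
  expect_equal(unname(rowMeans(z)), rep(0, 3), tolerance = 1e-12)
})

test_that("logistic LRT agrees with an independent likelihood maximization", {
  set.seed(41)
  n1 <- 14; n2 <- 16
  y <- rep(c(1, 0), c(n1, n2))
  expr <- rbind(
    g1 = c(rnorm(n1, 2, 0.5), rnorm(n2, 0.5, 0.5)),
    g2 = rnorm(n1 + n2, 1, 0.4),
    g3 = c(rexp(n1, 1), rexp(n2, 2)),
    g4 = rep(c(1.5, 0.1), c(n1, n2)) + rnorm(n1 + n2, 0, 0.2),
    g5 = runif(n1 + n2, 0, 3)
  )
  expr <- pmax(expr, 0)
  de <- differential_expression(expr, y, 1, 0)
  # oracle: direct Bernoulli log-likelihood maximization via optim
  # (Nelder-Mead + BFGS polish), independent of the IRLS path
  loglik <- function(beta, x) {
    eta <- beta[1] + beta[2] * x
    sum(y * eta - log1p(exp(eta)))
  }
  for (g in rownames(expr)) {
    x <- expr[g, ]
    fit0 <- stats::optim(c(0, 0), function(b) -loglik(b, x),
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
    fit <- stats::optim(fit0$par, function(b) -loglik(b, x),
                        method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 1000))
    ll_full <- -fit$value
    p_hat <- mean(y)
    ll_null <- sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
    stat_oracle <- 2 * (ll_full - ll_null)
    p_oracle <- stats::pchisq(stat_oracle, 1, lower.tail = FALSE)
    expect_equal(de$p_value[de$gene == g], p_oracle, tolerance = 1e-6)
  }
})

test_that("fold changes and significance follow the stated definitions", {
  set.seed(42)
  n <- 12
  y <- rep(c("a", "b"), each = n)
  same <- rep(abs(rnorm(2 * n, 1, 0.3)), 1)
  expr <- rbind(null_gene = c(same[1:n], same[1:n]),  # identical distributions
                up_gene = c(rep(3, n), rep(0.1, n)))
  de <- differential_expression(expr, y, "a", "b")
  # identical expression in both groups: log2fc 0, not significant
  expect_equal(de$log2fc[de$gene == "null_gene"], 0)
  expect_false(de$significant[de$gene == "null_gene"])
  # fold change definition: log2((mean expm1 + 1) / (mean expm1 + 1))
  m1 <- mean(expm1(expr["up_gene", 1:n]))
  m2 <- mean(expm1(expr["up_gene", n + 1:n]))
  expect_equal(de$log2fc[de$gene == "up_gene"], log2((m1 + 1) / (m2 + 1)))
  # perfect separation: result carries a convergence flag, p still in (0, 1]
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_true(is.logical(de$converged))
  # groups below 3 cells error
  expect_error(differential_expression(expr[, 1:4, drop = FALSE],
                                       y[1:4], "a", "b"), "3 cells")
})

test_that("planted DE genes are recovered at the stated cutoffs", {
  norm <- normalize_plates(gen1$counts)
  kept <- qc_filter(norm)$counts
  types <- assign_cell_types(kept)
  expr <- log_normalize(kept)
  sel <- types$call == "endothelial"
  de <- differential_expression(expr[, sel], types$genotype[sel],
                                "control", "knockout")
  truth <- gen1$truth$de_genes[gen1$truth$de_genes$cell_type == "endothelial", ]
  m <- merge(de, truth, by = "gene")
  strong <- abs(m$true_log2fc) >= 2
  expect_gte(mean(m$significant[strong]), 0.9)
  expect_true(all(sign(m$log2fc[m$significant]) ==
                    sign(m$true_log2fc[m$significant])))
  # parameter recovery at the study's group sizes (11 vs 20 cells)
  idx1 <- which(sel & types$genotype == "control")[1:11]
  idx2 <- which(sel & types$genotype == "knockout")[1:20]
  de_small <- differential_expression(expr[, c(idx1, idx2)],
                                      rep(c("control", "knockout"),
                                          c(11, 20)),
                                      "control", "knockout")
  ms <- merge(de_small, truth, by = "gene")
  expect_lte(median(abs(ms$log2fc - ms$true_log2fc)), 0.5)
})

test_that("hypergeometric tail equals the exhaustive tail-sum oracle", {
  # brute-force oracle: exact combinatorial tail sum
  tail_oracle <- function(k, K, N, n) {
    i <- k:min(K, n)
    if (length(i) == 0 || k > min(K, n)) return(0)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
  }
  max_err <- 0
  for (N in c(5, 10, 18, 25)) for (K in 0:N) for (n in c(0, 1, N %/% 2, N)) {
    for (k in 0:min(K, n)) {
      p_pkg <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      max_err <- max(max_err, abs(p_pkg - tail_oracle(k, K, N, n)))
    }
  }
  expect_lt(max_err, 1e-12)
  # enrichment record construction and reporting criteria
  universe <- paste0("g", 1:40)
  sets <- list(hit = paste0("g", 1:8), tiny = paste0("g", 1:4),
               off = paste0("g", 30:40))
  enr <- hypergeometric_enrichment(paste0("g", 1:8), sets, universe)
  hit <- enr[enr$set_name == "hit", ]
  expect_equal(hit$overlap_k, 8)
  expect_equal(hit$p_value, tail_oracle(8, 8, 40, 8), tolerance = 1e-12)
  expect_true(hit$reported)
  # overlap below 5 is never reported, however small the p-value
  tiny <- enr[enr$set_name == "tiny", ]
  expect_equal(tiny$overlap_k, 4)
  expect_lt(tiny$p_value, 0.01)
  expect_false(tiny$reported)
  # k = 0 -> p = 1
  expect_equal(enr$p_value[enr$set_name == "off"], 1)
  expect_error(hypergeometric_enrichment(character(0), sets, universe),
               "non-empty")
  expect_error(hypergeometric_enrichment("zz", sets, universe), "subset")
})

test_that("panel screening intersects significant DEG with panels", {
  de <- tibble::tibble(gene = c("A", "B", "C"),
                       log2fc = c(2, -3, 0.2),
                       p_value = c(0.001, 0.002, 0.8),
                       significant = c(TRUE, TRUE, FALSE),
                       converged = TRUE, pct_1 = 1, pct_2 = 1)
  hits <- panel_screen(de, list(apoptosis = c("B", "C", "D")))
  expect_equal(hits$gene, "B")
  expect_equal(hits$direction, "down_in_group1")
  expect_equal(nrow(panel_screen(de, list(wnt = c("X", "Y")))), 0)
  expect_warning(panel_screen(de, list(empty = character(0))), "empty")
})

test_that("GMT files round-trip through read and write", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g9"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[order(names(back))], sets[order(names(sets))])
})

test_that("MTX round trip preserves counts and annotations", {
  dir <- tempfile()
  write_counts_mtx(gen1$counts, dir)
  back <- read_counts_mtx(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"))
  expect_equal(unname(as.matrix(back$counts)),
               unname(as.matrix(gen1$counts$counts)))
  expect_equal(back$cells$genotype, gen1$counts$cells$genotype)
})
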