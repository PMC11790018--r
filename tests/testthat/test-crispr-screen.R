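# small hand-checkable screen: 1 target gene (2 guides), 1 essential
# control (2 guides), 1 nontargeting gene (2 guides)
toy_library <- data.frame(
  guide_id = c("A_sg1", "A_sg2", "E_sg1", "E_sg2", "N_sg1", "N_sg2"),
  gene = c("A", "A", "E", "E", "N", "N"),
  role = c("target", "target", "essential_control", "essential_control",
           "nontargeting_control", "nontargeting_control"),
  stringsAsFactors = FALSE)

toy_samples <- data.frame(
  sample_id = c("ref", "CL1_rep1"),
  cell_line = c("plasmid", "CL1"),
  timepoint = c("day0_reference", "endpoint"),
  replicate = c(1L, 1L), stringsAsFactors = FALSE)

# build a log2 abundance matrix whose endpoint-minus-reference LFCs are
# exactly `lfc`
toy_norm <- function(lfc) {
  m <- cbind(ref = rep(10, 6), CL1_rep1 = 10 + lfc)
  rownames(m) <- toy_library$guide_id
  m
}

test_that("normalization is scale invariant and hand-checkable", {
  counts <- matrix(c(10L, 30L, 20L, 60L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_counts(counts)
  expect_equal(norm[, "s1"], norm[, "s2"])
  # toy without per-million scaling: counts (0, 99), pseudocount 1
  norm2 <- normalize_counts(matrix(c(0L, 99L), ncol = 1,
                                   dimnames = list(c("a", "b"), "s")),
                            per_million = FALSE)
  expect_equal(unname(norm2[, 1]), c(0, log2(100)))
  expect_equal(norm2["b", 1], 6.643856, tolerance = 1e-6)
  # all-equal counts normalize to a constant column
  norm3 <- normalize_counts(matrix(5L, 3, 2))
  expect_true(diff(range(norm3)) == 0)
  expect_error(normalize_counts(matrix(c(0L, 0L, 1L, 1L), 2,
                                       dimnames = list(NULL, c("z", "ok")))),
               "z")
})

test_that("beta scores reproduce the hand-computed median + anchor", {
  # gene A guides at LFC -2 and -1 -> median -1.5; NT median 0,
  # essential median -1 -> beta(A) = -1.5
  norm <- toy_norm(c(-2, -1, -1, -1, 0, 0))
  bt <- compute_beta_scores(norm, toy_library, toy_samples)
  expect_equal(bt$beta["A", "CL1"], -1.5)
  expect_equal(bt$beta["N", "CL1"], 0)
  expect_equal(bt$beta["E", "CL1"], -1)
})

test_that("anchoring is exact for every cell line of a cohort", {
  co <- generate_cohort(tiny_config(seed = 21))
  bt <- compute_beta_scores(normalize_counts(co$screen),
                            co$screen$library, co$screen$samples)
  nt <- unique(co$screen$library$gene[
    co$screen$library$role == "nontargeting_control"])
  ess <- unique(co$screen$library$gene[
    co$screen$library$role == "essential_control"])
  for (cl in colnames(bt$beta)) {
    expect_lt(abs(median(bt$beta[nt, cl])), 1e-9)
    expect_lt(abs(median(bt$beta[ess, cl]) + 1), 1e-9)
  }
})

test_that("beta scores are invariant to per-sample count scaling", {
  co <- generate_cohort(tiny_config(seed = 22))
  b1 <- compute_beta_scores(normalize_counts(co$screen),
                            co$screen$library, co$screen$samples)
  counts2 <- co$screen$counts
  counts2[, 3] <- counts2[, 3] * 7L
  b2 <- compute_beta_scores(normalize_counts(counts2),
                            co$screen$library, co$screen$samples)
  expect_equal(b1$beta, b2$beta, tolerance = 1e-12)
})

test_that("a null endpoint gives beta 0 once essentials are planted", {
  # endpoint == reference except essentials depleted by 1
  norm <- toy_norm(c(0, 0, -1, -1, 0, 0))
  bt <- compute_beta_scores(norm, toy_library, toy_samples)
  expect_equal(unname(bt$beta["A", "CL1"]), 0)
  # degenerate anchoring: essentials indistinguishable from NT
  expect_error(compute_beta_scores(toy_norm(rep(0, 6)), toy_library,
                                   toy_samples),
               "degenerate")
})

test_that("replicate QC matches closed-form Pearson and flags breakage", {
  counts <- cbind(r1 = c(100L, 220L, 80L, 400L),
                  r2 = c(110L, 210L, 90L, 380L))
  rownames(counts) <- paste0("g", 1:4)
  samples <- data.frame(sample_id = c("r1", "r2"), cell_line = "CL1",
                        timepoint = "endpoint", replicate = 1:2)
  qc <- qc_screen(counts, samples)
  ln <- normalize_counts(counts)
  expect_equal(qc$replicate_correlations$pearson_r,
               pearson_oracle(ln[, 1], ln[, 2]), tolerance = 1e-12)
  # identical replicates: r = 1
  qc2 <- qc_screen(cbind(counts[, 1, drop = FALSE],
                         r2 = counts[, 1]), samples)
  expect_equal(qc2$replicate_correlations$pearson_r, 1)
  expect_true(qc2$pass)
  # single replicate: warning, representation still reported
  expect_warning(
    qc3 <- qc_screen(counts[, 1, drop = FALSE], samples[1, ],
                     count_floor = 90),
    "replicates")
  expect_equal(qc3$representation$frac_represented, 0.75)
})

test_that("a shuffled replicate decorrelates and fails QC", {
  co <- generate_cohort(tiny_config(seed = 23))
  counts <- co$screen$counts
  ep <- which(co$screen$samples$timepoint == "endpoint")[1:2]
  set.seed(1)
  counts[, ep[2]] <- sample(counts[, ep[2]])
  qc <- qc_screen(counts, co$screen$samples)
  line <- co$screen$samples$cell_line[ep[1]]
  r_broken <- qc$replicate_correlations$pearson_r[
    qc$replicate_correlations$cell_line == line]
  expect_lt(abs(r_broken), 0.2)
  expect_false(qc$pass)
})

test_that("hit calling is boundary inclusive at tau", {
  b <- matrix(c(-0.92, 0, -0.5, -0.49), nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"), "CL1"))
  h <- call_hits(b)
  expect_identical(unname(h[, 1]), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("differential dependency matches the closed-form t oracle", {
  b <- rbind(gA = c(0, 0.1, -0.1, -1, -0.9, -1.1),
             gB = c(0.2, 0.1, 0.3, 0.25, 0.15, 0.2))
  colnames(b) <- paste0("c", 1:6)
  groups <- setNames(rep(c("adult", "pediatric"), each = 3),
                     colnames(b))
  dd <- differential_dependency(b, groups)
  orc <- t_oracle(b["gA", 1:3], b["gA", 4:6])
  row <- dd[dd$gene == "gA", ]
  expect_equal(row$t_stat, orc$t, tolerance = 1e-12)
  expect_equal(row$p_value, orc$p, tolerance = 1e-12)
  expect_equal(row$delta, 1)
  expect_equal(dd$fdr, bh_oracle(dd$p_value), tolerance = 1e-12)
  expect_true(all(dd$fdr >= dd$p_value - 1e-12))
})

test_that("identical group distributions yield delta 0 and no call", {
  b <- rbind(gA = c(1, 2, 3, 1, 2, 3))
  colnames(b) <- paste0("c", 1:6)
  groups <- setNames(rep(c("adult", "pediatric"), each = 3), colnames(b))
  dd <- differential_dependency(b, groups)
  expect_equal(dd$delta, 0)
  expect_identical(dd$call, "none")
  # zero variance in both groups: flagged, p = 1, no exception
  b0 <- rbind(gz = rep(0, 6))
  colnames(b0) <- colnames(b)
  dd0 <- differential_dependency(b0, groups)
  expect_true(dd0$zero_variance)
  expect_equal(dd0$p_value, 1)
})

test_that("specificity calls respect the delta and FDR gates", {
  set.seed(42)
  n_gene <- 40
  b <- matrix(rnorm(n_gene * 20, 0, 0.05), nrow = n_gene,
              dimnames = list(sprintf("g%02d", 1:n_gene),
                              sprintf("c%02d", 1:20)))
  groups <- setNames(rep(c("adult", "pediatric"), each = 10),
                     colnames(b))
  b["g01", groups == "pediatric"] <- b["g01", groups == "pediatric"] - 0.74
  b["g02", groups == "adult"] <- b["g02", groups == "adult"] - 0.74
  b["g03", groups == "pediatric"] <- b["g03", groups == "pediatric"] - 0.05
  dd <- differential_dependency(b, groups)
  expect_identical(dd$call[dd$gene == "g01"], "pediatric_specific")
  expect_identical(dd$call[dd$gene == "g02"], "adult_specific")
  expect_identical(dd$call[dd$gene == "g03"], "none")  # below delta gate
})

test_that("BH adjustment equals the step-up oracle on random p-values", {
  set.seed(7)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("prevalence summary reproduces printed-count arithmetic", {
  h <- setNames(c(rep(TRUE, 49), rep(FALSE, 16), TRUE, rep(FALSE, 9)),
                sprintf("c%02d", 1:75))
  groups <- setNames(rep(c("pediatric", "adult"), c(65, 10)), names(h))
  pr <- dependency_prevalence(h, groups)
  expect_equal(pr$summary$percent, c(75, 10))
  expect_lt(pr$p_value, 0.001)
  # balanced table: p = 1
  h2 <- setNames(c(TRUE, FALSE, TRUE, FALSE), paste0("c", 1:4))
  g2 <- setNames(rep(c("a", "b"), each = 2), names(h2))
  expect_equal(dependency_prevalence(h2, g2)$p_value, 1)
  # [[3,0],[0,3]] enumerates to exactly 0.1 (2 x 1/20)
  h3 <- setNames(rep(c(TRUE, FALSE), each = 3), paste0("c", 1:6))
  g3 <- setNames(rep(c("a", "b"), each = 3), names(h3))
  expect_equal(dependency_prevalence(h3, g3)$p_value, 0.1,
               tolerance = 1e-12)
})

test_that("gene ranking orders by depletion with lexicographic ties", {
  b <- matrix(c(-2, -1, 0), nrow = 3,
              dimnames = list(c("g3", "g1", "g2"), "CL1"))
  rg <- rank_genes(b, "CL1")
  expect_identical(rg$gene, c("g3", "g1", "g2"))
  expect_identical(rg$rank, 1:3)
  b2 <- matrix(rep(0, 3), nrow = 3,
               dimnames = list(c("gb", "ga", "gc"), "CL1"))
  expect_identical(rank_genes(b2, "CL1")$gene, c("ga", "gb", "gc"))
  expect_error(rank_genes(b, "nope"), "unknown cell line")
})

test_that("the planted marker ranks first among targets when methylated", {
  co <- generate_cohort(tiny_config(seed = 24))
  bt <- compute_beta_scores(normalize_counts(co$screen),
                            co$screen$library, co$screen$samples)
  meth_lines <- names(co$truth$states)[co$truth$states == 1]
  top <- vapply(meth_lines, function(cl) rank_genes(bt, cl)$gene[1],
                character(1))
  expect_gte(mean(top == "MCL1"), 0.8)
})
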