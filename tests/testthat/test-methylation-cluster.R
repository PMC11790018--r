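test_that("locus restriction preserves order and partitions the matrix", {
  co <- generate_cohort(tiny_config(seed = 51))
  sub <- locus_submatrix(co$methylation, "BCL2L1")
  expect_equal(nrow(sub$beta), 44)
  expect_identical(rownames(sub$beta), rownames(co$methylation$beta)[1:44])
  bg <- locus_submatrix(co$methylation, "background")
  expect_identical(rbind(sub$beta, bg$beta), co$methylation$beta)
  expect_error(locus_submatrix(co$methylation, "nope"), "BCL2L1")
})

test_that("the planted co-methylated block is recovered exactly", {
  for (s in 1:5) {
    co <- generate_cohort(truth_config(n_background_cpgs = 5,
                                       n_genes_expression = 5,
                                       seed = 500 + s))
    sub <- locus_submatrix(co$methylation, "BCL2L1")
    cl <- cluster_cpg_sites(sub)
    truth_members <- names(co$truth$cluster_members)[
      co$truth$cluster_members]
    got <- cl$assignment$cluster[match(truth_members,
                                       cl$assignment$cpg)]
    expect_equal(length(unique(got)), 1)       # one shared label
    label <- unique(got)
    in_label <- cl$assignment$cpg[cl$assignment$cluster == label]
    expect_setequal(in_label, truth_members)   # and nothing else
  }
})

test_that("identical rows form a single cluster", {
  m <- matrix(rep(c(0.2, 0.8, 0.5, 0.6), times = 4), nrow = 4,
              byrow = TRUE,
              dimnames = list(paste0("cg", 1:4), paste0("s", 1:4)))
  cl <- cluster_cpg_sites(m)
  expect_equal(length(unique(cl$assignment$cluster)), 1)
})

test_that("the uniformly low block is flagged and excluded", {
  co <- generate_cohort(truth_config(n_background_cpgs = 5,
                                     n_genes_expression = 5, seed = 52))
  sub <- locus_submatrix(co$methylation, "BCL2L1")
  cl <- cluster_cpg_sites(sub)
  cfg <- co$truth$config
  low_ids <- rownames(sub$beta)[seq(cfg$cluster_size + 1,
                                    cfg$cluster_size + cfg$n_low_block)]
  low_rows <- cl$assignment[cl$assignment$cpg %in% low_ids, ]
  expect_true(all(!low_rows$candidate))
  expect_true(length(cl$low_clusters) >= 1)
})

test_that("clustering is invariant to row and sample permutations", {
  co <- generate_cohort(tiny_config(seed = 53))
  sub <- locus_submatrix(co$methylation, "BCL2L1")
  cl1 <- cluster_cpg_sites(sub)
  set.seed(1)
  perm_r <- sample(nrow(sub$beta))
  perm_c <- sample(ncol(sub$beta))
  cl2 <- cluster_cpg_sites(sub$beta[perm_r, perm_c])
  # same partition: compare co-membership of all pairs
  lab1 <- setNames(cl1$assignment$cluster, cl1$assignment$cpg)
  lab2 <- setNames(cl2$assignment$cluster, cl2$assignment$cpg)
  ids <- names(lab1)
  co1 <- outer(lab1[ids], lab1[ids], "==")
  co2 <- outer(lab2[ids], lab2[ids], "==")
  expect_identical(co1, co2)
})

test_that("constant CpG rows are tolerated with zeroed correlations", {
  m <- rbind(a = c(0.1, 0.2, 0.3, 0.4), b = c(0.12, 0.21, 0.33, 0.4),
             z = rep(0.5, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_message(cl <- cluster_cpg_sites(m), "constant")
  expect_equal(nrow(cl$assignment), 3)
})

test_that("response waterfall puts planted cluster sites first", {
  hit <- logical(10)
  for (s in 1:10) {
    co <- generate_cohort(truth_config(n_background_cpgs = 5,
                                       n_genes_expression = 5,
                                       seed = 600 + s))
    dd <- summarize_dose_response(co$dose_response)
    response <- setNames(dd$auc_raw, dd$cell_line)
    sub <- locus_submatrix(co$methylation, "BCL2L1")
    wf <- correlate_sites_with_response(sub, response)
    members <- names(co$truth$cluster_members)[co$truth$cluster_members]
    hit[s] <- all(wf$feature[1:10] %in% members)
  }
  expect_gte(mean(hit), 0.8)
})

test_that("a shuffled response removes cluster enrichment", {
  ps <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(tiny_config(seed = 700 + s))
    dd <- summarize_dose_response(co$dose_response)
    set.seed(s)
    response <- setNames(sample(dd$auc_raw), dd$cell_line)
    sub <- locus_submatrix(co$methylation, "BCL2L1")
    wf <- correlate_sites_with_response(sub, response)
    members <- names(co$truth$cluster_members)[co$truth$cluster_members]
    pos <- match(members, wf$feature)
    ps[s] <- wilcox.test(pos, setdiff(seq_len(nrow(wf)), pos))$p.value
  }
  expect_gt(mean(ps), 0.05)
})

test_that("a site equal to minus the response leads the waterfall", {
  set.seed(2)
  resp <- setNames(runif(10), paste0("s", 1:10))
  m <- rbind(anti = 1 - (resp - min(resp)) / diff(range(resp)),
             noise = runif(10))
  colnames(m) <- names(resp)
  wf <- correlate_sites_with_response(m, resp)
  expect_identical(wf$feature[1], "anti")
  expect_equal(wf$pearson_r[1], -1, tolerance = 1e-12)
})

test_that("binarization is boundary inclusive and validated", {
  expect_identical(unname(binarize_methylation(c(0.5, 0, 1, 0.49))),
                   c("methylated", "unmethylated", "methylated",
                     "unmethylated"))
  expect_identical(unname(binarize_methylation(c(0.2, 0.9), cutoff = 0)),
                   c("methylated", "methylated"))
  expect_error(binarize_methylation(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher 2x2 matches exhaustive enumeration up to N = 200", {
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(0:50, 4, replace = TRUE), nrow = 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    ft <- fisher_exact_2x2(tab)
    expect_equal(ft$p_value, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(ft$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # transpose sanity
    expect_equal(fisher_exact_2x2(t(tab))$p_value, ft$p_value,
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)
  f <- fisher_exact_2x2(matrix(c(49, 1, 16, 9), 2))
  expect_lt(f$p_value, 0.001)
  expect_equal(f$odds_ratio, 49 * 9 / 16, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               "nonnegative")
})

test_that("threshold scanning recovers the planted 0.5 cutoff", {
  chosen <- numeric(10)
  for (s in 1:10) {
    co <- generate_cohort(truth_config(n_background_cpgs = 5,
                                       n_genes_expression = 5,
                                       seed = 800 + s))
    dd <- summarize_dose_response(co$dose_response)
    labels <- setNames(dd$label, dd$cell_line)
    beta <- co$methylation$beta[co$truth$exemplar_cpg, ]
    chosen[s] <- scan_threshold(beta, labels)$chosen
  }
  expect_gte(mean(chosen == 0.5), 0.8)
})

test_that("single-candidate scans equal a direct Fisher test", {
  set.seed(4)
  beta <- setNames(runif(30), paste0("s", 1:30))
  labels <- setNames(sample(c("sensitive", "resistant"), 30,
                            replace = TRUE), names(beta))
  sc <- scan_threshold(beta, labels, candidates = 0.4)
  m <- factor(binarize_methylation(beta, 0.4),
              levels = c("methylated", "unmethylated"))
  tab <- table(m, factor(labels, levels = c("sensitive", "resistant")))
  expect_equal(sc$scan$p_value, fisher_exact_2x2(tab)$p_value,
               tolerance = 1e-12)
  expect_equal(sc$chosen, 0.4)
})

test_that("degenerate scans fall back to the smallest candidate", {
  beta <- setNames(rep(0.95, 10), paste0("s", 1:10))
  labels <- setNames(rep(c("sensitive", "resistant"), 5), names(beta))
  sc <- scan_threshold(beta, labels)
  expect_true(all(sc$scan$p_value == 1))
  expect_equal(sc$chosen, 0.1)
  expect_error(scan_threshold(beta, setNames(rep("sensitive", 10),
                                             names(beta))),
               "response class")
})

test_that("age-group methylation summary has power at a planted shift", {
  sig <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    n_ped <- 36; n_ad <- 182
    ids <- sprintf("s%03d", 1:(n_ped + n_ad))
    ages <- setNames(c(runif(n_ped, 3, 20), runif(n_ad, 22, 90)), ids)
    base <- matrix(runif(20 * length(ids), 0.2, 0.6), nrow = 20,
                   dimnames = list(sprintf("cg%02d", 1:20), ids))
    base[1:5, ages >= 21] <- base[1:5, ages >= 21] + 0.2
    out <- summarize_age_methylation(base, sprintf("cg%02d", 1:5), ages)
    sig <- sig + (out$p_value < 0.001)
  }
  expect_gte(sig, 9)
})

test_that("age summary nulls, statistics and degenerate input behave", {
  set.seed(5)
  ids <- sprintf("s%02d", 1:40)
  ages <- setNames(c(runif(20, 3, 20), runif(20, 22, 90)), ids)
  m <- matrix(runif(10 * 40), nrow = 10,
              dimnames = list(sprintf("cg%02d", 1:10), ids))
  out <- summarize_age_methylation(m, rownames(m)[1:3], ages)
  expect_gt(out$p_value, 1e-4)  # no planted shift
  gm <- summarize_age_methylation(m, ages = ages,
                                  statistic = "global_median")
  expect_equal(gm$per_sample$value,
               unname(apply(m, 2, median)))
  expect_error(summarize_age_methylation(m, character(0), ages),
               "site_set")
  ages2 <- setNames(c(10, rep(30, 39)), ids)
  expect_error(summarize_age_methylation(m, rownames(m)[1], ages2),
               ">= 2")
})
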