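# Locus-level CpG correlation clustering, binarization, exact-test
# cutoff scanning and age-group methylation summaries.

#' Restrict a methylation matrix to one locus
#'
#' @param meth A `methylation_matrix` (list with `beta` and `anno`) or a
#'   beta matrix accompanied by `anno`.
#' @param locus Locus name to keep (row order preserved).
#' @param anno Per-CpG annotation when `meth` is a plain matrix.
#' @return A `methylation_matrix` restricted to the locus.
#' @export
locus_submatrix <- function(meth, locus, anno = NULL) {
  if (inherits(meth, "methylation_matrix")) {
    anno <- meth$anno
    beta <- meth$beta
    cluster <- meth$cluster
  } else {
    beta <- meth
    cluster <- rep(NA, nrow(beta))
  }
  if (is.null(anno)) stop("per-CpG annotation required", call. = FALSE)
  keep <- anno$locus == locus
  if (!any(keep))
    stop("locus '", locus, "' not found; available: ",
         paste(unique(anno$locus), collapse = ", "), call. = FALSE)
  structure(list(beta = beta[keep, , drop = FALSE],
                 anno = anno[keep, , drop = FALSE],
                 cluster = cluster[keep]),
            class = "methylation_matrix")
}

#' Cluster CpG sites by correlation of their beta-values
#'
#' Computes the pairwise Pearson correlation of CpG rows, converts to the
#' distance 1 - r, and cuts an agglomerative tree (default average
#' linkage) at `cut_height`. Clusters whose mean beta is below
#' `low_mean` are flagged uniformly lowly methylated and excluded from
#' biomarker candidacy.
#'
#' @param sub A `methylation_matrix` (typically a locus submatrix) or
#'   CpG x sample beta matrix.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param cut_height Tree cut height on the 1 - r scale (default 0.5).
#' @param low_mean Mean-beta threshold flagging a low-methylation
#'   cluster (default 0.1).
#' @return List with `assignment` (data.frame cpg, cluster, candidate),
#'   `cluster_means` and `low_clusters`.
#' @export
cluster_cpg_sites <- function(sub, linkage = "average", cut_height = 0.5,
                              low_mean = 0.1) {
  beta <- if (inherits(sub, "methylation_matrix")) sub$beta else sub
  if (nrow(beta) < 2 || ncol(beta) < 3)
    stop("need >= 2 CpGs and >= 3 samples", call. = FALSE)
  sds <- apply(beta, 1, stats::sd)
  if (any(sds < 1e-12))
    message("constant CpG row(s); their correlations set to 0: ",
            paste(rownames(beta)[sds < 1e-12], collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(beta)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  means <- tapply(rowMeans(beta), cl, mean)
  low <- as.integer(names(means)[means < low_mean])
  assignment <- data.frame(cpg = rownames(beta), cluster = unname(cl),
                           candidate = !(cl %in% low),
                           stringsAsFactors = FALSE)
  list(assignment = assignment,
       cluster_means = data.frame(cluster = as.integer(names(means)),
                                  mean_beta = as.numeric(means),
                                  low_methylation =
                                    as.integer(names(means)) %in% low),
       low_clusters = low, tree = hc)
}

#' Waterfall of per-CpG correlation with drug response
#'
#' Pearson correlation of each CpG's beta-values with the response
#' (e.g. drug AUC), ordered by signed r ascending so the strongest
#' sensitivity association (most negative r) comes first.
#'
#' @param sub A `methylation_matrix` or beta matrix (CpGs x samples).
#' @param response Named numeric response vector aligned to samples.
#' @return data.frame (feature, pearson_r, p_value, bh_fdr,
#'   zero_variance) in waterfall order.
#' @export
correlate_sites_with_response <- function(sub, response) {
  beta <- if (inherits(sub, "methylation_matrix")) sub$beta else sub
  sc <- single_correlate(t(beta), response)
  sc[order(sc$pearson_r), ]
}

#' Binarize beta-values into methylated / unmethylated
#'
#' Methylated when beta >= cutoff (boundary inclusive).
#'
#' @param beta Numeric beta-values in [0, 1].
#' @param cutoff Binarization cutoff (default 0.5).
#' @return Character vector "methylated"/"unmethylated", names kept.
#' @export
binarize_methylation <- function(beta, cutoff = 0.5) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  out <- ifelse(beta >= cutoff, "methylated", "unmethylated")
  names(out) <- names(beta)
  out
}

#' Scan binarization cutoffs by Fisher's exact test
#'
#' For each candidate cutoff, binarizes the beta-values, builds the 2x2
#' methylation-by-response table and computes the two-sided exact p and
#' odds ratio. Degenerate cutoffs (all samples on one side) are recorded
#' with p = 1. The chosen cutoff minimizes p; ties go to the smallest
#' cutoff. P-values are reported uncorrected: the scan selects over
#' cutoffs and is exploratory.
#'
#' @param beta Per-sample beta-values (named).
#' @param labels Per-sample response class, "sensitive"/"resistant".
#' @param candidates Cutoff grid (default 0.1 to 0.9 step 0.1).
#' @return A `threshold_scan`: list with `scan` (per-cutoff table counts,
#'   p, odds ratio, degenerate flag) and `chosen` cutoff.
#' @export
scan_threshold <- function(beta, labels,
                           candidates = seq(0.1, 0.9, by = 0.1)) {
  if (length(candidates) == 0) stop("empty candidate grid", call. = FALSE)
  if (!is.null(names(beta)) && !is.null(names(labels)))
    labels <- labels[names(beta)]
  if (length(labels) != length(beta))
    stop("'labels' must align with 'beta'", call. = FALSE)
  lab <- factor(labels, levels = c("sensitive", "resistant"))
  if (anyNA(lab)) stop("labels must be 'sensitive'/'resistant'",
                       call. = FALSE)
  if (length(unique(lab)) < 2 || min(table(lab)) < 2)
    stop("need >= 2 samples in each response class", call. = FALSE)
  rows <- lapply(sort(candidates), function(cc) {
    m <- factor(binarize_methylation(beta, cc),
                levels = c("methylated", "unmethylated"))
    tab <- table(m, lab)
    degenerate <- any(rowSums(tab) == 0)
    ft <- if (degenerate) list(p_value = 1, odds_ratio = NA_real_)
          else fisher_exact_2x2(tab)
    data.frame(cutoff = cc, n_meth_sens = tab[1, 1],
               n_meth_res = tab[1, 2], n_unmeth_sens = tab[2, 1],
               n_unmeth_res = tab[2, 2], p_value = ft$p_value,
               odds_ratio = ft$odds_ratio, degenerate = degenerate)
  })
  scan <- do.call(rbind, rows)
  chosen <- scan$cutoff[which.min(scan$p_value)]  # first minimum: smallest
  structure(list(scan = scan, chosen = chosen,
                 note = "p-values uncorrected for selection over cutoffs"),
            class = "threshold_scan")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins; the two-sided p-value is
#' the sum of probabilities of all tables whose point probability does
#' not exceed the observed one (probability-mass convention). The odds
#' ratio is the sample cross-product (a*d)/(b*c).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with `p_value`, `odds_ratio` (NA with a flag when 0/0).
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(tab) == 0) stop("grand total must be positive", call. = FALSE)
  a <- tab[1, 1]
  m <- sum(tab[, 1])           # column-1 total
  n2 <- sum(tab[, 2])
  k <- sum(tab[1, ])           # row-1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (tab[1, 2] * tab[2, 1] == 0) {
    if (tab[1, 1] * tab[2, 2] == 0) NA_real_ else Inf
  } else tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or,
       odds_ratio_undefined = is.na(or))
}

#' Age-group methylation summary and test
#'
#' Per-sample summary statistic (mean beta over a site set, or the
#' median beta over all CpGs), split into pediatric (< age cutoff) and
#' adult groups and compared by an unpaired two-sided t-test.
#'
#' @param meth A `methylation_matrix` or beta matrix.
#' @param site_set CpG ids for `mean_over_sites` (ignored for
#'   `global_median`).
#' @param ages Named numeric ages aligned to samples.
#' @param age_cutoff Pediatric/adult split (default 21; pediatric <
#'   cutoff).
#' @param statistic `"mean_over_sites"` or `"global_median"`.
#' @param welch Use Welch's t-test (default Student's).
#' @return List with `per_sample` (data.frame sample, value, group),
#'   `group_means`, `t_stat`, `p_value`.
#' @export
summarize_age_methylation <- function(meth, site_set = NULL, ages,
                                      age_cutoff = 21,
                                      statistic = c("mean_over_sites",
                                                    "global_median"),
                                      welch = FALSE) {
  statistic <- match.arg(statistic)
  beta <- if (inherits(meth, "methylation_matrix")) meth$beta else meth
  ages <- ages[colnames(beta)]
  if (anyNA(ages)) stop("age missing for some samples", call. = FALSE)
  value <- if (statistic == "mean_over_sites") {
    if (is.null(site_set) || length(site_set) == 0)
      stop("empty site_set", call. = FALSE)
    if (!all(site_set %in% rownames(beta)))
      stop("site_set contains unknown CpGs", call. = FALSE)
    colMeans(beta[site_set, , drop = FALSE])
  } else {
    apply(beta, 2, stats::median)
  }
  group <- ifelse(ages < age_cutoff, "pediatric", "adult")
  if (length(unique(group)) < 2 || min(table(group)) < 2)
    stop("both age groups need >= 2 samples for the t-test",
         call. = FALSE)
  tt <- stats::t.test(value[group == "adult"],
                      value[group == "pediatric"], var.equal = !welch)
  list(per_sample = data.frame(sample_id = colnames(beta), value = value,
                               group = group, row.names = NULL,
                               stringsAsFactors = FALSE),
       group_means = tapply(value, group, mean),
       t_stat = unname(tt$statistic), p_value = tt$p.value)
}
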