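# Guide counts -> gene-level dependency (beta) scores and cohort tests.
#
# The estimator compares endpoint sgRNA representation with the day-0
# plasmid reference: per-guide log2 fold-change averaged over replicates,
# gene score = median across the gene's guides, then an affine anchoring
# per cell line so the nontargeting-control median sits at 0 and the
# core-essential-control median at -1. More negative = stronger growth
# dependency.

#' Library-size normalize and log-transform guide counts
#'
#' Scales every sample to equal total (counts per million by default),
#' adds a pseudocount and takes log2.
#'
#' @param counts A `count_matrix` (see [generate_screen_counts()]) or a
#'   guide x sample nonnegative integer matrix.
#' @param pseudocount Added before the log (default 1).
#' @param per_million Scale each sample to 1e6 total before the log;
#'   disable for hand-checkable toys.
#' @return Matrix of log2 normalized abundances (guides x samples).
#' @export
normalize_counts <- function(counts, pseudocount = 1, per_million = TRUE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  if (per_million) m <- sweep(m, 2, 1e6 / tot, "*")
  log2(m + pseudocount)
}

#' Compute anchored gene-level dependency (beta) scores
#'
#' Per-guide log2 fold-change of endpoint vs the day-0 reference (mean of
#' reference samples), averaged over endpoint replicates within each cell
#' line; the gene score is the median across its guides. Scores are then
#' affinely anchored per cell line so the median nontargeting-gene score
#' is 0 and the median essential-control-gene score is -1.
#'
#' @param norm Log2 normalized abundance matrix from [normalize_counts()].
#' @param library Guide manifest (guide_id, gene, role).
#' @param samples Sample metadata (sample_id, cell_line, timepoint,
#'   replicate); timepoint `day0_reference` marks the reference.
#' @return A `beta_score_table`: list with `beta` (gene x cell-line
#'   matrix, controls included) and `scaling` (per-line nontargeting and
#'   essential centers on the raw LFC scale).
#' @export
compute_beta_scores <- function(norm, library, samples) {
  if (!all(library$guide_id %in% rownames(norm)))
    stop("count matrix is missing library guides", call. = FALSE)
  norm <- norm[library$guide_id, , drop = FALSE]
  ref_ids <- samples$sample_id[samples$timepoint == "day0_reference"]
  if (length(ref_ids) == 0)
    stop("no day0_reference sample available", call. = FALSE)
  ref <- rowMeans(norm[, ref_ids, drop = FALSE])
  endpoints <- samples[samples$timepoint == "endpoint", , drop = FALSE]
  lines <- unique(endpoints$cell_line)
  genes <- unique(library$gene)
  gidx <- split(seq_len(nrow(library)), library$gene)[genes]
  nt_genes <- unique(library$gene[library$role == "nontargeting_control"])
  ess_genes <- unique(library$gene[library$role == "essential_control"])
  beta <- matrix(NA_real_, nrow = length(genes), ncol = length(lines),
                 dimnames = list(genes, lines))
  scaling <- data.frame(cell_line = lines, nt_center = NA_real_,
                        ess_center = NA_real_)
  for (i in seq_along(lines)) {
    sm <- endpoints$sample_id[endpoints$cell_line == lines[i]]
    lfc <- rowMeans(norm[, sm, drop = FALSE]) - ref
    raw <- vapply(gidx, function(ix) stats::median(lfc[ix]), numeric(1))
    m_nt <- stats::median(raw[nt_genes])
    m_ess <- stats::median(raw[ess_genes])
    if (abs(m_ess - m_nt) < 1e-12)
      stop("degenerate anchoring in cell line ", lines[i],
           ": essential and nontargeting medians coincide", call. = FALSE)
    beta[, i] <- (raw - m_nt) / (m_nt - m_ess)
    scaling$nt_center[i] <- m_nt
    scaling$ess_center[i] <- m_ess
  }
  structure(list(beta = beta, scaling = scaling,
                 roles = stats::setNames(
                   library$role[!duplicated(library$gene)], genes)),
            class = "beta_score_table")
}

#' Screen quality control: replicate correlation and representation
#'
#' Pearson correlation of log-normalized guide counts between endpoint
#' replicate pairs within each cell line, and the fraction of guides at or
#' above a count floor per sample. The screen passes when every replicate
#' pair correlates above `min_correlation`.
#'
#' @param counts A `count_matrix` or raw guide x sample matrix.
#' @param samples Sample metadata; taken from `counts` when absent.
#' @param count_floor Representation floor (default 30 reads).
#' @param min_correlation Replicate-pair pass threshold (default 0.5).
#' @return List with `replicate_correlations` (data.frame), `representation`
#'   (per-sample fraction of guides >= floor) and `pass`.
#' @export
qc_screen <- function(counts, samples = NULL, count_floor = 30,
                      min_correlation = 0.5) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(samples)) samples <- counts$samples
    counts <- counts$counts
  }
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(counts),
                          cell_line = colnames(counts),
                          timepoint = "endpoint", replicate = 1L)
  lognorm <- normalize_counts(counts)
  rep_tab <- samples[samples$timepoint == "endpoint", , drop = FALSE]
  pairs <- do.call(rbind, lapply(split(rep_tab, rep_tab$cell_line),
                                 function(d) {
    if (nrow(d) < 2) return(NULL)
    cmb <- utils::combn(d$sample_id, 2)
    data.frame(cell_line = d$cell_line[1], sample_a = cmb[1, ],
               sample_b = cmb[2, ],
               pearson_r = apply(cmb, 2, function(p)
                 stats::cor(lognorm[, p[1]], lognorm[, p[2]])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    warning("no cell line has >= 2 replicates; replicate correlations ",
            "omitted")
    pairs <- data.frame(cell_line = character(), sample_a = character(),
                        sample_b = character(), pearson_r = numeric())
  }
  representation <- data.frame(
    sample_id = colnames(counts),
    frac_represented = colMeans(counts >= count_floor))
  pass <- nrow(pairs) > 0 && all(pairs$pearson_r > min_correlation)
  list(replicate_correlations = pairs, representation = representation,
       pass = pass)
}

#' Call dependency hits from anchored beta scores
#'
#' A gene is a hit in a cell line when its dependency score is at or
#' below the essentiality threshold (boundary inclusive), signifying
#' reduced viability on knockout.
#'
#' @param betas A `beta_score_table` or gene x cell-line matrix.
#' @param tau Threshold (default -0.5).
#' @return Logical gene x cell-line matrix.
#' @export
call_hits <- function(betas, tau = -0.5) {
  b <- if (inherits(betas, "beta_score_table")) betas$beta else betas
  b <= tau
}

#' Two-group differential dependency across genes
#'
#' Per-gene two-sided unpaired t-test of dependency scores between adult
#' and pediatric cell lines, Benjamini-Hochberg adjusted across all tested
#' genes. The effect size is `delta = mean(adult) - mean(pediatric)`; a
#' gene is called `pediatric_specific` when `delta >= +delta_gate` and
#' `fdr < fdr_level` (stronger depletion in pediatric lines), and
#' `adult_specific` for the mirrored condition.
#'
#' @param betas A `beta_score_table` or gene x cell-line matrix.
#' @param groups Named character vector (cell line -> "pediatric"/"adult").
#' @param delta_gate Minimum |delta| for a call (default 0.1).
#' @param fdr_level FDR cutoff for a call (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @param include_controls Also test control genes (default FALSE).
#' @return data.frame with gene, group means, delta, t_stat, p_value, fdr,
#'   zero_variance flag and call.
#' @export
differential_dependency <- function(betas, groups, delta_gate = 0.1,
                                    fdr_level = 0.05, welch = FALSE,
                                    include_controls = FALSE) {
  b <- if (inherits(betas, "beta_score_table")) betas$beta else betas
  roles <- if (inherits(betas, "beta_score_table")) betas$roles else NULL
  if (!include_controls && !is.null(roles))
    b <- b[roles[rownames(b)] == "target", , drop = FALSE]
  groups <- groups[colnames(b)]
  if (anyNA(groups)) stop("group label missing for some cell lines",
                          call. = FALSE)
  a_idx <- which(groups == "adult")
  p_idx <- which(groups == "pediatric")
  if (length(a_idx) < 2 || length(p_idx) < 2)
    stop("both groups need >= 2 cell lines", call. = FALSE)
  res <- do.call(rbind, lapply(rownames(b), function(g) {
    xa <- b[g, a_idx]
    xp <- b[g, p_idx]
    zero_var <- stats::var(xa) < 1e-15 && stats::var(xp) < 1e-15
    if (zero_var) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(xa, xp, var.equal = !welch)
    }
    data.frame(gene = g, mean_beta_adult = mean(xa),
               mean_beta_pediatric = mean(xp),
               delta = mean(xa) - mean(xp),
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               zero_variance = zero_var, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$call <- "none"
  res$call[res$delta >= delta_gate & res$fdr < fdr_level] <-
    "pediatric_specific"
  res$call[res$delta <= -delta_gate & res$fdr < fdr_level] <-
    "adult_specific"
  res[order(res$p_value), ]
}

# half-up integer rounding for display percentages
percent_display <- function(x) floor(x * 100 + 0.5)

#' Dependency prevalence by group with an exact test
#'
#' Counts hit and non-hit cell lines per group for one gene, reports
#' display percentages (half-up integer rounding) and a two-sided
#' Fisher's exact test on the 2x2 table.
#'
#' @param hits Logical gene x cell-line matrix from [call_hits()], or a
#'   named logical vector per cell line.
#' @param groups Named character vector (cell line -> group label).
#' @param gene Gene to summarize when `hits` is a matrix.
#' @return List with `table` (group x hit counts), `summary` (per-group
#'   n_hit, n_total, percent), `p_value` and `odds_ratio`.
#' @export
dependency_prevalence <- function(hits, groups, gene = NULL) {
  h <- if (is.matrix(hits)) {
    if (is.null(gene)) stop("'gene' required with a hit matrix",
                            call. = FALSE)
    hits[gene, ]
  } else hits
  groups <- groups[names(h)]
  if (anyNA(groups)) stop("group label missing for some cell lines",
                          call. = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two nonempty groups required",
                            call. = FALSE)
  tab <- rbind(c(sum(h[groups == lv[1]]), sum(!h[groups == lv[1]])),
               c(sum(h[groups == lv[2]]), sum(!h[groups == lv[2]])))
  dimnames(tab) <- list(lv, c("hit", "no_hit"))
  if (any(rowSums(tab) == 0)) stop("empty group", call. = FALSE)
  ft <- fisher_exact_2x2(tab)
  summary <- data.frame(group = lv, n_hit = tab[, 1],
                        n_total = rowSums(tab),
                        percent = percent_display(tab[, 1] / rowSums(tab)))
  rownames(summary) <- NULL
  list(table = tab, summary = summary, p_value = ft$p_value,
       odds_ratio = ft$odds_ratio)
}

#' Rank genes by dependency within one cell line
#'
#' Most depleted (most negative score) first; ties broken
#' lexicographically by gene id.
#'
#' @param betas A `beta_score_table` or gene x cell-line matrix.
#' @param cell_line Cell line to rank.
#' @param include_controls Keep control genes in the ranking.
#' @return data.frame (gene, beta, rank), rank 1 = strongest dependency.
#' @export
rank_genes <- function(betas, cell_line, include_controls = FALSE) {
  b <- if (inherits(betas, "beta_score_table")) betas$beta else betas
  roles <- if (inherits(betas, "beta_score_table")) betas$roles else NULL
  if (!cell_line %in% colnames(b))
    stop("unknown cell line: ", cell_line, call. = FALSE)
  x <- b[, cell_line]
  if (!include_controls && !is.null(roles))
    x <- x[roles[names(x)] == "target"]
  ord <- order(x, names(x))
  data.frame(gene = names(x)[ord], beta = unname(x[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
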