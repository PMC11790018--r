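#' Configuration for a synthetic pharmacoepigenomic cohort
#'
#' Builds and validates the parameter set that defines a simulated cohort of
#' pediatric and adult tumor cell lines carrying a planted, co-methylated CpG
#' cluster whose methylation state drives both a gene dependency and drug
#' sensitivity. The defaults reproduce the study conditions the package's
#' analysis stages are benchmarked against: 65 pediatric and 10 adult lines,
#' methylation prevalences of 0.75 and 0.10, a 44-CpG locus containing one
#' 10-site co-methylated cluster, an expression/methylation correlation of
#' -0.87 at the exemplar site, planted dependency effects of -0.92
#' (methylated) and -0.18 (unmethylated), and 12-point dose response over
#' 0-20 uM.
#'
#' Methylation beta-values are drawn from bounded two-parameter (beta)
#' distributions: the methylated state from `beta_high_params` truncated to
#' [0.5, 1] (mode 0.8 by default) and the unmethylated state from
#' `beta_low_params` truncated to [0, 0.5) (mode 0.1), so the planted
#' state boundary sits exactly at beta = 0.5. Site-level jitter is reflected
#' at the state boundary, keeping every cluster site on its sample's side.
#'
#' @param n_pediatric,n_adult Number of pediatric / adult cell lines.
#' @param p_methylated_pediatric,p_methylated_adult Probability that a line in
#'   each age group carries the methylated cluster state.
#' @param n_locus_cpgs Total CpG sites at the biomarker locus (default 44).
#' @param cluster_size Number of co-methylated cluster sites (default 10).
#' @param n_low_block Sites forming a uniformly lowly methylated second block.
#' @param beta_high_params,beta_low_params Shape pairs of the bounded [0,1]
#'   distributions for the methylated / unmethylated latent state.
#' @param beta_lowblock_params Shape pair for the uniformly low block.
#' @param site_jitter_sd Site-level jitter SD added to the shared sample
#'   latent (beta-value units).
#' @param n_background_cpgs Independent background CpGs outside the locus.
#' @param n_genes_expression Genes in the expression matrix (first gene is the
#'   locus target whose expression tracks cluster methylation).
#' @param expr_methylation_slope Expression units lost per unit of mean
#'   cluster beta.
#' @param expr_noise_sd Expression noise SD; `NULL` (default) calibrates the
#'   noise so the realized correlation between target-gene expression and the
#'   exemplar cluster CpG matches `target_expr_corr`.
#' @param target_expr_corr Target Pearson correlation between target-gene
#'   expression and exemplar cluster-site methylation (default -0.87).
#' @param library_spec Guide library layout: list with `n_targets` (non-control
#'   target genes), `guides_per_gene`, `n_essential` (core-essential positive
#'   control genes), `n_nontargeting` (guides), `n_nt_genes` (pseudo-genes the
#'   nontargeting guides are grouped under).
#' @param planted_beta Named numeric map from group x methylation state to the
#'   true dependency effect of the marker gene, names
#'   `pediatric_methylated`, `pediatric_unmethylated`, `adult_methylated`,
#'   `adult_unmethylated` (beta-score units; negative = depletion).
#' @param n_effect_genes Additional target genes given fixed nonzero effects
#'   (drawn once per cohort from `effect_range`), providing a spread of true
#'   dependencies for estimator-recovery checks.
#' @param effect_range Range of the additional planted effects.
#' @param guide_jitter_sd SD of guide-level jitter around the gene effect.
#' @param sequencing_depth Expected reads per guide per sample.
#' @param dispersion Negative-binomial overdispersion of guide counts
#'   (variance = mu + dispersion * mu^2).
#' @param n_replicates Endpoint screen replicates per cell line.
#' @param n_day0_replicates Plasmid day-0 reference replicates.
#' @param dose_grid Dose grid in uM; default 0 plus 11 half-log-spaced points
#'   up to 20 uM.
#' @param ic50_methylated_log10nM_mean,ic50_methylated_log10nM_sd Lognormal
#'   parameters (log10 nM) of true IC50 in methylated lines.
#' @param resistant_ic50_floor True IC50 floor for unmethylated lines (nM);
#'   must exceed the maximum dose.
#' @param viability_noise_sd Gaussian viability noise SD (fraction of
#'   control), truncated so viability stays in [0, 1.2].
#' @param n_viability_replicates Replicate wells per dose.
#' @param n_mutation_genes,n_cnv_genes Binary mutation / copy-number features.
#' @param seed Integer seed; identical config + seed gives identical tables.
#'
#' @return An object of class `truth_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
truth_config <- function(n_pediatric = 65,
                         n_adult = 10,
                         p_methylated_pediatric = 0.75,
                         p_methylated_adult = 0.10,
                         n_locus_cpgs = 44,
                         cluster_size = 10,
                         n_low_block = 8,
                         beta_high_params = c(5, 2),
                         beta_low_params = c(1.3, 3.7),
                         beta_lowblock_params = c(1.5, 20),
                         site_jitter_sd = 0.05,
                         n_background_cpgs = 300,
                         n_genes_expression = 300,
                         expr_methylation_slope = 2,
                         expr_noise_sd = NULL,
                         target_expr_corr = -0.87,
                         library_spec = list(n_targets = 290,
                                             guides_per_gene = 4,
                                             n_essential = 62,
                                             n_nontargeting = 250,
                                             n_nt_genes = 2),
                         planted_beta = c(pediatric_methylated = -0.92,
                                          pediatric_unmethylated = -0.18,
                                          adult_methylated = -0.92,
                                          adult_unmethylated = -0.18),
                         n_effect_genes = 20,
                         effect_range = c(-0.8, 0.2),
                         guide_jitter_sd = 0.1,
                         sequencing_depth = 500,
                         dispersion = 0.02,
                         n_replicates = 2,
                         n_day0_replicates = 2,
                         dose_grid = c(0, 20 / sqrt(10)^(10:0)),
                         ic50_methylated_log10nM_mean = 2.6,
                         ic50_methylated_log10nM_sd = 0.4,
                         resistant_ic50_floor = 40000,
                         viability_noise_sd = 0.05,
                         n_viability_replicates = 2,
                         n_mutation_genes = 25,
                         n_cnv_genes = 25,
                         seed = 1) {
  cfg <- list(n_pediatric = n_pediatric, n_adult = n_adult,
              p_methylated_pediatric = p_methylated_pediatric,
              p_methylated_adult = p_methylated_adult,
              n_locus_cpgs = n_locus_cpgs, cluster_size = cluster_size,
              n_low_block = n_low_block,
              beta_high_params = beta_high_params,
              beta_low_params = beta_low_params,
              beta_lowblock_params = beta_lowblock_params,
              site_jitter_sd = site_jitter_sd,
              n_background_cpgs = n_background_cpgs,
              n_genes_expression = n_genes_expression,
              expr_methylation_slope = expr_methylation_slope,
              expr_noise_sd = expr_noise_sd,
              target_expr_corr = target_expr_corr,
              library_spec = library_spec,
              planted_beta = planted_beta,
              n_effect_genes = n_effect_genes,
              effect_range = effect_range,
              guide_jitter_sd = guide_jitter_sd,
              sequencing_depth = sequencing_depth,
              dispersion = dispersion,
              n_replicates = n_replicates,
              n_day0_replicates = n_day0_replicates,
              dose_grid = dose_grid,
              ic50_methylated_log10nM_mean = ic50_methylated_log10nM_mean,
              ic50_methylated_log10nM_sd = ic50_methylated_log10nM_sd,
              resistant_ic50_floor = resistant_ic50_floor,
              viability_noise_sd = viability_noise_sd,
              n_viability_replicates = n_viability_replicates,
              n_mutation_genes = n_mutation_genes,
              n_cnv_genes = n_cnv_genes,
              seed = seed)
  validate_truth_config(cfg)
  structure(cfg, class = "truth_config")
}

validate_truth_config <- function(cfg) {
  chk_count <- function(field, min = 0L) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x))
      stop("invalid truth_config field '", field, "': must be an integer >= ",
           min, call. = FALSE)
  }
  chk_prob <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("invalid truth_config field '", field,
           "': probability must lie in [0, 1]", call. = FALSE)
  }
  chk_pos <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop("invalid truth_config field '", field, "': must be positive",
           call. = FALSE)
  }
  for (f in c("n_pediatric", "n_adult", "n_locus_cpgs", "cluster_size",
              "n_low_block", "n_background_cpgs", "n_genes_expression",
              "n_effect_genes", "n_replicates", "n_day0_replicates",
              "n_viability_replicates", "n_mutation_genes", "n_cnv_genes"))
    chk_count(f)
  for (f in c("p_methylated_pediatric", "p_methylated_adult")) chk_prob(f)
  for (f in c("sequencing_depth", "resistant_ic50_floor")) chk_pos(f)
  for (f in c("site_jitter_sd", "guide_jitter_sd", "viability_noise_sd",
              "dispersion")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop("invalid truth_config field '", f, "': must be >= 0",
           call. = FALSE)
  }
  if (cfg$cluster_size + cfg$n_low_block > cfg$n_locus_cpgs)
    stop("invalid truth_config field 'cluster_size': cluster_size + ",
         "n_low_block must not exceed n_locus_cpgs", call. = FALSE)
  for (f in c("beta_high_params", "beta_low_params", "beta_lowblock_params"))
    if (length(cfg[[f]]) != 2L || any(cfg[[f]] <= 0))
      stop("invalid truth_config field '", f,
           "': need two positive shape parameters", call. = FALSE)
  dg <- cfg$dose_grid
  nz <- dg[dg > 0]
  if (any(dg < 0) || any(diff(dg) <= 0))
    stop("invalid truth_config field 'dose_grid': doses must be ",
         "nonnegative and strictly increasing", call. = FALSE)
  if (abs(max(dg) - 20) > 1e-9)
    stop("invalid truth_config field 'dose_grid': maximum dose must be 20 uM",
         call. = FALSE)
  if (length(nz) < 5L)
    stop("invalid truth_config field 'dose_grid': need >= 5 nonzero doses",
         call. = FALSE)
  if (cfg$resistant_ic50_floor <= max(dg) * 1000)
    stop("invalid truth_config field 'resistant_ic50_floor': must exceed ",
         "the maximum dose (nM)", call. = FALSE)
  ls <- cfg$library_spec
  need <- c("n_targets", "guides_per_gene", "n_essential", "n_nontargeting",
            "n_nt_genes")
  if (!is.list(ls) || !all(need %in% names(ls)))
    stop("invalid truth_config field 'library_spec': need fields ",
         paste(need, collapse = ", "), call. = FALSE)
  if (ls$guides_per_gene < 2L || ls$n_essential < 1L ||
      ls$n_nontargeting < 1L || ls$n_nt_genes < 1L || ls$n_targets < 1L)
    stop("invalid truth_config field 'library_spec': every target gene needs ",
         ">= 2 guides and each control role >= 1 guide", call. = FALSE)
  pb <- cfg$planted_beta
  need_pb <- c("pediatric_methylated", "pediatric_unmethylated",
               "adult_methylated", "adult_unmethylated")
  if (!is.numeric(pb) || !all(need_pb %in% names(pb)))
    stop("invalid truth_config field 'planted_beta': need named effects ",
         paste(need_pb, collapse = ", "), call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("invalid truth_config field 'seed'", call. = FALSE)
  if (!is.null(cfg$expr_noise_sd) &&
      (!is.numeric(cfg$expr_noise_sd) || cfg$expr_noise_sd < 0))
    stop("invalid truth_config field 'expr_noise_sd': must be NULL or >= 0",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.truth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  cell lines: %d pediatric + %d adult\n",
              x$n_pediatric, x$n_adult))
  cat(sprintf("  methylation prevalence: %.2f (pediatric), %.2f (adult)\n",
              x$p_methylated_pediatric, x$p_methylated_adult))
  cat(sprintf("  locus: %d CpGs, cluster of %d, low block of %d\n",
              x$n_locus_cpgs, x$cluster_size, x$n_low_block))
  ls <- x$library_spec
  cat(sprintf("  guide library: %d targets + %d essential @ %d/gene, %d NT\n",
              ls$n_targets, ls$n_essential, ls$guides_per_gene,
              ls$n_nontargeting))
  cat(sprintf("  doses: %d points, 0-%g uM; seed %d\n",
              length(x$dose_grid), max(x$dose_grid), x$seed))
  invisible(x)
}
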