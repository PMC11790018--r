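# Synthetic cohort generation with planted ground truth.
#
# The generator produces every table the analysis stages consume: sample
# annotations, a CpG x sample methylation matrix with one tightly
# co-methylated cluster, an expression matrix anti-correlated with cluster
# methylation, binary mutation/CNV tables, guide-level screen counts
# (day-0 plasmid reference + endpoint replicates), and 12-point
# dose-response curves whose true IC50 depends on the planted methylation
# state.

# beta distribution truncated to [lo, hi]
rtrunc_beta <- function(n, shape, lo = 0, hi = 1) {
  u <- stats::runif(n, stats::pbeta(lo, shape[1], shape[2]),
                    stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

# reflect values into (lo, hi); keeps jittered cluster values on their
# state's side of the planted 0.5 boundary
reflect_into <- function(x, lo, hi) {
  r <- hi - lo
  x <- (x - lo) %% (2 * r)
  ifelse(x > r, 2 * r - x, x) + lo
}

#' Four-parameter logistic viability model
#'
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`, with
#' viability `top` at dose 0. Doses and `ic50` must share a unit.
#'
#' @param dose Dose vector.
#' @param ic50 Curve midpoint (same unit as `dose`).
#' @param top,bottom Upper and lower viability asymptotes.
#' @param hill Hill slope.
#' @return Viability fractions.
#' @export
four_pl <- function(dose, ic50, top = 1, bottom = 0, hill = 1) {
  v <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  v[dose == 0] <- top
  v
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

sample_ids <- function(config) {
  c(sprintf("PED%03d", seq_len(config$n_pediatric)),
    sprintf("ADU%03d", seq_len(config$n_adult)))
}

#' Build the guide library manifest implied by a cohort configuration
#'
#' Lays out target genes (the first of which, `MCL1`, is the planted
#' marker dependency), core-essential positive-control genes, and
#' nontargeting guides grouped under pseudo-genes.
#'
#' @param config A [truth_config()].
#' @return data.frame with columns `guide_id`, `gene`, `role`.
#' @export
build_library <- function(config) {
  ls <- config$library_spec
  target_genes <- c("MCL1", sprintf("T%03d", seq_len(ls$n_targets))[-1])
  ess_genes <- sprintf("ESS%02d", seq_len(ls$n_essential))
  nt_genes <- sprintf("NTC%d", seq_len(ls$n_nt_genes))
  per_gene <- function(genes, role) {
    data.frame(
      guide_id = paste0(rep(genes, each = ls$guides_per_gene), "_sg",
                        rep(seq_len(ls$guides_per_gene), length(genes))),
      gene = rep(genes, each = ls$guides_per_gene),
      role = role, stringsAsFactors = FALSE)
  }
  nt <- data.frame(
    guide_id = sprintf("NT_sg%03d", seq_len(ls$n_nontargeting)),
    gene = rep_len(nt_genes, ls$n_nontargeting),
    role = "nontargeting_control", stringsAsFactors = FALSE)
  out <- rbind(per_gene(target_genes, "target"),
               per_gene(ess_genes, "essential_control"), nt)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic methylation matrix with a planted CpG cluster
#'
#' The locus holds `cluster_size` co-methylated sites sharing a per-sample
#' latent beta drawn from the high-state distribution (truncated to
#' [0.5, 1]) when the sample is methylated and from the low-state
#' distribution (truncated to [0, 0.5)) otherwise; site-level jitter is
#' reflected at the state boundary. A second block of `n_low_block` sites
#' is uniformly lowly methylated (shared latent from
#' `beta_lowblock_params`). Remaining locus sites and all background CpGs
#' are independent with intermediate site-specific means.
#'
#' @param config A [truth_config()].
#' @param states Integer/logical vector (one per sample): 1 = methylated.
#' @return A `methylation_matrix`: list with `beta` (CpG x sample matrix),
#'   `anno` (per-CpG metadata: cpg, locus, position, region) and `cluster`
#'   (logical, planted cluster membership per row).
#' @export
generate_methylation <- function(config, states) {
  validate_truth_config(config)
  ids <- sample_ids(config)
  n <- length(ids)
  if (length(states) != n)
    stop("'states' must have one entry per sample (", n, ")", call. = FALSE)
  states <- as.integer(states)
  set.seed(config$seed + 2L)

  jit <- config$site_jitter_sd
  # shared latent per sample for the co-methylated cluster
  lat <- ifelse(states == 1L,
                rtrunc_beta(n, config$beta_high_params, 0.5, 1),
                rtrunc_beta(n, config$beta_low_params, 0, 0.5))
  cluster <- vapply(seq_len(config$cluster_size), function(j) {
    x <- lat + stats::rnorm(n, 0, jit)
    ifelse(states == 1L, reflect_into(x, 0.5, 1), reflect_into(x, 0, 0.5))
  }, numeric(n))
  # uniformly low block (shared latent, stays near zero)
  low_lat <- rtrunc_beta(n, config$beta_lowblock_params, 0, 1)
  lowblk <- if (config$n_low_block > 0)
    vapply(seq_len(config$n_low_block), function(j)
      reflect_into(low_lat + stats::rnorm(n, 0, jit), 0, 1), numeric(n))
  else matrix(numeric(0), nrow = n)
  # independent locus remainder and background sites
  indep_site <- function(m) {
    mu <- stats::runif(1, 0.2, 0.8)
    stats::rbeta(m, mu * 10, (1 - mu) * 10)
  }
  n_rest <- config$n_locus_cpgs - config$cluster_size - config$n_low_block
  rest <- if (n_rest > 0) vapply(seq_len(n_rest), function(j) indep_site(n),
                                 numeric(n))
  else matrix(numeric(0), nrow = n)
  bg <- if (config$n_background_cpgs > 0)
    vapply(seq_len(config$n_background_cpgs), function(j) indep_site(n),
           numeric(n))
  else matrix(numeric(0), nrow = n)

  locus_beta <- t(cbind(cluster, lowblk, rest))
  beta <- rbind(locus_beta, t(bg))
  locus_ids <- sprintf("cgL%04d", seq_len(config$n_locus_cpgs))
  bg_ids <- sprintf("cgB%05d", seq_len(config$n_background_cpgs))
  rownames(beta) <- c(locus_ids, bg_ids)
  colnames(beta) <- ids
  is_cluster <- c(rep(TRUE, config$cluster_size),
                  rep(FALSE, config$n_locus_cpgs - config$cluster_size),
                  rep(FALSE, config$n_background_cpgs))
  anno <- data.frame(
    cpg = rownames(beta),
    locus = c(rep("BCL2L1", config$n_locus_cpgs),
              rep("background", config$n_background_cpgs)),
    position = c(seq(1000L, by = 150L,
                     length.out = config$n_locus_cpgs),
                 seq(10^6, by = 10^4,
                     length.out = config$n_background_cpgs)),
    region = ifelse(is_cluster, "island", "other"),
    stringsAsFactors = FALSE)
  structure(list(beta = beta, anno = anno, cluster = is_cluster),
            class = "methylation_matrix")
}

#' Generate an expression matrix anti-correlated with cluster methylation
#'
#' The first gene (`BCL2L1`) has expression
#' `intercept - slope * meanClusterBeta + noise`; when `expr_noise_sd` is
#' `NULL` the noise SD is calibrated from the realized sample moments so
#' that the Pearson correlation between that gene and the exemplar cluster
#' CpG (the first cluster site) matches `target_expr_corr`. All other
#' genes are independent noise.
#'
#' @param config A [truth_config()].
#' @param methylation A `methylation_matrix` from [generate_methylation()].
#' @return Numeric gene x sample matrix.
#' @export
generate_expression <- function(config, methylation) {
  validate_truth_config(config)
  beta <- methylation$beta
  cl <- which(methylation$cluster)
  set.seed(config$seed + 3L)
  n <- ncol(beta)
  m <- if (length(cl) > 0) colMeans(beta[cl, , drop = FALSE])
       else rep(0.5, n)
  e <- if (length(cl) > 0) beta[cl[1], ] else m
  slope <- config$expr_methylation_slope
  sigma <- config$expr_noise_sd
  if (is.null(sigma)) {
    tgt <- abs(config$target_expr_corr)
    vm <- stats::var(m)
    if (tgt <= 0 || vm < 1e-12 || slope == 0) {
      sigma <- 1
    } else {
      c1 <- slope * stats::cov(m, e) / stats::sd(e)
      s2 <- (c1 / tgt)^2 - slope^2 * vm
      if (s2 < 0) {
        warning("target expression correlation exceeds the exemplar/cluster ",
                "coupling; using noiseless expression")
        s2 <- 0
      }
      sigma <- sqrt(s2)
    }
  }
  target <- 10 - slope * m + stats::rnorm(n, 0, sigma)
  other <- if (config$n_genes_expression > 1) {
    mu <- stats::runif(config$n_genes_expression - 1, 5, 12)
    t(vapply(mu, function(g) stats::rnorm(n, g, 1), numeric(n)))
  } else matrix(numeric(0), ncol = n)
  expr <- rbind(matrix(target, nrow = 1), other)
  rownames(expr) <- c("BCL2L1",
                      sprintf("G%04d", seq_len(config$n_genes_expression))[-1])
  colnames(expr) <- colnames(beta)
  expr
}

#' Generate guide-level screen counts from planted gene effects
#'
#' Day-0 plasmid counts are negative-binomially overdispersed around
#' uniform representation at `sequencing_depth` reads per guide. Endpoint
#' expectation per guide and cell line is the day-0 expectation times
#' `2^(gene effect + guide jitter)`; replicates are independent draws.
#'
#' @param config A [truth_config()].
#' @param truth A `synthetic_truth` (from [generate_cohort()]) or any list
#'   with an `effects` gene x sample matrix and a `library` manifest.
#' @return A `count_matrix`: list with `counts` (guide x sample integer
#'   matrix), `samples` (sample metadata: sample_id, cell_line, timepoint,
#'   replicate) and `library` (the manifest).
#' @export
generate_screen_counts <- function(config, truth) {
  validate_truth_config(config)
  lib <- truth$library
  effects <- truth$effects
  lines <- colnames(effects)
  set.seed(config$seed + 4L)
  depth <- config$sequencing_depth
  if (depth < 1)
    warning("sequencing depth below 1 read per guide; library not ",
            "representable")
  ng <- nrow(lib)
  gene_of_guide <- match(lib$gene, rownames(effects))
  if (anyNA(gene_of_guide))
    stop("library gene missing from the effects matrix", call. = FALSE)

  day0 <- vapply(seq_len(config$n_day0_replicates), function(r)
    rnbinom_disp(ng, depth, config$dispersion), numeric(ng))
  # guide-level jitter around the gene effect, shared across replicates
  jitter <- matrix(stats::rnorm(ng * length(lines), 0,
                                config$guide_jitter_sd),
                   nrow = ng)
  jitter[lib$role == "nontargeting_control", ] <- 0
  end <- lapply(lines, function(cl) {
    ge <- effects[gene_of_guide, cl] + jitter[, match(cl, lines)]
    mu <- depth * 2^ge
    vapply(seq_len(config$n_replicates), function(r)
      rnbinom_disp(ng, mu, config$dispersion), numeric(ng))
  })
  counts <- cbind(day0, do.call(cbind, end))
  storage.mode(counts) <- "integer"
  rownames(counts) <- lib$guide_id
  samples <- rbind(
    data.frame(sample_id = sprintf("plasmid_rep%d",
                                   seq_len(config$n_day0_replicates)),
               cell_line = "plasmid", timepoint = "day0_reference",
               replicate = seq_len(config$n_day0_replicates),
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(rep(lines, each = config$n_replicates),
                                  "_rep",
                                  rep(seq_len(config$n_replicates),
                                      length(lines))),
               cell_line = rep(lines, each = config$n_replicates),
               timepoint = "endpoint",
               replicate = rep(seq_len(config$n_replicates), length(lines)),
               stringsAsFactors = FALSE))
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples, library = lib),
            class = "count_matrix")
}

#' Generate dose-response viability tables from planted IC50s
#'
#' Viability follows a four-parameter logistic curve (top 1, bottom 0,
#' hill 1) at each sample's true IC50, plus Gaussian noise truncated to
#' [0, 1.2]. Methylated samples draw their IC50 from a lognormal around
#' `ic50_methylated_log10nM_mean`; unmethylated samples sit at or above
#' `resistant_ic50_floor`, beyond the tested range.
#'
#' @param config A [truth_config()].
#' @param truth A list with `ic50_true` (named nM vector per sample).
#' @return Long-format data.frame: cell_line, drug, dose_uM, replicate,
#'   viability.
#' @export
generate_dose_response <- function(config, truth) {
  validate_truth_config(config)
  ic50 <- truth$ic50_true
  set.seed(config$seed + 5L)
  doses <- config$dose_grid
  grid <- expand.grid(dose_uM = doses,
                      replicate = seq_len(config$n_viability_replicates),
                      cell_line = names(ic50), stringsAsFactors = FALSE)
  mu <- four_pl(grid$dose_uM * 1000, ic50[grid$cell_line])
  v <- mu + stats::rnorm(nrow(grid), 0, config$viability_noise_sd)
  grid$viability <- pmin(pmax(v, 0), 1.2)
  grid$drug <- "MCL1i"
  grid[, c("cell_line", "drug", "dose_uM", "replicate", "viability")]
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Orchestrates all generators under a single seed: sample annotations,
#' methylation, expression, mutation/CNV binaries, screen counts and
#' dose-response curves, plus the `synthetic_truth` recording every
#' planted parameter (methylation states, true IC50s, per-gene effects,
#' cluster membership).
#'
#' @param config A [truth_config()].
#' @return List of class `synthetic_cohort` with elements `annotations`,
#'   `methylation`, `expression`, `mutations`, `cnv`, `screen`
#'   (a `count_matrix`), `dose_response`, and `truth`.
#' @examples
#' cohort <- generate_cohort(truth_config(n_pediatric = 8, n_adult = 4,
#'                                        n_background_cpgs = 20,
#'                                        n_genes_expression = 20))
#' table(cohort$truth$states, cohort$annotations$group)
#' @export
generate_cohort <- function(config) {
  validate_truth_config(config)
  ids <- sample_ids(config)
  n <- length(ids)
  group <- rep(c("pediatric", "adult"), c(config$n_pediatric, config$n_adult))
  set.seed(config$seed + 1L)
  states <- stats::rbinom(n, 1,
                          ifelse(group == "pediatric",
                                 config$p_methylated_pediatric,
                                 config$p_methylated_adult))
  names(states) <- ids
  age <- ifelse(group == "pediatric", stats::runif(n, 3, 20),
                stats::runif(n, 22, 70))
  annotations <- data.frame(
    sample_id = ids, group = group, age = round(age, 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    cancer_type = sample(c("HGG-A", "HGG-B", "HGG-C"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  lib <- build_library(config)
  genes <- unique(lib$gene)
  effects <- matrix(0, nrow = length(genes), ncol = n,
                    dimnames = list(genes, ids))
  effects[lib$gene[lib$role == "essential_control"], ] <- -1
  key <- paste(group, ifelse(states == 1L, "methylated", "unmethylated"),
               sep = "_")
  effects["MCL1", ] <- config$planted_beta[key]
  other_targets <- setdiff(unique(lib$gene[lib$role == "target"]), "MCL1")
  eff_genes <- if (config$n_effect_genes > 0)
    sample(other_targets, min(config$n_effect_genes, length(other_targets)))
  else character(0)
  if (length(eff_genes) > 0)
    effects[eff_genes, ] <- matrix(
      stats::runif(length(eff_genes), config$effect_range[1],
                   config$effect_range[2]),
      nrow = length(eff_genes), ncol = n)
  ic50 <- ifelse(states == 1L,
                 10^stats::rnorm(n, config$ic50_methylated_log10nM_mean,
                                 config$ic50_methylated_log10nM_sd),
                 config$resistant_ic50_floor *
                   10^abs(stats::rnorm(n, 0, 0.25)))
  names(ic50) <- ids

  mut_p <- stats::runif(config$n_mutation_genes, 0.05, 0.4)
  mutations <- matrix(stats::rbinom(config$n_mutation_genes * n, 1,
                                    rep(mut_p, n)),
                      nrow = config$n_mutation_genes,
                      dimnames = list(sprintf("MUT%03d",
                                              seq_len(config$n_mutation_genes)),
                                      ids))
  cnv_p <- stats::runif(config$n_cnv_genes, 0.05, 0.4)
  cnv <- matrix(stats::rbinom(config$n_cnv_genes * n, 1, rep(cnv_p, n)),
                nrow = config$n_cnv_genes,
                dimnames = list(sprintf("CNV%03d", seq_len(config$n_cnv_genes)),
                                ids))

  methylation <- generate_methylation(config, states)
  expression <- generate_expression(config, methylation)
  truth <- structure(list(
    states = states,
    groups = stats::setNames(group, ids),
    ic50_true = ic50,
    effects = effects,
    library = lib,
    cluster_members = stats::setNames(methylation$cluster,
                                      rownames(methylation$beta)),
    exemplar_cpg = if (any(methylation$cluster))
      rownames(methylation$beta)[which(methylation$cluster)[1]]
    else NA_character_,
    marker_gene = "MCL1",
    effect_genes = eff_genes,
    config = config), class = "synthetic_truth")
  screen <- generate_screen_counts(config, truth)
  dose <- generate_dose_response(config, truth)
  structure(list(annotations = annotations, methylation = methylation,
                 expression = expression, mutations = mutations, cnv = cnv,
                 screen = screen, dose_response = dose, truth = truth),
            class = "synthetic_cohort")
}
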