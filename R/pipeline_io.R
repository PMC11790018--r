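# Table I/O with schema validation, provenance logging, and the
# end-to-end pipeline: simulate -> screen -> dose -> biomarker ->
# methylation -> report. Interchange is plain TSV/CSV.

write_tsv <- function(d, path, row_names = FALSE) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

require_columns <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0)
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read and validate a guide library manifest (TSV)
#'
#' Columns: guide_id, gene, role (target / essential_control /
#' nontargeting_control). Guide ids must be unique, every target gene
#' needs >= 2 guides and each control role >= 1 guide.
#' @param path TSV path.
#' @return data.frame manifest.
#' @export
read_library <- function(path) {
  d <- read_tsv(path)
  require_columns(d, c("guide_id", "gene", "role"), path)
  if (anyDuplicated(d$guide_id))
    stop("file ", path, ": duplicated guide_id at row ",
         which(duplicated(d$guide_id))[1], call. = FALSE)
  ok_roles <- c("target", "essential_control", "nontargeting_control")
  bad <- which(!d$role %in% ok_roles)
  if (length(bad) > 0)
    stop("file ", path, ", column role, row ", bad[1],
         ": unknown role '", d$role[bad[1]], "'", call. = FALSE)
  tg <- table(d$gene[d$role == "target"])
  if (any(tg < 2))
    stop("file ", path, ": target gene(s) with < 2 guides: ",
         paste(names(tg)[tg < 2], collapse = ", "), call. = FALSE)
  for (r in c("essential_control", "nontargeting_control"))
    if (!any(d$role == r))
      stop("file ", path, ": no guide with role ", r, call. = FALSE)
  d
}

#' Read and validate a guide count matrix (TSV) against a manifest
#'
#' First column holds guide ids; remaining columns are samples of
#' nonnegative integer counts. Every guide must appear in the manifest
#' and every manifest guide in the matrix.
#' @param path TSV path.
#' @param library Manifest from [read_library()].
#' @param samples Sample metadata data.frame (sample_id, cell_line,
#'   timepoint, replicate).
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, library, samples) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (any(m < 0) || any(m != round(m)))
    stop("file ", path, ": counts must be nonnegative integers (first ",
         "offending row ", which(m < 0 | m != round(m))[1] %% nrow(m),
         ")", call. = FALSE)
  extra <- setdiff(rownames(m), library$guide_id)
  if (length(extra) > 0)
    stop("file ", path, ": guide absent from the manifest: ", extra[1],
         call. = FALSE)
  miss <- setdiff(library$guide_id, rownames(m))
  if (length(miss) > 0)
    stop("file ", path, ": manifest guide missing from counts: ",
         miss[1], call. = FALSE)
  require_columns(samples, c("sample_id", "cell_line", "timepoint",
                             "replicate"), "sample metadata")
  if (!any(samples$timepoint == "day0_reference"))
    stop("sample metadata: no day0_reference sample", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(list(counts = m[library$guide_id, samples$sample_id,
                            drop = FALSE],
                 samples = samples, library = library),
            class = "count_matrix")
}

#' Read and validate a methylation beta matrix (TSV, CpGs as rows)
#'
#' @param path TSV path; first column CpG ids, remaining columns samples.
#' @param anno_path Optional per-CpG annotation TSV (cpg, locus,
#'   position, region).
#' @return A `methylation_matrix`.
#' @export
read_methylation_matrix <- function(path, anno_path = NULL) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (anyDuplicated(rownames(m)))
    stop("file ", path, ": duplicated CpG ids", call. = FALSE)
  bad <- which(m < 0 | m > 1)
  if (length(bad) > 0) {
    rw <- (bad[1] - 1) %% nrow(m) + 1
    stop("file ", path, ", row ", rw, " (", rownames(m)[rw],
         "): beta-value outside [0, 1]", call. = FALSE)
  }
  anno <- if (!is.null(anno_path)) {
    a <- read_tsv(anno_path)
    require_columns(a, c("cpg", "locus", "position", "region"), anno_path)
    a[match(rownames(m), a$cpg), ]
  } else {
    data.frame(cpg = rownames(m), locus = "unknown",
               position = seq_len(nrow(m)), region = "other",
               stringsAsFactors = FALSE)
  }
  structure(list(beta = m, anno = anno, cluster = rep(NA, nrow(m))),
            class = "methylation_matrix")
}

#' Read and validate a long-format dose-response table (CSV)
#'
#' Columns: cell_line, drug, dose_uM, replicate, viability.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(d, c("cell_line", "drug", "dose_uM", "replicate",
                       "viability"), path)
  bad <- which(!is.finite(d$viability) | d$viability < 0)
  if (length(bad) > 0)
    stop("file ", path, ", column viability, row ", bad[1],
         ": must be finite and >= 0", call. = FALSE)
  if (any(d$dose_uM < 0))
    stop("file ", path, ": negative dose", call. = FALSE)
  d
}

#' Write every table of a synthetic cohort to a directory
#'
#' Emits sample annotations, methylation matrix + CpG annotation,
#' expression, mutation/CNV, library manifest, count matrix + sample
#' metadata, dose-response long CSV, and the planted truth tables.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  mat_df <- function(m, id) cbind(stats::setNames(
    data.frame(rownames(m), stringsAsFactors = FALSE), id),
    as.data.frame(m, check.names = FALSE))
  paths <- c(annotations = p("annotations.tsv"),
             methylation = p("methylation.tsv"),
             meth_anno = p("methylation_annotation.tsv"),
             expression = p("expression.tsv"),
             mutations = p("mutations.tsv"), cnv = p("cnv.tsv"),
             library = p("library.tsv"), counts = p("counts.tsv"),
             count_samples = p("count_samples.tsv"),
             dose = p("dose_response.csv"),
             truth_samples = p("truth_samples.tsv"),
             truth_effects = p("truth_effects.tsv"),
             truth_cluster = p("truth_cluster.tsv"))
  write_tsv(cohort$annotations, paths["annotations"])
  write_tsv(mat_df(cohort$methylation$beta, "cpg"), paths["methylation"])
  write_tsv(cohort$methylation$anno, paths["meth_anno"])
  write_tsv(mat_df(cohort$expression, "gene"), paths["expression"])
  write_tsv(mat_df(cohort$mutations, "gene"), paths["mutations"])
  write_tsv(mat_df(cohort$cnv, "gene"), paths["cnv"])
  write_tsv(cohort$screen$library, paths["library"])
  write_tsv(mat_df(cohort$screen$counts, "guide_id"), paths["counts"])
  write_tsv(cohort$screen$samples, paths["count_samples"])
  utils::write.csv(cohort$dose_response, paths["dose"],
                   row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  write_tsv(data.frame(sample_id = names(tr$states),
                       methylated = as.integer(tr$states),
                       group = unname(tr$groups),
                       ic50_true_nM = unname(tr$ic50_true)),
            paths["truth_samples"])
  write_tsv(mat_df(tr$effects, "gene"), paths["truth_effects"])
  write_tsv(data.frame(cpg = names(tr$cluster_members),
                       cluster_member = as.integer(tr$cluster_members)),
            paths["truth_cluster"])
  invisible(paths)
}

#' End-to-end pipeline configuration
#'
#' @param truth A [truth_config()] describing the synthetic cohort.
#' @param stages Stages to run, subset of `c("simulate", "screen",
#'   "dose", "biomarker", "methylation")`.
#' @param hit_tau Dependency hit threshold (default -0.5).
#' @param delta_gate,fdr_level Differential-dependency call gates.
#' @param sensitive_ic50_uM Drug-sensitivity IC50 threshold (uM).
#' @param rf An [rf_config()].
#' @param cluster_linkage,cluster_cut CpG clustering parameters.
#' @param cutoff_grid Binarization cutoffs scanned by Fisher testing.
#' @param age_cutoff Pediatric/adult age split (default 21).
#' @param locus Locus analyzed by the methylation stage.
#' @param reference_line AUC-normalization reference; `NULL` = largest
#'   raw AUC.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(truth = truth_config(),
                            stages = c("simulate", "screen", "dose",
                                       "biomarker", "methylation"),
                            hit_tau = -0.5, delta_gate = 0.1,
                            fdr_level = 0.05, sensitive_ic50_uM = 2,
                            rf = rf_config(seed = truth$seed),
                            cluster_linkage = "average",
                            cluster_cut = 0.5,
                            cutoff_grid = seq(0.1, 0.9, by = 0.1),
                            age_cutoff = 21, locus = "BCL2L1",
                            reference_line = NULL) {
  for (f in c("hit_tau", "delta_gate", "fdr_level", "sensitive_ic50_uM",
              "cluster_cut", "age_cutoff"))
    if (!is.finite(get(f))) stop("pipeline_config: '", f,
                                 "' must be finite", call. = FALSE)
  structure(list(truth = truth, stages = stages, hit_tau = hit_tau,
                 delta_gate = delta_gate, fdr_level = fdr_level,
                 sensitive_ic50_uM = sensitive_ic50_uM, rf = rf,
                 cluster_linkage = cluster_linkage,
                 cluster_cut = cluster_cut, cutoff_grid = cutoff_grid,
                 age_cutoff = age_cutoff, locus = locus,
                 reference_line = reference_line),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the enabled stages in order on a freshly generated cohort
#' and returns the report bundle: the dependency tables, dose-response
#' fits and sensitivity calls, the random-forest importance report and
#' single-correlate waterfall, the CpG cluster assignment and threshold
#' scan, and the age-group methylation comparison. When `outdir` is
#' given, all stage tables, the resolved configuration and a provenance
#' log (package version, seeds, parameters) are written there.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- stage("simulate", generate_cohort(config$truth))
    report$cohort <- cohort
  }
  groups <- if (!is.null(cohort))
    stats::setNames(cohort$annotations$group,
                    cohort$annotations$sample_id)
  if ("screen" %in% config$stages && !is.null(cohort)) {
    report$screen <- stage("screen", {
      lognorm <- normalize_counts(cohort$screen)
      betas <- compute_beta_scores(lognorm, cohort$screen$library,
                                   cohort$screen$samples)
      hits <- call_hits(betas, config$hit_tau)
      list(qc = qc_screen(cohort$screen),
           betas = betas, hits = hits,
           differential = differential_dependency(
             betas, groups, config$delta_gate, config$fdr_level),
           prevalence = dependency_prevalence(
             hits, groups, cohort$truth$marker_gene))
    })
  }
  if ("dose" %in% config$stages && !is.null(cohort)) {
    report$dose <- stage("dose", summarize_dose_response(
      cohort$dose_response, config$reference_line,
      config$sensitive_ic50_uM))
  }
  if ("biomarker" %in% config$stages && !is.null(report$dose)) {
    report$biomarker <- stage("biomarker", {
      response <- stats::setNames(report$dose$auc_raw,
                                  report$dose$cell_line)
      clin <- cohort$annotations[, c("group", "sex", "cancer_type")]
      rownames(clin) <- cohort$annotations$sample_id
      ft <- assemble_feature_table(cohort$expression,
                                   cohort$methylation,
                                   cohort$mutations, cohort$cnv, clin,
                                   variable_k = config$rf$variable_k)
      pf <- prefilter_top_correlated(ft, response,
                                     min(config$rf$prefilter_k,
                                         ncol(ft$x)))
      fit <- fit_rf_predict(pf, response, config$rf)
      list(features = pf, fit = fit,
           importance = normalize_importance(
             fit$importance, config$rf$top_score_threshold),
           single_correlate = single_correlate(pf, response),
           response = response)
    })
  }
  if ("methylation" %in% config$stages && !is.null(cohort)) {
    report$methylation <- stage("methylation", {
      sub <- locus_submatrix(cohort$methylation, config$locus)
      clusters <- cluster_cpg_sites(sub, config$cluster_linkage,
                                    config$cluster_cut)
      out <- list(locus = sub, clusters = clusters)
      if (!is.null(report$dose)) {
        response <- stats::setNames(report$dose$auc_raw,
                                    report$dose$cell_line)
        out$waterfall <- correlate_sites_with_response(sub, response)
        labels <- stats::setNames(report$dose$label,
                                  report$dose$cell_line)
        exemplar <- cohort$truth$exemplar_cpg
        if (!is.na(exemplar))
          out$threshold_scan <- scan_threshold(
            sub$beta[exemplar, ], labels, config$cutoff_grid)
      }
      ages <- stats::setNames(cohort$annotations$age,
                              cohort$annotations$sample_id)
      # biomarker candidate block: largest non-low cluster (ties: the
      # more methylated one)
      cand <- clusters$assignment
      sizes <- table(cand$cluster[cand$candidate])
      cm <- clusters$cluster_means
      best <- as.integer(names(sizes)[order(
        -sizes, -cm$mean_beta[match(as.integer(names(sizes)),
                                    cm$cluster)])][1])
      site_set <- cand$cpg[cand$candidate & cand$cluster == best]
      out$age_summary <- summarize_age_methylation(
        cohort$methylation, site_set, ages, config$age_cutoff)
      out
    })
  }
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  if (!is.null(report$cohort))
    write_cohort(report$cohort, file.path(outdir, "cohort"))
  if (!is.null(report$screen)) {
    b <- report$screen$betas$beta
    write_tsv(cbind(data.frame(gene = rownames(b)),
                    as.data.frame(b, check.names = FALSE)),
              file.path(outdir, "beta_scores.tsv"))
    write_tsv(report$screen$differential,
              file.path(outdir, "differential_dependency.tsv"))
    write_tsv(report$screen$qc$replicate_correlations,
              file.path(outdir, "qc_replicate_correlations.tsv"))
  }
  if (!is.null(report$dose))
    write_tsv(report$dose, file.path(outdir, "dose_response_fits.tsv"))
  if (!is.null(report$biomarker)) {
    write_tsv(report$biomarker$importance$report,
              file.path(outdir, "importance_report.tsv"))
    write_tsv(report$biomarker$single_correlate,
              file.path(outdir, "single_correlate.tsv"))
  }
  if (!is.null(report$methylation)) {
    write_tsv(report$methylation$clusters$assignment,
              file.path(outdir, "cluster_assignment.tsv"))
    if (!is.null(report$methylation$waterfall))
      write_tsv(report$methylation$waterfall,
                file.path(outdir, "waterfall.tsv"))
    if (!is.null(report$methylation$threshold_scan))
      write_tsv(report$methylation$threshold_scan$scan,
                file.path(outdir, "threshold_scan.tsv"))
  }
  prov <- list(
    package = "methylscreen",
    version = as.character(utils::packageVersion("methylscreen")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$truth$seed,
    stages = cfg$stages,
    parameters = list(hit_tau = cfg$hit_tau,
                      delta_gate = cfg$delta_gate,
                      fdr_level = cfg$fdr_level,
                      sensitive_ic50_uM = cfg$sensitive_ic50_uM,
                      cluster_linkage = cfg$cluster_linkage,
                      cluster_cut = cfg$cluster_cut,
                      cutoff_grid = cfg$cutoff_grid,
                      age_cutoff = cfg$age_cutoff,
                      rf = unclass(cfg$rf)),
    truth_config = unclass(cfg$truth))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(outdir)
}
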