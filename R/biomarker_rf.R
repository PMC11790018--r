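# Multi-omics feature assembly, correlation prefilter, cross-validated
# random-forest response modeling, and ranked-importance normalization
# for biomarker nomination.

#' Random-forest modeling configuration
#'
#' @param n_trees Trees per forest (default 500).
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Seed controlling fold assignment and forests.
#' @param prefilter_k Features kept by the correlation prefilter
#'   (default 400).
#' @param variable_k Features kept per continuous modality by variance
#'   (default 8000).
#' @param importance_kind `"permutation"` (default) or `"impurity"`.
#' @param top_score_threshold Normalized-importance cutoff flagging top
#'   contributing features (default 0.3).
#' @param mode `"regression"` on the continuous response (default) or
#'   `"classification"` on sensitive/resistant labels.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 500, cv_folds = 5, seed = 1,
                      prefilter_k = 400, variable_k = 8000,
                      importance_kind = c("permutation", "impurity"),
                      top_score_threshold = 0.3,
                      mode = c("regression", "classification")) {
  importance_kind <- match.arg(importance_kind)
  mode <- match.arg(mode)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (n_trees < 1 || prefilter_k < 1 || variable_k < 1)
    stop("n_trees, prefilter_k and variable_k must be positive",
         call. = FALSE)
  structure(list(n_trees = n_trees, cv_folds = cv_folds, seed = seed,
                 prefilter_k = prefilter_k, variable_k = variable_k,
                 importance_kind = importance_kind,
                 top_score_threshold = top_score_threshold, mode = mode),
            class = "rf_config")
}

#' Keep the most variable features of a matrix
#'
#' @param mat Feature x sample numeric matrix.
#' @param k Number of features to keep; when `k` exceeds the feature
#'   count all are kept with a warning. Ties broken by feature id.
#' @return Row-subset matrix (largest variance first).
#' @export
select_variable_features <- function(mat, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(mat)) {
    warning("k (", k, ") exceeds feature count (", nrow(mat),
            "); keeping all features")
    k <- nrow(mat)
  }
  v <- apply(mat, 1, stats::var)
  ord <- order(-v, rownames(mat))
  mat[ord[seq_len(k)], , drop = FALSE]
}

one_hot <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  cols <- lapply(names(clinical), function(nm) {
    x <- clinical[[nm]]
    if (is.numeric(x)) {
      out <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(x)
      out <- vapply(levels(f), function(l) as.numeric(f == l),
                    numeric(length(f)))
      colnames(out) <- paste(nm, levels(f), sep = "_")
    }
    out
  })
  do.call(cbind, cols)
}

#' Assemble a cell line x feature table from multi-omics blocks
#'
#' Applies per-modality variable selection to the continuous blocks
#' (expression, methylation), standardizes them, passes binary blocks
#' (mutation, CNV) through, one-hot encodes categorical clinical
#' variables, and column-binds everything over the common samples.
#' Samples missing from any block are dropped with a warning.
#'
#' @param expression,methylation Feature x sample numeric matrices.
#' @param mutations,cnv Binary feature x sample matrices (optional).
#' @param clinical data.frame with rownames = sample ids (optional);
#'   categorical columns are one-hot encoded.
#' @param variable_k Variance-selection size per continuous modality.
#' @return A `feature_table`: list with `x` (samples x features matrix)
#'   and `modality` (per-feature label).
#' @export
assemble_feature_table <- function(expression, methylation,
                                   mutations = NULL, cnv = NULL,
                                   clinical = NULL, variable_k = 8000) {
  if (inherits(methylation, "methylation_matrix"))
    methylation <- methylation$beta
  blocks <- list(expression = expression, methylation = methylation,
                 mutation = mutations, cnv = cnv)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  ids <- lapply(blocks, colnames)
  if (!is.null(clinical)) ids <- c(ids, list(rownames(clinical)))
  common <- Reduce(intersect, ids)
  if (length(common) == 0)
    stop("no samples shared across all blocks", call. = FALSE)
  dropped <- setdiff(unique(unlist(ids)), common)
  if (length(dropped) > 0)
    warning("samples absent from some blocks were dropped: ",
            paste(dropped, collapse = ", "))
  std <- function(m) {
    s <- t(scale(t(m)))
    s[!is.finite(s)] <- 0
    s
  }
  parts <- list()
  modality <- character(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]][, common, drop = FALSE]
    if (nm %in% c("expression", "methylation")) {
      b <- select_variable_features(b, min(variable_k, nrow(b)))
      b <- std(b)
    }
    parts[[nm]] <- t(b)
    modality <- c(modality, rep(nm, nrow(b)))
  }
  if (!is.null(clinical)) {
    cl <- one_hot(clinical[common, , drop = FALSE])
    rownames(cl) <- common
    parts$clinical <- cl
    modality <- c(modality, rep("clinical", ncol(cl)))
  }
  x <- do.call(cbind, parts)
  rownames(x) <- common
  if (anyNA(x)) stop("assembled feature table contains missing values",
                     call. = FALSE)
  structure(list(x = x, modality = stats::setNames(modality, colnames(x))),
            class = "feature_table")
}

feature_matrix <- function(features) {
  if (inherits(features, "feature_table")) features$x else features
}

# |Pearson r| of every feature column with the response; zero-variance
# features get r = 0
feature_correlations <- function(x, response) {
  response <- response[rownames(x)]
  if (anyNA(response)) stop("response missing for some samples",
                            call. = FALSE)
  r <- suppressWarnings(as.numeric(stats::cor(x, response)))
  r[!is.finite(r)] <- 0
  stats::setNames(r, colnames(x))
}

#' Keep the features most correlated with the response
#'
#' Ranks features by absolute Pearson correlation with the continuous
#' response (point-biserial for binary features) and keeps the top `k`;
#' ties broken by feature id.
#'
#' @param features A `feature_table` or samples x features matrix.
#' @param response Named numeric response aligned to samples.
#' @param k Features to keep (default 400).
#' @return A `feature_table` subset (column order: strongest first).
#' @export
prefilter_top_correlated <- function(features, response, k = 400) {
  x <- feature_matrix(features)
  if (k > ncol(x)) {
    warning("k (", k, ") exceeds feature count (", ncol(x),
            "); keeping all features")
    k <- ncol(x)
  }
  r <- feature_correlations(x, response)
  ord <- order(-abs(r), names(r))
  keep <- colnames(x)[ord[seq_len(k)]]
  modality <- if (inherits(features, "feature_table"))
    features$modality[keep] else NULL
  structure(list(x = x[, keep, drop = FALSE], modality = modality),
            class = "feature_table")
}

#' Cross-validated random-forest response model
#'
#' Seeded k-fold cross-validation of a [ranger::ranger] forest.
#' Out-of-fold predictions give the performance summary (Spearman
#' correlation and R-squared in regression mode; accuracy in
#' classification mode); the raw feature importance is the chosen
#' importance measure averaged over the fold models.
#'
#' @param features A `feature_table` or samples x features matrix.
#' @param response Named numeric response (regression) or
#'   sensitive/resistant labels (classification).
#' @param config An [rf_config()].
#' @return List with `oof_predictions`, `importance` (named, averaged
#'   over folds), `performance`, `folds`.
#' @export
fit_rf_predict <- function(features, response, config = rf_config()) {
  x <- feature_matrix(features)
  response <- response[rownames(x)]
  if (anyNA(response)) stop("response missing for some samples",
                            call. = FALSE)
  n <- nrow(x)
  if (config$cv_folds > n)
    stop("cv_folds exceeds the number of samples", call. = FALSE)
  if (n < 2 * config$cv_folds)
    stop("need >= 2 samples per fold", call. = FALSE)
  classification <- config$mode == "classification"
  y <- if (classification) factor(response) else as.numeric(response)
  set.seed(config$seed)
  folds <- sample(rep_len(seq_len(config$cv_folds), n))
  oof <- if (classification) factor(rep(NA, n), levels = levels(y))
         else rep(NA_real_, n)
  imp <- matrix(0, nrow = ncol(x), ncol = config$cv_folds,
                dimnames = list(colnames(x), NULL))
  dat <- data.frame(.y = y, x, check.names = FALSE)
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat[tr, , drop = FALSE],
      num.trees = config$n_trees, importance = config$importance_kind,
      seed = config$seed + f, num.threads = 1)
    pred <- stats::predict(fit, dat[!tr, , drop = FALSE],
                           num.threads = 1)$predictions
    oof[!tr] <- pred
    imp[, f] <- fit$variable.importance[colnames(x)]
  }
  importance <- rowMeans(imp)
  performance <- if (classification) {
    list(accuracy = mean(oof == y))
  } else {
    list(spearman = stats::cor(oof, y, method = "spearman"),
         r_squared = 1 - sum((y - oof)^2) / sum((y - mean(y))^2))
  }
  list(oof_predictions = stats::setNames(oof, rownames(x)),
       importance = importance, performance = performance, folds = folds)
}

#' Normalize ranked random-forest importances and flag top biomarkers
#'
#' Sorts raw importances descending, reports each feature's normalized
#' score (importance divided by the maximum importance, so scores lie in
#' [0, 1]) and flags features at or above the threshold as top
#' contributors. As a model-level diagnostic, fits a least-squares line
#' through the (rank, importance) profile and reports the gradient and
#' its concentration, |gradient| / (max importance x feature count).
#' Negative raw importances (possible under permutation importance) are
#' clipped at zero before normalization.
#'
#' @param raw Named numeric raw importances (>= 2 features, not all 0).
#' @param threshold Top-feature cutoff on the normalized score
#'   (default 0.3).
#' @return An `importance_report`: list with `report` (data.frame
#'   feature, raw_importance, rank, normalized_score, top_flag),
#'   `model_gradient`, `model_concentration`.
#' @export
normalize_importance <- function(raw, threshold = 0.3) {
  if (length(raw) < 2) stop("need >= 2 features", call. = FALSE)
  raw <- pmax(raw, 0)
  if (all(raw == 0))
    stop("all importances are zero: uninformative model", call. = FALSE)
  ord <- order(-raw, names(raw))
  sorted <- raw[ord]
  rank <- seq_along(sorted)
  slope <- stats::cov(rank, sorted) / stats::var(rank)
  mx <- unname(sorted[1])
  report <- data.frame(feature = names(sorted),
                       raw_importance = unname(sorted), rank = rank,
                       normalized_score = unname(sorted) / mx,
                       stringsAsFactors = FALSE)
  report$top_flag <- report$normalized_score >= threshold
  structure(list(report = report, model_gradient = abs(slope),
                 model_concentration = abs(slope) / (mx * length(sorted)),
                 threshold = threshold),
            class = "importance_report")
}

#' Per-feature Pearson correlation with the response
#'
#' Single-correlate analysis: Pearson r of every feature against the
#' continuous response, two-sided p from the t-distribution, BH-adjusted
#' across features, ranked by |r| descending. Zero-variance features get
#' r = 0, p = 1 and a flag.
#'
#' @param features A `feature_table` or samples x features matrix.
#' @param response Named numeric response aligned to samples (n >= 4).
#' @return data.frame (feature, pearson_r, p_value, bh_fdr, rank,
#'   zero_variance) ordered by rank.
#' @export
single_correlate <- function(features, response) {
  x <- feature_matrix(features)
  response <- response[rownames(x)]
  if (anyNA(response)) stop("response missing for some samples",
                            call. = FALSE)
  n <- nrow(x)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  r <- suppressWarnings(as.numeric(stats::cor(x, response)))
  zero_var <- !is.finite(r)
  r[zero_var] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[zero_var] <- 1
  p[abs(r) >= 1] <- 0
  out <- data.frame(feature = colnames(x), pearson_r = r, p_value = p,
                    bh_fdr = stats::p.adjust(p, method = "BH"),
                    zero_variance = zero_var, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$pearson_r), out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
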