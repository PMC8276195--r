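# Two-group differential expression with precision weights and
# empirical-Bayes moderated t statistics, run on both count matrices and
# merged into a consensus table.

#' Build a two-group design matrix
#' @param groups character/factor of group labels (exactly 2 levels).
#' @param batch optional batch labels.
#' @return design matrix with an intercept and a group contrast column
#'   (second level vs first).
#' @export
make_design <- function(groups, batch = NULL) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("two-group design requires exactly 2 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  if (!is.null(batch) && !all(is.na(batch)) &&
      length(unique(batch)) > 1) {
    stats::model.matrix(~ g + factor(batch))
  } else {
    stats::model.matrix(~g)
  }
}

#' Mean-variance precision weights for count data
#'
#' Transforms counts to log2 CPM (prior 0.5) and derives per-observation
#' precision weights from the lowess trend of sqrt(residual SD) against mean
#' log2 count (weight = fitted^-4), the standard variance-stabilising
#' treatment for RNA-seq linear models. Optionally combines the trend with
#' per-sample quality weights estimated from the sample-wise residual
#' variance.
#'
#' @param counts filtered features x samples matrix.
#' @param design design matrix from [make_design()].
#' @param size_factors per-sample normalisation factors (default TMM on the
#'   input counts).
#' @param quality_weights also estimate per-sample quality weights
#'   (default `FALSE`).
#' @return an [limma::EList] with components `E` (log2 CPM) and `weights`.
#' @export
voom_transform <- function(counts, design,
                           size_factors = tmm_factors(counts),
                           quality_weights = FALSE) {
  if (any(colSums(abs(design)) == 0) || qr(design)$rank < ncol(design)) {
    stop("design matrix is not full rank")
  }
  lib <- colSums(counts) * size_factors
  if (quality_weights) {
    limma::voomWithQualityWeights(counts, design, lib.size = lib)
  } else {
    limma::voom(counts, design, lib.size = lib)
  }
}

#' Moderated t-test per feature
#'
#' Weighted least squares per feature followed by empirical-Bayes variance
#' shrinkage (posterior variance `(d0*s0^2 + d*s^2)/(d0 + d)` with the prior
#' fitted by moment matching on the observed variance distribution) and BH
#' adjustment across features.
#'
#' @param v an [limma::EList] from [voom_transform()], or a log-expression
#'   matrix (then `weights` may be given separately).
#' @param design design matrix; the tested coefficient is `coef`.
#' @param coef column of the design to test (default 2, the group
#'   contrast).
#' @param weights optional observation weights when `v` is a plain matrix.
#' @return data.frame: `feature_id`, `logFC`, `t_stat`, `p_value`, `adj_p`.
#' @export
moderated_t <- function(v, design, coef = 2L, weights = NULL) {
  if (is.matrix(v) && !is.null(weights)) {
    v <- methods::new("EList", list(E = v, weights = weights))
  }
  n <- if (methods::is(v, "EList")) ncol(v$E) else ncol(v)
  if (n - ncol(design) <= 0) stop("zero residual degrees of freedom")
  fit <- limma::lmFit(v, design)
  fit <- limma::eBayes(fit)
  tt <- limma::topTable(fit, coef = coef, number = Inf, sort.by = "none")
  data.frame(feature_id = rownames(tt), logFC = tt$logFC, t_stat = tt$t,
             p_value = tt$P.Value, adj_p = tt$adj.P.Val,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#' @param p numeric vector of p-values in `[0, 1]`; `NA`/`NaN` not allowed.
#' @return adjusted p-values (step-up with monotonicity enforcement),
#'   order-invariant.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run two-group DE on one count matrix
#'
#' Filters, normalises (TMM), derives precision weights and fits the
#' moderated t-test; the workhorse behind [merge_de()].
#'
#' @param counts features x samples matrix.
#' @param groups group labels per sample.
#' @param batch optional batch labels.
#' @param config a [run_config()].
#' @param quality_weights use per-sample quality weights (default `FALSE`).
#' @return data.frame as [moderated_t()].
#' @export
de_one_method <- function(counts, groups, batch = NULL,
                          config = run_config(), quality_weights = FALSE) {
  min_s <- config$stats$min_samples
  if (is.null(min_s)) min_s <- min(table(groups))
  fl <- filter_low(counts, config$stats$cpm_threshold, min_s)
  design <- make_design(groups, batch)
  v <- voom_transform(fl$counts, design,
                      quality_weights = quality_weights)
  moderated_t(v, design)
}

#' Merge DE results from the two quantification tracks
#'
#' Produces a side-by-side table with per-method logFC and p-values, a
#' consensus label per feature (`both` / `genomic_only` /
#' `transcriptomic_only`, by significance of the BH-adjusted p at `alpha`),
#' and the union/intersection significant sets at both raw and adjusted
#' alpha.
#'
#' @param genomic_results,tx_results data.frames from [moderated_t()].
#' @param mode reported significant set: `"union"` (default) or
#'   `"intersection"`.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param log_expr optional normalised expression matrix; rows for the
#'   `mode` significant set are returned as `heatmap_matrix`.
#' @return list with `table` (merged data.frame), `sets` (list:
#'   `union_adj`, `intersection_adj`, `union_raw`, `intersection_raw`),
#'   `significant` (ids for `mode`), `heatmap_matrix` (or `NULL`).
#' @export
merge_de <- function(genomic_results, tx_results,
                     mode = c("union", "intersection"), alpha = 0.05,
                     log_expr = NULL) {
  mode <- match.arg(mode)
  feats <- sort(union(genomic_results$feature_id, tx_results$feature_id))
  gi <- match(feats, genomic_results$feature_id)
  ti <- match(feats, tx_results$feature_id)
  tab <- data.frame(
    feature_id = feats,
    logFC_genomic = genomic_results$logFC[gi],
    p_genomic = genomic_results$p_value[gi],
    adj_p_genomic = genomic_results$adj_p[gi],
    logFC_tx = tx_results$logFC[ti],
    p_tx = tx_results$p_value[ti],
    adj_p_tx = tx_results$adj_p[ti],
    stringsAsFactors = FALSE
  )
  sig_g <- !is.na(tab$adj_p_genomic) & tab$adj_p_genomic <= alpha
  sig_t <- !is.na(tab$adj_p_tx) & tab$adj_p_tx <= alpha
  tab$consensus <- ifelse(sig_g & sig_t, "both",
                          ifelse(sig_g, "genomic_only",
                                 ifelse(sig_t, "transcriptomic_only",
                                        "none")))
  raw_g <- !is.na(tab$p_genomic) & tab$p_genomic <= alpha
  raw_t <- !is.na(tab$p_tx) & tab$p_tx <= alpha
  sets <- list(
    union_adj = tab$feature_id[sig_g | sig_t],
    intersection_adj = tab$feature_id[sig_g & sig_t],
    union_raw = tab$feature_id[raw_g | raw_t],
    intersection_raw = tab$feature_id[raw_g & raw_t]
  )
  significant <- if (mode == "union") sets$union_adj else
    sets$intersection_adj
  heat <- NULL
  if (!is.null(log_expr)) {
    rows <- intersect(significant, rownames(log_expr))
    heat <- log_expr[rows, , drop = FALSE]
  }
  list(table = tab, sets = sets, significant = significant,
       heatmap_matrix = heat, mode = mode, alpha = alpha)
}

#' Classify consensus-significant features as up- or down-regulated
#'
#' A feature is `up` when its logFC is positive and the consensus adjusted p
#' is below `alpha` (`down` analogous). When both methods report a logFC
#' with conflicting signs the feature is flagged `discordant` and excluded
#' from the up/down counts.
#'
#' @param merged result of [merge_de()], or its `table`.
#' @param alpha significance level (default 0.05).
#' @param mode significance rule: `"union"` (significant in at least one
#'   method) or `"intersection"`.
#' @return list with `up`, `down`, `discordant` (feature id vectors) and
#'   `counts` (named integer).
#' @export
classify_updown <- function(merged, alpha = 0.05,
                            mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  tab <- if (is.data.frame(merged)) merged else merged$table
  sig_g <- !is.na(tab$adj_p_genomic) & tab$adj_p_genomic < alpha
  sig_t <- !is.na(tab$adj_p_tx) & tab$adj_p_tx < alpha
  sig <- if (mode == "union") sig_g | sig_t else sig_g & sig_t
  both_fc <- !is.na(tab$logFC_genomic) & !is.na(tab$logFC_tx)
  discordant <- sig & both_fc &
    sign(tab$logFC_genomic) * sign(tab$logFC_tx) < 0
  fc <- ifelse(!is.na(tab$logFC_genomic), tab$logFC_genomic, tab$logFC_tx)
  up <- sig & !discordant & fc > 0
  down <- sig & !discordant & fc < 0
  log_stage("classify_updown", up = sum(up), down = sum(down),
            discordant = sum(discordant))
  list(up = tab$feature_id[up], down = tab$feature_id[down],
       discordant = tab$feature_id[discordant],
       counts = c(up = sum(up), down = sum(down),
                  discordant = sum(discordant)))
}
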