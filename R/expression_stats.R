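# Filtering, normalisation and exploratory summaries, run in parallel on the
# genomic and transcriptomic count matrices.

#' Counts per million
#'
#' `counts[i,j] * 1e6 / (colSums(counts)[j] * size_factors[j])`; on the log2
#' scale a prior count (default 0.5) is added, scaled proportionally to the
#' effective library size as in standard CPM implementations.
#'
#' @param counts features x samples matrix.
#' @param size_factors per-sample normalisation factors (default 1).
#' @param log return log2 CPM (default `FALSE`).
#' @param prior prior count for the log transform (default 0.5).
#' @return matrix of the same shape.
#' @export
cpm_matrix <- function(counts, size_factors = rep(1, ncol(counts)),
                       log = FALSE, prior = 0.5) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  edgeR::cpm(counts, lib.size = lib * size_factors, log = log,
             prior.count = prior)
}

#' Filter lowly expressed features
#'
#' Keeps features with CPM at or above `cpm_threshold` in at least
#' `min_samples` samples (the usual "1 count per million" detection rule).
#' Idempotent.
#'
#' @param counts features x samples matrix.
#' @param cpm_threshold CPM detection threshold (default 1).
#' @param min_samples minimum number of samples passing; typically the size
#'   of the smallest experimental group.
#' @return list with `counts` (filtered matrix), `kept`, `removed` (ids),
#'   and `avg_log_cpm` (data.frame with per-feature average log2 CPM and a
#'   `kept` flag, for before/after filtering histograms).
#' @export
filter_low <- function(counts, cpm_threshold = 1, min_samples = 1L) {
  if (min_samples > ncol(counts)) {
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  }
  cpms <- cpm_matrix(counts)
  keep <- rowSums(cpms >= cpm_threshold) >= min_samples
  avg <- rowMeans(cpm_matrix(counts, log = TRUE))
  list(counts = counts[keep, , drop = FALSE],
       kept = rownames(counts)[keep],
       removed = rownames(counts)[!keep],
       avg_log_cpm = data.frame(feature_id = rownames(counts),
                                avg_log2_cpm = avg, kept = keep,
                                stringsAsFactors = FALSE))
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Composition-correction factors relative to library size, computed by the
#' weighted trimmed mean of gene-wise log ratios against a reference sample
#' (30% trim on M-values, 5% on A-values, inverse asymptotic-variance
#' weights); the `TMMwsp` variant pairs zeros by singleton pairing for
#' sparse data. Factors are rescaled to geometric mean 1.
#'
#' @param counts features x samples matrix.
#' @param variant `"TMM"` (default) or `"TMMwsp"`.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, variant = c("TMM", "TMMwsp")) {
  variant <- match.arg(variant)
  if (any(colSums(counts) == 0)) stop("all-zero sample in counts")
  f <- edgeR::calcNormFactors(as.matrix(counts), method = variant)
  stats::setNames(f, colnames(counts))
}

#' Relative-log-expression (median-of-ratios) size factors
#'
#' Per-sample median of count / feature-geometric-mean ratios over features
#' with a nonzero geometric mean, rescaled to geometric mean 1.
#'
#' @param counts features x samples matrix; at least one feature must be
#'   positive in every sample.
#' @param rescale rescale factors to geometric mean 1 (default `TRUE`).
#' @return named numeric vector of size factors.
#' @export
rle_factors <- function(counts, rescale = TRUE) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no feature is positive in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_gm[use]))
  })
  if (rescale) sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Relative-log-expression plot statistics
#'
#' Subtracts each feature's median from the log-expression matrix and
#' returns per-sample boxplot statistics of the centred values.
#'
#' @param log_expr features x samples log-expression matrix.
#' @return data.frame: `sample`, `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`.
#' @export
rle_plot_stats <- function(log_expr) {
  centred <- sweep(log_expr, 1, apply(log_expr, 1, stats::median))
  out <- lapply(seq_len(ncol(centred)), function(j) {
    s <- grDevices::boxplot.stats(centred[, j])$stats
    data.frame(sample = colnames(centred)[j], lower_whisker = s[1],
               q1 = s[2], median = s[3], q3 = s[4], upper_whisker = s[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Biotype detection summary
#'
#' For each sample and biotype: the biotype's share of the annotation
#' universe, the share of that biotype's features detected (count > 0), the
#' biotype's share among the sample's detected features, the number
#' detected, and quartiles of the nonzero count distribution.
#'
#' @param counts features x samples matrix.
#' @param biotype_map named character vector mapping feature id to biotype;
#'   every counted feature must be present.
#' @param annotation_universe optional named biotype vector for the full
#'   annotation (defaults to the counted features).
#' @return data.frame with one row per (sample, biotype): `sample`,
#'   `biotype`, `genome_pct`, `detected_pct_of_biotype`,
#'   `within_sample_pct`, `detected_n`, `count_q1`, `count_median`,
#'   `count_q3`.
#' @export
biodetection <- function(counts, biotype_map, annotation_universe = NULL) {
  missing_bt <- setdiff(rownames(counts), names(biotype_map))
  if (length(missing_bt)) {
    stop("feature(s) without biotype: ",
         paste(utils::head(missing_bt, 3), collapse = ", "))
  }
  if (is.null(annotation_universe)) {
    annotation_universe <- biotype_map[rownames(counts)]
  }
  uni_tab <- table(annotation_universe)
  biotypes <- sort(names(uni_tab))
  bt <- biotype_map[rownames(counts)]
  out <- list()
  for (s in colnames(counts)) {
    x <- counts[, s]
    det <- x > 0
    det_bt <- table(factor(bt[det], levels = biotypes))
    n_det <- sum(det)
    for (b in biotypes) {
      in_uni <- sum(annotation_universe == b)
      vals <- x[det & bt == b]
      qs <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75)) else
        c(NA, NA, NA)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, biotype = b,
        genome_pct = 100 * in_uni / length(annotation_universe),
        detected_pct_of_biotype =
          if (in_uni > 0) 100 * det_bt[[b]] / in_uni else 0,
        within_sample_pct = if (n_det > 0) 100 * det_bt[[b]] / n_det else 0,
        detected_n = det_bt[[b]],
        count_q1 = qs[[1]], count_median = qs[[2]], count_q3 = qs[[3]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sample ordination (MDS or PCA)
#'
#' MDS uses the pairwise leading-log-fold-change distance over the top 500
#' most heterogeneous features per sample pair; PCA is on centred,
#' transposed log-expression (first two components, with explained
#' variance).
#'
#' @param log_expr features x samples log-expression matrix (>= 3 samples).
#' @param kind `"MDS"` or `"PCA"`.
#' @param top number of features for the MDS distance (default 500).
#' @return data.frame with `sample`, `dim1`, `dim2`; for PCA an attribute
#'   `explained` holds the variance fractions of the two components.
#' @export
ordination <- function(log_expr, kind = c("MDS", "PCA"), top = 500L) {
  kind <- match.arg(kind)
  if (ncol(log_expr) < 3) stop("ordination needs at least 3 samples")
  if (kind == "PCA") {
    pc <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    out <- data.frame(sample = colnames(log_expr), dim1 = pc$x[, 1],
                      dim2 = pc$x[, 2], stringsAsFactors = FALSE)
    attr(out, "explained") <- expl[1:2]
    rownames(out) <- NULL
    return(out)
  }
  if (all(stats::dist(t(log_expr)) < 1e-12)) {
    out <- data.frame(sample = colnames(log_expr), dim1 = 0, dim2 = 0,
                      stringsAsFactors = FALSE)
    return(out)
  }
  mds <- limma::plotMDS(log_expr, top = top, plot = FALSE,
                        gene.selection = "pairwise")
  data.frame(sample = colnames(log_expr), dim1 = mds$x, dim2 = mds$y,
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on samples with Ward, complete or average linkage;
#' the Pearson correlation matrix of the samples is returned alongside for
#' heatmap-style summaries.
#'
#' @param log_expr features x samples log-expression matrix.
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return list with `hclust` (an [stats::hclust] object), `order` (sample
#'   labels in dendrogram order), `dist` (distance matrix), `correlation`
#'   (sample correlation matrix).
#' @export
cluster_samples <- function(log_expr,
                            linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  d <- stats::dist(t(log_expr))
  hc <- stats::hclust(d, method = method)
  list(hclust = hc, order = hc$labels[hc$order], dist = d,
       correlation = stats::cor(log_expr))
}

#' Run the exploratory analysis bundle on one count matrix
#'
#' Convenience wrapper: filtering, TMM/TMMwsp/RLE factors, log2 CPM, RLE
#' plot statistics, biodetection, MDS/PCA, clustering and correlation,
#' optionally written to TSV files.
#'
#' @param counts features x samples matrix.
#' @param groups character vector of group labels per sample.
#' @param biotype_map named biotype vector (optional; biodetection skipped
#'   when absent).
#' @param config a [run_config()].
#' @param out_dir optional output directory; a `label` prefixes file names.
#' @param label file-name prefix, e.g. `"genomic"`.
#' @return list with the individual results.
#' @export
eda_bundle <- function(counts, groups, biotype_map = NULL,
                       config = run_config(), out_dir = NULL,
                       label = "counts") {
  min_s <- config$stats$min_samples
  if (is.null(min_s)) min_s <- min(table(groups))
  fl <- filter_low(counts, config$stats$cpm_threshold, min_s)
  tmm <- tmm_factors(fl$counts, "TMM")
  tmmwsp <- tmm_factors(fl$counts, "TMMwsp")
  rle <- tryCatch(rle_factors(fl$counts), error = function(e) NULL)
  logcpm <- cpm_matrix(fl$counts, tmm, log = TRUE)
  res <- list(
    filtered = fl, factors = list(TMM = tmm, TMMwsp = tmmwsp, RLE = rle),
    log_cpm = logcpm,
    rle_stats = rle_plot_stats(logcpm),
    mds = ordination(logcpm, "MDS"),
    pca = ordination(logcpm, "PCA"),
    clustering = cluster_samples(logcpm, "ward"),
    biodetection = if (!is.null(biotype_map))
      biodetection(fl$counts, biotype_map) else NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, paste0(label, "_", f))
    write_counts(fl$counts, p("filtered_counts.tsv"))
    write_counts(logcpm, p("log2_cpm_tmm.tsv"))
    write_tsv_file(fl$avg_log_cpm, p("filter_histogram.tsv"))
    write_tsv_file(res$rle_stats, p("rle_stats.tsv"))
    write_tsv_file(res$mds, p("mds.tsv"))
    write_tsv_file(res$pca, p("pca.tsv"))
    fdf <- data.frame(sample = names(tmm), TMM = tmm, TMMwsp = tmmwsp,
                      RLE = if (is.null(rle)) NA else rle)
    write_tsv_file(fdf, p("norm_factors.tsv"))
    if (!is.null(res$biodetection)) {
      write_tsv_file(res$biodetection, p("biodetection.tsv"))
    }
  }
  res
}
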