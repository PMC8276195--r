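#' Default run configuration
#'
#' Central container for every tunable threshold of the toolkit. Values are
#' grouped by pipeline stage; all defaults reproduce the reference contracts
#' the pipeline was designed around (ungapped realignment of database
#' sequences at >=16 matched bases / 0 mismatches / <=100 loci; read
#' alignment at >=14 matched bases / <=1 mismatch / <=100 loci; 100
#' transcript-abundance bootstraps; CPM >= 1 detection filter; BH alpha
#' 0.05).
#'
#' @param ... named overrides of any default, using the nested names shown in
#'   the return value, e.g. `run_config(forge = list(min_match = 18))`.
#'   Overrides are merged recursively into the defaults.
#'
#' @return A list of class `snc_config` with components `forge`, `quant`,
#'   `stats`, `de` and `seed`:
#' \describe{
#'   \item{forge}{`max_seq_len` (exclusive upper bound on database sequence
#'     length, nt, default 100), `pirnabank_max_len` (exclusive bound for
#'     piRNA-database integration, default 69), `min_match`, `max_mismatch`,
#'     `max_loci` (realignment contract, defaults 16/0/100),
#'     `stringent_coding_filter` (drop features overlapping protein-coding
#'     exons/CDS, default `TRUE`), `region_gap` (max gap for region merging,
#'     bp, default 1000), `standard_chroms` (optional explicit chromosome
#'     list; `NULL` = autosomes + X/Y/MT by name pattern),
#'     `embedded_same_strand` (default `TRUE`).}
#'   \item{quant}{genomic contract `min_match`/`max_mismatch`/`max_loci`
#'     (14/1/100), `count_mode` one of `"fractional"`, `"all"`, `"unique"`,
#'     adapter trimming `adapter_max_error_rate` (0.1), `adapter_min_overlap`
#'     (3), `min_read_len` (15), transcriptomic `n_bootstraps` (100),
#'     `em_tol` (1e-8, on the abundance-proportion scale), `em_max_iter`
#'     (1000).}
#'   \item{stats}{`cpm_threshold` (1), `min_samples` (`NULL` = size of the
#'     smallest group).}
#'   \item{de}{`alpha` (0.05, on BH-adjusted p).}
#'   \item{seed}{integer RNG seed, default 1.}
#' }
#' @export
#' @examples
#' cfg <- run_config(quant = list(count_mode = "unique"))
#' cfg$quant$count_mode
run_config <- function(...) {
  cfg <- list(
    forge = list(
      max_seq_len = 100L,
      pirnabank_max_len = 69L,
      min_match = 16L,
      max_mismatch = 0L,
      max_loci = 100L,
      stringent_coding_filter = TRUE,
      region_gap = 1000L,
      standard_chroms = NULL,
      embedded_same_strand = TRUE
    ),
    quant = list(
      min_match = 14L,
      max_mismatch = 1L,
      max_loci = 100L,
      count_mode = "fractional",
      adapter_max_error_rate = 0.1,
      adapter_min_overlap = 3L,
      min_read_len = 15L,
      n_bootstraps = 100L,
      em_tol = 1e-8,
      em_max_iter = 1000L
    ),
    stats = list(cpm_threshold = 1, min_samples = NULL),
    de = list(alpha = 0.05),
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "snc_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$forge$max_seq_len > 0, cfg$forge$pirnabank_max_len > 0,
    cfg$forge$min_match > 0, cfg$forge$max_mismatch >= 0,
    cfg$forge$max_loci > 0, cfg$forge$region_gap >= 0,
    cfg$quant$min_match > 0, cfg$quant$max_mismatch >= 0,
    cfg$quant$max_loci > 0, cfg$quant$min_read_len > 0,
    cfg$quant$n_bootstraps >= 0, cfg$quant$em_tol > 0,
    cfg$quant$em_max_iter > 0,
    cfg$stats$cpm_threshold >= 0, cfg$de$alpha > 0, cfg$de$alpha <= 1
  )
  if (!cfg$quant$count_mode %in% c("fractional", "all", "unique")) {
    stop("count_mode must be one of 'fractional', 'all', 'unique'")
  }
  invisible(cfg)
}

#' @export
print.snc_config <- function(x, ...) {
  cat("sncforge run configuration\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# stage logging: record counts to stderr; forge/quant accumulate these into
# their stats TSVs as well
log_stage <- function(stage, ...) {
  vals <- c(...)
  msg <- paste0("[", stage, "] ",
                paste(names(vals), unname(vals), sep = "=", collapse = " "))
  message(msg)
  invisible(data.frame(stage = stage, key = names(vals),
                       value = as.character(unname(vals)),
                       stringsAsFactors = FALSE))
}
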