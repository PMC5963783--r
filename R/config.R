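#' Analysis configuration for a LEGO screen
#'
#' Bundles every numeric threshold used across library construction,
#' deconvolution, target mapping and hit calling, so that a whole screen is
#' reproducible from one object.
#'
#' @param fold_enrichment_min Vectors whose normalized copy number increases
#'   strictly more than this factor through selection are called transforming.
#' @param identity_min Minimum pairwise sequence identity (fraction) for two
#'   transcripts to be merged into one cluster.
#' @param coverage_min Minimum single-sided alignment coverage (fraction of the
#'   shorter sequence) for clustering.
#' @param alui_coverage_min A cluster survives only if the fraction of its
#'   theoretically producible vectors that were transforming strictly exceeds
#'   this value.
#' @param min_vectors_per_library Minimum number of distinct transforming
#'   vectors required independently in each of the two libraries.
#' @param expr_fold_threshold Expression flags (repressed/induced) are set when
#'   a fold change strictly exceeds this value.
#' @param max_alui_sites_db Transcripts with strictly more AluI sites than this
#'   are excluded from the search database.
#' @param max_tag_mismatches Total mismatches tolerated across the loop match
#'   plus the stem/reverse-complement-stem comparison during tag extraction.
#' @param max_map_mismatches Mismatches tolerated when mapping a tag back to a
#'   transcript (default 0: exact match).
#' @param loop_len Length of the hairpin loop in nt.
#' @param loop_seq The loop sequence itself (must have \code{loop_len} nt).
#' @param stem_len Guide/stem length in nt (19 or 20).
#' @param knockdown_range Range of knockdown fractions achieved by functional
#'   vectors.
#' @param driver_excess Fold excess of driver over tester cDNA in the first
#'   hybridization.
#' @param pseudocount Counts-per-million pseudocount used in enrichment ratios.
#' @param rng_seed Integer seed from which all randomness derives.
#'
#' @return An object of class \code{lego_config} (a validated list).
#' @examples
#' cfg <- lego_config()
#' cfg$fold_enrichment_min
#' @export
lego_config <- function(fold_enrichment_min = 3,
                        identity_min = 0.95,
                        coverage_min = 0.90,
                        alui_coverage_min = 0.15,
                        min_vectors_per_library = 3,
                        expr_fold_threshold = 1.66,
                        max_alui_sites_db = 500,
                        max_tag_mismatches = 1,
                        max_map_mismatches = 0,
                        loop_len = 9,
                        loop_seq = "TTCAAGAGA",
                        stem_len = 20,
                        knockdown_range = c(0.40, 0.80),
                        driver_excess = 60,
                        pseudocount = 0.5,
                        rng_seed = 1L) {
  cfg <- list(
    fold_enrichment_min = fold_enrichment_min,
    identity_min = identity_min,
    coverage_min = coverage_min,
    alui_coverage_min = alui_coverage_min,
    min_vectors_per_library = min_vectors_per_library,
    expr_fold_threshold = expr_fold_threshold,
    max_alui_sites_db = max_alui_sites_db,
    max_tag_mismatches = max_tag_mismatches,
    max_map_mismatches = max_map_mismatches,
    loop_len = as.integer(loop_len),
    loop_seq = toupper(loop_seq),
    stem_len = as.integer(stem_len),
    knockdown_range = knockdown_range,
    driver_excess = driver_excess,
    pseudocount = pseudocount,
    rng_seed = as.integer(rng_seed)
  )
  validate_lego_config(cfg)
  class(cfg) <- "lego_config"
  cfg
}

validate_lego_config <- function(cfg) {
  num <- c("fold_enrichment_min", "identity_min", "coverage_min",
           "alui_coverage_min", "min_vectors_per_library",
           "expr_fold_threshold", "max_alui_sites_db", "loop_len", "stem_len",
           "driver_excess", "pseudocount")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  if (cfg$max_tag_mismatches < 0 || cfg$max_map_mismatches < 0) {
    stop("mismatch allowances must be >= 0", call. = FALSE)
  }
  if (!cfg$stem_len %in% c(19L, 20L)) {
    stop("stem_len must be 19 or 20", call. = FALSE)
  }
  if (nchar(cfg$loop_seq) != cfg$loop_len) {
    stop("loop_seq must have loop_len = ", cfg$loop_len, " nt", call. = FALSE)
  }
  kr <- cfg$knockdown_range
  if (length(kr) != 2L || any(kr <= 0) || any(kr >= 1) || kr[1] > kr[2]) {
    stop("knockdown_range must lie strictly inside (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.lego_config <- function(x, ...) {
  cat("LEGO screen configuration\n")
  cat(sprintf("  enrichment > %g-fold; >=%d vectors/library; AluI coverage > %g%%\n",
              x$fold_enrichment_min, x$min_vectors_per_library,
              100 * x$alui_coverage_min))
  cat(sprintf("  clustering: identity >= %g%%, coverage >= %g%% (single-sided)\n",
              100 * x$identity_min, 100 * x$coverage_min))
  cat(sprintf("  hairpin: %d-nt stems, %d-nt loop (%s), <=%d tag mismatch(es)\n",
              x$stem_len, x$loop_len, x$loop_seq, x$max_tag_mismatches))
  cat(sprintf("  expression flag threshold: > %g-fold; seed %d\n",
              x$expr_fold_threshold, x$rng_seed))
  invisible(x)
}
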