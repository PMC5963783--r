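# Hit calling: dual-library suppressor criterion, ranking score, expression
# annotation.

round_half_up <- function(x) floor(x + 0.5)

#' Apply the dual-library suppressor criterion
#'
#' A transcript (cluster) is a suppressor candidate iff it is targeted by at
#' least \code{min_vectors_per_library} different transforming shRNA vectors
#' (distinct (AluI site, side) tags) selected independently from each of the
#' two libraries.
#'
#' @param records data.frame with one row per cluster: \code{gene_label},
#'   \code{n_vectors_lib1}, \code{n_vectors_lib2}, \code{n_vectors_total}
#'   (distinct vectors over both libraries), \code{max_possible_vectors}.
#' @param config A [lego_config()].
#' @return The rows passing the criterion.
#' @export
classify_suppressors <- function(records, config = lego_config()) {
  k <- config$min_vectors_per_library
  keep <- records$n_vectors_lib1 >= k & records$n_vectors_lib2 >= k
  records[keep, , drop = FALSE]
}

#' Score and rank suppressor records
#'
#' The percentage of transforming vectors is
#' \code{round(100 * n_vectors_total / max_possible_vectors)} (half-up to an
#' integer) and the ranking score is the exact integer product
#' \code{n_vectors_total * pct_transforming}. Records are sorted by
#' descending score, then descending percentage, then input order (stable),
#' which reproduces the published ordering of equal-score rows.
#'
#' @param records data.frame with \code{gene_label}, \code{n_vectors_total},
#'   \code{max_possible_vectors} (or a precomputed \code{pct_transforming}).
#' @return The records with \code{pct_transforming} and \code{ranking_score},
#'   ranked.
#' @export
score_and_rank <- function(records) {
  if (!"pct_transforming" %in% names(records)) {
    bad <- records$max_possible_vectors == 0
    if (any(bad)) {
      warning("excluding record(s) with zero possible vectors: ",
              paste(records$gene_label[bad], collapse = ", "))
      records <- records[!bad, , drop = FALSE]
    }
    records$pct_transforming <-
      round_half_up(100 * records$n_vectors_total /
                      records$max_possible_vectors)
  }
  records$ranking_score <- records$n_vectors_total * records$pct_transforming
  ord <- order(-records$ranking_score, -records$pct_transforming)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate suppressor records with expression behavior
#'
#' Joins fold-change columns from an expression table and sets boolean flags
#' at the strict \code{> expr_fold_threshold} rule (folds exactly at the
#' threshold are not flagged). Genes missing from the table get NA folds and
#' flags; malformed fold values yield a row-level warning and NA.
#'
#' @param records Ranked suppressor records with \code{gene_label}.
#' @param expression data.frame with \code{gene_label},
#'   \code{repression_fold_g1}, \code{repression_fold_g2},
#'   \code{induction_fold_anchor_loss}.
#' @param config A [lego_config()].
#' @return The records with fold columns and \code{repressed_g1},
#'   \code{repressed_g2}, \code{induced} flags.
#' @export
annotate_expression <- function(records, expression, config = lego_config()) {
  cols <- c("repression_fold_g1", "repression_fold_g2",
            "induction_fold_anchor_loss")
  idx <- match(records$gene_label, expression$gene_label)
  for (cl in cols) {
    v <- expression[[cl]][idx]
    vn <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(vn)
    if (any(bad)) {
      warning("malformed fold value for gene(s): ",
              paste(records$gene_label[bad], collapse = ", "))
    }
    records[[cl]] <- vn
  }
  thr <- config$expr_fold_threshold
  records$repressed_g1 <- records$repression_fold_g1 > thr
  records$repressed_g2 <- records$repression_fold_g2 > thr
  records$induced <- records$induction_fold_anchor_loss > thr
  records
}
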