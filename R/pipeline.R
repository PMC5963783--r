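# End-to-end pipeline: synthetic screen -> FASTQ -> deconvolution ->
# mapping -> hit table.

#' Run the full screen pipeline on a synthetic scenario
#'
#' Generates a transcriptome with planted suppressors, builds two subtracted
#' LEGO libraries (one per transformed driver genotype) through the SSH
#' kinetics, simulates two rounds of anchorless selection, emits
#' error-bearing FASTQ reads, deconvolves them into tag counts, calls
#' transforming vectors (> fold threshold), maps them to transcripts,
#' clusters redundant transcripts, picks the minimal explaining cluster set,
#' applies the AluI-coverage and ambiguity filters, and scores the dual-
#' library suppressor hits.
#'
#' All randomness flows from \code{scenario$rng_seed}; identical
#' scenario+config yields byte-identical outputs.
#'
#' @param scenario A [screen_scenario()].
#' @param config A [lego_config()].
#' @param params A [hybrid_params()] for the SSH stage.
#' @param outdir Optional directory; when given, FASTA/FASTQ/TSV
#'   intermediates and the hit table are written there and recorded in the
#'   manifest.
#' @param contrast Enrichment contrast passed to [call_transforming()]
#'   (default: pre vs final round).
#' @param verbose Print per-stage record counts.
#' @return Object of class \code{lego_screen}: the hit table (\code{hits}),
#'   the ground truth, per-stage intermediates, stage log and file manifest.
#' @examples
#' \donttest{
#' sc <- screen_scenario(n_transcripts = 40, n_suppressors = 3,
#'                       library_cells = 20000, reads_per_sample = 20000)
#' res <- run_screen_pipeline(sc)
#' res$hits$gene_label
#' }
#' @export
run_screen_pipeline <- function(scenario = screen_scenario(),
                                config = lego_config(),
                                params = NULL,
                                outdir = NULL, contrast = NULL,
                                verbose = FALSE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  manifest <- character(0)
  emit <- function(x, name) {
    if (!is.null(outdir)) {
      p <- file.path(outdir, name)
      if (is.data.frame(x)) write_tsv_table(x, p)
      manifest <<- c(manifest, p)
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  if (is.null(params)) {
    params <- hybrid_params(driver_excess = config$driver_excess)
  }

  # 1. synthetic transcriptome with planted suppressors
  tx <- generate_transcriptome(scenario)
  log_msg("transcriptome: %d transcripts, %d planted suppressors",
          nrow(tx$transcripts), length(tx$truth))
  if (!is.null(outdir)) {
    fa <- file.path(outdir, "transcriptome.fa")
    write_fasta(tx$transcripts, fa)
    manifest <- c(manifest, fa)
  }
  emit(tx$expression, "expression.tsv")

  # 2. SSH-subtracted library composition per driver genotype
  libs <- list(
    lib1 = library_composition(tx$transcripts, tx$expression$expr_tester,
                               tx$expression$expr_driver_g1, params, config),
    lib2 = library_composition(tx$transcripts, tx$expression$expr_tester,
                               tx$expression$expr_driver_g2, params, config)
  )
  for (nm in names(libs)) {
    emit(libs[[nm]]$catalog[, c("vector_id", "transcript_id", "gene_label",
                                "site_index", "side", "guide", "realizable",
                                "weight")],
         paste0("catalog_", nm, ".tsv"))
  }
  log_msg("libraries: %d / %d weighted vectors",
          sum(libs$lib1$catalog$weight > 0), sum(libs$lib2$catalog$weight > 0))

  # 3. selection (two rounds, two libraries)
  sel <- simulate_selection(libs, tx$truth, scenario, config)
  emit(sel$counts, "selection_counts.tsv")

  # 4. sequencing and deconvolution
  tag_rows <- list()
  for (lib in unique(sel$counts$library)) {
    for (smp in unique(sel$counts$sample)) {
      sub <- sel$counts[sel$counts$library == lib & sel$counts$sample == smp, ]
      reads <- emit_reads(sub, scenario, config,
                          sample_name = paste0(lib, "_", smp))
      if (!is.null(outdir)) {
        fq <- file.path(outdir, paste0(lib, "_", smp, ".fastq"))
        write_fastq(reads, fq)
        manifest <- c(manifest, fq)
        reads <- read_fastq(fq)
      }
      ext <- extract_tags(reads, config)
      log_msg("%s/%s: %d reads, %d accepted, %d discarded", lib, smp,
              ext$n_reads, ext$n_accepted, ext$n_discarded)
      cnt <- merge_error_tags(ext$counts)
      if (nrow(cnt) > 0L) {
        tag_rows[[paste(lib, smp)]] <-
          data.frame(library = lib, sample = smp, tag = cnt$tag,
                     count = cnt$count, stringsAsFactors = FALSE)
      }
    }
  }
  table <- normalize_counts(do.call(rbind, tag_rows))
  emit(table, "tag_counts.tsv")

  # 5. transforming-vector calls per library
  calls <- call_transforming(table, config, contrast)
  emit(calls, "transforming_calls.tsv")
  transforming <- calls[calls$is_transforming, ]
  log_msg("transforming tags: %d (lib1 %d, lib2 %d)",
          length(unique(transforming$tag)),
          sum(transforming$library == "lib1"),
          sum(transforming$library == "lib2"))
  if (nrow(transforming) == 0L) {
    stop("no transforming vectors called; nothing to map", call. = FALSE)
  }

  # 6. map tags, cluster hit transcripts, minimal set cover, coverage filter
  db <- build_db(tx$transcripts, config)
  mapped <- map_tags(unique(transforming$tag), db)
  log_msg("mapping: %d tags mapped, %d unmapped",
          length(unique(mapped$hits$tag)), length(mapped$unmapped))
  hit_tx <- db$transcripts[db$transcripts$id %in%
                             unique(mapped$hits$transcript_id), , drop = FALSE]
  clusters <- cluster_transcripts(hit_tx, config)
  member_of <- stats::setNames(
    rep(clusters$cluster_id, lengths(strsplit(clusters$members, ","))),
    unlist(strsplit(clusters$members, ",")))
  mapped$hits$cluster_id <- member_of[mapped$hits$transcript_id]
  cluster_tags <- lapply(split(mapped$hits$tag, mapped$hits$cluster_id),
                         unique)
  selected_ids <- minimal_cluster_set(cluster_tags,
                                      unique(mapped$hits$tag))
  selected <- clusters[clusters$cluster_id %in% selected_ids, , drop = FALSE]
  selected$n_tags <- vapply(selected$cluster_id,
                            function(cid) length(cluster_tags[[cid]]),
                            integer(1))
  selected <- filter_alui_coverage(selected, config)
  emit(selected, "clusters.tsv")
  log_msg("clusters: %d selected by cover, %d surviving filters",
          nrow(selected), sum(selected$status == "selected"))
  surviving <- selected[selected$status == "selected", , drop = FALSE]

  # 7. dual-library criterion, ranking, expression flags
  hits <- .build_hit_records(surviving, mapped$hits, transforming, config)
  hits <- classify_suppressors(hits, config)
  hits <- score_and_rank(hits)
  # informational alternative denominator: realizable (not theoretical)
  # vectors of the representative
  hits$realizable_vectors <- vapply(hits$representative, function(id) {
    tr <- db$transcripts[db$transcripts$id == id, ]
    sum(enumerate_vectors(tr, config)$realizable)
  }, integer(1))
  hits$pct_realizable <- ifelse(hits$realizable_vectors > 0,
                                round(100 * hits$n_vectors_total /
                                        hits$realizable_vectors), NA)
  expr <- tx$expression[, c("gene_label", "repression_fold_g1",
                            "repression_fold_g2",
                            "induction_fold_anchor_loss")]
  hits <- annotate_expression(hits, expr, config)
  emit(hits, "hit_table.tsv")

  out <- list(hits = hits, truth = tx$truth, expression = tx$expression,
              clusters = selected, calls = calls, tag_table = table,
              vector_truth = sel$vector_truth, mapped = mapped,
              scenario = scenario, config = config, manifest = manifest)
  class(out) <- "lego_screen"
  out
}

# One Table-1-style row per surviving cluster: distinct (site, side) vector
# counts per library and overall.
.build_hit_records <- function(surviving, hits, transforming, config) {
  rows <- lapply(seq_len(nrow(surviving)), function(i) {
    cid <- surviving$cluster_id[i]
    ctags <- unique(hits$tag[hits$cluster_id == cid])
    rep_id <- surviving$representative[i]
    # key each tag by its (site, side) on the representative (fall back to
    # any member hit so shared tags are not dropped)
    tag_key <- vapply(ctags, function(tg) {
      h <- hits[hits$tag == tg & hits$cluster_id == cid, , drop = FALSE]
      hr <- h[h$transcript_id == rep_id, , drop = FALSE]
      if (nrow(hr) == 0L) hr <- h[1, , drop = FALSE]
      paste0(hr$site_index[1], ":", hr$side[1])
    }, character(1))
    per_lib <- vapply(c("lib1", "lib2"), function(lib) {
      lt <- transforming$tag[transforming$library == lib]
      length(unique(tag_key[ctags %in% lt]))
    }, integer(1))
    data.frame(gene_label = surviving$gene_labels[i],
               cluster_id = cid,
               representative = rep_id,
               n_vectors_lib1 = per_lib[["lib1"]],
               n_vectors_lib2 = per_lib[["lib2"]],
               n_vectors_total = length(unique(tag_key)),
               max_possible_vectors = surviving$max_possible_vectors[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_label = character(), cluster_id = character(),
                      representative = character(),
                      n_vectors_lib1 = integer(), n_vectors_lib2 = integer(),
                      n_vectors_total = integer(),
                      max_possible_vectors = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.lego_screen <- function(x, ...) {
  cat("LEGO screen result:", nrow(x$hits), "suppressor hits",
      sprintf("(%d planted)\n", length(x$truth)))
  if (nrow(x$hits) > 0L) {
    print(head(x$hits[, c("gene_label", "ranking_score", "n_vectors_total",
                          "pct_transforming")], 15), row.names = FALSE)
  }
  invisible(x)
}
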