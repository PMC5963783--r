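# Synthetic-data generator: a transcriptome with planted suppressors, SSH
# library compositions, two rounds of anchorless selection, and error-bearing
# FASTQ reads, so that every downstream stage is testable without external
# data.

# Constant flanks around the sequenced hairpin (vector backbone on each side
# of the insert: promoter tail upstream, termination signal downstream).
.FLANK5 <- "GACGCCACCG"
.FLANK3 <- "TTTTTGGAAC"

#' Define a synthetic screen scenario
#'
#' The defaults are the study conditions the generator emulates: two
#' independently subtracted libraries (two transformed driver genotypes), a
#' 150,000-colony library complexity, functional vectors knocking their
#' target down by 40--80 percent, and planted suppressor transcripts repressed
#' in the transformed (driver) cells.
#'
#' @param n_transcripts Number of transcripts in the transcriptome.
#' @param length_range Range (nt) from which transcript lengths are drawn
#'   uniformly.
#' @param n_suppressors Number of planted suppressor transcripts.
#' @param suppressor_repression_range Range of repression folds (driver vs
#'   tester) for planted suppressors, per transformed genotype.
#' @param suppressor_induction_range Range of induction folds on anchor loss
#'   for planted suppressors.
#' @param background_log_sd Log-sd of the fold noise applied to non-suppressor
#'   genes between states.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of base
#'   expression levels.
#' @param nonfunctional_fraction Fraction of vectors achieving no knockdown
#'   (2 of 11 in the calibration experiment).
#' @param knockdown_threshold Minimum knockdown fraction a vector must achieve
#'   to transform a cell carrying it.
#' @param growth_boost Colony-growth factor applied to transforming vectors at
#'   each selection round.
#' @param off_target_rate Per-vector probability of transforming regardless of
#'   target (default 0).
#' @param rounds Number of selection rounds (a mobilized library is
#'   re-screened, hence 2).
#' @param library_cells Cell/colony complexity sampled per library.
#' @param reads_per_sample Sequencing depth per sample.
#' @param sequencing_error_rate Per-base substitution error rate.
#' @param rng_seed Integer seed; all generator randomness derives from it.
#' @return List of class \code{screen_scenario}.
#' @export
screen_scenario <- function(n_transcripts = 200L,
                            length_range = c(2000L, 4000L),
                            n_suppressors = 10L,
                            suppressor_repression_range = c(2, 6),
                            suppressor_induction_range = c(1.8, 4.5),
                            background_log_sd = 0.12,
                            expression_meanlog = log(100),
                            expression_sdlog = 1,
                            nonfunctional_fraction = 2 / 11,
                            knockdown_threshold = 0.5,
                            growth_boost = 50,
                            off_target_rate = 0,
                            rounds = 2L,
                            library_cells = 150000L,
                            reads_per_sample = 100000L,
                            sequencing_error_rate = 0.002,
                            rng_seed = 1L) {
  sc <- list(n_transcripts = as.integer(n_transcripts),
             length_range = as.integer(length_range),
             n_suppressors = as.integer(n_suppressors),
             suppressor_repression_range = suppressor_repression_range,
             suppressor_induction_range = suppressor_induction_range,
             background_log_sd = background_log_sd,
             expression_meanlog = expression_meanlog,
             expression_sdlog = expression_sdlog,
             nonfunctional_fraction = nonfunctional_fraction,
             knockdown_threshold = knockdown_threshold,
             growth_boost = growth_boost,
             off_target_rate = off_target_rate,
             rounds = as.integer(rounds),
             library_cells = as.integer(library_cells),
             reads_per_sample = as.integer(reads_per_sample),
             sequencing_error_rate = sequencing_error_rate,
             rng_seed = as.integer(rng_seed))
  probs <- c(sc$nonfunctional_fraction, sc$knockdown_threshold,
             sc$off_target_rate, sc$sequencing_error_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("scenario probabilities/fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sc$n_suppressors > sc$n_transcripts) {
    stop("cannot plant more suppressors than transcripts", call. = FALSE)
  }
  class(sc) <- "screen_scenario"
  sc
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic transcriptome with planted suppressors
#'
#' Transcript sequences are uniform random ACGT (AluI site density about one
#' per 256 nt). Expression levels are drawn for the tester state (anchorless
#' non-transformed) and two transformed driver genotypes; planted suppressors
#' are repressed in both driver genotypes and induced on anchor loss, with
#' folds strictly above the flag threshold by construction.
#'
#' @param scenario A [screen_scenario()].
#' @return List with \code{transcripts} (data.frame: id, gene_label, seq,
#'   length), \code{expression} (per-gene states and Table-1-style fold
#'   columns), and \code{truth} (planted suppressor ids).
#' @export
generate_transcriptome <- function(scenario = screen_scenario()) {
  set.seed(scenario$rng_seed)
  n <- scenario$n_transcripts
  ids <- sprintf("t%03d", seq_len(n))
  genes <- sprintf("Gene%03d", seq_len(n))
  lens <- scenario$length_range[1] +
    sample.int(scenario$length_range[2] - scenario$length_range[1] + 1L, n,
               replace = TRUE) - 1L
  seqs <- vapply(lens, .random_dna, character(1))
  suppressors <- sort(sample(ids, scenario$n_suppressors))
  is_sup <- ids %in% suppressors

  expr_tester <- rlnorm(n, scenario$expression_meanlog,
                        scenario$expression_sdlog)
  # attached state: suppressors are induced on anchor loss
  ind <- rep(1, n)
  ind[is_sup] <- runif(sum(is_sup), scenario$suppressor_induction_range[1],
                       scenario$suppressor_induction_range[2])
  ind[!is_sup] <- exp(rnorm(sum(!is_sup), 0, scenario$background_log_sd))
  expr_attached <- expr_tester / ind

  driver_expr <- function() {
    rep_fold <- exp(rnorm(n, 0, scenario$background_log_sd))
    rep_fold[is_sup] <- runif(sum(is_sup),
                              scenario$suppressor_repression_range[1],
                              scenario$suppressor_repression_range[2])
    list(expr = expr_tester / rep_fold, fold = rep_fold)
  }
  g1 <- driver_expr()  # TBX2-like transformed genotype
  g2 <- driver_expr()  # p53kd-like transformed genotype

  expression <- data.frame(
    transcript_id = ids,
    gene_label = genes,
    expr_tester = expr_tester,
    expr_attached = expr_attached,
    expr_driver_g1 = g1$expr,
    expr_driver_g2 = g2$expr,
    repression_fold_g1 = g1$fold,
    repression_fold_g2 = g2$fold,
    induction_fold_anchor_loss = ind,
    planted_suppressor = is_sup,
    stringsAsFactors = FALSE
  )
  list(transcripts = data.frame(id = ids, gene_label = genes, seq = seqs,
                                length = lens, stringsAsFactors = FALSE),
       expression = expression,
       truth = suppressors)
}

#' LEGO library composition from a transcriptome via SSH
#'
#' Digests every transcript, builds the tester/driver fragment pools from the
#' per-transcript expression levels, runs the SSH kinetics, and assigns each
#' realizable vector the subtracted share of the fragment its guide derives
#' from (left-side guides come from the upstream fragment, right-side guides
#' from the downstream fragment of their AluI site).
#'
#' @param transcripts Transcript data.frame.
#' @param expr_tester,expr_driver Named (by transcript id) or positionally
#'   matched expression vectors.
#' @param params A [hybrid_params()].
#' @param config A [lego_config()].
#' @return List with \code{catalog} (vector catalog with a \code{weight}
#'   column normalized to sum 1 over realizable vectors) and \code{ssh}
#'   (the fragment-level [run_ssh()] result).
#' @export
library_composition <- function(transcripts, expr_tester, expr_driver,
                                params = hybrid_params(),
                                config = lego_config()) {
  frag_list <- lapply(seq_len(nrow(transcripts)), function(i) {
    fr <- digest_alui(transcripts[i, ])
    fr$frag_index <- seq_len(nrow(fr))
    fr$tester <- expr_tester[i]
    fr$driver <- expr_driver[i]
    fr
  })
  frags <- do.call(rbind, frag_list)
  frags$species_id <- paste0(frags$transcript_id, ":f", frags$frag_index)
  pool <- species_pool(frags$species_id, frags$tester, frags$driver)
  ssh <- run_ssh(pool, params)
  share <- setNames(ssh$share, ssh$species_id)

  cat_list <- lapply(seq_len(nrow(transcripts)), function(i) {
    v <- enumerate_vectors(transcripts[i, ], config)
    if (nrow(v) == 0L) return(NULL)
    v$max_possible <- attr(v, "max_possible")
    # guide's source fragment: left side -> fragment j, right -> fragment j+1
    v$frag_index <- ifelse(v$side == "left", v$site_index, v$site_index + 1L)
    v
  })
  catalog <- do.call(rbind, cat_list)
  catalog$species_id <- paste0(catalog$transcript_id, ":f", catalog$frag_index)
  catalog$weight <- ifelse(catalog$realizable,
                           share[catalog$species_id], 0)
  catalog$weight[is.na(catalog$weight)] <- 0
  tot <- sum(catalog$weight)
  if (tot > 0) catalog$weight <- catalog$weight / tot
  rownames(catalog) <- NULL
  list(catalog = catalog, ssh = ssh)
}

#' Simulate two rounds of anchorless selection for two libraries
#'
#' A vector is transforming iff it targets a planted suppressor and its
#' knockdown efficacy (drawn once per unique guide from the knockdown range,
#' with a nonfunctional fraction achieving none) reaches the transformation
#' threshold; off-target transformation is an optional per-vector Bernoulli.
#' Pre-selection copy numbers are multinomial draws from the library
#' composition; at each round the weights of transforming vectors are boosted
#' by the colony-growth factor while the rest persist at single-cell
#' carryover, and copy numbers are redrawn multinomially.
#'
#' @param catalogs Named list of two vector catalogs (one per library), each
#'   from [library_composition()].
#' @param suppressors Character vector of planted suppressor transcript ids.
#' @param scenario A [screen_scenario()].
#' @param config A [lego_config()].
#' @return List with \code{counts} (long data.frame: library, sample, vector
#'   id, guide, count) and \code{vector_truth} (per unique guide: efficacy,
#'   transforming).
#' @export
simulate_selection <- function(catalogs, suppressors,
                               scenario = screen_scenario(),
                               config = lego_config()) {
  if (length(catalogs) == 0L ||
      any(!vapply(catalogs, function(x) nrow(x$catalog) > 0, logical(1)))) {
    stop("empty library: no vectors to select from", call. = FALSE)
  }
  guides <- sort(unique(unlist(lapply(catalogs, function(x)
    x$catalog$guide[x$catalog$realizable]))))
  hits_suppressor <- rep(FALSE, length(guides))
  for (x in catalogs) {
    cc <- x$catalog[x$catalog$realizable, ]
    hit <- tapply(cc$transcript_id %in% suppressors, cc$guide, any)
    m <- match(names(hit), guides)
    hits_suppressor[m] <- hits_suppressor[m] | as.vector(hit)
  }
  functional <- runif(length(guides)) >= scenario$nonfunctional_fraction
  efficacy <- ifelse(functional,
                     runif(length(guides), config$knockdown_range[1],
                           config$knockdown_range[2]), 0)
  off_target <- runif(length(guides)) < scenario$off_target_rate
  transforming <- (hits_suppressor &
                     efficacy >= scenario$knockdown_threshold) | off_target
  truth <- data.frame(guide = guides, efficacy = efficacy,
                      targets_suppressor = hits_suppressor,
                      off_target = off_target,
                      transforming = transforming,
                      stringsAsFactors = FALSE)
  tr <- setNames(transforming, guides)

  count_one <- function(lib_name) {
    cc <- catalogs[[lib_name]]$catalog
    cc <- cc[cc$realizable & cc$weight > 0, ]
    boost <- ifelse(tr[cc$guide], scenario$growth_boost, 1)
    samples <- list()
    w <- cc$weight
    pre <- as.vector(rmultinom(1, scenario$library_cells, w))
    samples[["pre"]] <- pre
    cur <- pre
    for (r in seq_len(scenario$rounds)) {
      w2 <- cur * boost
      if (sum(w2) == 0) w2 <- rep(1, length(w2))
      cur <- as.vector(rmultinom(1, scenario$library_cells, w2))
      samples[[paste0("post", r)]] <- cur
    }
    do.call(rbind, lapply(names(samples), function(s) {
      data.frame(library = lib_name, sample = s,
                 vector_id = cc$vector_id, guide = cc$guide,
                 count = samples[[s]], stringsAsFactors = FALSE)
    }))
  }
  counts <- do.call(rbind, lapply(names(catalogs), count_one))
  list(counts = counts, vector_truth = truth)
}

#' Emit error-bearing FASTQ reads for one sample
#'
#' Each read is \code{flank + G + guide + loop + revcomp(G + guide) + flank}
#' with independent per-base substitution errors; the read count per vector is
#' a multinomial draw proportional to its copy number.
#'
#' @param counts data.frame with \code{guide} and \code{count} for one sample.
#' @param scenario A [screen_scenario()].
#' @param config A [lego_config()].
#' @param path Optional FASTQ output path; when given the reads are written
#'   and the path returned invisibly.
#' @param sample_name Prefix for read ids.
#' @return data.frame of reads (id, seq) unless \code{path} is given.
#' @export
emit_reads <- function(counts, scenario = screen_scenario(),
                       config = lego_config(), path = NULL,
                       sample_name = "s") {
  counts <- counts[counts$count > 0, ]
  if (nrow(counts) == 0L) stop("no nonzero counts to sequence", call. = FALSE)
  nread <- as.vector(rmultinom(1, scenario$reads_per_sample, counts$count))
  stems <- paste0("G", counts$guide)
  templates <- paste0(.FLANK5, stems, config$loop_seq,
                      reverse_complement(stems), .FLANK3)
  seqs <- rep(templates, nread)
  seqs <- .apply_substitution_errors(seqs, scenario$sequencing_error_rate)
  reads <- data.frame(id = sprintf("%s_r%07d", sample_name,
                                   seq_along(seqs)),
                      seq = seqs, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(path))
  }
  reads
}

# Independent per-base substitutions to a different base at rate `rate`.
.apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}
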