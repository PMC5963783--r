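# Deconvolution: turn sequencing reads of amplified shRNA inserts into
# per-vector tag counts and call transforming vectors.

# Hamming distance between equal-length string vectors, computed per
# character position (vectorized over reads).
.hamming_vec <- function(x, y, len) {
  mm <- integer(length(x))
  for (j in seq_len(len)) {
    mm <- mm + (substr(x, j, j) != substr(y, j, j))
  }
  mm
}

#' Extract canonical hairpin tags from reads
#'
#' Locates the loop (exactly, or with one substitution via a positional
#' scan), takes \code{stem_len} nt on each side, and accepts a read iff the
#' total number of mismatches across the loop match plus the
#' stem/reverse-complement-stem comparison is at most
#' \code{max_tag_mismatches}. The canonical tag is the upstream stem read
#' 5'->3'; at a position where the two stems disagree the evidence is one
#' base against one, so the upstream base wins the tie. Reads without an
#' acceptable stem-loop-stem structure are discarded and counted.
#'
#' @param reads Character vector of read sequences, or a data.frame from
#'   [read_fastq()].
#' @param config A [lego_config()].
#' @return List of class \code{tag_extraction}: \code{counts} (data.frame
#'   tag/count, descending), \code{n_reads}, \code{n_accepted},
#'   \code{n_discarded}.
#' @export
extract_tags <- function(reads, config = lego_config()) {
  if (is.data.frame(reads)) reads <- reads$seq
  loop <- config$loop_seq
  k <- config$loop_len
  if (nchar(loop) != k) stop("loop sequence length does not match loop_len",
                             call. = FALSE)
  stem <- config$stem_len
  allow <- config$max_tag_mismatches
  n <- length(reads)
  tags <- rep(NA_character_, n)

  # fast path: exact loop match at a position with full stems on both sides
  pos <- regexpr(loop, reads, fixed = TRUE)
  len <- nchar(reads)
  ok <- pos >= stem + 1L & pos + k + stem - 1L <= len
  if (any(ok)) {
    up <- substr(reads[ok], pos[ok] - stem, pos[ok] - 1L)
    down <- substr(reads[ok], pos[ok] + k, pos[ok] + k + stem - 1L)
    mm <- .hamming_vec(up, reverse_complement(down), stem)
    acc <- mm <= allow
    tags[which(ok)[acc]] <- up[acc]
  }
  # fallback scan: reads without an exact, well-placed loop (e.g. a
  # sequencing error inside the loop)
  todo <- which(is.na(tags))
  if (length(todo) > 0L) {
    tags[todo] <- .scan_tags(reads[todo], loop, stem, allow)
  }
  accepted <- tags[!is.na(tags)]
  counts <- if (length(accepted) > 0L) {
    tab <- sort(table(accepted), decreasing = TRUE)
    data.frame(tag = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag = character(), count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, n_reads = n,
                 n_accepted = length(accepted),
                 n_discarded = n - length(accepted)),
            class = "tag_extraction")
}

# Positional scan over all valid loop offsets, vectorized over reads per
# offset; keeps the lowest-total-mismatch acceptable structure (leftmost on
# ties).
.scan_tags <- function(reads, loop, stem, allow) {
  n <- length(reads)
  len <- nchar(reads)
  best_mm <- rep(allow + 1L, n)
  best_tag <- rep(NA_character_, n)
  loop_chars <- strsplit(loop, "")[[1]]
  k <- length(loop_chars)
  max_off <- max(len) - k - stem + 1L
  for (o in seq(stem + 1L, max_off)) {
    valid <- which(o + k + stem - 1L <= len & best_mm > 0L)
    if (length(valid) == 0L) next
    lmm <- integer(length(valid))
    for (j in seq_len(k)) {
      lmm <- lmm + (substr(reads[valid], o + j - 1L, o + j - 1L) != loop_chars[j])
    }
    cand <- which(lmm <= allow)
    if (length(cand) == 0L) next
    ci <- valid[cand]
    up <- substr(reads[ci], o - stem, o - 1L)
    down <- substr(reads[ci], o + k, o + k + stem - 1L)
    tot <- lmm[cand] + .hamming_vec(up, reverse_complement(down), stem)
    improve <- tot <= allow & tot < best_mm[ci]
    best_mm[ci[improve]] <- tot[improve]
    best_tag[ci[improve]] <- up[improve]
  }
  best_tag
}

#' Error-correct a tag count table by absorbing near-duplicate tags
#'
#' Tags within Hamming distance 1 of a tag at least \code{ratio} times more
#' abundant are absorbed into it (sequencing/PCR error correction). Can be
#' disabled by calling with \code{ratio = Inf}.
#'
#' @param counts data.frame with \code{tag} and \code{count}.
#' @param ratio Minimum abundance ratio for absorption.
#' @return data.frame with the same columns, merged.
#' @export
merge_error_tags <- function(counts, ratio = 10) {
  if (nrow(counts) < 2L || !is.finite(ratio)) return(counts)
  counts <- counts[order(-counts$count, counts$tag), ]
  tags <- counts$tag
  cnt <- counts$count
  n <- length(tags)
  width <- nchar(tags[1])
  bases <- c("A", "C", "G", "T")
  # best (most abundant) Hamming-1 neighbor of every tag, vectorized per
  # (position, base) over all tags at once
  best_count <- rep(-Inf, n)
  best_idx <- rep(NA_integer_, n)
  for (p in seq_len(width)) {
    pre <- substr(tags, 1L, p - 1L)
    suf <- substr(tags, p + 1L, width)
    old <- substr(tags, p, p)
    for (b in bases) {
      sel <- which(old != b)
      if (length(sel) == 0L) next
      nb <- paste0(pre[sel], b, suf[sel])
      m <- match(nb, tags)
      hit <- which(!is.na(m))
      if (length(hit) == 0L) next
      i <- sel[hit]
      better <- cnt[m[hit]] > best_count[i]
      best_count[i[better]] <- cnt[m[hit]][better]
      best_idx[i[better]] <- m[hit][better]
    }
  }
  absorb_to <- ifelse(!is.na(best_idx) & best_count >= ratio * cnt,
                      best_idx, NA_integer_)
  # follow absorption chains (an absorbed tag never receives mass)
  final <- seq_len(n)
  has <- !is.na(absorb_to)
  final[has] <- absorb_to[has]
  repeat {
    nxt <- ifelse(!is.na(absorb_to[final]), absorb_to[final], final)
    if (all(nxt == final)) break
    final <- nxt
  }
  merged <- tapply(cnt, final, sum)
  keep <- as.integer(names(merged))
  out <- data.frame(tag = tags[keep], count = as.integer(merged),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$count, out$tag), , drop = FALSE]
}

#' Normalize a tag count table to counts per million
#'
#' Per-sample scaling so copy numbers are comparable between experiments;
#' raw counts are retained.
#'
#' @param table Long data.frame with columns \code{library}, \code{sample},
#'   \code{tag}, \code{count}.
#' @return The table with an added \code{cpm} column (each library/sample
#'   sums to 1e6).
#' @export
normalize_counts <- function(table) {
  key <- paste(table$library, table$sample)
  totals <- tapply(table$count, key, sum)
  if (any(totals == 0)) {
    stop("empty sample(s): ", paste(names(totals)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  table$cpm <- table$count / as.numeric(totals[key]) * 1e6
  table
}

#' Call transforming vectors from pre/post-selection counts
#'
#' The enrichment ratio is \code{(post_cpm + eps) / (pre_cpm + eps)} with the
#' configured pseudocount, so tags appearing from zero remain callable; a
#' vector is transforming iff the ratio strictly exceeds the enrichment
#' threshold. Both selection rounds are reported; the default contrast is
#' pre-selection vs the final round.
#'
#' @param table Normalized long table from [normalize_counts()] with samples
#'   \code{pre} and \code{post<r>}.
#' @param config A [lego_config()].
#' @param contrast Which post sample to compare against \code{pre}.
#' @return data.frame with one row per (tag, library): cpm of each sample,
#'   per-round enrichment ratios, \code{enrichment_ratio} for the chosen
#'   contrast, and \code{is_transforming}.
#' @export
call_transforming <- function(table, config = lego_config(),
                              contrast = NULL) {
  samples <- unique(table$sample)
  if (!"pre" %in% samples) stop("missing 'pre' sample", call. = FALSE)
  posts <- sort(samples[grepl("^post", samples)])
  if (length(posts) == 0L) stop("missing post-selection sample", call. = FALSE)
  if (is.null(contrast)) contrast <- posts[length(posts)]
  if (!contrast %in% posts) stop("unknown contrast sample: ", contrast,
                                 call. = FALSE)
  eps <- config$pseudocount
  wide <- NULL
  for (s in c("pre", posts)) {
    sub <- table[table$sample == s, c("library", "tag", "cpm")]
    names(sub)[3] <- paste0("cpm_", s)
    wide <- if (is.null(wide)) sub else
      merge(wide, sub, by = c("library", "tag"), all = TRUE)
  }
  cpm_cols <- paste0("cpm_", c("pre", posts))
  for (cl in cpm_cols) wide[[cl]][is.na(wide[[cl]])] <- 0
  for (s in posts) {
    wide[[paste0("ratio_", s)]] <-
      (wide[[paste0("cpm_", s)]] + eps) / (wide$cpm_pre + eps)
  }
  wide$enrichment_ratio <- wide[[paste0("ratio_", contrast)]]
  wide$is_transforming <- wide$enrichment_ratio > config$fold_enrichment_min
  wide[order(wide$library, -wide$enrichment_ratio), , drop = FALSE]
}

#' @export
print.tag_extraction <- function(x, ...) {
  cat("Tag extraction: ", x$n_accepted, "/", x$n_reads,
      " reads accepted (", x$n_discarded, " discarded), ",
      nrow(x$counts), " distinct tags\n", sep = "")
  invisible(x)
}
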