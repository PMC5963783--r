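# Target mapping: tags -> transcripts, redundancy clustering, minimal
# set-cover target identification, and the AluI-coverage filter.

#' Build a searchable transcript database
#'
#' Transcripts with more than \code{max_alui_sites_db} AluI sites are excluded
#' (highly repetitive entries). The index holds every candidate guide the
#' enzymatic model can produce (both strands, abutting an AluI cut in the
#' produced orientation) for O(1) tag lookup.
#'
#' @param transcripts Transcript data.frame (id, gene_label, seq).
#' @param config A [lego_config()].
#' @return Object of class \code{lego_db}: filtered transcripts, per-transcript
#'   AluI site counts, and the guide index.
#' @export
build_db <- function(transcripts, config = lego_config()) {
  sites <- count_alui_sites(transcripts$seq)
  keep <- sites <= config$max_alui_sites_db
  transcripts <- transcripts[keep, , drop = FALSE]
  sites <- sites[keep]
  if (nrow(transcripts) == 0L) {
    stop("empty database after AluI-site filtering", call. = FALSE)
  }
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(transcripts))) {
    v <- enumerate_vectors(transcripts[i, ], config)
    v <- v[v$realizable, , drop = FALSE]
    for (j in seq_len(nrow(v))) {
      g <- v$guide[j]
      hit <- data.frame(transcript_id = v$transcript_id[j],
                        gene_label = v$gene_label[j],
                        site_index = v$site_index[j], side = v$side[j],
                        stringsAsFactors = FALSE)
      prev <- if (exists(g, envir = index, inherits = FALSE))
        get(g, envir = index) else NULL
      assign(g, rbind(prev, hit), envir = index)
    }
  }
  structure(list(transcripts = transcripts,
                 alui_sites = setNames(sites, transcripts$id),
                 index = index,
                 config = config),
            class = "lego_db")
}

#' @export
print.lego_db <- function(x, ...) {
  cat("LEGO transcript DB:", nrow(x$transcripts), "transcripts,",
      sum(x$alui_sites), "AluI sites indexed\n")
  invisible(x)
}

#' Map tags to transcripts
#'
#' A tag hits a transcript iff it (or its reverse complement) matches a
#' transcript substring with at most \code{max_map_mismatches} mismatches
#' (default 0) and the match abuts an AluI cut in the orientation the
#' enzymatic model produces. With \code{require_cut = FALSE} the match may
#' lie anywhere (reference-free inputs); multi-hit tags retain all hits.
#'
#' @param tags Character vector of canonical tags.
#' @param db A [build_db()] result.
#' @param config A [lego_config()].
#' @param require_cut Whether matches must abut an AluI cut.
#' @return List with \code{hits} (data.frame tag, transcript_id, gene_label,
#'   site_index, side) and \code{unmapped} (character vector).
#' @export
map_tags <- function(tags, db, config = db$config, require_cut = TRUE) {
  tags <- unique(tags)
  res <- vector("list", length(tags))
  unmapped <- character(0)
  for (i in seq_along(tags)) {
    tg <- tags[i]
    hit <- NULL
    if (config$max_map_mismatches == 0L && require_cut) {
      if (exists(tg, envir = db$index, inherits = FALSE)) {
        hit <- get(tg, envir = db$index)
      }
    } else {
      hit <- .map_tag_scan(tg, db, config, require_cut)
    }
    if (is.null(hit) || nrow(hit) == 0L) {
      unmapped <- c(unmapped, tg)
    } else {
      hit$tag <- tg
      res[[i]] <- hit
    }
  }
  hits <- do.call(rbind, res)
  if (is.null(hits)) {
    hits <- data.frame(transcript_id = character(), gene_label = character(),
                       site_index = integer(), side = character(),
                       tag = character(), stringsAsFactors = FALSE)
  }
  list(hits = hits[, c("tag", "transcript_id", "gene_label", "site_index",
                       "side")],
       unmapped = unmapped)
}

# Mismatch-tolerant / cut-free scan over both strands of every transcript.
.map_tag_scan <- function(tag, db, config, require_cut) {
  maxmm <- config$max_map_mismatches
  out <- NULL
  for (i in seq_len(nrow(db$transcripts))) {
    tr <- db$transcripts[i, ]
    for (strand in c("+", "-")) {
      query <- if (strand == "+") tag else reverse_complement(tag)
      m <- Biostrings::matchPattern(query, Biostrings::DNAString(tr$seq),
                                    max.mismatch = maxmm)
      if (length(m) == 0L) next
      if (require_cut) {
        cuts <- alui_cut_positions(tr$seq)
        starts <- Biostrings::start(m)
        ends <- Biostrings::end(m)
        # sense guide starts at a cut (right side); antisense guide ends at
        # a cut (left side, reading away from the cut on the bottom strand)
        okpos <- if (strand == "+") (starts - 1L) %in% cuts
                 else ends %in% cuts
        if (!any(okpos)) next
      }
      out <- rbind(out, data.frame(transcript_id = tr$id,
                                   gene_label = tr$gene_label,
                                   site_index = NA_integer_, side = strand,
                                   stringsAsFactors = FALSE))
      break
    }
  }
  out
}

#' Cluster redundant transcripts
#'
#' Pairwise identity is computed by local alignment; two transcripts are
#' linked when identity over the aligned span is at least \code{identity_min}
#' and the alignment covers at least \code{coverage_min} of the shorter
#' sequence (single-sided coverage). Clusters are connected components of the
#' link graph; the representative is the longest member (ties by id). A
#' cluster is ambiguous when its members carry two or more distinct gene
#' labels (multiple gene copies).
#'
#' @param transcripts Transcript data.frame of the hit transcripts.
#' @param config A [lego_config()].
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{representative}, \code{members} (comma-joined), \code{gene_labels},
#'   \code{alui_sites} (of the representative), \code{max_possible_vectors},
#'   \code{ambiguous}.
#' @export
cluster_transcripts <- function(transcripts, config = lego_config()) {
  n <- nrow(transcripts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (.transcripts_linked(transcripts$seq[i], transcripts$seq[j],
                                config)) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    sub <- transcripts[idx, , drop = FALSE]
    rep_i <- order(-sub$length, sub$id)[1]
    labels <- sort(unique(sub$gene_label))
    sites <- count_alui_sites(sub$seq[rep_i])
    data.frame(representative = sub$id[rep_i],
               members = paste(sort(sub$id), collapse = ","),
               gene_labels = paste(labels, collapse = ","),
               n_members = nrow(sub),
               alui_sites = sites,
               max_possible_vectors = 2L * sites,
               ambiguous = length(labels) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$representative), , drop = FALSE]
  out$cluster_id <- paste0("c", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", "representative", "members", "gene_labels",
          "n_members", "alui_sites", "max_possible_vectors", "ambiguous")]
}

.transcripts_linked <- function(a, b, config) {
  if (identical(a, b)) return(TRUE)
  shorter <- min(nchar(a), nchar(b))
  pat <- if (nchar(a) <= nchar(b)) a else b
  sub <- if (nchar(a) <= nchar(b)) b else a
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(pat, sub, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1)
  identity <- Biostrings::pid(pa, type = "PID1") / 100
  span <- Biostrings::width(Biostrings::pattern(pa))
  coverage <- span / shorter
  identity >= config$identity_min && coverage >= config$coverage_min
}

#' Minimal set of clusters explaining all tags
#'
#' Exact minimum-cardinality set cover by breadth-first enumeration over
#' subset sizes 1, 2, ...; ties are broken by more total tags explained
#' (summed over members), then by lexicographic cluster-id vector. When more
#' than \code{exact_limit} candidate clusters are present an additive greedy
#' cover is used instead, with a warning.
#'
#' @param cluster_tags Named list: cluster_id -> character vector of tags the
#'   cluster explains.
#' @param tags Character vector of tags that must all be explained.
#' @param exact_limit Maximum number of clusters for exact enumeration.
#' @return Character vector of selected cluster ids.
#' @export
minimal_cluster_set <- function(cluster_tags, tags, exact_limit = 24L) {
  tags <- unique(tags)
  cluster_tags <- lapply(cluster_tags, function(x) intersect(unique(x), tags))
  covered <- unique(unlist(cluster_tags))
  orphan <- setdiff(tags, covered)
  if (length(orphan) > 0L) {
    stop("tags not explained by any cluster: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  ids <- names(cluster_tags)
  if (length(ids) > exact_limit) {
    warning("more than ", exact_limit,
            " candidate clusters; falling back to greedy set cover")
    return(.greedy_cover(cluster_tags, tags))
  }
  m <- length(tags)
  masks <- lapply(cluster_tags, function(x) tags %in% x)
  sizes <- vapply(masks, sum, numeric(1))
  for (s in seq_along(ids)) {
    combos <- combn(length(ids), s)
    best <- NULL
    best_total <- -Inf
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      cov <- Reduce(`|`, masks[sel])
      if (!all(cov)) next
      total <- sum(sizes[sel])
      cand_ids <- sort(ids[sel])
      if (is.null(best) || total > best_total ||
          (total == best_total && .lex_less(cand_ids, best))) {
        best <- cand_ids
        best_total <- total
      }
    }
    if (!is.null(best)) return(best)
  }
  stop("no cover found", call. = FALSE)  # unreachable: union covers all tags
}

.lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

.greedy_cover <- function(cluster_tags, tags) {
  ids <- names(cluster_tags)
  sizes <- vapply(cluster_tags, length, integer(1))
  chosen <- character(0)
  uncovered <- tags
  while (length(uncovered) > 0L) {
    gain <- vapply(cluster_tags, function(x) length(intersect(x, uncovered)),
                   integer(1))
    ord <- order(-gain, -sizes, ids)
    pick <- ord[1]
    if (gain[pick] == 0L) stop("greedy cover stalled", call. = FALSE)
    chosen <- c(chosen, ids[pick])
    uncovered <- setdiff(uncovered, cluster_tags[[pick]])
  }
  sort(chosen)
}

#' Filter clusters by AluI-site coverage and ambiguity
#'
#' Coverage is the number of distinct transforming tags the cluster explains
#' divided by the theoretical vector maximum of its representative (2 per
#' AluI site); a cluster survives iff coverage strictly exceeds
#' \code{alui_coverage_min}. Ambiguous clusters (multiple gene copies) are
#' removed, as are representatives without AluI sites (with a warning).
#'
#' @param clusters Cluster data.frame from [cluster_transcripts()] restricted
#'   to the selected set, with an added \code{n_tags} column (distinct
#'   transforming tags explained).
#' @param config A [lego_config()].
#' @return The clusters with \code{coverage} and \code{status} columns;
#'   status is one of \code{selected}, \code{low_coverage}, \code{ambiguous},
#'   \code{no_alui_sites}.
#' @export
filter_alui_coverage <- function(clusters, config = lego_config()) {
  status <- rep("selected", nrow(clusters))
  nosite <- clusters$alui_sites == 0L
  if (any(nosite)) {
    warning("removing cluster(s) whose representative has no AluI site: ",
            paste(clusters$cluster_id[nosite], collapse = ", "))
    status[nosite] <- "no_alui_sites"
  }
  coverage <- ifelse(clusters$max_possible_vectors > 0,
                     clusters$n_tags / clusters$max_possible_vectors, 0)
  status[!nosite & coverage <= config$alui_coverage_min] <- "low_coverage"
  status[clusters$ambiguous] <- "ambiguous"
  clusters$coverage <- coverage
  clusters$status <- status
  clusters
}
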