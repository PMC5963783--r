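# In-silico enzymatic library construction.
#
# AluI cuts the blunt site AG^CT. Coordinates are 0-based half-open; a cut
# position is recorded as the index of the C in AGCT, so a fragment that
# starts at a cut begins with "CT" and a fragment that ends at a cut ends
# with "AG".

alui_cut_positions <- function(seq) {
  m <- gregexpr("AGCT", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) + 1L  # 0-based index of the C = (start - 1) + 2
}

#' Count AluI (AGCT) sites in a sequence
#'
#' @param seq Character vector of DNA sequences.
#' @return Integer vector of site counts.
#' @export
count_alui_sites <- function(seq) {
  vapply(seq, function(s) length(alui_cut_positions(s)), integer(1),
         USE.NAMES = FALSE)
}

#' Digest a transcript with AluI
#'
#' Cuts between the G and C of every AGCT occurrence. The fragments tile the
#' transcript without gaps or overlaps; a transcript with no site yields a
#' single fragment.
#'
#' @param transcript One row of a transcript data.frame (or a list) with
#'   \code{id} and \code{seq}.
#' @return data.frame with columns \code{transcript_id}, \code{start},
#'   \code{end} (0-based half-open), \code{seq}, \code{left_cut},
#'   \code{right_cut}.
#' @examples
#' digest_alui(list(id = "t", seq = "AAAAGCTAAAA"))$seq  # "AAAAG" "CTAAAA"
#' @export
digest_alui <- function(transcript) {
  seq <- transcript$seq
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  cuts <- alui_cut_positions(seq)
  bounds <- c(0L, cuts, nchar(seq))
  n <- length(bounds) - 1L
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  data.frame(
    transcript_id = rep(transcript$id, n),
    start = start,
    end = end,
    seq = substring(seq, start + 1L, end),
    left_cut = c(FALSE, rep(TRUE, n - 1L)),
    right_cut = c(rep(TRUE, n - 1L), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Enumerate candidate shRNA vectors of a transcript
#'
#' Two vectors can be produced from each AluI site: the right-side guide is
#' the first \code{stem_len} nt of the downstream fragment (top strand,
#' beginning "CT"), and the left-side guide is the first \code{stem_len} nt of
#' the reverse complement of the upstream fragment (bottom strand, reading
#' away from the cut, also beginning "CT"). Candidates whose source fragment
#' is shorter than \code{stem_len} are unrealizable but still count toward
#' the theoretical maximum of 2 vectors per site, which is the denominator of
#' the percentage in the final ranking.
#'
#' @param transcript One transcript row/list with \code{id}, \code{seq} and
#'   optionally \code{gene_label}.
#' @param config A [lego_config()].
#' @return data.frame with columns \code{vector_id}, \code{transcript_id},
#'   \code{gene_label}, \code{site_index}, \code{side}, \code{guide}
#'   (NA when unrealizable), \code{realizable}; attribute
#'   \code{max_possible} = 2 x number of AluI sites.
#' @export
enumerate_vectors <- function(transcript, config = lego_config()) {
  seq <- transcript$seq
  gene <- if (!is.null(transcript$gene_label)) transcript$gene_label
          else transcript$id
  stem <- config$stem_len
  cuts <- alui_cut_positions(seq)
  s <- length(cuts)
  if (s == 0L) {
    out <- data.frame(vector_id = character(), transcript_id = character(),
                      gene_label = character(), site_index = integer(),
                      side = character(), guide = character(),
                      realizable = logical(), stringsAsFactors = FALSE)
    attr(out, "max_possible") <- 0L
    return(out)
  }
  bounds <- c(0L, cuts, nchar(seq))
  # fragment i spans [bounds[i], bounds[i+1]); site j sits between fragments
  # j and j+1
  up_len <- cuts - bounds[seq_len(s)]
  down_len <- bounds[seq_len(s) + 2L] - cuts
  left_ok <- up_len >= stem
  right_ok <- down_len >= stem
  left_guide <- ifelse(left_ok,
                       reverse_complement(substring(seq, cuts - stem + 1L, cuts)),
                       NA_character_)
  right_guide <- ifelse(right_ok,
                        substring(seq, cuts + 1L, cuts + stem),
                        NA_character_)
  out <- data.frame(
    vector_id = paste0(transcript$id, ":", rep(seq_len(s), each = 2L), ":",
                       rep(c("left", "right"), s)),
    transcript_id = transcript$id,
    gene_label = gene,
    site_index = rep(seq_len(s), each = 2L),
    side = rep(c("left", "right"), s),
    guide = as.vector(rbind(left_guide, right_guide)),
    realizable = as.vector(rbind(left_ok, right_ok)),
    stringsAsFactors = FALSE
  )
  attr(out, "max_possible") <- 2L * s
  out
}

#' Adapter geometry of the enzymatic construction
#'
#' MmeI cuts 18 bp into the cDNA leaving a 2-nt overhang (hence 20-nt guides
#' by default); the looped adapter C contributes the 9-nt loop plus a
#' double-stranded core later trimmed by BsgI (16-bp offset); BpmI (16-bp
#' offset) releases the insert. The geometry must satisfy
#' \code{2*adapterA_residual + 2*stem_len + adapterC_core_len == insert_len}.
#' With the default residual arm of 0 (BpmI cuts exactly at the AluI
#' junction, leaving AG overhangs) and 20-nt stems, the adapter-C core is
#' fixed at 51 nt by the 91-bp insert identity.
#'
#' @param stem_len Stem length (19 or 20 nt).
#' @param loop_len Loop length in nt.
#' @param insert_len_expected Expected double-stranded insert length in bp.
#' @param adapterA_residual Residual adapter-A arm left on each side after
#'   BpmI digestion, in nt.
#' @return An object of class \code{adapter_geometry}.
#' @export
adapter_geometry <- function(stem_len = 20L, loop_len = 9L,
                             insert_len_expected = 91L,
                             adapterA_residual = 0L) {
  core <- insert_len_expected - 2L * adapterA_residual - 2L * stem_len
  geom <- list(
    stem_len = as.integer(stem_len),
    loop_len = as.integer(loop_len),
    adapterA_residual = as.integer(adapterA_residual),
    adapterC_core_len = as.integer(core),
    mmeI_capture = 18L,
    mmeI_overhang = 2L,
    bpmI_offset = 16L,
    bsgI_offset = 16L,
    insert_len_expected = as.integer(insert_len_expected)
  )
  if (geom$adapterC_core_len < geom$loop_len) {
    stop("adapter geometry violates the insert-length identity: ",
         "the adapter-C core (", geom$adapterC_core_len,
         " nt) cannot hold the ", geom$loop_len, "-nt loop", call. = FALSE)
  }
  if (geom$adapterA_residual < 0L) {
    stop("adapterA_residual must be >= 0", call. = FALSE)
  }
  class(geom) <- "adapter_geometry"
  geom
}

# Fixed synthetic adapter sequences. The published adapter base sequences are
# not modeled; these stand-ins satisfy the geometry and avoid spurious AluI
# sites or loop matches (A/C alphabet only).
.adapter_filler <- function(n) {
  if (n == 0L) return("")
  substr(strrep("CA", ceiling(n / 2)), 1L, n)
}

#' Build the double-stranded 91-bp insert for a vector
#'
#' Symbolic simulation of the enzymatic chain (MmeI capture, adapter-C
#' ligation, nicking, Klenow extension, BpmI release): the insert is
#' \code{[arm][stem][adapter-C core incl. loop][revcomp(stem)][arm]} with AG
#' overhangs (the complementary ligation partner of the CT overhangs on the
#' recipient vector).
#'
#' @param vector One realizable vector row from [enumerate_vectors()].
#' @param geometry An [adapter_geometry()]; its \code{stem_len} must match
#'   the guide.
#' @param loop_seq Loop sequence placed at the center of the adapter-C core.
#' @return List of class \code{lego_insert} with elements \code{insert},
#'   \code{length}, \code{stem}, \code{overhang} ("AG"), and the component
#'   breakdown.
#' @export
build_insert <- function(vector, geometry = adapter_geometry(),
                         loop_seq = "TTCAAGAGA") {
  if (is.na(vector$guide)) {
    stop("build_insert requires a realizable vector", call. = FALSE)
  }
  if (nchar(vector$guide) != geometry$stem_len) {
    stop("guide length (", nchar(vector$guide),
         ") does not match geometry stem_len (", geometry$stem_len, ")",
         call. = FALSE)
  }
  if (nchar(loop_seq) != geometry$loop_len) {
    stop("loop_seq must have ", geometry$loop_len, " nt", call. = FALSE)
  }
  stem <- vector$guide
  pad <- geometry$adapterC_core_len - geometry$loop_len
  pad5 <- pad %/% 2L
  core <- paste0(.adapter_filler(pad5), loop_seq,
                 .adapter_filler(pad - pad5))
  arm <- .adapter_filler(geometry$adapterA_residual)
  insert <- paste0(arm, stem, core, reverse_complement(stem),
                   reverse_complement(arm))
  out <- list(
    insert = insert,
    length = nchar(insert),
    stem = stem,
    core = core,
    arm = arm,
    overhang = "AG",
    vector_id = vector$vector_id
  )
  stopifnot(out$length == geometry$insert_len_expected)
  class(out) <- "lego_insert"
  out
}

#' @export
print.lego_insert <- function(x, ...) {
  cat("LEGO shRNA insert (", x$length, " bp, ", x$overhang,
      " overhangs) from ", x$vector_id, "\n", sep = "")
  cat("  stem: ", x$stem, "\n", sep = "")
  invisible(x)
}

#' Hairpin transcript produced by a vector
#'
#' The vector's G reconstitutes part of the AluI site, so transcription starts
#' with GCT when the guide begins with CT; the hairpin is bounded by the
#' TTTTT termination signal.
#'
#' @param vector One realizable vector row.
#' @param config A [lego_config()] supplying the loop sequence.
#' @return The hairpin as a DNA-alphabet string:
#'   \code{G + guide + loop + revcomp(G + guide) + TTTTT}.
#' @export
assemble_vector_transcript <- function(vector, config = lego_config()) {
  if (is.na(vector$guide)) {
    stop("assemble_vector_transcript requires a realizable vector",
         call. = FALSE)
  }
  stem <- paste0("G", vector$guide)
  paste0(stem, config$loop_seq, reverse_complement(stem), "TTTTT")
}
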