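#' @import methods
#' @importFrom stats rbinom rlnorm rnorm runif rmultinom setNames aggregate
#' @importFrom utils combn read.delim write.table head
NULL

# Reference transcripts are single-stranded cDNA in sense orientation; the DB
# alphabet is strict ACGT, reads may additionally carry N.
DNA_STRICT <- "^[ACGT]*$"
DNA_READ <- "^[ACGTN]*$"

#' Read reference transcripts from a FASTA file
#'
#' Gene labels ride in the FASTA header as a \code{gene=} token (the
#' cluster-ambiguity rule downstream needs gene identity); headers without the
#' token default to the record id.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{id}, \code{gene_label}, \code{seq},
#'   \code{length}; one row per record.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 gene=MK3", "AGCTAG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    return(data.frame(id = character(), gene_label = character(),
                      seq = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("gene=", headers),
                 sub("^.*gene=([^\\s]+).*$", "\\1", headers, perl = TRUE),
                 ids)
  seqs <- toupper(as.character(set))
  bad <- !grepl(DNA_STRICT, seqs)
  if (any(bad)) {
    stop("non-ACGT base in reference record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) < 1L)) stop("empty sequence in FASTA", call. = FALSE)
  data.frame(id = ids, gene_label = gene, seq = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE, row.names = NULL)
}

#' Write transcripts to FASTA
#'
#' Inverse of [read_fasta()]: the \code{gene=} token is emitted so that a
#' round-trip preserves both sequence and gene label.
#'
#' @param transcripts data.frame with \code{id}, \code{gene_label}, \code{seq}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(transcripts$seq)
  names(set) <- paste0(transcripts$id, " gene=", transcripts$gene_label)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read sequencing reads from a FASTQ file
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual},
#'   \code{has_n} (whether the read carries any N base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      has_n = logical(), stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': truncated record at index ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  first <- lines[seq(1L, length(lines), by = 4L)]
  third <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(first, "@") | !startsWith(third, "+"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ '", path, "': bad record structure at index ",
         bad[1], call. = FALSE)
  }
  mism <- which(nchar(lines[seq(2L, length(lines), by = 4L)]) !=
                  nchar(lines[seq(4L, length(lines), by = 4L)]))
  if (length(mism) > 0L) {
    stop("FASTQ sequence/quality length mismatch in '", path,
         "' at record ", mism[1], call. = FALSE)
  }
  parsed <- tryCatch({
    set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(ids = names(set), seqs = as.character(set),
         quals = as.character(Biostrings::quality(set)))
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  seqs <- parsed$seqs
  quals <- parsed$quals
  data.frame(id = parsed$ids, seq = seqs, qual = quals,
             has_n = grepl("N", seqs, fixed = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with \code{id}, \code{seq}, and optionally
#'   \code{qual} (defaults to constant "I").
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized; the complement of N is N. An involution:
#' \code{reverse_complement(reverse_complement(x)) == x}.
#'
#' @param seq Character vector of ACGTN sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GCTAA")  # "TTAGC"
#' @export
reverse_complement <- function(seq) {
  bad <- !grepl(DNA_READ, seq)
  if (any(bad)) {
    stop("reverse_complement: sequence contains characters outside ACGTN",
         call. = FALSE)
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Read / write tab-delimited tables
#'
#' All intermediate tables of the pipeline (count tables, expression tables,
#' hit tables) are tab-delimited with a header row.
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return \code{read_tsv_table}: a data.frame; \code{write_tsv_table}:
#'   \code{path}, invisibly.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
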