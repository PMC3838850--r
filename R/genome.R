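#' Genome sequences
#'
#' A genome sequence is a plain list with elements `id`, `seq` (uppercase
#' character string over A,C,G,T,N) and `length`. All coordinates in the
#' package are 1-based inclusive on the forward strand; reverse-strand
#' features carry forward coordinates with `strand = "-"`.
#'
#' @param id sequence identifier.
#' @param seq nucleotide string; lowercase is folded to uppercase and any
#'   character outside A,C,G,T,N is mapped to N.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- gsub("[^ACGTN]", "N", seq)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  head <- substr(x$seq, 1L, 60L)
  cat(sprintf("<genome_sequence> %s: %d bp\n  %s%s\n", x$id, x$length, head,
              if (x$length > 60L) "..." else ""))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' @param path path to a FASTA file.
#' @return a named list of [genome_sequence()] objects (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA format error at line 1: empty file")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error at line ", first,
         ": expected header starting with '>'")
  # Delegate the actual parse to Biostrings, then normalise letters.
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("FASTA format error at line ", first, ": no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA format error: record with empty header")
  out <- lapply(seq_along(set), function(i)
    genome_sequence(ids[i], as.character(set[[i]])))
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes a list of [genome_sequence()] objects.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq character string over A,C,G,T,N.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Strand-aware subsequence
#'
#' Extracts `[start, end]` (forward coordinates, 1-based inclusive); for
#' `strand == "-"` the reverse complement is returned so the result reads in
#' gene direction.
#'
#' @param genome a [genome_sequence()].
#' @param start,end forward coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(start >= 1L, end <= genome$length, start <= end)
  s <- substr(genome$seq, start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# Integer encoding A=1,C=2,G=3,T=4, N/other = NA. Used by all scoring code.
encode_seq <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  m
}

# Map a forward-strand position to its coordinate on the reverse complement.
mirror_pos <- function(pos, len) len - pos + 1L
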