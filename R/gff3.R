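#' GFF3 input/output
#'
#' Features are held in a plain data.frame with columns `seqid`, `source`,
#' `type`, `start`, `end`, `score` (numeric, NA when missing), `strand`
#' (`"+"`, `"-"` or NA), `phase` (integer or NA) and `attributes` (the raw
#' `key=value;...` string). Coordinates are 1-based inclusive throughout.
#'
#' @param path path to a GFF3 file.
#' @param feature_filter optional character vector of feature types to keep.
#' @return a `gff_features` data.frame (possibly 0-row).
#' @export
read_gff3 <- function(path, feature_filter = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(empty_gff())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop("GFF3 format error at line ", keep[which(nf != 9L)[1L]],
         ": expected 9 tab-separated columns, got ", nf[nf != 9L][1L])
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end   <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | start > end)
  if (length(bad))
    stop("GFF3 format error at line ", keep[bad[1L]],
         ": invalid coordinates (require 1 <= start <= end)")
  strand <- m[, 7L]
  badstr <- which(!strand %in% c("+", "-", ".", "?"))
  if (length(badstr))
    stop("GFF3 format error at line ", keep[badstr[1L]],
         ": unknown strand symbol '", strand[badstr[1L]], "'")
  strand[strand %in% c(".", "?")] <- NA_character_
  score <- suppressWarnings(as.numeric(ifelse(m[, 6L] == ".", NA, m[, 6L])))
  phase <- suppressWarnings(as.integer(ifelse(m[, 8L] == ".", NA, m[, 8L])))
  out <- data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
                    start = start, end = end, score = score, strand = strand,
                    phase = phase, attributes = m[, 9L],
                    stringsAsFactors = FALSE)
  if (!is.null(feature_filter)) out <- out[out$type %in% feature_filter, ]
  rownames(out) <- NULL
  class(out) <- c("gff_features", "data.frame")
  out
}

empty_gff <- function() {
  out <- data.frame(seqid = character(), source = character(),
                    type = character(), start = integer(), end = integer(),
                    score = numeric(), strand = character(), phase = integer(),
                    attributes = character(), stringsAsFactors = FALSE)
  class(out) <- c("gff_features", "data.frame")
  out
}

#' Build a gff_features data.frame from vectors
#'
#' @param seqid,source,type,start,end,score,strand,phase,attributes columns;
#'   recycled to a common length.
#' @export
gff_features <- function(seqid, type, start, end, source = "genechain",
                         score = NA_real_, strand = NA_character_,
                         phase = NA_integer_, attributes = ".") {
  out <- data.frame(seqid = seqid, source = source, type = type,
                    start = as.integer(start), end = as.integer(end),
                    score = as.numeric(score), strand = strand,
                    phase = as.integer(phase), attributes = attributes,
                    stringsAsFactors = FALSE)
  class(out) <- c("gff_features", "data.frame")
  out
}

#' Write features as GFF3
#'
#' Features are written sorted by (seqid, start, end); the round trip through
#' [read_gff3()] is lossless for every column.
#'
#' @param features a `gff_features` data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    o <- order(features$seqid, features$start, features$end)
    f <- features[o, ]
    lines <- paste(f$seqid, f$source, f$type, f$start, f$end,
                   ifelse(is.na(f$score), ".", format_num(f$score)),
                   ifelse(is.na(f$strand), ".", f$strand),
                   ifelse(is.na(f$phase), ".", as.character(f$phase)),
                   ifelse(is.na(f$attributes) | f$attributes == "", ".",
                          f$attributes),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

# Full-precision numeric formatting so numeric round trips are exact.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(".")
    if (!is.finite(v)) return(as.character(v))
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.1f", v))
    sprintf("%.17g", v)
  }, "")
  out
}

#' Extract one attribute from GFF attribute strings
#'
#' @param features a `gff_features` data.frame (or its `attributes` column).
#' @param key attribute key, e.g. `"ID"`.
#' @return character vector (NA where the key is absent).
#' @export
gff_attr <- function(features, key) {
  att <- if (is.data.frame(features)) features$attributes else features
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(att, regexpr(pat, att, perl = TRUE))
  out <- rep(NA_character_, length(att))
  hit <- grepl(pat, att, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

make_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.null(v) || (length(v) == 1 && is.na(v)),
                   TRUE)]
  if (!length(kv)) return(".")
  paste(paste0(names(kv), "=", vapply(kv, as.character, "")), collapse = ";")
}

#' Read spliced EST/mRNA alignments from GFF3
#'
#' Each alignment is a set of `match_part` features sharing an `ID`
#' attribute; `identity` and `coverage` attributes (fractions in `[0,1]`)
#' must be present and agree across the blocks of one alignment.
#'
#' @param path GFF3 file of `match_part` features.
#' @return a list of `spliced_alignment` objects, each a list with
#'   `est_id`, `seqid`, `strand`, `blocks` (2-column matrix of start/end,
#'   ascending), `identity`, `coverage`.
#' @export
read_spliced_alignments <- function(path) {
  f <- read_gff3(path, feature_filter = "match_part")
  if (!nrow(f)) return(list())
  ids <- gff_attr(f, "ID")
  if (anyNA(ids)) stop("spliced alignment format error: match_part without ID")
  split_idx <- split(seq_len(nrow(f)), ids)
  out <- lapply(names(split_idx), function(id) {
    i <- split_idx[[id]]
    g <- f[i, ]
    if (length(unique(g$seqid)) != 1L)
      stop("spliced alignment format error: blocks of ID=", id,
           " on multiple seqids")
    if (anyNA(g$strand) || length(unique(g$strand)) != 1L)
      stop("spliced alignment format error: blocks of ID=", id,
           " on mixed or undefined strands")
    idn <- unique(gff_attr(g, "identity"))
    cov <- unique(gff_attr(g, "coverage"))
    if (length(idn) != 1L || length(cov) != 1L || anyNA(idn) || anyNA(cov))
      stop("spliced alignment format error: ID=", id,
           " identity/coverage missing or inconsistent across blocks")
    o <- order(g$start)
    blocks <- cbind(start = g$start[o], end = g$end[o])
    if (nrow(blocks) > 1L && any(blocks[-1L, 1L] <= blocks[-nrow(blocks), 2L]))
      stop("spliced alignment format error: ID=", id, " blocks overlap")
    spliced_alignment(est_id = id, seqid = g$seqid[1L], strand = g$strand[1L],
                      blocks = blocks, identity = as.numeric(idn),
                      coverage = as.numeric(cov))
  })
  names(out) <- names(split_idx)
  out
}

#' Construct a spliced alignment
#' @param est_id,seqid,strand,blocks,identity,coverage fields; `blocks` is a
#'   2-column matrix of ascending, non-overlapping 1-based intervals.
#' @export
spliced_alignment <- function(est_id, seqid, strand, blocks, identity,
                              coverage) {
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  stopifnot(identity >= 0, identity <= 1, coverage >= 0, coverage <= 1,
            strand %in% c("+", "-"), all(blocks[, 1L] <= blocks[, 2L]))
  structure(list(est_id = est_id, seqid = seqid, strand = strand,
                 blocks = blocks, identity = identity, coverage = coverage),
            class = "spliced_alignment")
}

#' Write spliced alignments as GFF3 match_part features
#' @param alignments list of `spliced_alignment` objects.
#' @param path output path.
#' @export
write_spliced_alignments <- function(alignments, path) {
  rows <- lapply(alignments, function(a) {
    gff_features(seqid = a$seqid, type = "match_part",
                 start = a$blocks[, 1L], end = a$blocks[, 2L],
                 strand = a$strand, source = "est",
                 attributes = make_attr(ID = a$est_id,
                                        identity = a$identity,
                                        coverage = a$coverage))
  })
  write_gff3(do.call(rbind, c(rows, list(make.row.names = FALSE))), path)
}

# Gaps between consecutive blocks of an alignment, as (start,end) intron
# intervals (first/last intronic base). 0-row matrix when unspliced.
alignment_gaps <- function(a) {
  b <- a$blocks
  if (nrow(b) < 2L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = b[-nrow(b), 2L] + 1L, end = b[-1L, 1L] - 1L)
}
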