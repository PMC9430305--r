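#' @importFrom stats median quantile rbinom rgeom rlnorm rnorm runif setNames
#' @importFrom utils head modifyList read.delim tail write.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Create a sequence record
#'
#' A minimal container for a named nucleotide sequence. Sequences are
#' uppercased, RNA U is converted to T, and any character outside
#' \code{A,C,G,T,N} is rejected.
#'
#' @param id sequence identifier (non-empty string).
#' @param seq nucleotide string.
#' @param description optional free-text description.
#' @return an object of class \code{seq_record} with fields \code{id},
#'   \code{description}, \code{seq}.
#' @export
seq_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_seq(seq)
  structure(list(id = id, description = description, seq = seq),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (!nzchar(seq)) stop("empty sequence")
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), VALID_BASES)
  if (length(bad))
    stop("invalid characters in sequence: ", paste(bad, collapse = ","))
  seq
}

#' Read a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file. Sequences are normalized:
#' uppercased, U mapped to T; characters outside A/C/G/T/N raise an error.
#' Empty sequences and records before the first header are parse errors that
#' name the offending line.
#'
#' @param path path to a FASTA file.
#' @return a list of \code{\link{seq_record}} objects; names are record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !hdr[1]) {
    off <- if (length(lines)) which(!grepl("^\\s*$", lines))[1] else 1L
    stop(sprintf("FASTA parse error at line %d: expected '>' header", off))
  }
  idx <- which(hdr)
  recs <- vector("list", length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    h <- sub("^>", "", lines[idx[i]])
    id <- sub("\\s.*$", "", h)
    desc <- sub("^\\S+\\s*", "", h)
    body <- lines[seq.int(idx[i] + 1L, length.out = bounds[i + 1L] - idx[i] - 1L)]
    seq <- paste(gsub("\\s", "", body), collapse = "")
    if (!nzchar(seq))
      stop(sprintf("FASTA parse error at line %d: empty sequence for '%s'",
                   idx[i], id))
    recs[[i]] <- seq_record(id, seq, desc)
  }
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ","))
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of \code{\link{seq_record}} objects.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$seq)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return the reverse complement; N maps to N.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Genomic interval (0-based, half-open)
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' \code{\link{format_interval}} is the only place the 1-based inclusive
#' shift happens.
#'
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must exceed \code{start}.
#' @param strand "+" or "-".
#' @return an object of class \code{genomic_interval}.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  stopifnot(is.character(contig), length(contig) == 1L,
            start >= 0, end > start, strand %in% c("+", "-"))
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "genomic_interval")
}

#' Format an interval in 1-based inclusive style
#'
#' Emits the conventional \code{contig:start-end} notation (1-based,
#' inclusive) used for printed genomic loci.
#'
#' @param x a \code{\link{genomic_interval}}.
#' @return a string.
#' @export
format_interval <- function(x) {
  sprintf("%s:%s-%s", x$contig, format(x$start + 1L, big.mark = ","),
          format(x$end, big.mark = ","))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s (%s)\n", format_interval(x), x$strand))
  invisible(x)
}

#' Write intervals as BED6
#'
#' BED is 0-based half-open, matching internal coordinates, so no shift is
#' applied.
#'
#' @param intervals list of \code{\link{genomic_interval}}.
#' @param path output path.
#' @param names,scores optional BED name and score columns.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL, scores = NULL) {
  n <- length(intervals)
  if (is.null(names)) names <- rep(".", n)
  if (is.null(scores)) scores <- rep(0, n)
  df <- data.frame(
    contig = vapply(intervals, `[[`, "", "contig"),
    start = vapply(intervals, `[[`, 0L, "start"),
    end = vapply(intervals, `[[`, 0L, "end"),
    name = names, score = scores,
    strand = vapply(intervals, `[[`, "", "strand"))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default pairwise alignment scoring
#'
#' Match +2, mismatch -1, gap opening 4, gap extension 1 (a gap of length L
#' costs \code{open + L * ext}). N scores 0 against everything, so it aligns
#' freely; identity counting treats N as a mismatch (see
#' \code{\link{gap_stripped_identity}}).
#'
#' @param match,mismatch,gap_open,gap_ext scoring parameters; gap penalties
#'   are positive costs.
#' @return a list usable as the \code{scoring} argument of
#'   \code{\link{global_align}}.
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap_open = 4, gap_ext = 1) {
  m <- matrix(mismatch, 5, 5, dimnames = list(VALID_BASES, VALID_BASES))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  list(matrix = m, gap_open = gap_open, gap_ext = gap_ext)
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' \code{Biostrings::pairwiseAlignment}).
#'
#' @param a,b \code{\link{seq_record}} objects or plain nucleotide strings.
#' @param scoring scoring scheme from \code{\link{align_scoring}}.
#' @return an object of class \code{pairwise_alignment} with fields
#'   \code{aligned_a}, \code{aligned_b} (gapped strings of equal length) and
#'   \code{score}.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  sa <- if (inherits(a, "seq_record")) a$seq else normalize_seq(a)
  sb <- if (inherits(b, "seq_record")) b$seq else normalize_seq(b)
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  out <- structure(list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)), class = "pairwise_alignment")
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d columns, score %.1f\n",
              nchar(x$aligned_a), x$score))
  invisible(x)
}

#' Gap-stripped percent identity
#'
#' Identity over alignment columns where neither row has a gap:
#' \code{matches / gap-free columns * 100}. N never counts as a match
#' (conservative identity), though it aligns freely.
#'
#' @param aln a \code{pairwise_alignment} from \code{\link{global_align}}.
#' @return percent identity in [0, 100].
#' @export
gap_stripped_identity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("undefined identity: zero gap-free columns")
  ca <- ca[keep]; cb <- cb[keep]
  matches <- sum(ca == cb & ca != "N")
  100 * matches / sum(keep)
}
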