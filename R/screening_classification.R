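# Length screening against subtype consensus lengths and deterministic
# subtype assignment by consensus identity.

#' Subtype consensus reference
#'
#' Couples a subtype label to its consensus sequence; the consensus length is
#' the denominator of the length screen.
#'
#' @param subtype one of "LTR5A", "LTR5B", "LTR5Hs".
#' @param record a \code{\link{seq_record}} holding the consensus.
#' @return an object of class \code{consensus_reference} with fields
#'   \code{subtype}, \code{record}, \code{full_length}.
#' @export
consensus_reference <- function(subtype, record) {
  stopifnot(subtype %in% c("LTR5A", "LTR5B", "LTR5Hs"),
            inherits(record, "seq_record"))
  structure(list(subtype = subtype, record = record,
                 full_length = nchar(record$seq)),
            class = "consensus_reference")
}

#' @export
print.consensus_reference <- function(x, ...) {
  cat(sprintf("<consensus> %s (%s, %d nt)\n", x$subtype, x$record$id,
              x$full_length))
  invisible(x)
}

ref_by_subtype <- function(refs, subtype) {
  for (r in refs) if (r$subtype == subtype) return(r)
  stop("no reference for subtype ", subtype)
}

#' Length screen
#'
#' Keeps a hit iff its element length is at least \code{frac} times the full
#' length of its subtype's consensus reference. Order is preserved; the
#' operation is idempotent.
#'
#' @param hits list of \code{element_hit}s (each carries a subtype call).
#' @param refs list of \code{\link{consensus_reference}}s covering every
#'   subtype present in \code{hits}.
#' @param frac minimum fraction of consensus length (default 0.60).
#' @return the surviving hits, in input order.
#' @export
length_screen <- function(hits, refs, frac = 0.60) {
  keep <- vapply(hits, function(h) {
    len <- h$interval$end - h$interval$start
    len >= frac * ref_by_subtype(refs, h$subtype)$full_length
  }, FALSE)
  hits[keep]
}

#' Screening report
#'
#' @inheritParams length_screen
#' @return data.frame with element length, reference length, and kept flag
#'   per hit.
#' @export
screening_report <- function(hits, refs, frac = 0.60) {
  data.frame(
    locus = vapply(hits, function(h) format_interval(h$interval), ""),
    subtype = vapply(hits, function(h) h$subtype, ""),
    length = vapply(hits, function(h) h$interval$end - h$interval$start, 0L),
    ref_length = vapply(hits, function(h)
      ref_by_subtype(refs, h$subtype)$full_length, 0L),
    kept = vapply(hits, function(h) {
      len <- h$interval$end - h$interval$start
      len >= frac * ref_by_subtype(refs, h$subtype)$full_length
    }, FALSE),
    stringsAsFactors = FALSE)
}

#' Classify an element by consensus identity
#'
#' Assigns the subtype of the reference with the highest gap-stripped
#' identity under global alignment. Ties are broken by higher coverage, then
#' by subtype name order (LTR5A < LTR5B < LTR5Hs). Classification is
#' independent of the length screen.
#'
#' @param element a \code{\link{seq_record}} (or nucleotide string).
#' @param refs list of at least two \code{\link{consensus_reference}}s.
#' @param scoring see \code{\link{align_scoring}}.
#' @return list with \code{subtype} and \code{identity} (percent).
#' @export
classify_by_consensus <- function(element, refs, scoring = align_scoring()) {
  stopifnot(length(refs) >= 2L)
  eseq <- if (inherits(element, "seq_record")) element$seq else normalize_seq(element)
  res <- lapply(refs, function(r) {
    aln <- global_align(eseq, r$record$seq, scoring)
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    cov <- sum(ca != "-" & cb != "-") / r$full_length
    list(subtype = r$subtype, identity = gap_stripped_identity(aln),
         coverage = cov)
  })
  idy <- vapply(res, `[[`, 0, "identity")
  cov <- vapply(res, `[[`, 0, "coverage")
  sub <- vapply(res, `[[`, "", "subtype")
  ord <- order(-idy, -cov, match(sub, c("LTR5A", "LTR5B", "LTR5Hs")))
  list(subtype = unname(sub[ord[1]]), identity = unname(idy[ord[1]]))
}
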