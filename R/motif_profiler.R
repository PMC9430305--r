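# TSS-relative anchoring of LTR elements, section extraction, IUPAC
# consensus motif scanning, and per-subtype frequency / co-occurrence /
# column-conservation statistics.

#' TSS-relative coordinate frame
#'
#' The frame is defined on an LTR5Hs reference: position 1 is the first base
#' of R; U3 occupies -792..0 (position 0 exists and belongs to U3, so the
#' printed sections -263..0 and 1..177 are adjacent and exhaustive).
#' \code{rel_to_index} converts a TSS-relative position to a 1-based index in
#' the frame reference sequence.
#'
#' @param rel TSS-relative position(s).
#' @param tss_index 1-based index of frame position 1 in the reference
#'   sequence (793 + 1 for a reference that starts at -792).
#' @return 1-based sequence index (integer).
#' @export
rel_to_index <- function(rel, tss_index) as.integer(rel + tss_index - 1L)

#' The four canonical LTR sections
#'
#' Section boundaries in TSS-relative coordinates (inclusive endpoints as
#' printed): 5Hs1 (-792..-553), 5Hs2 (-552..-264), 5Hs3 (-263..0, the
#' enhancer/core-promoter fragment), 5Hs4 (1..177). They partition -792..177
#' without gaps or overlap.
#'
#' @return data.frame with columns \code{name}, \code{start_rel},
#'   \code{end_rel}.
#' @export
ltr_sections <- function() {
  data.frame(
    name = c("5Hs1", "5Hs2", "5Hs3", "5Hs4"),
    start_rel = c(-792L, -552L, -263L, 1L),
    end_rel = c(-553L, -264L, 0L, 177L),
    stringsAsFactors = FALSE)
}

#' A single section spec
#'
#' @param name section name.
#' @param start_rel,end_rel inclusive TSS-relative endpoints
#'   (\code{start_rel < end_rel}).
#' @return one-row data.frame matching \code{\link{ltr_sections}} rows.
#' @export
section_spec <- function(name, start_rel, end_rel) {
  stopifnot(start_rel < end_rel)
  data.frame(name = name, start_rel = as.integer(start_rel),
             end_rel = as.integer(end_rel), stringsAsFactors = FALSE)
}

#' Anchor an element to the TSS-relative frame
#'
#' Globally aligns an element to the frame reference and returns a monotone
#' map from frame positions to element positions (NA where the frame base is
#' deleted in the element).
#'
#' @param element \code{\link{seq_record}} or nucleotide string.
#' @param frame_ref frame reference \code{\link{seq_record}}.
#' @param tss_index see \code{\link{rel_to_index}}.
#' @param min_identity anchoring fails (error) below this gap-stripped
#'   identity percent.
#' @param scoring see \code{\link{align_scoring}}.
#' @return object of class \code{frame_map}: list with \code{map} (integer
#'   vector over frame positions, 1-based element positions or NA),
#'   \code{tss_index}, \code{identity}.
#' @export
anchor_to_frame <- function(element, frame_ref, tss_index,
                            min_identity = 60, scoring = align_scoring()) {
  eseq <- if (inherits(element, "seq_record")) element$seq else normalize_seq(element)
  fseq <- if (inherits(frame_ref, "seq_record")) frame_ref$seq else normalize_seq(frame_ref)
  aln <- global_align(eseq, fseq, scoring)
  identity <- gap_stripped_identity(aln)
  if (identity < min_identity)
    stop(sprintf("anchoring error: identity %.1f%% < %.1f%%",
                 identity, min_identity))
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  map <- rep(NA_integer_, nchar(fseq))
  e_pos <- 0L; f_pos <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] != "-") e_pos <- e_pos + 1L
    if (cb[i] != "-") {
      f_pos <- f_pos + 1L
      if (ca[i] != "-") map[f_pos] <- e_pos
    }
  }
  structure(list(map = map, tss_index = as.integer(tss_index),
                 identity = identity), class = "frame_map")
}

#' Extract a section of an element via its frame map
#'
#' Returns the element subsequence spanning the outermost mapped positions of
#' the section. Elements mapping fewer than \code{min_cover} of the section's
#' positions are flagged for exclusion from that section's statistics.
#'
#' @param element \code{\link{seq_record}} or nucleotide string.
#' @param fmap a \code{frame_map} from \code{\link{anchor_to_frame}}.
#' @param section one row of \code{\link{ltr_sections}} (or
#'   \code{\link{section_spec}}).
#' @param min_cover minimum fraction of section positions mapped.
#' @return list with \code{seq} (NA when excluded), \code{coverage}, and
#'   \code{included}.
#' @export
extract_section <- function(element, fmap, section, min_cover = 0.8) {
  eseq <- if (inherits(element, "seq_record")) element$seq else element
  i1 <- rel_to_index(section$start_rel, fmap$tss_index)
  i2 <- rel_to_index(section$end_rel, fmap$tss_index)
  stopifnot(i1 >= 1L, i2 <= length(fmap$map))
  m <- fmap$map[i1:i2]
  coverage <- mean(!is.na(m))
  if (coverage < min_cover)
    return(list(seq = NA_character_, coverage = coverage, included = FALSE))
  rng <- range(m, na.rm = TRUE)
  list(seq = substr(eseq, rng[1], rng[2]), coverage = coverage,
       included = TRUE)
}

IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGTN]")

iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad)) stop("invalid IUPAC characters: ", paste(bad, collapse = ","))
  paste(IUPAC_CLASS[chars], collapse = "")
}

#' Motif definition
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string (exact matching; a sequence N
#'   matches only a motif N).
#' @param section optional section constraint (one row of
#'   \code{\link{ltr_sections}}).
#' @param source \code{"wildtype"} or \code{"mutant"} allele tag.
#' @return object of class \code{motif_def}.
#' @export
motif_def <- function(name, consensus, section = NULL, source = "wildtype") {
  stopifnot(nzchar(consensus))
  iupac_regex(consensus)  # validate
  structure(list(name = name, consensus = toupper(consensus),
                 section = section, source = source), class = "motif_def")
}

#' Default motif registry
#'
#' The transcription-factor binding sites profiled on the -263..0
#' enhancer/core-promoter fragment: TATA box (TATAAA), NF-kB
#' (AGGGAAAAACCG), TP53-1 (GGGCTGG), TP53-2 (GGGCAGC), POU2F1 (TGTATGCATAT).
#' With \code{extended = TRUE}, also YY1 (CCATNTT) and OCT4 (ATGCMAA, the
#' ATGCAAA/ATGCCAA pair as one IUPAC consensus).
#'
#' @param extended include the extra motifs.
#' @return named list of \code{\link{motif_def}}s.
#' @export
default_motif_registry <- function(extended = FALSE) {
  s3 <- section_spec("5Hs3", -263L, 0L)
  reg <- list(
    TATA = motif_def("TATA", "TATAAA", s3),
    `NF-kB` = motif_def("NF-kB", "AGGGAAAAACCG", s3),
    `TP53-1` = motif_def("TP53-1", "GGGCTGG", s3),
    `TP53-2` = motif_def("TP53-2", "GGGCAGC", s3),
    POU2F1 = motif_def("POU2F1", "TGTATGCATAT", s3))
  if (extended) {
    reg$YY1 <- motif_def("YY1", "CCATNTT")
    reg$OCT4 <- motif_def("OCT4", "ATGCMAA")
  }
  reg
}

#' Scan a sequence for an IUPAC motif
#'
#' Exact IUPAC-degenerate matching on the given (sense) strand; overlapping
#' matches are all reported.
#'
#' @param seq nucleotide string.
#' @param motif a \code{\link{motif_def}} or IUPAC string.
#' @return integer vector of 0-based match start positions.
#' @export
scan_motif <- function(seq, motif) {
  consensus <- if (inherits(motif, "motif_def")) motif$consensus else toupper(motif)
  if (is.na(seq) || !nzchar(seq)) return(integer(0))
  rx <- paste0("(?=", iupac_regex(consensus), ")")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-subtype motif frequency table
#'
#' An element counts as motif-present iff the motif matches at least once in
#' its extracted section sequence.
#'
#' @param section_seqs_by_subtype named list: subtype -> character vector of
#'   extracted section sequences (one per usable element).
#' @param motifs list of \code{\link{motif_def}}s.
#' @return data.frame with columns \code{subtype}, \code{motif},
#'   \code{n_total}, \code{n_present}, \code{percent} (rounded half-up to 2
#'   decimals). Subtypes with zero usable elements are omitted with a
#'   warning.
#' @export
motif_frequency_table <- function(section_seqs_by_subtype, motifs) {
  rows <- list()
  for (subtype in names(section_seqs_by_subtype)) {
    seqs <- section_seqs_by_subtype[[subtype]]
    seqs <- seqs[!is.na(seqs)]
    if (!length(seqs)) {
      warning("no usable elements for subtype ", subtype, "; row omitted")
      next
    }
    for (m in motifs) {
      present <- vapply(seqs, function(s) length(scan_motif(s, m)) > 0L, FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = subtype, motif = m$name, n_total = length(seqs),
        n_present = sum(present),
        percent = round_half_up(100 * sum(present) / length(seqs)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Motif co-occurrence frequency
#'
#' @param section_seqs character vector of extracted section sequences.
#' @param motif_a,motif_b \code{\link{motif_def}}s.
#' @return list with \code{count} (elements containing both motifs) and
#'   \code{percent}.
#' @export
cooccurrence_frequency <- function(section_seqs, motif_a, motif_b) {
  seqs <- section_seqs[!is.na(section_seqs)]
  if (!length(seqs)) stop("no usable elements")
  both <- vapply(seqs, function(s)
    length(scan_motif(s, motif_a)) > 0L && length(scan_motif(s, motif_b)) > 0L,
    FALSE)
  list(count = sum(both),
       percent = round_half_up(100 * sum(both) / length(seqs)))
}

#' Column conservation matrix
#'
#' Per-column base counts and information content over a positionally
#' anchored block of equal-length sequences. IC = 2 - H(column) in bits,
#' computed from A/C/G/T frequencies (gaps and N excluded from counts); no
#' small-sample correction.
#'
#' @param anchored_seqs character vector of equal-length sequences.
#' @return list with \code{counts} (4 x L matrix) and \code{ic} (length-L
#'   numeric, values in [0, 2]).
#' @export
conservation_matrix <- function(anchored_seqs) {
  stopifnot(length(anchored_seqs) >= 1L,
            length(unique(nchar(anchored_seqs))) == 1L)
  chars <- do.call(rbind, strsplit(toupper(anchored_seqs), "", fixed = TRUE))
  L <- ncol(chars)
  counts <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(counts)) counts[b, ] <- colSums(chars == b)
  ic <- apply(counts, 2L, function(col) {
    n <- sum(col)
    if (n == 0L) return(0)
    p <- col[col > 0] / n
    2 + sum(p * log2(p))
  })
  list(counts = counts, ic = as.numeric(ic))
}

#' Anchor a set of elements and extract one section from each
#'
#' Convenience wrapper: anchors every element to the frame, extracts the
#' section, and reports anchoring failures and low-coverage exclusions
#' instead of silently dropping them.
#'
#' @param elements list of \code{\link{seq_record}}s.
#' @param frame_ref,tss_index see \code{\link{anchor_to_frame}}.
#' @param section one row of \code{\link{ltr_sections}}.
#' @param min_identity,min_cover thresholds for anchoring and section
#'   coverage.
#' @return list with \code{seqs} (named character vector, NA where excluded)
#'   and \code{excluded} (data.frame of element id + reason).
#' @export
extract_sections <- function(elements, frame_ref, tss_index, section,
                             min_identity = 60, min_cover = 0.8) {
  seqs <- setNames(rep(NA_character_, length(elements)),
                   vapply(elements, `[[`, "", "id"))
  excl <- list()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    fmap <- tryCatch(
      anchor_to_frame(el, frame_ref, tss_index, min_identity),
      error = function(e) NULL)
    if (is.null(fmap)) {
      excl[[length(excl) + 1L]] <- data.frame(id = el$id,
                                              reason = "anchoring_failed")
      next
    }
    ex <- extract_section(el, fmap, section, min_cover)
    if (!ex$included) {
      excl[[length(excl) + 1L]] <- data.frame(id = el$id,
                                              reason = "section_coverage")
      next
    }
    seqs[[i]] <- ex$seq
  }
  list(seqs = seqs,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(id = character(0), reason = character(0)))
}
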