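# In-silico reporter inserts: section-replacement chimeras, site-directed
# mutants, reverse-orientation inserts, and motif-content validation.

#' Partition a frame reference into the four canonical sections
#'
#' Validates that the frame covers -792..177 and that the sections are
#' ordered, non-overlapping, and within the frame.
#'
#' @param frame_ref frame reference \code{\link{seq_record}}.
#' @param tss_index see \code{\link{rel_to_index}}.
#' @param sections section table (default \code{\link{ltr_sections}}).
#' @return the validated section data.frame.
#' @export
partition_sections <- function(frame_ref, tss_index,
                               sections = ltr_sections()) {
  n <- nchar(frame_ref$seq)
  i1 <- rel_to_index(sections$start_rel, tss_index)
  i2 <- rel_to_index(sections$end_rel, tss_index)
  if (any(i1 < 1L) || any(i2 > n))
    stop("frame reference shorter than the section span")
  o <- order(sections$start_rel)
  s <- sections[o, , drop = FALSE]
  if (any(s$start_rel >= s$end_rel))
    stop("invalid section: start_rel must be < end_rel")
  if (nrow(s) > 1L && any(s$start_rel[-1] <= s$end_rel[-nrow(s)]))
    stop("overlapping sections")
  sections
}

#' Site-directed mutation definition
#'
#' @param name mutation name.
#' @param from_seq wild-type site (must occur in the target).
#' @param to_seq replacement sequence (may differ in length).
#' @param occurrence which match to edit when \code{from_seq} occurs more
#'   than once; by default the match must be unique (silent off-target edits
#'   are refused).
#' @return object of class \code{mutation_def}.
#' @export
mutation_def <- function(name, from_seq, to_seq, occurrence = NULL) {
  stopifnot(nzchar(from_seq))
  structure(list(name = name, from_seq = toupper(from_seq),
                 to_seq = toupper(to_seq), occurrence = occurrence),
            class = "mutation_def")
}

#' Default site-directed mutation registry
#'
#' The wild-type -> LTR5B-variant edits used on the 5Hs3-5B reporter: TATA
#' (TATAA -> TGTAA), NF-kB (AGGGAAAAACCG -> AGGGGAGAATGG), TP53-1 (GGGCTGG ->
#' TGGCTGG), TP53-2 (GGGCAGC -> TGGCAGC), POU2F1 (TGTATGCATAT -> a 30-nt
#' replacement, so edits must handle unequal lengths).
#'
#' @return named list of \code{\link{mutation_def}}s.
#' @export
default_mutation_registry <- function() {
  list(
    TATA = mutation_def("TATA", "TATAA", "TGTAA"),
    `NF-kB` = mutation_def("NF-kB", "AGGGAAAAACCG", "AGGGGAGAATGG"),
    `TP53-1` = mutation_def("TP53-1", "GGGCTGG", "TGGCTGG"),
    `TP53-2` = mutation_def("TP53-2", "GGGCAGC", "TGGCAGC"),
    POU2F1 = mutation_def("POU2F1", "TGTATGCATAT",
                          "TAGAGTCAAACATAAATCTGGCCTATGTGC"))
}

#' Apply a site-directed mutation to a sequence
#'
#' @param seq nucleotide string.
#' @param m a \code{\link{mutation_def}}.
#' @return the edited sequence. Errors when \code{from_seq} is absent, or
#'   occurs more than once with \code{occurrence} unset.
#' @export
apply_site_mutation <- function(seq, m) {
  seq <- toupper(seq)
  hits <- gregexpr(m$from_seq, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop(sprintf("mutation %s: site '%s' not found", m$name, m$from_seq))
  if (length(hits) > 1L && is.null(m$occurrence))
    stop(sprintf("mutation %s: site '%s' occurs %d times; set occurrence",
                 m$name, m$from_seq, length(hits)))
  pos <- hits[[m$occurrence %||% 1L]]
  paste0(substr(seq, 1L, pos - 1L), m$to_seq,
         substr(seq, pos + nchar(m$from_seq), nchar(seq)))
}

#' Start a construct from a backbone
#'
#' @param backbone \code{\link{seq_record}} insert backbone (e.g. the LTR5B
#'   reference).
#' @param name construct name.
#' @return object of class \code{construct_record} with fields \code{name},
#'   \code{backbone_id}, \code{backbone_seq}, \code{edits},
#'   \code{final_seq}, \code{length_delta}.
#' @export
new_construct <- function(backbone, name = backbone$id) {
  structure(list(name = name, backbone_id = backbone$id,
                 backbone_seq = backbone$seq, edits = list(),
                 final_seq = backbone$seq, length_delta = 0L),
            class = "construct_record")
}

#' @export
print.construct_record <- function(x, ...) {
  cat(sprintf("<construct> %s on %s: %d edit(s), length delta %+d\n",
              x$name, x$backbone_id, length(x$edits), x$length_delta))
  invisible(x)
}

apply_one_edit <- function(seq, edit, frame_ref, tss_index) {
  if (edit$type == "section") {
    fmap <- anchor_to_frame(seq, frame_ref, tss_index)
    ex <- extract_section(seq, fmap, edit$section)
    if (!ex$included)
      stop("section '", edit$section$name, "' unmapped in backbone")
    i1 <- rel_to_index(edit$section$start_rel, tss_index)
    i2 <- rel_to_index(edit$section$end_rel, tss_index)
    rng <- range(fmap$map[i1:i2], na.rm = TRUE)
    paste0(substr(seq, 1L, rng[1] - 1L), edit$donor_seq,
           substr(seq, rng[2] + 1L, nchar(seq)))
  } else {
    apply_site_mutation(seq, edit$mutation)
  }
}

#' Replace a homologous section of a backbone with a donor's section
#'
#' Both backbone and donor are anchored to the frame; the backbone
#' subsequence homologous to the section is excised and replaced by the
#' donor's section sequence. Flanks are untouched and the edit is recorded on
#' the construct.
#'
#' @param construct a \code{construct_record} (or a backbone
#'   \code{\link{seq_record}}, which starts a new construct).
#' @param donor donor \code{\link{seq_record}} (e.g. the LTR5Hs reference).
#' @param section one row of \code{\link{ltr_sections}}.
#' @param frame_ref,tss_index the anchoring frame.
#' @return the updated \code{construct_record}.
#' @export
homologous_replace <- function(construct, donor, section, frame_ref,
                               tss_index) {
  if (inherits(construct, "seq_record")) construct <- new_construct(construct)
  dmap <- anchor_to_frame(donor, frame_ref, tss_index)
  dex <- extract_section(donor, dmap, section)
  if (!dex$included) stop("section '", section$name, "' unmapped in donor")
  edit <- list(type = "section", section = section, donor_id = donor$id,
               donor_seq = dex$seq)
  before <- nchar(construct$final_seq)
  construct$final_seq <- apply_one_edit(construct$final_seq, edit,
                                        frame_ref, tss_index)
  construct$edits <- c(construct$edits, list(edit))
  construct$length_delta <- construct$length_delta +
    (nchar(construct$final_seq) - before)
  construct
}

#' Add a site-directed mutation to a construct
#'
#' @param construct a \code{construct_record} (or backbone
#'   \code{\link{seq_record}}).
#' @param m a \code{\link{mutation_def}}.
#' @return the updated \code{construct_record}.
#' @export
add_mutation <- function(construct, m) {
  if (inherits(construct, "seq_record")) construct <- new_construct(construct)
  edit <- list(type = "mutation", mutation = m)
  before <- nchar(construct$final_seq)
  construct$final_seq <- apply_site_mutation(construct$final_seq, m)
  construct$edits <- c(construct$edits, list(edit))
  construct$length_delta <- construct$length_delta +
    (nchar(construct$final_seq) - before)
  construct
}

#' Replay a construct's edit list from its backbone
#'
#' Re-derives the final sequence by applying the ordered edits to the
#' backbone; coordinates are re-derived after each edit, so unequal-length
#' edits compose correctly.
#'
#' @param construct a \code{construct_record}.
#' @param frame_ref,tss_index the anchoring frame (needed for section
#'   edits).
#' @return the replayed final sequence (character).
#' @export
replay_edits <- function(construct, frame_ref = NULL, tss_index = NULL) {
  seq <- construct$backbone_seq
  for (edit in construct$edits)
    seq <- apply_one_edit(seq, edit, frame_ref, tss_index)
  seq
}

#' Reverse-orientation insert
#'
#' @param construct a \code{construct_record} or \code{\link{seq_record}}.
#' @return the reverse complement of the final insert sequence.
#' @export
reverse_insert <- function(construct) {
  seq <- if (inherits(construct, "construct_record")) construct$final_seq
  else construct$seq
  reverse_complement(seq)
}

#' Validate a construct's motif content
#'
#' Scans every registry motif in the backbone and in the final insert and
#' checks the length bookkeeping.
#'
#' @param construct a \code{construct_record}.
#' @param motifs named list of \code{\link{motif_def}}s.
#' @return data.frame with columns \code{motif}, \code{before},
#'   \code{after}, \code{change}; attribute \code{length_ok}.
#' @export
validate_construct <- function(construct, motifs = default_motif_registry()) {
  rows <- lapply(motifs, function(m) {
    b <- length(scan_motif(construct$backbone_seq, m)) > 0L
    a <- length(scan_motif(construct$final_seq, m)) > 0L
    data.frame(motif = m$name, before = b, after = a,
               change = if (b && !a) "lost" else if (!b && a) "gained"
               else "unchanged", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "length_ok") <-
    nchar(construct$final_seq) - nchar(construct$backbone_seq) ==
    construct$length_delta
  out
}
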