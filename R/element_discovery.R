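# k-mer seeded discovery of LTR-like loci against subtype consensus
# references: genome indexed at a fixed stride, query scanned at stride 1 in
# both orientations, co-linear seeds chained, candidates extended by global
# alignment.

#' Build a k-mer index of a genome
#'
#' Indexes every k-mer starting at offsets 0, step, 2*step, ... of each
#' contig. k-mers containing N are excluded; k-mers occurring more than
#' \code{max_kmer_freq} times (repeat-heavy) are dropped.
#'
#' @param genome list of \code{\link{seq_record}} contigs.
#' @param k k-mer size (default 11).
#' @param step indexing stride (default 5).
#' @param max_kmer_freq drop k-mers occurring more often than this.
#' @return an object of class \code{kmer_index}: a list with \code{k},
#'   \code{step}, \code{table} (k-mer -> data.frame(contig, offset); offsets
#'   0-based) and \code{contig_len}.
#' @export
build_kmer_index <- function(genome, k = 11L, step = 5L, max_kmer_freq = 1000L) {
  stopifnot(k >= 4L, step >= 1L)
  kmer <- character(0); contig <- character(0); offset <- integer(0)
  contig_len <- integer(0)
  for (rec in genome) {
    n <- nchar(rec$seq)
    contig_len[rec$id] <- n
    if (n < k) {
      warning("contig '", rec$id, "' shorter than k; skipped")
      next
    }
    off <- seq.int(0L, n - k, by = step)
    km <- substring(rec$seq, off + 1L, off + k)
    keep <- !grepl("N", km, fixed = TRUE)
    kmer <- c(kmer, km[keep])
    contig <- c(contig, rep(rec$id, sum(keep)))
    offset <- c(offset, off[keep])
  }
  tab <- if (length(kmer)) {
    cnt <- table(kmer)
    ok <- kmer %in% names(cnt)[cnt <= max_kmer_freq]
    split(data.frame(contig = contig[ok], offset = offset[ok],
                     stringsAsFactors = FALSE), kmer[ok])
  } else list()
  structure(list(k = as.integer(k), step = as.integer(step), table = tab,
                 contig_len = contig_len), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d step=%d, %d distinct k-mers over %d contig(s)\n",
              x$k, x$step, length(x$table), length(x$contig_len)))
  invisible(x)
}

# Chain seeds (g_off, q_off) on one contig/strand into co-linear runs.
chain_seeds <- function(g_off, q_off, gap_tol, diag_tol) {
  o <- order(g_off, q_off)
  g <- g_off[o]; q <- q_off[o]
  d <- g - q
  chain_id <- integer(length(g))
  cur <- 1L
  chain_id[1] <- cur
  for (i in seq_along(g)[-1]) {
    if (g[i] - g[i - 1L] > gap_tol || abs(d[i] - d[i - 1L]) > diag_tol)
      cur <- cur + 1L
    chain_id[i] <- cur
  }
  split(data.frame(g = g, q = q), chain_id)
}

#' Seed and chain candidate loci
#'
#' Queries a consensus reference against a k-mer index at stride 1 in both
#' orientations and chains co-linear seed runs (same contig and strand,
#' genomic gaps within \code{gap_tol}, diagonal drift within
#' \code{diag_tol}) into candidate intervals. Candidate spans are the seed
#' spans padded by the consensus overhangs and clipped to the contig.
#'
#' @param index a \code{\link{build_kmer_index}} result.
#' @param consensus a \code{\link{consensus_reference}} (or
#'   \code{\link{seq_record}}).
#' @param min_seeds minimum seeds per retained chain.
#' @param gap_tol maximum genomic gap between consecutive seeds in a chain.
#' @param diag_tol maximum diagonal (indel) drift between consecutive seeds.
#' @return list of candidate \code{\link{genomic_interval}}s, each with an
#'   \code{n_seeds} attribute.
#' @export
seed_and_chain <- function(index, consensus, min_seeds = 8L, gap_tol = 100L,
                           diag_tol = 50L) {
  stopifnot(inherits(index, "kmer_index"))
  qseq <- if (inherits(consensus, "consensus_reference"))
    consensus$record$seq else consensus$seq
  k <- index$k
  qlen <- nchar(qseq)
  if (qlen < k) return(list())
  candidates <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") qseq else reverse_complement(qseq)
    qoff <- seq.int(0L, qlen - k, by = 1L)
    qkm <- substring(qs, qoff + 1L, qoff + k)
    hit <- qkm %in% names(index$table)
    if (!any(hit)) next
    rows <- do.call(rbind, lapply(which(hit), function(i) {
      e <- index$table[[qkm[i]]]
      data.frame(contig = e$contig, g = e$offset, q = qoff[i],
                 stringsAsFactors = FALSE)
    }))
    for (ctg in unique(rows$contig)) {
      sub <- rows[rows$contig == ctg, , drop = FALSE]
      chains <- chain_seeds(sub$g, sub$q, gap_tol, diag_tol)
      for (ch in chains) {
        if (nrow(ch) < min_seeds) next
        first <- which.min(ch$g); last <- which.max(ch$g)
        start <- ch$g[first] - ch$q[first] - 10L
        end <- ch$g[last] + k + (qlen - ch$q[last] - k) + 10L
        start <- max(0L, start)
        end <- min(index$contig_len[[ctg]], end)
        if (end <= start) next
        iv <- genomic_interval(ctg, start, end, strand)
        attr(iv, "n_seeds") <- nrow(ch)
        candidates[[length(candidates) + 1L]] <- iv
      }
    }
  }
  candidates
}

#' Extend and score a candidate locus
#'
#' Globally aligns the strand-resolved candidate sequence to the consensus,
#' computes gap-stripped identity and consensus coverage, and trims the
#' interval to the first/last element base aligned within the consensus.
#'
#' @param candidate a candidate \code{\link{genomic_interval}}.
#' @param consensus a \code{\link{consensus_reference}}.
#' @param genome named list of \code{\link{seq_record}} contigs.
#' @param scoring see \code{\link{align_scoring}}.
#' @param identity_floor candidates with gap-stripped identity below this
#'   percent are discarded (returns NULL).
#' @return an \code{element_hit} (list with \code{interval}, \code{subtype},
#'   \code{identity}, \code{coverage}, \code{n_seeds}) or NULL.
#' @export
extend_and_score <- function(candidate, consensus, genome,
                             scoring = align_scoring(), identity_floor = 60) {
  rec <- genome[[candidate$contig]]
  stopifnot(!is.null(rec), candidate$end <= nchar(rec$seq))
  eseq <- substr(rec$seq, candidate$start + 1L, candidate$end)
  if (candidate$strand == "-") eseq <- reverse_complement(eseq)
  # ends-free fit: the whole consensus against a local stretch of the
  # padded candidate, so padding never bleeds into the reported boundaries
  aln <- Biostrings::pairwiseAlignment(
    consensus$record$seq, eseq, type = "global-local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  pa <- structure(list(
    aligned_a = as.character(Biostrings::alignedSubject(aln)),
    aligned_b = as.character(Biostrings::alignedPattern(aln)),
    score = Biostrings::score(aln)), class = "pairwise_alignment")
  identity <- gap_stripped_identity(pa)
  if (identity < identity_floor) {
    message(sprintf("candidate %s discarded: identity %.1f < %.1f",
                    format_interval(candidate), identity, identity_floor))
    return(NULL)
  }
  sstart <- Biostrings::start(Biostrings::subject(aln))
  send <- Biostrings::end(Biostrings::subject(aln))
  if (candidate$strand == "+") {
    start <- candidate$start + sstart - 1L
    end <- candidate$start + send
  } else {
    start <- candidate$end - send
    end <- candidate$end - sstart + 1L
  }
  # fraction of consensus positions aligned to element bases: insensitive to
  # element insertions, sensitive to truncation
  ca <- strsplit(pa$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(pa$aligned_b, "", fixed = TRUE)[[1]]
  coverage <- sum(ca != "-" & cb != "-") / consensus$full_length
  structure(list(
    interval = genomic_interval(candidate$contig, start, end, candidate$strand),
    subtype = consensus$subtype,
    identity = identity,
    coverage = coverage,
    n_seeds = attr(candidate, "n_seeds") %||% NA_integer_),
    class = "element_hit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.element_hit <- function(x, ...) {
  cat(sprintf("<hit> %s (%s) %s  id=%.2f cov=%.3f seeds=%s\n",
              format_interval(x$interval), x$interval$strand, x$subtype,
              x$identity, x$coverage, x$n_seeds))
  invisible(x)
}

reciprocal_overlap <- function(a, b) {
  if (a$contig != b$contig) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Discover LTR-like elements in a genome
#'
#' Runs seed-and-chain plus extend-and-score for every consensus reference,
#' then collapses overlapping hits (reciprocal overlap > 50%) to the hit with
#' the highest identity x coverage; the winning reference's subtype becomes
#' the hit's subtype call.
#'
#' @param genome list of \code{\link{seq_record}} contigs.
#' @param refs list of \code{\link{consensus_reference}}s (at least one).
#' @param config list overriding defaults \code{k}, \code{step},
#'   \code{min_seeds}, \code{gap_tol}, \code{diag_tol},
#'   \code{identity_floor}, \code{max_kmer_freq}.
#' @return list of \code{element_hit}s sorted by (contig, start).
#' @export
discover_elements <- function(genome, refs, config = list()) {
  if (length(refs) == 0L) stop("at least one consensus reference required")
  cfg <- modifyList(list(k = 11L, step = 5L, min_seeds = 8L, gap_tol = 100L,
                         diag_tol = 50L, identity_floor = 60,
                         max_kmer_freq = 1000L), config)
  if (is.null(names(genome)))
    names(genome) <- vapply(genome, `[[`, "", "id")
  idx <- build_kmer_index(genome, cfg$k, cfg$step, cfg$max_kmer_freq)
  hits <- list()
  for (ref in refs) {
    cands <- seed_and_chain(idx, ref, cfg$min_seeds, cfg$gap_tol, cfg$diag_tol)
    for (cand in cands) {
      h <- suppressMessages(
        extend_and_score(cand, ref, genome, identity_floor = cfg$identity_floor))
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(list())
  score <- vapply(hits, function(h) h$identity * h$coverage, 0)
  accepted <- list()
  for (i in order(-score)) {
    h <- hits[[i]]
    clash <- any(vapply(accepted, function(a)
      reciprocal_overlap(a$interval, h$interval) > 0.5, FALSE))
    if (!clash) accepted[[length(accepted) + 1L]] <- h
  }
  ord <- order(vapply(accepted, function(h) h$interval$contig, ""),
               vapply(accepted, function(h) h$interval$start, 0L))
  accepted[ord]
}

#' Tabulate element hits
#'
#' @param hits list of \code{element_hit}s.
#' @return a data.frame with one row per hit (1-based inclusive coordinates
#'   in the \code{locus} column, 0-based half-open in \code{start}/\code{end}).
#' @export
hits_table <- function(hits) {
  data.frame(
    contig = vapply(hits, function(h) h$interval$contig, ""),
    start = vapply(hits, function(h) h$interval$start, 0L),
    end = vapply(hits, function(h) h$interval$end, 0L),
    strand = vapply(hits, function(h) h$interval$strand, ""),
    subtype = vapply(hits, function(h) h$subtype, ""),
    identity = vapply(hits, function(h) h$identity, 0),
    coverage = vapply(hits, function(h) h$coverage, 0),
    n_seeds = vapply(hits, function(h) as.integer(h$n_seeds), 0L),
    locus = vapply(hits, function(h) format_interval(h$interval), ""),
    stringsAsFactors = FALSE)
}
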