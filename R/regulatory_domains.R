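# GREAT-style basal-plus-extension regulatory domains and element-to-gene
# association.

#' Build basal+extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain (\code{basal_up} bp upstream,
#' \code{basal_down} bp downstream of the TSS) extended in both directions to
#' the nearer of the neighboring gene's basal boundary, \code{max_ext} bp, or
#' the contig edge. Extended domains may still overlap other genes' basal
#' regions, per the GREAT convention.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{contig},
#'   \code{tss} (0-based), \code{strand} ("+"/"-").
#' @param basal_up,basal_down,max_ext rule parameters in bp (defaults
#'   5000 / 1000 / 1e6).
#' @param contig_len optional named vector of contig lengths for edge
#'   clipping.
#' @return data.frame with basal and extended interval columns (0-based
#'   half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000L,
                                     basal_down = 1000L, max_ext = 1000000L,
                                     contig_len = NULL) {
  stopifnot(all(c("gene_id", "contig", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ","))
  stopifnot(all(genes$strand %in% c("+", "-")))
  up <- ifelse(genes$strand == "+", basal_up, basal_down)
  down <- ifelse(genes$strand == "+", basal_down, basal_up)
  basal_start <- pmax(0L, genes$tss - up)
  basal_end <- genes$tss + down
  ext_start <- basal_start
  ext_end <- basal_end
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$contig == genes$contig[i])
    left <- same[genes$tss[same] < genes$tss[i] |
                   (genes$tss[same] == genes$tss[i] & same < i)]
    right <- same[genes$tss[same] > genes$tss[i] |
                    (genes$tss[same] == genes$tss[i] & same > i)]
    lbound <- max(c(0, basal_start[i] - max_ext,
                    pmin(basal_end[left], basal_start[i])))
    rbound <- min(c(basal_end[i] + max_ext,
                    pmax(basal_start[right], basal_end[i])))
    if (!is.null(contig_len)) {
      n <- contig_len[[genes$contig[i]]]
      rbound <- min(rbound, n)
      basal_end[i] <- min(basal_end[i], n)
      if (rbound < basal_end[i]) rbound <- basal_end[i]
    }
    ext_start[i] <- min(lbound, basal_start[i])
    ext_end[i] <- max(rbound, basal_end[i])
  }
  data.frame(gene_id = genes$gene_id, contig = genes$contig,
             tss = genes$tss, strand = genes$strand,
             basal_start = as.integer(basal_start),
             basal_end = as.integer(basal_end),
             ext_start = as.integer(ext_start),
             ext_end = as.integer(ext_end),
             stringsAsFactors = FALSE)
}

#' Associate elements with regulatory domains
#'
#' An element is associated with every gene whose extended domain contains
#' the element's interval midpoint. Distance is midpoint - TSS, sign-flipped
#' for minus-strand genes so that positive means downstream of the gene.
#' Element strand is ignored.
#'
#' @param hits list of \code{element_hit}s (or of
#'   \code{\link{genomic_interval}}s).
#' @param domains result of \code{\link{build_regulatory_domains}}.
#' @param whole_element if TRUE, require only any overlap of the element
#'   interval with the extended domain instead of midpoint containment.
#' @return data.frame with columns \code{element}, \code{gene_id},
#'   \code{distance} (bp, strand-adjusted).
#' @export
associate_elements <- function(hits, domains, whole_element = FALSE) {
  rows <- list()
  for (h in hits) {
    iv <- if (inherits(h, "element_hit")) h$interval else h
    mid <- (iv$start + iv$end) %/% 2L
    on_ctg <- domains[domains$contig == iv$contig, , drop = FALSE]
    sel <- if (whole_element)
      on_ctg$ext_start < iv$end & on_ctg$ext_end > iv$start
    else
      on_ctg$ext_start <= mid & mid < on_ctg$ext_end
    if (!any(sel)) next
    g <- on_ctg[sel, , drop = FALSE]
    dist <- mid - g$tss
    dist[g$strand == "-"] <- -dist[g$strand == "-"]
    rows[[length(rows) + 1L]] <- data.frame(
      element = format_interval(iv), gene_id = g$gene_id,
      distance = as.integer(dist), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(element = character(0), gene_id = character(0),
                      distance = integer(0)))
  do.call(rbind, rows)
}

#' Three-set Venn region counts
#'
#' @param assoc_by_subtype named list of three character vectors (gene ids
#'   associated with each subtype).
#' @return named integer vector of the 7 Venn region counts plus
#'   \code{union}; region counts sum to the union cardinality.
#' @export
overlap_sets <- function(assoc_by_subtype) {
  stopifnot(length(assoc_by_subtype) == 3L)
  sets <- lapply(assoc_by_subtype, unique)
  nm <- names(sets)
  if (is.null(nm)) nm <- c("A", "B", "C")
  a <- sets[[1]]; b <- sets[[2]]; c_ <- sets[[3]]
  abc <- intersect(intersect(a, b), c_)
  ab <- setdiff(intersect(a, b), abc)
  ac <- setdiff(intersect(a, c_), abc)
  bc <- setdiff(intersect(b, c_), abc)
  only_a <- setdiff(a, union(b, c_))
  only_b <- setdiff(b, union(a, c_))
  only_c <- setdiff(c_, union(a, b))
  out <- c(length(only_a), length(only_b), length(only_c),
           length(ab), length(ac), length(bc), length(abc),
           length(union(union(a, b), c_)))
  names(out) <- c(nm, paste(nm[1], nm[2], sep = "&"),
                  paste(nm[1], nm[3], sep = "&"),
                  paste(nm[2], nm[3], sep = "&"),
                  paste(nm, collapse = "&"), "union")
  out
}

#' Read gene models from a 4-column TSV
#'
#' Columns: gene_id, contig, tss (0-based), strand.
#'
#' @param path TSV path (header optional, detected from first line).
#' @return data.frame suitable for \code{\link{build_regulatory_domains}}.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene", tolower(first))
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df) <- c("gene_id", "contig", "tss", "strand")
  df$tss <- as.integer(df$tss)
  df
}
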