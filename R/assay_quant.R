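# Quantification of dual-luciferase reporter plates, RT-qPCR (2^-ddCT), and
# ChIP-qPCR enrichment, plus the one-way ANOVA used for group comparison.

check_plate <- function(plate) {
  need <- c("construct", "stimulus", "replicate", "firefly", "renilla")
  stopifnot(all(need %in% names(plate)))
  if (any(plate$renilla <= 0)) stop("renilla must be positive")
  if (any(plate$firefly <= 0)) stop("firefly must be positive")
  plate
}

#' Normalized luciferase fold change
#'
#' mean(firefly/Renilla) over the construct's wells in the given stimulus,
#' divided by mean(firefly/Renilla) over the empty-vector wells in plain
#' medium. The denominator is always the medium condition, regardless of the
#' stimulus of the numerator. Replicates are aggregated as the arithmetic
#' mean of per-well ratios.
#'
#' @param plate data.frame with columns \code{construct}, \code{stimulus},
#'   \code{replicate}, \code{firefly}, \code{renilla}.
#' @param construct construct name.
#' @param stimulus stimulus name (e.g. "medium", "TNF-a", "PMA-ionomycin").
#' @param empty_vector_id name of the empty-vector control construct.
#' @return fold change (positive number).
#' @export
normalized_fold_change <- function(plate, construct, stimulus,
                                   empty_vector_id = "empty") {
  plate <- check_plate(plate)
  num <- plate[plate$construct == construct & plate$stimulus == stimulus, ]
  den <- plate[plate$construct == empty_vector_id &
                 plate$stimulus == "medium", ]
  if (!nrow(num))
    stop(sprintf("no wells for (%s, %s)", construct, stimulus))
  if (!nrow(den))
    stop("no empty-vector wells in medium")
  denom <- mean(den$firefly / den$renilla)
  if (denom <= 0) stop("non-positive denominator mean")
  mean(num$firefly / num$renilla) / denom
}

check_qpcr <- function(data) {
  need <- c("sample", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(data)))
  if (any(data$ct <= 0 | data$ct >= 45)) stop("ct must be in (0, 45)")
  data
}

mean_ct <- function(data, sample, gene) {
  v <- data$ct[data$sample == sample & data$gene == gene]
  if (!length(v)) stop(sprintf("no CT values for (%s, %s)", sample, gene))
  mean(v)
}

#' 2^-ddCT relative expression fold
#'
#' dCT = mean CT(target) - mean CT(reference) per sample; ddCT =
#' dCT(treated) - dCT(control); fold = 2^-ddCT.
#'
#' @param data data.frame with columns \code{sample}, \code{gene},
#'   \code{replicate}, \code{ct}.
#' @param target_gene,ref_gene gene names (reference e.g. beta-actin).
#' @param treated,control sample names.
#' @return the expression fold change.
#' @export
ddct_fold <- function(data, target_gene, ref_gene, treated, control) {
  data <- check_qpcr(data)
  dct_treated <- mean_ct(data, treated, target_gene) -
    mean_ct(data, treated, ref_gene)
  dct_control <- mean_ct(data, control, target_gene) -
    mean_ct(data, control, ref_gene)
  2^-(dct_treated - dct_control)
}

#' ChIP-qPCR relative enrichment
#'
#' Default method: ddCT fold enrichment of the target probe over a
#' negative-control probe, \code{2^-[(CT_IP - CT_input)_target -
#' (CT_IP - CT_input)_NC]}. With \code{method = "percent_input"} returns
#' \code{100 * 2^-(CT_IP - CT_input)} for the target probe alone.
#'
#' @param data data.frame with columns \code{sample}, \code{gene} (probe),
#'   \code{replicate}, \code{ct}.
#' @param target_probe,nc_probe probe names.
#' @param ip_sample,input_sample sample names for the immunoprecipitate and
#'   the input chromatin.
#' @param method "ddct" (default) or "percent_input".
#' @return enrichment fold (or percent of input).
#' @export
chip_relative_enrichment <- function(data, target_probe, nc_probe,
                                     ip_sample, input_sample,
                                     method = c("ddct", "percent_input")) {
  method <- match.arg(method)
  data <- check_qpcr(data)
  dct_target <- mean_ct(data, ip_sample, target_probe) -
    mean_ct(data, input_sample, target_probe)
  if (method == "percent_input") return(100 * 2^-dct_target)
  dct_nc <- mean_ct(data, ip_sample, nc_probe) -
    mean_ct(data, input_sample, nc_probe)
  2^-(dct_target - dct_nc)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA over k groups (via \code{stats::lm}). When every
#' group has zero within-group variance but the means differ, F is infinite
#' and p is reported as 0 with the \code{degenerate} flag set.
#'
#' @param groups list of numeric replicate vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{degenerate}.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2L,
            all(vapply(groups, length, 0L) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw == 0 && ssb > 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  if (ssb == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, degenerate = FALSE))
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1], degenerate = FALSE)
}

#' Read a luciferase plate TSV
#'
#' Columns: construct, stimulus, replicate, firefly, renilla.
#'
#' @param path TSV path with header.
#' @return validated data.frame.
#' @export
read_plate <- function(path) check_plate(read.delim(path, stringsAsFactors = FALSE))

#' Read a qPCR CT table TSV
#'
#' Columns: sample, gene, replicate, ct.
#'
#' @param path TSV path with header.
#' @return validated data.frame.
#' @export
read_qpcr <- function(path) check_qpcr(read.delim(path, stringsAsFactors = FALSE))
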