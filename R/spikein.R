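#' ERCC spike-in size factors (median-of-ratios on spike-in rows)
#'
#' Because spike-ins are added in proportion to cell number, scaling
#' every sample so its spike-in counts agree recovers absolute,
#' per-cell-comparable expression: global transcriptome shifts that
#' library-size or TPM normalization cancels remain visible.  The
#' estimator is the median-of-ratios restricted to spike-in rows:
#' \deqn{f_s = \mathrm{median}_i\; c_{is} / (\prod_s c_{is})^{1/S}}
#' over spike-ins \eqn{i} with a positive geometric mean; normalized
#' counts are \code{counts / factor}.
#'
#' @param counts genes x samples count matrix with rownames; spike-in
#'   rows identified by \code{spikePrefix}.
#' @param spikePrefix rowname prefix flagging spike-ins
#'   (default \code{"ERCC-"}).
#' @return Named positive numeric vector of per-sample size factors.
#' @export
spikeinSizeFactors <- function(counts, spikePrefix = "ERCC-") {
  spike <- counts[startsWith(rownames(counts), spikePrefix), ,
                  drop = FALSE]
  if (nrow(spike) == 0L)
    stop("no spike-in rows (prefix '", spikePrefix, "') in counts")
  logGeo <- rowMeans(log(spike))
  use <- is.finite(logGeo)  # spike-ins nonzero in every sample
  if (!any(use))
    stop("no spike-in is nonzero across all samples")
  # median of log ratios, exponentiated (geometric interpolation at
  # even counts, the standard median-of-ratios convention)
  factors <- apply(spike[use, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - logGeo[use])))
  if (any(!is.finite(factors) | factors <= 0))
    stop("degenerate spike-in size factor")
  factors
}

#' Transcripts per million
#'
#' Standard TPM: per-gene count rate \code{count / length}, scaled so
#' each sample's biological rates sum to 1e6.  Spike-in rows are
#' excluded from the denominator (and from the output) so TPM reflects
#' the biological transcriptome only.
#'
#' @param counts genes x samples count matrix with rownames.
#' @param lengths named numeric effective gene lengths in bp (> 0),
#'   covering at least the biological genes.
#' @param spikePrefix rowname prefix flagging spike-in rows.
#' @return TPM matrix over the biological genes.
#' @export
tpm <- function(counts, lengths, spikePrefix = "ERCC-") {
  bio <- counts[!startsWith(rownames(counts), spikePrefix), ,
                drop = FALSE]
  if (nrow(bio) == 0L) stop("no biological genes in counts")
  len <- lengths[rownames(bio)]
  if (anyNA(len) || any(len <= 0))
    stop("every biological gene needs a positive length")
  rate <- bio / len
  denom <- colSums(rate)
  if (any(denom <= 0)) stop("zero total rate in some sample")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Spike-in-scaled fold changes with the highly-expressed filter
#'
#' Computes per-gene log2 fold changes (treatment over reference) on
#' spike-in-normalized counts with a pseudocount, together with the
#' base-mean TPM filter (\code{base_mean_tpm > filterTpm}) used to
#' restrict attention to highly expressed genes.
#'
#' @param counts genes x samples count matrix with rownames (spike-in
#'   rows included; they are normalized along but reported separately
#'   via \code{is_spikein}).
#' @param conditions named character vector mapping sample name to
#'   condition; exactly two conditions.
#' @param lengths named numeric gene lengths for TPM.
#' @param conditionOrder optional length-2 (reference, treatment);
#'   default sorted unique conditions.
#' @param sizeFactors per-sample factors; default
#'   [spikeinSizeFactors()].  Pass
#'   \code{librarySizeFactors(counts)} to see what relative
#'   normalization would report instead.
#' @param filterTpm base-mean TPM threshold (strict \code{>}; default
#'   10).
#' @param pseudocount added to normalized condition means before the
#'   ratio (default 0.5).
#' @param spikePrefix rowname prefix flagging spike-in rows.
#' @return data.frame with \code{gene_id}, \code{base_mean_tpm},
#'   \code{log2_fold_change}, \code{passes_filter}, \code{is_spikein}.
#' @export
foldChanges <- function(counts, conditions, lengths,
                        conditionOrder = NULL, sizeFactors = NULL,
                        filterTpm = 10, pseudocount = 0.5,
                        spikePrefix = "ERCC-") {
  if (is.null(colnames(counts)) ||
      !all(colnames(counts) %in% names(conditions)))
    stop("count columns must be named and covered by 'conditions'")
  conds <- conditions[colnames(counts)]
  if (is.null(conditionOrder))
    conditionOrder <- base::sort(unique(conds))
  if (length(unique(conds)) != 2L ||
      !setequal(unique(conds), conditionOrder))
    stop("exactly two conditions are required")
  if (is.null(sizeFactors))
    sizeFactors <- spikeinSizeFactors(counts, spikePrefix)
  norm <- sweep(counts, 2, sizeFactors[colnames(counts)], "/")
  meanA <- rowMeans(norm[, conds == conditionOrder[1L], drop = FALSE])
  meanB <- rowMeans(norm[, conds == conditionOrder[2L], drop = FALSE])
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))
  spike <- startsWith(rownames(counts), spikePrefix)
  baseMean <- rep(NA_real_, nrow(counts))
  tpmMat <- tpm(counts, lengths, spikePrefix)
  baseMean[!spike] <- rowMeans(tpmMat)[rownames(counts)[!spike]]
  data.frame(gene_id = rownames(counts),
             base_mean_tpm = baseMean,
             log2_fold_change = log2fc,
             passes_filter = !spike & !is.na(baseMean) &
               baseMean > filterTpm,
             is_spikein = spike,
             row.names = NULL)
}

#' Library-size (total-count) size factors
#'
#' The relative normalization foil to [spikeinSizeFactors()]: scales
#' each sample by its total biological counts (rescaled to geometric
#' mean 1).  Under a global transcriptome shift this cancels the shift
#' — which is exactly why spike-ins are needed to detect one.
#'
#' @param counts genes x samples count matrix.
#' @param spikePrefix spike-in rows are excluded from the totals.
#' @return Named positive numeric vector of per-sample factors.
#' @export
librarySizeFactors <- function(counts, spikePrefix = "ERCC-") {
  bio <- counts[!startsWith(rownames(counts), spikePrefix), ,
                drop = FALSE]
  totals <- colSums(bio)
  if (any(totals <= 0)) stop("zero library size in some sample")
  totals / exp(mean(log(totals)))
}
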