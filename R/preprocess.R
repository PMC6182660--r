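# Probe filtering and baseline normalisation applied ahead of signature
# selection and network analysis.

#' Remove low-intensity probes
#'
#' Default mode drops probes whose maximum log2 intensity is below
#' `max_log2` (4 RFU); alternatively `n_remove` drops exactly the given
#' number of probes with the lowest mean intensity. Both criteria are
#' offered because array pipelines state the cut either way; survivor order
#' is preserved.
#'
#' @param matrix expression matrix.
#' @param max_log2 threshold on per-probe maximum log2 intensity.
#' @param n_remove optional count of lowest-mean probes to drop instead.
#' @return filtered expression matrix.
#' @export
filter_low_intensity <- function(matrix, max_log2 = 4.0, n_remove = NULL) {
  validate_expression_matrix(matrix)
  if (nrow(matrix) == 0L) stop("empty expression matrix")
  if (!is.null(n_remove)) {
    if (n_remove >= nrow(matrix)) {
      stop("n_remove must be smaller than the probe count")
    }
    if (n_remove <= 0L) return(matrix)
    means <- rowMeans(matrix)
    drop <- rank(means, ties.method = "first") <= n_remove
    return(matrix[!drop, , drop = FALSE])
  }
  keep <- apply(matrix, 1L, max) >= max_log2
  matrix[keep, , drop = FALSE]
}

#' Retain the probes with greatest median absolute deviation
#'
#' The MAD here is the unscaled median of absolute deviations from the probe
#' median (no consistency factor -- the scaling would not change the
#' ranking). Ties are broken by probe identifier for determinism.
#'
#' @param matrix expression matrix.
#' @param k number of probes to keep.
#' @return expression matrix restricted to the k most variable probes, in
#'   the original probe order.
#' @export
select_high_mad <- function(matrix, k) {
  validate_expression_matrix(matrix)
  if (k <= 0L) stop("k must be positive")
  if (k > nrow(matrix)) stop("k exceeds the probe count")
  mads <- apply(matrix, 1L, function(v) stats::median(abs(v - stats::median(v))))
  ord <- order(-mads, rownames(matrix))
  keep <- sort(ord[seq_len(k)])
  matrix[keep, , drop = FALSE]
}

#' Intersect the probe universes of two matrices
#'
#' @param a,b expression matrices.
#' @return character vector of common probe identifiers (order of `a`).
#' @export
intersect_probes <- function(a, b) {
  intersect(rownames(a), rownames(b))
}

#' Normalise follow-up samples against each participant's baseline
#'
#' For every non-baseline trial sample, subtracts the same participant's
#' baseline (timepoint 0) log2 values probe-wise; baseline samples are
#' excluded from the output. Normalisation never crosses participants.
#'
#' @param matrix expression matrix containing baseline and follow-up
#'   samples.
#' @param samples sample table covering the matrix columns.
#' @return expression matrix of baseline-normalised log2 differences.
#' @export
baseline_normalize <- function(matrix, samples) {
  validate_expression_matrix(matrix)
  validate_sample_table(samples)
  st <- samples[samples$sample_id %in% colnames(matrix), , drop = FALSE]
  base <- st[st$timepoint_months == 0, , drop = FALSE]
  follow <- st[st$timepoint_months > 0, , drop = FALSE]
  if (nrow(follow) == 0L) stop("no follow-up samples to normalise")
  base_of <- stats::setNames(base$sample_id, base$participant_id)
  missing <- setdiff(follow$participant_id, names(base_of))
  if (length(missing)) {
    stop("participant missing baseline sample: ", missing[1L])
  }
  out <- matrix[, follow$sample_id, drop = FALSE] -
    matrix[, base_of[follow$participant_id], drop = FALSE]
  colnames(out) <- follow$sample_id
  out
}
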