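## Transcription factor activity (TFA) estimation.
##
## A TF's unobserved activity is estimated from the expression of its known
## targets: writing X = P A with P the signed prior connectivity matrix
## (genes x TFs) and X the (half-tau shifted) expression of the prior genes,
## the least-squares activity estimate is A-hat = pinv(P) X. TFs with no
## targets in the prior use their own measured expression as a proxy.

#' Estimate transcription factor activities from a prior topology
#'
#' Computes the least-squares activity estimate `A = P* X`, where `P*` is the
#' Moore-Penrose pseudo-inverse of the prior connectivity matrix (computed by
#' singular value decomposition with relative cutoff 1e-10, so rank-deficient
#' priors from duplicated target sets are handled) and `X` is the half-tau
#' response restricted to the prior's genes. Rows for TFs whose prior column
#' is all zero are replaced by that TF's measured expression.
#'
#' @param prior a [prior_matrix()] whose genes are a subset of the
#'   expression genes.
#' @param halftau_expression genes x samples matrix from
#'   [build_halftau_response()].
#' @param expression the [expression_dataset()] providing fallback TF
#'   expression rows.
#' @param clip if `TRUE`, prior magnitudes (e.g. motif counts) are clipped to
#'   signs in -1/0/+1 before inversion; default uses them as stored.
#' @return An object of class `activity_matrix`: list with `tfs`, `samples`,
#'   `values` (TFs x samples) and a logical `fallback` flag per TF.
#' @export
estimate_activities <- function(prior, halftau_expression, expression,
                                clip = FALSE) {
  missing_genes <- setdiff(prior$genes, rownames(halftau_expression))
  if (length(missing_genes))
    stop_msg("prior gene(s) absent from expression: %s", missing_genes[1])
  P <- prior$values
  if (clip) P <- sign(P)
  X <- halftau_expression[prior$genes, , drop = FALSE]
  fallback <- colSums(P != 0) == 0
  A <- MASS::ginv(P, tol = 1e-10) %*% X
  rownames(A) <- prior$tfs
  colnames(A) <- colnames(X)
  if (any(fallback)) {
    fb_tfs <- prior$tfs[fallback]
    absent <- setdiff(fb_tfs, expression$genes)
    if (length(absent))
      stop_msg("TF '%s' has no prior targets and no expression row for fallback",
               absent[1])
    A[fb_tfs, ] <- expression$values[fb_tfs, colnames(A), drop = FALSE]
  }
  structure(list(tfs = prior$tfs, samples = colnames(A), values = A,
                 fallback = stats::setNames(fallback, prior$tfs)),
            class = "activity_matrix")
}

#' Use measured TF expression directly as activities
#'
#' The no-prior alternative: each TF's activity is its own expression row.
#'
#' @param expression an [expression_dataset()].
#' @param tfs character vector of TF identifiers, all present among the
#'   expression genes.
#' @return An `activity_matrix` with every TF flagged as expression fallback.
#' @export
expression_as_activities <- function(expression, tfs) {
  if (length(tfs) == 0) stop_msg("empty TF list")
  absent <- setdiff(tfs, expression$genes)
  if (length(absent)) stop_msg("TF '%s' not found in expression genes", absent[1])
  A <- expression$values[tfs, , drop = FALSE]
  structure(list(tfs = tfs, samples = expression$samples, values = A,
                 fallback = stats::setNames(rep(TRUE, length(tfs)), tfs)),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("Activity matrix: %d TFs x %d samples (%d expression-fallback)\n",
              length(x$tfs), length(x$samples), sum(x$fallback)))
  invisible(x)
}
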