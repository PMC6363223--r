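## Edge confidence scores and bootstrap rank aggregation.
##
## A selected predictor's confidence for one gene and dataset is
## c = 1 - sigma2_full / sigma2_reduced, comparing the residual variance of
## the OLS refit on the full selected support against the refit with that
## predictor removed. Because the reduced model is nested in the full one,
## c always lies in [0, 1]. Stability across resamples is captured by
## refitting on bootstraps of the conditions and rank-averaging.

## OLS residual sum of squares from Gram products; support given as index set
ols_rss <- function(G, cvec, yty, idx) {
  if (length(idx) == 0) return(yty)
  beta <- solve(G[idx, idx, drop = FALSE], cvec[idx])
  max(yty - sum(cvec[idx] * beta), 0)
}

## greedily drop exactly collinear predictors (later in canonical order) so
## the OLS refit is well posed
prune_collinear <- function(G, idx) {
  keep <- integer(0)
  for (k in idx) {
    test <- c(keep, k)
    ok <- tryCatch({
      qr(G[test, test, drop = FALSE])$rank == length(test)
    }, error = function(e) FALSE)
    if (ok) keep <- test
  }
  keep
}

#' Variance-explained confidence scores for a fitted support
#'
#' For each dataset, refits ordinary least squares on the selected support of
#' `W` and on the support with each selected predictor removed in turn, and
#' scores predictor k as `1 - sigma2_full / sigma2_without_k`. Unselected
#' predictors score 0; exactly collinear duplicates are dropped from the
#' refit (the later TF in canonical order) and scored 0.
#'
#' @param support a `weight_decomposition` from [fit_gene()] or
#'   [select_model()] (only the nonzero pattern of `W` is used).
#' @param tasks list of [gene_task()]s, or the `solver_state` they produced.
#' @return TFs x datasets matrix of confidences in \[0, 1\].
#' @export
confidence_scores <- function(support, tasks) {
  state <- if (inherits(tasks, "solver_state")) tasks else
    precompute_covariances(tasks)
  W <- support$W
  out <- matrix(0, state$p, state$d, dimnames = dimnames(W))
  for (d in seq_len(state$d)) {
    sel <- which(W[, d] != 0)
    if (length(sel) == 0) next
    G <- state$G[[d]]
    cvec <- state$c[[d]]
    yty <- state$yty[d]
    keep <- prune_collinear(G, sel)
    if (length(keep) == 0) next
    rss_full <- ols_rss(G, cvec, yty, keep)
    for (k in keep) {
      rss_red <- ols_rss(G, cvec, yty, setdiff(keep, k))
      if (rss_red <= .Machine$double.eps) {
        out[k, d] <- 0
      } else {
        out[k, d] <- min(max(1 - rss_full / rss_red, 0), 1)
      }
    }
  }
  out
}

#' Rank-average scored edge matrices into a ranked network
#'
#' Each TFs x genes score matrix (e.g. one per bootstrap) is converted to
#' fractional ranks (descending score, ties get average ranks), the ranks are
#' averaged across matrices, and the averaged ranks are mapped affinely to
#' confidences in \[0, 1\] anchored at the best possible rank (1, confidence
#' 1) and the worst (the number of edges, confidence 0).
#'
#' @param score_matrices list of TFs x genes numeric matrices sharing
#'   dimensions and dimnames.
#' @param dataset_id label stored on the result.
#' @return A `ranked_network` data frame with columns `tf`, `gene`,
#'   `confidence`, `rank` (a permutation of 1..edges, descending confidence,
#'   ties broken lexicographically).
#' @export
rank_combine <- function(score_matrices, dataset_id = "network") {
  if (length(score_matrices) == 0) stop_msg("no score matrices")
  dims <- dim(score_matrices[[1]])
  dn <- dimnames(score_matrices[[1]])
  for (m in score_matrices)
    if (!identical(dim(m), dims)) stop_msg("score matrices differ in shape")
  ranks <- vapply(score_matrices, function(m) rank_desc(as.vector(m)),
                  numeric(prod(dims)))
  avg <- rowMeans(as.matrix(ranks))
  n_edges <- prod(dims)
  conf <- if (n_edges > 1) (n_edges - avg) / (n_edges - 1) else 1
  edges <- data.frame(tf = rep(dn[[1]], times = dims[2]),
                      gene = rep(dn[[2]], each = dims[1]),
                      confidence = conf, stringsAsFactors = FALSE)
  finalize_network(edges, dataset_id)
}

## order edges by descending confidence (ties lexicographic) and attach the
## dense rank column
finalize_network <- function(edges, dataset_id) {
  ord <- order(-edges$confidence, edges$tf, edges$gene)
  edges <- edges[ord, , drop = FALSE]
  edges$rank <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  structure(edges, class = c("ranked_network", "data.frame"),
            dataset_id = dataset_id)
}

#' Combine ranked networks by rank averaging
#'
#' Ensemble combination over the same edge universe (the STL-C / MTL-C
#' construction): per-network fractional ranks are recomputed from the
#' confidences (ties averaged), averaged across networks, and rescaled to
#' \[0, 1\] as in [rank_combine()].
#'
#' @param networks list of `ranked_network` data frames over identical
#'   (tf, gene) universes.
#' @param dataset_id label for the combined network.
#' @return A combined `ranked_network`.
#' @export
combine_networks <- function(networks, dataset_id = "combined") {
  if (length(networks) == 0) stop_msg("no networks to combine")
  ref <- networks[[1]]
  key <- function(n) paste(n$tf, n$gene, sep = "\r")
  ref_key <- sort(key(ref))
  rank_sum <- NULL
  for (n in networks) {
    if (!identical(sort(key(n)), ref_key))
      stop_msg("networks cover different edge universes")
    n <- n[order(n$tf, n$gene), , drop = FALSE]
    fr <- rank_desc(n$confidence)
    rank_sum <- if (is.null(rank_sum)) fr else rank_sum + fr
  }
  base <- networks[[1]][order(networks[[1]]$tf, networks[[1]]$gene), , drop = FALSE]
  avg <- rank_sum / length(networks)
  n_edges <- length(avg)
  conf <- if (n_edges > 1) (n_edges - avg) / (n_edges - 1) else 1
  edges <- data.frame(tf = base$tf, gene = base$gene, confidence = conf,
                      stringsAsFactors = FALSE)
  finalize_network(edges, dataset_id)
}
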