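## Synthetic multi-study benchmark generator.
##
## Emulates the statistical structure the inference method assumes: each
## dataset's expression is a sparse weighted sum of latent TF activities plus
## Gaussian noise, a configurable fraction of each gene's regulators is
## shared (same TF, same signed weight) across datasets while the rest are
## dataset-unique, and priors can be corrupted at a controlled recall with
## one uniformly sampled false edge added per `denominator` kept true edges.
## All randomness derives from one integer seed through named substreams
## (truth / activities / noise / prior / splits) so each component is
## independently reproducible.

#' Sample a multi-dataset ground-truth regulatory network
#'
#' Per gene, `edges_per_gene` regulators are planted; a `shared_fraction` of
#' them (rounded) is drawn once and copied — including the signed weight —
#' to every dataset, while the remainder is drawn independently per dataset.
#' Nonzero weights are uniform on ±\[0.5, 2\].
#'
#' @param genes,tfs integer counts (or character id vectors).
#' @param datasets number of datasets.
#' @param edges_per_gene regulators planted per gene (<= number of TFs).
#' @param shared_fraction fraction of each gene's edges shared across
#'   datasets, in \[0, 1\].
#' @param seed integer seed.
#' @return A `synthetic_truth`: list with per-dataset weight matrices `W`
#'   (genes x TFs), the logical `shared` mask, and the generating settings.
#' @export
generate_truth <- function(genes = 100, tfs = 10, datasets = 3,
                           edges_per_gene = 2, shared_fraction = 0.8,
                           seed = 1) {
  gene_ids <- if (is.character(genes)) genes else
    sprintf("g%04d", seq_len(genes))
  tf_ids <- if (is.character(tfs)) tfs else sprintf("tf%03d", seq_len(tfs))
  p <- length(tf_ids)
  if (edges_per_gene > p) stop_msg("edges_per_gene exceeds the number of TFs")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop_msg("shared_fraction must be in [0, 1]")
  set.seed(substream_seed(seed, "truth"))
  n_shared <- round(shared_fraction * edges_per_gene)
  W <- replicate(datasets,
                 matrix(0, length(gene_ids), p,
                        dimnames = list(gene_ids, tf_ids)),
                 simplify = FALSE)
  shared <- matrix(FALSE, length(gene_ids), p,
                   dimnames = list(gene_ids, tf_ids))
  draw_weight <- function(k) runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
  for (g in gene_ids) {
    sh_idx <- sample.int(p, n_shared)
    sh_w <- draw_weight(n_shared)
    shared[g, sh_idx] <- TRUE
    n_uniq <- edges_per_gene - n_shared
    for (d in seq_len(datasets)) {
      W[[d]][g, sh_idx] <- sh_w
      if (n_uniq > 0) {
        pool <- setdiff(seq_len(p), sh_idx)
        u_idx <- pool[sample.int(length(pool), n_uniq)]
        W[[d]][g, u_idx] <- draw_weight(n_uniq)
      }
    }
  }
  structure(list(W = W, shared = shared, genes = gene_ids, tfs = tf_ids,
                 datasets = datasets, edges_per_gene = edges_per_gene,
                 shared_fraction = shared_fraction, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d genes x %d TFs, %d datasets, %d edges/gene (%.0f%% shared)\n",
              length(x$genes), length(x$tfs), x$datasets, x$edges_per_gene,
              100 * x$shared_fraction))
  invisible(x)
}

#' Generate expression datasets from a synthetic truth
#'
#' Latent activities are i.i.d. standard normal per sample (independent
#' across datasets); expression is `X = W_true A + noise` with Gaussian noise
#' of standard deviation `noise_sigma`. Optionally activities follow an AR(1)
#' process along a single time series (for testing the time-delay machinery).
#'
#' @param truth a [generate_truth()] result.
#' @param samples_per_dataset samples per dataset (recycled).
#' @param noise_sigma noise standard deviation, >= 0 (expression units).
#' @param timeseries if `TRUE`, samples form one time series with AR(1)
#'   activities.
#' @param ar AR(1) coefficient used when `timeseries = TRUE`.
#' @param delta_t time step between consecutive samples.
#' @return List of [expression_dataset()] objects; each carries its
#'   activity matrix as attribute `"activities"`.
#' @export
generate_expression <- function(truth, samples_per_dataset = 50,
                                noise_sigma = 1, timeseries = FALSE,
                                ar = 0.8, delta_t = 10) {
  if (noise_sigma < 0) stop_msg("noise_sigma must be >= 0")
  ns <- rep_len(samples_per_dataset, truth$datasets)
  p <- length(truth$tfs)
  out <- vector("list", truth$datasets)
  for (d in seq_len(truth$datasets)) {
    n <- ns[d]
    set.seed(substream_seed(truth$seed, "activities", d))
    if (timeseries) {
      A <- matrix(0, p, n)
      A[, 1] <- rnorm(p)
      for (j in seq_len(n - 1))
        A[, j + 1] <- ar * A[, j] + sqrt(1 - ar^2) * rnorm(p)
    } else {
      A <- matrix(rnorm(p * n), p, n)
    }
    dimnames(A) <- list(truth$tfs, sprintf("d%d_s%03d", d, seq_len(n)))
    set.seed(substream_seed(truth$seed, "noise", d))
    X <- truth$W[[d]] %*% A +
      matrix(rnorm(length(truth$genes) * n, sd = noise_sigma),
             length(truth$genes), n)
    dimnames(X) <- list(truth$genes, colnames(A))
    md <- if (timeseries) {
      data.frame(sample = colnames(A), is_timeseries = TRUE,
                 is_first_in_series = seq_len(n) == 1,
                 previous_sample = c(NA, colnames(A)[-n]),
                 delta_t = c(NA, rep(delta_t, n - 1)),
                 stringsAsFactors = FALSE)
    } else NULL
    ds <- expression_dataset(X, md, sprintf("synthetic_%d", d))
    attr(ds, "activities") <- A
    out[[d]] <- ds
  }
  out
}

## (tf, gene, sign) edge list of the union of planted edges across datasets
truth_edges <- function(truth) {
  any_w <- Reduce(`+`, lapply(truth$W, function(w) (w != 0) * 1))
  idx <- which(any_w != 0, arr.ind = TRUE)
  sgn <- vapply(seq_len(nrow(idx)), function(r) {
    for (w in truth$W) {
      v <- w[idx[r, 1], idx[r, 2]]
      if (v != 0) return(sign(v))
    }
    1
  }, numeric(1))
  data.frame(tf = truth$tfs[idx[, 2]], gene = truth$genes[idx[, 1]],
             sign = sgn, stringsAsFactors = FALSE)
}

#' Gold standard of planted edges
#'
#' @param truth a [generate_truth()] result.
#' @param dataset optional dataset index; default is the union of edges
#'   planted in any dataset.
#' @return A [gold_standard()].
#' @export
gold_standard_from_truth <- function(truth, dataset = NULL) {
  if (is.null(dataset)) return(gold_standard(truth_edges(truth)))
  w <- truth$W[[dataset]]
  idx <- which(w != 0, arr.ind = TRUE)
  gold_standard(data.frame(tf = truth$tfs[idx[, 2]],
                           gene = truth$genes[idx[, 1]],
                           sign = sign(w[idx])))
}

#' Corrupt the planted topology into a noisy prior
#'
#' Keeps a `recall` fraction of the true (union) edges and adds one
#' uniformly sampled false edge for every `denominator` kept true edges
#' (default 1 false per 5 true; `denominator = Inf` disables false edges).
#' False edges are drawn from cells that are non-edges in every dataset, so
#' the false set is disjoint from the truth by construction, and are flagged
#' in the result for later scoring of true-vs-false prior recovery.
#'
#' @param truth a [generate_truth()] result.
#' @param recall fraction of true edges kept, in (0, 1].
#' @param denominator kept-true edges per false edge added.
#' @param seed integer seed (defaults to the truth's prior substream).
#' @return A [prior_matrix()] with attributes `true_edges` and
#'   `false_edges` (data frames of flagged entries).
#' @export
corrupt_prior <- function(truth, recall = 1, denominator = 5, seed = NULL) {
  if (recall <= 0 || recall > 1) stop_msg("recall must be in (0, 1]")
  set.seed(if (is.null(seed)) substream_seed(truth$seed, "prior")
           else as.integer(seed))
  edges <- truth_edges(truth)
  n_keep <- round(recall * nrow(edges))
  keep <- edges[sort(sample.int(nrow(edges), n_keep)), , drop = FALSE]
  n_false <- if (is.finite(denominator)) floor(n_keep / denominator) else 0L
  P <- matrix(0, length(truth$genes), length(truth$tfs),
              dimnames = list(truth$genes, truth$tfs))
  P[cbind(match(keep$gene, truth$genes), match(keep$tf, truth$tfs))] <- keep$sign
  false_df <- data.frame(tf = character(0), gene = character(0),
                         sign = numeric(0), stringsAsFactors = FALSE)
  if (n_false > 0) {
    any_true <- Reduce(`|`, lapply(truth$W, function(w) w != 0))
    non_edges <- which(!any_true)
    if (length(non_edges) < n_false)
      stop_msg("not enough non-edges to sample %d false prior entries", n_false)
    pick <- sample(non_edges, n_false)
    sgn <- sample(c(-1, 1), n_false, replace = TRUE)
    P[pick] <- sgn
    rc <- arrayInd(pick, dim(any_true))
    false_df <- data.frame(tf = truth$tfs[rc[, 2]], gene = truth$genes[rc[, 1]],
                           sign = sgn, stringsAsFactors = FALSE)
  }
  pr <- prior_matrix(P)
  attr(pr, "true_edges") <- keep
  attr(pr, "false_edges") <- false_df
  pr
}

#' Random prior/evaluation splits of a gold standard
#'
#' Partitions the gold standard into a prior part (for activity estimation
#' and penalty weighting) and a disjoint evaluation part, `n_splits` times
#' independently. Within each split the two parts are exhaustive.
#'
#' @param gold a [gold_standard()].
#' @param prior_fraction fraction of edges assigned to the prior, in (0, 1).
#' @param n_splits number of independent splits.
#' @param seed integer seed.
#' @return List of length `n_splits`; each element has `prior` and `eval`
#'   gold standards.
#' @export
split_gold_standard <- function(gold, prior_fraction = 0.5, n_splits = 10,
                                seed = 1) {
  if (prior_fraction <= 0 || prior_fraction >= 1)
    stop_msg("prior_fraction must be in (0, 1)")
  set.seed(substream_seed(seed, "splits"))
  n <- nrow(gold)
  n_prior <- max(1, round(prior_fraction * n))
  if (n_prior >= n) n_prior <- n - 1
  lapply(seq_len(n_splits), function(i) {
    idx <- sort(sample.int(n, n_prior))
    list(prior = gold_standard(as.data.frame(gold)[idx, , drop = FALSE]),
         eval = gold_standard(as.data.frame(gold)[-idx, , drop = FALSE]))
  })
}

#' Prior connectivity matrix from a gold-standard edge list
#'
#' @param gold a [gold_standard()] (e.g. the prior part of a split).
#' @param genes,tfs full universes for the matrix dimensions.
#' @return A [prior_matrix()] with ±1 entries at the gold edges.
#' @export
prior_from_gold <- function(gold, genes, tfs) {
  P <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  keep <- gold$gene %in% genes & gold$tf %in% tfs
  g <- gold[keep, , drop = FALSE]
  P[cbind(match(g$gene, genes), match(g$tf, tfs))] <- g$sign
  prior_matrix(P)
}
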