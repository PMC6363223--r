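## Per-gene regression: single-task lasso and the multitask sparse +
## block-sparse ("dirty") model.
##
## For one target gene with D datasets (tasks), the coefficient matrix W
## (TFs x datasets) is decomposed as W = S + B: S carries dataset-specific
## edges under an elementwise l1/l1 penalty (weighted by the adaptive prior
## matrix Phi), B carries edges conserved across datasets under a row-wise
## l1/linf penalty. Both are fitted jointly by cyclical coordinate descent
## with cached covariance (Gram) products, and the penalty pair is chosen by
## the extended BIC with gamma = 1.

#' Bundle one gene's design/response for one dataset
#'
#' @param design TFs x n numeric matrix of (standardized) activities.
#' @param response numeric vector of length n of (standardized) expression.
#' @param dataset_id dataset identifier.
#' @return A `gene_task` list with `design`, `response`, `n`, `dataset_id`.
#' @export
gene_task <- function(design, response, dataset_id = "task") {
  if (!is.matrix(design)) design <- matrix(design, nrow = 1)
  if (ncol(design) != length(response))
    stop_msg("design has %d samples but response has %d", ncol(design),
             length(response))
  if (length(response) < 2) stop_msg("a task needs at least 2 samples")
  if (anyNA(design) || any(!is.finite(design)) || any(!is.finite(response)))
    stop_msg("non-finite values in task data")
  list(design = design, response = as.numeric(response),
       n = length(response), dataset_id = dataset_id)
}

## standardize a gene task in place (rows of design and the response z-scored
## with population sd, so inner products scale as n)
standardize_gene_task <- function(task) {
  task$design <- standardize_rows(task$design)
  task$response <- standardize_vector(task$response)
  task
}

#' Cache covariance products for the coordinate-descent solver
#'
#' Stores the per-task cross-products `A A'` (TFs x TFs) and `A y` (TFs),
#' which dominate runtime and are reused across every penalty pair and sweep.
#'
#' @param tasks list of [gene_task()] objects (one per dataset), already
#'   standardized.
#' @return A `solver_state` list with per-task Gram matrices `G`, moment
#'   vectors `c`, sample counts `n` and response sums of squares `yty`.
#' @export
precompute_covariances <- function(tasks) {
  if (length(tasks) == 0) stop_msg("no tasks")
  p <- nrow(tasks[[1]]$design)
  for (t in tasks) if (nrow(t$design) != p) stop_msg("tasks disagree on TF count")
  structure(list(
    G = lapply(tasks, function(t) tcrossprod(t$design)),
    c = lapply(tasks, function(t) as.vector(t$design %*% t$response)),
    n = vapply(tasks, function(t) t$n, numeric(1)),
    yty = vapply(tasks, function(t) sum(t$response^2), numeric(1)),
    p = p, d = length(tasks),
    tfs = rownames(tasks[[1]]$design)
  ), class = "solver_state")
}

#' Adaptive-lasso penalty weights from prior topology
#'
#' For one target gene, builds the TFs x datasets weight matrix `Phi` applied
#' to the l1 penalty on `S`: a TF present in dataset `d`'s prior for this
#' gene gets weight `1/rho`, all others get 1, and each column is rescaled to
#' sum to the number of TFs. With `rho = 1` the matrix is all ones. The
#' weights apply to `S` only, never to `B`, so prior support encourages
#' dataset-specific inclusion without forcing conservation.
#'
#' @param priors a [prior_matrix()] or a list of them, one per dataset (each
#'   dataset may have its own prior).
#' @param gene target gene identifier.
#' @param rho prior weight, >= 1; larger values favor prior edges more.
#' @param tfs character vector giving the canonical TF order.
#' @param n_datasets number of datasets (defaults to `length(priors)` when a
#'   list is given).
#' @return TFs x datasets numeric matrix of positive penalty weights.
#' @export
build_penalty_matrix <- function(priors, gene, rho = 1, tfs = NULL,
                                 n_datasets = NULL) {
  if (rho < 1) stop_msg("prior weight rho must be >= 1")
  if (inherits(priors, "prior_matrix")) {
    n_datasets <- n_datasets %||% 1L
    priors <- rep(list(priors), n_datasets)
  }
  n_datasets <- n_datasets %||% length(priors)
  tfs <- tfs %||% priors[[1]]$tfs
  p <- length(tfs)
  phi <- matrix(1, p, n_datasets, dimnames = list(tfs, NULL))
  for (d in seq_len(n_datasets)) {
    pr <- priors[[min(d, length(priors))]]
    if (gene %in% pr$genes) {
      in_prior <- tfs %in% pr$tfs[pr$values[gene, ] != 0]
      phi[in_prior, d] <- 1 / rho
    }
    phi[, d] <- phi[, d] * p / sum(phi[, d])
  }
  phi
}

#' One coordinate-descent sweep over the dataset-specific component S
#'
#' Applies, for every TF k and dataset d, the soft-threshold update of the
#' least-squares coordinate update with `B` held fixed; the threshold is
#' `n_d * Phi[k,d] * lambda_s` on the inner-product scale.
#'
#' @param state a `solver_state` from [precompute_covariances()].
#' @param S,B current TFs x datasets component matrices.
#' @param phi penalty weight matrix from [build_penalty_matrix()].
#' @param lambda_s elementwise penalty level, > 0.
#' @return Updated `S`.
#' @export
update_S <- function(state, S, B, phi, lambda_s) {
  cpp_sweep_s(state$G, state$c, state$n, state$yty, S, B, phi, lambda_s)
}

#' One coordinate-descent sweep over the conserved component B
#'
#' Each TF row of `B` is updated by the exact proximal operator of the
#' `lambda_b * ||B_k||_inf` penalty under the task-weighted quadratic formed
#' from the least-squares updates with `S` fixed; the whole row is set to
#' zero when the weighted l1 mass of the updates is below `lambda_b`. With a
#' single dataset this reduces to the scalar soft-threshold.
#'
#' @inheritParams update_S
#' @param lambda_b row (l1/linf) penalty level, > 0.
#' @return Updated `B`.
#' @export
update_B <- function(state, S, B, lambda_b) {
  cpp_sweep_b(state$G, state$c, state$n, state$yty, S, B, lambda_b)
}

#' Fit the multitask decomposition for one gene at fixed penalties
#'
#' Alternates [update_S()] and [update_B()] sweeps until the largest
#' coefficient change drops below `tol` (default 1e-6) or `max_sweeps` is
#' reached. The objective is non-increasing across sweeps. A previous fit can
#' seed the solver (warm start).
#'
#' @param tasks list of [gene_task()]s, or a precomputed `solver_state`.
#' @param phi penalty weights (TFs x datasets).
#' @param lambda_s,lambda_b penalty levels, > 0.
#' @param warm optional previous `weight_decomposition` for warm starting.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_sweeps sweep cap.
#' @param fit_b set `FALSE` to freeze `B` at zero (pure lasso / single-task).
#' @return A `weight_decomposition`: list with `S`, `B`, `W = S + B`,
#'   `lambda_s`, `lambda_b`, `converged`, `sweeps`, `objective`.
#' @export
fit_gene <- function(tasks, phi, lambda_s, lambda_b, warm = NULL,
                     tol = 1e-6, max_sweeps = 1000L, fit_b = TRUE) {
  state <- if (inherits(tasks, "solver_state")) tasks else
    precompute_covariances(tasks)
  if (lambda_s <= 0 || lambda_b <= 0) stop_msg("penalties must be positive")
  S0 <- if (!is.null(warm)) warm$S else matrix(0, state$p, state$d)
  B0 <- if (!is.null(warm)) warm$B else matrix(0, state$p, state$d)
  r <- cpp_fit_gene(state$G, state$c, state$n, state$yty, phi,
                    lambda_s, lambda_b, S0, B0, tol, as.integer(max_sweeps),
                    fit_b)
  dimnames(r$S) <- dimnames(r$B) <- dimnames(r$W) <-
    list(state$tfs, names(state$G))
  structure(list(S = r$S, B = r$B, W = r$W, lambda_s = lambda_s,
                 lambda_b = lambda_b, converged = r$converged,
                 sweeps = r$sweeps, objective = r$objective),
            class = "weight_decomposition")
}

#' Penalty grid for multitask model selection
#'
#' The row-penalty levels follow `lambda_b = c * sqrt(d * log(p) / n_bar)`
#' with `n_bar` the mean task sample count, for `c` log-spaced over
#' `c_range` (default 20 points in \[0.01, 10\]); for each `lambda_b`,
#' `lambda_s` is placed at fixed ratios strictly inside (1/2, 1). The grid is
#' returned from most to least penalized for warm-start traversal.
#'
#' @param tasks list of [gene_task()]s or a `solver_state`.
#' @param c_range interval searched for the scale factor `c`.
#' @param c_grid_size number of log-spaced `c` values.
#' @param ratios `lambda_s / lambda_b` ratios, all strictly in (1/2, 1).
#' @return data frame with columns `lambda_s`, `lambda_b`, `c`, `ratio`.
#' @export
lambda_grid <- function(tasks, c_range = c(0.01, 10), c_grid_size = 20L,
                        ratios = c(0.55, 0.65, 0.75, 0.85, 0.95)) {
  state <- if (inherits(tasks, "solver_state")) tasks else
    precompute_covariances(tasks)
  if (any(ratios <= 0.5 | ratios >= 1))
    stop_msg("lambda ratios must lie strictly inside (1/2, 1)")
  cs <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = c_grid_size))
  n_bar <- mean(state$n)
  p <- max(state$p, 2)  # log(1) = 0 would collapse the grid
  lb <- cs * sqrt(state$d * log(p) / n_bar)
  grid <- expand.grid(ratio = sort(ratios, decreasing = TRUE),
                      i = rev(seq_along(lb)))
  out <- data.frame(lambda_s = grid$ratio * lb[grid$i],
                    lambda_b = lb[grid$i],
                    c = cs[grid$i], ratio = grid$ratio)
  out  # ordered: largest lambda_b first, then largest ratio
}

#' Extended Bayesian information criterion for a fitted decomposition
#'
#' Computes `(1/d) * sum_d [ n_d log(RSS_d / n_d) + k_d log(n_d) +
#' 2 gamma log C(p d, k_d) ]` with `k_d` the support size of column `d` of
#' `W`. `gamma = 0` recovers the ordinary BIC averaged across tasks. An
#' exactly zero residual sum of squares is floored at machine epsilon.
#'
#' @param fit a `weight_decomposition` (or any list with a `W` matrix).
#' @param tasks list of [gene_task()]s the fit was computed from.
#' @param gamma EBIC weight in \[0, 1\].
#' @return EBIC value (numeric scalar).
#' @export
ebic <- function(fit, tasks, gamma = 1) {
  if (gamma < 0 || gamma > 1) stop_msg("gamma must be in [0, 1]")
  W <- fit$W
  p <- nrow(W)
  d <- length(tasks)
  vals <- vapply(seq_len(d), function(j) {
    t <- tasks[[j]]
    resid <- t$response - as.vector(crossprod(t$design, W[, j]))
    rss <- max(sum(resid^2), .Machine$double.eps)
    kd <- sum(W[, j] != 0)
    t$n * log(rss / t$n) + kd * log(t$n) + 2 * gamma * lchoose(p * d, kd)
  }, numeric(1))
  mean(vals)
}

#' Select the EBIC-optimal penalty pair over a grid
#'
#' Fits the whole grid in warm-start order (most to least penalized) and
#' returns the decomposition minimizing the EBIC with the given `gamma`
#' (default 1). EBIC ties prefer the smaller support, then the larger
#' penalties.
#'
#' @inheritParams fit_gene
#' @param grid data frame of penalty pairs from [lambda_grid()].
#' @param gamma EBIC weight in \[0, 1\].
#' @return The winning `weight_decomposition`, with `ebic`, the searched
#'   `grid` (with per-point EBIC values) and the selected index attached.
#' @export
select_model <- function(tasks, phi, grid, gamma = 1, tol = 1e-6,
                         max_sweeps = 1000L, fit_b = TRUE) {
  state <- if (inherits(tasks, "solver_state")) tasks else
    precompute_covariances(tasks)
  if (nrow(grid) == 0) stop_msg("empty penalty grid")
  if (gamma < 0 || gamma > 1) stop_msg("gamma must be in [0, 1]")
  r <- cpp_select_model(state$G, state$c, state$n, state$yty, phi,
                        grid$lambda_s, grid$lambda_b, gamma, tol,
                        as.integer(max_sweeps), fit_b)
  dimnames(r$S) <- dimnames(r$B) <- dimnames(r$W) <- list(state$tfs, NULL)
  structure(list(S = r$S, B = r$B, W = r$W,
                 lambda_s = r$lambda_s, lambda_b = r$lambda_b,
                 converged = r$converged, sweeps = r$sweeps,
                 objective = r$objective, ebic = r$ebic,
                 index = r$index,
                 grid = cbind(grid, ebic = r$ebic_path,
                              support = r$support_path)),
            class = "weight_decomposition")
}

#' Single-task lasso fit for one gene with EBIC selection
#'
#' The single-dataset baseline: solves the l1-penalized least squares
#' `argmin (1/2n) ||y - A' w||^2 + lambda ||w||_1` by cyclical coordinate
#' descent for every `lambda` in the path (warm-started, largest first) and
#' returns the fit minimizing the single-task EBIC. Structurally this is the
#' S-only special case of the multitask solver.
#'
#' @param design TFs x n matrix of (standardized) activities.
#' @param response numeric response vector of length n (standardized).
#' @param lambda_path decreasing vector of penalty levels; defaults to the
#'   distinct `lambda_s` values of the multitask grid machinery with d = 1.
#' @param phi optional per-TF penalty weights (adaptive lasso), length p.
#' @param gamma EBIC weight.
#' @param gene gene identifier carried through to the result.
#' @inheritParams fit_gene
#' @return An `stl_fit`: list with `gene`, coefficient vector `w`, selected
#'   `lambda`, `ebic`, and the searched path.
#' @export
fit_lasso_gene <- function(design, response, lambda_path = NULL, phi = NULL,
                           gamma = 1, gene = NA_character_, tol = 1e-6,
                           max_sweeps = 1000L) {
  task <- gene_task(design, response)
  state <- precompute_covariances(list(task))
  if (is.null(lambda_path)) {
    g <- lambda_grid(state)
    lambda_path <- sort(unique(g$lambda_s), decreasing = TRUE)
  }
  if (any(lambda_path <= 0)) stop_msg("lambda values must be positive")
  lambda_path <- sort(lambda_path, decreasing = TRUE)
  phim <- matrix(if (is.null(phi)) 1 else phi, nrow = state$p, ncol = 1)
  grid <- data.frame(lambda_s = lambda_path, lambda_b = lambda_path * 2)
  r <- cpp_select_model(state$G, state$c, state$n, state$yty, phim,
                        grid$lambda_s, grid$lambda_b, gamma, tol,
                        as.integer(max_sweeps), FALSE)
  w <- as.vector(r$W)
  names(w) <- state$tfs
  structure(list(gene = gene, w = w, lambda = r$lambda_s, ebic = r$ebic,
                 path = data.frame(lambda = lambda_path, ebic = r$ebic_path,
                                   support = r$support_path),
                 converged = r$converged),
            class = "stl_fit")
}
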