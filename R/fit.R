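## End-to-end inference: expression + priors -> TF activities -> per-gene
## multitask (or single-task) regression across bootstraps -> rank-averaged
## edge confidences -> ranked networks (+ optional gold-standard evaluation).

## Align datasets, estimate activities and build design/response pairs.
prepare_run <- function(datasets, priors, tfa_mode = "prior_pinv", tau = 0,
                        clip_prior = FALSE) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  datasets <- align_genes(datasets)
  n_data <- length(datasets)
  if (inherits(priors, "prior_matrix")) priors <- rep(list(priors), n_data)
  if (length(priors) == 1 && n_data > 1) priors <- rep(priors, n_data)
  if (length(priors) != n_data)
    stop_msg("need one prior (or one per dataset); got %d for %d datasets",
             length(priors), n_data)
  tau <- rep_len(tau, n_data)
  genes <- datasets[[1]]$genes
  tfs <- sort(unique(unlist(lapply(priors, function(p) p$tfs))))
  pairs <- vector("list", n_data)
  priors_used <- vector("list", n_data)
  for (d in seq_len(n_data)) {
    ds <- datasets[[d]]
    pr <- priors[[d]]
    common_genes <- intersect(pr$genes, ds$genes)
    pv <- matrix(0, length(common_genes), length(tfs),
                 dimnames = list(common_genes, tfs))
    pv[, intersect(pr$tfs, tfs)] <-
      pr$values[common_genes, intersect(pr$tfs, tfs), drop = FALSE]
    pr_full <- prior_matrix(pv)
    priors_used[[d]] <- pr_full
    act <- if (tfa_mode == "expression") {
      expression_as_activities(ds, intersect(tfs, ds$genes))
    } else {
      halftau <- build_halftau_response(ds, tau[d])
      estimate_activities(pr_full, halftau, ds, clip = clip_prior)
    }
    if (!identical(act$tfs, tfs)) {
      av <- matrix(0, length(tfs), length(ds$samples),
                   dimnames = list(tfs, ds$samples))
      av[act$tfs, ] <- act$values
      act$values <- av
      act$tfs <- tfs
    }
    pairs[[d]] <- build_regression_pairs(ds, act$values, tau[d])
  }
  list(pairs = pairs, priors = priors_used, genes = genes, tfs = tfs,
       dataset_ids = vapply(datasets, function(d) d$dataset_id, character(1)),
       datasets = datasets)
}

## One full fit over (possibly resampled) conditions; returns per-dataset
## TFs x genes confidence score matrices.
fit_networks_once <- function(prepared, mode = "mtl", boot_idx = NULL,
                              rho = 1, gamma = 1, c_range = c(0.01, 10),
                              c_grid_size = 20L,
                              ratios = c(0.55, 0.65, 0.75, 0.85, 0.95),
                              tol = 1e-6, max_sweeps = 1000L,
                              num_workers = 1L) {
  tfs <- prepared$tfs
  genes <- prepared$genes
  p <- length(tfs)
  n_data <- length(prepared$pairs)
  ## per-dataset standardized matrices and covariance caches
  states <- lapply(seq_len(n_data), function(d) {
    pr <- prepared$pairs[[d]]
    idx <- if (is.null(boot_idx)) seq_len(pr$n) else boot_idx[[d]]
    A <- standardize_rows(pr$design[tfs, idx, drop = FALSE])
    Y <- standardize_rows(pr$response[genes, idx, drop = FALSE])
    list(G = tcrossprod(A), C = A %*% t(Y), yty = rowSums(Y^2),
         n = length(idx))
  })
  nvec <- vapply(states, `[[`, numeric(1), "n")
  ## prior support masks (TFs x genes), FALSE where the prior has no row
  support_masks <- lapply(prepared$priors, function(pr) {
    m <- matrix(FALSE, p, length(genes), dimnames = list(tfs, genes))
    common <- intersect(pr$genes, genes)
    m[, common] <- t(pr$values[common, tfs, drop = FALSE] != 0)
    m
  })
  shared_state <- structure(list(p = p, d = n_data, n = nvec), class = "solver_state")
  grid_mtl <- lambda_grid(shared_state, c_range, c_grid_size, ratios)
  grids_stl <- lapply(seq_len(n_data), function(d) {
    st <- structure(list(p = p, d = 1L, n = nvec[d]), class = "solver_state")
    g <- lambda_grid(st, c_range, c_grid_size, ratios)
    lam <- sort(unique(g$lambda_s), decreasing = TRUE)
    data.frame(lambda_s = lam, lambda_b = lam * 2)
  })
  fit_one_gene <- function(i) {
    phi <- matrix(1, p, n_data)
    for (d in seq_len(n_data)) {
      phi[support_masks[[d]][, i], d] <- 1 / rho
      phi[, d] <- phi[, d] * p / sum(phi[, d])
    }
    if (mode == "mtl") {
      Glist <- lapply(states, `[[`, "G")
      clist <- lapply(states, function(s) s$C[, i])
      yty <- vapply(states, function(s) s$yty[i], numeric(1))
      r <- cpp_select_model(Glist, clist, nvec, yty, phi,
                            grid_mtl$lambda_s, grid_mtl$lambda_b, gamma,
                            tol, as.integer(max_sweeps), TRUE)
      st <- structure(list(G = Glist, c = clist, n = nvec, yty = yty,
                           p = p, d = n_data, tfs = tfs),
                      class = "solver_state")
      confidence_scores(list(W = r$W), st)
    } else {
      vapply(seq_len(n_data), function(d) {
        s <- states[[d]]
        r <- cpp_select_model(list(s$G), list(s$C[, i]), nvec[d], s$yty[i],
                              phi[, d, drop = FALSE],
                              grids_stl[[d]]$lambda_s, grids_stl[[d]]$lambda_b,
                              gamma, tol, as.integer(max_sweeps), FALSE)
        st <- structure(list(G = list(s$G), c = list(s$C[, i]), n = nvec[d],
                             yty = s$yty[i], p = p, d = 1L, tfs = tfs),
                        class = "solver_state")
        confidence_scores(list(W = r$W), st)[, 1]
      }, numeric(p))
    }
  }
  res <- if (num_workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(genes), fit_one_gene,
                       mc.cores = num_workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_along(genes), fit_one_gene)
  }
  lapply(seq_len(n_data), function(d) {
    m <- vapply(res, function(r) r[, d], numeric(p))
    dimnames(m) <- list(tfs, genes)
    m
  })
}

#' Bootstrap the conditions and refit
#'
#' For each bootstrap, condition columns are resampled with replacement
#' jointly in the design and response (so time-linked pairs stay aligned),
#' the full per-gene fit and confidence scoring is rerun, and the resulting
#' score matrices are returned. Bootstrap `b` is seeded with `seed + b`, so
#' results are deterministic given `seed`.
#'
#' @param datasets list of [expression_dataset()]s (or a `prepared` run).
#' @param priors a [prior_matrix()] or list of them, one per dataset.
#' @param n_boot number of bootstraps (>= 1).
#' @param seed integer seed.
#' @param resample set `FALSE` for identity "bootstraps" (a single plain
#'   fit per replicate).
#' @param mode `"mtl"` (joint fit) or `"stl"` (per-dataset lasso).
#' @param tfa_mode `"prior_pinv"` (activities from the prior pseudo-inverse)
#'   or `"expression"` (TF expression as activities).
#' @param tau regulatory time delay per dataset (time units).
#' @param rho prior weight, >= 1.
#' @param gamma EBIC weight.
#' @param num_workers genes are fitted in parallel with this many workers;
#'   results are identical to serial execution.
#' @param ... further arguments to the solver (`c_range`, `c_grid_size`,
#'   `ratios`, `tol`, `max_sweeps`).
#' @return List of length `n_boot`; element `b` is the list of per-dataset
#'   TFs x genes confidence score matrices for bootstrap `b`.
#' @export
run_bootstraps <- function(datasets, priors, n_boot = 20, seed = 42,
                           resample = TRUE, mode = "mtl",
                           tfa_mode = "prior_pinv", tau = 0, rho = 1,
                           gamma = 1, num_workers = 1L, ...) {
  if (n_boot < 1) stop_msg("n_boot must be >= 1")
  prepared <- if (is.list(datasets) && !is.null(datasets$pairs)) datasets
  else prepare_run(datasets, priors, tfa_mode, tau)
  ns <- vapply(prepared$pairs, `[[`, numeric(1), "n")
  lapply(seq_len(n_boot), function(b) {
    idx <- NULL
    if (resample) {
      set.seed(as.integer(seed) + b)
      idx <- lapply(ns, function(n) sample.int(n, n, replace = TRUE))
    }
    out <- fit_networks_once(prepared, mode = mode, boot_idx = idx, rho = rho,
                             gamma = gamma, num_workers = num_workers, ...)
    attr(out, "boot_idx") <- idx
    out
  })
}

#' Infer regulatory networks across multiple expression datasets
#'
#' The main fitting function. Runs the full pipeline: gene alignment across
#' datasets, half-tau response construction, TF activity estimation from the
#' prior, per-gene sparse + block-sparse multitask regression (or
#' single-task lasso) with adaptive prior weighting and EBIC selection
#' across bootstraps of the conditions, and bootstrap rank-averaging into
#' per-dataset ranked networks plus a rank-combined ensemble network. If a
#' gold standard is supplied the networks are evaluated by precision-recall.
#'
#' @param datasets an [expression_dataset()] or list of them.
#' @param priors a [prior_matrix()] or a list, one per dataset.
#' @param gold optional [gold_standard()] for evaluation.
#' @param mode `"mtl"` for joint multitask inference, `"stl"` for
#'   independent per-dataset lasso models.
#' @param tfa_mode `"prior_pinv"` or `"expression"`.
#' @param tau regulatory time delay, scalar or per dataset.
#' @param prior_weight adaptive penalty prior weight rho (>= 1); 1 disables
#'   prior-biased selection (the prior still drives activity estimation).
#' @param n_boot bootstraps of the conditions (paper default 20).
#' @param gamma EBIC weight (default 1).
#' @param seed integer seed controlling the bootstrap resampling.
#' @param num_workers per-gene parallelism; output is identical to serial.
#' @param resample set `FALSE` to disable bootstrap resampling.
#' @param clip_prior clip prior magnitudes to signs before activity
#'   estimation.
#' @param ... solver options (`c_range`, `c_grid_size`, `ratios`, `tol`,
#'   `max_sweeps`).
#' @return An object of class `multigrn` with elements `networks` (one
#'   `ranked_network` per dataset), `combined`, `evaluation` (PR curves and
#'   AUPRs, when `gold` given), and the run settings.
#' @examples
#' truth <- generate_truth(genes = 30, tfs = 5, datasets = 2, seed = 7)
#' expr <- generate_expression(truth, samples_per_dataset = 30)
#' prior <- corrupt_prior(truth, recall = 0.7)
#' fit <- multigrn(expr, prior, gold = gold_standard_from_truth(truth),
#'                 n_boot = 2, seed = 7)
#' fit
#' @export
multigrn <- function(datasets, priors, gold = NULL, mode = c("mtl", "stl"),
                     tfa_mode = c("prior_pinv", "expression"), tau = 0,
                     prior_weight = 1, n_boot = 20, gamma = 1, seed = 42,
                     num_workers = 1L, resample = TRUE, clip_prior = FALSE,
                     ...) {
  mode <- match.arg(mode)
  tfa_mode <- match.arg(tfa_mode)
  if (prior_weight < 1) stop_msg("prior_weight must be >= 1")
  prepared <- prepare_run(datasets, priors, tfa_mode, tau, clip_prior)
  boots <- run_bootstraps(prepared, NULL, n_boot = n_boot, seed = seed,
                          resample = resample, mode = mode, tau = tau,
                          rho = prior_weight, gamma = gamma,
                          num_workers = num_workers, ...)
  n_data <- length(prepared$pairs)
  networks <- lapply(seq_len(n_data), function(d) {
    rank_combine(lapply(boots, `[[`, d), prepared$dataset_ids[d])
  })
  names(networks) <- prepared$dataset_ids
  combined <- if (n_data > 1) combine_networks(networks) else networks[[1]]
  evaluation <- NULL
  if (!is.null(gold)) {
    curves <- lapply(networks, precision_recall, gold = gold)
    curves$combined <- precision_recall(combined, gold)
    evaluation <- list(pr = curves,
                       aupr = vapply(curves, aupr, numeric(1)))
  }
  structure(list(networks = networks, combined = combined,
                 evaluation = evaluation,
                 mode = mode, tfa_mode = tfa_mode, tau = tau,
                 prior_weight = prior_weight, n_boot = n_boot,
                 gamma = gamma, seed = seed,
                 genes = prepared$genes, tfs = prepared$tfs,
                 dataset_ids = prepared$dataset_ids,
                 call = match.call()),
            class = "multigrn")
}

#' @export
print.multigrn <- function(x, ...) {
  cat(sprintf("Multi-study regulatory network fit (%s, %d bootstraps)\n",
              toupper(x$mode), x$n_boot))
  cat(sprintf("  %d genes, %d TFs, %d dataset(s): %s\n", length(x$genes),
              length(x$tfs), length(x$dataset_ids),
              paste(x$dataset_ids, collapse = ", ")))
  if (!is.null(x$evaluation)) {
    a <- x$evaluation$aupr
    cat("  AUPR: ", paste(sprintf("%s = %.3f", names(a), a), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.multigrn <- function(object, confidence_cutoff = 0.5, ...) {
  tab <- data.frame(
    network = c(object$dataset_ids,
                if (length(object$dataset_ids) > 1) "combined"),
    edges_above_cutoff = vapply(
      c(object$networks,
        if (length(object$dataset_ids) > 1) list(object$combined)),
      function(n) sum(n$confidence >= confidence_cutoff), numeric(1)))
  if (!is.null(object$evaluation)) {
    tab$aupr <- object$evaluation$aupr[c(object$dataset_ids,
                                         if (length(object$dataset_ids) > 1)
                                           "combined")]
  }
  structure(list(table = tab, cutoff = confidence_cutoff,
                 mode = object$mode), class = "summary.multigrn")
}

#' @export
print.summary.multigrn <- function(x, ...) {
  cat(sprintf("Networks (%s), edges with confidence >= %.2f:\n",
              toupper(x$mode), x$cutoff))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Edge confidences of a fitted multi-study network
#'
#' @param object a [multigrn()] fit.
#' @param dataset dataset id or index; `"combined"` for the ensemble.
#' @param ... unused.
#' @return TFs x genes matrix of confidences in \[0, 1\].
#' @export
coef.multigrn <- function(object, dataset = "combined", ...) {
  net <- if (identical(dataset, "combined")) object$combined
  else object$networks[[dataset]]
  m <- matrix(0, length(object$tfs), length(object$genes),
              dimnames = list(object$tfs, object$genes))
  m[cbind(net$tf, net$gene)] <- net$confidence
  m
}

#' Plot precision-recall curves of a fitted network
#'
#' @param x a [multigrn()] fit (evaluated against a gold standard).
#' @param ... passed to [graphics::plot()].
#' @export
plot.multigrn <- function(x, ...) {
  if (is.null(x$evaluation))
    stop_msg("fit has no evaluation; supply a gold standard to multigrn()")
  curves <- x$evaluation$pr
  cols <- seq_along(curves)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", ...)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$recall, curves[[i]]$precision, col = cols[i])
  graphics::legend("topright",
                   legend = sprintf("%s (AUPR %.3f)", names(curves),
                                    x$evaluation$aupr),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
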