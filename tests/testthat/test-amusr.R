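test_that("penalty matrix follows the prior rule and column rescaling", {
  genes <- paste0("g", 1:3)
  tfs <- paste0("tf", 1:4)
  P <- matrix(0, 3, 4, dimnames = list(genes, tfs))
  P["g1", "tf4"] <- 1
  pr <- prior_matrix(P)
  ## rho = 1: all ones regardless of the prior
  expect_equal(build_penalty_matrix(pr, "g1", rho = 1, tfs = tfs),
               matrix(1, 4, 1, dimnames = list(tfs, NULL)))
  ## 4 TFs, one in the prior, rho = 2: (1,1,1,0.5) rescaled by 4/3.5
  phi <- build_penalty_matrix(pr, "g1", rho = 2, tfs = tfs)
  expect_equal(unname(phi[, 1]), c(1, 1, 1, 0.5) * 4 / 3.5)
  expect_equal(sum(phi), 4)  # column sums to the TF count
  expect_true(all(phi > 0))
  ## per-dataset priors give different columns
  P2 <- matrix(0, 3, 4, dimnames = list(genes, tfs))
  P2["g1", "tf1"] <- -1
  phi2 <- build_penalty_matrix(list(pr, prior_matrix(P2)), "g1", rho = 2,
                               tfs = tfs)
  expect_equal(unname(phi2[, 1]), c(1, 1, 1, 0.5) * 4 / 3.5)
  expect_equal(unname(phi2[, 2]), c(0.5, 1, 1, 1) * 4 / 3.5)
  expect_error(build_penalty_matrix(pr, "g1", rho = 0.5), "rho")
})

test_that("cached covariance products equal direct dense recomputation", {
  tasks <- random_instance(p = 4, d = 3, n = 15, seed = 51)
  st <- precompute_covariances(tasks)
  for (j in 1:3) {
    A <- tasks[[j]]$design
    expect_equal(st$G[[j]], A %*% t(A), tolerance = 1e-10)
    expect_equal(st$c[[j]], as.vector(A %*% tasks[[j]]$response),
                 tolerance = 1e-10)
  }
  ## orthonormal design: A A' = n I
  A <- orthonormal_design(3, 12, seed = 2)
  st2 <- precompute_covariances(list(gene_task(A, rnorm(12))))
  expect_equal(st2$G[[1]], diag(3) * 12,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("S sweep soft-thresholds the least-squares update, scaled by phi", {
  ## 1 task, 2 orthonormal predictors: closed form per coordinate
  A <- orthonormal_design(2, 10, seed = 4)
  set.seed(4)
  y <- rnorm(10)
  st <- precompute_covariances(list(gene_task(A, y)))
  alpha <- as.vector(A %*% y)  # inner-product scale
  n <- 10
  lam <- 0.08
  S0 <- matrix(0, 2, 1); B0 <- matrix(0, 2, 1)
  S1 <- update_S(st, S0, B0, matrix(1, 2, 1), lam)
  oracle <- sign(alpha) * pmax(abs(alpha) - n * lam, 0) / n
  expect_equal(unname(S1[, 1]), oracle, tolerance = 1e-10)
  ## below-threshold updates land exactly on zero
  big <- max(abs(alpha)) / n + 0.01
  expect_true(all(update_S(st, S0, B0, matrix(1, 2, 1), big) == 0))
  ## phi -> 0 disables shrinkage: the least-squares update survives intact
  S_free <- update_S(st, S0, B0, matrix(0, 2, 1), lam)
  expect_equal(unname(S_free[, 1]), alpha / n, tolerance = 1e-10)
})

test_that("B row updates implement the exact l1/linf proximal operator", {
  ## single dataset: reduces to the scalar soft-threshold (same as S, phi=1)
  tasks <- random_instance(p = 3, d = 1, n = 12, seed = 61)
  st <- precompute_covariances(tasks)
  S0 <- matrix(0, 3, 1); B0 <- matrix(0, 3, 1)
  lam <- 0.1
  expect_equal(update_B(st, S0, B0, lam),
               update_S(st, S0, B0, matrix(1, 3, 1), lam), tolerance = 1e-12)

  ## two tasks, unit Gram diagonal, least-squares updates a = (0.9, 0.9):
  ## with lambda_b = 0.4 the max-norm prox clips both to the shared 0.7
  n <- 8
  mk_task <- function(target, seed) {
    set.seed(seed)
    a <- standardize_vector_test(rnorm(n))
    r <- rnorm(n)
    r <- r - a * sum(a * r) / sum(a * a)   # orthogonal residual
    gene_task(matrix(a, 1, n, dimnames = list("tf1", NULL)), target * a + r)
  }
  st2 <- precompute_covariances(list(mk_task(0.9, 1), mk_task(0.9, 2)))
  B1 <- update_B(st2, matrix(0, 1, 2), matrix(0, 1, 2), lambda_b = 0.4)
  expect_equal(unname(B1), matrix(c(0.7, 0.7), 1, 2), tolerance = 1e-10)
  ## numeric convex-minimization oracle on the same 2-variable row objective
  row_obj <- function(b) 0.5 * sum((b - c(0.9, 0.9))^2) + 0.4 * max(abs(b))
  opt <- optim(c(0, 0), row_obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12))
  expect_equal(unname(B1[1, ]), opt$par, tolerance = 1e-4)

  ## zero condition: weighted l1 mass of the updates below lambda_b
  st3 <- precompute_covariances(list(mk_task(0.2, 3), mk_task(0.15, 4)))
  B3 <- update_B(st3, matrix(0, 1, 2), matrix(0, 1, 2), lambda_b = 0.4)
  expect_true(all(B3 == 0))
})

test_that("fit_gene solves the joint objective and shrinks fully when asked", {
  tasks <- random_instance(p = 4, d = 2, n = 15, seed = 71)
  phi <- matrix(1, 4, 2)
  ## penalties above the full-shrinkage thresholds give W = 0
  fitz <- fit_gene(tasks, phi, lambda_s = 100, lambda_b = 150)
  expect_true(all(fitz$W == 0))
  ## moderate penalties: objective within tolerance of the subgradient oracle
  for (i in 1:5) {
    set.seed(400 + i)
    tk <- random_instance(p = sample(2:4, 1), d = sample(2:3, 1),
                          n = sample(8:20, 1), seed = 500 + i)
    p <- nrow(tk[[1]]$design); d <- length(tk)
    ph <- matrix(1, p, d)
    ls <- runif(1, 0.03, 0.2); lb <- ls / runif(1, 0.6, 0.9)
    fit <- fit_gene(tk, ph, ls, lb, tol = 1e-9, max_sweeps = 5000)
    f_cd <- objective_direct(tk, fit$S, fit$B, ph, ls, lb)
    f_or <- subgradient_objective(tk, ph, ls, lb, iters = 2e4)
    expect_lte((f_cd - f_or) / max(abs(f_or), 1e-10), 1e-3)
    expect_equal(fit$W, fit$S + fit$B)
  }
})

test_that("alternating sweeps never increase the objective", {
  tasks <- random_instance(p = 5, d = 3, n = 10, seed = 81)
  st <- precompute_covariances(tasks)
  phi <- matrix(1, 5, 3)
  ls <- 0.05; lb <- 0.08
  S <- matrix(0, 5, 3); B <- matrix(0, 5, 3)
  f_prev <- objective_direct(tasks, S, B, phi, ls, lb)
  for (sweep in 1:25) {
    S <- update_S(st, S, B, phi, ls)
    f1 <- objective_direct(tasks, S, B, phi, ls, lb)
    expect_lte(f1, f_prev + 1e-12)
    B <- update_B(st, S, B, lb)
    f2 <- objective_direct(tasks, S, B, phi, ls, lb)
    expect_lte(f2, f1 + 1e-12)
    f_prev <- f2
  }
})

test_that("noise-free shared support is recovered and duplicated tasks agree", {
  set.seed(91)
  p <- 5; n <- 30
  mk <- function(seed) {
    set.seed(seed)
    A <- t(apply(matrix(rnorm(p * n), p, n), 1, standardize_vector_test))
    rownames(A) <- paste0("tf", 1:p)
    y <- as.vector(A[2, ]) * 1.5          # one shared regulator, no noise
    gene_task(A, standardize_vector_test(y))
  }
  tasks <- list(mk(1), mk(2), mk(3))
  fit <- fit_gene(tasks, matrix(1, p, 3), lambda_s = 0.02, lambda_b = 0.03,
                  tol = 1e-10)
  expect_true(all(fit$W[2, ] != 0))
  expect_true(all(fit$W[-2, ] == 0))
  ## identical tasks replicated: all W columns identical
  same <- list(mk(7), mk(7), mk(7))
  fit2 <- fit_gene(same, matrix(1, p, 3), 0.05, 0.07, tol = 1e-10)
  expect_equal(fit2$W[, 1], fit2$W[, 2])
  expect_equal(fit2$W[, 2], fit2$W[, 3])
})

test_that("a perfect prior never loses true edges on orthonormal designs", {
  set.seed(101)
  p <- 4; n <- 20; d <- 2
  A <- orthonormal_design(p, n, seed = 101)
  mk <- function(seed) {
    set.seed(seed)
    y <- as.vector(A[1, ] * 0.8 + A[3, ] * -0.6) + rnorm(n, sd = 0.5)
    gene_task(A, y)
  }
  tasks <- list(mk(1), mk(2))
  true_idx <- c(1, 3)
  for (lam in c(0.05, 0.15, 0.3)) {
    flat <- fit_gene(tasks, matrix(1, p, d), lam, lam / 0.75, tol = 1e-9)
    phi0 <- matrix(1, p, d)
    phi0[true_idx, ] <- 0  # perfect prior confidence: no penalty on truth
    informed <- fit_gene(tasks, phi0, lam, lam / 0.75, tol = 1e-9)
    n_true_flat <- sum(flat$W[true_idx, ] != 0)
    n_true_informed <- sum(informed$W[true_idx, ] != 0)
    expect_gte(n_true_informed, n_true_flat)
  }
})

test_that("the penalty grid respects the printed constraints", {
  tasks <- random_instance(p = 4, d = 3, n = 12, seed = 111)
  g <- lambda_grid(tasks, c_range = c(0.01, 10), c_grid_size = 20)
  expect_equal(nrow(g), 20 * 5)
  ratio <- g$lambda_s / g$lambda_b
  expect_true(all(ratio > 0.5 & ratio < 1))
  expect_equal(range(g$c), c(0.01, 10))
  ## lambda_b formula at the endpoints
  nbar <- mean(vapply(tasks, `[[`, numeric(1), "n"))
  expect_equal(max(g$lambda_b), 10 * sqrt(3 * log(4) / nbar))
  expect_equal(min(g$lambda_b), 0.01 * sqrt(3 * log(4) / nbar))
  ## deterministic and ordered most -> least penalized
  g2 <- lambda_grid(tasks, c_range = c(0.01, 10), c_grid_size = 20)
  expect_identical(g, g2)
  expect_true(all(diff(g$lambda_b) <= 1e-12))
  expect_error(lambda_grid(tasks, ratios = c(0.4, 0.6)), "strictly inside")
})

test_that("EBIC matches its definition, BIC limit and hand-computed case", {
  ## hand case: d = 1, n = 10, RSS = 10, k = 1, p = 3, gamma = 1
  A <- orthonormal_design(3, 10, seed = 5)
  w <- c(2, 0, 0)
  set.seed(5)
  r <- rnorm(10)
  r <- r - t(A) %*% solve(tcrossprod(A), A %*% r)  # orthogonal to all rows
  r <- as.vector(r) * sqrt(10 / sum(r^2))          # ||r||^2 = 10
  y <- as.vector(crossprod(A, w)) + r
  tasks <- list(gene_task(A, y))
  fit <- list(W = matrix(w, 3, 1))
  expect_equal(ebic(fit, tasks, gamma = 1), log(10) + 2 * log(3),
               tolerance = 1e-10)
  ## gamma = 0 recovers the plain BIC (no combinatorial term)
  expect_equal(ebic(fit, tasks, gamma = 0), log(10), tolerance = 1e-10)
  ## empty model: (1/d) sum n_d log(RSS_d / n_d) exactly
  fit0 <- list(W = matrix(0, 3, 1))
  expect_equal(ebic(fit0, tasks, gamma = 1), 10 * log(sum(y^2) / 10))
  expect_error(ebic(fit, tasks, gamma = 2), "gamma")
  ## C++ and R implementations agree on random fits
  tk <- random_instance(4, 2, 12, seed = 9)
  st <- precompute_covariances(tk)
  Wr <- matrix(rnorm(8) * rbinom(8, 1, 0.5), 4, 2)
  expect_equal(multigrn:::cpp_ebic(st$G, st$c, st$n, st$yty, Wr, 1),
               ebic(list(W = Wr), tk, 1), tolerance = 1e-8)
})

test_that("select_model returns the grid-wide EBIC minimum and recovers truth", {
  tasks <- random_instance(p = 3, d = 2, n = 25, seed = 121)
  phi <- matrix(1, 3, 2)
  grid <- lambda_grid(tasks, c_grid_size = 6, ratios = c(0.6, 0.8))
  sel <- select_model(tasks, phi, grid)
  ## single-pair grid returns that fit
  one <- select_model(tasks, phi, grid[5, ])
  expect_equal(one$lambda_s, grid$lambda_s[5])
  ## exhaustive re-evaluation oracle: every grid point refitted cold and
  ## scored with the independent R-side EBIC
  ebics <- vapply(seq_len(nrow(grid)), function(i) {
    f <- fit_gene(tasks, phi, grid$lambda_s[i], grid$lambda_b[i], tol = 1e-8)
    ebic(f, tasks, gamma = 1)
  }, numeric(1))
  expect_lte(sel$ebic, min(ebics) + 1e-6)

  ## planted sparse support with n >> p is recovered in >= 9/10 seeds; note
  ## the EBIC here scores the penalized fit, so excluding each spurious
  ## predictor costs about twice its squared max spurious z-score against
  ## log(n) gained -- exact support recovery therefore needs n large, not
  ## merely n > p
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    p <- 5; n <- 1000
    tk <- lapply(1:2, function(j) {
      A <- t(apply(matrix(rnorm(p * n), p, n), 1, standardize_vector_test))
      rownames(A) <- paste0("tf", 1:p)
      y <- as.vector(A[2, ]) + rnorm(n, sd = 0.3)
      gene_task(A, standardize_vector_test(y))
    })
    sel_s <- select_model(tk, matrix(1, p, 2), lambda_grid(tk))
    supp <- unname(which(rowSums(sel_s$W != 0) > 0))
    if (identical(supp, 2L)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
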