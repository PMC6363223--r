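# Independent oracles and fixture builders used across the test suite.
# Everything here is deliberately naive (dense algebra, subgradient descent,
# exhaustive enumeration) and shares no code path with the package solver.

# objective of the multitask sparse + block-sparse problem, computed directly
# from raw task matrices:
#   sum_d (1/(2 n_d)) ||y_d - A_d' w_d||^2
#   + lambda_s * sum |phi * S| + lambda_b * sum_k max_d |B_kd|
objective_direct <- function(tasks, S, B, phi, lambda_s, lambda_b) {
  W <- S + B
  loss <- 0
  for (d in seq_along(tasks)) {
    t <- tasks[[d]]
    r <- t$response - as.vector(crossprod(t$design, W[, d]))
    loss <- loss + sum(r^2) / (2 * t$n)
  }
  loss + lambda_s * sum(abs(phi * S)) + lambda_b * sum(apply(abs(B), 1, max))
}

# brute-force convex minimizer: subgradient descent over (S, B) jointly with
# a diminishing step size, tracking the best objective seen; works on cached
# cross-products so 1e5 iterations stay affordable in plain R
subgradient_minimize <- function(tasks, phi, lambda_s, lambda_b,
                                 iters = 1e5) {
  p <- nrow(tasks[[1]]$design)
  d <- length(tasks)
  nv <- vapply(tasks, `[[`, numeric(1), "n")
  yty <- vapply(tasks, function(t) sum(t$response^2), numeric(1))
  # stacked representation: coefficients as length p*d vectors, loss terms
  # through one block-diagonal Gram matrix already scaled by 1/n_d
  Gbig <- matrix(0, p * d, p * d)
  cbig <- numeric(p * d)
  for (j in seq_len(d)) {
    idx <- (j - 1) * p + seq_len(p)
    Gbig[idx, idx] <- tcrossprod(tasks[[j]]$design) / nv[j]
    cbig[idx] <- as.vector(tasks[[j]]$design %*% tasks[[j]]$response) / nv[j]
  }
  const <- sum(yty / (2 * nv))
  phiv <- as.vector(phi)
  s <- numeric(p * d)
  b <- numeric(p * d)
  rowmax <- function(v) {
    m <- abs(matrix(v, p, d))
    out <- m[, 1]
    if (d > 1) for (j in 2:d) out <- pmax(out, m[, j])
    out
  }
  obj <- function(s, b, mx) {
    w <- s + b
    const - sum(w * cbig) + 0.5 * sum(w * (Gbig %*% w)) +
      lambda_s * sum(abs(phiv * s)) + lambda_b * sum(mx)
  }
  best <- obj(s, b, numeric(p))
  best_s <- s; best_b <- b
  a0 <- 1 / max(sqrt(sum(cbig^2)) + lambda_s + lambda_b, 1e-8)
  for (it in seq_len(iters)) {
    gs <- as.vector(Gbig %*% (s + b)) - cbig
    mxv <- rep(rowmax(b), d)
    is_max <- (abs(b) == mxv) & (mxv > 0)
    cnt <- rep(pmax(rowSums(matrix(is_max, p, d)), 1), d)
    step <- a0 / sqrt(it)
    s <- s - step * (gs + lambda_s * phiv * sign(s))
    b <- b - step * (gs + lambda_b * sign(b) * is_max / cnt)
    f <- obj(s, b, rowmax(b))
    if (f < best) {
      best <- f
      best_s <- s; best_b <- b
    }
  }
  list(objective = best, S = matrix(best_s, p, d), B = matrix(best_b, p, d))
}

# Same subgradient scheme compiled at test time for speed (plain Rcpp, no
# code shared with the package solver); falls back to the R loop if the
# toolchain is unavailable. Returns the best objective value seen.
subgradient_oracle_env <- new.env()
subgradient_objective <- function(tasks, phi, lambda_s, lambda_b,
                                  iters = 1e5) {
  if (is.null(subgradient_oracle_env$fn) &&
      is.null(subgradient_oracle_env$failed)) {
    subgradient_oracle_env$fn <- tryCatch({
      Rcpp::cppFunction('
double subgrad_best(NumericMatrix Gbig, NumericVector cbig, int p, int d,
                    NumericVector phiv, double lambda_s, double lambda_b,
                    double constant, int iters) {
  int m = p * d;
  std::vector<double> s(m, 0.0), b(m, 0.0), w(m), g(m);
  double best = constant;
  double a0 = 0.0;
  for (int i = 0; i < m; ++i) a0 += cbig[i] * cbig[i];
  a0 = 1.0 / std::max(std::sqrt(a0) + lambda_s + lambda_b, 1e-8);
  for (int it = 1; it <= iters; ++it) {
    for (int i = 0; i < m; ++i) w[i] = s[i] + b[i];
    for (int i = 0; i < m; ++i) {
      double acc = -cbig[i];
      for (int j = 0; j < m; ++j) acc += Gbig(i, j) * w[j];
      g[i] = acc;
    }
    double step = a0 / std::sqrt((double) it);
    // subgradient of the row-wise max norm on B
    for (int k = 0; k < p; ++k) {
      double mx = 0.0;
      for (int j = 0; j < d; ++j)
        mx = std::max(mx, std::fabs(b[j * p + k]));
      int cnt = 0;
      if (mx > 0)
        for (int j = 0; j < d; ++j)
          if (std::fabs(b[j * p + k]) == mx) ++cnt;
      for (int j = 0; j < d; ++j) {
        int i = j * p + k;
        double sub = g[i];
        if (mx > 0 && std::fabs(b[i]) == mx)
          sub += lambda_b * ((b[i] > 0) ? 1.0 : -1.0) / cnt;
        b[i] -= step * sub;
      }
    }
    for (int i = 0; i < m; ++i) {
      double sg = (s[i] > 0) ? 1.0 : ((s[i] < 0) ? -1.0 : 0.0);
      s[i] -= step * (g[i] + lambda_s * phiv[i] * sg);
    }
    // objective at the new point
    double f = constant;
    for (int i = 0; i < m; ++i) w[i] = s[i] + b[i];
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += Gbig(i, j) * w[j];
      f += 0.5 * w[i] * acc - w[i] * cbig[i];
      f += lambda_s * phiv[i] * std::fabs(s[i]);
    }
    for (int k = 0; k < p; ++k) {
      double mx = 0.0;
      for (int j = 0; j < d; ++j)
        mx = std::max(mx, std::fabs(b[j * p + k]));
      f += lambda_b * mx;
    }
    if (f < best) best = f;
  }
  return best;
}')
    }, error = function(e) {
      subgradient_oracle_env$failed <- TRUE
      NULL
    })
  }
  if (is.null(subgradient_oracle_env$fn))
    return(subgradient_minimize(tasks, phi, lambda_s, lambda_b, iters)$objective)
  p <- nrow(tasks[[1]]$design)
  d <- length(tasks)
  nv <- vapply(tasks, `[[`, numeric(1), "n")
  Gbig <- matrix(0, p * d, p * d)
  cbig <- numeric(p * d)
  for (j in seq_len(d)) {
    idx <- (j - 1) * p + seq_len(p)
    Gbig[idx, idx] <- tcrossprod(tasks[[j]]$design) / nv[j]
    cbig[idx] <- as.vector(tasks[[j]]$design %*% tasks[[j]]$response) / nv[j]
  }
  const <- sum(vapply(tasks, function(t) sum(t$response^2), numeric(1)) /
                 (2 * nv))
  subgradient_oracle_env$fn(Gbig, cbig, p, d, as.vector(phi), lambda_s,
                            lambda_b, const, as.integer(iters))
}

# population-sd z-score used to build standardized fixtures
standardize_vector_test <- function(x) {
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

# random standardized multitask instance
random_instance <- function(p, d, n, seed) {
  set.seed(seed)
  lapply(seq_len(d), function(j) {
    A <- matrix(rnorm(p * n), p, n)
    A <- t(apply(A, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
    if (p == 1) A <- matrix(A, 1, n)
    rownames(A) <- paste0("tf", seq_len(p))
    y <- rnorm(n)
    y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
    gene_task(A, y, paste0("t", j))
  })
}

# a design with exactly orthogonal rows scaled so <A_k, A_k> = n, with
# column means ~0 irrelevant because tests feed it unstandardized on purpose
orthonormal_design <- function(p, n, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))  # n x p, orthonormal columns
  A <- t(q) * sqrt(n)                        # p x n, <A_k, A_l> = n * I
  rownames(A) <- paste0("tf", seq_len(p))
  A
}

# exhaustive prefix-sum precision-recall oracle over a labelled ranking
aupr_enumerate <- function(hits, n_gold) {
  tp <- 0
  area <- 0
  prev_recall <- 0
  for (i in seq_along(hits)) {
    if (hits[i]) tp <- tp + 1
    recall <- tp / n_gold
    area <- area + (tp / i) * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

# small steady-state expression fixture written/read in tests
make_fixture_dataset <- function(genes = 6, samples = 8, seed = 1,
                                 id = "fix") {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), genes, samples,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expression_dataset(m, dataset_id = id)
}
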