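test_that("confidence scores equal nested-OLS variance shares", {
  ## two orthogonal predictors with known variance shares: y = x1 + x2 + e,
  ## |x1|^2 = 2, |x2|^2 = 1, |e|^2 = 3 (all mutually orthogonal), so
  ## c_1 = 1 - 3/(3+2) = 0.4 and c_2 = 1 - 3/(3+1) = 0.25
  A <- rbind(tf1 = c(sqrt(2), 0, 0), tf2 = c(0, 1, 0))
  y <- c(sqrt(2), 1, sqrt(3))
  tasks <- list(gene_task(A, y))
  W <- matrix(c(1, 1), 2, 1, dimnames = list(rownames(A), NULL))
  cs <- confidence_scores(list(W = W), tasks)
  expect_equal(unname(cs[, 1]), c(0.4, 0.25), tolerance = 1e-10)

  ## single predictor explaining the response exactly scores 1
  A2 <- matrix(c(1, 2, -1), 1, 3, dimnames = list("tf1", NULL))
  cs2 <- confidence_scores(list(W = matrix(2, 1, 1)),
                           list(gene_task(A2, 2 * as.vector(A2))))
  expect_equal(unname(cs2[1, 1]), 1)

  ## predictor whose removal leaves the residual unchanged scores 0
  A3 <- rbind(tf1 = c(1, 1, -2, 0), tf2 = c(0, 2, 2, -4) * 0)
  A3["tf2", ] <- c(1, -1, 0, 0)
  y3 <- c(1, 1, -2, 0)  # exactly tf1's profile; tf2 orthogonal & irrelevant
  W3 <- matrix(c(1, 1), 2, 1)
  cs3 <- confidence_scores(list(W = W3), list(gene_task(A3, y3)))
  expect_equal(unname(cs3[2, 1]), 0)
})

test_that("confidence scores stay in [0, 1] and collinear duplicates drop", {
  set.seed(33)
  for (i in 1:50) {
    tasks <- random_instance(p = 4, d = 2, n = 10, seed = 600 + i)
    W <- matrix(rnorm(8) * rbinom(8, 1, 0.6), 4, 2)
    cs <- confidence_scores(list(W = W), tasks)
    expect_true(all(cs >= 0 & cs <= 1))
    expect_true(all(cs[W == 0] == 0))
  }
  ## exactly collinear pair: the later TF is dropped and scored 0
  x <- c(1, -1, 2, 0, 1)
  A <- rbind(tf1 = x, tf2 = x, tf3 = c(0, 1, 0, -1, 1))
  y <- x + rnorm(5, sd = 0.1)
  W <- matrix(c(1, 1, 1), 3, 1)
  cs <- confidence_scores(list(W = W), list(gene_task(A, y)))
  expect_equal(unname(cs[2, 1]), 0)
  expect_gt(cs[1, 1], 0)
})

test_that("rank_combine averages ranks and rescales to [0, 1]", {
  m1 <- matrix(c(0.9, 0.5, 0.1, 0.7, 0.3, 0.2), 2, 3,
               dimnames = list(c("tf1", "tf2"), c("g1", "g2", "g3")))
  ## identical matrices: ordering equals the single-matrix ordering
  net1 <- rank_combine(list(m1), "a")
  net2 <- rank_combine(list(m1, m1, m1), "a")
  expect_equal(net1[, c("tf", "gene", "rank")], net2[, c("tf", "gene", "rank")])
  expect_equal(max(net1$confidence), 1)
  expect_equal(min(net1$confidence), 0)
  expect_equal(sort(net1$rank), seq_len(6))

  ## reversed rankings cancel: all average ranks tie
  m_rev <- matrix(c(0.1, 0.5, 0.9, 0.3, 0.7, 0.8), 2, 3,
                  dimnames = dimnames(m1))
  ## hand arithmetic: ranks of m1 are (1,3,6,2,4,5); of m_rev (6,4,1,5,3,2)
  comb <- rank_combine(list(m1, m_rev))
  expect_equal(length(unique(comb$confidence)), 1)

  ## all-zero scores: everything ties at the midpoint set by average ranks
  z <- matrix(0, 2, 3, dimnames = dimnames(m1))
  netz <- rank_combine(list(z))
  expect_equal(unique(netz$confidence), 0.5)
  expect_error(rank_combine(list(m1, matrix(0, 3, 3))), "shape")
})

test_that("combine_networks is idempotent and cancels reversed orders", {
  m <- matrix(runif(12), 3, 4,
              dimnames = list(paste0("tf", 1:3), paste0("g", 1:4)))
  net <- rank_combine(list(m), "a")
  ## combining a network with itself keeps the ordering
  same <- combine_networks(list(net, net, net))
  expect_equal(same[, c("tf", "gene", "rank")], net[, c("tf", "gene", "rank")])
  ## two fully reversed networks tie everywhere
  rev_net <- net
  rev_net$confidence <- 1 - rev_net$confidence
  rev_net <- multigrn:::finalize_network(
    rev_net[, c("tf", "gene", "confidence")], "b")
  both <- combine_networks(list(net, rev_net))
  expect_equal(length(unique(both$confidence)), 1)
  ## mismatched universes fail
  m2 <- m[, 1:3]
  expect_error(combine_networks(list(net, rank_combine(list(m2), "c"))),
               "universes")
})

test_that("bootstraps are deterministic and identity resampling is a plain fit", {
  truth <- generate_truth(genes = 15, tfs = 4, datasets = 2,
                          edges_per_gene = 2, shared_fraction = 1, seed = 5)
  expr <- generate_expression(truth, samples_per_dataset = 20, noise_sigma = 0.3)
  prior <- corrupt_prior(truth, recall = 1, denominator = Inf)
  b1 <- run_bootstraps(expr, prior, n_boot = 2, seed = 99)
  b2 <- run_bootstraps(expr, prior, n_boot = 2, seed = 99)
  expect_identical(b1, b2)
  ## identity bootstrap equals a single plain fit, repeated
  plain <- run_bootstraps(expr, prior, n_boot = 2, seed = 1, resample = FALSE)
  expect_identical(plain[[1]], plain[[2]])
  ## resampled column multisets replay an independently seeded sampler
  ns <- vapply(expr, function(d) length(d$samples), numeric(1))
  for (b in 1:2) {
    set.seed(99 + b)
    expected_idx <- lapply(ns, function(n) sample.int(n, n, replace = TRUE))
    expect_identical(attr(b1[[b]], "boot_idx"), expected_idx)
  }
})
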