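make_network <- function(tfs, genes, conf) {
  edges <- data.frame(tf = tfs, gene = genes, confidence = conf)
  multigrn:::finalize_network(edges, "test")
}

test_that("AUPR hits analytic values for extreme rankings", {
  ## gold universe is {tf1, tf2} x {g1, g2}: 4 candidate edges, 3 of them gold
  gold2 <- gold_standard(data.frame(tf = c("tf1", "tf1", "tf2"),
                                    gene = c("g1", "g2", "g1"), sign = 1))
  univ <- expand.grid(tf = c("tf1", "tf2"), gene = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  key <- paste(univ$tf, univ$gene)
  is_gold <- key %in% c("tf1 g1", "tf1 g2", "tf2 g1")
  ## gold edges ranked first: AUPR = 1
  net_best <- make_network(univ$tf, univ$gene, ifelse(is_gold, 0.9, 0.1))
  expect_equal(aupr(precision_recall(net_best, gold2)), 1)
  ## gold edges ranked last: step-sum oracle over every prefix
  net_worst <- make_network(univ$tf, univ$gene, ifelse(is_gold, 0.1, 0.9))
  pr <- precision_recall(net_worst, gold2)
  expect_equal(aupr(pr), aupr_enumerate(sort(is_gold), 3))
  ## precision at full recall equals gold prevalence in the universe
  expect_equal(pr$precision[length(pr$precision)], 3 / 4)
  expect_error(precision_recall(net_best, gold2[0, ]), "empty")
})

test_that("random rankings score near prevalence; AUPR ignores monotone rescale", {
  set.seed(55)
  n_edges <- 600
  tfs <- rep(paste0("tf", sprintf("%02d", 1:20)), each = 30)
  genes <- rep(paste0("g", sprintf("%02d", 1:30)), times = 20)
  ## gold spread along a coprime stride so the universe covers every candidate
  gold_idx <- ((0:59) * 37) %% 600 + 1
  gold <- gold_standard(data.frame(tf = tfs[gold_idx], gene = genes[gold_idx],
                                   sign = 1))
  stopifnot(setequal(unique(tfs), unique(gold$tf)),
            setequal(unique(genes), unique(gold$gene)))
  auprs <- replicate(300, {
    conf <- runif(n_edges)
    aupr(precision_recall(make_network(tfs, genes, conf), gold))
  })
  prevalence <- nrow(gold) / n_edges
  expect_lt(abs(mean(auprs) - prevalence), 0.03)
  ## strictly monotone transformation leaves AUPR unchanged
  conf <- runif(n_edges)
  a1 <- aupr(precision_recall(make_network(tfs, genes, conf), gold))
  a2 <- aupr(precision_recall(make_network(tfs, genes, plogis(5 * conf)), gold))
  expect_equal(a1, a2)
})

test_that("edges outside the gold universe are excluded before ranking", {
  gold <- gold_standard(data.frame(tf = "tf1", gene = c("g1", "g2"), sign = 1))
  net <- make_network(c("tfX", "tf1", "tf1", "tf1"),
                      c("g1", "g1", "g9", "g2"),
                      c(0.99, 0.8, 0.7, 0.6))
  pr <- precision_recall(net, gold)
  ## tfX and g9 rows dropped: 2 candidates, both gold, perfect curve
  expect_equal(attr(pr, "n_candidates"), 2)
  expect_equal(aupr(pr), 1)
})

test_that("precision-cutoff filtering returns the maximal qualifying prefix", {
  gold <- gold_standard(data.frame(tf = "tf1", gene = paste0("g", 1:3), sign = 1))
  ## top-3 gold, 4th not: precision at 4 is 0.75 >= 0.5, extends through 4;
  ## at 5 with another miss precision drops to 0.6, still >= 0.5
  net <- make_network(rep("tf1", 5), c("g1", "g2", "g3", "g4", "g5"),
                      c(0.9, 0.8, 0.7, 0.6, 0.5))
  got <- filter_at_precision(net, gold, 0.5)
  expect_gte(nrow(got), 3)
  ## every returned prefix keeps precision >= cutoff at its end
  hits <- paste(got$tf, got$gene) %in% paste(gold$tf, gold$gene)
  expect_gte(sum(hits) / nrow(got), 0.5)
  ## cutoff 1.0 with a non-gold top edge gives the empty set: the top-ranked
  ## in-universe edge (tf1 -> g3) is a miss, so no prefix reaches precision 1
  net_bad <- make_network(rep("tf1", 2), c("g3", "g1"), c(0.9, 0.2))
  gold_mixed <- gold_standard(data.frame(tf = c("tf1", "tf2"),
                                         gene = c("g1", "g3"), sign = 1))
  got2 <- filter_at_precision(net_bad, gold_mixed, 1)
  expect_equal(nrow(got2), 0)
  expect_error(filter_at_precision(net, gold, 0), "cutoff")
})

test_that("overlap counts partition edges by exact membership", {
  a <- data.frame(tf = c("t1", "t1", "t2"), gene = c("g1", "g2", "g3"))
  b <- data.frame(tf = c("t1", "t2"), gene = c("g1", "g3"))
  cc <- data.frame(tf = "t1", gene = "g1")
  counts <- overlap_counts(list(A = a, B = b, C = cc))
  expect_equal(unname(counts[["A&B&C"]]), 1)  # t1-g1 everywhere
  expect_equal(unname(counts[["A&B"]]), 1)    # t2-g3
  expect_equal(unname(counts[["A"]]), 1)      # t1-g2
  expect_equal(unname(counts[["B"]]), 0)
  expect_equal(sum(counts), 3)                # partition of the union
  ## identical sets: everything lands in the shared-by-all cell
  same <- overlap_counts(list(x = a, y = a))
  expect_equal(unname(same[["x&y"]]), nrow(a))
  expect_equal(unname(same[["x"]]) + unname(same[["y"]]), 0)
})
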