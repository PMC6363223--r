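## Gold-standard evaluation: precision-recall curves, AUPR, precision-cutoff
## filtering and cross-network edge overlap.

## restrict a ranked network to the gold TF/gene universe, preserving order
restrict_to_gold <- function(network, gold) {
  keep <- network$tf %in% attr(gold, "tfs") & network$gene %in% attr(gold, "genes")
  net <- network[keep, , drop = FALSE]
  net[order(net$rank), , drop = FALSE]
}

#' Precision-recall curve of a ranked network against a gold standard
#'
#' Candidate edges are restricted to TFs and genes present in the gold
#' standard before ranking; the ranked list is then swept prefix by prefix.
#' The area under the curve is the step integral `sum(precision *
#' delta(recall))` (no interpolation). Gold-standard signs are ignored:
#' evaluation is on edge presence only.
#'
#' @param network a `ranked_network`.
#' @param gold a [gold_standard()].
#' @return A `pr_curve`: data frame of (recall, precision) points with the
#'   `aupr`, candidate and gold counts as attributes.
#' @export
precision_recall <- function(network, gold) {
  if (nrow(gold) == 0) stop_msg("empty gold standard")
  net <- restrict_to_gold(network, gold)
  if (nrow(net) == 0) stop_msg("no candidate edges within the gold universe")
  gold_key <- paste(gold$tf, gold$gene, sep = "\r")
  hit <- paste(net$tf, net$gene, sep = "\r") %in% gold_key
  tp <- cumsum(hit)
  precision <- tp / seq_along(tp)
  recall <- tp / nrow(gold)
  aupr <- sum(precision * diff(c(0, recall)))
  structure(data.frame(recall = recall, precision = precision),
            class = c("pr_curve", "data.frame"),
            aupr = aupr, n_gold = nrow(gold), n_candidates = nrow(net))
}

#' Area under the precision-recall curve
#' @param x a `pr_curve` from [precision_recall()].
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(x) attr(x, "aupr")

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("Precision-recall curve: %d candidates vs %d gold edges, AUPR = %.4f\n",
              attr(x, "n_candidates"), attr(x, "n_gold"), attr(x, "aupr")))
  invisible(x)
}

#' Edges passing a precision cutoff
#'
#' Returns the maximal ranked prefix (within the gold universe) whose
#' precision is at least `cutoff`; an empty prefix is allowed.
#'
#' @inheritParams precision_recall
#' @param cutoff precision threshold in (0, 1].
#' @return Data frame of the qualifying edges in rank order.
#' @export
filter_at_precision <- function(network, gold, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff > 1) stop_msg("cutoff must be in (0, 1]")
  net <- restrict_to_gold(network, gold)
  if (nrow(net) == 0) return(net)
  gold_key <- paste(gold$tf, gold$gene, sep = "\r")
  hit <- paste(net$tf, net$gene, sep = "\r") %in% gold_key
  precision <- cumsum(hit) / seq_along(hit)
  ok <- which(precision >= cutoff)
  if (length(ok) == 0) return(net[0, , drop = FALSE])
  net[seq_len(max(ok)), , drop = FALSE]
}

#' Venn-style overlap counts across edge sets
#'
#' Tallies, for every nonempty combination of the input networks, the number
#' of edges found in exactly that combination.
#'
#' @param edge_sets named list of data frames with columns `tf`, `gene`.
#' @return Named integer vector; names are `&`-joined set names.
#' @export
overlap_counts <- function(edge_sets) {
  if (is.null(names(edge_sets)))
    names(edge_sets) <- paste0("net", seq_along(edge_sets))
  keys <- lapply(edge_sets, function(e) paste(e$tf, e$gene, sep = "\r"))
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(edge_sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(edge_sets)[row], collapse = "&"))
  sets <- names(edge_sets)
  all_patterns <- unlist(lapply(seq_along(sets), function(k)
    apply(combn(sets, k), 2, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = all_patterns))
  out <- as.integer(counts)
  names(out) <- all_patterns
  out
}
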