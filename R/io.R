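## Domain containers and file input/output.
##
## Expression data are tab-delimited genes x samples tables with a per-sample
## metadata sheet describing steady-state vs time-series structure. Priors are
## signed genes x TFs connectivity matrices (entries may be +/-1 or signed
## motif counts). Gold standards are (tf, gene, sign) edge lists.

#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with per-sample metadata and a
#' dataset identifier. Metadata rows must cover every sample and describe the
#' time-series structure: `is_timeseries`, `is_first_in_series`,
#' `previous_sample` (the preceding sample in the series, `NA` for
#' steady-state or series-initial samples) and `delta_t` (time since the
#' previous sample, in the dataset's time units).
#'
#' @param values numeric matrix, genes in rows (rownames) and samples in
#'   columns (colnames); no missing values.
#' @param metadata data frame with columns `sample`, `is_timeseries`,
#'   `is_first_in_series`, `previous_sample`, `delta_t`; one row per sample.
#'   If `NULL`, all samples are treated as steady-state.
#' @param dataset_id character scalar naming the dataset.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, metadata = NULL, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_msg("expression values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop_msg("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop_msg("duplicate gene identifier: %s", genes[duplicated(genes)][1])
  if (anyDuplicated(samples))
    stop_msg("duplicate sample identifier: %s", samples[duplicated(samples)][1])
  if (anyNA(values) || any(!is.finite(values)))
    stop_msg("expression matrix for '%s' contains missing or non-finite values",
             dataset_id)
  if (is.null(metadata)) {
    metadata <- data.frame(sample = samples,
                           is_timeseries = FALSE,
                           is_first_in_series = FALSE,
                           previous_sample = NA_character_,
                           delta_t = NA_real_,
                           stringsAsFactors = FALSE)
  }
  metadata <- validate_metadata(metadata, samples)
  structure(list(dataset_id = dataset_id, genes = genes, samples = samples,
                 values = values, metadata = metadata),
            class = "expression_dataset")
}

validate_metadata <- function(md, samples) {
  req <- c("sample", "is_timeseries", "is_first_in_series",
           "previous_sample", "delta_t")
  missing_cols <- setdiff(req, names(md))
  if (length(missing_cols))
    stop_msg("metadata missing column(s): %s", paste(missing_cols, collapse = ", "))
  md$sample <- as.character(md$sample)
  md$previous_sample <- as.character(md$previous_sample)
  md$previous_sample[md$previous_sample %in% c("", "NA", "none")] <- NA_character_
  md$is_timeseries <- as.logical(md$is_timeseries)
  md$is_first_in_series <- as.logical(md$is_first_in_series)
  md$delta_t <- as.numeric(md$delta_t)
  if (anyDuplicated(md$sample))
    stop_msg("duplicate sample in metadata: %s", md$sample[duplicated(md$sample)][1])
  extra <- setdiff(md$sample, samples)
  if (length(extra))
    stop_msg("metadata lists sample absent from expression matrix: %s", extra[1])
  absent <- setdiff(samples, md$sample)
  if (length(absent))
    stop_msg("sample missing from metadata: %s", absent[1])
  md <- md[match(samples, md$sample), , drop = FALSE]
  rownames(md) <- NULL
  needs_prev <- md$is_timeseries & !md$is_first_in_series
  if (any(needs_prev & is.na(md$previous_sample)))
    stop_msg("time-series sample without previous_sample: %s",
             md$sample[needs_prev & is.na(md$previous_sample)][1])
  if (any(!needs_prev & !is.na(md$previous_sample)))
    stop_msg("previous_sample set on non-continuation sample: %s",
             md$sample[!needs_prev & !is.na(md$previous_sample)][1])
  has_prev <- !is.na(md$previous_sample)
  if (any(has_prev & (is.na(md$delta_t) | md$delta_t <= 0)))
    stop_msg("delta_t must be > 0 whenever previous_sample is set (sample %s)",
             md$sample[has_prev & (is.na(md$delta_t) | md$delta_t <= 0)][1])
  bad_prev <- setdiff(md$previous_sample[has_prev], md$sample)
  if (length(bad_prev))
    stop_msg("previous_sample '%s' not present in metadata", bad_prev[1])
  ## cycle check by walking each chain
  prev <- stats::setNames(md$previous_sample, md$sample)
  for (s in md$sample) {
    seen <- character(0)
    cur <- s
    while (!is.na(prev[[cur]])) {
      if (cur %in% seen) stop_msg("previous_sample links form a cycle at %s", cur)
      seen <- c(seen, cur)
      cur <- prev[[cur]]
    }
  }
  md
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s': %d genes x %d samples (%d time-series)\n",
              x$dataset_id, length(x$genes), length(x$samples),
              sum(x$metadata$is_timeseries)))
  invisible(x)
}

#' Construct a signed prior connectivity matrix
#'
#' @param values numeric matrix, genes x TFs, with dimnames. Positive entries
#'   denote known activation, negative repression, zero no known interaction;
#'   magnitudes may carry motif counts.
#' @return An object of class `prior_matrix` with fields `genes`, `tfs`,
#'   `values`.
#' @export
prior_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_msg("prior must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_msg("prior matrix must have gene rownames and TF colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_msg("duplicate identifiers in prior matrix")
  if (anyNA(values)) stop_msg("prior matrix contains missing values")
  structure(list(genes = rownames(values), tfs = colnames(values),
                 values = values),
            class = "prior_matrix")
}

#' @export
print.prior_matrix <- function(x, ...) {
  cat(sprintf("Prior matrix: %d genes x %d TFs, %d signed entries\n",
              length(x$genes), length(x$tfs), sum(x$values != 0)))
  invisible(x)
}

#' Construct a gold standard edge set
#'
#' @param edges data frame with columns `tf`, `gene`, `sign` (signs in -1/+1).
#' @return Object of class `gold_standard`: the edge data frame plus derived
#'   `tfs` and `genes` universes as attributes.
#' @export
gold_standard <- function(edges) {
  req <- c("tf", "gene", "sign")
  if (!all(req %in% names(edges))) stop_msg("gold standard needs columns tf, gene, sign")
  edges <- data.frame(tf = as.character(edges$tf), gene = as.character(edges$gene),
                      sign = as.numeric(edges$sign), stringsAsFactors = FALSE)
  key <- paste(edges$tf, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1, ]
    stop_msg("duplicate gold-standard edge: %s -> %s", d$tf, d$gene)
  }
  if (!all(edges$sign %in% c(-1, 1)))
    stop_msg("gold-standard signs must be -1 or +1")
  structure(edges, class = c("gold_standard", "data.frame"),
            tfs = sort(unique(edges$tf)), genes = sort(unique(edges$gene)))
}

#' Read an expression dataset from TSV files
#'
#' The expression file is tab-delimited with gene identifiers in the first
#' column and a header row of sample identifiers. The metadata file is a
#' tab-delimited table with columns `sample`, `is_timeseries`,
#' `is_first_in_series`, `previous_sample`, `delta_t` covering every sample.
#'
#' @param path path to the expression TSV.
#' @param metadata_path optional path to the sample metadata TSV; if omitted
#'   all samples are treated as steady-state.
#' @param dataset_id dataset identifier; defaults to the file name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, metadata_path = NULL, dataset_id = NULL) {
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop_msg("expression file '%s' is empty", path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!apply(m, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col)))))]
    stop_msg("non-numeric expression values in column(s): %s",
             paste(bad, collapse = ", "))
  }
  rownames(m) <- genes
  md <- NULL
  if (!is.null(metadata_path)) {
    md <- read.delim(metadata_path, stringsAsFactors = FALSE)
  }
  expression_dataset(m, md, dataset_id)
}

#' Read a signed prior connectivity matrix from TSV
#'
#' Expects a tab-delimited genes x TFs table (first column gene ids, header
#' row TF ids). Signs are preserved as stored; all-zero rows and columns are
#' kept because they are meaningful downstream (TFs with an all-zero prior
#' column fall back to measured expression as activity).
#'
#' @param path path to the prior TSV.
#' @return A [prior_matrix()].
#' @export
read_prior <- function(path) {
  tab <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop_msg("cannot read prior file '%s': %s",
                                               path, conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) < 2) stop_msg("prior file '%s' is empty", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_msg("non-numeric entries in prior file '%s'", path)
  rownames(m) <- as.character(tab[[1]])
  prior_matrix(m)
}

#' Read a gold standard edge list from TSV
#'
#' Accepts either a 3-column edge list (`tf`, `gene`, `sign`) or a genes x TFs
#' signed matrix in the same layout as a prior file (auto-detected by header).
#'
#' @param path path to the TSV.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("tf", "gene") %in% names(tab))) {
    if (!"sign" %in% names(tab)) tab$sign <- 1
    return(gold_standard(tab[, c("tf", "gene", "sign")]))
  }
  ## matrix layout: convert nonzero cells to edges
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_msg("gold standard file '%s' not recognized", path)
  rownames(m) <- as.character(tab[[1]])
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_msg("gold standard file '%s' has no edges", path)
  gold_standard(data.frame(tf = colnames(m)[idx[, 2]],
                           gene = rownames(m)[idx[, 1]],
                           sign = sign(m[idx])))
}

#' Write a ranked network to TSV
#'
#' Emits columns `tf`, `gene`, `combined_confidence`, `rank`, sorted by
#' descending confidence with ties broken lexicographically by TF then gene.
#'
#' @param network a `ranked_network` data frame (see [rank_combine()]).
#' @param path output file path.
#' @export
write_network <- function(network, path) {
  stopifnot(all(c("tf", "gene", "confidence", "rank") %in% names(network)))
  ord <- order(-network$confidence, network$tf, network$gene)
  out <- network[ord, c("tf", "gene", "confidence", "rank")]
  names(out)[3] <- "combined_confidence"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression dataset (and its metadata) to TSV
#'
#' Inverse of [read_expression()]; used by the synthetic-data generator.
#'
#' @param dataset an [expression_dataset()].
#' @param path expression TSV path.
#' @param metadata_path optional metadata TSV path.
#' @export
write_expression <- function(dataset, path, metadata_path = NULL) {
  tab <- data.frame(gene = dataset$genes, dataset$values, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    write.table(dataset$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Write a prior matrix to TSV
#' @param prior a [prior_matrix()].
#' @param path output path.
#' @export
write_prior <- function(prior, path) {
  tab <- data.frame(gene = prior$genes, prior$values, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict datasets to their common genes
#'
#' Every dataset is restricted to the intersection of all gene sets, in one
#' canonical (lexicographically sorted) order, so downstream per-gene models
#' line up across datasets.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @return List of datasets over the shared, sorted gene set.
#' @export
align_genes <- function(datasets) {
  if (length(datasets) < 1) stop_msg("align_genes needs at least one dataset")
  common <- Reduce(intersect, lapply(datasets, function(d) d$genes))
  if (length(common) == 0) stop_msg("no genes shared across datasets")
  common <- sort(common)
  lapply(datasets, function(d) {
    expression_dataset(d$values[common, , drop = FALSE], d$metadata, d$dataset_id)
  })
}
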