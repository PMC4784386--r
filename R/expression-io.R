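#' Read a genes x samples expression table with phenotype labels
#'
#' Reads a tab-separated expression table (header row of sample ids, first
#' column of gene ids, log-scale intensities) together with a two-column
#' phenotype file mapping every sample id to `case` or `control`.
#'
#' All cells must be finite numbers; a non-numeric or missing cell is an
#' error naming the offending gene and sample. Sample ids must be unique.
#' Gene ids may repeat (multiple probes per gene); see
#' [collapse_duplicate_genes()].
#'
#' @param path Path to the expression TSV.
#' @param label_path Path to the phenotype TSV with columns `sample_id` and
#'   `group` (values `case`/`control`).
#' @return A tibble with a `gene_id` character column followed by one
#'   numeric column per sample, carrying the label tibble in the
#'   `"labels"` attribute (retrieve with [expr_labels()]).
#' @export
read_expression_table <- function(path, label_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs a gene-id column and at least one sample column")
  sample_ids <- names(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  gene_ids <- as.character(raw[[1L]])
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)), USE.NAMES = TRUE)
  )
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(NULL, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite cell for gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  labels <- read_labels(label_path)
  missing <- setdiff(sample_ids, labels$sample_id)
  if (length(missing) > 0L)
    stop("sample(s) missing from label file: ", paste(missing, collapse = ", "))
  labels <- labels[match(sample_ids, labels$sample_id), , drop = FALSE]
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                           tibble::as_tibble(vals))
  message(sprintf("read expression table: %d genes x %d samples (%d case, %d control)",
                  nrow(expr), length(sample_ids),
                  sum(labels$group == "case"), sum(labels$group == "control")))
  structure(expr, labels = labels)
}

read_labels <- function(path) {
  labels <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(labels)))
    stop("label file must have columns 'sample_id' and 'group'")
  if (anyDuplicated(labels$sample_id))
    stop("duplicate sample id(s) in label file")
  bad <- setdiff(unique(labels$group), c("case", "control"))
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'case' or 'control')")
  tibble::tibble(sample_id = labels$sample_id, group = labels$group)
}

#' Retrieve the phenotype labels attached to an expression tibble
#'
#' @param expr An expression tibble as returned by
#'   [read_expression_table()] or [generate_dataset()].
#' @return A tibble with columns `sample_id` and `group`.
#' @export
expr_labels <- function(expr) {
  labels <- attr(expr, "labels")
  if (is.null(labels))
    stop("expression tibble carries no labels; pass `labels` explicitly")
  labels
}

#' Write an expression tibble (and optionally its labels) to TSV
#'
#' @param expr Expression tibble (`gene_id` first column).
#' @param path Output path for the expression TSV.
#' @param labels Optional label tibble; defaults to the attached labels if
#'   present.
#' @param label_path Output path for the label TSV (required when labels
#'   are written).
#' @return `expr`, invisibly.
#' @export
write_expression_table <- function(expr, path, labels = attr(expr, "labels"),
                                   label_path = NULL) {
  readr::write_tsv(tibble::as_tibble(expr), path, progress = FALSE)
  if (!is.null(labels)) {
    if (is.null(label_path))
      stop("label_path required to write labels")
    readr::write_tsv(labels, label_path, progress = FALSE)
  }
  invisible(expr)
}

# genes x samples numeric matrix (rownames = gene ids) from the tidy form
expr_matrix <- function(expr) {
  stopifnot(names(expr)[1L] == "gene_id")
  m <- as.matrix(expr[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

check_labeled <- function(expr, labels) {
  sample_ids <- names(expr)[-1L]
  if (!setequal(labels$sample_id, sample_ids) ||
      anyDuplicated(labels$sample_id))
    stop("labels must cover exactly the sample columns of `expr`")
  labels <- labels[match(sample_ids, labels$sample_id), , drop = FALSE]
  if (!all(c("case", "control") %in% labels$group))
    stop("both 'case' and 'control' labels must be present")
  labels
}

#' Collapse duplicated gene ids to the probe with the highest mean intensity
#'
#' When several rows (probes) share a gene id, the row with the largest row
#' mean is kept; exact ties keep the first-occurring row. Row order of the
#' surviving rows is preserved, so the operation is the identity on
#' duplicate-free input and is idempotent.
#'
#' @param expr Expression tibble (`gene_id` first column).
#' @return Expression tibble with unique `gene_id`s; labels attribute, if
#'   any, is preserved.
#' @export
collapse_duplicate_genes <- function(expr) {
  m <- expr_matrix(expr)
  means <- rowMeans(m)
  keep <- rep(TRUE, nrow(expr))
  dup_genes <- unique(expr$gene_id[duplicated(expr$gene_id)])
  for (g in dup_genes) {
    idx <- which(expr$gene_id == g)
    best <- idx[which.max(means[idx])]  # which.max keeps first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  out <- expr[keep, , drop = FALSE]
  attr(out, "labels") <- attr(expr, "labels")
  out
}

#' Read named gene sets from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with
#' fewer than three fields are an error; duplicate gene ids within a set
#' are dropped (set semantics); an empty file yields an empty list with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty gene-set file: ", path)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields",
                 which(n_fields < 3L)[1L]))
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                    vapply(fields, `[[`, character(1L), 1L))
  }
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  if (any(lengths(sets) == 0L))
    stop("gene set(s) with no genes: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets
}

#' Write / read a ranked gene list as TSV
#'
#' The on-disk form has columns `rank`, `gene_id`, `score`; rank 1 is the
#' most disease-relevant gene.
#'
#' @param ranked Ranked-list tibble with columns `rank`, `gene_id`, `score`.
#' @param path File path.
#' @return For the writer, `ranked` invisibly; for the reader, the tibble.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(all(c("rank", "gene_id", "score") %in% names(ranked)))
  readr::write_tsv(ranked[c("rank", "gene_id", "score")], path, progress = FALSE)
  invisible(ranked)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  rl <- readr::read_tsv(path, col_types = readr::cols(
    rank = "i", gene_id = "c", score = "d"), progress = FALSE)
  validate_ranked_list(rl)
}

# ranks 1-based consecutive, unique gene ids
validate_ranked_list <- function(rl) {
  if (anyDuplicated(rl$gene_id)) stop("duplicate gene ids in ranked list")
  if (nrow(rl) > 0L && !identical(as.integer(rl$rank), seq_len(nrow(rl))))
    stop("ranks must be 1-based and consecutive")
  tibble::as_tibble(rl)
}

new_ranked_list <- function(gene_id, score) {
  validate_ranked_list(tibble::tibble(
    rank = seq_along(gene_id), gene_id = as.character(gene_id),
    score = as.numeric(score)))
}
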