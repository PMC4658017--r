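#' Expression matrix with per-cell sample labels
#'
#' The central container of the pipeline: a genes x cells matrix of
#' non-negative abundance values (FPKM/TPM scale) together with a map
#' assigning every cell to the sample (batch/preparation) it came from.
#' Gene-level operations are row-wise; cell-level operations are column-wise.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene IDs),
#'   cells in columns (unique colnames = cell IDs); all entries finite and
#'   non-negative.
#' @param sample_of_cell named character vector mapping every cell ID to a
#'   sample label.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` and `samples` (the per-cell label vector, ordered as the matrix
#'   columns).
#' @export
expression_matrix <- function(values, sample_of_cell) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_fmt("`values` must be a numeric matrix")
  gid <- rownames(values); cid <- colnames(values)
  if (is.null(gid) || is.null(cid))
    stop_fmt("`values` must have gene rownames and cell colnames")
  if (anyDuplicated(gid)) stop_fmt("duplicate gene IDs")
  if (anyDuplicated(cid)) stop_fmt("duplicate cell IDs")
  if (anyNA(values) || any(!is.finite(values)))
    stop_fmt("expression values must be finite (missing values are not allowed)")
  if (any(values < 0)) stop_fmt("negative expression value encountered")
  if (is.null(names(sample_of_cell)))
    stop_fmt("`sample_of_cell` must be named by cell ID")
  missing <- setdiff(cid, names(sample_of_cell))
  if (length(missing) > 0)
    stop_fmt("cells missing from metadata: %s", paste(missing, collapse = ", "))
  samples <- as.character(sample_of_cell[cid])
  names(samples) <- cid
  structure(list(values = values, samples = samples), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells, %d sample(s) [%s]\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples)),
              paste(unique(x$samples), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

n_genes <- function(E) nrow(E$values)
n_cells <- function(E) ncol(E$values)

#' Cell IDs belonging to one sample
#' @param E an `ExpressionMatrix`.
#' @param sample a sample label.
#' @return character vector of cell IDs.
#' @export
cells_of_sample <- function(E, sample) {
  if (!sample %in% E$samples) stop_fmt("unknown sample '%s'", sample)
  names(E$samples)[E$samples == sample]
}

#' Sample labels present in an expression matrix
#' @param E an `ExpressionMatrix`.
#' @return character vector of unique sample labels in column order.
#' @export
sample_labels <- function(E) unique(unname(E$samples))

as_values_matrix <- function(E) {
  if (inherits(E, "ExpressionMatrix")) E$values
  else if (is.matrix(E)) E
  else stop_fmt("expected an ExpressionMatrix or a numeric matrix")
}

samples_of <- function(E, samples = NULL) {
  if (inherits(E, "ExpressionMatrix")) return(E$samples)
  s <- samples %||% attr(E, "sample_of_cell")
  if (is.null(s)) stop_fmt("per-cell sample labels required but not supplied")
  s[colnames(E)]
}

#' Read an expression matrix and its cell metadata from TSV
#'
#' The matrix file has a header row of cell IDs and a first column of gene
#' IDs; the metadata file has columns `cell_id` and `sample`. Cell order
#' follows the matrix header.
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the cell metadata TSV.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, metadata_path) {
  raw <- read_tsv(matrix_path)
  if (ncol(raw) < 2) stop_fmt("matrix TSV needs a gene column plus >=1 cell column")
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) stop_fmt("duplicate gene IDs in %s", matrix_path)
  cells <- colnames(raw)[-1]
  if (anyDuplicated(cells)) stop_fmt("duplicate cell IDs in %s", matrix_path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop_fmt("non-numeric expression values in %s", matrix_path)
  dimnames(vals) <- list(genes, cells)
  meta <- read_tsv(metadata_path)
  if (!all(c("cell_id", "sample") %in% colnames(meta)))
    stop_fmt("metadata must have columns cell_id and sample")
  missing <- setdiff(cells, meta$cell_id)
  if (length(missing) > 0)
    stop_fmt("cells absent from metadata: %s", paste(missing, collapse = ", "))
  extra <- setdiff(meta$cell_id, cells)
  if (length(extra) > 0)
    warn_fmt("metadata rows for cells not in the matrix are ignored: %s",
             paste(extra, collapse = ", "))
  so <- stats::setNames(as.character(meta$sample), meta$cell_id)
  expression_matrix(vals, so)
}

#' Write an expression matrix and its cell metadata as TSV
#' @param E an `ExpressionMatrix`.
#' @param matrix_path,metadata_path output paths.
#' @return the matrix path, invisibly.
#' @export
write_expression_matrix <- function(E, matrix_path, metadata_path) {
  df <- data.frame(gene_id = rownames(E$values), E$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(data.frame(cell_id = names(E$samples), sample = unname(E$samples)),
            metadata_path)
  invisible(matrix_path)
}

#' Floor all expression values at a minimal abundance
#'
#' Replaces every value below `floor` by `floor` (default 0.01 FPKM), so that
#' downstream log transforms and correlation-based similarity are defined.
#' Idempotent.
#'
#' @param E an `ExpressionMatrix`.
#' @param floor positive minimal expression value.
#' @return a floored `ExpressionMatrix`.
#' @export
apply_expression_floor <- function(E, floor = 0.01) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    stop_fmt("`floor` must be a single positive number")
  E$values[E$values < floor] <- floor
  E
}

#' Gene set collection
#' @param sets named list of character vectors (set name -> gene IDs).
#' @param universe optional character vector of gene IDs containing every set.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0 || is.null(names(sets)))
    stop_fmt("`sets` must be a non-empty named list")
  if (any(lengths(sets) == 0)) stop_fmt("empty gene set")
  sets <- lapply(sets, unique)
  if (!is.null(universe)) {
    out <- setdiff(unique(unlist(sets)), universe)
    if (length(out) > 0)
      stop_fmt("set genes outside the universe: %s", paste(out, collapse = ", "))
  }
  structure(list(sets = sets, universe = universe), class = "GeneSetCollection")
}

#' Read gene sets from GMT or from a gene/cell-type association table
#'
#' In `association_table` format (TSV with columns gene, cell_type,
#' support_pvalue, direction), a gene joins a cell type's set only if it has
#' at least one positive association with `support_pvalue < pvalue_max` and,
#' when `require_no_negative` is set, no negative association for that cell
#' type. Empty resulting sets are dropped.
#'
#' @param path input file.
#' @param format `"gmt"` or `"association_table"`.
#' @param pvalue_max significance threshold on the experimental support
#'   p-value (default 0.05).
#' @param require_no_negative drop genes with any negative evidence for the
#'   cell type (default TRUE).
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path, format = c("gmt", "association_table"),
                           pvalue_max = 0.05, require_no_negative = TRUE) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad) > 0) stop_fmt("malformed GMT line %d", bad[1])
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1), 1)
    return(gene_set_collection(sets))
  }
  tab <- read_tsv(path)
  need <- c("gene", "cell_type", "support_pvalue", "direction")
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0)
    stop_fmt("association table missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(tab$direction %in% c("positive", "negative")))
    stop_fmt("direction must be 'positive' or 'negative'")
  sets <- lapply(split(tab, tab$cell_type), function(d) {
    pos <- unique(d$gene[d$direction == "positive" & d$support_pvalue < pvalue_max])
    if (require_no_negative) {
      neg <- unique(d$gene[d$direction == "negative"])
      pos <- setdiff(pos, neg)
    }
    pos
  })
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stop_fmt("no gene set survives the evidence filters")
  gene_set_collection(sets)
}

#' Marker panel
#' @param markers named list (cell type -> ordered character vector of marker
#'   gene IDs); lists non-empty, no duplicates within a cell type.
#' @return object of class `MarkerPanel`.
#' @export
marker_panel <- function(markers) {
  if (length(markers) == 0 || is.null(names(markers)))
    stop_fmt("`markers` must be a non-empty named list")
  if (any(lengths(markers) == 0)) stop_fmt("empty marker list")
  dup <- vapply(markers, anyDuplicated, integer(1))
  if (any(dup > 0))
    stop_fmt("duplicate markers within cell type '%s'", names(markers)[dup > 0][1])
  structure(list(markers = markers), class = "MarkerPanel")
}

#' Read a marker panel from a TSV with columns cell_type, gene
#' @param path input file.
#' @return a [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("cell_type", "gene") %in% colnames(tab)))
    stop_fmt("marker table must have columns cell_type and gene")
  marker_panel(lapply(split(tab$gene, tab$cell_type), as.character))
}

#' Read a transcription-factor catalog (one gene ID per line, optional
#' `gene` header)
#' @param path input file.
#' @return character vector of gene IDs.
#' @export
read_tf_catalog <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (length(x) > 0 && tolower(x[1]) == "gene") x <- x[-1]
  if (length(x) == 0) stop_fmt("empty TF catalog")
  unique(x)
}
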