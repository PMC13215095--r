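#' Construct a two-class expression set
#'
#' An `expr_set` bundles a genes x samples numeric matrix with a two-level
#' sample classification (one level designated the "case" class, the other
#' the "control"). It is the input container for every selection and
#' balance-auditing function in the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless `gene_ids`
#'   / `sample_ids` are supplied.
#' @param classes Named character vector (or factor) mapping every sample id
#'   to one of exactly two class labels.
#' @param case_label Which of the two labels is the case (e.g. tumor) class.
#'   Defaults to `"case"` when that label is present, otherwise to the first
#'   label in order of appearance (a message records the choice).
#' @param gene_ids,sample_ids Optional explicit identifiers overriding
#'   dimnames.
#' @param scale_tag Free-text tag recording the scale of the values
#'   (e.g. `"log2-normalized"`, `"counts"`); stored as metadata only.
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (named numeric matrix), `classes` (named character), `case`, `control`
#'   and `scale_tag`.
#'
#' @details Validation is strict: gene and sample ids must be unique and
#'   non-empty, all values finite, every sample classified, exactly two
#'   classes each with at least two samples. Duplicate gene ids are an
#'   error, never merged.
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cls <- setNames(c("case", "case", "control", "control"), colnames(m))
#' es <- expression_set(m, cls)
#' es
#' @export
expression_set <- function(values, classes, case_label = NULL,
                           gene_ids = NULL, sample_ids = NULL,
                           scale_tag = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- gene_ids %||% rownames(values)
  sample_ids <- sample_ids %||% colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("gene and sample identifiers are required (dimnames or arguments)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort("identifier lengths must match matrix dimensions")
  }
  if (any(gene_ids == "") || any(sample_ids == "")) {
    abort("empty gene or sample identifier")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    abort(paste0("duplicate gene id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample id(s)")
  }
  if (!all(is.finite(values))) {
    abort("expression values must be finite (no NA/NaN/Inf)")
  }
  classes <- stats::setNames(as.character(classes), names(classes))
  if (is.null(names(classes))) abort("`classes` must be named by sample id")
  missing <- setdiff(sample_ids, names(classes))
  if (length(missing)) {
    abort(paste0("sample(s) missing from class map: ",
                 paste(missing, collapse = ", ")))
  }
  classes <- classes[sample_ids]
  labels <- unique(classes)
  if (length(labels) != 2L) {
    abort(paste0("expected exactly two classes, found ", length(labels), ": ",
                 paste(labels, collapse = ", ")))
  }
  if (is.null(case_label)) {
    case_label <- if ("case" %in% labels) "case" else {
      inform(paste0("designating '", labels[1], "' as the case class"))
      labels[1]
    }
  }
  if (!case_label %in% labels) {
    abort(paste0("case_label '", case_label, "' not among class labels"))
  }
  control_label <- setdiff(labels, case_label)
  counts <- table(classes)
  if (any(counts < 2L)) abort("each class needs at least 2 samples")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, classes = classes,
         case = case_label, control = control_label,
         scale_tag = scale_tag),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat("<expr_set> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  case ('", x$case, "'): ", sum(x$classes == x$case),
      "  control ('", x$control, "'): ", sum(x$classes == x$control),
      "\n", sep = "")
  cat("  scale: ", x$scale_tag, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Gene and sample accessors for expression sets
#' @param x An `expr_set`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# Case / control column index helpers (internal).
case_cols <- function(x) which(x$classes == x$case)
control_cols <- function(x) which(x$classes == x$control)

#' Subset an expression set to a gene universe
#'
#' @param x An `expr_set`.
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return A new `expr_set`.
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing)) {
    abort(paste0("gene(s) not in matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  expression_set(x$values[genes, , drop = FALSE], x$classes,
                 case_label = x$case, scale_tag = x$scale_tag)
}

#' Swap case and control designation
#'
#' Relabels the classes of an expression set, exchanging case and control.
#' Useful for symmetry checks: oriented AUCs and mvAUC are invariant under
#' the swap, while every log fold change is negated.
#'
#' @param x An `expr_set`.
#' @return An `expr_set` with the case/control roles exchanged.
#' @export
swap_classes <- function(x) {
  expression_set(x$values, x$classes, case_label = x$control,
                 scale_tag = x$scale_tag)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) abort(paste0("empty file: ", path))
  has_tab <- grepl("\t", first, fixed = TRUE)
  has_comma <- grepl(",", first, fixed = TRUE)
  if (has_tab && has_comma) {
    abort(paste0("ambiguous delimiter (both tab and comma) in ", path))
  }
  if (has_tab) "\t" else if (has_comma) "," else {
    abort(paste0("cannot detect delimiter (expected tab or comma) in ", path))
  }
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a two-class expression matrix from disk
#'
#' Reads a tab- or comma-delimited genes x samples matrix (first column gene
#' ids, header row sample ids) together with a two-column class map
#' (sample id, label), and validates the pair into an [expression_set()].
#'
#' @param path Path to the expression matrix (TSV or CSV; delimiter
#'   auto-detected, ambiguous files are rejected).
#' @param class_map_path Path to the delimited two-column class map.
#' @param case_label,scale_tag Passed to [expression_set()].
#' @return An `expr_set`.
#' @export
read_expression <- function(path, class_map_path, case_label = NULL,
                            scale_tag = "unspecified") {
  delim <- detect_delim(path)
  tab <- read_delim_quiet(path, delim)
  if (ncol(tab) < 2L) abort("expression table needs a gene column and samples")
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric cell in expression matrix")
  storage.mode(vals) <- "double"
  rownames(vals) <- genes

  cdelim <- detect_delim(class_map_path)
  cmap <- read_delim_quiet(class_map_path, cdelim)
  if (ncol(cmap) < 2L) abort("class map needs two columns: sample id, label")
  classes <- stats::setNames(as.character(cmap[[2]]), as.character(cmap[[1]]))
  expression_set(vals, classes, case_label = case_label,
                 scale_tag = scale_tag)
}

#' Write an expression set to disk
#'
#' Writes the matrix as TSV (column `gene_id` first) plus a two-column
#' class-map TSV. Round-trips through [read_expression()].
#'
#' @param x An `expr_set`.
#' @param path Output path for the matrix TSV.
#' @param class_map_path Output path for the class map TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, class_map_path) {
  tab <- tibble::as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  cmap <- tibble(sample_id = sample_ids(x),
                 label = unname(x$classes[sample_ids(x)]))
  readr::write_tsv(cmap, class_map_path, progress = FALSE)
  invisible(x)
}

#' Convert an expression set to a long tibble
#'
#' @param x An `expr_set`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `class`, `value`.
#' @method tidy expr_set
#' @export
tidy.expr_set <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    mutate(class = unname(x$classes[.data$sample_id]),
           .before = "value")
}

#' @method glance expr_set
#' @export
glance.expr_set <- function(x, ...) {
  tibble(n_genes = nrow(x$values), n_samples = ncol(x$values),
         n_case = sum(x$classes == x$case),
         n_control = sum(x$classes == x$control),
         case = x$case, control = x$control, scale_tag = x$scale_tag)
}
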