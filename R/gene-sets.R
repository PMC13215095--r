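#' Gene set collections
#'
#' A gene set collection is stored as a tibble with one row per set:
#' columns `set_name` (unique), `description` (free text, preserved
#' verbatim) and `members` (list-column of deduplicated gene-id vectors).
#' The collection label (e.g. `"hallmark"`, `"kegg"`) lives in the
#' `collection_label` attribute.
#'
#' @param set_names Character vector of unique set names.
#' @param members List of character vectors of member gene ids; duplicates
#'   within a set are dropped with first-occurrence order preserved.
#' @param descriptions Character vector of descriptions (recycled `""`).
#' @param collection_label Label attached to the whole collection.
#' @return A `gene_sets` tibble.
#' @export
gene_set_collection <- function(set_names, members, descriptions = "",
                                collection_label = "custom") {
  set_names <- as.character(set_names)
  if (anyDuplicated(set_names)) {
    abort(paste0("duplicate set name(s): ",
                 paste(unique(set_names[duplicated(set_names)]),
                       collapse = ", ")))
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) < 1L) && length(members)) {
    abort("every gene set needs at least one member")
  }
  out <- tibble(set_name = set_names,
                description = rep_len(as.character(descriptions),
                                      length(set_names)),
                members = members)
  attr(out, "collection_label") <- collection_label
  class(out) <- c("gene_sets", class(out))
  out
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("<gene_sets> '", attr(x, "collection_label"), "', ", nrow(x),
      " sets\n", sep = "")
  NextMethod()
}

#' Read a GMT gene set file
#'
#' Standard Broad/MSigDB GMT dialect: one set per line, tab-separated
#' fields `name`, `description`, then member gene ids. Members are
#' deduplicated with order preserved; lines with fewer than three fields
#' and duplicate set names are rejected.
#'
#' @param path Path to a GMT file.
#' @param collection_label Label to attach (default: file name sans
#'   extension).
#' @return A `gene_sets` collection.
#' @export
read_gmt <- function(path, collection_label = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  }
  label <- collection_label %||%
    sub("\\.[^.]*$", "", basename(path))
  gene_set_collection(
    set_names = vapply(fields, `[[`, character(1), 1L),
    descriptions = vapply(fields, `[[`, character(1), 2L),
    members = lapply(fields, function(f) f[-(1:2)]),
    collection_label = label
  )
}

#' Write a gene set collection as GMT
#'
#' @param x A `gene_sets` collection.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_gmt <- function(x, path) {
  lines <- purrr::pmap_chr(
    list(x$set_name, x$description, x$members),
    function(n, d, m) paste(c(n, d, m), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(x)
}

#' Extract the member lists of a collection as a named list
#'
#' @param x A `gene_sets` collection.
#' @return Named list of character vectors.
#' @export
as_gene_list <- function(x) stats::setNames(x$members, x$set_name)
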