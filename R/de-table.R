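#' Read an externally produced differential-expression result table
#'
#' Adapter for result tables exported by other DE tools. A column mapping
#' names the source columns to interpret as gene id, log fold change,
#' p-value and adjusted p-value; the result is a harmonized tibble tagged
#' with the producing method.
#'
#' @param path Delimited table (TSV or CSV, auto-detected).
#' @param method_label Name of the method that produced the table.
#' @param mapping Named list/character with entries `gene`, `logfc`,
#'   `pvalue`, `padj` giving the source column names. Defaults to common
#'   names (`gene`, `log2FoldChange`, `pvalue`, `padj`).
#' @return A `de_table` tibble with columns `gene_id`, `logfc`, `pvalue`,
#'   `padj`, `direction` and attribute `method_label`.
#' @export
read_de_table <- function(path, method_label,
                          mapping = list(gene = "gene",
                                         logfc = "log2FoldChange",
                                         pvalue = "pvalue",
                                         padj = "padj")) {
  delim <- detect_delim(path)
  tab <- read_delim_quiet(path, delim)
  if (!nrow(tab)) abort("no rows in DE table")
  req <- c("gene", "logfc", "pvalue", "padj")
  missing_keys <- setdiff(req, names(mapping))
  if (length(missing_keys)) {
    abort(paste0("mapping lacks entries: ", paste(missing_keys, collapse = ", ")))
  }
  cols <- unlist(mapping[req])
  absent <- setdiff(cols, names(tab))
  if (length(absent)) {
    abort(paste0("unmappable column(s): ", paste(absent, collapse = ", ")))
  }
  out <- tibble(
    gene_id = as.character(tab[[cols[["gene"]]]]),
    logfc = as.numeric(tab[[cols[["logfc"]]]]),
    pvalue = as.numeric(tab[[cols[["pvalue"]]]]),
    padj = as.numeric(tab[[cols[["padj"]]]])
  )
  as_de_table(out, method_label)
}

# Validate and classify a DE tibble; shared by the adapter and wrst_de().
as_de_table <- function(out, method_label) {
  if (anyDuplicated(out$gene_id)) {
    abort(paste0("duplicate gene id(s) in DE table: ",
                 paste(unique(out$gene_id[duplicated(out$gene_id)])[1:1],
                       collapse = ", ")))
  }
  if (any(!is.finite(out$pvalue)) || any(out$pvalue < 0 | out$pvalue > 1)) {
    abort("p-value outside [0, 1]")
  }
  if (any(!is.finite(out$padj)) || any(out$padj < 0 | out$padj > 1)) {
    abort("adjusted p-value outside [0, 1]")
  }
  if (any(!is.finite(out$logfc))) abort("non-finite logFC")
  out <- mutate(out, direction = dplyr::case_when(
    .data$logfc > 0 ~ "up",
    .data$logfc < 0 ~ "down",
    TRUE ~ "flat"
  ))
  attr(out, "method_label") <- method_label
  class(out) <- c("de_table", class(out))
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("<de_table> method '", attr(x, "method_label"), "'\n", sep = "")
  NextMethod()
}
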