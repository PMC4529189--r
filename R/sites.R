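#' Parse and render phosphosite identifiers
#'
#' A phosphosite is identified by its host protein's official gene symbol and
#' the phosphorylated residue, e.g. serine 136 of BAD. The rendered identifier
#' concatenates the two with a separator: `"BAD;S136"`. This convention keys
#' rows of quantitative matrices and members of kinase-substrate sets so the
#' two can be intersected.
#'
#' @param x character vector of rendered identifiers.
#' @param gene character vector of gene symbols.
#' @param residue character vector like `"S136"`: one-letter amino acid
#'   (S, T or Y) followed by the 1-based sequence position.
#' @param separator single string separating gene and residue. Default `";"`.
#'
#' @return `parse_site_id()` returns a data.frame with columns `gene`,
#'   `residue`, `aa` (the residue letter) and `position`. `render_site_id()`
#'   returns a character vector. `render_site_id(parse_site_id(x)) == x`.
#'
#' @examples
#' parse_site_id("BAD;S136")
#' render_site_id("AKT1S1", "T246")
#' @export
parse_site_id <- function(x, separator = ";") {
  if (!is.character(x)) .stopf("site identifiers must be character")
  pos <- regexpr(separator, x, fixed = TRUE)
  if (any(pos < 0)) {
    .stopf("malformed site identifier(s): %s",
           paste(utils::head(x[pos < 0], 5L), collapse = ", "))
  }
  gene <- substr(x, 1L, pos - 1L)
  residue <- substr(x, pos + nchar(separator), nchar(x))
  ok <- grepl("^[STY][0-9]+$", residue) & nzchar(gene)
  if (!all(ok)) {
    .stopf("invalid residue in site identifier(s): %s",
           paste(utils::head(x[!ok], 5L), collapse = ", "))
  }
  data.frame(gene = gene,
             residue = residue,
             aa = substr(residue, 1L, 1L),
             position = as.integer(sub("^[STY]", "", residue)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_site_id
#' @export
render_site_id <- function(gene, residue, separator = ";") {
  ok <- grepl("^[STY][0-9]+$", residue)
  if (!all(ok)) {
    .stopf("invalid residue(s): %s",
           paste(utils::head(residue[!ok], 5L), collapse = ", "))
  }
  paste0(gene, separator, residue)
}
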