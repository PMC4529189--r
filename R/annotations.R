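#' Kinase-substrate annotation databases
#'
#' An annotation database maps each kinase to the set of phosphosite
#' identifiers it is known to phosphorylate. A site may appear under several
#' kinases; during enrichment analysis it then counts once for each of them.
#' Internally the database is a named list of character vectors with class
#' `"annotation_db"` plus a `species` attribute.
#'
#' @param x named list of character vectors (kinase -> site IDs).
#' @param species species label (free text, e.g. `"human"`).
#'
#' @return An object of class `"annotation_db"`.
#' @seealso [read_phosphositeplus()], [read_gmt()], [restrict_to_dataset()]
#' @export
annotation_db <- function(x, species = NA_character_) {
  if (!is.list(x) || (length(x) > 0L && is.null(names(x)))) {
    .stopf("annotation database must be a named list of character vectors")
  }
  x <- lapply(x, function(s) sort(unique(as.character(s))))
  if (any(lengths(x) == 0L)) {
    x <- x[lengths(x) > 0L]
  }
  structure(x, class = "annotation_db", species = species)
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("Kinase-substrate annotation DB: %d kinases, %d interactions",
              length(x), sum(lengths(x))))
  sp <- attr(x, "species")
  if (!is.na(sp)) cat(sprintf(" [%s]", sp))
  cat("\n")
  if (length(x)) {
    sizes <- lengths(x)
    cat(sprintf("  substrates per kinase: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' @export
`[.annotation_db` <- function(x, i) {
  annotation_db(unclass(x)[i], species = attr(x, "species"))
}

#' Read a PhosphoSitePlus-style kinase-substrate table
#'
#' Parses a tab-separated kinase-substrate table with `KINASE`, `SUBSTRATE`
#' and `SUB_ORG` header columns plus a residue column (named `SUB_MOD_RSD` in
#' current releases). Leading banner lines before the header are skipped.
#' Rows are filtered to the requested substrate organism; substrate site
#' identifiers are built as gene symbol + separator + residue, and duplicate
#' kinase-site interactions collapse to one.
#'
#' @param path path to the tab-separated table.
#' @param species substrate organism; rows whose `SUB_ORG` differs are
#'   dropped.
#' @param separator separator for rendered site identifiers. Default `";"`.
#' @param residue_column name of the column holding the phosphorylated
#'   residue. Default `"SUB_MOD_RSD"`.
#' @param uppercase_genes upper-case gene symbols (the human convention).
#'   Defaults to `TRUE` when `species` is `"human"` (case-insensitive),
#'   `FALSE` otherwise, and can be forced either way.
#'
#' @return An [annotation_db()]. Empty after the species filter -> a warning
#'   is raised and an empty database returned.
#' @export
read_phosphositeplus <- function(path, species, separator = ";",
                                 residue_column = "SUB_MOD_RSD",
                                 uppercase_genes = NULL) {
  if (!nzchar(species)) .stopf("species must be non-empty")
  lines <- readLines(path, warn = FALSE)
  is_header <- vapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    all(c("KINASE", "SUBSTRATE", "SUB_ORG") %in% f)
  }, logical(1), USE.NAMES = FALSE)
  if (!any(is_header)) {
    # no banner-skipping rescue possible: report what is missing
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    missing <- setdiff(c("KINASE", "SUBSTRATE", "SUB_ORG"), f)
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  skip <- which(is_header)[1] - 1L
  tab <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!residue_column %in% names(tab)) {
    .stopf("missing required column(s): %s", residue_column)
  }
  tab <- tab[tab$SUB_ORG == species, , drop = FALSE]
  if (nrow(tab) == 0L) {
    .warnf("no interactions left after filtering to species '%s'", species)
    return(annotation_db(list(), species = species))
  }
  if (is.null(uppercase_genes)) {
    uppercase_genes <- tolower(species) == "human"
  }
  gene <- as.character(tab$SUBSTRATE)
  if (uppercase_genes) gene <- toupper(gene)
  ids <- render_site_id(gene, as.character(tab[[residue_column]]), separator)
  annotation_db(split(ids, as.character(tab$KINASE)), species = species)
}

#' Read and write GMT kinase-set files
#'
#' GMT is the plain-text gene-set interchange format: one set per line with
#' tab-separated fields set name, description, then member identifiers. Here
#' each set is a kinase and the members are phosphosite identifiers.
#'
#' @param path file path.
#' @param db an [annotation_db()].
#' @param species species label to attach to the parsed database.
#'
#' @return `read_gmt()` returns an [annotation_db()] (empty file -> empty
#'   database with a warning). `write_gmt()` writes members sorted so that
#'   write-read-write round-trips byte-identically, and returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path, species = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    .warnf("empty GMT file: %s", path)
    return(annotation_db(list(), species = species))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    .stopf("GMT line %d has fewer than 3 tab-separated fields", short[1])
  }
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  annotation_db(sets, species = species)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], "na", sort(db[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict an annotation database to the sites of a dataset
#'
#' Enrichment statistics are computed over the sites actually quantified in a
#' dataset, so each kinase's substrate set is intersected with those sites
#' first. Kinases retaining fewer than `min_substrates` in-dataset sites are
#' dropped: a kinase with a single in-dataset substrate cannot drive
#' enrichment but would still compete in the per-cluster minimum p-value.
#'
#' @param db an [annotation_db()].
#' @param sites character vector of site identifiers present in the dataset.
#' @param min_substrates minimum surviving substrate count for a kinase to be
#'   kept (>= 1). Default 2.
#'
#' @return An [annotation_db()]; idempotent, never adds sites or kinases.
#' @export
restrict_to_dataset <- function(db, sites, min_substrates = 2L) {
  stopifnot(inherits(db, "annotation_db"))
  if (min_substrates < 1L) .stopf("min_substrates must be >= 1")
  kept <- lapply(db, function(s) s[s %in% sites])
  kept <- kept[lengths(kept) >= min_substrates]
  annotation_db(kept, species = attr(db, "species"))
}
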