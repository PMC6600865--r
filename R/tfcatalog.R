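#' @import methods
#' @importFrom data.table fread fwrite as.data.table
NULL

#' TFCatalog: a harmonized transcription-factor catalog
#'
#' A `TFCatalog` couples the native identifiers of a TF resource (motif-model
#' ids, model names, gene symbols, ...) with a rectangular metadata table that
#' carries one row per native identifier and an obligatory `HGNC` column
#' holding the gene symbol used as the cross-catalog key.  Native identifiers
#' may repeat (several motif models can describe one gene) and several native
#' identifiers may map to one HGNC symbol.
#'
#' @slot name single non-empty string labelling the catalog.
#' @slot native_ids character vector of catalog-native identifiers, one per
#'   record; duplicates permitted.
#' @slot hgnc_map data.frame with `length(native_ids)` rows and a column named
#'   exactly `HGNC`; any further columns are source-specific metadata carried
#'   opaquely.
#' @exportClass TFCatalog
setClass("TFCatalog", representation(
  name = "character",
  native_ids = "character",
  hgnc_map = "data.frame"
))

setValidity("TFCatalog", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@native_ids) != nrow(object@hgnc_map))
    msg <- c(msg, sprintf("length(native_ids) [%d] != nrow(hgnc_map) [%d]",
                          length(object@native_ids), nrow(object@hgnc_map)))
  if (!("HGNC" %in% colnames(object@hgnc_map)))
    msg <- c(msg, "hgnc_map must contain a column named exactly 'HGNC'")
  if (length(msg)) msg else TRUE
})

#' Construct a TFCatalog
#'
#' @param name catalog label (single non-empty string).
#' @param native_ids character vector of native identifiers, one per record.
#' @param hgnc_map data.frame with one row per native id and an `HGNC` column.
#' @return a [TFCatalog-class] object.
#' @examples
#' tab <- data.frame(id = c("T1", "T2"), HGNC = c("TFAP2B", "TP53"))
#' TFCatalog("demo", tab$id, tab)
#' @export
TFCatalog <- function(name, native_ids, hgnc_map) {
  hgnc_map <- as.data.frame(hgnc_map, stringsAsFactors = FALSE)
  new("TFCatalog", name = as.character(name),
      native_ids = as.character(native_ids), hgnc_map = hgnc_map)
}

#' @describeIn TFCatalog-class number of records (native identifiers)
#' @param x a TFCatalog
#' @export
setMethod("length", "TFCatalog", function(x) length(x@native_ids))

setMethod("show", "TFCatalog", function(object) {
  ids <- object@native_ids
  uni <- hgnc_universe(object)
  cat("TFCatalog instance", object@name, "\n")
  cat(" ", length(ids), "native ids", if (length(ids))
    paste0("(", ids[1L], " ... ", ids[length(ids)], ")") else "", "\n")
  cat(" ", length(uni), "unique HGNC symbols\n")
  invisible(object)
})

#' Catalog accessors
#'
#' `catalog_name()`, `native_ids()` and `hgnc_map()` extract the three
#' components of a [TFCatalog-class].
#' @param x a TFCatalog
#' @return the corresponding slot.
#' @export
catalog_name <- function(x) x@name

#' @rdname catalog_name
#' @export
native_ids <- function(x) x@native_ids

#' @rdname catalog_name
#' @export
hgnc_map <- function(x) x@hgnc_map

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           encoding = "UTF-8", quote = "")
  tab
}

.apply_rename <- function(tab, rename) {
  if (length(rename)) {
    for (i in seq_along(rename)) {
      hit <- match(rename[[i]], colnames(tab))
      if (!is.na(hit)) colnames(tab)[hit] <- names(rename)[i]
    }
  }
  tab
}

.require_cols <- function(tab, cols, path) {
  miss <- setdiff(cols, colnames(tab))
  if (length(miss))
    stop("schema error in ", path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(tab)
}

#' Load a CISBP-schema TF catalog snapshot
#'
#' Reads a tab-separated CISBP-style snapshot (>= 28 columns in the wild; only
#' three are interpreted).  The first column supplies the native motif-model
#' identifiers, `TF_Name` supplies the HGNC symbols, and `Family_Name` must be
#' present for downstream family annotation.  All columns are carried through
#' into the catalog's metadata table; an `HGNC` column is added from
#' `TF_Name`.  Row order is preserved.
#'
#' @param path TSV file with a header row.
#' @param rename optional named character vector mapping canonical column
#'   names (names) to the spellings used in the file (values), for snapshots
#'   whose headers deviate.
#' @param name catalog label.
#' @return a [TFCatalog-class].
#' @export
load_cisbp_catalog <- function(path, rename = character(0), name = "CISBP") {
  tab <- .apply_rename(.read_tsv(path), rename)
  if (nrow(tab) == 0L)
    stop("empty catalog: ", path, " has a header but no data rows",
         call. = FALSE)
  .require_cols(tab, c("TF_Name", "Family_Name"), path)
  tab$HGNC <- tab$TF_Name
  TFCatalog(name, tab[[1L]], tab)
}

#' Load a HOCOMOCO-schema TF catalog snapshot
#'
#' Reads a tab-separated HOCOMOCO-style snapshot (nine columns).  The `Model`
#' column supplies native model names, the `Transcription factor` column
#' supplies HGNC symbols, and the `TF class` column (retained verbatim,
#' including any TFClass subfamily suffix such as `{2.3.3}`) must be present.
#'
#' @inheritParams load_cisbp_catalog
#' @return a [TFCatalog-class].
#' @export
load_hocomoco_catalog <- function(path, rename = character(0),
                                  name = "HOCOMOCO") {
  tab <- .apply_rename(.read_tsv(path), rename)
  if (nrow(tab) == 0L)
    stop("empty catalog: ", path, " has a header but no data rows",
         call. = FALSE)
  .require_cols(tab, c("Model", "Transcription factor", "TF class"), path)
  tab$HGNC <- tab[["Transcription factor"]]
  TFCatalog(name, tab[["Model"]], tab)
}

#' Build a TF catalog from direct GO annotations
#'
#' Filters a two-column gene-symbol/GO-id annotation table to the symbols
#' directly annotated to `go_id` (no ontology-ancestor propagation) and
#' returns them as a catalog whose native ids are the symbols themselves.
#' The default term GO:0003700 is "DNA binding transcription factor
#' activity".
#'
#' @param annotation_table data.frame (or TSV path) with columns `SYMBOL` and
#'   `GO` (order-insensitive; first two columns used when names differ).
#' @param go_id GO term id to filter on.
#' @param name catalog label.
#' @return a [TFCatalog-class]; empty, with a warning, when `go_id` is absent.
#' @export
load_go_catalog <- function(annotation_table, go_id = "GO:0003700",
                            name = "GO") {
  if (is.character(annotation_table) && length(annotation_table) == 1L)
    annotation_table <- .read_tsv(annotation_table)
  tab <- as.data.frame(annotation_table, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("annotation table needs a symbol column and a GO-id column",
         call. = FALSE)
  sym_col <- if ("SYMBOL" %in% colnames(tab)) "SYMBOL" else colnames(tab)[1L]
  go_col <- if ("GO" %in% colnames(tab)) "GO" else colnames(tab)[2L]
  keep <- !is.na(tab[[go_col]]) & tab[[go_col]] == go_id
  syms <- tab[[sym_col]][keep]
  if (!length(syms))
    warning("GO id ", go_id, " not present in annotation table; ",
            "returning an empty catalog", call. = FALSE)
  TFCatalog(name, syms,
            data.frame(HGNC = as.character(syms), GO = rep(go_id, length(syms)),
                       stringsAsFactors = FALSE))
}

#' HGNC universe of a catalog
#'
#' The deduplicated set of non-missing, non-blank HGNC symbols in a catalog.
#' Symbols are compared case-sensitively after stripping surrounding
#' whitespace.  The number of missing/blank entries excluded is attached as
#' attribute `n_blank`.
#'
#' @param catalog a [TFCatalog-class].
#' @return character vector of unique symbols (order of first appearance),
#'   with attribute `n_blank`.
#' @export
hgnc_universe <- function(catalog) {
  stopifnot(is(catalog, "TFCatalog"))
  h <- trimws(catalog@hgnc_map$HGNC)
  bad <- is.na(h) | !nzchar(h)
  out <- unique(h[!bad])
  attr(out, "n_blank") <- sum(bad)
  out
}

#' Membership-signature overlap counts across catalogs
#'
#' For a list of catalogs, computes for every HGNC symbol in the union of
#' their universes which catalogs contain it, and tabulates the number of
#' symbols per membership signature.  Signatures are the member catalog names
#' sorted alphabetically and joined with `"&"`, which makes the result
#' invariant to the order the catalogs are supplied in.  Only non-empty
#' signatures appear; counts sum to the size of the union.
#'
#' @param catalogs list of two or more [TFCatalog-class] objects with
#'   distinct names.
#' @return data.frame with columns `region` (signature), `count`, and
#'   `n_catalogs` (signature cardinality), sorted by descending count then
#'   signature.
#' @export
overlap_counts <- function(catalogs) {
  stopifnot(is.list(catalogs), length(catalogs) >= 2L)
  nms <- vapply(catalogs, catalog_name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate catalog names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  universes <- lapply(catalogs, hgnc_universe)
  all_syms <- unique(unlist(universes, use.names = FALSE))
  member <- vapply(universes, function(u) all_syms %in% u,
                   logical(length(all_syms)))
  if (length(all_syms) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(sort(nms[row]), collapse = "&"))
  tab <- table(sig)
  out <- data.frame(region = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$n_catalogs <- lengths(strsplit(out$region, "&", fixed = TRUE))
  out <- out[order(-out$count, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class frequency table for a catalog
#'
#' Counts the number of distinct TFs (values of `tf_column`) annotated to each
#' value of `class_column`, so a TF represented by several records in one
#' class is counted once.  Rows are sorted by descending count; ties are
#' broken by class string ascending.
#'
#' @param catalog a [TFCatalog-class].
#' @param class_column name of the class column in `hgnc_map(catalog)`.
#' @param tf_column name of the TF-identifier column counted distinctly.
#' @return data.frame with columns `class` and `n_tfs`.
#' @export
class_frequency <- function(catalog, class_column, tf_column = "HGNC") {
  tab <- hgnc_map(catalog)
  miss <- setdiff(c(class_column, tf_column), colnames(tab))
  if (length(miss))
    stop("schema error: catalog '", catalog_name(catalog),
         "' lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  cls <- tab[[class_column]]
  tf <- tab[[tf_column]]
  keep <- !is.na(cls) & nzchar(cls) & !is.na(tf) & nzchar(tf)
  pairs <- unique(data.frame(class = cls[keep], tf = tf[keep],
                             stringsAsFactors = FALSE))
  agg <- stats::aggregate(tf ~ class, data = pairs, FUN = length)
  names(agg)[2L] <- "n_tfs"
  agg <- agg[order(-agg$n_tfs, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Parse a TFClass-suffixed class label
#'
#' HOCOMOCO class strings append the dotted TFClass subfamily id in braces,
#' e.g. `"More than 3 adjacent zinc finger factors{2.3.3}"`.  This splits the
#' trailing `{...}` suffix off when it holds one to three dot-separated
#' non-negative integers; otherwise the whole string is kept as the label
#' (with `malformed = TRUE` when braces are present but not well-formed).
#'
#' @param raw non-empty class string.
#' @return list with elements `raw`, `label`, `subfamily_id` (`NA` when
#'   absent) and `malformed` (logical).
#' @examples
#' parse_tfclass_label("HOX-related factors{3.1.1}")$subfamily_id
#' @export
parse_tfclass_label <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  m <- regmatches(raw, regexec("^(.*)\\{([0-9]+(\\.[0-9]+){0,2})\\}$", raw))[[1]]
  if (length(m)) {
    return(list(raw = raw, label = sub("[ \t]+$", "", m[2L]),
                subfamily_id = m[3L], malformed = FALSE))
  }
  malformed <- grepl("[{}]", raw)
  if (malformed)
    warning("malformed TFClass suffix in label: ", raw, call. = FALSE)
  list(raw = raw, label = raw, subfamily_id = NA_character_,
       malformed = malformed)
}
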