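#' Read a GWAS-catalog-style table
#'
#' Expects a TSV with the five fields EBI-style exports print —
#' `DISEASE.TRAIT` (or `DISEASE_TRAIT`), `MAPPED_GENE`, `SNPS`, `CHR_ID`,
#' `CHR_POS` — plus any number of extra columns, which are carried through
#' untouched.  The trait column is canonicalised to `DISEASE.TRAIT`.
#'
#' @param table data.frame or TSV path.
#' @return data.frame of class `GwasCatalog`.
#' @export
gwas_catalog <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- data.table::fread(table, sep = "\t", header = TRUE,
                               data.table = FALSE, colClasses = "character",
                               quote = "")
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  hit <- match("DISEASE_TRAIT", colnames(tab))
  if (!is.na(hit)) colnames(tab)[hit] <- "DISEASE.TRAIT"
  req <- c("DISEASE.TRAIT", "MAPPED_GENE", "SNPS", "CHR_ID", "CHR_POS")
  miss <- setdiff(req, colnames(tab))
  if (length(miss))
    stop("GWAS table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pos <- suppressWarnings(as.numeric(tab$CHR_POS))
  bad <- !is.na(tab$CHR_POS) & nzchar(tab$CHR_POS) & (is.na(pos) | pos < 0)
  if (any(bad))
    stop("CHR_POS not parseable as a non-negative integer in ",
         sum(bad), " record(s)", call. = FALSE)
  class(tab) <- c("GwasCatalog", "data.frame")
  tab
}

#' Split a multi-gene MAPPED_GENE field
#'
#' GWAS-catalog exports pack several symbols into one field using the
#' delimiters `"; "`, `", "` and `" - "`.  Splits on all three, trims
#' whitespace, drops empties, preserves order.
#'
#' @param field MAPPED_GENE string (vectorised).
#' @return character vector of symbols (a list when `length(field) > 1`).
#' @examples
#' split_mapped_genes("A - B; C")
#' @export
split_mapped_genes <- function(field) {
  one <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    parts <- trimws(strsplit(x, "; |, | - ")[[1]])
    parts[nzchar(parts)]
  }
  if (length(field) == 1L) one(field) else lapply(field, one)
}

#' TFs that are direct GWAS hits for a trait
#'
#' Finds the records whose `DISEASE.TRAIT` equals `trait` exactly
#' (case-sensitive), splits their mapped-gene fields, intersects the symbols
#' with the catalog's HGNC universe, and returns one row per hit TF with the
#' family annotation from the first catalog occurrence.  Rows are ordered by
#' first appearance in the catalog.
#'
#' @param trait trait string, matched exactly.
#' @param gwas a [gwas_catalog()].
#' @param catalog a [TFCatalog-class].
#' @param family_column family column in `hgnc_map(catalog)`.
#' @return data.frame with columns `HGNC` and the family column; zero rows
#'   when the trait is absent.
#' @export
direct_hits <- function(trait, gwas, catalog,
                        family_column = "Family_Name") {
  stopifnot(nzchar(trait))
  tab <- hgnc_map(catalog)
  if (!family_column %in% colnames(tab))
    stop("schema error: catalog lacks column '", family_column, "'",
         call. = FALSE)
  rec <- gwas[gwas$`DISEASE.TRAIT` == trait, , drop = FALSE]
  genes <- as.character(unique(unlist(split_mapped_genes(rec$MAPPED_GENE),
                                      use.names = FALSE)))
  idx <- match(genes, trimws(tab$HGNC))  # first catalog occurrence
  hit <- !is.na(idx)
  out <- data.frame(HGNC = genes[hit],
                    family = as.character(tab[[family_column]])[idx[hit]],
                    stringsAsFactors = FALSE)
  names(out)[2L] <- family_column
  out <- out[order(idx[hit]), , drop = FALSE]  # catalog order
  rownames(out) <- NULL
  out
}

#' Traits most commonly mapped to the targets of a TF
#'
#' Pipeline: remap the collection's members to symbols (when `id_map` is
#' supplied and the collection is entrez-typed), take the union of targets of
#' `tf` via [targets_of()], select the GWAS records with at least one mapped
#' gene in that target set, and tabulate records per trait.  A record counts
#' once per trait even when several of its mapped genes are targets.  Trait
#' counts are sorted alphabetically by trait for determinism.
#'
#' @param tf HGNC symbol of the TF.
#' @param collection a [GeneSetCollection] of TF-target sets.
#' @param gwas a [gwas_catalog()].
#' @param id_map entrez-to-symbol map (data.frame or named vector); required
#'   when the collection is entrez-typed.
#' @return list with `hits` (the matching records, five GWAS columns
#'   retained) and `trait_counts` (data.frame trait/n, alphabetical).
#' @export
top_traits_of_targets <- function(tf, collection, gwas, id_map = NULL) {
  stopifnot(nzchar(tf))
  if (collection$id_type == "entrez") {
    if (is.null(id_map))
      stop("collection is entrez-typed; an entrez-to-symbol id_map ",
           "is required", call. = FALSE)
    collection <- remap_identifiers(collection, id_map, to_type = "symbol")
  }
  targets <- targets_of(collection, tf)
  empty <- list(
    hits = gwas[integer(0),
                c("DISEASE.TRAIT", "MAPPED_GENE", "SNPS", "CHR_ID", "CHR_POS"),
                drop = FALSE],
    trait_counts = data.frame(trait = character(0), n = integer(0),
                              stringsAsFactors = FALSE))
  if (!length(targets)) {
    message("no target sets found for TF '", tf, "'")
    return(empty)
  }
  gene_lists <- split_mapped_genes(gwas$MAPPED_GENE)
  if (nrow(gwas) == 1L) gene_lists <- list(gene_lists)
  keep <- vapply(gene_lists, function(g) any(g %in% targets), logical(1))
  hits <- gwas[keep,
               c("DISEASE.TRAIT", "MAPPED_GENE", "SNPS", "CHR_ID", "CHR_POS"),
               drop = FALSE]
  rownames(hits) <- NULL
  tc <- table(hits$`DISEASE.TRAIT`)
  trait_counts <- data.frame(trait = names(tc), n = as.integer(tc),
                             stringsAsFactors = FALSE)
  trait_counts <- trait_counts[order(trait_counts$trait), , drop = FALSE]
  rownames(trait_counts) <- NULL
  list(hits = hits, trait_counts = trait_counts)
}

#' Restrict a GWAS catalog to one chromosome
#'
#' @param gwas a [gwas_catalog()].
#' @param chrom chromosome id string (e.g. `"17"`).
#' @return the filtered [gwas_catalog()]; idempotent.
#' @export
filter_by_chrom <- function(gwas, chrom) {
  out <- gwas[!is.na(gwas$CHR_ID) & gwas$CHR_ID == as.character(chrom), ,
              drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GwasCatalog", "data.frame")
  out
}
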