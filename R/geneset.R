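#' Gene-set collection containers
#'
#' A `GeneSetCollection` is a lightweight list-based container for named gene
#' sets sharing one identifier type, as used for MSigDb-style TF-target (TFT)
#' collections.  Each set is a list with fields `name`, `description` and
#' `members` (unique, non-empty identifiers in file order).
#'
#' @param sets list of gene sets, each a list(name, description, members).
#' @param name collection label.
#' @param id_type `"entrez"` or `"symbol"` — shared by all sets.
#' @return object of class `GeneSetCollection`.
#' @export
GeneSetCollection <- function(sets = list(), name = "collection",
                              id_type = c("entrez", "symbol")) {
  id_type <- match.arg(id_type)
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  structure(list(name = name, sets = sets, id_type = id_type),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  ids <- unique(unlist(lapply(x$sets, `[[`, "members"), use.names = FALSE))
  cat("GeneSetCollection", x$name, "\n")
  cat(" ", length(x$sets), "sets;", length(ids), "unique identifiers;",
      "id type:", x$id_type, "\n")
  if (length(x$sets)) {
    nm <- set_names(x)
    cat("  names:", paste(utils::head(nm, 3), collapse = ", "),
        if (length(nm) > 3) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Names of the sets in a collection
#' @param collection a GeneSetCollection
#' @return character vector of set names in collection order.
#' @export
set_names <- function(collection) {
  vapply(collection$sets, `[[`, character(1), "name")
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then member identifiers.
#' Lines with fewer than three fields are an error citing the line number.
#' Duplicate member identifiers within a line are dropped with a per-set
#' count recorded in attribute `n_dupes` of the returned collection.
#'
#' @param path GMT file.
#' @param id_type identifier type of the members.
#' @param name collection label (defaults to the file name).
#' @return a [GeneSetCollection].
#' @export
read_gmt <- function(path, id_type = c("entrez", "symbol"), name = NULL) {
  id_type <- match.arg(id_type)
  if (is.null(name)) name <- basename(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  dupes <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields",
           call. = FALSE)
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    dupes[i] <- sum(duplicated(mem))
    sets[[i]] <- list(name = f[1L], description = f[2L],
                      members = unique(mem))
  }
  coll <- GeneSetCollection(sets, name = name, id_type = id_type)
  if (sum(dupes))
    warning(sum(dupes), " duplicate member id(s) dropped across ",
            sum(dupes > 0), " set(s)", call. = FALSE)
  attr(coll, "n_dupes") <- stats::setNames(dupes, set_names(coll))
  coll
}

#' Write a collection to a GMT file
#'
#' Inverse of [read_gmt()]: one line per set, tab-separated, LF endings,
#' UTF-8.  `read_gmt(write_gmt(x))` reproduces names, descriptions, members
#' and order.
#'
#' @param collection a [GeneSetCollection].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

.is_motif_token <- function(tok) {
  nchar(tok) >= 6L && all(strsplit(tok, "", fixed = TRUE)[[1]] %in% .IUPAC)
}

.is_qualifier_token <- function(tok) {
  grepl("^Q[0-9]+$", tok) || grepl("^[0-9]+$", tok) || grepl("^[A-Za-z]$", tok)
}

#' Parse an MSigDb TFT-style set name
#'
#' TFT set names are underscore-delimited strings mixing a motif in IUPAC
#' codes, a gene-like token, and version qualifiers, e.g.
#' `"GGGNNTTTCC_NFKB_Q6_01"`.  Tokens are classified in order: the first
#' token of length >= 6 drawn wholly from the IUPAC nucleotide alphabet is
#' the motif; tokens matching `Q<digits>`, bare digits, or a single letter
#' are qualifiers; the leftmost remaining token is the candidate gene, and
#' anything after it joins the qualifiers.  The gene token is matched against
#' `hgnc_universe` exactly (case-insensitive, `match_kind = "exact"`), then
#' with trailing digits stripped (`"close"`), else `"unknown"`.  The literal
#' token `UNKNOWN` forces `match_kind = "unknown"`.
#'
#' Joining `tokens` with underscores always reproduces `raw`.
#'
#' @param raw set name.
#' @param hgnc_universe character vector of symbols to match against.
#' @return list with `raw`, `tokens`, `roles` (parallel to tokens, one of
#'   motif/gene/qualifier), `motif_token`, `gene_token`, `matched_hgnc`
#'   (each `NA` when absent), `match_kind`, `qualifier_tokens`.
#' @examples
#' parse_tft_name("GGGNNTTTCC_NFKB_Q6_01", character(0))
#' @export
parse_tft_name <- function(raw, hgnc_universe = character(0)) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  toks <- strsplit(raw, "_", fixed = TRUE)[[1]]
  roles <- rep(NA_character_, length(toks))
  motif_idx <- which(vapply(toks, .is_motif_token, logical(1)))
  if (length(motif_idx)) roles[motif_idx[1L]] <- "motif"
  for (i in which(is.na(roles)))
    if (.is_qualifier_token(toks[i])) roles[i] <- "qualifier"
  remaining <- which(is.na(roles))
  if (length(remaining)) {
    roles[remaining[1L]] <- "gene"
    roles[remaining[-1L]] <- "qualifier"
  }
  motif_token <- if (any(roles == "motif")) toks[roles == "motif"] else NA_character_
  gene_token <- if (any(roles == "gene")) toks[roles == "gene"] else NA_character_
  matched <- NA_character_
  kind <- "unknown"
  if (!is.na(gene_token) && gene_token != "UNKNOWN") {
    uni <- as.character(hgnc_universe)
    hit <- match(toupper(gene_token), toupper(uni))
    if (!is.na(hit)) {
      matched <- uni[hit]
      kind <- "exact"
    } else {
      # strip trailing digits one at a time, retrying at each step
      stripped <- gene_token
      while (grepl("[0-9]$", stripped)) {
        stripped <- sub("[0-9]$", "", stripped)
        if (!nzchar(stripped)) break
        hit <- match(toupper(stripped), toupper(uni))
        if (!is.na(hit)) {
          matched <- uni[hit]
          kind <- "close"
          break
        }
      }
    }
  }
  list(raw = raw, tokens = toks, roles = roles,
       motif_token = motif_token, gene_token = gene_token,
       matched_hgnc = matched, match_kind = kind,
       qualifier_tokens = toks[!is.na(roles) & roles == "qualifier"])
}

#' Parse every set name of a collection into a table
#'
#' @param collection a [GeneSetCollection].
#' @param hgnc_universe symbols to match gene tokens against.
#' @return data.frame with columns raw, motif_token, gene_token,
#'   matched_hgnc, match_kind.
#' @export
parse_collection_names <- function(collection, hgnc_universe = character(0)) {
  rows <- lapply(set_names(collection), function(nm) {
    p <- parse_tft_name(nm, hgnc_universe)
    data.frame(raw = p$raw, motif_token = p$motif_token,
               gene_token = p$gene_token, matched_hgnc = p$matched_hgnc,
               match_kind = p$match_kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(raw = character(0), motif_token = character(0),
                      gene_token = character(0), matched_hgnc = character(0),
                      match_kind = character(0))
  out
}

#' Grep set names
#'
#' Returns the names of sets whose name matches `pattern` (a regular
#' expression), in collection order.
#'
#' @param collection a [GeneSetCollection].
#' @param pattern regular expression.
#' @return character vector of matching set names.
#' @export
grep_sets <- function(collection, pattern) {
  tryCatch(suppressWarnings(grepl(pattern, "")), error = function(e)
    stop("invalid pattern: ", conditionMessage(e), call. = FALSE))
  grep(pattern, set_names(collection), value = TRUE)
}

#' Remap member identifiers of a collection
#'
#' Translates each member through `id_map`; unmapped members are dropped and
#' per-set drop counts recorded in attribute `n_dropped`.  Translated member
#' lists are deduplicated; the collection's `id_type` becomes `to_type`.
#'
#' @param collection a [GeneSetCollection].
#' @param id_map data.frame whose first column holds source ids and second
#'   column target ids, or a named character vector (names = source ids).
#' @param to_type identifier type after remapping.
#' @return a remapped [GeneSetCollection].
#' @export
remap_identifiers <- function(collection, id_map, to_type = "symbol") {
  if (is.data.frame(id_map)) {
    if (nrow(id_map) == 0L) stop("empty id map", call. = FALSE)
    map <- stats::setNames(as.character(id_map[[2L]]),
                           as.character(id_map[[1L]]))
  } else {
    if (!length(id_map)) stop("empty id map", call. = FALSE)
    map <- id_map
  }
  dropped <- integer(length(collection$sets))
  sets <- vector("list", length(collection$sets))
  for (i in seq_along(collection$sets)) {
    s <- collection$sets[[i]]
    new_ids <- unname(map[s$members])
    dropped[i] <- sum(is.na(new_ids))
    s$members <- unique(new_ids[!is.na(new_ids)])
    sets[[i]] <- s
  }
  out <- GeneSetCollection(sets, name = collection$name, id_type = to_type)
  attr(out, "n_dropped") <- stats::setNames(dropped, set_names(out))
  out
}

#' Merged target list for one TF
#'
#' Unions the members of every set whose parsed name matches `tf_symbol`
#' (via [parse_tft_name()]'s `matched_hgnc`).  Returns an empty character
#' vector when no set matches.
#'
#' @param collection a [GeneSetCollection].
#' @param tf_symbol HGNC symbol of the TF.
#' @param hgnc_universe symbols used for gene-token matching; defaults to
#'   `tf_symbol` itself, which suffices for exact/close matching of one TF.
#' @return character vector of target identifiers (first-appearance order).
#' @export
targets_of <- function(collection, tf_symbol, hgnc_universe = tf_symbol) {
  stopifnot(nzchar(tf_symbol))
  hit_sets <- Filter(function(s) {
    p <- parse_tft_name(s$name, hgnc_universe)
    !is.na(p$matched_hgnc) && p$matched_hgnc == tf_symbol
  }, collection$sets)
  unique(unlist(lapply(hit_sets, `[[`, "members"), use.names = FALSE))
}
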