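#' Genomic intervals (0-based, half-open)
#'
#' All in-package coordinates are 0-based half-open, the BED convention:
#' an interval covers positions `start .. end-1`.  1-based inclusive syntax
#' accepted at the command line is converted once at that boundary.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start, `0 <= start < end`.
#' @param end 0-based exclusive end.
#' @return list of class `GenomicInterval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ",
         end, ")", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end),
            class = "GenomicInterval")
}

#' @export
format.GenomicInterval <- function(x, ...)
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))

#' @export
print.GenomicInterval <- function(x, ...) {
  cat("GenomicInterval", format(x), "(0-based, half-open)\n")
  invisible(x)
}

#' Parse a 1-based inclusive region string
#'
#' Converts `"chr17:38077001-38084000"` (the convention genomics users type)
#' to the internal 0-based half-open representation.
#'
#' @param region string `chrom:start-end`, 1-based inclusive.
#' @return a [genomic_interval()].
#' @export
parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (!length(m))
    stop("cannot parse region '", region, "'; expected chrom:start-end",
         call. = FALSE)
  s1 <- as.numeric(gsub(",", "", m[3L], fixed = TRUE))
  e1 <- as.numeric(gsub(",", "", m[4L], fixed = TRUE))
  genomic_interval(m[2L], s1 - 1, e1)
}

.NEGLOG10P_CAP <- 400

#' Negative log10 of a binding p-value
#'
#' `-log10(p)` with `p = 0` mapped to a documented cap of 400 (flagged via
#' attribute `capped`) so downstream tables stay finite.
#'
#' @param pvalue numeric vector of p-values in \[0, 1\].
#' @return numeric vector of the same length.
#' @export
neglog10p <- function(pvalue) {
  out <- -log10(pvalue)
  capped <- is.infinite(out) & out > 0
  out[capped] <- .NEGLOG10P_CAP
  attr(out, "capped") <- capped
  out
}

# default scored-BED dialect: the column order the fixture generator writes
.SCORED_BED_COLS <- c(chrom = 1L, start = 2L, end = 3L, motif_id = 4L,
                      score = 5L, strand = 6L, pvalue = 7L)

.read_scored_bed <- function(file = NULL, columns = .SCORED_BED_COLS,
                             text = NULL) {
  if (is.null(text) && file.size(file) == 0)
    return(.empty_sites())
  if (is.null(text) && grepl("\\.gz$", file)) {
    con <- gzfile(file, open = "rt")   # bgzip is valid gzip
    on.exit(close(con))
    text <- readLines(con)
    if (!length(text)) return(.empty_sites())
  }
  raw <- if (is.null(text))
    data.table::fread(file, sep = "\t", header = FALSE, data.table = FALSE)
  else
    data.table::fread(text = text, sep = "\t", header = FALSE,
                      data.table = FALSE)
  if (!nrow(raw))
    return(.empty_sites())
  data.frame(chrom = as.character(raw[[columns[["chrom"]]]]),
             start = as.numeric(raw[[columns[["start"]]]]),
             end = as.numeric(raw[[columns[["end"]]]]),
             motif_id = as.character(raw[[columns[["motif_id"]]]]),
             score = as.numeric(raw[[columns[["score"]]]]),
             strand = as.character(raw[[columns[["strand"]]]]),
             pvalue = as.numeric(raw[[columns[["pvalue"]]]]),
             stringsAsFactors = FALSE)
}

.empty_sites <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             motif_id = character(0), score = numeric(0),
             strand = character(0), pvalue = numeric(0),
             neglog10p = numeric(0), stringsAsFactors = FALSE)
}

.finish_sites <- function(df, interval) {
  # coerce coordinate columns so the indexed and linear paths agree exactly
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$score <- as.numeric(df$score)
  df$pvalue <- as.numeric(df$pvalue)
  keep <- df$chrom == interval$chrom & df$start < interval$end &
    df$end > interval$start
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$neglog10p <- as.numeric(neglog10p(df$pvalue))
  rownames(df) <- NULL
  df
}

#' Query a scored binding track by interval
#'
#' Harvests all scored sites overlapping `interval` (any shared base, under
#' half-open semantics) from a position-sorted BED-like track of motif-scan
#' scores with a p-value column.  When `file` is bgzip-compressed and a tabix
#' index (`.tbi`) sits beside it, the query goes through the index; otherwise
#' — or if the indexed read fails — the whole file is scanned linearly, with
#' a warning in the corrupt-index case.  Both paths return identical record
#' sets.
#'
#' @param file path to the track (plain or bgzipped `.gz` with `.tbi`).
#' @param interval a [genomic_interval()].
#' @param columns named integer vector mapping the seven dialect fields
#'   (chrom, start, end, motif_id, score, strand, pvalue) to column numbers.
#' @param use_index set `FALSE` to force the linear scan.
#' @return data.frame of sites sorted by start: chrom, start, end, motif_id,
#'   score, strand, pvalue, neglog10p.  Chromosomes absent from the file
#'   yield an empty result, not an error.
#' @export
query_track <- function(file, interval, columns = .SCORED_BED_COLS,
                        use_index = TRUE) {
  stopifnot(inherits(interval, "GenomicInterval"))
  if (!file.exists(file)) stop("track not found: ", file, call. = FALSE)
  tbi <- paste0(file, ".tbi")
  if (use_index && grepl("\\.gz$", file) && file.exists(tbi)) {
    hits <- tryCatch({
      tf <- Rsamtools::TabixFile(file, index = tbi)
      if (!interval$chrom %in% Rsamtools::seqnamesTabix(tf))
        return(.finish_sites(.empty_sites()[, 1:7], interval))
      # tabix cannot index coordinates past 2^29; clamp the query end
      param <- GenomicRanges::GRanges(
        interval$chrom,
        IRanges::IRanges(min(interval$start + 1, 2^29 - 1),
                         min(interval$end, 2^29 - 1)))
      res <- Rsamtools::scanTabix(tf, param = param)[[1]]
      if (!length(res)) .empty_sites()[, 1:7] else
        .read_scored_bed(columns = columns, text = res)
    }, error = function(e) {
      warning("indexed query failed (", conditionMessage(e),
              "); falling back to linear scan", call. = FALSE)
      NULL
    })
    if (!is.null(hits)) return(.finish_sites(hits, interval))
  }
  .finish_sites(.read_scored_bed(file, columns), interval)
}

#' A set of binding tracks with per-file metadata
#'
#' Bundles an ordered list of scored-track files with a metadata table that
#' has one row per file and obligatory columns `Mtag` (motif-model tag, e.g.
#' `M0635_1`) and `HGNC` (the TF the motif is associated with).
#'
#' @param files character vector of track file paths.
#' @param metadata data.frame with `length(files)` rows, columns `Mtag` and
#'   `HGNC`.
#' @return object of class `BindingTrackSet`.
#' @export
binding_track_set <- function(files, metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(metadata) != length(files))
    stop("metadata must have one row per file", call. = FALSE)
  miss <- setdiff(c("Mtag", "HGNC"), colnames(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(files = as.character(files), metadata = metadata),
            class = "BindingTrackSet")
}

#' @export
print.BindingTrackSet <- function(x, ...) {
  cat("BindingTrackSet with", length(x$files), "files\n")
  print(utils::head(x$metadata))
  invisible(x)
}

#' Apply a per-file, per-interval map over a track set
#'
#' For every file (in metadata order) and every query interval (in input
#' order), harvests the overlapping sites and applies `map_fn` to the hit
#' table.  The result is a list with one element per file, each a list with
#' one element per interval — mirroring the reduce-by-file protocol of
#' genomic-files tooling.
#'
#' @param tracks a [binding_track_set()].
#' @param intervals list of [genomic_interval()] objects.
#' @param map_fn function applied to each hit data.frame; defaults to
#'   identity.  An error raised for one file is re-signalled with the file
#'   identity attached.
#' @param columns column map forwarded to [query_track()].
#' @return nested list, `result[[file]][[interval]]`.
#' @export
reduce_by_file <- function(tracks, intervals, map_fn = identity,
                           columns = .SCORED_BED_COLS) {
  stopifnot(inherits(tracks, "BindingTrackSet"), length(tracks$files) >= 1L)
  if (inherits(intervals, "GenomicInterval")) intervals <- list(intervals)
  stopifnot(length(intervals) >= 1L)
  out <- lapply(seq_along(tracks$files), function(i) {
    f <- tracks$files[i]
    lapply(intervals, function(iv) {
      tryCatch(map_fn(query_track(f, iv, columns = columns)),
               error = function(e)
                 stop("error in file '", basename(f), "': ",
                      conditionMessage(e), call. = FALSE))
    })
  })
  names(out) <- basename(tracks$files)
  out
}

#' Annotate a track set with TF family labels from a catalog
#'
#' Matches each track's `HGNC` value against the catalog's symbol column and
#' copies the family annotation from the FIRST matching catalog row;
#' unmatched tracks get `NA`.
#'
#' @param tracks a [binding_track_set()].
#' @param catalog a [TFCatalog-class] whose `hgnc_map` holds `family_column`.
#' @param family_column name of the family column, e.g. `"Family_Name"`.
#' @return the metadata table with a `family` column appended.
#' @export
annotate_family <- function(tracks, catalog, family_column = "Family_Name") {
  tab <- hgnc_map(catalog)
  if (!family_column %in% colnames(tab))
    stop("catalog lacks column '", family_column, "'", call. = FALSE)
  md <- tracks$metadata
  idx <- match(md$HGNC, tab$HGNC)
  md$family <- ifelse(is.na(idx), NA_character_,
                      as.character(tab[[family_column]])[idx])
  md
}

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, peak (summit offset from start; -1 when not called).
#' Intervals are 0-based half-open.
#'
#' @param path narrowPeak file.
#' @return data.frame with the ten columns; empty files give zero rows.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(0), numeric(0), numeric(0), character(0),
                 numeric(0), character(0), numeric(0), numeric(0),
                 numeric(0), numeric(0), stringsAsFactors = FALSE), cols))
  raw <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  if (ncol(raw) != 10L) {
    nf <- utils::count.fields(path, sep = "\t")
    bad <- which(nf != 10L)[1L]
    stop("narrowPeak format error: expected 10 columns, line ",
         if (is.na(bad)) 1L else bad, " has ",
         if (is.na(bad)) ncol(raw) else nf[bad], call. = FALSE)
  }
  names(raw) <- cols
  raw$chrom <- as.character(raw$chrom)
  raw$name <- as.character(raw$name)
  raw$strand <- as.character(raw$strand)
  raw
}

#' Write peaks back to narrowPeak
#' @param peaks data.frame as returned by [read_narrowpeak()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  data.table::fwrite(peaks, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Registry of ChIP-seq experiments
#'
#' One row per experiment: cell line, TF (HGNC symbol), and the peak file the
#' experiment's calls live in.  Rows must be unique.
#'
#' @param table data.frame (or TSV path) with columns `cell_line`, `tf_hgnc`,
#'   `peak_file`.
#' @return data.frame of class `EncodeRegistry`.
#' @export
encode_registry <- function(table) {
  if (is.character(table) && length(table) == 1L)
    table <- data.table::fread(table, sep = "\t", header = TRUE,
                               data.table = FALSE, colClasses = "character")
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_line", "tf_hgnc", "peak_file"), colnames(tab))
  if (length(miss))
    stop("registry lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab[, c("cell_line", "tf_hgnc", "peak_file")]))
    stop("registry rows must be unique on (cell_line, tf_hgnc, peak_file)",
         call. = FALSE)
  class(tab) <- c("EncodeRegistry", "data.frame")
  tab
}

#' Peaks overlapping a region, per experiment
#'
#' Selects the registry experiments for one TF (optionally restricted to some
#' cell lines), reads each experiment's narrowPeak file, and returns the
#' peaks overlapping `region` per experiment.  Experiments whose peak file is
#' missing are reported in the result (with `NULL` peaks and a warning), not
#' silently dropped; a TF absent from the registry yields an empty result
#' with a message.
#'
#' @param registry an [encode_registry()].
#' @param tf HGNC symbol of the TF.
#' @param region a [genomic_interval()].
#' @param cell_lines optional character vector restricting the cell lines.
#' @return named list (names `cell_line:tf`) of peak data.frames.
#' @export
peaks_in_region <- function(registry, tf, region, cell_lines = NULL) {
  stopifnot(inherits(region, "GenomicInterval"))
  sel <- registry$tf_hgnc == tf
  if (!is.null(cell_lines)) sel <- sel & registry$cell_line %in% cell_lines
  rows <- registry[sel, , drop = FALSE]
  if (!nrow(rows)) {
    message("no registry experiments for TF '", tf, "'")
    return(stats::setNames(list(), character(0)))
  }
  out <- vector("list", nrow(rows))
  names(out) <- paste(rows$cell_line, rows$tf_hgnc, sep = ":")
  for (i in seq_len(nrow(rows))) {
    f <- rows$peak_file[i]
    if (!file.exists(f)) {
      warning("peak file missing for experiment ", names(out)[i], ": ", f,
              call. = FALSE)
      out[i] <- list(NULL)
      next
    }
    pk <- read_narrowpeak(f)
    keep <- pk$chrom == region$chrom & pk$start < region$end &
      pk$end > region$start
    out[[i]] <- pk[keep, , drop = FALSE]
  }
  out
}

#' Flatten a harvest into the plotting-table export
#'
#' Concatenates per-file query results over one region into the TSV-ready
#' table used to plot binding-affinity landscapes: chrom, start, end,
#' motif_id, neglog10p, HGNC, family.
#'
#' @param tracks a [binding_track_set()].
#' @param interval a [genomic_interval()].
#' @param catalog optional [TFCatalog-class] supplying family labels.
#' @param family_column family column in the catalog.
#' @return data.frame, one row per harvested site.
#' @export
harvest_scores <- function(tracks, interval, catalog = NULL,
                           family_column = "Family_Name") {
  md <- if (!is.null(catalog))
    annotate_family(tracks, catalog, family_column)
  else cbind(tracks$metadata, family = NA_character_)
  res <- reduce_by_file(tracks, list(interval))
  rows <- lapply(seq_along(res), function(i) {
    hits <- res[[i]][[1]]
    if (!nrow(hits)) return(NULL)
    data.frame(hits[, c("chrom", "start", "end", "motif_id", "neglog10p")],
               HGNC = md$HGNC[i], family = md$family[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), motif_id = character(0),
                      neglog10p = numeric(0), HGNC = character(0),
                      family = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
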