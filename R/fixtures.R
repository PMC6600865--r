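#' Synthetic fixtures with planted, exactly-known structure
#'
#' The fixture generators build offline stand-ins for the real resources the
#' package consumes — catalog snapshots, TFT gene-set collections, scored
#' binding tracks, narrowPeak experiment sets, GWAS tables — each shipped
#' with its ground truth so module outputs can be checked exactly.  All
#' generators are deterministic: a fixed seed yields byte-identical files.
#' Gene symbols come from a synthetic namespace (`G0001`, `TFG1`, ...) plus a
#' few real symbols (`TFAP2B`, `YY1`, `MTF1`, `TP53`) so documented examples
#' run verbatim.
#'
#' @name fixtures
NULL

.FAMILIES <- c("C2H2 ZF", "Homeodomain", "bHLH", "bZIP", "Forkhead",
               "Nuclear receptor", "Ets", "Sox", "Myb/SANT", "GATA")

.HOCO_CLASSES <- c(
  "More than 3 adjacent zinc finger factors{2.3.3}",
  "HOX-related factors{3.1.1}",
  "NK-related factors{3.1.2}",
  "Paired-related HD factors{3.1.3}",
  "Forkhead box (FOX) factors{3.3.1}",
  "Ets-related factors{3.5.2}",
  "POU domain factors{3.1.10}",
  "Tal-related factors{1.2.3}")

.REAL_SYMBOLS <- c("TFAP2B", "YY1", "MTF1", "TP53")

#' Default planted membership-signature counts
#'
#' Four catalogs mirroring the CISBP / HOCOMOCO / GO / MSigDb-TFT comparison;
#' the four-way intersection (119) and the CISBP-exclusive region (475) are
#' set to the published comparison's counts, the remaining signatures to
#' plausible mid-sized regions.
#'
#' @return data.frame with columns `region` and `count`.
#' @export
default_signature_counts <- function() {
  data.frame(
    region = c("CISBP", "HOCOMOCO", "GO", "TFT",
               "CISBP&HOCOMOCO", "CISBP&GO", "CISBP&TFT",
               "GO&HOCOMOCO", "HOCOMOCO&TFT", "GO&TFT",
               "CISBP&GO&HOCOMOCO", "CISBP&HOCOMOCO&TFT", "CISBP&GO&TFT",
               "GO&HOCOMOCO&TFT", "CISBP&GO&HOCOMOCO&TFT"),
    count = c(475L, 40L, 120L, 160L,
              150L, 90L, 200L,
              10L, 25L, 30L,
              60L, 180L, 70L,
              15L, 119L),
    stringsAsFactors = FALSE)
}

.rand_iupac <- function(n, min_len = 8L, max_len = 12L) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    paste(sample(c("A", "C", "G", "T", "N", "W", "R", "Y"), len,
                 replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a suite of TF catalogs with planted overlap structure
#'
#' Assigns every synthetic symbol to exactly one membership signature (so
#' the planted counts are the exact truth for [overlap_counts()]), then
#' materialises each catalog in its native schema: a CISBP-style table
#' (first-column motif ids, several records per gene, `TF_Name`,
#' `Family_Name`, opaque filler columns), a HOCOMOCO-style nine-column table
#' (`Model`, `Transcription factor`, `TF class` with TFClass suffixes), a
#' two-column GO annotation table (with off-term decoy rows), and a TFT-style
#' catalog whose symbols pass through the set-name parsing heuristic.
#' Files are written under `dir` and re-loaded through the package loaders.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed; fixed seed gives byte-identical files.
#' @param signature_counts data.frame(region, count) with `&`-joined,
#'   alphabetically sorted catalog names; defaults to
#'   [default_signature_counts()].
#' @return list with `catalogs` (named list of [TFCatalog-class]), `truth`
#'   (the planted table, sorted like [overlap_counts()] output), `files`
#'   (named paths), and `symbols` (per-signature symbol lists).
#' @export
make_catalog_suite <- function(dir = tempfile("catsuite"), seed = 1L,
                               signature_counts = default_signature_counts()) {
  stopifnot(all(signature_counts$count >= 0))
  if (anyDuplicated(signature_counts$region))
    stop("signature_counts regions must be unique", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cat_names <- sort(unique(unlist(
    strsplit(signature_counts$region, "&", fixed = TRUE))))

  # assign each symbol exactly one signature
  total <- sum(signature_counts$count)
  syms <- sprintf("G%04d", seq_len(total))
  full_sig <- paste(cat_names, collapse = "&")
  if (full_sig %in% signature_counts$region) {
    # plant the real example symbols inside the all-catalogs region
    first <- sum(signature_counts$count[
      seq_len(match(full_sig, signature_counts$region) - 1L)])
    k <- min(length(.REAL_SYMBOLS),
             signature_counts$count[match(full_sig, signature_counts$region)])
    if (k > 0) syms[first + seq_len(k)] <- .REAL_SYMBOLS[seq_len(k)]
  }
  sig_of <- rep(signature_counts$region, signature_counts$count)
  symbols <- split(syms, sig_of)[unique(sig_of)]

  members <- function(cat) {
    unlist(symbols[vapply(names(symbols), function(s)
      cat %in% strsplit(s, "&", fixed = TRUE)[[1]], logical(1))],
      use.names = FALSE)
  }

  files <- list()
  catalogs <- list()
  for (cat in cat_names) {
    mem <- members(cat)
    if (cat == "GO") {
      decoys <- sprintf("D%04d", seq_len(max(1L, length(mem) %/% 3L)))
      tab <- rbind(
        data.frame(SYMBOL = mem, GO = "GO:0003700",
                   stringsAsFactors = FALSE),
        data.frame(SYMBOL = decoys, GO = "GO:0005515",
                   stringsAsFactors = FALSE))
      tab <- tab[sample(nrow(tab)), , drop = FALSE]
      f <- file.path(dir, "go_annotations.tsv")
      data.table::fwrite(tab, f, sep = "\t", quote = FALSE)
      files[[cat]] <- f
      catalogs[[cat]] <- load_go_catalog(f, name = cat)
    } else if (cat == "HOCOMOCO") {
      tab <- data.frame(
        Model = paste0(mem, "_HUMAN.H11MO.0.A"),
        `Transcription factor` = mem,
        `Model length` = sample(8:20, length(mem), replace = TRUE),
        Quality = sample(c("A", "B", "C", "D"), length(mem), replace = TRUE),
        Rank = seq_along(mem),
        `TF class` = sample(.HOCO_CLASSES, length(mem), replace = TRUE),
        `TF family` = "synthetic",
        `Data source` = "fixture",
        Species = "Homo sapiens",
        check.names = FALSE, stringsAsFactors = FALSE)
      f <- file.path(dir, "hocomoco.tsv")
      data.table::fwrite(tab, f, sep = "\t", quote = FALSE)
      files[[cat]] <- f
      catalogs[[cat]] <- load_hocomoco_catalog(f, name = cat)
    } else if (cat == "TFT") {
      motifs <- .rand_iupac(length(mem))
      nms <- paste0(motifs, "_", mem, "_Q6")
      sets <- lapply(seq_along(mem), function(i)
        list(name = nms[i], description = "synthetic TFT set",
             members = as.character(sample(1e4:5e4, 5L))))
      coll <- GeneSetCollection(sets, name = "TFT", id_type = "entrez")
      f <- file.path(dir, "tft.gmt")
      write_gmt(coll, f)
      files[[cat]] <- f
      parsed <- parse_collection_names(coll, hgnc_universe = mem)
      hits <- parsed$matched_hgnc[!is.na(parsed$matched_hgnc)]
      catalogs[[cat]] <- TFCatalog(cat, parsed$raw,
                                   data.frame(HGNC = parsed$matched_hgnc,
                                              stringsAsFactors = FALSE))
    } else { # CISBP-style (also any extra catalog names)
      reps <- sample(1:3, length(mem), replace = TRUE)
      tf_name <- rep(mem, reps)
      fam <- rep(sample(.FAMILIES, length(mem), replace = TRUE), reps)
      n <- length(tf_name)
      tab <- data.frame(
        TF_ID = sprintf("T%06d_1.02", seq_len(n)),
        TF_Name = tf_name,
        Family_Name = fam,
        TF_Species = "Homo_sapiens",
        TF_Status = sample(c("D", "I"), n, replace = TRUE),
        Motif_Type = sample(c("SELEX", "ChIP-seq", "Transfac"), n,
                            replace = TRUE),
        DBID = sprintf("ENSG%011d", sample(1e5:9e5, n)),
        stringsAsFactors = FALSE)
      f <- file.path(dir, paste0(tolower(cat), ".tsv"))
      data.table::fwrite(tab, f, sep = "\t", quote = FALSE)
      files[[cat]] <- f
      catalogs[[cat]] <- load_cisbp_catalog(f, name = cat)
    }
  }
  truth <- signature_counts[signature_counts$count > 0, , drop = FALSE]
  truth$n_catalogs <- lengths(strsplit(truth$region, "&", fixed = TRUE))
  truth <- truth[order(-truth$count, truth$region), , drop = FALSE]
  rownames(truth) <- NULL
  list(catalogs = catalogs, truth = truth, files = files, symbols = symbols)
}

#' Generate a TFT-style GMT collection with a known parse table
#'
#' Builds underscore-delimited set names from planted (motif, gene,
#' qualifier) templates — some sets motif-less, some with the literal
#' `UNKNOWN` gene token — plus entrez-style members and an entrez-to-symbol
#' map covering a stated fraction of all members.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param genes character vector of planted TF symbols.
#' @param n_unknown number of `UNKNOWN`-gene sets appended.
#' @param members_per_set set size.
#' @param map_coverage fraction of member ids present in the id map.
#' @return list with `collection`, `file`, `truth` (raw / motif_token /
#'   gene_token per set), `id_map` (entrez data.frame), `universe`.
#' @export
make_tft_collection <- function(dir = tempfile("tft"), seed = 1L,
                                genes = c("TFG1", "TFG2", "TFG3", "YY1",
                                          "MTF1", "TP53"),
                                n_unknown = 2L, members_per_set = 8L,
                                map_coverage = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  motifs <- .rand_iupac(length(genes))
  has_motif <- seq_along(genes) %% 2L == 1L   # alternate motif-full/-less
  quals <- c("Q6", "Q2", "01", "02", "Q6_01")
  raw <- character(length(genes))
  for (i in seq_along(genes)) {
    q <- sample(quals, 1L)
    raw[i] <- if (has_motif[i]) paste0(motifs[i], "_", genes[i], "_", q)
    else paste0(genes[i], "_", q)
  }
  unk <- if (n_unknown > 0)
    paste0(.rand_iupac(n_unknown), "_UNKNOWN") else character(0)
  all_names <- c(raw, unk)
  truth <- data.frame(
    raw = all_names,
    motif_token = c(ifelse(has_motif, motifs, NA_character_),
                    sub("_UNKNOWN$", "", unk)),
    gene_token = c(genes, rep("UNKNOWN", n_unknown)),
    match_kind = c(rep("exact", length(genes)), rep("unknown", n_unknown)),
    stringsAsFactors = FALSE)
  pool <- as.character(sample(1000:99999, length(all_names) * members_per_set))
  sets <- lapply(seq_along(all_names), function(i)
    list(name = all_names[i], description = "synthetic",
         members = pool[(i - 1L) * members_per_set + seq_len(members_per_set)]))
  coll <- GeneSetCollection(sets, name = "tft-fixture", id_type = "entrez")
  f <- file.path(dir, "fixture.gmt")
  write_gmt(coll, f)
  ids <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  n_map <- round(map_coverage * length(ids))
  mapped <- sort(sample(ids, n_map))
  id_map <- data.frame(entrez = mapped,
                       symbol = sprintf("SYM%05d", seq_along(mapped)),
                       stringsAsFactors = FALSE)
  list(collection = coll, file = f, truth = truth, id_map = id_map,
       universe = genes)
}

#' Generate sorted, indexed scored-BED binding tracks
#'
#' Writes `n_files` position-sorted tracks of motif-scan scores (dialect:
#' chrom, start, end, motif_id, score, strand, pvalue) with p-values drawn
#' log-uniformly over \[1e-8, 1\], bgzips and tabix-indexes each, and
#' records, for each probe interval, the exact overlap count computed
#' directly from the in-memory site table (independent of the query path).
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param n_files number of track files (16 mirrors the published
#'   illustration set).
#' @param sites_per_file sites per track.
#' @param chrom chromosome name used for all sites.
#' @param span numeric length-2: genomic window the sites fall in (0-based).
#' @param site_len length of each scored site.
#' @param n_probes number of probe intervals to record truth for.
#' @param index also write bgzip + tabix siblings (requires Rsamtools).
#' @return list with `tracks` (a [binding_track_set()] over the indexed
#'   files when `index`, else the plain ones), `plain_files`, `metadata`,
#'   `sites` (per-file data.frames), `probes`, `truth`
#'   (file x probe hit counts).
#' @export
make_scored_track <- function(dir = tempfile("tracks"), seed = 1L,
                              n_files = 16L, sites_per_file = 400L,
                              chrom = "chr17",
                              span = c(38.0e6, 38.2e6), site_len = 12L,
                              n_probes = 5L, index = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  mtags <- sprintf("M%04d_1", sample(1000:9999, n_files))
  hgnc <- c(.REAL_SYMBOLS,
            sprintf("TFX%02d", seq_len(max(0L, n_files - length(.REAL_SYMBOLS)))))
  hgnc <- hgnc[seq_len(n_files)]
  metadata <- data.frame(Mtag = mtags, HGNC = hgnc, stringsAsFactors = FALSE)
  plain <- character(n_files)
  gz <- character(n_files)
  sites <- vector("list", n_files)
  for (i in seq_len(n_files)) {
    start <- as.integer(sort(sample(seq(span[1], span[2] - site_len),
                                    sites_per_file)))
    pv <- 10^stats::runif(sites_per_file, -8, 0)   # log-uniform [1e-8, 1]
    df <- data.frame(chrom = chrom, start = start,
                     end = start + as.integer(site_len),
                     motif_id = mtags[i],
                     score = round(stats::runif(sites_per_file, 0, 30), 3),
                     strand = sample(c("+", "-"), sites_per_file,
                                     replace = TRUE),
                     pvalue = signif(pv, 6), stringsAsFactors = FALSE)
    df <- df[order(df$start, df$end), , drop = FALSE]
    plain[i] <- file.path(dir, paste0(mtags[i], "sort.bed"))
    data.table::fwrite(df, plain[i], sep = "\t", col.names = FALSE,
                       quote = FALSE, scipen = 50)
    if (index) {
      gz[i] <- Rsamtools::bgzip(plain[i], paste0(plain[i], ".gz"),
                                overwrite = TRUE)
      Rsamtools::indexTabix(gz[i], format = "bed")
    }
    sites[[i]] <- df
  }
  probes <- lapply(seq_len(n_probes), function(j) {
    s <- sample(seq(span[1], span[2]), 1L)
    genomic_interval(chrom, s, min(span[2], s + sample(2e3:2e4, 1L)))
  })
  truth <- do.call(rbind, lapply(seq_len(n_files), function(i) {
    data.frame(file = basename(plain[i]), probe = seq_len(n_probes),
               count = vapply(probes, function(p)
                 sum(sites[[i]]$chrom == p$chrom &
                       sites[[i]]$start < p$end &
                       sites[[i]]$end > p$start), integer(1)),
               stringsAsFactors = FALSE)
  }))
  files <- if (index) gz else plain
  list(tracks = binding_track_set(files, metadata), plain_files = plain,
       metadata = metadata, sites = sites, probes = probes, truth = truth)
}

#' Generate an ENCODE-style experiment registry with narrowPeak files
#'
#' Plants a peak cluster in a stated region for one TF across several cell
#' lines (with per-line planted in-region counts), adds out-of-region decoy
#' peaks, and writes one narrowPeak file per experiment plus the registry
#' TSV.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param tf TF symbol the cluster belongs to.
#' @param cell_lines cell line names (one experiment each).
#' @param region a [genomic_interval()] the cluster is planted in.
#' @param in_region_counts integer vector (recycled over cell lines) of
#'   planted overlapping-peak counts.
#' @param n_decoys out-of-region peaks per file.
#' @return list with `registry`, `registry_file`, `truth`
#'   (cell_line / n_in_region).
#' @export
make_encode_fixture <- function(dir = tempfile("encode"), seed = 1L,
                                tf = "CEBPB",
                                cell_lines = c("HepG2", "K562", "A549",
                                               "IMR90"),
                                region = genomic_interval("chr17", 38.08e6,
                                                          38.12e6),
                                in_region_counts = c(6L, 3L, 2L, 4L),
                                n_decoys = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  in_region_counts <- rep_len(in_region_counts, length(cell_lines))
  rows <- list()
  for (i in seq_along(cell_lines)) {
    k <- in_region_counts[i]
    in_start <- sort(sample(seq(region$start, region$end - 500L), k))
    dec_start <- sort(sample(seq(region$end + 1e5, region$end + 5e5),
                             n_decoys))
    starts <- c(in_start, dec_start)
    pk <- data.frame(chrom = region$chrom, start = starts,
                     end = starts + sample(200:400, length(starts),
                                           replace = TRUE),
                     name = sprintf("%s_%s_pk%02d", cell_lines[i], tf,
                                    seq_along(starts)),
                     score = sample(100:1000, length(starts), replace = TRUE),
                     strand = ".",
                     signalValue = round(stats::runif(length(starts), 1, 20), 2),
                     pValue = -1, qValue = -1,
                     peak = sample(50:150, length(starts), replace = TRUE),
                     stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("%s_%s.narrowPeak", cell_lines[i], tf))
    write_narrowpeak(pk, f)
    rows[[i]] <- data.frame(cell_line = cell_lines[i], tf_hgnc = tf,
                            peak_file = f, stringsAsFactors = FALSE)
  }
  reg <- encode_registry(do.call(rbind, rows))
  rf <- file.path(dir, "registry.tsv")
  data.table::fwrite(as.data.frame(reg), rf, sep = "\t", quote = FALSE)
  list(registry = reg, registry_file = rf,
       truth = data.frame(cell_line = cell_lines, n_in_region = in_region_counts,
                          stringsAsFactors = FALSE))
}

#' Generate a GWAS-catalog table with planted trait links
#'
#' Plants (trait, gene) association records — `planted` rows become records
#' whose `MAPPED_GENE` contains the gene (a third of them inside multi-gene
#' fields with mixed delimiters) — and pads with noise records over decoy
#' genes.  The per-trait record counts for any target-gene set, and the
#' direct-hit answers, follow exactly from `planted`.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param planted data.frame with columns `trait` and `gene`; one GWAS
#'   record is emitted per row.
#' @param n_noise number of decoy records appended.
#' @param chrom chromosome id used for all records.
#' @return list with `gwas` (a [gwas_catalog()]), `file`, and `planted`.
#' @export
make_gwas_table <- function(dir = tempfile("gwas"), seed = 1L,
                            planted = data.frame(
                              trait = c("Trait A", "Trait A", "Trait B"),
                              gene = c("G0001", "G0002", "G0001"),
                              stringsAsFactors = FALSE),
                            n_noise = 15L, chrom = "17") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  decoys <- sprintf("NOISE%03d", seq_len(max(1L, n_noise)))
  mk_field <- function(gene, i) {
    style <- i %% 3L
    if (style == 0L) gene
    else if (style == 1L) paste(gene, decoys[(i %% length(decoys)) + 1L],
                                sep = " - ")
    else paste(decoys[(i %% length(decoys)) + 1L], gene, sep = "; ")
  }
  prows <- lapply(seq_len(nrow(planted)), function(i)
    data.frame(`DISEASE.TRAIT` = planted$trait[i],
               MAPPED_GENE = mk_field(planted$gene[i], i),
               SNPS = sprintf("rs%07d", sample(1e6:9e6, 1L)),
               CHR_ID = chrom,
               CHR_POS = as.character(sample(1e6:8e7, 1L)),
               check.names = FALSE, stringsAsFactors = FALSE))
  nrows <- lapply(seq_len(n_noise), function(i)
    data.frame(`DISEASE.TRAIT` = sprintf("Noise trait %02d", (i %% 5L) + 1L),
               MAPPED_GENE = decoys[(i %% length(decoys)) + 1L],
               SNPS = sprintf("rs%07d", sample(1e6:9e6, 1L)),
               CHR_ID = chrom,
               CHR_POS = as.character(sample(1e6:8e7, 1L)),
               check.names = FALSE, stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(prows, nrows))
  f <- file.path(dir, "gwas.tsv")
  data.table::fwrite(tab, f, sep = "\t", quote = FALSE)
  list(gwas = gwas_catalog(f), file = f, planted = planted)
}
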