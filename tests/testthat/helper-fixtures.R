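# shared helpers: small on-disk catalog snapshots built in code

write_cisbp_tsv <- function(path, tf_names, families = NULL, ids = NULL) {
  n <- length(tf_names)
  if (is.null(families)) families <- rep("FamA", n)
  if (is.null(ids)) ids <- sprintf("T%06d_1.02", seq_len(n))
  tab <- data.frame(TF_ID = ids, TF_Name = tf_names, Family_Name = families,
                    TF_Species = "Homo_sapiens", stringsAsFactors = FALSE)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  path
}

write_hocomoco_tsv <- function(path, tfs, classes = NULL) {
  n <- length(tfs)
  if (is.null(classes)) classes <- rep("HOX-related factors{3.1.1}", n)
  tab <- data.frame(Model = paste0(tfs, "_HUMAN.H11MO.0.A"),
                    `Transcription factor` = tfs,
                    `Model length` = 10L, Quality = "A", Rank = seq_len(n),
                    `TF class` = classes, `TF family` = "f",
                    `Data source` = "t", Species = "Homo sapiens",
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  path
}

simple_catalog <- function(name, symbols, families = NULL) {
  if (is.null(families)) families <- rep("FamA", length(symbols))
  TFCatalog(name, symbols,
            data.frame(HGNC = symbols, Family_Name = families,
                       stringsAsFactors = FALSE))
}

# independent overlap oracle: per-symbol membership enumeration
brute_overlap <- function(catalogs) {
  nms <- vapply(catalogs, tfkit::catalog_name, character(1))
  unis <- lapply(catalogs, tfkit::hgnc_universe)
  syms <- unique(unlist(unis))
  sigs <- vapply(syms, function(s)
    paste(sort(nms[vapply(unis, function(u) s %in% u, logical(1))]),
          collapse = "&"), character(1))
  tab <- sort(table(sigs), decreasing = TRUE)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

# independent scan oracle over an in-memory site table
brute_hits <- function(sites, interval) {
  keep <- sites$chrom == interval$chrom & sites$start < interval$end &
    sites$end > interval$start
  out <- sites[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

random_interval <- function(chrom = "chr17", span = c(38.0e6, 38.2e6)) {
  s <- sample(seq(span[1] - 5e4, span[2] + 5e4), 1L)
  genomic_interval(chrom, s, s + sample(c(50, 500, 5e3, 3e4), 1L))
}
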