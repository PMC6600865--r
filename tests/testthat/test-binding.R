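test_that("interval construction and 1-based region parsing enforce half-open bounds", {
  iv <- genomic_interval("chr17", 100, 200)
  expect_equal(iv$start, 100)
  expect_error(genomic_interval("chr17", 200, 100), "invalid interval")
  expect_error(genomic_interval("chr17", -1, 10), "invalid interval")
  reg <- parse_region("chr17:38077001-38084000")
  expect_equal(reg$chrom, "chr17")
  expect_equal(reg$start, 38077000)   # 1-based inclusive -> 0-based half-open
  expect_equal(reg$end, 38084000)
  expect_error(parse_region("chr17 38077001"), "cannot parse")
})

test_that("score transform is -log10 with a finite cap at p = 0", {
  expect_equal(as.numeric(neglog10p(0.001)), 3.0)
  capped <- neglog10p(c(0, 0.1))
  expect_equal(as.numeric(capped), c(400, 1))
  expect_equal(attr(capped, "capped"), c(TRUE, FALSE))
  # monotone decreasing in p
  p <- sort(10^runif(50, -8, 0))
  expect_true(all(diff(as.numeric(neglog10p(p))) <= 0))
})

test_that("indexed track queries equal the linear scan and the in-memory oracle", {
  trk <- make_scored_track(withr::local_tempdir(), seed = 13, n_files = 3,
                           sites_per_file = 250, n_probes = 3)
  set.seed(14)
  for (i in seq_along(trk$tracks$files)) {
    for (rep in 1:8) {
      iv <- random_interval()
      indexed <- query_track(trk$tracks$files[i], iv)
      linear <- query_track(trk$plain_files[i], iv)
      expect_identical(indexed, linear)
      oracle <- brute_hits(trk$sites[[i]], iv)
      expect_equal(indexed$start, as.numeric(oracle$start))
      expect_equal(indexed$pvalue, oracle$pvalue)
      # results sorted, in-bounds, with the derived score attached
      expect_true(!is.unsorted(indexed$start))
      expect_true(all(indexed$start < iv$end & indexed$end > iv$start))
      expect_equal(indexed$neglog10p, -log10(indexed$pvalue))
    }
  }
})

test_that("queries off the data return empty frames, not errors", {
  trk <- make_scored_track(withr::local_tempdir(), seed = 15, n_files = 1,
                           sites_per_file = 50)
  up <- query_track(trk$tracks$files[1], genomic_interval("chr17", 0, 100))
  expect_equal(nrow(up), 0L)
  other <- query_track(trk$tracks$files[1],
                       genomic_interval("chrZ", 0, 1e9))
  expect_equal(nrow(other), 0L)
  expect_named(other, c("chrom", "start", "end", "motif_id", "score",
                        "strand", "pvalue", "neglog10p"))
})

test_that("a corrupt index falls back to the linear scan with a warning", {
  trk <- make_scored_track(withr::local_tempdir(), seed = 16, n_files = 1,
                           sites_per_file = 60)
  gz <- trk$tracks$files[1]
  writeBin(as.raw(1:32), paste0(gz, ".tbi"))   # clobber the index
  iv <- trk$probes[[1]]
  expect_warning(hits <- query_track(gz, iv), "linear scan")
  expect_identical(hits, query_track(trk$plain_files[1], iv))
})

test_that("reduce_by_file yields the file-by-interval cross product of single queries", {
  trk <- make_scored_track(withr::local_tempdir(), seed = 17, n_files = 3,
                           sites_per_file = 120, n_probes = 2)
  res <- reduce_by_file(trk$tracks, trk$probes[1:2])
  expect_length(res, 3L)
  expect_equal(names(res), basename(trk$tracks$files))
  for (i in 1:3) {
    expect_length(res[[i]], 2L)
    for (j in 1:2)
      expect_identical(res[[i]][[j]],
                       query_track(trk$tracks$files[i], trk$probes[[j]]))
  }
  # map_fn applied per cell; its errors carry the file identity
  counts <- reduce_by_file(trk$tracks, trk$probes[1:2], map_fn = nrow)
  expect_equal(counts[[2]][[1]],
               nrow(query_track(trk$tracks$files[2], trk$probes[[1]])))
  expect_error(reduce_by_file(trk$tracks, trk$probes[1],
                              map_fn = function(x) stop("boom")),
               basename(trk$tracks$files[1]))
})

test_that("a 16-file track set keeps metadata order through reduce_by_file", {
  trk <- make_scored_track(withr::local_tempdir(), seed = 18, n_files = 16,
                           sites_per_file = 40, n_probes = 1)
  res <- reduce_by_file(trk$tracks, trk$probes[1])
  expect_length(res, 16L)
  expect_equal(names(res), basename(trk$tracks$files))
})

test_that("family annotation copies the first catalog occurrence per symbol", {
  cat <- TFCatalog("c", c("m1", "m2", "m3"),
                   data.frame(HGNC = c("TP53", "TP53", "YY1"),
                              Family_Name = c("p53", "p53-alt", "C2H2 ZF")))
  ts <- binding_track_set(c("f1", "f2", "f3"),
                          data.frame(Mtag = c("M1", "M2", "M3"),
                                     HGNC = c("TP53", "YY1", "ABSENT")))
  md <- annotate_family(ts, cat)
  expect_equal(md$family, c("p53", "C2H2 ZF", NA))
  expect_error(annotate_family(ts, cat, "Missing_Col"), "Missing_Col")
})

test_that("narrowPeak reading applies BED6+4 semantics and round-trips", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr17\t100\t200\tp1\t0\t.\t5.5\t-1\t-1\t50", f)
  pk <- read_narrowpeak(f)
  expect_equal(pk$start, 100)
  expect_equal(pk$end, 200)
  expect_equal(pk$peak, 50)
  expect_equal(pk$signalValue, 5.5)
  file.create(f2 <- withr::local_tempfile())
  expect_equal(nrow(read_narrowpeak(f2)), 0L)
  writeLines("chr17\t100\t200", f3 <- withr::local_tempfile())
  expect_error(read_narrowpeak(f3), "10 columns")
  # 25-peak write/read round trip
  set.seed(19)
  starts <- sort(sample(1:1e6, 25))
  peaks <- data.frame(chrom = "chr2", start = starts, end = starts + 300,
                      name = sprintf("p%02d", 1:25), score = 0, strand = ".",
                      signalValue = round(runif(25), 3), pValue = -1,
                      qValue = -1, peak = 150L)
  f4 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(peaks, f4)
  back <- read_narrowpeak(f4)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$name, peaks$name)
})

test_that("per-experiment peak retrieval recovers planted in-region counts", {
  enc <- make_encode_fixture(withr::local_tempdir(), seed = 20,
                             in_region_counts = c(6L, 3L, 2L, 4L))
  region <- genomic_interval("chr17", 38.08e6, 38.12e6)
  res <- peaks_in_region(enc$registry, "CEBPB", region)
  expect_length(res, 4L)
  expect_equal(unname(vapply(res, nrow, integer(1))),
               enc$truth$n_in_region)
  # region on an unused chromosome: same groups, all empty
  res0 <- peaks_in_region(enc$registry, "CEBPB",
                          genomic_interval("chr9", 1, 1000))
  expect_length(res0, 4L)
  expect_true(all(vapply(res0, nrow, integer(1)) == 0L))
  # restrict to one cell line
  res1 <- peaks_in_region(enc$registry, "CEBPB", region,
                          cell_lines = "HepG2")
  expect_length(res1, 1L)
  # absent TF: empty with a notice, not an error
  expect_message(none <- peaks_in_region(enc$registry, "NOPE", region),
                 "no registry experiments")
  expect_length(none, 0L)
})

test_that("missing peak files are reported per experiment, not dropped", {
  enc <- make_encode_fixture(withr::local_tempdir(), seed = 22,
                             cell_lines = c("HepG2", "K562"),
                             in_region_counts = c(2L, 3L))
  file.remove(enc$registry$peak_file[1])
  region <- genomic_interval("chr17", 38.08e6, 38.12e6)
  expect_warning(res <- peaks_in_region(enc$registry, "CEBPB", region),
                 "missing")
  expect_length(res, 2L)
  expect_null(res[[1]])
  expect_equal(nrow(res[[2]]), 3L)
})

test_that("the harvest table carries symbol and family for every hit", {
  dir <- withr::local_tempdir()
  trk <- make_scored_track(dir, seed = 23, n_files = 4, sites_per_file = 80)
  cat <- TFCatalog("c", trk$metadata$Mtag,
                   data.frame(HGNC = trk$metadata$HGNC,
                              Family_Name = rep(c("f1", "f2"), 2)))
  iv <- genomic_interval("chr17", 38.0e6, 38.2e6)
  tab <- harvest_scores(trk$tracks, iv, cat)
  expect_equal(nrow(tab), 4 * 80)
  expect_named(tab, c("chrom", "start", "end", "motif_id", "neglog10p",
                      "HGNC", "family"))
  expect_setequal(unique(tab$HGNC), trk$metadata$HGNC)
  expect_false(any(is.na(tab$family)))
})
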