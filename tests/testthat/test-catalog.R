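test_that("CISBP-schema loading keeps row order, duplicates, and the id->symbol map", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # 40 unique symbols, first 10 repeated once -> 50 records
  syms <- sprintf("GENE%02d", 1:40)
  write_cisbp_tsv(f, c(syms, syms[1:10]),
                  ids = c("T004843_1.02", sprintf("T%06d_1.02", 2:50)))
  cat <- load_cisbp_catalog(f)
  expect_s4_class(cat, "TFCatalog")
  expect_length(cat, 50L)
  expect_equal(native_ids(cat)[1], "T004843_1.02")
  expect_equal(hgnc_map(cat)$HGNC[1], "GENE01")
  expect_setequal(hgnc_universe(cat), syms)
  expect_length(hgnc_universe(cat), 40L)
})

test_that("loaders reject empty and mis-schema'd files with named columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("TF_ID\tTF_Name\tFamily_Name", f)
  expect_error(load_cisbp_catalog(f), "empty catalog")
  writeLines(c("TF_ID\tFoo", "T1\tx"), f)
  expect_error(load_cisbp_catalog(f), "TF_Name")
  expect_error(load_cisbp_catalog(tempfile("nope")), "not found")
})

test_that("HOCOMOCO-schema loading retains class strings verbatim", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cls <- c("More than 3 adjacent zinc finger factors{2.3.3}",
           "HOX-related factors{3.1.1}", "Homeodomain")
  write_hocomoco_tsv(f, c("ZNF1", "HOXA1", "PAX1"), cls)
  cat <- load_hocomoco_catalog(f)
  expect_equal(hgnc_map(cat)[["TF class"]], cls)
  expect_equal(native_ids(cat), paste0(c("ZNF1", "HOXA1", "PAX1"),
                                       "_HUMAN.H11MO.0.A"))
  # single-row file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_hocomoco_tsv(f2, "GATA3")
  cat2 <- load_hocomoco_catalog(f2)
  expect_length(cat2, 1L)
  expect_length(hgnc_universe(cat2), 1L)
})

test_that("header rename map accommodates variant snapshot spellings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(Model = "A_X", TF = "A", L = 1, Q = "A", R = 1,
                    Class = "Homeodomain", Fam = "f", Src = "s",
                    Sp = "Hs", stringsAsFactors = FALSE)
  data.table::fwrite(tab, f, sep = "\t", quote = FALSE)
  cat <- load_hocomoco_catalog(
    f, rename = c("Transcription factor" = "TF", "TF class" = "Class"))
  expect_equal(hgnc_universe(cat), "A", ignore_attr = TRUE)
})

test_that("GO catalog takes only direct annotations to the requested term", {
  tab <- data.frame(SYMBOL = c("TP53", "ACTB"),
                    GO = c("GO:0003700", "GO:0005515"))
  cat <- load_go_catalog(tab)
  expect_equal(hgnc_universe(cat), "TP53", ignore_attr = TRUE)
  expect_warning(empty <- load_go_catalog(tab, go_id = "GO:9999999"),
                 "empty catalog")
  expect_length(empty, 0L)
  # 30 planted among 100 rows, order-insensitive recovery
  planted <- sprintf("TFP%02d", 1:30)
  big <- data.frame(SYMBOL = c(planted, sprintf("OTH%02d", 1:70)),
                    GO = c(rep("GO:0003700", 30), rep("GO:0008150", 70)))
  big <- big[sample(nrow(big)), ]
  expect_setequal(hgnc_universe(load_go_catalog(big)), planted)
})

test_that("the HGNC universe deduplicates and reports blanks", {
  cat <- TFCatalog("t", c("a", "b", "c"),
                   data.frame(HGNC = c("A", "A", "B")))
  expect_equal(hgnc_universe(cat), c("A", "B"), ignore_attr = TRUE)
  cat2 <- TFCatalog("t", c("a", "b", "c"),
                    data.frame(HGNC = c("A", "", " B ")))
  u <- hgnc_universe(cat2)
  expect_equal(as.character(u), c("A", "B"))
  expect_equal(attr(u, "n_blank"), 1L)
})

test_that("TFCatalog enforces its structural invariants", {
  expect_error(TFCatalog("", "a", data.frame(HGNC = "A")), "non-empty")
  expect_error(TFCatalog("x", c("a", "b"), data.frame(HGNC = "A")),
               "native_ids")
  expect_error(TFCatalog("x", "a", data.frame(Symbol = "A")), "HGNC")
})

test_that("overlap counts match exhaustive per-symbol enumeration and conserve the union", {
  set.seed(42)
  pools <- list(A = sprintf("S%03d", 1:60), B = sprintf("S%03d", 31:90),
                C = sprintf("S%03d", c(1:10, 81:120)))
  cats <- Map(simple_catalog, names(pools), pools)
  oc <- overlap_counts(unname(cats))
  oracle <- brute_overlap(unname(cats))
  expect_equal(oc[order(oc$region), c("region", "count")],
               oracle[order(oracle$region), c("region", "count")],
               ignore_attr = TRUE)
  expect_equal(sum(oc$count),
               length(unique(unlist(lapply(cats, hgnc_universe)))))
  # permutation invariance
  oc2 <- overlap_counts(unname(cats)[c(3, 1, 2)])
  expect_equal(oc[order(oc$region), ], oc2[order(oc2$region), ],
               ignore_attr = TRUE)
})

test_that("overlap of identical catalogs is pure intersection; duplicate names refused", {
  c1 <- simple_catalog("X", c("A", "B", "C"))
  c2 <- simple_catalog("Y", c("A", "B", "C"))
  oc <- overlap_counts(list(c1, c2))
  expect_equal(nrow(oc), 1L)
  expect_equal(oc$region, "X&Y")
  expect_equal(oc$count, 3L)
  expect_error(overlap_counts(list(c1, simple_catalog("X", "A"))),
               "duplicate")
})

test_that("class frequencies count each TF once per class, ranked with lexicographic ties", {
  cat <- TFCatalog("t", sprintf("m%d", 1:7),
                   data.frame(HGNC = c("A", "A", "A", "B", "C", "D", "E"),
                              Fam = c("zf", "zf", "zf", "zf", "hd", "hd", "ab")))
  cf <- class_frequency(cat, "Fam")
  expect_equal(cf$class, c("hd", "zf", "ab"))   # tie at 2 broken A-to-Z
  expect_equal(cf$n_tfs, c(2L, 2L, 1L))
  # one TF in 5 rows of one class -> 1
  cat2 <- TFCatalog("t", sprintf("m%d", 1:5),
                    data.frame(HGNC = rep("A", 5), Fam = rep("zf", 5)))
  expect_equal(class_frequency(cat2, "Fam")$n_tfs, 1L)
  expect_error(class_frequency(cat2, "Nope"), "schema")
  # planted distinct counts vs a brute-force group-and-count
  set.seed(9)
  n <- 200
  tab <- data.frame(HGNC = sample(sprintf("T%02d", 1:40), n, replace = TRUE),
                    Fam = sample(c("f1", "f2", "f3"), n, replace = TRUE))
  cat3 <- TFCatalog("t", sprintf("m%d", 1:n), tab)
  cf3 <- class_frequency(cat3, "Fam")
  oracle <- sapply(split(tab$HGNC, tab$Fam), function(x) length(unique(x)))
  expect_equal(cf3$n_tfs[match(names(oracle), cf3$class)],
               unname(as.integer(oracle)))
})

test_that("TFClass suffix parsing splits dotted subfamilies and round-trips", {
  p <- parse_tfclass_label("More than 3 adjacent zinc finger factors{2.3.3}")
  expect_equal(p$label, "More than 3 adjacent zinc finger factors")
  expect_equal(p$subfamily_id, "2.3.3")
  expect_equal(parse_tfclass_label("HOX-related factors{3.1.1}")$subfamily_id,
               "3.1.1")
  plain <- parse_tfclass_label("Homeodomain")
  expect_true(is.na(plain$subfamily_id))
  expect_equal(plain$label, "Homeodomain")
  expect_warning(bad <- parse_tfclass_label("Weird{x.y}"), "malformed")
  expect_true(bad$malformed)
  expect_equal(bad$label, "Weird{x.y}")
  # reconstruction property over generated well-formed labels
  set.seed(11)
  for (i in 1:50) {
    lab <- paste(sample(letters, 8), collapse = "")
    sub <- paste(sample(0:20, sample(1:3, 1)), collapse = ".")
    raw <- paste0(lab, "{", sub, "}")
    q <- parse_tfclass_label(raw)
    expect_identical(paste0(q$label, "{", q$subfamily_id, "}"), raw)
  }
})
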