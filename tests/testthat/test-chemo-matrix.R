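test_that("packaged detection tables load with the printed dimensions", {
  eup <- read_detection_table(chemo_example("detections_eupnoi.csv"))
  expect_s3_class(eup, "detection_matrix")
  expect_equal(dim(eup$states), c(40L, 10L))
  dys <- read_detection_table(chemo_example("detections_dyspnoi.csv"))
  expect_equal(nrow(dys$states), 33L)
  lc <- read_detection_table(
    chemo_example("detections_laniatores_cyphophthalmi.csv"))
  expect_equal(nrow(lc$states), 12L)
  expect_true(all(eup$states %in% detection_states()))
})

test_that("malformed detection tables are rejected with informative errors", {
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_detection_table(empty), "empty")

  bad_symbol <- tiny_detection_csv(c("taxon,NQ,BQ", "SpA,D,x"))
  expect_error(read_detection_table(bad_symbol), "SpA.*BQ|BQ.*SpA")

  ragged <- tiny_detection_csv(c("taxon,NQ,BQ", "SpA,D,N", "SpB,D"))
  expect_error(read_detection_table(ragged), "row 2")

  unknown <- tiny_detection_csv(c("taxon,NQ,XYZ", "SpA,D,N"))
  expect_error(read_detection_table(unknown), "XYZ")

  dup <- tiny_detection_csv(c("taxon,NQ", "SpA,D", "SpA,N"))
  expect_error(read_detection_table(dup), "duplicate")
})

test_that("binarize applies the default quinone coding policy", {
  dm <- opiliones_detections()
  cm <- binarize(dm)
  # one positively detected benzoquinone, no naphthoquinone evidence
  expect_equal(unname(cm["Megabunus_armatus", c("NQ_class", "BQ_class")]),
               c("absent", "present"))
  # all not_detected row
  expect_equal(unname(cm["Mitostoma_chrysomelas", ]), c("absent", "absent"))
  # all inconclusive row carries no evidence either way
  expect_equal(unname(cm["Odiellus_sp", ]), c("missing", "missing"))
  # partial detections are positive evidence
  expect_equal(unname(cm["Nemastoma_dentigerum", "NQ_class"]), "present")
  # "-" (data missing) cells leave the benzoquinone character missing
  expect_equal(unname(cm["Opilio_ruzickai", "BQ_class"]), "missing")
  # anthraquinones are not part of the default characters
  expect_false("AQ_class" %in% colnames(cm))
  cm3 <- binarize(dm, default_coding_policy(include_anthraquinones = TRUE))
  expect_equal(unname(cm3["Paranemastoma_bicuspidatum", "AQ_class"]),
               "present")
})

test_that("per-taxon class coding matches a cell-by-cell scan of the raw table", {
  dm <- opiliones_detections()
  cm <- binarize(dm)
  nq_codes <- c("NQ", "MNQ", "MOQ", "MMOQ", "ND", "CNQ")
  for (tx in rownames(dm$states)) {
    row <- dm$states[tx, nq_codes]
    expect_equal(cm[tx, "NQ_class"] == "present",
                 any(row %in% c("detected", "partial")),
                 info = tx)
  }
})

test_that("binarize is deterministic and permutation-invariant", {
  dm <- opiliones_detections()
  cm1 <- binarize(dm)
  cm2 <- binarize(dm)
  expect_identical(cm1, cm2)
  perm <- dm
  ridx <- rev(seq_len(nrow(dm$states)))
  cidx <- rev(seq_len(ncol(dm$states)))
  perm$states <- dm$states[ridx, cidx]
  cmp <- binarize(perm)
  expect_identical(cmp[rownames(cm1), colnames(cm1)], unclass(cm1)[, ])
})

test_that("a policy naming an absent compound code is a configuration error", {
  dm <- read_detection_table(chemo_example("detections_eupnoi.csv"))
  bad <- coding_policy(list(X_class = c("NQ", "NOPE")))
  expect_error(binarize(dm, bad), "NOPE")
})

test_that("summaries equal a brute-force scan and respect filters", {
  dm <- opiliones_detections()
  s <- summarize_detections(dm, suborder = c("Eupnoi", "Dyspnoi"))
  # brute force over the raw cells
  pal <- dm$lineage$taxon[dm$lineage$suborder %in% c("Eupnoi", "Dyspnoi")]
  raw <- dm$states[rownames(dm$states) %in% pal, ]
  expect_equal(s$n_compounds_positive,
               sum(apply(raw, 2, function(col)
                 any(col %in% c("detected", "partial")))))
  expect_equal(s$n_taxa, length(pal))

  # counts are invariant to taxon ordering
  perm <- dm
  perm$states <- dm$states[rev(seq_len(nrow(dm$states))), ]
  s2 <- summarize_detections(perm, suborder = c("Eupnoi", "Dyspnoi"))
  expect_equal(s2$taxa_per_compound[names(s$taxa_per_compound)],
               s$taxa_per_compound)

  # all-not_detected slice supports nothing
  s0 <- summarize_detections(dm, genus = "Leiobunum")
  expect_equal(s0$n_compounds_positive, 0L)

  expect_error(summarize_detections(dm, genus = "NoSuchGenus"),
               "NoSuchGenus")
  expect_error(summarize_detections(dm, states = "sighted"), "sighted")
})

test_that("character matrices round-trip through NEXUS and CSV", {
  cm <- binarize(opiliones_detections())
  nex <- tempfile(fileext = ".nex")
  write_character_nexus(cm, nex)
  back <- ape::read.nexus.data(nex)
  expect_equal(length(back), nrow(cm))
  sym <- c(present = "1", absent = "0", missing = "?")
  expect_equal(unlist(back[["Megabunus_armatus"]], use.names = FALSE),
               unname(sym[cm["Megabunus_armatus", ]]))
  csv <- tempfile(fileext = ".csv")
  write_character_csv(cm, csv)
  df <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(df$NQ_class[match("Phalangium_opilio", df$taxon)], "present")
})
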