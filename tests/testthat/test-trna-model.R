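test_that("the packaged model defines all 22 genes with validated structure", {
  expect_length(model$genes, 22)
  expect_s3_class(model, "trna_model")
  # spans cover each gene exactly once and do not overlap
  sp <- model$spans[order(model$spans$start), ]
  expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
  # light-strand gene set
  light <- names(Filter(function(g) g$strand == "light", model$genes))
  expect_setequal(light, c("MT-TQ", "MT-TA", "MT-TN", "MT-TC", "MT-TY",
                           "MT-TS1", "MT-TE", "MT-TP"))
  for (g in model$genes) {
    # pairing symmetric and involutive
    paired <- !is.na(g$partner)
    expect_true(all(g$partner[g$partner[paired]] == names(g$partner)[paired]),
                info = g$gene)
    # paired positions are stem elements, stems pair completely (even size)
    expect_true(all(g$element[paired] %in%
                      c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")),
                info = g$gene)
    stems <- names(g$element)[g$element %in%
                                c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")]
    expect_true(all(!is.na(g$partner[stems])), info = g$gene)
    expect_true(length(stems) %% 2 == 0, info = g$gene)
    # numbering injective, element map total
    expect_false(anyDuplicated(g$labels) > 0, info = g$gene)
    expect_true(all(g$labels %in% names(g$element)), info = g$gene)
  }
})

test_that("corrupted definition files are rejected with the gene named", {
  stab <- readLines(mt_extdata("mt_trna_structure_synthetic.tsv"))
  # break pairing symmetry: make MT-TT position 25 point to an unpaired label
  bad <- sub("^MT-TT\t25\td_stem\t10", "MT-TT\t25\td_stem\t14", stab)
  tf <- tempfile(fileext = ".tsv"); writeLines(bad, tf)
  expect_error(load_trna_model(structure_file = tf), "MT-TT")

  gtab <- readLines(mt_extdata("mt_trna_genes.tsv"))
  expect_error(
    load_trna_model(genes_file = textConnection(gtab[!grepl("^MT-TM\t", gtab)])),
    "MT-TM")
})

test_that("locate_position reproduces the reported gene, position and element", {
  loc <- locate_position(golden$position, model)
  expect_equal(loc$gene, golden$gene)
  expect_equal(loc$trna_position, as.character(golden$trna_position))
  keep <- !(golden$position %in% LOCATION_EXCEPTIONS)
  expect_equal(loc$element[keep], normalize_element(golden$location[keep]))
})

test_that("locate_position agrees with a brute-force span scan", {
  set.seed(42)
  pos <- sample.int(16569, 10000)
  loc <- locate_position(pos, model)
  sp <- model$spans
  brute <- vapply(pos, function(p) {
    hit <- sp$gene[sp$start <= p & p <= sp$end]
    if (length(hit)) hit else NA_character_
  }, character(1))
  expect_equal(loc$gene, brute)
  # non-tRNA coordinates are a distinguished NA result, not an error
  expect_true(is.na(locate_position(5000, model)$gene))
  expect_error(locate_position(0, model), "1\\.\\.16569")
  expect_error(locate_position(16570, model), "1\\.\\.16569")
})

test_that("tRNA-strand bases complement light-strand genes and use U", {
  expect_equal(trna_strand_base(model$genes[["MT-TT"]], "C"), "C")
  expect_equal(trna_strand_base(model$genes[["MT-TT"]], "T"), "U")
  expect_equal(trna_strand_base(model$genes[["MT-TP"]], "A"), "U")
  expect_equal(trna_strand_base(model$genes[["MT-TQ"]], "G"), "C")
  expect_equal(trna_strand_base(model$genes[["MT-TQ"]], c("A", "C")), c("U", "G"))
  expect_error(trna_strand_base(model$genes[["MT-TT"]], "N"), "A,C,G,T")
})

test_that("pairing partners exist for stems and not for loops or termini", {
  w49 <- pairing_partner(model$genes[["MT-TW"]], "49")
  expect_false(is.na(w49))
  expect_equal(model$genes[["MT-TW"]]$element[[w49]], "t_stem")
  expect_true(is.na(pairing_partner(model$genes[["MT-TM"]], "55")))
  expect_true(is.na(pairing_partner(model$genes[["MT-TA"]], "73")))
  expect_error(pairing_partner(model$genes[["MT-TA"]], "99"), "unknown")
})

test_that("cloverleaf rendering marks highlights inside the right element", {
  r <- render_cloverleaf(model$genes[["MT-TT"]], "25")
  expect_true(grepl("\\[25", r[grepl("d_stem", r)]))
  r2 <- render_cloverleaf(model$genes[["MT-TP"]], "34")
  expect_true(grepl("\\[34", r2[grepl("anticodon_loop", r2)]))
  r3 <- render_cloverleaf(model$genes[["MT-TP"]])
  expect_false(any(grepl("\\[", r3)))
  expect_error(render_cloverleaf(model$genes[["MT-TP"]], "999"), "unknown")
  # every position appears exactly once across element blocks
  g <- model$genes[["MT-TN"]]
  body <- paste(render_cloverleaf(g), collapse = " ")
  for (lbl in g$labels) {
    expect_equal(lengths(regmatches(body, gregexpr(
      paste0("(^| |\\[)", lbl, "[ACGU]"), body))), 1, info = lbl)
  }
})

test_that("element synonym normalization covers the reported vocabulary", {
  expect_equal(
    normalize_element(c("ACC-stem", "ACC stem", "ACC terminus", "DHU-stem",
                        "D-stem", "DHU-loop", "D-loop", "AC stem",
                        "Anticodon stem", "AC loop", "Anticodon loop",
                        "T-stem", "T-loop", "Variable loop", "D-A junction")),
    c("acceptor_stem", "acceptor_stem", "acceptor_terminus", "d_stem",
      "d_stem", "d_loop", "d_loop", "anticodon_stem", "anticodon_stem",
      "anticodon_loop", "anticodon_loop", "t_stem", "t_loop",
      "variable_loop", "junction"))
  expect_error(normalize_element("inner loop"), "unrecognized")
})
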