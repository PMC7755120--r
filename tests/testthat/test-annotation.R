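ann_one <- function(position, ref, alt, ci,
                    case_carriers = 1, control_carriers = 0) {
  annotate_variants(
    data.frame(position = position, ref = ref, alt = alt,
               case_carriers = case_carriers,
               control_carriers = control_carriers, ci = ci),
    model = model)
}

test_that("annotation fills gene, tRNA bases, element and pairing effect", {
  a <- ann_one(4452, "T", "C", 100)
  expect_equal(a$gene, "MT-TM")
  expect_equal(a$trna_position, "55")
  expect_equal(a$element, "t_loop")
  expect_equal(a$wc_status, "not_applicable")
  expect_equal(a$trna_ref, "U")

  b <- ann_one(5558, "A", "G", 100)
  expect_equal(b$gene, "MT-TW")
  expect_equal(b$trna_position, "49")
  expect_equal(b$element, "t_stem")
  expect_equal(b$wc_status, "disrupts_pair")
  expect_equal(b$wc_before, "A-U")

  # light-strand: heavy-strand A>G reads U>C on the tRNA
  p <- ann_one(15992, "A", "G", 100)
  expect_equal(p$gene, "MT-TP")
  expect_equal(c(p$trna_ref, p$trna_alt), c("U", "C"))

  expect_error(ann_one(16570, "A", "G", 100), "1\\.\\.16569")
  expect_error(ann_one(5000, "A", "G", 100), "not in any mt-tRNA")
  expect_error(
    annotate_variants(data.frame(position = 4452, ref = "T", alt = "C",
                                 case_carriers = 1, control_carriers = 0),
                      model = model),
    "no conservation source")
})

test_that("wc_effect distinguishes disruption, creation and no change", {
  # acceptor-stem A-U pair broken by A>G
  e <- wc_effect(model$genes[["MT-TG"]], "70", "A", "G")
  expect_equal(e$status, "disrupts_pair")
  expect_equal(e$before_pair, "A-U")
  # U-G wobble (non-WC here) resolved to C-G by U>C
  e2 <- wc_effect(model$genes[["MT-TV"]], "6", "U", "C")
  expect_equal(e2$status, "creates_pair")
  expect_equal(e2$after_pair, "C-G")
  # loop position
  e3 <- wc_effect(model$genes[["MT-TM"]], "55", "U", "C")
  expect_equal(e3$status, "not_applicable")
  expect_error(wc_effect(model$genes[["MT-TM"]], "99", "U", "C"), "unknown")
  expect_error(wc_effect(model$genes[["MT-TM"]], "55", "U", "X"), "A,C,G,U")
})

test_that("wc_effect of the reverse substitution is the inverse effect", {
  stems <- do.call(rbind, lapply(model$genes, function(g) {
    lbl <- names(g$element)[!is.na(g$partner)]
    data.frame(gene = g$gene, label = lbl, stringsAsFactors = FALSE)
  }))
  set.seed(11)
  pick <- stems[sample.int(nrow(stems), 60), ]
  for (i in seq_len(nrow(pick))) {
    g <- model$genes[[pick$gene[i]]]
    ref <- g$base[[pick$label[i]]]
    for (alt in setdiff(c("A", "C", "G", "U"), ref)) {
      fwd <- wc_effect(g, pick$label[i], ref, alt)$status
      rev <- wc_effect(g, pick$label[i], alt, ref)$status
      expected <- c(disrupts_pair = "creates_pair",
                    creates_pair = "disrupts_pair",
                    no_pair_change = "no_pair_change")[[fwd]]
      expect_equal(rev, expected, info = paste(pick$gene[i], pick$label[i], ref, alt))
    }
  }
})

test_that("structural impact needs a pairing change in stems and
           conservation or a tertiary site elsewhere", {
  # stem + disruption
  expect_true(ann_one(15950, "G", "A", 100)$impact)
  # conserved loop position at the 8-14 tertiary core
  d <- ann_one(12279, "A", "G", 100)
  expect_true(d$tertiary_site)
  expect_true(d$impact)
  # non-conserved loop with no tertiary site
  expect_false(ann_one(593, "T", "C", 29)$impact)
  # stem position whose reference pair is already non-WC and stays non-WC
  q <- ann_one(4394, "C", "T", 44)
  expect_equal(q$wc_status, "no_pair_change")
  expect_false(q$impact)
})

test_that("deletions get no WC call and qualify only via stem or tertiary site", {
  d <- ann_one(5878, "T", "del", 64)
  expect_equal(d$kind, "deletion")
  expect_equal(d$wc_status, "not_applicable")
  expect_true(d$tertiary_site)   # position 14, D-loop tertiary core
  expect_true(d$impact)
  # conserved loop deletion away from any tertiary/functional site
  d2 <- ann_one(636, "A", "del", 90)  # MT-TF 62, plain T-loop position
  expect_false(d2$tertiary_site)
  expect_false(d2$impact)
})

test_that("annotation is deterministic and idempotent", {
  v <- read_variants(mt_extdata("tic_cohort_variants.tsv"))
  a1 <- annotate_variants(v, model = model)
  a2 <- annotate_variants(v, model = model)
  expect_identical(a1, a2)
  # annotating an already-annotated frame changes nothing
  a3 <- annotate_variants(a1, model = model)
  expect_identical(a3[names(a1)], a1)
})

test_that("alignments override a supplied ci column when given", {
  g <- model$genes[["MT-TM"]]
  aln <- synth_alignment(g, target_ci = c("55" = 87.5), seed = 4)
  a <- annotate_variants(
    data.frame(position = 4452, ref = "T", alt = "C", case_carriers = 1,
               control_carriers = 0, ci = 10),
    model = model, alignments = list("MT-TM" = aln))
  expect_equal(a$ci, 87.5)
  expect_true(a$conserved)
})
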