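# Shared fixtures: the packaged structure model and the cohort screening
# table with its reported annotation columns (used as golden expectations).

model <- load_trna_model()

golden <- utils::read.delim(mt_extdata("tic_cohort_variants.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE)

# Rows where the reported table is internally inconsistent with its own
# printed tRNA positions/pairs (see the methods vignette); excluded from
# the corresponding golden comparisons.
LOCATION_EXCEPTIONS <- c(15924, 15927, 15928, 15932)
JUNCTION_ARROW_EXCEPTIONS <- c(7492, 16000)

run_golden_screen <- function(...) {
  screen(read_variants(mt_extdata("tic_cohort_variants.tsv")),
         n_cases = 494, n_controls = 485, model = model, ...)
}

# Independent brute-force conservation oracle: plain row counting on the
# alignment matrix, no package logic.
brute_ci <- function(aln, label, mode = "non_gap") {
  col <- aln$mat[, aln$column_map[[label]]]
  hb <- col[aln$human]
  other <- col[-aln$human]
  gap <- other %in% c("-", ".")
  n <- if (mode == "non_gap") sum(!gap) else length(other)
  if (n == 0) 0 else 100 * sum(other[!gap] == hb) / n
}
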