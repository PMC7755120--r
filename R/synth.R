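# Seeded synthetic-data generators: variant tables with known true tiers,
# per-gene alignments with prescribed per-column conservation, and cohorts
# with prescribed clinical margins.  Defaults emulate the study conditions
# of the packaged cohort screen: 494 cases, 485 controls, a 16-species
# alignment, and an 18/12/43 putative/rare-conserved/polymorphism mix over
# 73 variants.

trna_to_genomic_base <- function(gene, trna_base) {
  b <- ifelse(trna_base == "U", "T", trna_base)
  if (identical(gene$strand, "light")) b <- unname(comp_dna[b])
  b
}

genomic_position_of <- function(gene, label) {
  k <- match(label, gene$labels)
  if (gene$strand == "heavy") gene$start + k - 1L else gene$end - k + 1L
}

#' Generate a synthetic case/control variant table with known tiers
#'
#' Places variants at real mt-tRNA positions of the structure model and
#' draws conservation values and carrier counts so that each variant's
#' true screening tier is known by construction: putative variants are
#' conserved, absent from controls and impact-bearing (stem placements get
#' an allele chosen to disrupt or create a Watson-Crick pair); rare
#' conserved variants are conserved with control carriers strictly below
#' the frequency cutoff; polymorphisms are either non-conserved or
#' conserved-but-common.  Classification of the output by [screen()] is
#' deterministic given the generated attributes, so tier recovery is exact.
#'
#' @param n_variants number of variants to generate.
#' @param tier_mix named fractions over
#'   `putative_mutation`, `rare_conserved_variant`, `polymorphism`
#'   (must sum to 1; counts are rounded largest-remainder).
#' @param n_cases,n_controls cohort sizes.
#' @param model a `trna_model`.
#' @param seed integer seed; same seed, same output.
#' @param cutoff control frequency cutoff used to bound the rare range.
#' @param exclude_positions genomic positions to avoid (e.g. the packaged
#'   cohort table's positions, for collision-free mixing).
#' @return list with `variants` (data frame: position, ref, alt,
#'   case_carriers, control_carriers, ci) and `truth` (position, tier).
#' @export
synth_variants <- function(n_variants = 73,
                           tier_mix = c(putative_mutation = 18 / 73,
                                        rare_conserved_variant = 12 / 73,
                                        polymorphism = 43 / 73),
                           n_cases = 494, n_controls = 485,
                           model = default_model(), seed = 1,
                           cutoff = 0.01, exclude_positions = NULL) {
  tiers <- c("putative_mutation", "rare_conserved_variant", "polymorphism")
  if (!all(names(tier_mix) %in% tiers) || abs(sum(tier_mix) - 1) > 1e-9) {
    stop("tier_mix must be fractions over the three tiers summing to 1")
  }
  mix <- stats::setNames(rep(0, 3), tiers)
  mix[names(tier_mix)] <- tier_mix
  n_tier <- floor(mix * n_variants)
  rem <- n_variants - sum(n_tier)
  if (rem > 0) {
    o <- order(mix * n_variants - n_tier, decreasing = TRUE)
    n_tier[o[seq_len(rem)]] <- n_tier[o[seq_len(rem)]] + 1
  }
  max_rare <- ceiling(cutoff * n_controls) - 1
  if (n_tier[["rare_conserved_variant"]] > 0 && max_rare < 1) {
    stop("infeasible request: rare tier requested but cutoff*n_controls < 2")
  }
  set.seed(as.integer(seed))

  cand <- do.call(rbind, lapply(model$genes, function(g) {
    data.frame(gene = g$gene, label = g$labels,
               position = vapply(g$labels, function(l) genomic_position_of(g, l),
                                 integer(1)),
               stringsAsFactors = FALSE)
  }))
  cand <- cand[!(cand$position %in% exclude_positions), ]
  if (nrow(cand) < n_variants) stop("not enough candidate positions")
  pick <- cand[sample.int(nrow(cand), n_variants), ]
  tier <- rep(tiers, times = n_tier)

  out <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    g <- model$genes[[pick$gene[i]]]
    lbl <- pick$label[i]
    tref <- g$base[[lbl]]
    partner <- g$partner[[lbl]]
    stem <- !is.na(partner)
    talt <- if (stem) {
      pb <- g$base[[partner]]
      if (is_wc_pair(tref, pb)) {
        sample(setdiff(c("A", "C", "G", "U"), tref), 1)   # any change disrupts
      } else {
        unname(comp_rna[pb])                               # creates a WC pair
      }
    } else {
      sample(setdiff(c("A", "C", "G", "U"), tref), 1)
    }
    ci <- switch(tier[i],
      putative_mutation = sample(76:100, 1),
      rare_conserved_variant = sample(76:100, 1),
      polymorphism = if (stats::runif(1) < 0.85) sample(5:75, 1) else sample(76:100, 1))
    ctrl <- switch(tier[i],
      putative_mutation = 0L,
      rare_conserved_variant = sample(seq_len(max_rare), 1),
      polymorphism = if (ci > 75) {
        sample(ceiling(cutoff * n_controls):(2 * ceiling(cutoff * n_controls)), 1)
      } else sample(0:max_rare, 1))
    out[[i]] <- data.frame(
      position = pick$position[i],
      ref = trna_to_genomic_base(g, tref),
      alt = trna_to_genomic_base(g, talt),
      case_carriers = sample(1:3, 1),
      control_carriers = ctrl, ci = ci, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, out)
  list(variants = variants,
       truth = data.frame(position = variants$position, tier = tier,
                          stringsAsFactors = FALSE))
}

#' Generate a multi-species alignment with prescribed conservation
#'
#' Builds a gapless alignment of the gene's reference sequence (human row)
#' plus `n_species` synthetic vertebrate rows such that
#' [conservation_index()] reproduces each requested per-position CI
#' exactly: a target of `ci` percent at a position makes exactly
#' `ci/100 * n_species` species match the human base there.  Targets must
#' therefore be multiples of `100/n_species`; anything else is rejected,
#' naming the position.  Positions without a target are drawn with 90%
#' per-species identity.
#'
#' @param gene a `trna_gene`.
#' @param target_ci named numeric vector: conventional position label ->
#'   target CI percent.
#' @param n_species number of non-human species (default 16).
#' @param seed integer seed.
#' @return a `species_alignment`.
#' @export
synth_alignment <- function(gene, target_ci = numeric(), n_species = 16,
                            seed = 1) {
  stopifnot(inherits(gene, "trna_gene"))
  if (length(target_ci)) {
    if (is.null(names(target_ci)) || !all(names(target_ci) %in% gene$labels)) {
      stop("target_ci must be named by conventional positions of ", gene$gene)
    }
    m <- target_ci / 100 * n_species
    bad <- abs(m - round(m)) > 1e-9
    if (any(bad)) {
      stop("unattainable CI target at position ", names(target_ci)[bad][1],
           ": ", target_ci[bad][1], "% is not a multiple of 100/", n_species)
    }
  }
  set.seed(as.integer(seed))
  L <- length(gene$labels)
  human <- unname(gene$base[gene$labels])
  mat <- matrix("", nrow = n_species + 1L, ncol = L)
  mat[1, ] <- human
  for (j in seq_len(L)) {
    lbl <- gene$labels[j]
    n_match <- if (lbl %in% names(target_ci)) {
      as.integer(round(target_ci[[lbl]] / 100 * n_species))
    } else {
      stats::rbinom(1, n_species, 0.9)
    }
    col <- c(rep(human[j], n_match),
             sample(setdiff(c("A", "C", "G", "U"), human[j]),
                    n_species - n_match, replace = TRUE))
    mat[-1, j] <- col
  }
  species <- c("Homo_sapiens", sprintf("species_%02d", seq_len(n_species)))
  rownames(mat) <- species
  structure(list(gene_id = gene$gene, species = species, mat = mat,
                 human = 1L,
                 column_map = stats::setNames(seq_len(L), gene$labels)),
            class = "species_alignment")
}

#' Write a species alignment as multi-FASTA
#'
#' Inverse of [read_species_alignment()] (headers `>species|gene_id`).
#'
#' @param aln a `species_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_species_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "species_alignment"))
  lines <- as.vector(rbind(paste0(">", aln$species, "|", aln$gene_id),
                           apply(aln$mat, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic tic-disorder cohort
#'
#' Default margins are the published clinical summary of the 494-case
#' cohort (403 male; onset bands 129/334/31; diagnoses TS 146 / CTD 134 /
#' PTD 214; symptom counts blinking 415, grimacing 246, throat clearing
#' 234, shrug 131, head shake 140, spit 26; prior medications
#' 248/112/101/24/9).  With `exact = TRUE` the realized counts equal the
#' targets exactly (assignments shuffled by seed); otherwise each margin
#' is drawn binomially at the target rate.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param counts named list of target counts (see default).
#' @param exact logical; exact counts or binomial draws.
#' @return data frame of subject records (see [summarize_cohort()]).
#' @export
synth_cohort <- function(n = 494, seed = 1,
                         counts = list(
                           male = 403,
                           onset_band = c("<6" = 129, "6-12" = 334, "12-18" = 31),
                           diagnosis = c(TS = 146, CTD = 134, PTD = 214),
                           symptoms = c(blinking = 415, grimacing = 246,
                                        throat_clearing = 234, shrug = 131,
                                        head_shake = 140, spit = 26),
                           prior_drugs = c("0" = 248, "1" = 112, "2" = 101,
                                           "3" = 24, "4" = 9)),
                         exact = TRUE) {
  set.seed(as.integer(seed))
  scale_counts <- function(x) {
    if (n == sum(x)) return(x)
    y <- round(x / sum(x) * n)
    y[1] <- y[1] + (n - sum(y))
    y
  }
  draw_exclusive <- function(cnt) {
    cnt <- scale_counts(cnt)
    if (exact) sample(rep(names(cnt), times = cnt)) else
      sample(names(cnt), n, replace = TRUE, prob = cnt / sum(cnt))
  }
  sex <- if (exact) {
    sample(c(rep("male", min(counts$male, n)),
             rep("female", max(n - counts$male, 0))))
  } else {
    ifelse(stats::runif(n) < counts$male / n, "male", "female")
  }
  sym_flags <- vapply(names(counts$symptoms), function(s) {
    k <- counts$symptoms[[s]]
    if (exact) sample(c(rep(TRUE, min(k, n)), rep(FALSE, max(n - k, 0))))
    else stats::runif(n) < k / n
  }, logical(n))
  symptoms <- apply(sym_flags, 1, function(f) {
    paste(names(counts$symptoms)[f], collapse = ",")
  })
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age_years = round(stats::runif(n, 0.5, 14), 1),
    onset_band = draw_exclusive(counts$onset_band),
    diagnosis = draw_exclusive(counts$diagnosis),
    symptoms = symptoms,
    prior_drugs = draw_exclusive(counts$prior_drugs),
    stringsAsFactors = FALSE)
}
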