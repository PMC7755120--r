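# Three-criterion screen: conservation, control-cohort frequency, and
# predicted structural impact -> variant tiers and headline tallies.

#' Control-cohort frequency class
#'
#' Classifies the control carrier fraction as `absent` (0 carriers),
#' `rare_below_1pct` (0 < fraction < cutoff) or `common_1pct_or_more`
#' (fraction >= cutoff).  The comparison is exact: carrier counts and the
#' cutoff are compared as integer cross-products, so boundary fractions are
#' never decided by floating-point rounding.
#'
#' @param control_carriers integer vector of control carrier counts.
#' @param n_controls control cohort size.
#' @param cutoff frequency cutoff as a fraction (default 0.01, i.e. 1%).
#' @return data frame with columns `label` and `control_fraction`.
#' @examples
#' frequency_class(c(0, 4, 7), 485)
#' @export
frequency_class <- function(control_carriers, n_controls, cutoff = 0.01) {
  if (length(n_controls) != 1L || is.na(n_controls) || n_controls <= 0) {
    stop("n_controls must be a single positive count")
  }
  if (any(control_carriers < 0) || any(control_carriers > n_controls)) {
    stop("control_carriers must lie in 0..n_controls")
  }
  # exact rational comparison: carriers/n < cutoff  <=>  carriers*SCALE < cutoff*SCALE*n
  scale <- 1e6
  cut_num <- round(cutoff * scale)
  rare <- control_carriers * scale < cut_num * n_controls
  label <- ifelse(control_carriers == 0, "absent",
                  ifelse(rare, "rare_below_1pct", "common_1pct_or_more"))
  data.frame(label = label,
             control_fraction = control_carriers / n_controls,
             stringsAsFactors = FALSE)
}

#' Classify annotated variants into pathogenicity tiers
#'
#' Applies the three screening criteria to each annotated variant:
#' interspecies conservation (CI strictly above threshold), control-cohort
#' frequency, and predicted structural/functional impact.  Under the
#' default policy (`"absent_only"`) a variant is a `putative_mutation` only
#' when conserved, absent from controls, and impact-bearing; policy
#' `"rare_allowed"` also promotes conserved impact-bearing variants present
#' in under 1% of controls.  Conserved variants failing the putative bar
#' but not common in controls are `rare_conserved_variant`; everything not
#' conserved or common in controls is a `polymorphism`.
#'
#' @param annotated data frame from [annotate_variants()].
#' @param n_controls control cohort size.
#' @param cutoff control frequency cutoff (fraction).
#' @param policy `"absent_only"` (default) or `"rare_allowed"`.
#' @return `annotated` extended with `freq_label`, `control_fraction`,
#'   `tier` and a human-readable `reasons` audit column.
#' @export
classify_variants <- function(annotated, n_controls,
                              cutoff = 0.01,
                              policy = c("absent_only", "rare_allowed")) {
  policy <- match.arg(policy)
  need <- c("conserved", "impact", "control_carriers")
  if (!all(need %in% names(annotated))) {
    stop("annotated must come from annotate_variants()")
  }
  fc <- frequency_class(annotated$control_carriers, n_controls, cutoff)
  a <- annotated
  a$freq_label <- fc$label
  a$control_fraction <- fc$control_fraction
  freq_ok <- if (policy == "absent_only") fc$label == "absent" else
    fc$label %in% c("absent", "rare_below_1pct")
  putative <- a$conserved & freq_ok & a$impact
  common <- fc$label == "common_1pct_or_more"
  tier <- ifelse(putative, "putative_mutation",
                 ifelse(a$conserved & !common, "rare_conserved_variant",
                        "polymorphism"))
  a$tier <- tier
  a$reasons <- sprintf(
    "conserved=%s(ci=%s);controls=%s(%d);impact=%s;policy=%s",
    ifelse(a$conserved, "yes", "no"), format(a$ci, trim = TRUE),
    fc$label, a$control_carriers, ifelse(a$impact, "yes", "no"), policy)
  a
}

#' Run the full mt-tRNA variant screen
#'
#' End-to-end pipeline: structural annotation ([annotate_variants()]),
#' three-criterion classification ([classify_variants()]), and report
#' tallies (per-gene counts, conservation/frequency partition, structural
#' partition of the putative tier, Watson-Crick disruption count, novelty,
#' summed putative-tier case carriers and their prevalence among cases).
#' Prevalence assumes no case carries two putative variants (carrier counts
#' are summed per variant).
#'
#' @param variants data frame of variants, or path to a TSV readable by
#'   [read_variants()].
#' @param n_cases,n_controls cohort sizes.
#' @param model a `trna_model`.
#' @param alignments optional named list of per-gene `species_alignment`
#'   objects; when absent, the input must carry a `ci` column.
#' @param catalog optional data frame (`position`, `known`).
#' @param ci_threshold conservation threshold in percent (default 75).
#' @param control_cutoff control frequency cutoff as a fraction (default 0.01).
#' @param policy putative-tier frequency policy, see [classify_variants()].
#' @param mode CI gap-counting mode, see [conservation_index()].
#' @return an object of class `mt_screen`: list with `variants` (classified
#'   table), `per_gene`, `counts`, and `params`.
#' @examples
#' scr <- screen(read_variants(mt_extdata("tic_cohort_variants.tsv")),
#'               n_cases = 494, n_controls = 485)
#' scr
#' @export
screen <- function(variants, n_cases, n_controls,
                   model = default_model(), alignments = NULL, catalog = NULL,
                   ci_threshold = 75, control_cutoff = 0.01,
                   policy = c("absent_only", "rare_allowed"),
                   mode = c("non_gap", "all_species")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_variants(variants)
  }
  if (!nrow(variants)) stop("empty variant set")
  if (missing(n_cases) || missing(n_controls)) {
    stop("n_cases and n_controls are required")
  }
  ann <- annotate_variants(variants, model = model, alignments = alignments,
                           catalog = catalog, ci_threshold = ci_threshold,
                           mode = mode)
  cls <- classify_variants(ann, n_controls, cutoff = control_cutoff,
                           policy = policy)
  o <- order(cls$gene, cls$position)
  cls <- cls[o, , drop = FALSE]
  rownames(cls) <- NULL

  put <- cls[cls$tier == "putative_mutation", , drop = FALSE]
  put_stem <- put$element %in% STEM_ELEMENTS
  conserved <- cls[cls$conserved, , drop = FALSE]
  per_gene <- as.data.frame(table(gene = cls$gene), stringsAsFactors = FALSE)
  names(per_gene) <- c("gene", "n_variants")
  per_gene$n_putative <- vapply(per_gene$gene, function(g) {
    sum(put$gene == g)
  }, integer(1))

  carriers <- sum(put$case_carriers)
  counts <- list(
    n_variants = nrow(cls),
    n_conserved = nrow(conserved),
    conserved_freq = c(
      absent = sum(conserved$freq_label == "absent"),
      rare_below_1pct = sum(conserved$freq_label == "rare_below_1pct"),
      common_1pct_or_more = sum(conserved$freq_label == "common_1pct_or_more")),
    tiers = c(putative_mutation = sum(cls$tier == "putative_mutation"),
              rare_conserved_variant = sum(cls$tier == "rare_conserved_variant"),
              polymorphism = sum(cls$tier == "polymorphism")),
    putative_elements = c(
      loop = sum(put$element %in% LOOP_ELEMENTS),
      stem = sum(put_stem),
      terminal_junction = sum(put$element %in% c("junction", "acceptor_terminus"))),
    putative_stem_wc_disrupt = sum(put_stem & put$wc_status == "disrupts_pair"),
    novelty = c(novel = sum(cls$known %in% FALSE), known = sum(cls$known %in% TRUE)),
    putative_case_carriers = carriers,
    prevalence_percent = round(100 * carriers / n_cases, 2))
  structure(list(variants = cls, per_gene = per_gene, counts = counts,
                 params = list(n_cases = n_cases, n_controls = n_controls,
                               ci_threshold = ci_threshold,
                               control_cutoff = control_cutoff,
                               policy = policy, mode = mode)),
            class = "mt_screen")
}

#' @export
print.mt_screen <- function(x, ...) {
  c0 <- x$counts
  cat("mt-tRNA variant screen (", c0$n_variants, " variants, ",
      x$params$n_cases, " cases / ", x$params$n_controls, " controls)\n", sep = "")
  cat("  conserved (CI > ", x$params$ci_threshold, "%): ", c0$n_conserved,
      "  [absent ", c0$conserved_freq[["absent"]],
      " / rare ", c0$conserved_freq[["rare_below_1pct"]],
      " / common ", c0$conserved_freq[["common_1pct_or_more"]], "]\n", sep = "")
  cat("  tiers: putative ", c0$tiers[["putative_mutation"]],
      ", rare conserved ", c0$tiers[["rare_conserved_variant"]],
      ", polymorphism ", c0$tiers[["polymorphism"]], "\n", sep = "")
  pe <- c0$putative_elements
  cat("  putative structure: ", pe[["loop"]], " loop / ", pe[["stem"]],
      " stem / ", pe[["terminal_junction"]], " terminal-junction (",
      c0$putative_stem_wc_disrupt, " stem WC-disrupting)\n", sep = "")
  cat("  putative carriers: ", c0$putative_case_carriers, " cases (",
      sprintf("%.2f", c0$prevalence_percent), "% prevalence)\n", sep = "")
  cat("  novelty: ", c0$novelty[["novel"]], " novel / ",
      c0$novelty[["known"]], " known\n", sep = "")
  invisible(x)
}

#' @export
summary.mt_screen <- function(object, ...) {
  print(object)
  cat("\nper-gene tallies:\n")
  print(object$per_gene, row.names = FALSE)
  invisible(object)
}

#' Barplot of variant tiers per gene
#'
#' @param x an `mt_screen`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mt_screen <- function(x, ...) {
  tab <- table(tier = x$variants$tier, gene = x$variants$gene)
  graphics::barplot(tab, las = 2, legend.text = rownames(tab),
                    ylab = "variants", ...)
  invisible(x)
}
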