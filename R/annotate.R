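# Structural annotation of mtDNA variants: gene assignment, tRNA-level
# bases, cloverleaf element, Watson-Crick pairing effect, conservation,
# and the structural/functional impact predicate.

# Conventional positions treated as functional/tertiary-core sites by
# default (anticodon wobble 34, positions 37/38 flanking the anticodon,
# T-loop 55/58, discriminator 73, and the 8/14/18 tertiary core).
DEFAULT_FUNCTIONAL_SITES <- c("8", "14", "18", "34", "37", "38", "55", "58", "73")

WC_PAIRS <- c("A-U", "U-A", "G-C", "C-G")

is_wc_pair <- function(b1, b2) paste(b1, b2, sep = "-") %in% WC_PAIRS

#' Watson-Crick pairing effect of a base change
#'
#' For a stem position, compares the canonical-pair status of the reference
#' base against the gene's stem partner with that of the variant base:
#' `disrupts_pair` when a Watson-Crick pair (A-U or G-C; G-U wobble counts
#' as non-WC) becomes non-WC, `creates_pair` in the converse case,
#' `no_pair_change` otherwise.  Loop, junction and terminus positions give
#' `not_applicable`.  Pairs are reported as `(variant base)-(partner base)`.
#'
#' @param gene a `trna_gene`.
#' @param position conventional position label.
#' @param trna_ref,trna_alt tRNA-strand bases (`A`,`C`,`G`,`U`), or `NA`
#'   alt for a deletion.
#' @return list with `status`, `before_pair`, `after_pair`.
#' @export
wc_effect <- function(gene, position, trna_ref, trna_alt) {
  stopifnot(inherits(gene, "trna_gene"))
  position <- as.character(position)
  if (!position %in% gene$labels) {
    stop("unknown position ", position, " for ", gene$gene)
  }
  ok <- c("A", "C", "G", "U")
  if (!trna_ref %in% ok || !(is.na(trna_alt) || trna_alt %in% ok)) {
    stop("tRNA bases must be in A,C,G,U")
  }
  partner <- gene$partner[[position]]
  if (is.na(partner) || is.na(trna_alt)) {
    return(list(status = if (is.na(partner)) "not_applicable" else "no_pair_change",
                before_pair = NA_character_, after_pair = NA_character_))
  }
  pb <- gene$base[[partner]]
  before_wc <- is_wc_pair(trna_ref, pb)
  after_wc <- is_wc_pair(trna_alt, pb)
  status <- if (before_wc && !after_wc) "disrupts_pair"
            else if (!before_wc && after_wc) "creates_pair"
            else "no_pair_change"
  list(status = status,
       before_pair = paste(trna_ref, pb, sep = "-"),
       after_pair = paste(trna_alt, pb, sep = "-"))
}

#' Structural/functional impact predicate
#'
#' A variant is predicted to alter tRNA structure or function when it
#' (a) sits in a stem and its base change disrupts or creates a
#' Watson-Crick pair, or (b) sits outside a stem at a tertiary-interaction
#' or functional site, or at an interspecies-conserved position.
#' Deletions qualify only via stem placement or a tertiary/functional site.
#'
#' @param annotated a data frame as returned by [annotate_variants()]
#'   (columns `element`, `wc_status`, `tertiary_site`, `conserved`, `kind`).
#' @return logical vector.
#' @export
structural_impact <- function(annotated) {
  stem <- annotated$element %in% STEM_ELEMENTS
  wc_hit <- annotated$wc_status %in% c("disrupts_pair", "creates_pair")
  deletion <- annotated$kind == "deletion"
  impact <- ifelse(stem, wc_hit,
                   annotated$tertiary_site |
                     (!deletion & annotated$conserved %in% TRUE))
  # deletions in a stem count through placement alone (no WC pair to compare)
  impact[deletion & stem] <- TRUE
  impact
}

#' Annotate mtDNA variants against the tRNA structure model
#'
#' Assigns each variant to its mt-tRNA gene, converts the heavy-strand
#' alleles to tRNA-strand bases, determines the conventional cloverleaf
#' position and structural element, evaluates the Watson-Crick pairing
#' effect, attaches the conservation index (from per-gene alignments when
#' supplied, otherwise from a `ci` column of the input), and evaluates the
#' structural-impact predicate.
#'
#' @param variants data frame with columns `position`, `ref`, `alt`
#'   (heavy-strand alleles; `alt = "del"` marks a single-base deletion),
#'   `case_carriers`, `control_carriers`, and optionally `ci` and `known`.
#' @param model a `trna_model`.
#' @param alignments optional named list of `species_alignment` objects,
#'   keyed by gene id, used to compute CI.
#' @param catalog optional data frame (`position`, `known`) overriding the
#'   `known` column.
#' @param ci_threshold conservation threshold in percent.
#' @param tertiary_sites conventional position labels treated as
#'   functional sites in every gene (gene-specific tertiary interaction
#'   partners from the model are always added).
#' @param mode CI gap-counting mode, see [conservation_index()].
#' @return the input data frame extended with annotation columns
#'   (`gene`, `trna_position`, `element`, `trna_ref`, `trna_alt`,
#'   `wc_status`, `wc_before`, `wc_after`, `ci`, `conserved`,
#'   `tertiary_site`, `impact`).
#' @export
annotate_variants <- function(variants, model = default_model(),
                              alignments = NULL, catalog = NULL,
                              ci_threshold = 75,
                              tertiary_sites = DEFAULT_FUNCTIONAL_SITES,
                              mode = c("non_gap", "all_species")) {
  mode <- match.arg(mode)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt", "case_carriers", "control_carriers")
  if (!all(need %in% names(v))) {
    stop("variants must have columns: ", paste(need, collapse = ", "))
  }
  if (any(v$case_carriers < 0) || any(v$control_carriers < 0)) {
    stop("carrier counts must be non-negative")
  }
  v$kind <- ifelse(toupper(v$alt) %in% c("DEL", "-", ""), "deletion", "substitution")
  sub <- v$kind == "substitution"
  if (any(sub & toupper(v$ref) == toupper(v$alt))) {
    stop("ref and alt alleles identical at position ",
         v$position[sub & toupper(v$ref) == toupper(v$alt)][1])
  }
  loc <- locate_position(v$position, model)
  if (anyNA(loc$gene)) {
    stop("position(s) not in any mt-tRNA gene: ",
         paste(loc$position[is.na(loc$gene)], collapse = ","))
  }
  v$gene <- loc$gene
  v$trna_position <- loc$trna_position
  v$element <- loc$element

  n <- nrow(v)
  v$trna_ref <- v$trna_alt <- NA_character_
  v$wc_status <- v$wc_before <- v$wc_after <- NA_character_
  v$tertiary_site <- FALSE
  ci_sup <- if ("ci" %in% names(v)) v$ci else rep(NA_real_, n)
  v$ci <- NA_real_
  for (i in seq_len(n)) {
    g <- model$genes[[v$gene[i]]]
    v$trna_ref[i] <- trna_strand_base(g, v$ref[i])
    if (v$kind[i] == "substitution") {
      v$trna_alt[i] <- trna_strand_base(g, v$alt[i])
    }
    wc <- if (v$kind[i] == "deletion") {
      list(status = "not_applicable", before_pair = NA, after_pair = NA)
    } else {
      wc_effect(g, v$trna_position[i], v$trna_ref[i], v$trna_alt[i])
    }
    v$wc_status[i] <- wc$status
    v$wc_before[i] <- wc$before_pair
    v$wc_after[i] <- wc$after_pair
    v$tertiary_site[i] <- v$trna_position[i] %in% tertiary_sites ||
      v$trna_position[i] %in% as.vector(g$tertiary)
    if (!is.null(alignments) && !is.null(alignments[[v$gene[i]]])) {
      v$ci[i] <- conservation_index(alignments[[v$gene[i]]], v$trna_position[i],
                                    threshold = ci_threshold,
                                    mode = mode)$ci_percent
    } else if (!is.na(ci_sup[i])) {
      v$ci[i] <- ci_sup[i]
    } else {
      stop("no conservation source for position ", v$position[i],
           ": supply per-gene alignments or a 'ci' column")
    }
  }
  v$conserved <- is_conserved(v$ci, ci_threshold)
  if (!is.null(catalog)) {
    m <- match(v$position, catalog$position)
    v$known <- toupper(catalog$known[m]) == "Y"
  } else if ("known" %in% names(v)) {
    v$known <- if (is.character(v$known)) toupper(v$known) == "Y" else as.logical(v$known)
  } else {
    v$known <- NA
  }
  v$impact <- structural_impact(v)
  v
}
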