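# rCRS (NC_012920.1) genome length; variant coordinates are validated against it.
RCRS_LENGTH <- 16569L

STEM_ELEMENTS <- c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")
LOOP_ELEMENTS <- c("d_loop", "anticodon_loop", "variable_loop", "t_loop")

#' Normalize a structural-element synonym
#'
#' Maps the element vocabulary used in published mt-tRNA variant tables
#' ("ACC-stem", "DHU-loop", "AC loop", "D-A junction", ...) onto the
#' canonical element names used throughout this package.
#'
#' @param x character vector of element names or synonyms.
#' @return character vector of canonical names (one of
#'   `acceptor_stem`, `acceptor_terminus`, `d_stem`, `d_loop`,
#'   `anticodon_stem`, `anticodon_loop`, `variable_loop`, `t_stem`,
#'   `t_loop`, `junction`).
#' @examples
#' normalize_element(c("ACC-stem", "DHU-loop", "AC loop"))
#' @export
normalize_element <- function(x) {
  key <- tolower(gsub("[ _-]+", " ", trimws(x)))
  map <- c(
    "acc stem" = "acceptor_stem", "accstem" = "acceptor_stem",
    "acceptor stem" = "acceptor_stem", "acceptor_stem" = "acceptor_stem",
    "acc terminus" = "acceptor_terminus", "acceptor terminus" = "acceptor_terminus",
    "acceptor_terminus" = "acceptor_terminus",
    "dhu stem" = "d_stem", "d stem" = "d_stem", "d_stem" = "d_stem",
    "dhu loop" = "d_loop", "d loop" = "d_loop", "d_loop" = "d_loop",
    "ac stem" = "anticodon_stem", "anticodon stem" = "anticodon_stem",
    "anticodon_stem" = "anticodon_stem",
    "ac loop" = "anticodon_loop", "anticodon loop" = "anticodon_loop",
    "anticodon_loop" = "anticodon_loop",
    "t stem" = "t_stem", "t_stem" = "t_stem",
    "t loop" = "t_loop", "t_loop" = "t_loop",
    "variable loop" = "variable_loop", "variable_loop" = "variable_loop",
    "d a junction" = "junction", "a d junction" = "junction",
    "junction" = "junction")
  key <- gsub("_", " ", key)
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unrecognized structural element name(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

comp_dna <- c(A = "T", C = "G", G = "C", T = "A")
comp_rna <- c(A = "U", C = "G", G = "C", U = "A")

#' Genomic allele to tRNA-strand base
#'
#' Eight of the 22 human mt-tRNA genes are encoded on the light strand while
#' variants are conventionally reported as heavy-strand (rCRS) alleles; for
#' those genes the tRNA-level base is the Watson-Crick complement of the
#' reported allele.  Thymine is rendered as uracil at the tRNA level.
#'
#' @param gene a `trna_gene` (see [load_trna_model()]).
#' @param genomic_base character vector of heavy-strand alleles (`A`,`C`,`G`,`T`).
#' @return character vector of tRNA-strand bases in the `ACGU` alphabet.
#' @examples
#' m <- load_trna_model()
#' trna_strand_base(m$genes[["MT-TP"]], "A")  # light strand -> "U"
#' @export
trna_strand_base <- function(gene, genomic_base) {
  stopifnot(inherits(gene, "trna_gene"))
  b <- toupper(genomic_base)
  if (!all(b %in% c("A", "C", "G", "T"))) {
    stop("genomic_base must be one of A,C,G,T; got: ",
         paste(setdiff(b, c("A", "C", "G", "T")), collapse = ","))
  }
  if (identical(gene$strand, "light")) b <- unname(comp_dna[b])
  unname(ifelse(b == "T", "U", b))
}

label_sort_key <- function(lbl) {
  base <- suppressWarnings(as.integer(sub("[a-z]+$", "", lbl)))
  suf <- sub("^[0-9]+", "", lbl)
  base + ifelse(suf == "", 0, match(suf, letters) / 100)
}

#' Load the mitochondrial tRNA structure model
#'
#' Reads the packaged (or a user-supplied) definition of the 22 human
#' mitochondrial tRNA genes: rCRS spans and strands, the conventional
#' cloverleaf position label of every nucleotide, structural elements,
#' Watson-Crick stem pairing partners, and tertiary (long-range)
#' interaction partners.  All structural invariants are validated at load
#' time: complete gene set, non-overlapping spans, unique position labels
#' per gene, symmetric and involutive pairing restricted to stem elements.
#'
#' @param genes_file,structure_file,tertiary_file paths to the three
#'   definition tables; defaults are the packaged fixtures.  See the file
#'   headers under `system.file("extdata", package = "mtscreen")` for the
#'   documented schema.
#' @return an object of class `trna_model`: a list with `genes` (named list
#'   of `trna_gene` objects) and `spans` (a data frame index used by
#'   [locate_position()]).
#' @examples
#' m <- load_trna_model()
#' length(m$genes)  # 22
#' @export
load_trna_model <- function(genes_file = mt_extdata("mt_trna_genes.tsv"),
                            structure_file = mt_extdata("mt_trna_structure_synthetic.tsv"),
                            tertiary_file = mt_extdata("mt_trna_tertiary.tsv")) {
  gtab <- utils::read.delim(genes_file, comment.char = "#", stringsAsFactors = FALSE)
  stab <- utils::read.delim(structure_file, comment.char = "#",
                            colClasses = "character")
  ttab <- utils::read.delim(tertiary_file, comment.char = "#",
                            colClasses = "character")

  need <- c("gene", "amino_acid", "start", "end", "strand")
  if (!all(need %in% names(gtab))) stop("gene table missing columns")
  expected <- c("MT-TA", "MT-TC", "MT-TD", "MT-TE", "MT-TF", "MT-TG", "MT-TH",
                "MT-TI", "MT-TK", "MT-TL1", "MT-TL2", "MT-TM", "MT-TN", "MT-TP",
                "MT-TQ", "MT-TR", "MT-TS1", "MT-TS2", "MT-TT", "MT-TV", "MT-TW",
                "MT-TY")
  missing <- setdiff(expected, gtab$gene)
  if (length(missing)) {
    stop("gene definition file is missing gene(s): ", paste(missing, collapse = ", "))
  }
  if (any(gtab$start > gtab$end)) {
    bad <- gtab$gene[gtab$start > gtab$end]
    stop("gene ", bad[1], ": start > end")
  }
  o <- order(gtab$start)
  gs <- gtab[o, ]
  if (any(gs$start[-1] <= gs$end[-nrow(gs)])) {
    i <- which(gs$start[-1] <= gs$end[-nrow(gs)])[1]
    stop("overlapping spans: ", gs$gene[i], " and ", gs$gene[i + 1])
  }

  genes <- list()
  for (i in seq_len(nrow(gtab))) {
    g <- gtab$gene[i]
    s <- stab[stab$gene == g, ]
    if (!nrow(s)) stop("structure table has no rows for gene ", g)
    L <- gtab$end[i] - gtab$start[i] + 1L
    if (nrow(s) != L) {
      stop("gene ", g, ": structure rows (", nrow(s), ") != span length (", L, ")")
    }
    if (anyDuplicated(s$label)) {
      stop("gene ", g, ": duplicate position label ",
           s$label[duplicated(s$label)][1])
    }
    partner <- stats::setNames(s$partner, s$label)
    paired <- partner != ""
    miss <- setdiff(partner[paired], s$label)
    if (length(miss)) {
      stop("gene ", g, ": pairing partner ", miss[1], " is not a position label")
    }
    back <- partner[partner[paired]]
    if (!all(back == names(partner)[paired])) {
      bad <- names(partner)[paired][back != names(partner)[paired]][1]
      stop("gene ", g, ": pairing_map not symmetric at position ", bad)
    }
    elem <- stats::setNames(s$element, s$label)
    if (!all(elem[paired] %in% STEM_ELEMENTS)) {
      bad <- names(elem)[paired & !(elem %in% STEM_ELEMENTS)][1]
      stop("gene ", g, ": paired position ", bad, " is not in a stem element")
    }
    # stems must pair completely (even cardinality via full pairing)
    stem_lbl <- names(elem)[elem %in% STEM_ELEMENTS]
    if (!all(partner[stem_lbl] != "")) {
      bad <- stem_lbl[partner[stem_lbl] == ""][1]
      stop("gene ", g, ": stem position ", bad, " has no pairing partner")
    }
    tg <- ttab[ttab$gene == g, , drop = FALSE]
    tert <- if (nrow(tg)) {
      if (!all(c(tg$pos1, tg$pos2) %in% s$label)) {
        stop("gene ", g, ": tertiary interaction names unknown position")
      }
      cbind(tg$pos1, tg$pos2)
    } else matrix(character(0), ncol = 2)
    genes[[g]] <- structure(list(
      gene = g, amino_acid = gtab$amino_acid[i],
      start = as.integer(gtab$start[i]), end = as.integer(gtab$end[i]),
      strand = gtab$strand[i], labels = s$label,
      element = elem, partner = replace(partner, !paired, NA_character_),
      base = stats::setNames(s$base, s$label), tertiary = tert),
      class = "trna_gene")
  }
  structure(list(genes = genes,
                 spans = data.frame(gene = gtab$gene, start = gtab$start,
                                    end = gtab$end, stringsAsFactors = FALSE)),
            class = "trna_model")
}

.model_cache <- new.env(parent = emptyenv())

# Default model, loaded once per session.
default_model <- function() {
  if (is.null(.model_cache$model)) .model_cache$model <- load_trna_model()
  .model_cache$model
}

#' Map rCRS coordinates onto tRNA genes and cloverleaf positions
#'
#' For each 1-based rCRS coordinate, reports the mt-tRNA gene containing it
#' (if any), the conventional cloverleaf position label, and the structural
#' element.  Coordinates outside any tRNA gene yield `NA` fields (this is a
#' distinguished result, not an error); coordinates outside the rCRS range
#' are an error.
#'
#' @param position integer vector of rCRS coordinates (1..16569).
#' @param model a `trna_model`; default the packaged model.
#' @return data frame with columns `position`, `gene`, `trna_position`,
#'   `element`.
#' @examples
#' locate_position(c(4452, 5000))
#' @export
locate_position <- function(position, model = default_model()) {
  position <- as.integer(position)
  if (anyNA(position) || any(position < 1L) || any(position > RCRS_LENGTH)) {
    stop("position must lie in 1..", RCRS_LENGTH)
  }
  sp <- model$spans
  idx <- vapply(position, function(p) {
    w <- which(sp$start <= p & p <= sp$end)
    if (length(w)) w else NA_integer_
  }, integer(1))
  gene <- ifelse(is.na(idx), NA_character_, sp$gene[idx])
  lab <- el <- rep(NA_character_, length(position))
  hit <- !is.na(idx)
  for (i in which(hit)) {
    g <- model$genes[[gene[i]]]
    k <- if (g$strand == "heavy") position[i] - g$start + 1L else g$end - position[i] + 1L
    lab[i] <- g$labels[k]
    el[i] <- unname(g$element[lab[i]])
  }
  data.frame(position = position, gene = gene, trna_position = lab,
             element = el, stringsAsFactors = FALSE)
}

#' Watson-Crick stem partner of a cloverleaf position
#'
#' @param gene a `trna_gene`.
#' @param position conventional position label (e.g. `"28"`, `"27a"`).
#' @return the partner label, or `NA` for unpaired (loop/junction/terminus)
#'   positions.
#' @export
pairing_partner <- function(gene, position) {
  stopifnot(inherits(gene, "trna_gene"))
  position <- as.character(position)
  if (!all(position %in% gene$labels)) {
    stop("unknown position(s) for ", gene$gene, ": ",
         paste(setdiff(position, gene$labels), collapse = ","))
  }
  unname(gene$partner[position])
}

#' Text rendering of a tRNA cloverleaf
#'
#' Deterministic ASCII rendering: one block per structural element listing
#' its conventional positions and reference bases, with `[..]` markers on
#' highlighted positions.  A text analogue of the usual cloverleaf figure.
#'
#' @param gene a `trna_gene`.
#' @param highlight character vector of position labels to mark.
#' @return character vector of lines, invisibly also printed by
#'   `cat(x, sep = "\n")`.
#' @export
render_cloverleaf <- function(gene, highlight = character()) {
  stopifnot(inherits(gene, "trna_gene"))
  highlight <- as.character(highlight)
  if (!all(highlight %in% gene$labels)) {
    stop("unknown highlight position(s): ",
         paste(setdiff(highlight, gene$labels), collapse = ","))
  }
  order_elems <- c("acceptor_stem", "junction", "d_stem", "d_loop",
                   "anticodon_stem", "anticodon_loop", "variable_loop",
                   "t_stem", "t_loop", "acceptor_terminus")
  fmt <- function(lbl) {
    b <- unname(gene$base[lbl])
    ifelse(lbl %in% highlight, paste0("[", lbl, b, "]"), paste0(lbl, b))
  }
  lines <- c(sprintf("%s (tRNA-%s, %s:%d-%d, %s strand)", gene$gene,
                     gene$amino_acid, "rCRS", gene$start, gene$end, gene$strand))
  for (e in order_elems) {
    lbl <- gene$labels[gene$element[gene$labels] == e]
    if (!length(lbl)) next
    lines <- c(lines, sprintf("  %-17s %s", e, paste(fmt(lbl), collapse = " ")))
  }
  if (nrow(gene$tertiary)) {
    lines <- c(lines, sprintf("  %-17s %s", "tertiary",
                              paste(gene$tertiary[, 1], gene$tertiary[, 2],
                                    sep = "-", collapse = " ")))
  }
  lines
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(render_cloverleaf(x), sep = "\n")
  invisible(x)
}

#' @export
print.trna_model <- function(x, ...) {
  cat("mt-tRNA structure model:", length(x$genes), "genes,",
      sum(x$spans$end - x$spans$start + 1), "positions\n")
  invisible(x)
}
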