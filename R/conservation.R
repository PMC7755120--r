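# Interspecies conservation index from a per-gene multi-species alignment.

#' Read a per-gene multi-species tRNA alignment
#'
#' Reads an aligned multi-FASTA (one record per species, headers
#' `>species|gene_id`), identifies the human row, and maps the gene's
#' conventional cloverleaf positions onto alignment columns via the
#' ungapped human sequence.  Gap characters `-` and `.` are accepted;
#' `T`/`U` are unified and case is ignored.
#'
#' @param path FASTA file.
#' @param gene a `trna_gene` the alignment belongs to.
#' @param human_pattern regular expression identifying the human row among
#'   the species names (case-insensitive).
#' @return an object of class `species_alignment`: gene id, species names,
#'   an aligned character matrix, the human row index, and `column_map`
#'   (conventional position label -> alignment column).
#' @export
read_species_alignment <- function(path, gene,
                                   human_pattern = "homo|human") {
  stopifnot(inherits(gene, "trna_gene"))
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("empty alignment: ", path)
  nm <- names(seqs)
  species <- sub("\\|.*$", "", nm)
  gid <- ifelse(grepl("\\|", nm), sub("^[^|]*\\|", "", nm), NA_character_)
  if (any(!is.na(gid) & gid != gene$gene)) {
    stop("alignment records are labelled for gene ",
         stats::na.omit(gid[gid != gene$gene])[1], ", not ", gene$gene)
  }
  chars <- toupper(as.character(seqs))
  if (length(unique(nchar(chars))) != 1L) {
    stop("alignment rows have unequal lengths in ", path)
  }
  mat <- do.call(rbind, strsplit(chars, ""))
  mat[mat == "T"] <- "U"
  rownames(mat) <- species
  human <- grep(human_pattern, species, ignore.case = TRUE)
  if (length(human) != 1L) {
    stop("alignment must contain exactly one human row (pattern '",
         human_pattern, "'); found ", length(human))
  }
  hrow <- mat[human, ]
  nongap <- which(!(hrow %in% c("-", ".")))
  if (length(nongap) != length(gene$labels)) {
    stop("ungapped human row length (", length(nongap),
         ") does not match gene length (", length(gene$labels), ") for ",
         gene$gene)
  }
  column_map <- stats::setNames(nongap, gene$labels)
  structure(list(gene_id = gene$gene, species = species, mat = mat,
                 human = human, column_map = column_map),
            class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat("species alignment for", x$gene_id, ":", length(x$species), "species,",
      ncol(x$mat), "columns\n")
  invisible(x)
}

#' Interspecies conservation index at a cloverleaf position
#'
#' The conservation index (CI) of a position is the percentage of non-human
#' species whose aligned nucleotide is identical to the human nucleotide.
#' Under the default counting mode (`"non_gap"`) species with a gap at the
#' column are excluded from the denominator; under `"all_species"` they
#' count as mismatches.
#'
#' @param aln a `species_alignment`.
#' @param position conventional position label(s).
#' @param threshold conservation threshold in percent (default 75; a
#'   position is called conserved when CI strictly exceeds it).
#' @param mode gap-handling mode, `"non_gap"` (default) or `"all_species"`.
#' @return data frame with columns `position`, `ci_percent`,
#'   `n_species_counted`, `is_conserved`.
#' @export
conservation_index <- function(aln, position, threshold = 75,
                               mode = c("non_gap", "all_species")) {
  stopifnot(inherits(aln, "species_alignment"))
  mode <- match.arg(mode)
  position <- as.character(position)
  if (!all(position %in% names(aln$column_map))) {
    stop("position(s) not mapped in alignment: ",
         paste(setdiff(position, names(aln$column_map)), collapse = ","))
  }
  if (nrow(aln$mat) < 2L) stop("alignment has no non-human species")
  res <- lapply(position, function(p) {
    col <- aln$mat[, aln$column_map[[p]]]
    hb <- col[aln$human]
    other <- col[-aln$human]
    gap <- other %in% c("-", ".")
    n <- if (mode == "non_gap") sum(!gap) else length(other)
    matches <- sum(other[!gap] == hb)
    ci <- if (n == 0L) 0 else 100 * matches / n
    data.frame(position = p, ci_percent = ci, n_species_counted = n,
               is_conserved = is_conserved(ci, threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Conservation threshold test
#'
#' TRUE when the conservation index strictly exceeds the threshold
#' (a CI of exactly 75 is not conserved under the default threshold).
#'
#' @param ci_percent numeric vector of CI values in percent (0..100).
#' @param threshold threshold in percent, default 75.
#' @return logical vector.
#' @examples
#' is_conserved(c(82, 75, 49))
#' @export
is_conserved <- function(ci_percent, threshold = 75) {
  if (any(ci_percent < 0 | ci_percent > 100, na.rm = TRUE)) {
    stop("ci_percent must lie in 0..100")
  }
  ci_percent > threshold
}
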