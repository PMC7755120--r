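# Readers and writers: variant TSV (with m.POS notation support), minimal
# VCF ingestion, and screen report output.

#' Parse variant notation strings
#'
#' Parses `m.<pos><ref>><alt>` substitutions (e.g. `m.10055A>G`) and
#' `m.<pos>del<base>` single-base deletions (e.g. `m.5878delT`).
#'
#' @param x character vector of notation strings.
#' @return data frame with columns `position`, `ref`, `alt` (`alt = "del"`
#'   for deletions).
#' @examples
#' parse_variant_notation(c("m.4373T>C", "m.5878delT"))
#' @export
parse_variant_notation <- function(x) {
  x <- trimws(x)
  sub_pat <- "^m\\.([0-9]+)([ACGT])>([ACGT])$"
  del_pat <- "^m\\.([0-9]+)del([ACGT])$"
  is_sub <- grepl(sub_pat, x)
  is_del <- grepl(del_pat, x)
  if (any(!(is_sub | is_del))) {
    bad <- which(!(is_sub | is_del))[1]
    stop("malformed variant notation at entry ", bad, ": '", x[bad], "'")
  }
  position <- integer(length(x))
  ref <- alt <- character(length(x))
  position[is_sub] <- as.integer(sub(sub_pat, "\\1", x[is_sub]))
  position[is_del] <- as.integer(sub(del_pat, "\\1", x[is_del]))
  ref[is_sub] <- sub(sub_pat, "\\2", x[is_sub])
  ref[is_del] <- sub(del_pat, "\\2", x[is_del])
  alt[is_sub] <- sub(sub_pat, "\\3", x[is_sub])
  alt[is_del] <- "del"
  data.frame(position = position, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Reads a TSV of mtDNA variants with heavy-strand alleles.  Two layouts
#' are accepted: explicit columns (`position`, `ref`, `alt`,
#' `case_carriers`, `control_carriers`, optional `ci`, `known`) or a
#' `notation` column holding `m.POS REF>ALT` strings alongside the count
#' columns.  Alleles are validated and duplicate records rejected, with
#' the offending file line reported.
#'
#' @param path TSV file.
#' @return data frame of variants.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  hdr_line <- which(!startsWith(raw, "#"))[1]
  x <- utils::read.delim(text = raw[hdr_line:length(raw)],
                         colClasses = "character")
  for (col in intersect(c("position", "case_carriers", "control_carriers", "ci"),
                        names(x))) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if ("notation" %in% names(x)) {
    x <- cbind(parse_variant_notation(x$notation),
               x[setdiff(names(x), c("notation", "position", "ref", "alt"))])
  }
  need <- c("position", "ref", "alt", "case_carriers", "control_carriers")
  if (!all(need %in% names(x))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "),
         " (or a 'notation' column)")
  }
  line_of <- function(i) hdr_line + i  # data row i -> file line number
  x$ref <- toupper(x$ref)
  x$alt <- ifelse(toupper(x$alt) %in% c("DEL", "-", ""), "del", toupper(x$alt))
  bad <- which(!(x$ref %in% c("A", "C", "G", "T")) |
                 !(x$alt %in% c("A", "C", "G", "T", "del")))
  if (length(bad)) {
    stop("invalid allele at line ", line_of(bad[1]), " of ", path)
  }
  bad <- which(x$alt != "del" & x$ref == x$alt)
  if (length(bad)) {
    stop("ref equals alt at line ", line_of(bad[1]), " of ", path)
  }
  key <- paste(x$position, x$ref, x$alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant record at line ", line_of(which(duplicated(key))[1]),
         " of ", path)
  }
  if (any(x$case_carriers < 0, na.rm = TRUE) ||
      any(x$control_carriers < 0, na.rm = TRUE)) {
    stop("carrier counts must be non-negative in ", path)
  }
  x
}

#' Read a known-variant catalog
#'
#' @param path TSV with columns `position`, `known` (Y/N).
#' @return data frame.
#' @export
read_catalog <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("position", "known") %in% names(x))) {
    stop("catalog must have columns position, known")
  }
  x
}

#' Minimal VCF ingestion
#'
#' Reads chrM SNVs and 1-bp deletions from a VCF (via the vcfR package)
#' into the variant-table layout.  Accepted chromosome names: `chrM`,
#' `MT`, `NC_012920.1`.  A record REF=`XY` ALT=`X` is interpreted as a
#' deletion of the base at POS+1.  When genotypes are present,
#' `case_carriers` counts the samples carrying the alternate allele;
#' `control_carriers` is zero (control counts come from a separate table).
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return data frame of variants (no `ci` column).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants_vcf requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single record comes back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no records in ", path)
  ok_chrom <- c("chrM", "MT", "NC_012920.1")
  if (!all(fix$CHROM %in% ok_chrom)) {
    stop("unsupported chromosome name(s): ",
         paste(unique(setdiff(fix$CHROM, ok_chrom)), collapse = ","),
         " (accepted: ", paste(ok_chrom, collapse = ","), ")")
  }
  pos <- as.integer(fix$POS)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  snv <- nchar(ref) == 1 & nchar(alt) == 1
  del1 <- nchar(ref) == 2 & nchar(alt) == 1 & substr(ref, 1, 1) == alt
  if (!all(snv | del1)) {
    stop("only SNVs and 1-bp deletions are supported (record ",
         which(!(snv | del1))[1], ")")
  }
  carriers <- rep(1L, nrow(fix))
  gt <- tryCatch(vcfR::extract.gt(vcf), error = function(e) NULL)
  if (!is.null(gt) && ncol(gt)) {
    carriers <- apply(gt, 1, function(g) sum(grepl("1", g), na.rm = TRUE))
  }
  data.frame(
    position = ifelse(del1, pos + 1L, pos),
    ref = ifelse(del1, substr(ref, 2, 2), ref),
    alt = ifelse(del1, "del", alt),
    case_carriers = as.integer(carriers),
    control_carriers = 0L, stringsAsFactors = FALSE)
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Write screen report files
#'
#' Writes three TSVs into `dir`: `per_variant.tsv` (the classified table,
#' sorted by gene then position, including the per-variant criterion audit
#' column), `per_gene.tsv`, and `summary.tsv` (headline counts plus a
#' configuration echo and package version).  Output is deterministic:
#' rerunning on the same input gives byte-identical files.  Percentages
#' are fixed to two decimals.
#'
#' @param x an `mt_screen`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "mt_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- x$variants
  v$control_percent <- fmt2(100 * v$control_fraction)
  v$case_percent <- fmt2(100 * v$case_carriers / x$params$n_cases)
  v$control_fraction <- NULL
  f1 <- file.path(dir, "per_variant.tsv")
  utils::write.table(v, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "per_gene.tsv")
  utils::write.table(x$per_gene, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  c0 <- x$counts
  kv <- rbind(
    c("tool_version", as.character(utils::packageVersion("mtscreen"))),
    c("n_cases", x$params$n_cases), c("n_controls", x$params$n_controls),
    c("ci_threshold", x$params$ci_threshold),
    c("control_cutoff", x$params$control_cutoff),
    c("policy", x$params$policy), c("counting_mode", x$params$mode),
    c("n_variants", c0$n_variants), c("n_conserved", c0$n_conserved),
    c("conserved_absent", c0$conserved_freq[["absent"]]),
    c("conserved_rare", c0$conserved_freq[["rare_below_1pct"]]),
    c("conserved_common", c0$conserved_freq[["common_1pct_or_more"]]),
    c("putative", c0$tiers[["putative_mutation"]]),
    c("rare_conserved", c0$tiers[["rare_conserved_variant"]]),
    c("polymorphism", c0$tiers[["polymorphism"]]),
    c("putative_loop", c0$putative_elements[["loop"]]),
    c("putative_stem", c0$putative_elements[["stem"]]),
    c("putative_terminal_junction", c0$putative_elements[["terminal_junction"]]),
    c("putative_stem_wc_disrupt", c0$putative_stem_wc_disrupt),
    c("novel", c0$novelty[["novel"]]), c("known", c0$novelty[["known"]]),
    c("putative_case_carriers", c0$putative_case_carriers),
    c("prevalence_percent", fmt2(c0$prevalence_percent)))
  f3 <- file.path(dir, "summary.tsv")
  utils::write.table(data.frame(key = kv[, 1], value = kv[, 2]), f3,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
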