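#' Construct an allele catalog
#'
#' An allele catalog names the nucleotide alleles observed at each amplicon
#' locus. It is the unit counted by allele numbers, rarefaction and the
#' drift simulator's retention statistic. The default locus set is the
#' three analysed DQA fragments (exon 2, intron 2a, exon 4) of lengths
#' 99, 89 and 92 bp.
#'
#' @param alleles data.frame with columns `allele_id`, `locus_id`,
#'   `sequence` (A/C/G/T only; lowercase accepted and uppercased).
#' @param loci named integer vector of expected fragment lengths per locus.
#'   Defaults to the lengths of the alleles supplied per locus.
#' @return An object of class `allele_catalog`: list with elements
#'   `alleles` (data.frame) and `loci` (named integer vector).
#' @examples
#' cat3 <- allele_catalog(data.frame(
#'   allele_id = c("a1", "a2"), locus_id = "ex2",
#'   sequence = c(strrep("ACG", 33), strrep("ACT", 33))))
#' @export
allele_catalog <- function(alleles, loci = NULL) {
  stopifnot(is.data.frame(alleles),
            all(c("allele_id", "locus_id", "sequence") %in% names(alleles)))
  alleles$allele_id <- as.character(alleles$allele_id)
  alleles$locus_id <- as.character(alleles$locus_id)
  alleles$sequence <- toupper(as.character(alleles$sequence))
  bad <- grepl("[^ACGT]", alleles$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in allele(s): ",
         paste(alleles$allele_id[bad], collapse = ", "))
  }
  key <- paste(alleles$locus_id, alleles$allele_id, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate allele id(s) within a locus: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (is.null(loci)) {
    loci <- vapply(split(nchar(alleles$sequence), alleles$locus_id),
                   function(l) l[1], integer(1))
  } else {
    if (is.null(names(loci))) stop("`loci` must be a named vector of lengths")
    loci <- vapply(loci, as.integer, integer(1))
    missing_locus <- setdiff(alleles$locus_id, names(loci))
    if (length(missing_locus)) {
      stop("allele(s) reference loci absent from `loci`: ",
           paste(missing_locus, collapse = ", "))
    }
  }
  len_ok <- nchar(alleles$sequence) == unname(loci[alleles$locus_id])
  if (!all(len_ok)) {
    stop("allele length differs from its locus's expected length: ",
         paste(alleles$allele_id[!len_ok], collapse = ", "))
  }
  structure(list(alleles = alleles, loci = loci), class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("allele catalog:", nrow(x$alleles), "allele(s) at",
      length(x$loci), "locus/loci\n")
  for (l in names(x$loci)) {
    cat("  ", l, " (", x$loci[[l]], " bp): ",
        sum(x$alleles$locus_id == l), " allele(s)\n", sep = "")
  }
  invisible(x)
}

#' Read an allele catalog from FASTA
#'
#' Headers must encode locus and allele as `locus|allele`. Sequences are
#' uppercased on read; non-ACGT characters and duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return An [allele_catalog()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  has_sep <- grepl("|", headers, fixed = TRUE)
  if (!all(has_sep)) {
    stop("FASTA header(s) missing the 'locus|allele' separator: ",
         paste(headers[!has_sep], collapse = ", "))
  }
  locus_id <- sub("\\|.*$", "", headers)
  allele_id <- sub("^[^|]*\\|", "", headers)
  allele_catalog(data.frame(allele_id = allele_id, locus_id = locus_id,
                            sequence = as.character(seqs),
                            stringsAsFactors = FALSE))
}

#' Write an allele catalog to FASTA
#'
#' Inverse of [read_fasta()]: headers are `locus|allele`.
#'
#' @param catalog an [allele_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "allele_catalog"))
  seqs <- Biostrings::DNAStringSet(catalog$alleles$sequence)
  names(seqs) <- paste(catalog$alleles$locus_id, catalog$alleles$allele_id,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

# sequences of one locus as a named character vector
catalog_sequences <- function(catalog, locus) {
  a <- catalog$alleles[catalog$alleles$locus_id == locus, ]
  stats::setNames(a$sequence, a$allele_id)
}
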