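#' Construct a genotype matrix
#'
#' Per-sample, per-locus unordered diploid allele calls plus the sample
#' metadata (calibrated ages, regions). At most two distinct alleles per
#' (sample, locus) entry; homozygotes are encoded as `allele1 == allele2`.
#'
#' @param calls data.frame with columns `sample_id`, `locus_id`, `allele1`,
#'   `allele2`. A missing (failed) locus is simply an absent row.
#' @param samples data.frame of sample records with columns `sample_id`,
#'   `age_cal_bp` and optionally `age_is_bound`, `region`, `material`.
#'   Defaults to the distinct sample ids in `calls` with `NA` ages.
#' @param catalog optional [allele_catalog()]; when supplied every allele id
#'   must be present in it.
#' @return Object of class `genotype_matrix`: list with `calls` and
#'   `samples` data.frames.
#' @export
genotype_matrix <- function(calls, samples = NULL, catalog = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "locus_id", "allele1", "allele2") %in%
                  names(calls)))
  for (col in c("sample_id", "locus_id", "allele1", "allele2"))
    calls[[col]] <- as.character(calls[[col]])
  key <- paste(calls$sample_id, calls$locus_id)
  if (anyDuplicated(key)) {
    stop("more than one genotype row for (sample, locus): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (!is.null(catalog)) {
    known <- paste(catalog$alleles$locus_id, catalog$alleles$allele_id)
    used <- unique(c(paste(calls$locus_id, calls$allele1),
                     paste(calls$locus_id, calls$allele2)))
    unknown <- setdiff(used, known)
    if (length(unknown)) {
      bad <- calls[paste(calls$locus_id, calls$allele1) %in% unknown |
                     paste(calls$locus_id, calls$allele2) %in% unknown, ]
      stop("allele(s) absent from catalog for sample(s) ",
           paste(unique(paste0(bad$sample_id, "/", bad$locus_id)),
                 collapse = ", "))
    }
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = unique(calls$sample_id),
                          age_cal_bp = NA_real_, stringsAsFactors = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(calls$sample_id %in% samples$sample_id))
    stop("calls reference sample ids missing from the sample table")
  if (!"age_cal_bp" %in% names(samples)) samples$age_cal_bp <- NA_real_
  if (any(!is.na(samples$age_cal_bp) & samples$age_cal_bp < 0))
    stop("age_cal_bp must be non-negative")
  structure(list(calls = calls, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$calls), "calls,",
      nrow(x$samples), "samples,",
      length(unique(x$calls$locus_id)), "locus/loci\n")
  if ("period" %in% names(x$samples))
    print(table(x$samples$period))
  invisible(x)
}

#' Read a genotype table from CSV
#'
#' The canonical interchange format between pipeline stages: one row per
#' (sample, locus) with columns `sample_id`, `age_cal_bp`, `locus_id`,
#' `allele1`, `allele2`. Rows with both allele cells empty (a failed locus)
#' are dropped silently; rows with exactly one empty cell are an error.
#'
#' @param path CSV file.
#' @param catalog optional [allele_catalog()] used to validate allele ids.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, catalog = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "age_cal_bp", "locus_id", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genotype CSV missing column(s): ", paste(miss, collapse = ", "))
  empty1 <- is.na(df$allele1) | df$allele1 == ""
  empty2 <- is.na(df$allele2) | df$allele2 == ""
  if (any(xor(empty1, empty2))) {
    bad <- df[xor(empty1, empty2), ]
    stop("half-empty genotype row(s) for: ",
         paste(paste0(bad$sample_id, "/", bad$locus_id), collapse = ", "))
  }
  calls <- df[!empty1, c("sample_id", "locus_id", "allele1", "allele2")]
  samples <- unique(df[, c("sample_id", "age_cal_bp")])
  samples$age_cal_bp <- as.numeric(samples$age_cal_bp)
  extra <- intersect(c("age_is_bound", "region", "material"), names(df))
  if (length(extra))
    samples <- unique(df[, c("sample_id", "age_cal_bp", extra)])
  samples$age_cal_bp <- as.numeric(samples$age_cal_bp)
  genotype_matrix(calls, samples = samples, catalog = catalog)
}

#' Write a genotype matrix to CSV
#'
#' @param matrix a [genotype_matrix()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  df <- merge(matrix$calls, matrix$samples, by = "sample_id", sort = FALSE)
  first <- c("sample_id", "age_cal_bp", "locus_id", "allele1", "allele2")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign samples to temporal periods
#'
#' Labels every sample `mainland` (strictly older than `mainland_min_age`),
#' `island` (strictly younger than `island_max_age`) or `excluded`
#' (in between). The defaults follow the study design: the continental
#' population predates 13 cal ka; the isolated island population postdates
#' 10 cal ka, after rising sea levels cut Wrangel Island off.
#'
#' @param x a [genotype_matrix()] or a sample data.frame with `age_cal_bp`.
#' @param mainland_min_age years BP; ages above it are mainland.
#' @param island_max_age years BP; ages below it are island.
#' @return Same object with a `period` column added to the sample table.
#' @examples
#' s <- data.frame(sample_id = c("a", "b", "c"),
#'                 age_cal_bp = c(14431, 8318, 11000))
#' assign_periods(s)$period
#' @export
assign_periods <- function(x, mainland_min_age = 13000,
                           island_max_age = 10000) {
  stopifnot(mainland_min_age > island_max_age)
  samples <- if (inherits(x, "genotype_matrix")) x$samples else x
  stopifnot(is.data.frame(samples), "age_cal_bp" %in% names(samples))
  age <- samples$age_cal_bp
  samples$period <- ifelse(age > mainland_min_age, "mainland",
                           ifelse(age < island_max_age, "island",
                                  "excluded"))
  if (inherits(x, "genotype_matrix")) {
    x$samples <- samples
    x
  } else {
    samples
  }
}

#' Radiocarbon-dated sample metadata shipped with the package
#'
#' Calibrated ages (years BP), regions and materials of the 24 specimens
#' genotyped at all three DQA loci. Ages printed as lower bounds
#' (e.g. ">= 49 000") carry `age_is_bound = TRUE` and are used at their
#' bound value.
#'
#' @return data.frame with columns `sample_id`, `age_cal_bp`,
#'   `age_is_bound`, `material`, `region`.
#' @export
mammoth_samples <- function() {
  path <- system.file("extdata", "mammoth_samples.csv",
                      package = "mhcdrift", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$age_is_bound <- as.logical(df$age_is_bound)
  df
}
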