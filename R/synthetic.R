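#' Dual-index tag scheme for pooled amplicon sequencing
#'
#' Both PCR primers carry a 6-nt tag; the (forward, reverse) tag pair
#' identifies a (sample, replicate). Every pair of tags must differ at two
#' or more positions so that a single sequencing error cannot re-assign a
#' read. The default set of 8 tags allows 64 pairs.
#'
#' @param n_samples,n_replicates how many (sample, replicate) slots to pair.
#' @param tags character vector of 6-nt tags.
#' @return Object of class `tag_scheme`: list with `tags` and `pairing`
#'   (data.frame sample_idx, replicate, forward_tag, reverse_tag).
#' @export
tag_scheme <- function(n_samples, n_replicates = 2,
                       tags = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT",
                                "ACACAC", "CACACA", "GTGTGT", "TGTGTG")) {
  stopifnot(all(nchar(tags) == 6), !anyDuplicated(tags))
  n <- length(tags)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (hamming(tags[i], tags[j]) < 2)
        stop("tags must differ at >= 2 positions: ", tags[i], " vs ", tags[j])
    }
  }
  slots <- n_samples * n_replicates
  if (slots > n * n) {
    stop("more sample x replicate slots (", slots,
         ") than tag pairs (", n * n, ")")
  }
  grid <- expand.grid(reverse_tag = tags, forward_tag = tags,
                      stringsAsFactors = FALSE)[seq_len(slots),
                                                c("forward_tag",
                                                  "reverse_tag")]
  pairing <- data.frame(sample_idx = rep(seq_len(n_samples),
                                         each = n_replicates),
                        replicate = rep(seq_len(n_replicates), n_samples),
                        grid, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(tags = tags, pairing = pairing), class = "tag_scheme")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Read error model for synthetic amplicon data
#'
#' @param per_base_error substitution probability per sequenced base.
#' @param deamination_rate probability per read that a single C-to-T (or
#'   G-to-A) post-mortem damage artifact is introduced at a uniformly
#'   chosen eligible site.
#' @param ado_prob probability that one allelic copy fails to amplify
#'   (drops out) in one PCR replicate.
#' @param depth_mean expected number of reads per replicate (Poisson).
#' @return Object of class `read_error_model`.
#' @export
read_error_model <- function(per_base_error = 0, deamination_rate = 0,
                             ado_prob = 0, depth_mean = 100) {
  p <- c(per_base_error, deamination_rate, ado_prob)
  stopifnot(all(p >= 0 & p <= 1), depth_mean > 0)
  structure(list(per_base_error = per_base_error,
                 deamination_rate = deamination_rate,
                 ado_prob = ado_prob, depth_mean = depth_mean),
            class = "read_error_model")
}

#' Draw diploid genotypes from known allele frequencies
#'
#' Hardy-Weinberg sampling: the two gene copies of each individual are
#' drawn independently from the supplied frequencies, per locus. Observed
#' heterozygosity of the draw approaches `1 - sum(p^2)` as `n` grows.
#'
#' @param freqs_per_locus named list; each element a named numeric vector
#'   of allele frequencies (summing to 1) whose names are allele ids.
#' @param n_samples number of diploid individuals.
#' @param seed optional integer seed.
#' @param sample_prefix prefix for generated sample ids.
#' @return A [genotype_matrix()].
#' @export
generate_genotypes <- function(freqs_per_locus, n_samples, seed = NULL,
                               sample_prefix = "S") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(freqs_per_locus), length(freqs_per_locus) > 0,
            n_samples >= 1)
  for (l in names(freqs_per_locus)) {
    f <- freqs_per_locus[[l]]
    if (is.null(names(f))) stop("frequencies must be named by allele id")
    if (abs(sum(f) - 1) > 1e-8)
      stop("frequencies for locus ", l, " sum to ", sum(f), ", not 1")
  }
  ids <- sprintf("%s%0*d", sample_prefix, nchar(n_samples), seq_len(n_samples))
  calls <- do.call(rbind, lapply(names(freqs_per_locus), function(l) {
    f <- freqs_per_locus[[l]]
    a1 <- sample(names(f), n_samples, replace = TRUE, prob = f)
    a2 <- sample(names(f), n_samples, replace = TRUE, prob = f)
    data.frame(sample_id = ids, locus_id = l, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }))
  genotype_matrix(calls)
}

#' Wright-Fisher drift of an allele-frequency vector
#'
#' @param freqs named frequency vector summing to 1.
#' @param generations number of discrete generations.
#' @param N_e diploid effective size (2*N_e gene copies resampled each
#'   generation).
#' @return Drifted frequency vector (same names).
#' @export
drift_frequencies <- function(freqs, generations, N_e) {
  stopifnot(generations >= 0, N_e >= 1)
  f <- freqs
  for (g in seq_len(generations)) {
    counts <- stats::rmultinom(1, 2 * N_e, f)[, 1]
    f <- counts / (2 * N_e)
  }
  f
}

#' Generate a two-stratum temporal dataset with known drift
#'
#' Mainland genotypes are drawn from the founder frequencies; island
#' frequencies are a Wright-Fisher trajectory of the founder frequencies
#' (`drift_generations` generations at diploid size `N_e`), from which the
#' island genotypes are then drawn. With `drift_generations = 0` both
#' strata share the founder frequencies.
#'
#' @param founder_freqs named list of named frequency vectors per locus.
#' @param n_mainland,n_island diploid sample sizes of the two strata.
#' @param drift_generations generations of drift separating the strata.
#' @param N_e diploid effective size during the drift phase.
#' @param seed optional integer seed.
#' @param mainland_age,island_age ages (years BP) stamped on the samples so
#'   that [assign_periods()] reproduces the strata.
#' @return A [genotype_matrix()] with `period` set on the sample table.
#' @export
generate_temporal_dataset <- function(founder_freqs, n_mainland, n_island,
                                      drift_generations, N_e, seed = NULL,
                                      mainland_age = 20000,
                                      island_age = 5000) {
  if (!is.null(seed)) set.seed(seed)
  island_freqs <- lapply(founder_freqs, drift_frequencies,
                         generations = drift_generations, N_e = N_e)
  main <- generate_genotypes(founder_freqs, n_mainland,
                             sample_prefix = "ML")
  isl <- generate_genotypes(island_freqs, n_island, sample_prefix = "WI")
  calls <- rbind(main$calls, isl$calls)
  samples <- rbind(
    data.frame(sample_id = unique(main$calls$sample_id),
               age_cal_bp = mainland_age, stringsAsFactors = FALSE),
    data.frame(sample_id = unique(isl$calls$sample_id),
               age_cal_bp = island_age, stringsAsFactors = FALSE))
  assign_periods(genotype_matrix(calls, samples = samples))
}

#' Default synthetic primer pairs
#'
#' Fixed arbitrary primer sequences per locus for the read generator and
#' trimmer. Any named list of `c(forward, reverse)` pairs may be used
#' instead.
#'
#' @param loci locus ids.
#' @return named list of length-2 character vectors (forward, reverse),
#'   both given 5'->3' on their own strand.
#' @export
default_primers <- function(loci) {
  pool <- c("TGACCGATTCGAGCTTAGGA", "CGTTAGCACCTGAAGTCGAC",
            "GATCCTAGGTTCAACGTGCA", "ACGGTTCGATCCATGGACTA",
            "TTGCAGGATCCGTAACGTCA", "GGAACTTCGCATGATCCGTA",
            "CATGGTACCGAATTCGGACT", "TGGATCGTACGCTTAAGCCA")
  if (2 * length(loci) > length(pool))
    stop("not enough built-in primers for ", length(loci), " loci")
  out <- list()
  for (i in seq_along(loci)) {
    out[[loci[i]]] <- c(pool[2 * i - 1], pool[2 * i])
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute each base independently with prob p (uniform over other bases)
add_base_errors <- function(seq, p) {
  if (p <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < p)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

# at most one C->T (or G->A) artifact per read, uniform over eligible sites
add_deamination <- function(seq, rate) {
  if (rate <= 0 || stats::runif(1) >= rate) return(seq)
  bases <- strsplit(seq, "")[[1]]
  eligible <- which(bases %in% c("C", "G"))
  if (!length(eligible)) return(seq)
  i <- eligible[sample.int(length(eligible), 1)]
  bases[i] <- if (bases[i] == "C") "T" else "A"
  paste(bases, collapse = "")
}

#' Generate tagged amplicon reads with known ground truth
#'
#' Each (sample, replicate, locus) amplification yields a Poisson number of
#' reads of layout `forward_tag + forward_primer + allele +
#' revcomp(reverse_primer) + revcomp(reverse_tag)`. Allelic dropout removes
#' a gene copy from a replicate before reads are drawn; per-base error and
#' at most one deamination artifact per read are applied to the allele
#' insert. Replicates are independent PCRs sharing the genotype.
#'
#' @param genotypes a [genotype_matrix()].
#' @param catalog an [allele_catalog()] providing allele sequences.
#' @param scheme a [tag_scheme()] with at least
#'   `n_samples * n_replicates` pairs.
#' @param error_model a [read_error_model()].
#' @param n_replicates PCR replicates per sample (default 2).
#' @param primers named list of `c(forward, reverse)` primer pairs per
#'   locus; default [default_primers()].
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame read_id, sequence), `truth`
#'   (data.frame sample_id, locus_id, replicate, allele1, allele2,
#'   a1_dropped, a2_dropped) and `primers`.
#' @export
generate_reads <- function(genotypes, catalog, scheme,
                           error_model = read_error_model(),
                           n_replicates = 2, primers = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(catalog, "allele_catalog"),
            inherits(scheme, "tag_scheme"),
            inherits(error_model, "read_error_model"))
  loci <- unique(genotypes$calls$locus_id)
  if (is.null(primers)) primers <- default_primers(loci)
  sample_ids <- unique(genotypes$calls$sample_id)
  if (length(sample_ids) * n_replicates > nrow(scheme$pairing))
    stop("tag scheme has too few pairs for ", length(sample_ids),
         " samples x ", n_replicates, " replicates")
  pair_of <- scheme$pairing
  pair_of$sample_id <- sample_ids[pair_of$sample_idx]

  reads <- list()
  truth <- list()
  k <- 0L
  for (r in seq_len(nrow(genotypes$calls))) {
    call <- genotypes$calls[r, ]
    seqs <- catalog_sequences(catalog, call$locus_id)
    pr <- primers[[call$locus_id]]
    if (is.null(pr)) stop("no primers for locus ", call$locus_id)
    for (rep_i in seq_len(n_replicates)) {
      tags <- pair_of[pair_of$sample_id == call$sample_id &
                        pair_of$replicate == rep_i, ]
      copies <- c(call$allele1, call$allele2)
      dropped <- stats::runif(2) < error_model$ado_prob
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = call$sample_id, locus_id = call$locus_id,
        replicate = rep_i, allele1 = call$allele1, allele2 = call$allele2,
        a1_dropped = dropped[1], a2_dropped = dropped[2],
        stringsAsFactors = FALSE)
      surviving <- copies[!dropped]
      if (!length(surviving)) next
      depth <- stats::rpois(1, error_model$depth_mean)
      if (depth == 0) next
      src <- sample(surviving, depth, replace = TRUE)
      for (a in src) {
        insert <- seqs[[a]]
        insert <- add_base_errors(insert, error_model$per_base_error)
        insert <- add_deamination(insert, error_model$deamination_rate)
        k <- k + 1L
        reads[[k]] <- data.frame(
          read_id = sprintf("read%07d", k),
          sequence = paste0(tags$forward_tag, pr[1], insert,
                            revcomp(pr[2]), revcomp(tags$reverse_tag)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = if (k) do.call(rbind, reads) else
         data.frame(read_id = character(), sequence = character()),
       truth = do.call(rbind, truth), primers = primers)
}

#' Write reads as 4-line FASTQ (constant quality)
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param path output FASTQ.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}
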