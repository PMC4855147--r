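#' Demultiplex dual-tagged reads
#'
#' A read is assigned to a (sample, replicate) slot iff both its 5' tag
#' (first 6 bases) and its 3' tag (reverse complement of the last 6 bases)
#' match a scheme tag within `max_mismatch`, and the resulting tag pair is
#' in the scheme's pairing. Reads whose tag is ambiguous (two scheme tags
#' within tolerance) or unmatched go to the unassigned bin with a reason.
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param scheme a [tag_scheme()].
#' @param max_mismatch per-tag mismatch tolerance (default 1).
#' @return list with `assigned` (read_id, sequence with tags stripped,
#'   sample_idx, replicate) and `unassigned` (read_id, reason).
#' @export
demultiplex <- function(reads, scheme, max_mismatch = 1) {
  stopifnot(inherits(scheme, "tag_scheme"))
  tags <- scheme$tags
  pairing_key <- paste(scheme$pairing$forward_tag,
                       scheme$pairing$reverse_tag)
  assigned <- list()
  unassigned <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    n <- nchar(s)
    if (n < 12) {
      unassigned[[length(unassigned) + 1L]] <-
        data.frame(read_id = reads$read_id[i], reason = "too_short")
      next
    }
    t5 <- substr(s, 1, 6)
    t3 <- revcomp(substr(s, n - 5, n))
    m5 <- match_tag(t5, tags, max_mismatch)
    m3 <- match_tag(t3, tags, max_mismatch)
    reason <- NULL
    if (is.na(m5) || is.na(m3)) {
      reason <- "tag_unmatched"
    } else if (m5 == 0L || m3 == 0L) {
      reason <- "tag_ambiguous"
    }
    if (is.null(reason)) {
      slot <- match(paste(tags[m5], tags[m3]), pairing_key)
      if (is.na(slot)) reason <- "pair_not_in_scheme"
    }
    if (is.null(reason)) {
      assigned[[length(assigned) + 1L]] <- data.frame(
        read_id = reads$read_id[i],
        sequence = substr(s, 7, n - 6),
        sample_idx = scheme$pairing$sample_idx[slot],
        replicate = scheme$pairing$replicate[slot],
        stringsAsFactors = FALSE)
    } else {
      unassigned[[length(unassigned) + 1L]] <-
        data.frame(read_id = reads$read_id[i], reason = reason)
    }
  }
  empty_a <- data.frame(read_id = character(), sequence = character(),
                        sample_idx = integer(), replicate = integer())
  empty_u <- data.frame(read_id = character(), reason = character())
  list(assigned = if (length(assigned)) do.call(rbind, assigned) else empty_a,
       unassigned = if (length(unassigned)) do.call(rbind, unassigned)
                    else empty_u)
}

# index of the unique tag within max_mismatch; NA if none, 0L if ambiguous
match_tag <- function(obs, tags, max_mismatch) {
  d <- vapply(tags, hamming, numeric(1), b = obs)
  hits <- which(d <= max_mismatch)
  if (length(hits) == 0) NA_integer_
  else if (length(hits) > 1) 0L
  else hits
}

#' Trim locus primers from demultiplexed reads
#'
#' Matches each read's prefix against a locus's forward primer and its
#' suffix against the reverse complement of the reverse primer, both
#' within `max_mismatch`. Reads matching exactly one locus are trimmed to
#' the inter-primer fragment; reads without both primers (or matching more
#' than one locus) are dropped and counted, never fatal.
#'
#' @param reads data.frame with `read_id`, `sequence` (tags already
#'   stripped, e.g. by [demultiplex()]).
#' @param primer_pairs named list of `c(forward, reverse)` per locus.
#' @param max_mismatch per-primer mismatch tolerance (default 1).
#' @return list with `trimmed` (read table plus `locus_id`) and `dropped`
#'   (read_id, reason).
#' @export
trim_primers <- function(reads, primer_pairs, max_mismatch = 1) {
  rc_rev <- lapply(primer_pairs, function(p) revcomp(p[2]))
  trimmed <- list()
  dropped <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    n <- nchar(s)
    hit <- character(0)
    for (l in names(primer_pairs)) {
      fp <- primer_pairs[[l]][1]
      rp <- rc_rev[[l]]
      if (n < nchar(fp) + nchar(rp)) next
      ok_f <- hamming(substr(s, 1, nchar(fp)), fp) <= max_mismatch
      ok_r <- hamming(substr(s, n - nchar(rp) + 1, n), rp) <= max_mismatch
      if (ok_f && ok_r) hit <- c(hit, l)
    }
    if (length(hit) == 1) {
      fp_n <- nchar(primer_pairs[[hit]][1])
      rp_n <- nchar(rc_rev[[hit]])
      row <- reads[i, , drop = FALSE]
      row$sequence <- substr(s, fp_n + 1, n - rp_n)
      row$locus_id <- hit
      trimmed[[length(trimmed) + 1L]] <- row
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        read_id = reads$read_id[i],
        reason = if (length(hit)) "multiple_locus_match" else
          "primer_not_found", stringsAsFactors = FALSE)
    }
  }
  list(trimmed = if (length(trimmed)) do.call(rbind, trimmed) else
         cbind(reads[0, , drop = FALSE], locus_id = character()),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(read_id = character(), reason = character()))
}

#' Cluster one replicate's reads by exact sequence identity
#'
#' Identical reads form a cluster; clusters holding at least
#' `min_frequency` of the replicate's reads (inclusive) become allele
#' candidates. Clusters are ordered by read count, ties broken by
#' lexicographic sequence order, so outputs are deterministic.
#'
#' @param sequences character vector of trimmed read sequences.
#' @param min_frequency candidate threshold as a fraction of reads
#'   (default 0.05).
#' @return Object of class `cluster_set`: data.frame `clusters` with
#'   `sequence`, `count`, `frequency`, `candidate`; or a failed set for
#'   empty input.
#' @export
cluster_replicate <- function(sequences, min_frequency = 0.05) {
  if (length(sequences) == 0) {
    return(structure(list(clusters = data.frame(
      sequence = character(), count = integer(), frequency = numeric(),
      candidate = logical()), n_reads = 0L, failed = TRUE),
      class = "cluster_set"))
  }
  tab <- table(sequences)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df$frequency <- df$count / sum(df$count)
  df$candidate <- df$frequency >= min_frequency
  structure(list(clusters = df, n_reads = length(sequences),
                 failed = FALSE), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster set:", nrow(x$clusters), "cluster(s),", x$n_reads,
      "reads,", sum(x$clusters$candidate), "candidate(s)\n")
  invisible(x)
}

candidates_of <- function(cs) {
  if (inherits(cs, "cluster_set")) cs$clusters$sequence[cs$clusters$candidate]
  else as.character(cs)
}

# TRUE iff a and b have equal length and differ only by C<->T / G<->A
# substitutions (at least one difference) - the signature of post-mortem
# cytosine deamination on either strand
is_damage_variant <- function(a, b) {
  if (nchar(a) != nchar(b) || a == b) return(FALSE)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- which(av != bv)
  all(vapply(d, function(i) {
    p <- sort(c(av[i], bv[i]))
    identical(p, c("C", "T")) || identical(p, c("A", "G"))
  }, logical(1)))
}

#' Reconcile replicate candidate sets into a consensus genotype
#'
#' Candidates present in both primary replicates are accepted. A candidate
#' seen in only one replicate (a "singleton") is discarded when it differs
#' from an accepted candidate only by C/T and/or G/A changes - the
#' deamination damage signature - unless an identical sequence is among
#' the accepted alleles of any other sample (`dataset_allele_pool`) or in
#' an external allele list, in which case it is retained. Singletons not
#' explained by damage force a failed call unless a third replicate
#' arbitrates (majority over three replicates). One accepted allele gives
#' a homozygote pending a concordant third replicate; two give a
#' heterozygote; more than two fail the sample (contamination/paralogy
#' flag).
#'
#' @param cluster_sets list of 2 (optionally 3) [cluster_replicate()]
#'   results, or plain character vectors of candidate sequences.
#' @param dataset_allele_pool accepted allele sequences from other samples
#'   in the run.
#' @param external_alleles user-supplied external catalog sequences (e.g.
#'   a related species' alleles).
#' @return Object of class `consensus_genotype`: list with `alleles`,
#'   `status` (one of heterozygote, homozygote_confirmed,
#'   homozygote_pending_third_replicate, failed) and `discarded`
#'   (data.frame sequence, reason).
#' @export
reconcile_replicates <- function(cluster_sets,
                                 dataset_allele_pool = character(),
                                 external_alleles = character()) {
  reps <- lapply(cluster_sets, candidates_of)
  n_rep <- length(reps)
  if (n_rep < 2 || n_rep > 3)
    stop("expected 2 primary replicates (plus an optional third), got ",
         n_rep)
  rescue <- unique(c(dataset_allele_pool, external_alleles))
  discarded <- data.frame(sequence = character(), reason = character(),
                          stringsAsFactors = FALSE)
  all_cand <- unique(unlist(reps))
  support <- vapply(all_cand,
                    function(s) sum(vapply(reps, function(r) s %in% r,
                                           logical(1))), integer(1))

  if (n_rep == 3) {
    accepted <- all_cand[support >= 2]
    minority <- all_cand[support == 1]
    if (length(minority)) {
      discarded <- rbind(discarded, data.frame(
        sequence = minority, reason = "no_majority_in_three_replicates"))
    }
  } else {
    accepted <- all_cand[support == 2]
    singletons <- all_cand[support == 1]
    unresolved <- character(0)
    for (s in singletons) {
      if (s %in% rescue) {
        accepted <- c(accepted, s)
      } else if (length(accepted) &&
                 any(vapply(accepted, is_damage_variant, logical(1),
                            b = s))) {
        discarded <- rbind(discarded, data.frame(
          sequence = s, reason = "deamination_singleton"))
      } else {
        unresolved <- c(unresolved, s)
      }
    }
    if (length(unresolved)) {
      discarded <- rbind(discarded, data.frame(
        sequence = unresolved, reason = "unresolved_singleton"))
      return(structure(list(alleles = sort(accepted), status = "failed",
                            discarded = discarded),
                       class = "consensus_genotype"))
    }
  }

  accepted <- sort(unique(accepted))
  status <-
    if (length(accepted) == 0) "failed"
    else if (length(accepted) > 2) "failed"
    else if (length(accepted) == 2) "heterozygote"
    else if (n_rep == 3) "homozygote_confirmed"
    else "homozygote_pending_third_replicate"
  structure(list(alleles = accepted, status = status,
                 discarded = discarded), class = "consensus_genotype")
}

#' @export
print.consensus_genotype <- function(x, ...) {
  cat("consensus:", x$status, "-", length(x$alleles), "allele(s);",
      nrow(x$discarded), "discarded\n")
  invisible(x)
}

#' Call genotypes from demultiplexed, trimmed reads
#'
#' Runs the full scoring procedure for every (sample, locus): per-replicate
#' identical-read clustering at `min_frequency`, then replicate
#' reconciliation with the damage filter. Reconciliation is done in two
#' passes so that the cross-sample rescue pool contains the alleles
#' accepted in both replicates of every other sample.
#'
#' @param reads data.frame with `sequence`, `sample_id`, `replicate`,
#'   `locus_id` (e.g. [demultiplex()] + [trim_primers()] output, with
#'   `sample_idx` mapped to ids).
#' @param min_frequency candidate threshold (default 0.05).
#' @param external_alleles external rescue catalog (sequences).
#' @return list with `consensus` (data.frame sample_id, locus_id, allele1,
#'   allele2, status), `genotypes` (a [genotype_matrix()] of the
#'   non-failed calls, alleles named by sequence), `discards` and
#'   `cluster_sets`.
#' @export
call_genotypes <- function(reads, min_frequency = 0.05,
                           external_alleles = character()) {
  stopifnot(all(c("sequence", "sample_id", "replicate", "locus_id") %in%
                  names(reads)))
  groups <- split(reads, list(reads$sample_id, reads$locus_id),
                  drop = TRUE, sep = "\r")
  n_rep <- max(reads$replicate)
  cluster_sets <- lapply(groups, function(g) {
    lapply(seq_len(n_rep), function(r) {
      cluster_replicate(g$sequence[g$replicate == r],
                        min_frequency = min_frequency)
    })
  })
  # pass 1: provisional consensus with no rescue pool
  pass1 <- lapply(cluster_sets, reconcile_replicates,
                  external_alleles = external_alleles)
  meta <- do.call(rbind, strsplit(names(cluster_sets), "\r", fixed = TRUE))
  pool_by_group <- lapply(pass1, function(x) x$alleles)
  # pass 2: rescue pool = alleles accepted for any *other* sample
  consensus <- vector("list", length(cluster_sets))
  discards <- list()
  for (i in seq_along(cluster_sets)) {
    others <- unlist(pool_by_group[meta[, 1] != meta[i, 1]],
                     use.names = FALSE)
    cg <- reconcile_replicates(cluster_sets[[i]],
                               dataset_allele_pool = unique(others),
                               external_alleles = external_alleles)
    al <- cg$alleles
    consensus[[i]] <- data.frame(
      sample_id = meta[i, 1], locus_id = meta[i, 2],
      allele1 = if (length(al)) al[1] else NA_character_,
      allele2 = if (length(al) >= 2) al[2] else
        if (length(al)) al[1] else NA_character_,
      status = cg$status, stringsAsFactors = FALSE)
    if (nrow(cg$discarded)) {
      discards[[length(discards) + 1L]] <-
        cbind(sample_id = meta[i, 1], locus_id = meta[i, 2], cg$discarded)
    }
  }
  consensus <- do.call(rbind, consensus)
  ok <- consensus$status != "failed" & !is.na(consensus$allele1)
  gm <- genotype_matrix(consensus[ok, c("sample_id", "locus_id",
                                        "allele1", "allele2")])
  list(consensus = consensus, genotypes = gm,
       discards = if (length(discards)) do.call(rbind, discards) else
         data.frame(sample_id = character(), locus_id = character(),
                    sequence = character(), reason = character()),
       cluster_sets = cluster_sets)
}

#' Estimate the allelic dropout rate
#'
#' Allelic dropout (ADO) is the failure of one allele of a true
#' heterozygote to amplify in a PCR replicate. The rate is the fraction of
#' replicate amplifications of consensus-heterozygous (sample, locus)
#' entries that show only one of the two consensus alleles. The
#' probability that a sample scored homozygous from `k` concordant
#' replicates is a false negative is `ado_rate^k`.
#'
#' @param consensus data.frame with `sample_id`, `locus_id`, `allele1`,
#'   `allele2`, `status` (from [call_genotypes()]).
#' @param replicate_candidates data.frame with `sample_id`, `locus_id`,
#'   `replicate`, `sequence`: the candidate alleles of each replicate.
#' @param k number of concordant homozygous replicates backing a
#'   homozygote call (default 2).
#' @return Object of class `ado_estimate`: list with `ado_rate`,
#'   `n_informative`, `n_dropout`, `false_negative_prob`, `k`.
#' @export
estimate_ado <- function(consensus, replicate_candidates, k = 2) {
  het <- consensus[consensus$status == "heterozygote", , drop = FALSE]
  if (!nrow(het)) {
    return(structure(list(ado_rate = NA_real_, n_informative = 0L,
                          n_dropout = 0L, false_negative_prob = NA_real_,
                          k = k, undefined = TRUE),
                     class = "ado_estimate"))
  }
  n_inf <- 0L
  n_drop <- 0L
  for (i in seq_len(nrow(het))) {
    rc <- replicate_candidates[
      replicate_candidates$sample_id == het$sample_id[i] &
        replicate_candidates$locus_id == het$locus_id[i], , drop = FALSE]
    for (r in unique(rc$replicate)) {
      present <- c(het$allele1[i], het$allele2[i]) %in%
        rc$sequence[rc$replicate == r]
      if (!any(present)) next      # total failure, not ADO-informative
      n_inf <- n_inf + 1L
      if (sum(present) == 1) n_drop <- n_drop + 1L
    }
  }
  if (n_inf == 0L) {
    return(structure(list(ado_rate = NA_real_, n_informative = 0L,
                          n_dropout = 0L, false_negative_prob = NA_real_,
                          k = k, undefined = TRUE),
                     class = "ado_estimate"))
  }
  rate <- n_drop / n_inf
  structure(list(ado_rate = rate, n_informative = n_inf,
                 n_dropout = n_drop, false_negative_prob = rate^k,
                 k = k, undefined = FALSE), class = "ado_estimate")
}

#' @export
print.ado_estimate <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("ADO estimate: undefined (no informative amplifications)\n")
  } else {
    cat(sprintf(
      "ADO rate %.4f (%d/%d amplifications); P(false homozygote | %d concordant replicates) = %.4f\n",
      x$ado_rate, x$n_dropout, x$n_informative, x$k,
      x$false_negative_prob))
  }
  invisible(x)
}
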