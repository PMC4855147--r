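# Shared fixtures and independent oracles, all built in code.

# aliases for package internals exercised directly by tests
revcomp <- function(x) mhcdrift:::revcomp(x)
candidates_of <- function(x) mhcdrift:::candidates_of(x)
is_damage_variant <- function(a, b) mhcdrift:::is_damage_variant(a, b)

# n allele sequences of a given length, mutually distinguishable and not
# mere C/T-G/A variants of one another (variant i carries an A<->C change
# at position i plus a second change further right)
make_allele_seqs <- function(len, n, prefix = "a") {
  base <- substr(strrep("ACGTTGCA", ceiling(len / 8)), 1, len)
  out <- character(n)
  out[1] <- base
  if (n > 1) {
    for (i in 2:n) {
      b <- strsplit(base, "")[[1]]
      b[i] <- if (b[i] == "A") "C" else "A"
      b[len - i + 1] <- if (b[len - i + 1] == "G") "C" else "G"
      out[i] <- paste(b, collapse = "")
    }
  }
  stats::setNames(out, paste0(prefix, seq_len(n)))
}

make_test_catalog <- function(loci = c(ex2 = 99L, in2a = 89L, ex4 = 92L),
                              n_alleles = 7) {
  alleles <- do.call(rbind, lapply(names(loci), function(l) {
    s <- make_allele_seqs(loci[[l]], n_alleles, prefix = paste0(l, "_"))
    data.frame(allele_id = names(s), locus_id = l, sequence = unname(s),
               stringsAsFactors = FALSE)
  }))
  allele_catalog(alleles, loci = loci)
}

# genotype matrix realizing the printed per-locus diversity table:
# heterozygote counts from round(H_O * n), allele counts and unique-allele
# structure as printed
printed_diversity_matrix <- function() {
  het_pairs <- function(a, k) {
    # k distinct unordered heterozygous pairs over alleles a
    idx <- cbind(seq_along(a), c(seq_along(a)[-1], 1))
    pairs <- list()
    off <- 1
    while (length(pairs) < k) {
      for (i in seq_along(a)) {
        j <- ((i + off - 1) %% length(a)) + 1
        if (i != j) pairs[[length(pairs) + 1]] <- c(a[i], a[j])
        if (length(pairs) == k) break
      }
      off <- off + 1
    }
    pairs
  }
  build <- function(locus, ids, alleles, n_het, n_hom) {
    hp <- het_pairs(alleles, n_het)
    hom <- rep(alleles, length.out = n_hom)
    g <- c(lapply(seq_len(n_het), function(i) hp[[i]]),
           lapply(hom, function(a) c(a, a)))
    do.call(rbind, lapply(seq_along(g), function(i) {
      data.frame(sample_id = ids[i], locus_id = locus,
                 allele1 = g[[i]][1], allele2 = g[[i]][2],
                 stringsAsFactors = FALSE)
    }))
  }
  m_ids <- sprintf("M%02d", 1:12)
  w_ids <- sprintf("W%02d", 1:12)
  calls <- rbind(
    build("exon2", m_ids, paste0("e", 1:7), 10, 2),
    build("exon2", w_ids, paste0("e", 1:5), 7, 5),
    build("intron2a", m_ids, paste0("i", 1:7), 11, 1),
    build("intron2a", w_ids, paste0("i", 1:5), 7, 5),
    build("exon4", m_ids, paste0("x", 1:5), 12, 0),
    build("exon4", w_ids, paste0("x", 1:2), 4, 8))
  samples <- data.frame(sample_id = c(m_ids, w_ids),
                        age_cal_bp = rep(c(20000, 5000), each = 12))
  assign_periods(genotype_matrix(calls, samples = samples))
}

# closed-form Ewens expectation of the number of alleles in a sample of
# n gene copies under the neutral infinite-alleles model
ewens_expected_k <- function(theta, n) sum(theta / (theta + 0:(n - 1)))

# independent site-count oracle built on seqinr's translation
oracle_site_counts <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  tr <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
  S <- 0
  N <- 0
  for (cd in codons) {
    aa <- tr(cd)
    b <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
        mb <- b
        mb[pos] <- alt
        maa <- tr(paste(mb, collapse = ""))
        if (maa == "*") next
        if (maa == aa) S <- S + 1 / 3 else N <- N + 1 / 3
      }
    }
  }
  c(S = S, N = N)
}

# brute-force rarefaction: average number of distinct alleles over every
# subset of g gene copies
bruteforce_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2, function(ix) length(unique(copies[ix]))))
}
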