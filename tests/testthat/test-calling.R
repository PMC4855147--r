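make_read_df <- function(seqs) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("demultiplexing tolerates one tag mismatch but not two", {
  sc <- tag_scheme(2, 2)
  insert <- strrep("ACGT", 10)
  mk <- function(ft, rt) paste0(ft, insert, revcomp(rt))
  p <- sc$pairing
  exact <- mk(p$forward_tag[1], p$reverse_tag[1])
  one_mm <- mk(sub("^.", "T", p$forward_tag[1]), p$reverse_tag[1])
  # forward tag 1 is AAAAAA; two mismatches takes it beyond tolerance
  two_mm <- mk(sub("^..", "TT", p$forward_tag[1]), p$reverse_tag[1])
  out <- demultiplex(make_read_df(c(exact, one_mm, two_mm)), sc)
  expect_equal(nrow(out$assigned), 2)
  expect_equal(out$assigned$sample_idx, c(1L, 1L))
  expect_equal(out$assigned$replicate, c(1L, 1L))
  expect_equal(out$assigned$sequence, rep(insert, 2))
  expect_equal(out$unassigned$read_id, "r003")
})

test_that("ambiguous tags are routed to the unassigned bin", {
  # a 6-mer exactly 1 away from two scheme tags is ambiguous
  sc <- tag_scheme(2, 2, tags = c("AAAAAA", "AAAATT", "GGGGGG", "TTTTTT"))
  insert <- strrep("ACGT", 10)
  ambig <- paste0("AAAAAT", insert, revcomp("AAAAAA"))
  out <- demultiplex(make_read_df(ambig), sc)
  expect_equal(nrow(out$assigned), 0)
  expect_equal(out$unassigned$reason, "tag_ambiguous")
})

test_that("primer trimming returns the inter-primer fragment", {
  primers <- default_primers(c("ex2", "in2a"))
  allele <- strrep("ACGTTGCA", 12)
  good <- paste0(primers$ex2[1], allele, revcomp(primers$ex2[2]))
  mm1 <- paste0(sub("^.", "A", sub("^T", "G", primers$ex2[1])), allele,
                revcomp(primers$ex2[2]))
  no_rev <- paste0(primers$ex2[1], allele)
  out <- trim_primers(make_read_df(c(good, mm1, no_rev)), primers)
  expect_equal(nrow(out$trimmed), 2)
  expect_equal(unique(out$trimmed$sequence), allele)
  expect_equal(unique(out$trimmed$locus_id), "ex2")
  expect_equal(out$dropped$reason, "primer_not_found")
})

test_that("clustering applies the >= 5% threshold inclusively", {
  a <- strrep("AC", 20)
  b <- strrep("AG", 20)
  # 96:4 -> only A; 95:5 (exactly 5%) -> both
  cs1 <- cluster_replicate(c(rep(a, 96), rep(b, 4)))
  expect_equal(cs1$clusters$sequence[cs1$clusters$candidate], a)
  cs2 <- cluster_replicate(c(rep(a, 95), rep(b, 5)))
  expect_setequal(cs2$clusters$sequence[cs2$clusters$candidate], c(a, b))
  cs3 <- cluster_replicate(rep(a, 100))
  expect_equal(cs3$clusters$frequency, 1)
  expect_true(cluster_replicate(character(0))$failed)
})

test_that("raising the frequency threshold never adds candidates", {
  set.seed(42)
  pool <- vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T"), 30,
                                              replace = TRUE),
                                        collapse = ""), character(1))
  for (rep_i in 1:10) {
    reads <- sample(pool, 200, replace = TRUE,
                    prob = stats::runif(6))
    prev <- NULL
    for (thr in c(0.01, 0.05, 0.1, 0.3)) {
      cand <- candidates_of(cluster_replicate(reads, thr))
      if (!is.null(prev)) expect_true(all(cand %in% prev))
      prev <- cand
    }
  }
})

test_that("replicate reconciliation follows the scoring rules", {
  A <- strrep("ACGGTCAT", 12)
  B <- sub("C", "T", A)  # differs from A by one C->T change

  # both replicates agree on two alleles -> heterozygote
  r <- reconcile_replicates(list(c(A, B), c(A, B)))
  expect_equal(r$status, "heterozygote")
  expect_setequal(r$alleles, c(A, B))

  # concordant homozygote needs a third replicate to confirm
  r2 <- reconcile_replicates(list(A, A))
  expect_equal(r2$status, "homozygote_pending_third_replicate")
  r3 <- reconcile_replicates(list(A, A, A))
  expect_equal(r3$status, "homozygote_confirmed")

  # damage singleton (C/T difference, found nowhere else) is discarded
  r4 <- reconcile_replicates(list(c(A, B), A))
  expect_equal(r4$status, "homozygote_pending_third_replicate")
  expect_equal(r4$alleles, A)
  expect_equal(r4$discarded$reason, "deamination_singleton")

  # ... unless an identical sequence was accepted in another sample
  r5 <- reconcile_replicates(list(c(A, B), A), dataset_allele_pool = B)
  expect_equal(r5$status, "heterozygote")
  expect_setequal(r5$alleles, c(A, B))

  # ... or is in the external allele list
  r6 <- reconcile_replicates(list(c(A, B), A), external_alleles = B)
  expect_equal(r6$status, "heterozygote")

  # a singleton not explained by damage fails the call
  D <- sub("G", "C", A)  # G->C is not a deamination signature
  r7 <- reconcile_replicates(list(c(A, D), A))
  expect_equal(r7$status, "failed")
  expect_true("unresolved_singleton" %in% r7$discarded$reason)

  # more than two concordant candidates flags contamination
  E <- sub("T", "A", A)
  r8 <- reconcile_replicates(list(c(A, D, E), c(A, D, E)))
  expect_equal(r8$status, "failed")
})

test_that("damage-variant detection is restricted to C/T and G/A changes", {
  A <- "ACGT"
  expect_true(is_damage_variant("ATGT", A))   # C->T
  expect_true(is_damage_variant("ACAT", A))   # G->A
  expect_true(is_damage_variant("ATAT", A))   # both
  expect_false(is_damage_variant("CCGT", A))  # A->C
  expect_false(is_damage_variant(A, A))       # identical
  expect_false(is_damage_variant("ACG", A))   # length mismatch
})

test_that("zero-error synthetic pipeline recovers the truth exactly", {
  catalog <- make_test_catalog(n_alleles = 4)
  freqs <- lapply(stats::setNames(names(catalog$loci),
                                  names(catalog$loci)), function(l) {
    a <- catalog$alleles$allele_id[catalog$alleles$locus_id == l]
    stats::setNames(rep(1 / length(a), length(a)), a)
  })
  gm <- generate_genotypes(freqs, 8, seed = 11)
  sc <- tag_scheme(8, 2)
  out <- generate_reads(gm, catalog, sc,
                        read_error_model(depth_mean = 60), seed = 12)
  dm <- demultiplex(out$reads, sc)
  expect_equal(nrow(dm$unassigned), 0)
  tr <- trim_primers(dm$assigned, out$primers)
  expect_equal(nrow(tr$dropped), 0)
  sample_ids <- unique(gm$calls$sample_id)
  tr$trimmed$sample_id <- sample_ids[tr$trimmed$sample_idx]
  called <- call_genotypes(tr$trimmed)
  expect_true(all(called$consensus$status %in%
                    c("heterozygote", "homozygote_pending_third_replicate")))
  # compare called sequences against the intended genotypes
  seq_of <- stats::setNames(catalog$alleles$sequence,
                            paste(catalog$alleles$locus_id,
                                  catalog$alleles$allele_id))
  for (i in seq_len(nrow(gm$calls))) {
    want <- sort(unname(seq_of[paste(gm$calls$locus_id[i],
                                     c(gm$calls$allele1[i],
                                       gm$calls$allele2[i]))]))
    got <- called$consensus[
      called$consensus$sample_id == gm$calls$sample_id[i] &
        called$consensus$locus_id == gm$calls$locus_id[i], ]
    expect_equal(sort(unique(c(got$allele1, got$allele2))),
                 sort(unique(want)))
  }
})

test_that("injected deamination is removed by the damage filter", {
  catalog <- make_test_catalog(loci = c(ex2 = 99L), n_alleles = 3)
  freqs <- list(ex2 = stats::setNames(rep(1 / 3, 3),
                                      paste0("ex2_", 1:3)))
  gm <- generate_genotypes(freqs, 6, seed = 21)
  sc <- tag_scheme(6, 2)
  out <- generate_reads(gm, catalog, sc,
                        read_error_model(deamination_rate = 0.15,
                                         depth_mean = 80), seed = 22)
  dm <- demultiplex(out$reads, sc)
  tr <- trim_primers(dm$assigned, out$primers)
  sample_ids <- unique(gm$calls$sample_id)
  tr$trimmed$sample_id <- sample_ids[tr$trimmed$sample_idx]
  called <- call_genotypes(tr$trimmed)
  # every damage-discarded sequence differs from an accepted allele only
  # at C/T or G/A positions
  disc <- called$discards[called$discards$reason == "deamination_singleton", ]
  if (nrow(disc)) {
    accepted <- unique(c(called$consensus$allele1,
                         called$consensus$allele2))
    accepted <- accepted[!is.na(accepted)]
    for (s in disc$sequence) {
      expect_true(any(vapply(accepted, is_damage_variant, logical(1),
                             b = s)))
    }
  }
  # no spurious extra alleles survive: all calls use true catalog sequences
  ok <- called$consensus$status != "failed"
  expect_true(all(c(called$consensus$allele1[ok],
                    called$consensus$allele2[ok]) %in%
                    catalog$alleles$sequence))
})

test_that("ADO estimator recovers an injected dropout rate", {
  # direct binomial check on synthetic per-replicate candidate tables
  set.seed(33)
  ado <- 0.2
  n_entries <- 250  # 500 replicate amplifications of heterozygotes
  cons <- data.frame(sample_id = sprintf("s%03d", 1:n_entries),
                     locus_id = "l", allele1 = "A", allele2 = "B",
                     status = "heterozygote")
  rc <- list()
  for (i in seq_len(n_entries)) {
    for (r in 1:2) {
      drop1 <- stats::runif(1) < ado
      seqs <- if (drop1) "A" else c("A", "B")
      rc[[length(rc) + 1L]] <- data.frame(
        sample_id = cons$sample_id[i], locus_id = "l", replicate = r,
        sequence = seqs, stringsAsFactors = FALSE)
    }
  }
  est <- estimate_ado(cons, do.call(rbind, rc))
  expect_equal(est$n_informative, 2 * n_entries)
  se <- sqrt(ado * (1 - ado) / est$n_informative)
  expect_lt(abs(est$ado_rate - ado), 3 * se)
  expect_equal(est$false_negative_prob, est$ado_rate^2)

  # no dropout -> rate 0; no heterozygotes -> undefined, flagged
  rc0 <- data.frame(sample_id = "s001", locus_id = "l",
                    replicate = c(1, 1, 2, 2),
                    sequence = c("A", "B", "A", "B"))
  est0 <- estimate_ado(cons[1, ], rc0)
  expect_equal(est0$ado_rate, 0)
  expect_equal(est0$false_negative_prob, 0)
  est_na <- estimate_ado(data.frame(sample_id = "x", locus_id = "l",
                                    allele1 = "A", allele2 = "A",
                                    status = "homozygote_confirmed"),
                         rc0)
  expect_true(est_na$undefined)

  # at a rate near 0.2, two concordant replicates keep the
  # false-homozygote probability below the 0.05 design target
  expect_lt(est$false_negative_prob, 0.05)
  est_k3 <- estimate_ado(cons, do.call(rbind, rc), k = 3)
  expect_equal(est_k3$false_negative_prob, est_k3$ado_rate^3)
})
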