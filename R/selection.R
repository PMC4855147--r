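# Nei-Gojobori (1986) synonymous/non-synonymous analysis with
# Jukes-Cantor correction and codon-based Z-tests of selection.
#
# Counting conventions: every possible single-base change carries weight
# 1/3 of a site; changes producing stop codons are excluded from both the
# site and the difference counts, so codons adjacent to stops contribute
# slightly less than 3 sites in total. Multi-position codon differences
# are averaged over all substitution orderings whose intermediates avoid
# stop codons.

BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

check_no_stops <- function(codons, what = "sequence") {
  aa <- translate_codon(codons)
  if (any(aa == "*"))
    stop("internal stop codon in ", what, " at codon position ",
         paste(which(aa == "*"), collapse = ", "))
  invisible(codons)
}

#' In-frame codon alignment with an antigen-binding-region mask
#'
#' @param sequences named character vector of equal-length, in-frame
#'   nucleotide sequences (no internal stop codons).
#' @param abr_mask integer codon indices designated antigen-binding
#'   (ABR); may be empty.
#' @return Object of class `codon_alignment`: list with `sequences`,
#'   `codon_count`, `abr_mask`.
#' @export
codon_alignment <- function(sequences, abr_mask = integer()) {
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("sequences are not all the same length")
  if (length(sequences) < 2) stop("need >= 2 sequences")
  codon_count <- lens[1] / 3
  for (i in seq_along(sequences))
    check_no_stops(split_codons(sequences[i]),
                   what = paste0("sequence ", i))
  abr_mask <- sort(unique(as.integer(abr_mask)))
  if (length(abr_mask) &&
      (min(abr_mask) < 1 || max(abr_mask) > codon_count))
    stop("abr_mask outside 1..", codon_count)
  structure(list(sequences = sequences, codon_count = codon_count,
                 abr_mask = abr_mask), class = "codon_alignment")
}

# per-codon (syn, counted) site fractions; stop-bound changes excluded
codon_sites <- function(codon) {
  aa <- translate_codon(codon)
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  counted <- 0
  for (pos in 1:3) {
    for (alt in setdiff(BASES, b[pos])) {
      mb <- b
      mb[pos] <- alt
      maa <- translate_codon(paste(mb, collapse = ""))
      if (maa == "*") next
      counted <- counted + 1
      if (maa == aa) syn <- syn + 1
    }
  }
  c(syn = syn / 3, nonsyn = (counted - syn) / 3)
}

#' Nei-Gojobori synonymous and non-synonymous site counts
#'
#' For each codon position, each of the three possible base changes
#' contributes 1/3 of a site, synonymous or non-synonymous according to
#' the standard genetic code; changes to stop codons are excluded.
#'
#' @param codon_sequence in-frame nucleotide string (no internal stops).
#' @return named vector `c(S = ..., N = ...)`.
#' @examples
#' ng_site_counts("TTT")  # S = 1/3
#' @export
ng_site_counts <- function(codon_sequence) {
  codons <- check_no_stops(split_codons(codon_sequence))
  per <- vapply(codons, codon_sites, numeric(2))
  c(S = sum(per["syn", ]), N = sum(per["nonsyn", ]))
}

PERMS <- list(`1` = list(1L),
              `2` = list(1:2, 2:1),
              `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# average (syn, nonsyn) differences between two codons over all
# substitution orderings avoiding stop intermediates; NULL if no valid path
codon_diffs <- function(ca, cb) {
  if (ca == cb) return(c(syn = 0, nonsyn = 0))
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  d <- which(a != b)
  tot <- c(syn = 0, nonsyn = 0)
  n_valid <- 0L
  for (ord in PERMS[[length(d)]]) {
    cur <- a
    path <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (pos in d[ord]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- translate_codon(paste(cur, collapse = ""))
      aa_nxt <- translate_codon(paste(nxt, collapse = ""))
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_nxt == aa_cur) path["syn"] <- path["syn"] + 1
      else path["nonsyn"] <- path["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) {
      tot <- tot + path
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(NULL)
  tot / n_valid
}

#' Nei-Gojobori pairwise proportions of differences
#'
#' Codons differing at several positions are scored by averaging the
#' synonymous/non-synonymous assignments over all substitution orderings
#' whose intermediate codons avoid stops; codons with no stop-free
#' pathway are skipped and counted. Site counts are averaged over the two
#' sequences.
#'
#' @param seq_a,seq_b equal-length in-frame nucleotide strings.
#' @return list with `Sd`, `Nd` (difference counts), `S`, `N` (mean site
#'   counts), `pS`, `pN` (proportions) and `skipped_codons`.
#' @export
ng_pairwise <- function(seq_a, seq_b) {
  ca <- check_no_stops(split_codons(seq_a), "seq_a")
  cb <- check_no_stops(split_codons(seq_b), "seq_b")
  if (length(ca) != length(cb)) stop("sequences differ in codon count")
  Sd <- Nd <- S <- N <- 0
  skipped <- 0L
  for (i in seq_along(ca)) {
    dd <- codon_diffs(ca[i], cb[i])
    if (is.null(dd)) {
      skipped <- skipped + 1L
      next
    }
    sa <- codon_sites(ca[i])
    sb <- codon_sites(cb[i])
    Sd <- Sd + dd[["syn"]]
    Nd <- Nd + dd[["nonsyn"]]
    S <- S + (sa[["syn"]] + sb[["syn"]]) / 2
    N <- N + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
  }
  list(Sd = Sd, Nd = Nd, S = S, N = N,
       pS = if (S > 0) Sd / S else NA_real_,
       pN = if (N > 0) Nd / N else NA_real_,
       skipped_codons = skipped)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` for a proportion of differences
#' `p < 3/4`; returns `NA` with a warning at or beyond saturation.
#'
#' @param p proportion of sites differing.
#' @return Corrected distance.
#' @export
jukes_cantor <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE))
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  if (any(p >= 0.75, na.rm = TRUE))
    warning("proportion(s) at or beyond Jukes-Cantor saturation (p >= 3/4)")
  out
}

# per-pair, per-codon difference arrays and per-seq, per-codon site arrays
ng_codon_tables <- function(seqs) {
  codon_lists <- lapply(seqs, split_codons)
  n_codon <- length(codon_lists[[1]])
  n_seq <- length(seqs)
  s_site <- n_site <- matrix(0, n_seq, n_codon)
  for (i in seq_len(n_seq)) {
    per <- vapply(codon_lists[[i]], codon_sites, numeric(2))
    s_site[i, ] <- per["syn", ]
    n_site[i, ] <- per["nonsyn", ]
  }
  pairs <- utils::combn(n_seq, 2)
  sd <- nd <- matrix(NA_real_, ncol(pairs), n_codon)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    for (k in seq_len(n_codon)) {
      dd <- codon_diffs(codon_lists[[i]][k], codon_lists[[j]][k])
      if (!is.null(dd)) {
        sd[p, k] <- dd[["syn"]]
        nd[p, k] <- dd[["nonsyn"]]
      }
    }
  }
  list(pairs = pairs, s_site = s_site, n_site = n_site, sd = sd, nd = nd)
}

# mean JC-corrected dN and dS over pairs, restricted to codon columns
mean_d_from_tables <- function(tab, cols) {
  dn <- ds <- numeric(ncol(tab$pairs))
  for (p in seq_len(ncol(tab$pairs))) {
    i <- tab$pairs[1, p]; j <- tab$pairs[2, p]
    valid <- cols[!is.na(tab$sd[p, cols])]
    Sd <- sum(tab$sd[p, valid])
    Nd <- sum(tab$nd[p, valid])
    S <- sum((tab$s_site[i, valid] + tab$s_site[j, valid]) / 2)
    N <- sum((tab$n_site[i, valid] + tab$n_site[j, valid]) / 2)
    ds[p] <- if (S > 0) suppressWarnings(jukes_cantor(Sd / S)) else 0
    dn[p] <- if (N > 0) suppressWarnings(jukes_cantor(Nd / N)) else 0
  }
  c(d_N = mean(dn), d_S = mean(ds))
}

#' Mean pairwise dN and dS with codon-bootstrap standard errors
#'
#' `d_N` and `d_S` are the means over all unordered sequence pairs of the
#' Jukes-Cantor-corrected Nei-Gojobori proportions, restricted to the
#' selected codons. Standard errors come from resampling codon columns
#' with replacement; the SE of the difference `d_N - d_S` is taken from
#' the joint bootstrap (not from quadrature, unless requested).
#'
#' @param alignment a [codon_alignment()] or character vector of in-frame
#'   sequences.
#' @param codons codon indices to analyse: an integer vector, `"abr"` /
#'   `"non_abr"` (using the alignment's mask) or NULL for all codons.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @param se_diff_quadrature compute SE(d_N - d_S) as
#'   `sqrt(SE_N^2 + SE_S^2)` instead of from the joint bootstrap.
#' @return Object of class `dnds_result`: list with `d_N`, `d_S`,
#'   `se_d_N`, `se_d_S`, `se_diff`, `ratio` (0 when `d_N` is 0; NA when
#'   `d_S` is 0 and `d_N > 0`) and `n_codons`.
#' @export
mean_dnds <- function(alignment, codons = NULL, n_bootstrap = 1000,
                      seed = NULL, se_diff_quadrature = FALSE) {
  if (!inherits(alignment, "codon_alignment"))
    alignment <- codon_alignment(alignment)
  cols <- select_codons(alignment, codons)
  if (!length(cols)) stop("codon selection is empty")
  tab <- ng_codon_tables(alignment$sequences)
  point <- mean_d_from_tables(tab, cols)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, n_bootstrap, 2)
  for (b in seq_len(n_bootstrap)) {
    bcols <- sample(cols, length(cols), replace = TRUE)
    boot[b, ] <- mean_d_from_tables(tab, bcols)
  }
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  se_diff <- if (se_diff_quadrature) sqrt(sum(se^2)) else
    stats::sd(boot[, 1] - boot[, 2], na.rm = TRUE)
  d_N <- point[["d_N"]]; d_S <- point[["d_S"]]
  ratio <- if (is.na(d_N) || is.na(d_S)) NA_real_
    else if (d_N == 0) 0
    else if (d_S == 0) NA_real_
    else d_N / d_S
  structure(list(d_N = d_N, d_S = d_S, se_d_N = se[1], se_d_S = se[2],
                 se_diff = se_diff, ratio = ratio,
                 n_codons = length(cols), n_bootstrap = n_bootstrap),
            class = "dnds_result")
}

select_codons <- function(alignment, codons) {
  all_cols <- seq_len(alignment$codon_count)
  if (is.null(codons)) return(all_cols)
  if (is.character(codons)) {
    return(switch(codons,
                  abr = alignment$abr_mask,
                  non_abr = setdiff(all_cols, alignment$abr_mask),
                  stop("unknown codon selection '", codons, "'")))
  }
  as.integer(codons)
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "dN = %.3f +/- %.3f, dS = %.3f +/- %.3f, dN/dS = %s (%d codons)\n",
    x$d_N, x$se_d_N, x$d_S, x$se_d_S,
    ifelse(is.na(x$ratio), "undefined", sprintf("%.2f", x$ratio)),
    x$n_codons))
  invisible(x)
}

#' Codon-based Z-test of selection
#'
#' Tests of positive selection (`dN > dS`), neutrality (`dN != dS`) and
#' purifying selection (`dN < dS`) against a normal reference. The
#' positive test uses `Z = (dN - dS)/SE`; the purifying test reports the
#' sign-flipped statistic `(dS - dN)/SE`; one-tailed p-values are 1 when
#' the statistic points away from the alternative; the neutrality test is
#' two-tailed.
#'
#' @param d_N,d_S mean non-synonymous and synonymous distances.
#' @param se_diff standard error of `d_N - d_S` (bootstrap).
#' @param hypothesis one of `"positive"`, `"neutral"`, `"purifying"`.
#' @return list with `hypothesis`, `Z`, `p`.
#' @export
z_test <- function(d_N, d_S, se_diff,
                   hypothesis = c("positive", "neutral", "purifying")) {
  hypothesis <- match.arg(hypothesis)
  if (se_diff == 0) {
    z <- 0
    return(list(hypothesis = hypothesis, Z = z, p = 1))
  }
  z <- (d_N - d_S) / se_diff
  p <- switch(hypothesis,
              positive = if (z <= 0) 1 else stats::pnorm(z,
                                                         lower.tail = FALSE),
              purifying = if (-z <= 0) 1 else stats::pnorm(-z,
                                                           lower.tail = FALSE),
              neutral = min(1, 2 * stats::pnorm(abs(z),
                                                lower.tail = FALSE)))
  if (hypothesis == "purifying") z <- -z
  list(hypothesis = hypothesis, Z = z, p = p)
}

#' All three selection Z-tests for a codon selection
#'
#' Convenience wrapper: [mean_dnds()] followed by [z_test()] for the
#' positive, neutral and purifying hypotheses.
#'
#' @inheritParams mean_dnds
#' @return data.frame with one row per hypothesis: `Z`, `p`, plus the
#'   underlying `d_N`, `d_S`, `se_diff`.
#' @export
codon_z_tests <- function(alignment, codons = NULL, n_bootstrap = 1000,
                          seed = NULL) {
  d <- mean_dnds(alignment, codons = codons, n_bootstrap = n_bootstrap,
                 seed = seed)
  do.call(rbind, lapply(c("positive", "neutral", "purifying"),
                        function(h) {
    zt <- z_test(d$d_N, d$d_S, d$se_diff, h)
    data.frame(hypothesis = h, Z = zt$Z, p = zt$p, d_N = d$d_N,
               d_S = d$d_S, se_diff = d$se_diff,
               stringsAsFactors = FALSE)
  }))
}
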