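# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately straight-line base R, independent of the package internals it
# checks.

# Tiny hand-built annotation: full-length and orphan integrations.
makeToyAnnotation <- function() {
  gr <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(start = c(101, 451, 5451, 9001, 12001, 12351, 17351),
                     end   = c(450, 5450, 5800, 9350, 12350, 17350, 17700)),
    strand = c("+", "+", "+", "-", "-", "-", "-"))
  S4Vectors::mcols(gr)$family <- c("famA", "famA", "famA", "famA",
                                   "famB", "famB", "famB")
  S4Vectors::mcols(gr)$role <- c("LTR5", "internal", "LTR3", "orphanLTR",
                                 "LTR3", "internal", "LTR5")
  S4Vectors::mcols(gr)$integration_id <- c("i1", "i1", "i1", "i2",
                                           "i3", "i3", "i3")
  S4Vectors::mcols(gr)$locus_id <- paste0("L", 1:7)
  RepeatAnnotation(gr)
}

# Straight-line recomputation of the enrichment pipeline on plain data
# frames: CPM -> filter -> FE -> median -> z-score, no package calls.
bruteForceEnrichment <- function(cc, lt, fam_of) {
  cc <- cc[cc$input_count >= 1, ]
  cc$family <- fam_of[cc$locus_id]
  fams <- sort(unique(unname(fam_of)))
  ds <- lt$dataset
  raw <- matrix(NA_real_, length(fams), length(ds),
                dimnames = list(fams, ds))
  for (d in ds) {
    sub <- cc[cc$dataset == d, ]
    chip_cpm <- sub$chip_count / lt$chip_total[lt$dataset == d] * 1e6
    input_cpm <- sub$input_count / lt$input_total[lt$dataset == d] * 1e6
    fe <- chip_cpm / input_cpm
    for (f in fams) {
      v <- fe[sub$family == f]
      if (length(v)) raw[f, d] <- median(v)
    }
  }
  raw <- raw[!apply(raw, 1, anyNA), , drop = FALSE]
  z <- apply(raw, 2, function(m) (m - mean(m)) / sd(m))
  list(raw = raw, z = z)
}

# Literal per-integration dedup rule on a plain data.frame.
bruteForceDedup <- function(df) {
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$integration_id),
                        function(ii) {
    roles <- df$role[ii]
    if (any(roles == "LTR5")) ii[roles == "LTR5"][1] else ii[1]
  }))
  sort(unname(keep))
}

# Per-base brute-force profile for one anchor.
bruteForceProfileRow <- function(cov_vec, pos, strand, window_up,
                                 window_down, bin_size) {
  a0 <- if (strand == "-") pos - 1 else pos
  offs <- seq.int(-window_up, window_down - 1)
  g <- if (strand == "-") a0 - offs else a0 + offs
  vals <- rep(NA_real_, length(g))
  ok <- g >= 0 & g < length(cov_vec)
  vals[ok] <- cov_vec[g[ok] + 1]
  n_bins <- (window_up + window_down) / bin_size
  sapply(seq_len(n_bins), function(j) {
    v <- vals[((j - 1) * bin_size + 1):(j * bin_size)]
    if (anyNA(v)) NA_real_ else mean(v)
  })
}

# Exhaustive peak-assignment oracle: enumerate every injective mapping of
# apo peaks to bound peaks restricted to admissible pairs; return the best
# (max matched, then min total Euclidean-weighted CSP distance).
bruteForceAssignment <- function(apo, bound, tol_h, tol_n) {
  n_a <- nrow(apo); n_b <- nrow(bound)
  dh <- outer(apo$dH, bound$dH, `-`)
  dn <- outer(apo$dN, bound$dN, `-`)
  dmat <- sqrt(dh^2 + (dn / 5)^2)
  adm <- (dh / tol_h)^2 + (dn / tol_n)^2 <= 1 + 1e-12
  best <- list(count = -1, total = Inf)
  rec <- function(a, used, count, total) {
    if (a > n_a) {
      if (count > best$count ||
          (count == best$count && total < best$total - 1e-15)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    for (b in seq_len(n_b)) {
      if (!used[b] && adm[a, b]) rec(a + 1, replace(used, b, TRUE),
                                     count + 1, total + dmat[a, b])
    }
    rec(a + 1, used, count, total)
  }
  rec(1, logical(n_b), 0, 0)
  best
}

# Manual Benjamini-Hochberg step-up.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
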