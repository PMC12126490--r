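#' Aggregate per-base signal into fixed-width genomic bins
#'
#' Tiles each chromosome from coordinate 0 in `bin_width` bp bins (the last
#' bin truncated at the chromosome end) and sums the per-base signal within
#' each bin, so total signal is conserved exactly.
#'
#' @param coverage named list of per-base numeric vectors, one per chromosome.
#' @param bin_width bin width in bp (default 5000, the genome-wide
#'   correlation scale).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `signal`.
#' @export
binSignal <- function(coverage, bin_width = 5000L) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  rows <- lapply(names(coverage), function(chrom) {
    v <- coverage[[chrom]]
    len <- length(v)
    if (len == 0L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, len)
    idx <- findInterval(seq_len(len) - 1L, starts)
    data.frame(chrom = chrom, start = starts, end = ends,
               signal = as.numeric(tapply(v, idx, sum)))
  })
  do.call(rbind, rows)
}

# Full-enumeration two-sided permutation p for Spearman rho (tie-free input).
exactSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- permuteAll(n)
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(rep(i, nrow(sub)), sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation between two binned tracks
#'
#' Rho from midrank-tied ranks. The p-value is exact (full permutation
#' enumeration) for n <= 9 tie-free vectors and a t-distribution
#' approximation otherwise -- the exact null is combinatorially infeasible at
#' genome-wide n.
#'
#' @param x,y equal-length numeric vectors (length >= 3), not constant.
#' @return list with `rho`, `p`, `n`, `method` ("exact" or "t-approximation").
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tie_free <- !any(duplicated(x)) && !any(duplicated(y))
  if (n <= 9L && tie_free) {
    p <- exactSpearmanP(x, y)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Correlate two coverage tracks at fixed genomic bins
#'
#' Convenience composition: bin both tracks on the shared tiling, then
#' Spearman-correlate the per-bin values. Zero-signal bins are retained.
#'
#' @param coverage_x,coverage_y named lists of per-base vectors on the same
#'   genome.
#' @param bin_width bp.
#' @return list with the per-bin data.frame (`bins`) and the correlation
#'   summary (`rho`, `p`, `n`, `method`).
#' @export
binCorrelation <- function(coverage_x, coverage_y, bin_width = 5000L) {
  if (!identical(sort(names(coverage_x)), sort(names(coverage_y)))) {
    stopf("tracks cover different chromosome sets")
  }
  bx <- binSignal(coverage_x, bin_width)
  by <- binSignal(coverage_y, bin_width)
  if (!identical(bx[c("chrom", "start", "end")], by[c("chrom", "start", "end")])) {
    stopf("tracks disagree on chromosome lengths")
  }
  bins <- data.frame(bx[c("chrom", "start", "end")], x = bx$signal, y = by$signal)
  c(list(bins = bins), spearmanCorrelation(bins$x, bins$y))
}
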