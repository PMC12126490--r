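#' Ligand-depletion binding isotherm (forward model)
#'
#' Predicted signal change for protein at total concentration `P` titrated
#' with ligand `L`:
#' `dI = dImax * ((L + P + Kd) - sqrt((L + P + Kd)^2 - 4 P L)) / (2 P)`.
#' The quadratic form accounts for ligand depletion, so it stays valid when
#' protein and Kd are of comparable magnitude. The discriminant is clamped at
#' zero (within 1e-12 of the branch point) so exact stoichiometric saturation
#' with Kd = 0 does not produce NaN.
#'
#' @param L ligand concentration(s), >= 0 (vectorized).
#' @param P total protein concentration, > 0.
#' @param kd dissociation constant, >= 0; same units as L and P.
#' @param delta_i_max maximal signal change.
#' @return predicted signal change(s).
#' @export
predictDeltaI <- function(L, P, kd, delta_i_max) {
  if (P <= 0) stopf("protein concentration P must be > 0")
  if (any(L < 0)) stopf("ligand concentrations must be >= 0")
  if (kd < 0) stopf("kd must be >= 0")
  s <- L + P + kd
  disc <- s^2 - 4 * P * L
  disc[disc < 0] <- 0          # numerical guard at the branch point
  delta_i_max * (s - sqrt(disc)) / (2 * P)
}

#' Fit the binding isotherm to a titration series
#'
#' Nonlinear least squares for (Kd, dImax) with Kd bounded at zero.
#' Initialization: dImax at the largest observed response, Kd at the ligand
#' concentration closest to half-maximal response.
#'
#' @param series data.frame with columns `L` and `I_obs` (e.g. from
#'   [simulateTitration()] or [readTitrationTsv()]).
#' @param p_total protein concentration; taken from the series' `p_total`
#'   attribute when omitted.
#' @return a [TitrationFit-class].
#' @export
fitBindingIsotherm <- function(series, p_total = attr(series, "p_total")) {
  if (is.null(p_total)) stopf("p_total must be given or attached to the series")
  if (nrow(series) < 4L) stopf("need >= 4 titration points to fit two parameters")
  L <- series$L
  y <- series$I_obs
  if (stats::sd(y) == 0) stopf("degenerate flat titration series: cannot fit")
  di0 <- max(y)
  kd0 <- max(L[which.min(abs(y - di0 / 2))], min(L[L > 0], na.rm = TRUE))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ predictDeltaI(L, p_total, kd, dimax),
      start = list(kd = kd0, dimax = di0),
      lower = c(kd = 0, dimax = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("isotherm fit failed to converge: %s", conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(kd = NA_real_, dimax = NA_real_))
  new("TitrationFit",
      kd = unname(est[["kd"]]), deltaIMax = unname(est[["dimax"]]),
      se = c(kd = unname(se[["kd"]]), deltaIMax = unname(se[["dimax"]])),
      residualNorm = sqrt(sum(stats::residuals(fit)^2)),
      fitted = as.numeric(stats::fitted(fit)),
      converged = fit$convInfo$isConv %||% TRUE,
      pTotal = p_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise replicate isotherm fits
#'
#' The reported dissociation constant is the mean over independent replicate
#' experiments with its sample standard deviation.
#'
#' @param fits list of [TitrationFit-class] objects.
#' @return data.frame with `kd_mean`, `kd_sd`, `n`.
#' @export
summariseReplicateFits <- function(fits) {
  kds <- vapply(fits, kd, numeric(1))
  data.frame(kd_mean = mean(kds),
             kd_sd = if (length(kds) > 1L) stats::sd(kds) else NA_real_,
             n = length(kds))
}

#' Chemical shift perturbation, Euclidean-weighted
#'
#' `sqrt(dH^2 + (dN/5)^2)` in ppm: the nitrogen axis is down-weighted by its
#' wider chemical shift range.
#'
#' @param d_h,d_n proton and nitrogen shift changes in ppm (vectorized).
#' @return CSP in ppm.
#' @export
cspEuclidean <- function(d_h, d_n) {
  sqrt(d_h^2 + (d_n / 5)^2)
}

#' Chemical shift perturbation, weighted absolute (Hamming-distance form)
#'
#' `|dH| + alpha * |dN|`; the default alpha of 0.105 is the ratio of backbone
#' 1H to 15N chemical shift ranges in an HSQC spectrum.
#'
#' @param d_h,d_n shift changes in ppm (vectorized).
#' @param alpha nitrogen scaling factor, > 0.
#' @return combined CSP in ppm.
#' @export
cspCombined <- function(d_h, d_n, alpha = 0.105) {
  if (alpha <= 0) stopf("alpha must be > 0")
  abs(d_h) + alpha * abs(d_n)
}

# Optimal one-to-one matching within a connected component of the
# admissibility graph: maximize matches, then minimize total distance.
# Exhaustive recursion; realistic components have very few conflicts.
assignComponent <- function(apo_idx, bound_idx, dmat, adm) {
  best <- list(count = -1L, total = Inf, match = integer(0))
  n_a <- length(apo_idx)
  recurse <- function(k, used, match, count, total) {
    if (k > n_a) {
      if (count > best$count ||
          (count == best$count && total < best$total - 1e-15)) {
        best <<- list(count = count, total = total, match = match)
      }
      return(invisible())
    }
    # bound on achievable matches prunes hopeless branches
    if (count + (n_a - k + 1L) < best$count) return(invisible())
    a <- apo_idx[k]
    for (j in seq_along(bound_idx)) {
      b <- bound_idx[j]
      if (!used[j] && adm[a, b]) {
        used[j] <- TRUE
        match[k] <- b
        recurse(k + 1L, used, match, count + 1L, total + dmat[a, b])
        used[j] <- FALSE
      }
    }
    match[k] <- NA_integer_
    recurse(k + 1L, used, match, count, total)
  }
  recurse(1L, logical(length(bound_idx)), rep(NA_integer_, n_a), 0L, 0)
  best$match
}

#' Match apo and bound HSQC peaks and classify residues
#'
#' Each assigned apo peak is matched one-to-one to a bound peak under the
#' Euclidean-weighted CSP metric, admissible when the displacement falls
#' inside the `(tol_h, tol_n)` ellipse. The matching is globally optimal
#' (maximum number of matches, then minimum total CSP distance), computed
#' exactly per connected component of the admissibility graph. An unmatched
#' apo peak with no bound peak above `intensity_floor` times its apo
#' intensity inside the ellipse is called `disappeared`; otherwise it is
#' `unassigned` (a nearby bound peak exists but was claimed by another
#' residue).
#'
#' @param apo data.frame with columns `residue`, `dH`, `dN`, `intensity`;
#'   residue ids must be unique.
#' @param bound data.frame with columns `dH`, `dN`, `intensity` (assignments
#'   unknown).
#' @param tol_h,tol_n matching tolerances in ppm (defaults 0.05 and 0.5).
#' @param intensity_floor fraction of apo intensity below which a bound peak
#'   does not rescue a residue from the disappeared call (default 0.2).
#' @param alpha passed to [cspCombined()].
#' @return data.frame, one row per apo residue: `residue`, `status`
#'   (`matched`/`disappeared`/`unassigned`), `d_h`, `d_n`, `csp_eq_euclid`,
#'   `csp_eq_combined`.
#' @export
matchPeaks <- function(apo, bound, tol_h = 0.05, tol_n = 0.5,
                       intensity_floor = 0.2, alpha = 0.105) {
  if (anyDuplicated(apo$residue)) stopf("duplicate residue ids in the apo list")
  if (tol_h <= 0 || tol_n <= 0) stopf("tolerances must be positive")
  n_a <- nrow(apo)
  n_b <- nrow(bound)
  dh <- outer(apo$dH, bound$dH, `-`)
  dn <- outer(apo$dN, bound$dN, `-`)
  dmat <- matrix(cspEuclidean(-dh, -dn), n_a, n_b)
  adm <- (dh / tol_h)^2 + (dn / tol_n)^2 <= 1 + 1e-12
  loud <- outer(apo$intensity, bound$intensity,
                function(a, b) b >= intensity_floor * a)

  # connected components of the bipartite admissibility graph
  match <- rep(NA_integer_, n_a)
  seen_a <- logical(n_a)
  seen_b <- logical(n_b)
  for (a0 in seq_len(n_a)) {
    if (seen_a[a0]) next
    qa <- a0
    comp_a <- integer(0); comp_b <- integer(0)
    while (length(qa)) {
      a <- qa[1L]; qa <- qa[-1L]
      if (seen_a[a]) next
      seen_a[a] <- TRUE
      comp_a <- c(comp_a, a)
      bs <- which(adm[a, ] & !seen_b)
      for (b in bs) {
        seen_b[b] <- TRUE
        comp_b <- c(comp_b, b)
        qa <- c(qa, which(adm[, b] & !seen_a))
      }
    }
    if (length(comp_b)) {
      match[comp_a] <- assignComponent(comp_a, comp_b, dmat, adm)
    }
  }

  status <- character(n_a)
  d_h <- d_n <- rep(NA_real_, n_a)
  for (a in seq_len(n_a)) {
    if (!is.na(match[a])) {
      status[a] <- "matched"
      d_h[a] <- bound$dH[match[a]] - apo$dH[a]
      d_n[a] <- bound$dN[match[a]] - apo$dN[a]
    } else {
      rescue <- any(adm[a, ] & loud[a, ])
      status[a] <- if (rescue) "unassigned" else "disappeared"
    }
  }
  data.frame(residue = apo$residue, status = status, d_h = d_h, d_n = d_n,
             csp_eq_euclid = ifelse(is.na(d_h), NA_real_, cspEuclidean(d_h, d_n)),
             csp_eq_combined = ifelse(is.na(d_h), NA_real_,
                                      cspCombined(d_h, d_n, alpha)))
}

#' FRAP dip depth of the non-bleached half
#'
#' Smooths the unbleached-half trace with a Savitzky-Golay filter and reads
#' the dip at each probe time as `1 - min(smoothed)` within a symmetric time
#' window around it. Intensities must be normalized so the pre-bleach
#' baseline is 1; depths are clamped to `[0, 1]`.
#'
#' @param curve data.frame with columns `time` and `intensity_unbleached`
#'   (e.g. from [simulateFrapCurve()] or [readFrapTsv()]).
#' @param probe_times seconds at which to read the dip.
#' @param sg_window odd Savitzky-Golay window length in frames (default 11).
#' @param sg_order polynomial order (default 3), < `sg_window`.
#' @param probe_window half-width of the search window around each probe
#'   time, seconds (default 5).
#' @return data.frame with columns `probe_time`, `dip_depth`, `t_min`.
#' @export
frapDipDepth <- function(curve, probe_times, sg_window = 11L, sg_order = 3L,
                         probe_window = 5) {
  tt <- curve$time
  y <- curve$intensity_unbleached
  if (sg_window %% 2L == 0L || sg_window <= sg_order) {
    stopf("sg_window must be odd and greater than sg_order")
  }
  if (sg_window >= length(y)) {
    stopf("sg_window (%d) must be shorter than the series (%d frames)",
          sg_window, length(y))
  }
  sm <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  rows <- lapply(probe_times, function(t0) {
    sel <- which(abs(tt - t0) <= probe_window)
    if (!length(sel)) stopf("probe time %.3g s outside the series", t0)
    i <- sel[which.min(sm[sel])]
    data.frame(probe_time = t0,
               dip_depth = min(max(1 - sm[i], 0), 1),
               t_min = tt[i])
  })
  do.call(rbind, rows)
}
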