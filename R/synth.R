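#' Simulation configuration for the synthetic genomics inputs
#'
#' Bundles every knob of the repeat-annotation and count-table generators.
#' Defaults emulate a small desk-scale study: a handful of repeat families
#' with full-length integrations (5'LTR - internal - 3'LTR) plus solitary
#' ("orphan") LTRs, and overdispersed sequencing counts.
#'
#' @param seed integer; fixes every downstream draw.
#' @param n_families number of repeat families.
#' @param loci_per_family integrations simulated per family.
#' @param genome_length single-chromosome genome size in bp.
#' @param enrichment_factors per-family, per-dataset planted ChIP/input fold
#'   enrichment: a named list, one numeric vector per dataset, each named by
#'   family (or a single number recycled to all families). All values > 0.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size); sizes >= 1e6 switch to the Poisson branch.
#' @param library_sizes named list per dataset with elements `chip` and
#'   `input`: library totals used to scale means and to normalize to CPM.
#' @param input_mean expected input fragment count per locus at the input
#'   library's stated size.
#' @param ltr_length,internal_length segment lengths in bp.
#' @param orphan_fraction fraction of integrations that are orphan LTRs.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_families = 20L,
                             loci_per_family = 100L,
                             genome_length = 6e7,
                             enrichment_factors = 1,
                             nb_dispersion = 10,
                             library_sizes = list(
                               chip1 = list(chip = 1e6, input = 1e6)),
                             input_mean = 20,
                             ltr_length = 350L,
                             internal_length = 5000L,
                             orphan_fraction = 0.3) {
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (input_mean <= 0) stopf("input_mean must be positive")
  if (orphan_fraction < 0 || orphan_fraction > 1) {
    stopf("orphan_fraction must lie in [0, 1]")
  }
  fams <- sprintf("family_%02d", seq_len(n_families))
  ef <- lapply(names(library_sizes), function(ds) {
    v <- if (is.list(enrichment_factors)) enrichment_factors[[ds]] else enrichment_factors
    if (is.null(v)) stopf("no enrichment factors for dataset '%s'", ds)
    if (length(v) == 1L && is.null(names(v))) v <- stats::setNames(rep(v, n_families), fams)
    if (!all(fams %in% names(v))) {
      stopf("enrichment factors must cover every family for dataset '%s'", ds)
    }
    v <- v[fams]
    if (any(v <= 0)) stopf("enrichment factors must be > 0 (dataset '%s')", ds)
    v
  })
  names(ef) <- names(library_sizes)
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    families = fams, loci_per_family = as.integer(loci_per_family),
    genome_length = genome_length, enrichment_factors = ef,
    nb_dispersion = nb_dispersion, library_sizes = library_sizes,
    input_mean = input_mean, ltr_length = as.integer(ltr_length),
    internal_length = as.integer(internal_length),
    orphan_fraction = orphan_fraction), class = "SimulationConfig")
}

#' Simulate a family-labelled repeat annotation
#'
#' Places non-overlapping integrations on a single synthetic chromosome.
#' Each integration is either full-length -- a 5' LTR, internal segment and
#' 3' LTR, contiguous and on one randomly drawn strand, sharing an
#' integration id -- or an orphan LTR with its own id. On the minus strand
#' the biological 5' LTR occupies the right-most (highest-coordinate)
#' segment.
#'
#' @param config a [simulationConfig()] object.
#' @return a [RepeatAnnotation-class].
#' @export
simulateRepeatAnnotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  full_len <- 2L * config$ltr_length + config$internal_length
  n_int <- config$n_families * config$loci_per_family
  withSeed(deriveSeed(config$seed, "simulateRepeatAnnotation"), {
    is_orphan <- stats::runif(n_int) < config$orphan_fraction
    lens <- ifelse(is_orphan, config$ltr_length, full_len)
    # gap >= 1 bp between integrations so loci never touch
    starts <- placeNonOverlapping(lens + 1L, config$genome_length)
    strands <- sample(c("+", "-"), n_int, replace = TRUE)
    fam <- rep(config$families, each = config$loci_per_family)
    int_id <- sprintf("int_%05d", seq_len(n_int))

    rows <- vector("list", n_int)
    for (i in seq_len(n_int)) {
      s <- starts[i]
      if (is_orphan[i]) {
        rows[[i]] <- data.frame(start = s, width = config$ltr_length,
                                role = "orphanLTR", strand = strands[i],
                                family = fam[i], integration_id = int_id[i])
      } else {
        seg_w <- c(config$ltr_length, config$internal_length, config$ltr_length)
        seg_s <- s + cumsum(c(0L, seg_w[-3L]))
        roles <- if (strands[i] == "+") c("LTR5", "internal", "LTR3")
                 else c("LTR3", "internal", "LTR5")
        rows[[i]] <- data.frame(start = seg_s, width = seg_w, role = roles,
                                strand = strands[i], family = fam[i],
                                integration_id = int_id[i])
      }
    }
    df <- do.call(rbind, rows)
    gr <- GRanges("chrSim",
                  IRanges(start = df$start + 1L, width = df$width),
                  strand = df$strand)
    mcols(gr)$family <- df$family
    mcols(gr)$role <- df$role
    mcols(gr)$integration_id <- df$integration_id
    names(gr) <- NULL
    S4Vectors::metadata(gr)$genome_length <- config$genome_length
    RepeatAnnotation(gr)
  })
}

# Sample non-overlapping placements of the given lengths in [0, genome_length),
# uniform over valid configurations: draw the free space consumed before each
# locus via sorted uniform spacings, then lay the loci down in random order.
# Errors naming the constraint when the loci cannot fit at all.
placeNonOverlapping <- function(lengths, genome_length) {
  n <- length(lengths)
  free <- genome_length - sum(lengths)
  if (free < 0) {
    stopf("cannot place %d loci totalling %d bp in a %g bp genome: non-overlap constraint unsatisfiable (combined length exceeds genome_length)",
          n, sum(lengths), genome_length)
  }
  perm <- sample.int(n)                      # random left-to-right order
  u <- sort(floor(stats::runif(n, 0, free + 1)))
  ordered_lengths <- lengths[perm]
  starts_sorted <- u + cumsum(c(0L, ordered_lengths[-n]))
  starts <- integer(n)
  starts[perm] <- as.integer(starts_sorted)
  starts
}

# NB draw parameterized by (mean, size); Poisson branch for size >= 1e6.
rCounts <- function(n, mu, size) {
  if (size >= 1e6) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a per-locus ChIP/input count table
#'
#' Input counts are negative binomial with mean `input_mean` (scaled by the
#' dataset's input library size relative to 1e6) and size `nb_dispersion`;
#' ChIP counts have mean multiplied by the planted per-family enrichment
#' factor and the ChIP/input library-size ratio, so CPM normalization is
#' exercised non-trivially.
#'
#' @param annotation a [RepeatAnnotation-class].
#' @param config the same [simulationConfig()] used for the annotation.
#' @return a [LocusCounts-class].
#' @export
simulateCountTable <- function(annotation, config) {
  stopifnot(is(annotation, "RepeatAnnotation"), inherits(config, "SimulationConfig"))
  gr <- annotationRanges(annotation)
  loci <- mcols(gr)$locus_id
  fam <- mcols(gr)$family
  datasets <- names(config$library_sizes)
  withSeed(deriveSeed(config$seed, "simulateCountTable"), {
    tabs <- lapply(datasets, function(ds) {
      ls <- config$library_sizes[[ds]]
      ef <- config$enrichment_factors[[ds]][fam]
      if (anyNA(ef)) stopf("enrichment factor undefined for some family in dataset '%s'", ds)
      input_mu <- config$input_mean * ls$input / 1e6
      chip_mu <- config$input_mean * ef * ls$chip / 1e6
      data.frame(locus_id = loci, dataset = ds,
                 chip_count = rCounts(length(gr), chip_mu, config$nb_dispersion),
                 input_count = rCounts(length(gr), input_mu, config$nb_dispersion))
    })
    cc <- do.call(rbind, tabs)
    lt <- data.frame(
      dataset = datasets,
      chip_total = vapply(datasets, function(ds) {
        max(config$library_sizes[[ds]]$chip, sum(cc$chip_count[cc$dataset == ds]))
      }, numeric(1)),
      input_total = vapply(datasets, function(ds) {
        max(config$library_sizes[[ds]]$input, sum(cc$input_count[cc$dataset == ds]))
      }, numeric(1)))
    LocusCounts(cc, lt)
  })
}

#' Simulate a fluorescence titration series
#'
#' Forward-evaluates the ligand-depletion (quadratic) binding isotherm at the
#' given ligand concentrations and adds Gaussian noise; `noise_sd = 0`
#' reproduces the model exactly.
#'
#' @param kd dissociation constant (same concentration units as the series).
#' @param delta_i_max maximal signal change.
#' @param p_total protein concentration, > 0.
#' @param ligand_series non-negative ligand concentrations.
#' @param noise_sd intensity noise standard deviation.
#' @param seed integer.
#' @return data.frame with columns `L`, `I_obs` and attribute `p_total`.
#' @export
simulateTitration <- function(kd, delta_i_max, p_total, ligand_series,
                              noise_sd = 0, seed = 1L) {
  if (length(ligand_series) == 0L) stopf("ligand_series must be non-empty")
  if (any(ligand_series < 0)) stopf("ligand concentrations must be non-negative")
  if (kd < 0) stopf("kd must be >= 0")
  mu <- predictDeltaI(ligand_series, p_total, kd, delta_i_max)
  obs <- if (noise_sd > 0) {
    withSeed(deriveSeed(seed, "simulateTitration"),
             mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  out <- data.frame(L = ligand_series, I_obs = obs)
  attr(out, "p_total") <- p_total
  out
}

#' Simulate apo and bound HSQC peak lists
#'
#' Generates an apo amide peak list with well-separated random positions,
#' then a bound list in which `shifted_set` residues are displaced by the
#' planted (dH, dN) shift and `disappeared_set` residues are absent.
#'
#' @param n_residues number of assigned residues.
#' @param shifted_set,disappeared_set disjoint integer residue ids in
#'   `1..n_residues`.
#' @param shift_magnitudes list with elements `dH`, `dN` (ppm), recycled over
#'   the shifted set.
#' @param seed integer.
#' @return list with data.frames `apo` and `bound`
#'   (columns residue, dH, dN, intensity).
#' @export
simulatePeakLists <- function(n_residues, shifted_set = integer(),
                              disappeared_set = integer(),
                              shift_magnitudes = list(dH = 0.1, dN = 0.5),
                              seed = 1L) {
  ids <- seq_len(n_residues)
  if (!all(shifted_set %in% ids) || !all(disappeared_set %in% ids)) {
    stopf("residue ids must lie in 1..%d", n_residues)
  }
  if (length(intersect(shifted_set, disappeared_set))) {
    stopf("shifted_set and disappeared_set must be disjoint")
  }
  withSeed(deriveSeed(seed, "simulatePeakLists"), {
    # amide-like chemical shift ranges; grid placement keeps peaks separated
    # by far more than typical matching tolerances
    grid_h <- seq(6.5, 10.5, length.out = ceiling(sqrt(n_residues)))
    grid_n <- seq(105, 135, length.out = ceiling(sqrt(n_residues)))
    pos <- expand.grid(dH = grid_h, dN = grid_n)[sample(
      length(grid_h) * length(grid_n), n_residues), ]
    apo <- data.frame(residue = ids, dH = pos$dH, dN = pos$dN,
                      intensity = stats::runif(n_residues, 0.5, 1.5))
    bound <- apo
    if (length(shifted_set)) {
      dh <- rep_len(shift_magnitudes$dH, length(shifted_set))
      dn <- rep_len(shift_magnitudes$dN, length(shifted_set))
      i <- match(shifted_set, bound$residue)
      bound$dH[i] <- bound$dH[i] + dh
      bound$dN[i] <- bound$dN[i] + dn
    }
    if (length(disappeared_set)) {
      bound <- bound[!bound$residue %in% disappeared_set, ]
    }
    # bound-state assignments are unknown in a real titration
    bound$residue <- NA_integer_
    rownames(bound) <- NULL
    list(apo = apo, bound = bound)
  })
}

#' Simulate a half-bleach FRAP recovery curve
#'
#' The unbleached-half trace is 1 minus a smooth Gaussian transient of the
#' planted depth centred at `dip_time`; the bleached-half trace is an
#' exponential recovery. With `noise_sd = 0` the analytic minimum of the
#' unbleached trace is exactly `1 - dip_depth`.
#'
#' @param dip_depth planted dip depth, in `[0, 1)`.
#' @param dip_time seconds; must fall inside the sampled span.
#' @param n_frames,frame_dt series length and spacing (s).
#' @param noise_sd Gaussian noise sd on normalized intensity.
#' @param seed integer.
#' @param dip_width Gaussian sd of the transient, seconds.
#' @return data.frame with columns `time`, `intensity_bleached`,
#'   `intensity_unbleached`.
#' @export
simulateFrapCurve <- function(dip_depth, dip_time, n_frames = 200L,
                              frame_dt = 0.25, noise_sd = 0, seed = 1L,
                              dip_width = 2) {
  if (dip_depth < 0 || dip_depth >= 1) stopf("dip_depth must lie in [0, 1)")
  tt <- (seq_len(n_frames) - 1L) * frame_dt
  if (dip_time < min(tt) || dip_time > max(tt)) {
    stopf("dip_time %.3g s outside the sampled span [%.3g, %.3g] s",
          dip_time, min(tt), max(tt))
  }
  # dip_time lands exactly on a frame when compatible with frame_dt, so the
  # noiseless series minimum equals 1 - dip_depth exactly
  unb <- 1 - dip_depth * exp(-(tt - dip_time)^2 / (2 * dip_width^2))
  ble <- 0.2 + 0.6 * (1 - exp(-tt / 20))
  if (noise_sd > 0) {
    withSeed(deriveSeed(seed, "simulateFrapCurve"), {
      unb <- unb + stats::rnorm(n_frames, 0, noise_sd)
      ble <- ble + stats::rnorm(n_frames, 0, noise_sd)
    })
  }
  data.frame(time = tt, intensity_bleached = ble, intensity_unbleached = unb)
}
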