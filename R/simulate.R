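#' @title Synthetic ATR FT-IR spectrum generator
#' @description Gaussian band-mixture emulation of dried body-fluid spectra,
#'   with donor-level and replicate-level lognormal amplitude variability,
#'   smooth baseline wander, instrument noise, an aging transform and a
#'   panel of off-template interferents.
#' @name simulate
NULL

.band <- function(center, width, amplitude) {
  stopifnot(width > 0, amplitude > 0)
  list(center = center, width = width, amplitude = amplitude)
}

#' Construct a fluid band template
#'
#' @param fluid Fluid label.
#' @param bands Data frame with columns `center` (cm-1), `width` (Gaussian
#'   sigma, cm-1) and `amplitude` (relative absorbance, > 0); at least three
#'   bands.
#' @param donor_cv Coefficient of variation of the per-donor lognormal
#'   band-amplitude multipliers.
#' @param replicate_cv Coefficient of variation of the per-replicate
#'   multipliers.
#' @param baseline_scale Amplitude of the smooth baseline wander.
#' @return A `fluid_template` object.
#' @export
fluid_template <- function(fluid, bands, donor_cv = 0.045,
                           replicate_cv = 0.03, baseline_scale = 0.01) {
  bands <- as.data.frame(bands)
  stopifnot(nrow(bands) >= 3L, all(bands$width > 0), all(bands$amplitude > 0),
            donor_cv >= 0, replicate_cv >= 0)
  structure(list(fluid = fluid, bands = bands, donor_cv = donor_cv,
                 replicate_cv = replicate_cv,
                 baseline_scale = baseline_scale),
            class = "fluid_template")
}

#' Default band templates for the five body fluids
#'
#' Band centers follow the characteristic assignments of dried body-fluid
#' infrared spectra: protein Amide A/I/II/III bands for blood, saliva and
#' semen (blood strongest, from hemoglobin and serum albumin), thiocyanate
#' (2057 cm-1) and lipid C-H / C=O bands plus a glycoprotein sugar envelope
#' for saliva, a strong sugar band at 1056 cm-1 and a methyl band at
#' 1393 cm-1 for semen, urea bands (1592, 1457, 1154 cm-1) with weak
#' creatinine features for urine, and lactate bands (1580, 1416, 1121,
#' 1040 cm-1) plus urea at 1455 cm-1 for sweat. Amplitudes are relative and
#' only their pattern matters after total-area normalization; widths default
#' to 25-45 cm-1 for sharp bands and 120-140 cm-1 for the Amide A / N-H /
#' water envelopes.
#'
#' @return Named list of [fluid_template()] objects, one per fluid.
#' @export
default_fluid_templates <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  list(
    blood = fluid_template("blood", b(
      3285, 120, 0.55,   # Amide A
      1640,  30, 1.00,   # Amide I
      1532,  30, 0.75,   # Amide II
      1240,  30, 0.35,   # Amide III
      1080,  45, 0.18)), # glucose
    saliva = fluid_template("saliva", b(
      3279, 120, 0.35,
      1640,  30, 0.55,
      1537,  30, 0.40,
      1239,  30, 0.20,
      2057,  25, 0.12,   # SCN-
      2943,  25, 0.10,   # lipid CH asym
      2854,  25, 0.07,   # lipid CH sym
      1743,  25, 0.08,   # ester C=O
      1045,  45, 0.55)), # glycoprotein sugars
    semen = fluid_template("semen", b(
      3268, 120, 0.40,
      1622,  30, 0.60,
      1547,  30, 0.45,
      1056,  35, 0.55,   # PSA / fructose sugars
      1393,  25, 0.20)), # methyl
    urine = fluid_template("urine", b(
      3350, 140, 0.30,   # urea N-H envelope
      1592,  35, 1.00,   # urea C=O
      1457,  30, 0.70,   # urea C-N
      1154,  30, 0.35,   # urea NH2 deformation
      1334,  25, 0.15,   # creatinine
      1237,  25, 0.12)), # creatinine
    sweat = fluid_template("sweat", b(
      3300, 140, 0.25,
      1650,  30, 0.12,   # amide I (sweat proteins / amino acids)
      1580,  35, 0.75,   # lactate
      1545,  30, 0.07,   # amide II
      1455,  30, 0.60,   # urea
      1416,  30, 0.50,   # lactate
      1121,  30, 0.35,   # lactate
      1040,  30, 0.30))  # lactate
  )
}

# p x n_bands matrix of unit-height Gaussian band profiles
.band_profiles <- function(bands, grid) {
  vapply(seq_len(nrow(bands)), function(j) {
    exp(-(grid - bands$center[j])^2 / (2 * bands$width[j]^2))
  }, numeric(length(grid)))
}

.lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

# smooth low-frequency baseline: constant offset plus two random cosine modes
.baseline <- function(grid, scale, offset = 0.02) {
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  offset + scale * (stats::rnorm(1) * cospi(u) + stats::rnorm(1) * cospi(2 * u))
}

#' Simulate one spectrum from a band template
#'
#' The noiseless spectrum is the sum of the template's Gaussian bands with
#' each amplitude scaled by its donor and replicate multipliers, plus a
#' smooth baseline. I.i.d. Gaussian noise is added and the result clipped at
#' zero; output is in absorbance mode (not area-normalized).
#'
#' @param template A [fluid_template()].
#' @param donor_mult Per-band donor multipliers (recycled scalar allowed).
#' @param grid Wavenumber grid.
#' @param noise_sd Standard deviation of the additive noise.
#' @param baseline_offset Constant absorbance offset keeping the signal away
#'   from the zero clip.
#' @return Numeric absorbance vector on `grid`. Uses the current RNG state;
#'   seed outside for reproducibility.
#' @export
simulate_spectrum <- function(template, donor_mult = 1, grid = default_grid(),
                              noise_sd = 0.002, baseline_offset = 0.02) {
  stopifnot(noise_sd >= 0)
  nb <- nrow(template$bands)
  donor_mult <- rep_len(donor_mult, nb)
  rep_mult <- .lognormal_mult(nb, template$replicate_cv)
  G <- .band_profiles(template$bands, grid)
  y <- as.vector(G %*% (template$bands$amplitude * donor_mult * rep_mult)) +
    .baseline(grid, template$baseline_scale, baseline_offset)
  if (noise_sd > 0) y <- y + stats::rnorm(length(grid), sd = noise_sd)
  pmax(y, 0)
}

#' Aging transforms for the five fluids
#'
#' Aging multiplies each decaying band region by a smooth Gaussian-windowed
#' factor equal to exp(-rate x days elapsed) at the band center, and adds a
#' broad humidity/water feature at 3300 cm-1 that grows and saturates with
#' age. Defaults: protein Amide I/II decay for blood, saliva and semen
#' (rate 0.004 per day), urea decay for urine (1592/1457 cm-1, 0.005 per
#' day) and sweat (1455 cm-1, 0.004 per day); the humidity gain is
#' strongest for urine and sweat. The fresh reference age is 1 day.
#'
#' @return Named list of aging models (one per fluid), each with
#'   `decay_bands` (named vector center -> rate per day), `decay_width`,
#'   `gain_center`, `gain_width`, `gain_scale`, `gain_rate` and `fresh_age`.
#' @export
default_aging_models <- function() {
  am <- function(decay, gain_scale) {
    list(decay_bands = decay, decay_width = 30,
         gain_center = 3300, gain_width = 140,
         gain_scale = gain_scale, gain_rate = 0.02, fresh_age = 1L)
  }
  list(
    blood  = am(c("1640" = 0.004, "1532" = 0.004), 0.03),
    saliva = am(c("1640" = 0.004, "1537" = 0.004), 0.03),
    semen  = am(c("1622" = 0.004, "1547" = 0.004), 0.03),
    urine  = am(c("1592" = 0.005, "1457" = 0.005), 0.08),
    sweat  = am(c("1455" = 0.004), 0.08)
  )
}

#' Apply an aging transform to spectra
#'
#' @param x Absorbance vector or matrix (rows = spectra) on `grid`.
#' @param model One element of [default_aging_models()].
#' @param age_days Target age; must be >= the model's fresh reference age.
#'   At the fresh age the input is returned unchanged.
#' @param grid Wavenumber grid.
#' @return Aged spectra with the dimensions of `x`.
#' @export
apply_aging <- function(x, model, age_days, grid = default_grid()) {
  dd <- age_days - model$fresh_age
  if (dd < 0) stop("domain error: age precedes the fresh reference",
                   call. = FALSE)
  if (dd == 0) return(x)
  m <- rep(1, length(grid))
  for (j in seq_along(model$decay_bands)) {
    ctr <- as.numeric(names(model$decay_bands)[j])
    f <- 1 - exp(-model$decay_bands[[j]] * dd)
    m <- m * (1 - f * exp(-(grid - ctr)^2 / (2 * model$decay_width^2)))
  }
  gain <- model$gain_scale * (1 - exp(-model$gain_rate * dd)) *
    exp(-(grid - model$gain_center)^2 / (2 * model$gain_width^2))
  if (is.matrix(x)) {
    sweep(x, 2L, m, "*") + matrix(gain, nrow(x), length(grid), byrow = TRUE)
  } else {
    x * m + gain
  }
}

#' Reference sampling design
#'
#' The study design the generator reproduces by default: 10 blood donors
#' with 10 replicate spectra each, 18 saliva / 20 semen / 20 urine donors
#' with 5 replicates and 15 sweat donors with 5 replicates, i.e. 100, 90,
#' 100, 100 and 75 spectra (475 total, 83 donors) per age examined.
#'
#' @param ages Integer vector of sample ages in days (1 = fresh).
#' @param seed RNG seed recorded with the design.
#' @return A design list consumed by [simulate_dataset()].
#' @export
reference_design <- function(ages = 1L, seed = 1L) {
  list(per_fluid = data.frame(
    fluid = fluid_labels(),
    n_donors = c(10L, 18L, 20L, 20L, 15L),
    replicates = c(10L, 5L, 5L, 5L, 5L)),
    ages = as.integer(ages), seed = as.integer(seed))
}

#' Custom sampling design
#'
#' @param fluids Fluid labels to simulate.
#' @param n_donors,replicates Per-fluid donor and replicate counts
#'   (recycled).
#' @param ages Ages in days.
#' @param seed RNG seed.
#' @return A design list consumed by [simulate_dataset()].
#' @export
dataset_design <- function(fluids = fluid_labels(), n_donors = 10L,
                           replicates = 5L, ages = 1L, seed = 1L) {
  stopifnot(all(n_donors >= 1L), all(replicates >= 1L))
  list(per_fluid = data.frame(
    fluid = fluids,
    n_donors = rep_len(as.integer(n_donors), length(fluids)),
    replicates = rep_len(as.integer(replicates), length(fluids))),
    ages = as.integer(ages), seed = as.integer(seed))
}

#' Simulate a body-fluid spectra dataset
#'
#' Donor band-amplitude multipliers are drawn once per donor and shared by
#' all of that donor's replicates and ages; replicate multipliers, baseline
#' wander and noise are redrawn per spectrum. Aged spectra receive the
#' fluid's aging transform before noise. The whole dataset is reproducible
#' from `design$seed`.
#'
#' @param design From [reference_design()] or [dataset_design()].
#' @param templates Named list of [fluid_template()] per fluid.
#' @param aging Named list of aging models per fluid (see
#'   [default_aging_models()]); only used when `design$ages` goes beyond the
#'   fresh age.
#' @param grid Wavenumber grid.
#' @param noise_sd,baseline_offset Passed to the per-spectrum generator.
#' @return A [spectra_set()] in absorbance mode (not yet area-normalized)
#'   with fully populated metadata.
#' @export
simulate_dataset <- function(design, templates = default_fluid_templates(),
                             aging = default_aging_models(),
                             grid = default_grid(), noise_sd = 0.002,
                             baseline_offset = 0.02) {
  set.seed(design$seed)
  rows <- list(); meta <- list(); ri <- 0L
  for (f in seq_len(nrow(design$per_fluid))) {
    fluid <- design$per_fluid$fluid[f]
    tpl <- templates[[fluid]]
    if (is.null(tpl)) stop("no template for fluid '", fluid, "'",
                           call. = FALSE)
    nb <- nrow(tpl$bands)
    G <- .band_profiles(tpl$bands, grid)
    for (d in seq_len(design$per_fluid$n_donors[f])) {
      donor_id <- sprintf("%s_d%02d", fluid, d)
      dm <- .lognormal_mult(nb, tpl$donor_cv)
      for (age in design$ages) {
        for (r in seq_len(design$per_fluid$replicates[f])) {
          rm <- .lognormal_mult(nb, tpl$replicate_cv)
          y <- as.vector(G %*% (tpl$bands$amplitude * dm * rm)) +
            .baseline(grid, tpl$baseline_scale, baseline_offset)
          if (age > 1L) y <- apply_aging(y, aging[[fluid]], age, grid)
          if (noise_sd > 0) y <- y + stats::rnorm(length(grid), sd = noise_sd)
          ri <- ri + 1L
          rows[[ri]] <- pmax(y, 0)
          meta[[ri]] <- data.frame(
            sample_id = sprintf("%s_a%03d_r%02d", donor_id, age, r),
            fluid = fluid, donor_id = donor_id, age_days = age)
        }
      }
    }
  }
  s <- spectra_set(do.call(rbind, rows), grid, do.call(rbind, meta),
                   "absorbance")
  attr(s, "seed") <- design$seed
  s
}

#' Bulk-simulate fresh spectra of one fluid as a matrix
#'
#' Vectorized equivalent of drawing `n_donors x replicates` fresh spectra
#' with [simulate_dataset()] for a single fluid, without metadata: donor
#' multipliers are drawn once per donor and shared across that donor's
#' replicates. Intended for large Monte-Carlo calibration studies (e.g.
#' estimating Q-test acceptance rates from 10^5-10^6 draws) where the
#' per-spectrum bookkeeping of [simulate_dataset()] would dominate the
#' runtime.
#'
#' @param template A [fluid_template()].
#' @param n_donors,replicates Donor and per-donor replicate counts.
#' @param grid Wavenumber grid.
#' @param noise_sd,baseline_offset As in [simulate_spectrum()].
#' @return `(n_donors x replicates)` x `length(grid)` absorbance matrix
#'   (not area-normalized). Uses the current RNG state; seed outside.
#' @export
simulate_fluid_matrix <- function(template, n_donors, replicates = 5L,
                                  grid = default_grid(), noise_sd = 0.002,
                                  baseline_offset = 0.02) {
  nb <- nrow(template$bands)
  n <- n_donors * replicates
  G <- .band_profiles(template$bands, grid)              # p x nb
  D <- matrix(.lognormal_mult(n_donors * nb, template$donor_cv),
              n_donors, nb)
  M <- D[rep(seq_len(n_donors), each = replicates), , drop = FALSE] *
    matrix(.lognormal_mult(n * nb, template$replicate_cv), n, nb)
  X <- tcrossprod(sweep(M, 2L, template$bands$amplitude, "*"), G)
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  X <- X + baseline_offset +
    template$baseline_scale *
    (tcrossprod(stats::rnorm(n), cospi(u)) +
       tcrossprod(stats::rnorm(n), cospi(2 * u)))
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * length(grid),
                                                 sd = noise_sd),
                                    n, length(grid))
  pmax(X, 0)
}

#' Simulate a panel of non-body-fluid interferents
#'
#' Each panel member is a random Gaussian band mixture whose band-center set
#' is rejection-sampled to differ from every fluid template in at least two
#' of that fluid's three strongest bands (no interferent band within
#' 50 cm-1). Members behave like single "donors" with replicate spectra.
#'
#' @param panel_size Number of interferent types.
#' @param reps Replicate spectra per type.
#' @param templates Fluid templates to stay distinguishable from.
#' @param grid Wavenumber grid.
#' @param noise_sd,baseline_offset As in [simulate_spectrum()].
#' @param seed RNG seed.
#' @return A [spectra_set()] with fluids labeled `non_bf:panelNN`.
#' @export
simulate_non_bf <- function(panel_size = 14L, reps = 5L,
                            templates = default_fluid_templates(),
                            grid = default_grid(), noise_sd = 0.002,
                            baseline_offset = 0.02, seed = 1L) {
  stopifnot(panel_size >= 1L, reps >= 1L)
  set.seed(seed)
  major <- lapply(templates, function(t) {
    o <- order(t$bands$amplitude, decreasing = TRUE)
    t$bands$center[o[seq_len(min(3L, length(o)))]]
  })
  sets <- list(); meta <- list(); ri <- 0L
  for (pmem in seq_len(panel_size)) {
    name <- sprintf("non_bf:panel%02d", pmem)
    for (try in 1:1000) {
      nb <- sample(4:8, 1L)
      centers <- stats::runif(nb, 700, 3600)
      ok <- all(vapply(major, function(mc) {
        sum(vapply(mc, function(c0) any(abs(centers - c0) <= 50), logical(1))) <= 1L
      }, logical(1)))
      if (ok) break
      if (try == 1000) stop("could not draw an off-template interferent",
                            call. = FALSE)
    }
    tpl <- fluid_template(name, data.frame(
      center = centers,
      width = stats::runif(nb, 20, 60),
      amplitude = stats::runif(nb, 0.2, 1.0)),
      donor_cv = 0, replicate_cv = 0.05)
    for (r in seq_len(reps)) {
      ri <- ri + 1L
      sets[[ri]] <- simulate_spectrum(tpl, 1, grid, noise_sd, baseline_offset)
      meta[[ri]] <- data.frame(
        sample_id = sprintf("panel%02d_r%02d", pmem, r),
        fluid = name, donor_id = sprintf("panel%02d", pmem), age_days = 1L)
    }
  }
  spectra_set(do.call(rbind, sets), grid, do.call(rbind, meta), "absorbance")
}
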