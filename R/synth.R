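# Synthetic DCE-MRI cohort generator. Each patient is a single-slice dynamic
# series (1 pre-contrast + 8 post-contrast frames) with a known lesion mask,
# known per-pixel time-to-peak phase, and class-dependent subregion texture.

#' Kinetic parameter set for synthetic enhancement curves
#'
#' Pixels inside the lesion follow a piecewise-linear rise to their peak
#' relative enhancement at the pixel's time-to-peak phase, then decay
#' geometrically (washout). Background tissue has no systematic enhancement.
#'
#' @param ttp_mixture Probability vector over the 8 post-contrast phases:
#'   the fraction of lesion pixels peaking at each phase. Must sum to 1.
#' @param peak_enhancement_range Interval for per-pixel peak relative
#'   enhancement (dimensionless; 1.0 means +100% over baseline).
#' @param washout_rate Per-phase fractional decay after the peak, in (0, 1).
#' @param noise_sd Additive Gaussian noise, gray-level units.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(ttp_mixture = rep(1 / 8, 8),
                           peak_enhancement_range = c(1.0, 2.0),
                           washout_rate = 0.15,
                           noise_sd = 2.0) {
  ttp_mixture <- as.numeric(ttp_mixture)
  if (length(ttp_mixture) != 8L || any(ttp_mixture < 0) ||
      abs(sum(ttp_mixture) - 1) > 1e-12) {
    stop("ttp_mixture must be 8 non-negative probabilities summing to 1")
  }
  if (length(peak_enhancement_range) != 2L ||
      any(peak_enhancement_range <= 0) || diff(peak_enhancement_range) < 0) {
    stop("peak_enhancement_range must be a positive increasing interval")
  }
  if (washout_rate <= 0 || washout_rate >= 1) {
    stop("washout_rate must lie in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    ttp_mixture = ttp_mixture,
    peak_enhancement_range = peak_enhancement_range,
    washout_rate = washout_rate,
    noise_sd = noise_sd
  ), class = "kinetic_params")
}

#' Generate an irregular elliptical lesion mask
#'
#' A star-shaped region: an ellipse with random center, axes and orientation,
#' radially perturbed by smooth periodic noise. The area lands between 1% and
#' 25% of the grid; the mask is a single 4-connected component.
#'
#' @param seed Integer seed; identical seeds give identical masks.
#' @param grid `(rows, cols)`, each at least 32.
#' @param label Class label (accepted for interface symmetry; the geometry
#'   model is label-independent).
#' @return Logical matrix mask.
#' @export
generate_lesion <- function(seed, grid = c(128L, 128L), label = "benign") {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 32L)) {
    stop("grid must be at least 32 x 32")
  }
  local_seed_eval(seed, {
    nr <- grid[1]; nc <- grid[2]
    npix <- nr * nc
    target_area <- stats::runif(1, 0.03, 0.15) * npix
    aspect <- stats::runif(1, 1, 2.2)
    b_ax <- sqrt(target_area / (pi * aspect))
    a_ax <- aspect * b_ax
    theta0 <- stats::runif(1, 0, pi)
    cr <- nr / 2 + stats::runif(1, -0.1, 0.1) * nr
    cc <- nc / 2 + stats::runif(1, -0.1, 0.1) * nc
    # smooth periodic radial perturbation from a low-order Fourier series
    kmax <- 5L
    amp <- stats::rnorm(kmax, 0, 1 / seq_len(kmax))
    phs <- stats::runif(kmax, 0, 2 * pi)
    rr <- matrix(seq_len(nr), nr, nc) - cr
    cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
    u <- cos(theta0) * cm + sin(theta0) * rr
    v <- -sin(theta0) * cm + cos(theta0) * rr
    ang <- atan2(v / b_ax, u / a_ax)
    pert <- matrix(0, nr, nc)
    for (k in seq_len(kmax)) pert <- pert + amp[k] * cos(k * ang + phs[k])
    pert <- 1 + 0.12 * pert
    mask <- (u / a_ax)^2 + (v / b_ax)^2 <= pert^2
    mask <- largest_component(mask)
    mask <- fill_holes(mask)
    lo <- 0.01 * npix; hi <- 0.25 * npix
    if (sum(mask) < lo || sum(mask) > hi) {
      # radial perturbation pushed the area out of bounds; fall back to the
      # unperturbed ellipse, which is within bounds by construction
      mask <- (u / a_ax)^2 + (v / b_ax)^2 <= 1
    }
    mask
  })
}

#' Assign spatially coherent time-to-peak phases inside a mask
#'
#' Draws a smooth Gaussian random field over the grid and bins its values at
#' the mixture's quantiles, so the phase proportions match `ttp_mixture`
#' (up to rounding) while phases form contiguous patches rather than
#' salt-and-pepper noise.
#'
#' @param mask Logical lesion mask.
#' @param ttp_mixture Probability vector over phases 1..8.
#' @param seed Integer seed.
#' @param corr_len Correlation length of the assignment field, pixels.
#' @return Integer matrix: phase 1..8 inside the mask, `NA` outside.
#' @export
assign_ttp <- function(mask, ttp_mixture, seed, corr_len = 3) {
  stopifnot(length(ttp_mixture) == 8L, abs(sum(ttp_mixture) - 1) < 1e-9)
  local_seed_eval(seed, {
    g <- gaussian_field(nrow(mask), ncol(mask), corr_len)
    vals <- g[mask]
    qs <- stats::quantile(vals, probs = cumsum(ttp_mixture)[1:7],
                          type = 1, names = FALSE)
    phase <- 1L + rowSums(outer(vals, qs, `>`))
    out <- matrix(NA_integer_, nrow(mask), ncol(mask))
    out[mask] <- as.integer(phase)
    out
  })
}

# True relative-enhancement curve: linear rise to `peak` at phase `ttp`,
# then geometric washout. Vectorized over pixels.
enhancement_curve <- function(ttp, peak, washout_rate, phase) {
  ifelse(phase <= ttp,
         peak * phase / ttp,
         peak * (1 - washout_rate)^(phase - ttp))
}

#' Generate one synthetic DCE study
#'
#' Builds the pre-contrast image and 8 post-contrast images for a patient.
#' Lesion pixels follow `I(t) = I(t0) * (1 + H(t)) + noise` with `H`
#' rising linearly to its maximum exactly at the pixel's injected TTP phase
#' and decaying geometrically afterward; background pixels have no
#' systematic enhancement. Per-pixel peak enhancement is modulated by a
#' zone-wise Gaussian random field, which plants class-dependent texture.
#'
#' @param mask Logical lesion mask (truth).
#' @param ttp Integer matrix of injected TTP phases (1..8) inside the mask.
#' @param kin A [kinetic_params()] object.
#' @param seed Integer seed.
#' @param texture Optional list with `corr_len` and `amp`, each a named
#'   vector over zones `early`, `moderate`, `late`: correlation length
#'   (pixels) and relative amplitude of the peak-enhancement field.
#' @param baseline Mean pre-contrast tissue intensity, gray-level units.
#' @param peak_mid Center of the per-pixel peak-enhancement field before
#'   zone-wise modulation; defaults to the midpoint of
#'   `kin$peak_enhancement_range`.
#' @param label,cohort,patient_id Metadata carried on the study.
#' @return A `dce_study`: list with `pre` (matrix), `post` (R x C x 8 array),
#'   `label`, `cohort`, `patient_id`, `pixel_spacing` and `truth`
#'   (`mask`, `ttp`).
#' @export
generate_study <- function(mask, ttp, kin, seed,
                           texture = NULL,
                           baseline = 200, peak_mid = NULL,
                           label = "benign", cohort = "training",
                           patient_id = "P000") {
  stopifnot(inherits(kin, "kinetic_params"), is.logical(mask))
  if (any(is.na(ttp[mask]))) stop("every lesion pixel needs an injected TTP")
  if (is.null(texture)) {
    texture <- list(
      corr_len = c(early = 2.5, moderate = 2.5, late = 2.5),
      amp = c(early = 0.25, moderate = 0.25, late = 0.25)
    )
  }
  local_seed_eval(seed, {
    nr <- nrow(mask); nc <- ncol(mask)
    base_img <- baseline * (1 + 0.05 * gaussian_field(nr, nc, 8))
    base_img <- pmax(base_img, 1)

    rng <- kin$peak_enhancement_range
    p_mid <- if (is.null(peak_mid)) mean(rng) else peak_mid
    peak <- matrix(p_mid, nr, nc)
    zone_of <- function(tt) ifelse(tt <= 4L, 1L, ifelse(tt <= 6L, 2L, 3L))
    zones <- c("early", "moderate", "late")
    zg_sd <- if (is.null(texture$zone_gain_sd)) 0 else texture$zone_gain_sd
    zone_gain <- exp(stats::rnorm(3, 0, zg_sd))
    for (zi in 1:3) {
      g <- gaussian_field(nr, nc, texture$corr_len[[zones[zi]]])
      sel <- mask & !is.na(ttp) & zone_of(ttp) == zi
      peak[sel] <- p_mid * zone_gain[zi] *
        (1 + texture$amp[[zones[zi]]] * g[sel])
    }
    peak <- pmin(pmax(peak, rng[1]), rng[2])

    noise <- function() {
      if (kin$noise_sd > 0) {
        matrix(stats::rnorm(nr * nc, 0, kin$noise_sd), nr, nc)
      } else matrix(0, nr, nc)
    }
    pre <- base_img + noise()
    post <- array(0, dim = c(nr, nc, 8))
    H <- matrix(0, nr, nc)
    for (t in 1:8) {
      H[] <- 0
      H[mask] <- enhancement_curve(ttp[mask], peak[mask],
                                   kin$washout_rate, t)
      post[, , t] <- base_img * (1 + H) + noise()
    }
    structure(list(
      pre = pre, post = post,
      label = label, cohort = cohort, patient_id = patient_id,
      pixel_spacing = c(1, 1), seed = seed,
      truth = list(mask = mask, ttp = ttp)
    ), class = "dce_study")
  })
}

#' Scenario presets for cohort generation
#'
#' Each preset defines, per class, population-level distributions from which
#' patient-level parameters are drawn: the mean time-to-peak mixture (with a
#' per-patient log-normal jitter so that zone proportions overlap between
#' classes), the per-patient peak-enhancement and washout ranges, and the
#' zone-wise texture field of the peak-enhancement map (spatial correlation
#' length and amplitude, jittered per patient). In `default` and `strong`,
#' malignant lesions peak earlier on average and carry rougher texture
#' (shorter correlation length, higher amplitude) in the early and late
#' subregions; the moderate subregion's texture is class-identical, and the
#' whole-lesion view mixes all three zones. In `null` both classes are
#' generated from identical settings.
#'
#' @param scenario One of `"default"`, `"null"`, `"strong"`.
#' @return Named list with `benign` and `malignant` entries (population
#'   parameter lists) plus `noise_sd` and jitter scales.
#' @export
scenario_preset <- function(scenario = c("default", "null", "strong")) {
  scenario <- match.arg(scenario)
  benign <- list(
    ttp_mixture = c(0.06, 0.09, 0.13, 0.17, 0.19, 0.16, 0.11, 0.09),
    corr_len = c(early = 3.2, moderate = 3.2, late = 3.2),
    amp = c(early = 0.30, moderate = 0.30, late = 0.30)
  )
  malignant <- switch(scenario,
    null = benign,
    default = list(
      ttp_mixture = c(0.11, 0.15, 0.17, 0.17, 0.14, 0.11, 0.08, 0.07),
      corr_len = c(early = 1.8, moderate = 4.5, late = 1.8),
      amp = c(early = 0.38, moderate = 0.24, late = 0.38)
    ),
    strong = list(
      ttp_mixture = c(0.16, 0.19, 0.19, 0.16, 0.11, 0.08, 0.06, 0.05),
      corr_len = c(early = 1.0, moderate = 3.2, late = 1.0),
      amp = c(early = 0.55, moderate = 0.30, late = 0.55)
    )
  )
  list(
    benign = benign, malignant = malignant,
    noise_sd_range = c(4, 9),
    peak_mid_range = c(1.2, 1.8),
    peak_clamp = c(0.5, 3.0),
    zone_gain_sd = 0.30,
    washout_range = c(0.10, 0.20),
    mixture_jitter_sd = if (scenario == "strong") 0.25 else 0.45,
    # patient-level texture modifiers: one shared factor per patient (base
    # roughness, class-independent nuisance) plus a small per-zone jitter
    shared_tex_sd = if (scenario == "strong") 0.15 else 0.30,
    zone_tex_sd = 0.08
  )
}

# Draw one patient's kinetic and texture parameters from a class preset.
draw_patient_params <- function(preset, label, seed) {
  cls <- preset[[label]]
  local_seed_eval(seed, {
    mix <- cls$ttp_mixture * exp(stats::rnorm(8, 0, preset$mixture_jitter_sd))
    mix <- mix / sum(mix)
    p_mid <- stats::runif(1, preset$peak_mid_range[1], preset$peak_mid_range[2])
    washout <- stats::runif(1, preset$washout_range[1],
                            preset$washout_range[2])
    noise_sd <- stats::runif(1, preset$noise_sd_range[1],
                             preset$noise_sd_range[2])
    corr_shared <- exp(stats::rnorm(1, 0, preset$shared_tex_sd))
    amp_shared <- exp(stats::rnorm(1, 0, preset$shared_tex_sd))
    zj <- preset$zone_tex_sd
    list(
      kin = kinetic_params(
        ttp_mixture = mix,
        peak_enhancement_range = preset$peak_clamp,
        washout_rate = washout,
        noise_sd = noise_sd
      ),
      peak_mid = p_mid,
      texture = list(
        corr_len = cls$corr_len * corr_shared * exp(stats::rnorm(3, 0, zj)),
        amp = cls$amp * amp_shared * exp(stats::rnorm(3, 0, zj)),
        zone_gain_sd = preset$zone_gain_sd
      )
    )
  })
}

#' Generate a synthetic cohort
#'
#' @param n_benign,n_malignant Patient counts (each at least 1).
#' @param scenario Preset name, see [scenario_preset()].
#' @param seed Integer master seed; every study derives its own substream.
#' @param cohort Cohort tag carried on each study (`"training"` or
#'   `"validation"`). The validation tag applies a mild scanner surrogate
#'   (slightly different baseline intensity and noise).
#' @param grid Image grid `(rows, cols)`.
#' @return List of `dce_study` objects, benign first, with `truth` attached
#'   to each.
#' @export
generate_cohort <- function(n_benign, n_malignant,
                            scenario = "default", seed = 17L,
                            cohort = "training", grid = c(128L, 128L)) {
  if (n_benign < 1 || n_malignant < 1) stop("cohort counts must be >= 1")
  preset <- scenario_preset(scenario)
  scanner_gain <- if (cohort == "validation") 1.06 else 1.0
  noise_gain <- if (cohort == "validation") 1.15 else 1.0
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  studies <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    s_par <- derive_seed(seed, 4L * k)
    s_mask <- derive_seed(seed, 4L * k + 1L)
    s_ttp <- derive_seed(seed, 4L * k + 2L)
    s_img <- derive_seed(seed, 4L * k + 3L)
    par <- draw_patient_params(preset, lab, s_par)
    kin <- par$kin
    kin$noise_sd <- kin$noise_sd * noise_gain
    mask <- generate_lesion(s_mask, grid, lab)
    ttp <- assign_ttp(mask, kin$ttp_mixture, s_ttp)
    studies[[k]] <- generate_study(
      mask, ttp, kin, s_img, texture = par$texture,
      baseline = 200 * scanner_gain, peak_mid = par$peak_mid,
      label = lab, cohort = cohort,
      patient_id = sprintf("%s%03d", if (cohort == "training") "T" else "V", k)
    )
  }
  studies
}
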