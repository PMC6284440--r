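# Synthetic microscopy fields, cohorts and tumor-volume trajectories with
# known ground truth. These emulate the study conditions of the RAD51
# immunofluorescence assay: crowded elliptical nuclei, a geminin-positive
# S/G2 subpopulation, punctate foci with diameters inside and outside the
# 0.42-1.15 um scoring band, pervasive gamma-H2AX damage foci, and
# exponential tumor growth/regression under treatment.

#' Per-marker focus count model
#'
#' Describes how many foci a nucleus carries for one marker. Each nucleus is
#' independently "focus-forming" with probability `forming_fraction`; forming
#' nuclei draw their in-band focus count from Poisson(`lambda_forming`),
#' non-forming nuclei from Poisson(`lambda_nonforming`). The defaults
#' (Poisson(12) vs Poisson(0.3)) separate the two classes cleanly under the
#' 5-or-more-foci positivity rule.
#'
#' @param forming_fraction probability in \[0,1\] that a nucleus forms foci.
#' @param lambda_forming,lambda_nonforming Poisson means for the two classes.
#' @param count optional fixed focus count per nucleus (overrides the Poisson
#'   draws; used to construct exact ground truths).
#' @param diameters optional vector of focus diameters in um, recycled across
#'   each nucleus's foci (overrides the random diameter model).
#' @return A `marker_model` list.
#' @export
marker_model <- function(forming_fraction = 0.6, lambda_forming = 12,
                         lambda_nonforming = 0.3, count = NULL,
                         diameters = NULL) {
  stopifnot(forming_fraction >= 0, forming_fraction <= 1,
            lambda_forming >= 0, lambda_nonforming >= 0)
  structure(list(forming_fraction = forming_fraction,
                 lambda_forming = lambda_forming,
                 lambda_nonforming = lambda_nonforming,
                 count = count, diameters = diameters),
            class = "marker_model")
}

# Center-distance factor f such that two equal circles of radius r placed
# f*(r1+r2) apart overlap by `cap` of one circle's area (lens formula).
overlap_cap_factor <- function(cap) {
  if (cap <= 0) return(1)
  f <- function(x) 2 * acos(x / 2) - (x / 2) * sqrt(4 - x^2) - cap * pi
  x <- uniroot(f, c(1e-6, 2 - 1e-9))$root  # x = d / r
  x / 2
}

#' Specification of one synthetic microscopy field
#'
#' @param field_shape integer (height, width) in pixels.
#' @param pixel_size pixel size in um/pixel.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius c(mean, sd) of the nuclear radius in um.
#' @param geminin_fraction probability that a nucleus is geminin-positive.
#' @param markers named list of [marker_model()]s, one per foci channel.
#' @param focus_diameter c(mean, sd, min, max) of focus diameters in um
#'   (Normal truncated to \[min, max\]).
#' @param focus_min_sep minimum center-to-center distance between foci of
#'   one nucleus in um; foci are distinct resolvable puncta, so spots are
#'   placed by dart throwing at this separation (a focus that cannot be
#'   placed after 200 tries is dropped, and the ground truth reflects what
#'   was rendered).
#' @param focus_peak_snr ratio of focus peak amplitude to the background
#'   noise sd (for noise-free fields the amplitude reference is 0.02).
#' @param background_level baseline intensity of every channel.
#' @param nuclear_level added intensity inside nuclei on the nuclear channel.
#' @param geminin_level added intensity inside geminin-positive nuclei on the
#'   geminin channel (default 5x the background, mirroring a strong stain).
#' @param noise_sd additive Gaussian noise sd on every channel (0 = none).
#' @param overlap_cap maximum allowed pairwise nuclear area overlap fraction.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return A `field_spec` list validated against its invariants.
#' @export
field_spec <- function(field_shape = c(512L, 512L), pixel_size = 0.11,
                       n_nuclei = 25,
                       nucleus_radius = c(mean = 3.5, sd = 0.4),
                       geminin_fraction = 0.5,
                       markers = list(RAD51 = marker_model()),
                       focus_diameter = c(mean = 0.7, sd = 0.12,
                                          min = 0.45, max = 1.1),
                       focus_min_sep = 1.3,
                       focus_peak_snr = 8, background_level = 0.1,
                       nuclear_level = 0.5,
                       geminin_level = 5 * background_level,
                       noise_sd = 0.02, overlap_cap = 0.1, seed = 1L) {
  if (any(field_shape <= 0) || pixel_size <= 0)
    abort("field dimensions and pixel size must be positive",
          class = "rad51score_invalid_spec")
  if (n_nuclei < 0 || geminin_fraction < 0 || geminin_fraction > 1)
    abort("n_nuclei must be >= 0 and geminin_fraction in [0,1]",
          class = "rad51score_invalid_spec")
  if (any(focus_diameter[c("mean", "min", "max")] <= 0))
    abort("focus diameters must be positive",
          class = "rad51score_invalid_spec")
  stopifnot(length(markers) >= 1, !is.null(names(markers)))
  structure(list(field_shape = as.integer(field_shape),
                 pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 geminin_fraction = geminin_fraction, markers = markers,
                 focus_diameter = focus_diameter,
                 focus_min_sep = focus_min_sep,
                 focus_peak_snr = focus_peak_snr,
                 background_level = background_level,
                 nuclear_level = nuclear_level,
                 geminin_level = geminin_level, noise_sd = noise_sd,
                 overlap_cap = overlap_cap, seed = as.integer(seed)),
            class = "field_spec")
}

# Sample nucleus centers/shapes with rejection on the pairwise overlap cap.
place_nuclei <- function(spec) {
  n <- spec$n_nuclei
  if (n == 0)
    return(data.frame(nucleus_id = integer(), row = numeric(),
                      col = numeric(), a_px = numeric(), b_px = numeric(),
                      theta = numeric(), radius_um = numeric()))
  h <- spec$field_shape[1]; w <- spec$field_shape[2]
  fac <- overlap_cap_factor(spec$overlap_cap)
  r_um <- pmax(rtruncnorm(n, spec$nucleus_radius[["mean"]],
                          spec$nucleus_radius[["sd"]],
                          lo = 0.5 * spec$nucleus_radius[["mean"]]), 0.5)
  r_px <- r_um / spec$pixel_size
  ecc <- runif(n, 0, 0.25)
  a <- r_px * (1 + ecc); b <- r_px / (1 + ecc)
  theta <- runif(n, 0, pi)
  rows <- cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:500) {
      m <- a[i] + 2  # keep whole nucleus inside the field
      if (2 * m >= h || 2 * m >= w)
        abort("nuclei too large for the field", class = "rad51score_invalid_spec")
      rr <- runif(1, m, h - m); cc <- runif(1, m, w - m)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        d <- sqrt((rows[j] - rr)^2 + (cols[j] - cc)^2)
        ok <- all(d >= fac * (r_px[j] + r_px[i]))
      }
      if (ok) { rows[i] <- rr; cols[i] <- cc; placed <- TRUE; break }
    }
    if (!placed)
      abort("could not place nuclei under the overlap cap; reduce n_nuclei",
            class = "rad51score_invalid_spec")
  }
  data.frame(nucleus_id = seq_len(n), row = rows, col = cols,
             a_px = a, b_px = b, theta = theta, radius_um = r_um)
}

# Logical mask of one ellipse on the pixel grid (1-based centers).
ellipse_mask_idx <- function(h, w, row0, col0, a, b, theta) {
  r1 <- max(1L, floor(row0 - a)); r2 <- min(h, ceiling(row0 + a))
  c1 <- max(1L, floor(col0 - a)); c2 <- min(w, ceiling(col0 + a))
  rs <- r1:r2; cs <- c1:c2
  dr <- outer(rs - row0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - col0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  sel <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  cbind(row = rs[sel[, 1]], col = cs[sel[, 2]])
}

# Draw foci for one nucleus under one marker model.
draw_foci <- function(mm, forming, nuc, spec) {
  k <- if (!is.null(mm$count)) mm$count
       else rpois(1, if (forming) mm$lambda_forming else mm$lambda_nonforming)
  if (k == 0)
    return(data.frame(row = numeric(), col = numeric(),
                      diameter_um = numeric()))
  if (!is.null(mm$diameters)) {
    d <- rep_len(mm$diameters, k)
  } else {
    fd <- spec$focus_diameter
    d <- rtruncnorm(k, fd[["mean"]], fd[["sd"]], fd[["min"]], fd[["max"]])
  }
  # dart-throwing: uniform in the ellipse (shrunk so spots lie well inside
  # the boundary) at a minimum pairwise separation that grows with the two
  # spot diameters, so rendered puncta stay resolvable; largest spots are
  # placed first (they are the hardest to fit)
  d <- sort(d, decreasing = TRUE)
  rows <- cols <- dd <- numeric(0)
  for (i in seq_len(k)) {
    for (try in 1:200) {
      s <- 0.78 * sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
      u <- s * cos(phi) * nuc$a_px; v <- s * sin(phi) * nuc$b_px
      rr <- nuc$row + u * cos(nuc$theta) - v * sin(nuc$theta)
      cc <- nuc$col + u * sin(nuc$theta) + v * cos(nuc$theta)
      sep_px <- pmax(spec$focus_min_sep,
                     0.8 * (dd + d[i]) + 0.25) / spec$pixel_size
      if (!length(rows) ||
          all((rows - rr)^2 + (cols - cc)^2 >= sep_px^2)) {
        rows <- c(rows, rr); cols <- c(cols, cc); dd <- c(dd, d[i])
        break
      }
    }
  }
  if (!length(rows))
    return(data.frame(row = numeric(), col = numeric(),
                      diameter_um = numeric()))
  data.frame(row = rows, col = cols, diameter_um = dd)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

# Add a 2-D Gaussian spot (FWHM = diameter) to a channel, in place.
render_spot <- function(img, row0, col0, diameter_px, amplitude) {
  sg <- diameter_px * FWHM_TO_SIGMA
  hw <- ceiling(4 * sg)
  h <- nrow(img); w <- ncol(img)
  r1 <- max(1L, floor(row0 - hw)); r2 <- min(h, ceiling(row0 + hw))
  c1 <- max(1L, floor(col0 - hw)); c2 <- min(w, ceiling(col0 + hw))
  rs <- r1:r2; cs <- c1:c2
  g <- exp(-outer((rs - row0)^2, (cs - col0)^2, "+") / (2 * sg^2))
  img[rs, cs] <- img[rs, cs] + amplitude * g
  img
}

#' Synthesize one multi-channel field with ground truth
#'
#' Renders a nuclear channel (elliptical nuclei), a geminin channel (elevated
#' only inside geminin-positive nuclei) and one channel per foci marker
#' (2-D Gaussian spots whose full width at half maximum equals the nominal
#' focus diameter), all over a flat background with additive Gaussian noise.
#' The returned ground truth describes exactly what was rendered.
#'
#' @param spec a [field_spec()].
#' @param field_id,sample_id,area_id identifiers stamped on the output.
#' @param render if `FALSE`, skip image rendering and return ground truth
#'   only (fast path for distributional checks).
#' @return list with `field` (a [field_image()], or `NULL` when
#'   `render = FALSE`) and `truth` (list of `nuclei` and `foci` data frames;
#'   coordinates are 0-based (row, col) pixel positions).
#' @export
synthesize_field <- function(spec, field_id = "F1", sample_id = "S1",
                             area_id = "A1", render = TRUE) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, {
    nuc <- place_nuclei(spec)
    nuc$geminin <- if (nrow(nuc)) runif(nrow(nuc)) < spec$geminin_fraction
                   else logical()
    foci <- do.call(rbind, c(list(
      data.frame(nucleus_id = integer(), marker = character(),
                 row = numeric(), col = numeric(), diameter_um = numeric())),
      unlist(lapply(names(spec$markers), function(mk) {
        mm <- spec$markers[[mk]]
        lapply(seq_len(nrow(nuc)), function(i) {
          forming <- runif(1) < mm$forming_fraction
          f <- draw_foci(mm, forming, nuc[i, ], spec)
          if (!nrow(f)) return(NULL)
          cbind(nucleus_id = nuc$nucleus_id[i], marker = mk, f)
        })
      }), recursive = FALSE)))
    truth <- list(
      nuclei = transform(nuc, row = row - 1, col = col - 1),
      foci = transform(foci, row = row - 1, col = col - 1))
    if (!render)
      return(list(field = NULL, truth = truth))

    h <- spec$field_shape[1]; w <- spec$field_shape[2]
    bg <- spec$background_level
    nuclear <- matrix(bg, h, w)
    geminin <- matrix(bg, h, w)
    jitter <- runif(max(nrow(nuc), 1), 0.85, 1.15)
    for (i in seq_len(nrow(nuc))) {
      idx <- ellipse_mask_idx(h, w, nuc$row[i], nuc$col[i],
                              nuc$a_px[i], nuc$b_px[i], nuc$theta[i])
      nuclear[idx] <- bg + spec$nuclear_level * jitter[i]
      if (nuc$geminin[i]) geminin[idx] <- bg + spec$geminin_level * jitter[i]
    }
    noise_ref <- if (spec$noise_sd > 0) spec$noise_sd else 0.02
    amp <- spec$focus_peak_snr * noise_ref
    channels <- list(nuclear = nuclear, geminin = geminin)
    for (mk in names(spec$markers)) {
      ch <- matrix(bg, h, w)
      f <- foci[foci$marker == mk, , drop = FALSE]
      for (j in seq_len(nrow(f)))
        ch <- render_spot(ch, f$row[j], f$col[j],
                          f$diameter_um[j] / spec$pixel_size, amp)
      channels[[mk]] <- ch
    }
    if (spec$noise_sd > 0)
      channels <- lapply(channels, function(ch)
        ch + matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
    field <- field_image(channels, pixel_size = spec$pixel_size,
                         field_id = field_id, sample_id = sample_id,
                         area_id = area_id)
    list(field = field, truth = truth)
  })
}

#' Specification of a synthetic PDX cohort
#'
#' Per-model RAD51 and HRD scores are drawn from class-conditional truncated
#' normal distributions; HRR-deficient models regress under PARP inhibition
#' and proficient models progress, via class-dependent exponential growth
#' rates. Defaults mirror the separations reported for PARPi-sensitive vs
#' -resistant xenograft cohorts (sensitive RAD51 scores near 1.25\%,
#' resistant near 66.5\%).
#'
#' @param n_models number of models (> 0).
#' @param deficient_fraction fraction of HRR-deficient models; when
#'   `deficient_fraction * n_models` is an integer the class counts are exact
#'   (deterministic allocation, then shuffle).
#' @param rad51_score_model list of `deficient`/`proficient` c(mean, sd, lo,
#'   hi) truncated-normal parameters on the \[0,100\] percent scale.
#' @param hrd_score_model same structure for the genomic-scar HRD score
#'   (consumed as a given number; higher = more deficient).
#' @param response_misclass probability that a model's response label
#'   contradicts its true HRR class (0 = labels follow class exactly).
#' @param volume_model list of `deficient`/`proficient` c(k, noise_sd):
#'   exponential rate per day (k < 0 regression) and log-normal
#'   measurement noise sd.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_models = 28, deficient_fraction = 0.25,
                        rad51_score_model = list(
                          deficient = c(mean = 1.25, sd = 0.5, lo = 0, hi = 10),
                          proficient = c(mean = 66.54, sd = 10, lo = 10.001,
                                         hi = 100)),
                        hrd_score_model = list(
                          deficient = c(mean = 55, sd = 15, lo = 0, hi = 100),
                          proficient = c(mean = 28, sd = 15, lo = 0, hi = 100)),
                        response_misclass = 0,
                        volume_model = list(
                          deficient = c(k = log(0.04) / 20, noise_sd = 0.05),
                          proficient = c(k = log(1.3) / 20, noise_sd = 0.05)),
                        seed = 1L) {
  if (n_models <= 0)
    abort("n_models must be positive", class = "rad51score_invalid_spec")
  stopifnot(deficient_fraction >= 0, deficient_fraction <= 1)
  structure(list(n_models = as.integer(n_models),
                 deficient_fraction = deficient_fraction,
                 rad51_score_model = rad51_score_model,
                 hrd_score_model = hrd_score_model,
                 response_misclass = response_misclass,
                 volume_model = volume_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_class_scores <- function(model, cls) {
  p <- model[[cls]]
  rtruncnorm(1, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])
}

#' Simulate a cohort table with ground-truth HRR classes
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per model: `model_id`, `true_class`
#'   ("deficient"/"proficient"), `rad51_score`, `hrd_score`, `responder`
#'   (logical) and `k` (true tumor growth rate per day).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_models
    n_def <- round(spec$deficient_fraction * n)
    cls <- sample(rep(c("deficient", "proficient"), c(n_def, n - n_def)))
    rad51 <- vapply(cls, function(cl)
      draw_class_scores(spec$rad51_score_model, cl), numeric(1))
    hrd <- vapply(cls, function(cl)
      draw_class_scores(spec$hrd_score_model, cl), numeric(1))
    responder <- cls == "deficient"
    flip <- runif(n) < spec$response_misclass
    responder[flip] <- !responder[flip]
    k <- vapply(ifelse(responder, "deficient", "proficient"), function(cl)
      spec$volume_model[[cl]][["k"]], numeric(1))
    data.frame(model_id = sprintf("M%02d", seq_len(n)), true_class = cls,
               rad51_score = unname(rad51), hrd_score = unname(hrd),
               responder = responder, k = unname(k),
               stringsAsFactors = FALSE)
  })
}

#' Simulate one tumor-volume trajectory
#'
#' Volumes follow \eqn{V(t) = V_1 e^{k (t - 1)}} with multiplicative
#' log-normal measurement noise; k < 0 models regression under an effective
#' drug, k > 0 progression.
#'
#' @param k exponential rate per day.
#' @param schedule measurement days; must start at day 1 (bi-weekly caliper
#'   schedule through day 21 by default).
#' @param v1 volume at day 1 in mm^3.
#' @param noise_sd sd of the log-normal measurement noise (0 = noise-free).
#' @param model_id,animal_id,arm identifiers stamped on the series.
#' @param seed integer seed.
#' @return data.frame (`model_id`, `animal_id`, `arm`, `day`, `volume_mm3`).
#' @export
simulate_volume_series <- function(k, schedule = c(1, 4, 8, 11, 15, 18, 21),
                                   v1 = 150, noise_sd = 0.05,
                                   model_id = "M01", animal_id = "a1",
                                   arm = "olaparib", seed = 1L) {
  if (schedule[1] != 1)
    abort("measurement schedule must start at day 1",
          class = "rad51score_invalid_spec")
  with_seed(seed, {
    v <- v1 * exp(k * (schedule - 1))
    if (noise_sd > 0) {
      eps <- rlnorm(length(schedule), 0, noise_sd)
      eps[1] <- 1  # the day-1 baseline anchors the series
      v <- v * eps
    }
    data.frame(model_id = model_id, animal_id = animal_id, arm = arm,
               day = schedule, volume_mm3 = v, stringsAsFactors = FALSE)
  })
}
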