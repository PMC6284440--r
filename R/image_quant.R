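# Per-nucleus quantification of multi-channel immunofluorescence fields:
# nucleus segmentation, geminin positivity calling, and band-limited focus
# detection. Imaging primitives (Gaussian filtering, distance transform,
# labelling, seeded propagation) come from EBImage; the detector itself —
# band-pass enhancement, local-maximum candidates, half-maximum sizing and
# the inclusive diameter band — is implemented here.

#' Construct a multi-channel field image
#'
#' @param channels named list of equally shaped numeric matrices; must
#'   contain `nuclear`, `geminin` and at least one marker channel.
#' @param pixel_size pixel size in um/pixel (> 0).
#' @param field_id,sample_id,area_id identifiers (the area is one
#'   representative region of a section).
#' @return A `field_image` object.
#' @export
field_image <- function(channels, pixel_size, field_id = "F1",
                        sample_id = "S1", area_id = "A1") {
  if (pixel_size <= 0) abort("pixel_size must be positive")
  if (!all(c("nuclear", "geminin") %in% names(channels)) ||
      length(channels) < 3)
    abort("channels must include 'nuclear', 'geminin' and >= 1 marker")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share one shape")
  structure(list(channels = channels, pixel_size = pixel_size,
                 field_id = field_id, sample_id = sample_id,
                 area_id = area_id),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image %s/%s/%s: %dx%d px @ %.3f um/px; channels: %s>\n",
              x$sample_id, x$area_id, x$field_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Nucleus segmentation parameters
#'
#' @param min_area_um2 regions smaller than this are discarded (um^2).
#' @param smooth_sigma Gaussian smoothing sigma in pixels applied to the
#'   nuclear channel and to the distance map before seed finding.
#' @param min_separation_um minimum distance between watershed seeds; local
#'   maxima of the smoothed distance map closer than this are suppressed.
#' @param discard_border drop nuclei touching the field border (their focus
#'   counts would be truncated).
#' @return A `segment_params` list.
#' @export
segment_params <- function(min_area_um2 = 20, smooth_sigma = 2,
                           min_separation_um = 4, discard_border = TRUE) {
  structure(list(min_area_um2 = min_area_um2, smooth_sigma = smooth_sigma,
                 min_separation_um = min_separation_um,
                 discard_border = discard_border),
            class = "segment_params")
}

# Strict-ish local maxima of a matrix: >= all 8 neighbours and > at least
# one, above `thr`. Returns (row, col, value), brightest first.
local_maxima <- function(m, thr) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  ge <- matrix(TRUE, h, w); gt <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    ge <- ge & (m >= nb)
    gt <- gt | (m > nb)
  }
  idx <- which(ge & gt & m > thr, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  out <- data.frame(row = idx[, 1], col = idx[, 2], value = m[idx])
  out[order(-out$value), , drop = FALSE]
}

# Greedy minimum-separation suppression: keep the brightest of any pair
# closer than `min_sep` pixels.
suppress_close <- function(peaks, min_sep) {
  if (nrow(peaks) <= 1) return(peaks)
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    j <- which(keep)
    keep[i] <- !length(j) ||
      all((peaks$row[j] - peaks$row[i])^2 +
          (peaks$col[j] - peaks$col[i])^2 >= min_sep^2)
  }
  peaks[keep, , drop = FALSE]
}

as_matrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

#' Segment nuclei by Otsu thresholding and distance-transform watershed
#'
#' The smoothed nuclear channel is thresholded (Otsu), cleaned by a
#' morphological opening and hole filling, and touching nuclei are split by
#' seeded propagation on the smoothed distance map: one label per local
#' maximum retained after minimum-separation suppression.
#'
#' @param field a [field_image()] (or a bare numeric matrix).
#' @param params a [segment_params()].
#' @return integer label matrix (0 = background, 1..n = nuclei). A blank
#'   (zero-variance) channel yields zero labels with a warning.
#' @export
segment_nuclei <- function(field, params = segment_params()) {
  img <- if (inherits(field, "field_image")) field$channels$nuclear else field
  px <- if (inherits(field, "field_image")) field$pixel_size else 1
  if (stats::var(as.vector(img)) == 0) {
    warning("blank nuclear channel: no nuclei segmented")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  sm <- as_matrix(EBImage::gblur(img, sigma = params$smooth_sigma))
  v <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(v))
  mask <- v > thr
  brush <- EBImage::makeBrush(5, shape = "disc")
  mask <- as_matrix(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0.5
  mask <- as_matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  dist <- as_matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  dsm <- as_matrix(EBImage::gblur(dist, sigma = params$smooth_sigma))
  peaks <- local_maxima(dsm, thr = 1)       # seeds at least 1 px inside
  peaks <- peaks[mask[cbind(peaks$row, peaks$col)], , drop = FALSE]
  peaks <- suppress_close(peaks, params$min_separation_um / px)
  if (!nrow(peaks)) return(matrix(0L, nrow(img), ncol(img)))
  seeds <- matrix(0L, nrow(img), ncol(img))
  seeds[cbind(peaks$row, peaks$col)] <- seq_len(nrow(peaks))
  # large lambda makes the split essentially geodesic-distance-driven
  # (Voronoi tessellation of the mask around the seeds), which divides
  # touching nuclei at the neck rather than by intensity gradients
  lab <- as_matrix(EBImage::propagate(EBImage::Image(dsm),
                                      EBImage::Image(seeds),
                                      mask = EBImage::Image(mask * 1),
                                      lambda = 100))
  lab <- round(lab)
  # drop small regions and border-touching nuclei, then relabel 1..n
  min_px <- params$min_area_um2 / px^2
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  tab <- tabulate(lab[lab > 0])
  drop <- which(tab < min_px)
  if (params$discard_border) drop <- union(drop, setdiff(border, 0))
  lab[lab %in% drop] <- 0
  old <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(old)) out[lab == old[i]] <- i
  out
}

# Otsu threshold on a numeric vector: the cut (midpoint between adjacent
# sorted values) maximizing between-class variance.
otsu_vector <- function(x) {
  s <- sort(unique(x))
  if (length(s) < 2) return(NA_real_)
  cuts <- (s[-1] + s[-length(s)]) / 2
  bcv <- vapply(cuts, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

#' Call geminin positivity per nucleus
#'
#' Default policy `"otsu"`: threshold the set of per-nucleus mean geminin
#' intensities by Otsu's criterion, guarded against degenerate unimodal
#' inputs — calls are all-negative unless the split achieves at least
#' `min_fold` contrast between the two groups. Policy `"fixed"` compares
#' each nucleus mean to `threshold`.
#'
#' @param labels label matrix from [segment_nuclei()].
#' @param geminin geminin channel matrix (same shape as `labels`).
#' @param policy `"otsu"` or `"fixed"`.
#' @param threshold fixed intensity threshold (policy `"fixed"`).
#' @param min_fold minimum positive/negative mean-intensity fold change for
#'   an Otsu split to be accepted.
#' @return named logical vector, one entry per label.
#' @export
call_geminin_positive <- function(labels, geminin, policy = c("otsu", "fixed"),
                                  threshold = NULL, min_fold = 1.5) {
  policy <- match.arg(policy)
  if (!identical(dim(labels), dim(geminin)))
    abort("labels and geminin channel shapes differ")
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(setNames(logical(), character()))
  means <- vapply(ids, function(i) mean(geminin[labels == i]), numeric(1))
  pos <- if (policy == "fixed") {
    means > threshold
  } else if (length(ids) < 2 || diff(range(means)) < 1e-12) {
    rep(FALSE, length(ids))  # no bimodality to threshold
  } else {
    t <- otsu_vector(means)
    p <- means > t
    if (!any(p) || all(p) ||
        mean(means[p]) < min_fold * max(mean(means[!p]), 1e-12))
      rep(FALSE, length(ids)) else p
  }
  setNames(pos, ids)
}

#' Focus detection parameters
#'
#' @param diameter_min,diameter_max inclusive equivalent-diameter band in um
#'   (defaults 0.42 and 1.15, the scoring band for RAD51 foci).
#' @param min_foci_per_cell focus-positivity threshold (>= this many in-band
#'   foci; default 5).
#' @param detection_sensitivity candidate threshold in units of the robust
#'   background sd of the band-pass image (default 3).
#' @param enhance_sigma c(low, high) band-pass (difference-of-Gaussians)
#'   sigmas in pixels at 0.11 um/px; `NULL` derives them from the diameter
#'   band once at construction, so later edits to the band alone act as a
#'   pure post-filter on measured diameters.
#' @param measure_sigma smoothing sigma (px) for half-maximum sizing; its
#'   width is subtracted in quadrature from measured diameters.
#' @return A `foci_params` list.
#' @export
foci_params <- function(diameter_min = 0.42, diameter_max = 1.15,
                        min_foci_per_cell = 5, detection_sensitivity = 3,
                        enhance_sigma = NULL, measure_sigma = 1) {
  if (diameter_min <= 0 || diameter_min >= diameter_max)
    abort("need 0 < diameter_min < diameter_max")
  if (min_foci_per_cell < 1) abort("min_foci_per_cell must be >= 1")
  structure(list(diameter_min = diameter_min, diameter_max = diameter_max,
                 min_foci_per_cell = min_foci_per_cell,
                 detection_sensitivity = detection_sensitivity,
                 enhance_sigma = enhance_sigma,
                 measure_sigma = measure_sigma),
            class = "foci_params")
}

# Detect foci across a whole channel against a label matrix. Returns one row
# per retained focus with its nucleus label and 0-based center coordinates.
detect_foci_labels <- function(channel, labels, pixel_size, params) {
  qc <- character()
  dmin_px <- params$diameter_min / pixel_size
  dmax_px <- params$diameter_max / pixel_size
  if (dmin_px < 2)
    qc <- c(qc, sprintf(
      "pixel size %.3f um is coarse: diameter_min spans %.1f px (< 2)",
      pixel_size, dmin_px))
  sig <- params$enhance_sigma
  if (is.null(sig))
    sig <- c(dmin_px * FWHM_TO_SIGMA, dmax_px * FWHM_TO_SIGMA * 1.5)
  enh <- as_matrix(EBImage::gblur(channel, sigma = sig[1])) -
         as_matrix(EBImage::gblur(channel, sigma = sig[2]))
  noise <- mad(enh)
  thr <- params$detection_sensitivity * max(noise, 1e-12)
  peaks <- local_maxima(enh, thr)
  peaks <- suppress_close(peaks, dmin_px)
  empty <- data.frame(nucleus_id = integer(), row = numeric(),
                      col = numeric(), diameter_um = numeric())
  attr(empty, "qc_warnings") <- qc
  if (!nrow(peaks)) return(empty)
  # keep candidates whose center falls inside a nucleus
  lab_at <- labels[cbind(peaks$row, peaks$col)]
  peaks <- peaks[lab_at > 0, , drop = FALSE]
  lab_at <- lab_at[lab_at > 0]
  if (!nrow(peaks)) return(empty)
  # half-maximum sizing on a lightly smoothed channel
  sm <- as_matrix(EBImage::gblur(channel, sigma = params$measure_sigma))
  bg <- median(sm)
  prom_thr <- params$detection_sensitivity * max(mad(sm), 1e-12)
  hw <- ceiling(2 * dmax_px)
  h <- nrow(channel); w <- ncol(channel)
  kern_um <- 2 * sqrt(2 * log(2)) * params$measure_sigma * pixel_size
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    r0 <- peaks$row[i]; c0 <- peaks$col[i]
    rs <- max(1, r0 - hw):min(h, r0 + hw)
    cs <- max(1, c0 - hw):min(w, c0 + hw)
    win <- sm[rs, cs, drop = FALSE]
    peak <- sm[r0, c0]
    if (peak - bg < prom_thr) return(NULL)
    above <- win >= bg + 0.5 * (peak - bg)
    comp <- as_matrix(EBImage::bwlabel(EBImage::Image(above * 1)))
    id <- comp[match(r0, rs), match(c0, cs)]
    if (id == 0) return(NULL)
    sel <- comp == id
    # a region touching the window edge is larger than the band allows
    if (any(sel[1, ]) || any(sel[nrow(sel), ]) ||
        any(sel[, 1]) || any(sel[, ncol(sel)])) return(NULL)
    d_obs <- 2 * sqrt(sum(sel) / pi) * pixel_size
    d <- sqrt(max(d_obs^2 - kern_um^2, 0))
    data.frame(nucleus_id = lab_at[i], row = r0 - 1, col = c0 - 1,
               diameter_um = d)
  })
  out <- do.call(rbind, c(list(empty), res))
  out <- out[out$diameter_um >= params$diameter_min &
             out$diameter_um <= params$diameter_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_warnings") <- qc
  out
}

#' Detect nuclear foci in a diameter band
#'
#' Band-pass (difference-of-Gaussians) enhancement tuned to the diameter
#' band, local-maximum candidates above `detection_sensitivity` robust
#' background sds, each candidate grown to its half-maximum region; the
#' equivalent diameter is \eqn{2\sqrt{area/\pi}} times the pixel size
#' (corrected for the measurement smoothing). Only foci with
#' `diameter_min <= d <= diameter_max` (both bounds inclusive) and center
#' inside the nucleus mask are returned.
#'
#' @param channel marker channel matrix.
#' @param mask logical matrix: the nucleus mask (non-empty).
#' @param pixel_size um/pixel.
#' @param params a [foci_params()].
#' @return data.frame (`row`, `col` 0-based center, `diameter_um`), with a
#'   `qc_warnings` attribute (e.g. a too-coarse pixel size).
#' @export
detect_foci <- function(channel, mask, pixel_size, params = foci_params()) {
  if (!any(mask)) abort("nucleus mask is empty")
  f <- detect_foci_labels(channel, matrix(as.integer(mask), nrow(mask)),
                          pixel_size, params)
  f$nucleus_id <- NULL
  f
}

# Inclusive band predicate shared by the detector and tests.
in_diameter_band <- function(d, params) {
  d >= params$diameter_min & d <= params$diameter_max
}

#' Quantify one field into per-nucleus records
#'
#' Runs segmentation, geminin calling, and per-marker focus detection, and
#' emits one record per retained nucleus.
#'
#' @param field a [field_image()].
#' @param foci a [foci_params()].
#' @param seg a [segment_params()].
#' @param geminin_policy,geminin_threshold see [call_geminin_positive()].
#' @param markers marker channels to quantify (default: all channels other
#'   than `nuclear` and `geminin`).
#' @return data.frame with columns `sample_id`, `field_id`, `area_id`,
#'   `nucleus_id`, `area_um2`, `geminin`, then per marker `<marker>_foci`
#'   (in-band count) and `<marker>_pos` (count >= `min_foci_per_cell`).
#' @export
quantify_field <- function(field, foci = foci_params(),
                           seg = segment_params(),
                           geminin_policy = "otsu", geminin_threshold = NULL,
                           markers = NULL) {
  stopifnot(inherits(field, "field_image"))
  if (is.null(markers))
    markers <- setdiff(names(field$channels), c("nuclear", "geminin"))
  labels <- segment_nuclei(field, seg)
  ids <- sort(unique(labels[labels > 0]))
  rec <- data.frame(sample_id = field$sample_id, field_id = field$field_id,
                    area_id = field$area_id, nucleus_id = ids,
                    area_um2 = tabulate(labels[labels > 0])[ids] *
                      field$pixel_size^2,
                    stringsAsFactors = FALSE)
  gem <- call_geminin_positive(labels, field$channels$geminin,
                               policy = geminin_policy,
                               threshold = geminin_threshold)
  rec$geminin <- as.logical(gem[as.character(ids)])
  for (mk in markers) {
    f <- detect_foci_labels(field$channels[[mk]], labels, field$pixel_size,
                            foci)
    cnt <- integer(length(ids))
    if (nrow(f)) {
      t <- table(factor(f$nucleus_id, levels = ids))
      cnt <- as.integer(t)
    }
    rec[[paste0(mk, "_foci")]] <- cnt
    rec[[paste0(mk, "_pos")]] <- cnt >= foci$min_foci_per_cell
  }
  rec
}
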