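# Microscopy-style quantification on synthetic or simulation-derived 2-D
# images and puncta-count time series: segmentation, puncta statistics and
# volume estimate, nucleation-kinetics fitting, Pearson correlation, and
# the logistic phase-boundary regression.

#' Synthesize a nucleus-like image with Gaussian puncta
#'
#' Gaussian spots of peak `intensity` and width `punctum_radius` on a
#' constant background with additive Gaussian noise; ground-truth centers
#' are returned for truth-based tests.
#'
#' @param n_puncta Number of puncta.
#' @param punctum_radius Gaussian sigma of each punctum (pixels).
#' @param intensity Peak intensity above background.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param image_size c(rows, cols).
#' @param seed Integer seed.
#' @param min_separation Minimum center separation (pixels).
#' @return list with `image` (matrix) and `centers` (n x 2).
#' @export
synthesize_nucleus_image <- function(n_puncta, punctum_radius = 2,
                                     intensity = 100, background = 10,
                                     noise_sd = 2, image_size = c(128, 128),
                                     seed = 1L,
                                     min_separation = 6 * punctum_radius) {
  nr <- image_size[1]; nc <- image_size[2]
  margin <- ceiling(4 * punctum_radius)
  if (n_puncta > 0 && (nr - 2 * margin < 1 || nc - 2 * margin < 1))
    stop("puncta do not fit in the frame")
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_puncta) {
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (!nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_separation) {
        centers <- rbind(centers, cand)
      } else {
        tries <- tries + 1
        if (tries > 5000) stop("puncta do not fit in the frame")
      }
    }
    img <- matrix(background, nr, nc)
    if (n_puncta > 0) {
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(nrow(centers))) {
        d2 <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2
        img <- img + intensity * exp(-d2 / (2 * punctum_radius^2))
      }
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    list(image = img, centers = centers)
  })
}

# IsoData (iterative intermeans) threshold.
isodata_threshold <- function(x) {
  x <- as.numeric(x)
  if (max(x) == min(x)) return(NA_real_)
  t0 <- mean(range(x))
  for (i in 1:200) {
    lo <- x[x <= t0]; hi <- x[x > t0]
    if (!length(hi) || !length(lo)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-10 * (max(x) - min(x))) return(t1)
    t0 <- t1
  }
  t0
}

#' Segment puncta in a single-channel image
#'
#' Gaussian smoothing, morphological (rolling-ball style) background
#' subtraction with a disc of radius `background_radius` (default 4 px),
#' automatic global threshold (IsoData or Otsu) and 8-connected component
#' labelling.
#'
#' @param image Numeric matrix.
#' @param method `"ISODATA"` (default) or `"OTSU"`.
#' @param smooth_sigma Gaussian smoothing sigma (px); 0 disables.
#' @param background_radius Disc radius for background subtraction (px).
#' @param min_area Minimum component area kept (px).
#' @return Integer label matrix (0 = background).
#' @export
segment_puncta <- function(image, method = c("ISODATA", "OTSU"),
                           smooth_sigma = 1, background_radius = 4,
                           min_area = 2) {
  method <- match.arg(method)
  if (max(image) == min(image))
    return(matrix(0L, nrow(image), ncol(image)))
  img <- image
  if (smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
  if (background_radius > 0) {
    brush <- EBImage::makeBrush(2 * background_radius + 1, shape = "disc")
    bg <- as.matrix(EBImage::opening(EBImage::Image(img), brush))
    img <- img - bg
  }
  thr <- if (method == "ISODATA") {
    isodata_threshold(img)
  } else {
    rng <- range(img)
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * (rng[2] - rng[1]) + rng[1]
  }
  if (is.na(thr)) return(matrix(0L, nrow(image), ncol(image)))
  mask <- matrix(as.integer(img > thr), nrow(img), ncol(img))
  lab <- cpp_label8(mask)
  if (min_area > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[] <- match(lab, keep, nomatch = 0L)
    }
  }
  lab
}

#' Puncta statistics and condensate volume estimate
#'
#' The volume estimate raises the mean punctum area to the power 3/2 and
#' multiplies by the punctum count.
#'
#' @param labels Integer label matrix from [segment_puncta()].
#' @param pixel_area Physical area per pixel (default 1).
#' @return list with `count`, `mean_area`, `total_area`, `volume_estimate`.
#' @export
puncta_stats <- function(labels, pixel_area = 1) {
  ids <- labels[labels > 0]
  count <- length(unique(ids))
  if (count == 0)
    return(list(count = 0L, mean_area = NA_real_, total_area = 0,
                volume_estimate = 0))
  areas <- as.numeric(table(ids)) * pixel_area
  list(count = count, mean_area = mean(areas), total_area = sum(areas),
       volume_estimate = count * mean(areas)^(3 / 2))
}

#' Pearson correlation between two images
#'
#' @param a,b Numeric matrices of equal shape.
#' @param region Optional logical mask or `list(rows =, cols =)` index
#'   ranges restricting the comparison.
#' @export
pearson_correlation <- function(a, b, region = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  if (!is.null(region)) {
    if (is.matrix(region)) {
      a <- a[region]; b <- b[region]
    } else {
      a <- a[region$rows, region$cols]; b <- b[region$rows, region$cols]
    }
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant input")
  stats::cor(a, b)
}

#' Fit nucleation kinetics to a puncta-count time series
#'
#' Delay: the time of the first frame that begins two consecutive strict
#' increases. Slope: least-squares slope over the maximal-R^2 window
#' (>= 3 frames) starting at the delay frame. Number density: the count at
#' the final frame.
#'
#' @param counts Integer puncta counts per frame (length >= 4).
#' @param frame_interval Time between frames (e.g. seconds).
#' @return list with `delay`, `slope`, `number_density`, `fit_window`
#'   (frame indices) — `delay`/`slope` are NA when the series never
#'   increases twice consecutively.
#' @export
fit_nucleation_kinetics <- function(counts, frame_interval) {
  n <- length(counts)
  stopifnot(n >= 4)
  times <- (seq_len(n) - 1) * frame_interval
  inc <- diff(counts) > 0
  i <- match(TRUE, inc[-length(inc)] & inc[-1])
  if (is.na(i))
    return(list(delay = NA_real_, slope = NA_real_,
                number_density = counts[n], fit_window = NULL))
  s0 <- i + 1L  # first frame of the rising pair
  delay <- times[s0]
  best <- NULL
  best_r2 <- -Inf
  for (e in seq.int(s0 + 2L, n)) {
    w <- s0:e
    fit <- stats::lm(counts[w] ~ times[w])
    # exact-linear windows trigger lm's perfect-fit note; R^2 = 1 is fine
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (is.nan(r2)) r2 <- -Inf
    # prefer the longest window among (numerically) equal-best R^2
    if (r2 > best_r2 + 1e-9 || (abs(r2 - best_r2) <= 1e-9 && !is.null(best))) {
      best_r2 <- max(r2, best_r2)
      best <- list(window = w, slope = unname(coef(fit)[2]))
    }
  }
  list(delay = delay, slope = best$slope, number_density = counts[n],
       fit_window = best$window)
}

#' Logistic regression phase boundary
#'
#' Fits a logistic model of the phase-separation flag on log10
#' concentration and inverse valence and returns the 50% decision contour.
#' Perfectly separable data are reported as a separating threshold with a
#' flag instead of divergent coefficients.
#'
#' @param points data.frame with columns `core_concentration`,
#'   `inverse_valence`, `phase_separated`.
#' @return list with `coefficients`, `separated`, `threshold` (on the
#'   separating variable when `separated`), and `boundary(conc)` giving the
#'   inverse valence of the 50% contour.
#' @export
logistic_phase_boundary <- function(points) {
  ps <- as.logical(points$phase_separated)
  if (length(unique(ps)) < 2)
    stop("both phase classes must be present")
  lc <- log10(points$core_concentration)
  iv <- points$inverse_valence
  sep_iv <- max(iv[!ps]) < min(iv[ps]) || max(iv[ps]) < min(iv[!ps])
  sep_lc <- max(lc[!ps]) < min(lc[ps]) || max(lc[ps]) < min(lc[!ps])
  fit <- suppressWarnings(glm(ps ~ lc + iv, family = binomial()))
  p <- stats::fitted(fit)
  separated <- sep_iv || sep_lc || all(p < 1e-6 | p > 1 - 1e-6)
  if (separated) {
    threshold <- if (sep_iv) {
      if (max(iv[!ps]) < min(iv[ps]))
        (max(iv[!ps]) + min(iv[ps])) / 2
      else
        (max(iv[ps]) + min(iv[!ps])) / 2
    } else {
      # separation along concentration
      (max(lc[!ps]) + min(lc[ps])) / 2
    }
    return(list(coefficients = NULL, separated = TRUE,
                threshold = threshold,
                threshold_variable = if (sep_iv) "inverse_valence" else "log10_concentration",
                boundary = function(conc) rep(if (sep_iv) threshold else NA_real_,
                                              length(conc))))
  }
  cf <- coef(fit)
  list(coefficients = cf, separated = FALSE, threshold = NA_real_,
       boundary = function(conc) -(cf[1] + cf[2] * log10(conc)) / cf[3])
}

#' Project a simulation state to a microscopy-like 2-D image
#'
#' Molecule reference points are projected along an axis, blurred with a
#' Gaussian point-spread function and sampled on a pixel grid; intensity is
#' proportional to the local molecule count.
#'
#' @param state A `sim_state`.
#' @param topology A `topology`.
#' @param axis Projection axis (`"x"`, `"y"` or `"z"`).
#' @param psf_sigma PSF sigma (nm).
#' @param pixel_size Pixel edge (nm).
#' @return Numeric intensity matrix.
#' @export
project_simulation <- function(state, topology, axis = "z", psf_sigma = 10,
                               pixel_size = 5) {
  ax <- match(axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  ref <- reference_particles(topology)
  pts <- state$positions[ref, keep, drop = FALSE]
  L <- box_lengths(state$box)[keep]
  n1 <- max(2L, ceiling(L[1] / pixel_size))
  n2 <- max(2L, ceiling(L[2] / pixel_size))
  img <- matrix(0, n1, n2)
  halfw <- ceiling(4 * psf_sigma / pixel_size)
  for (k in seq_len(nrow(pts))) {
    c1 <- pts[k, 1] / pixel_size + 0.5
    c2 <- pts[k, 2] / pixel_size + 0.5
    i1 <- max(1L, floor(c1 - halfw)):min(n1, ceiling(c1 + halfw))
    i2 <- max(1L, floor(c2 - halfw)):min(n2, ceiling(c2 + halfw))
    g1 <- exp(-((i1 - c1) * pixel_size)^2 / (2 * psf_sigma^2))
    g2 <- exp(-((i2 - c2) * pixel_size)^2 / (2 * psf_sigma^2))
    img[i1, i2] <- img[i1, i2] + outer(g1, g2)
  }
  img
}

#' Write / read 16-bit TIFF images
#'
#' @param image Numeric matrix (scaled to the 16-bit range on write).
#' @param path File path.
#' @export
write_image <- function(image, path) {
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
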