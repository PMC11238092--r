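test_that("synthetic nucleus images are deterministic with known SNR", {
  a <- synthesize_nucleus_image(5, seed = 3)
  b <- synthesize_nucleus_image(5, seed = 3)
  expect_identical(a$image, b$image)
  expect_equal(nrow(a$centers), 5)
  # zero puncta leaves pure background + noise
  blank <- synthesize_nucleus_image(0, background = 10, noise_sd = 2,
                                    seed = 1)
  expect_equal(mean(blank$image), 10, tolerance = 0.1)
  # SNR follows directly from the inputs
  clean <- synthesize_nucleus_image(1, intensity = 80, background = 5,
                                    noise_sd = 0, seed = 2)
  expect_equal(max(clean$image) - 5, 80, tolerance = 1)
})

test_that("segmentation recovers well-separated high-SNR puncta", {
  truth <- synthesize_nucleus_image(10, punctum_radius = 2, intensity = 120,
                                    background = 12, noise_sd = 3,
                                    image_size = c(160, 160), seed = 7)
  for (m in c("ISODATA", "OTSU")) {
    lab <- segment_puncta(truth$image, method = m)
    st <- puncta_stats(lab)
    expect_lte(abs(st$count - 10), 1)
  }
  # recovered centroids sit within a punctum radius of the truth
  lab <- segment_puncta(truth$image)
  cent <- t(vapply(seq_len(max(lab)), function(k) {
    ix <- which(lab == k, arr.ind = TRUE)
    colMeans(ix)
  }, numeric(2)))
  dmin <- apply(cent, 1, function(ct)
    min(sqrt(rowSums(sweep(truth$centers, 2, ct)^2))))
  expect_lt(max(dmin), 2.5)
})

test_that("segmentation handles blank input and intensity rescaling", {
  blank <- matrix(5, 64, 64)
  expect_equal(max(segment_puncta(blank)), 0)
  img <- synthesize_nucleus_image(6, seed = 11, image_size = c(128, 128))$image
  lab1 <- segment_puncta(img)
  lab2 <- segment_puncta(img * 37.5)
  expect_identical(lab1 > 0, lab2 > 0)  # thresholds are scale-covariant
})

test_that("puncta statistics implement the 3/2-power volume estimate", {
  lab <- matrix(0L, 20, 20)
  # 10 puncta of 4 px each
  for (k in 1:10) lab[(2 * k - 1):(2 * k), 1:2] <- k
  st <- puncta_stats(lab)
  expect_equal(st$count, 10)
  expect_equal(st$mean_area, 4)
  expect_equal(st$volume_estimate, 10 * 4^1.5)  # = 80
  # empty label image
  st0 <- puncta_stats(matrix(0L, 5, 5))
  expect_equal(st0$count, 0)
  expect_equal(st0$volume_estimate, 0)
  # doubling every area scales the volume by 2^(3/2)
  lab2 <- matrix(0L, 40, 20)
  for (k in 1:10) lab2[(4 * k - 3):(4 * k), 1:2] <- k
  expect_equal(puncta_stats(lab2)$volume_estimate / st$volume_estimate,
               2^1.5)
})

test_that("Pearson correlation identities and null distribution", {
  set.seed(5)
  a <- matrix(rnorm(10000), 100, 100)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a + 3), -1)
  expect_error(pearson_correlation(a, matrix(2, 100, 100)), "constant")
  # independent noise images decorrelate: |PCC| < 0.05 in 99% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(cor(rnorm(10000), rnorm(10000))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # symmetry and affine invariance
  b <- matrix(rnorm(10000), 100, 100)
  expect_equal(pearson_correlation(a, b), pearson_correlation(b, a))
  expect_equal(pearson_correlation(2.5 * a + 7, b),
               pearson_correlation(a, b), tolerance = 1e-12)
})

test_that("nucleation-kinetics fit follows the stated rules", {
  out <- fit_nucleation_kinetics(c(0, 0, 0, 2, 4, 6, 6, 6), 2)
  expect_equal(out$delay, 6)
  expect_equal(out$slope, 1)
  expect_equal(out$number_density, 6)
  # exhaustive-window oracle: best R^2 window starting at the delay frame
  counts <- c(1, 1, 2, 1, 3, 6, 9, 12, 13, 13)
  got <- fit_nucleation_kinetics(counts, 1)
  s0 <- got$fit_window[1]
  r2_of <- function(w) summary(lm(counts[w] ~ w))$r.squared
  cands <- lapply(seq.int(s0 + 2, length(counts)), function(e) s0:e)
  r2s <- vapply(cands, r2_of, numeric(1))
  best <- max(r2s)
  expect_equal(r2_of(got$fit_window), best, tolerance = 1e-9)
  # never-increasing series
  none <- fit_nucleation_kinetics(c(3, 3, 2, 2, 1), 1)
  expect_true(is.na(none$delay) && is.na(none$slope))
  expect_equal(none$number_density, 1)
  # strictly linear series returns the construction slope exactly
  lin <- fit_nucleation_kinetics(0:7, 0.5)
  expect_equal(lin$slope, 2)
})

test_that("logistic phase boundary finds a valence-separable threshold", {
  set.seed(9)
  n <- 120
  iv <- runif(n, 0.1, 0.9)
  conc <- 10^runif(n, -1, 1)
  ps <- iv > 0.5
  fit <- logistic_phase_boundary(
    data.frame(core_concentration = conc, inverse_valence = iv,
               phase_separated = ps))
  expect_true(fit$separated)
  expect_equal(fit$threshold, 0.5, tolerance = 0.02)
  expect_error(logistic_phase_boundary(
    data.frame(core_concentration = conc, inverse_valence = iv,
               phase_separated = TRUE)), "both phase classes")
})

test_that("non-separable logistic fits give a boundary and swap symmetry", {
  set.seed(10)
  n <- 400
  iv <- runif(n, 0, 1)
  conc <- 10^runif(n, -1, 1)
  lp <- 8 * (iv - 0.5) + 1.5 * log10(conc)
  ps <- runif(n) < stats::plogis(lp)
  pts <- data.frame(core_concentration = conc, inverse_valence = iv,
                    phase_separated = ps)
  fit <- logistic_phase_boundary(pts)
  expect_false(fit$separated)
  # decision contour at conc = 1 close to iv = 0.5
  expect_equal(unname(fit$boundary(1)), 0.5, tolerance = 0.1)
  swapped <- pts
  swapped$phase_separated <- !pts$phase_separated
  fit2 <- logistic_phase_boundary(swapped)
  expect_equal(unname(fit2$coefficients), -unname(fit$coefficients),
               tolerance = 1e-6)
})

test_that("simulation projection produces localized, count-linear images", {
  box <- box_spec(100, 100, 100)
  topo <- point_topology(1, "CORELET", box)
  topo$positions <- matrix(c(25, 60, 50), 1, 3)
  st <- initial_state(topo)
  img <- project_simulation(st, topo, axis = "z", psf_sigma = 5,
                            pixel_size = 5)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(5, 12), tolerance = 1)
  # intensity integral proportional to molecule count
  topo3 <- point_topology(3, "CORELET", box)
  topo3$positions <- rbind(c(25, 60, 50), c(70, 20, 10), c(50, 50, 90))
  img3 <- project_simulation(initial_state(topo3), topo3, "z", 5, 5)
  expect_equal(sum(img3) / sum(img), 3, tolerance = 0.01)
})

test_that("16-bit TIFF round trip preserves relative intensities", {
  img <- synthesize_nucleus_image(4, seed = 2, image_size = c(64, 64))$image
  f <- tempfile(fileext = ".tif")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(dim(back), dim(img))
  expect_gt(cor(as.numeric(back), as.numeric(img)), 0.9999)
})
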