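test_that("background correction removes flat and planar backgrounds", {
  flat <- matrix(100, 64, 64)
  expect_equal(correct_background(flat), matrix(0, 64, 64),
               tolerance = 1e-6)

  expect_warning(z <- correct_background(matrix(0, 32, 32)), "all-zero")
  expect_equal(z, matrix(0, 32, 32))

  # planar gradient + bright discs: empty-region residual is tiny relative
  # to the disc amplitude
  g <- gen_foci_image(n_nuclei = 3, foci_per_nucleus = 0, dim_px = 192,
                      background = 200, gradient = 500, seed = 51)
  corrected <- correct_background(g$image$nuclear_channel)
  empty <- corrected[g$image$nuclear_channel < 800]  # off-nucleus pixels
  expect_lt(median(empty), 0.01 * 2000)

  # idempotence within tolerance
  twice <- correct_background(corrected)
  expect_lt(max(abs(twice - corrected)), 0.02 * 2000)
})

test_that("noiseless discs segment to the planted count with disc-like shape", {
  g <- gen_foci_image(n_nuclei = 5, foci_per_nucleus = 0, seed = 52)
  seg <- segment_nuclei(g$image)
  expect_equal(nrow(seg$nuclei), 5)
  expect_equal(seg$nuclei$area, rep(pi * 11.3^2, 5), tolerance = 0.05)
  expect_true(all(seg$nuclei$shape_ratio <= 1.1))
  expect_true(all(seg$nuclei$lw_ratio < 1.1))
})

test_that("an undersized nucleus is excluded by the area filter and tallied", {
  g <- gen_foci_image(n_nuclei = 4, foci_per_nucleus = 0,
                      plant_undersized_nucleus = TRUE, seed = 53)
  expect_true(any(g$truth$nuclei$filtered))
  seg <- segment_nuclei(g$image)
  expect_equal(nrow(seg$nuclei), 4)
  expect_true("area" %in% seg$qc$reason)
})

test_that("retained objects satisfy every filter bound exactly as configured", {
  g <- gen_foci_image(n_nuclei = 5, foci_per_nucleus = 3, snr = 5, seed = 54)
  seg <- segment_nuclei(g$image)
  bounds <- list(area = c(100, 1500), shape_ratio = c(1, 5),
                 lw_ratio = c(1, 5), avg_intensity = c(500, 8000),
                 total_intensity = c(2e5, 5e7))
  for (f in names(bounds)) {
    expect_true(all(seg$nuclei[[f]] >= bounds[[f]][1] &
                      seg$nuclei[[f]] <= bounds[[f]][2]))
  }
  det <- detect_foci(g$image, seg)
  fbounds <- list(area = c(1, 30), shape_ratio = c(1, 5), lw_ratio = c(1, 5),
                  avg_intensity = c(500, 16000),
                  total_intensity = c(3e2, 1e6))
  for (f in names(fbounds)) {
    expect_true(all(det$foci[[f]] >= fbounds[[f]][1] &
                      det$foci[[f]] <= fbounds[[f]][2]))
  }
})

test_that("noiseless fields recover exact per-nucleus focus counts", {
  for (k in c(0, 1, 3, 10)) {
    g <- gen_foci_image(n_nuclei = 5, foci_per_nucleus = k, seed = 60 + k)
    seg <- suppressWarnings(segment_nuclei(g$image))
    det <- suppressWarnings(detect_foci(g$image, seg))
    expect_equal(det$records$n_foci, rep(k, 5),
                 label = sprintf("counts at k = %d", k))
  }
})

test_that("an oversized focus fails the 1-30 um2 filter", {
  g <- gen_foci_image(n_nuclei = 3, foci_per_nucleus = 1,
                      plant_oversized_focus = TRUE, seed = 65)
  seg <- segment_nuclei(g$image)
  det <- detect_foci(g$image, seg)
  # the oversized plant is excluded by the area filter; the separated
  # in-bound foci are all still counted
  expect_true(all(det$foci$area <= 30))
  expect_equal(sum(det$records$n_foci), sum(!g$truth$foci$filtered))
})

test_that("counts are invariant to translation and 90-degree rotation", {
  g <- gen_foci_image(n_nuclei = 4, foci_per_nucleus = 3, seed = 66)
  base_counts <- function(img) {
    seg <- segment_nuclei(img)
    sort(detect_foci(img, seg)$records$n_foci)
  }
  ref <- base_counts(g$image)

  rot <- foci_image(t(g$image$nuclear_channel)[ncol(g$image$nuclear_channel):1, ],
                    t(g$image$foci_channel)[ncol(g$image$foci_channel):1, ],
                    pixel_size = g$image$pixel_size)
  expect_equal(base_counts(rot), ref)

  shift <- function(m, dx, dy) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  # small translation; nuclei sit away from borders by construction
  tr <- foci_image(shift(g$image$nuclear_channel, 3, 2),
                   shift(g$image$foci_channel, 3, 2),
                   pixel_size = g$image$pixel_size)
  expect_equal(base_counts(tr), ref)
})

test_that("adding a planted focus never lowers the noiseless count", {
  g1 <- gen_foci_image(n_nuclei = 3, foci_per_nucleus = 2, seed = 67)
  g2 <- gen_foci_image(n_nuclei = 3, foci_per_nucleus = 3, seed = 67)
  c1 <- detect_foci(g1$image, segment_nuclei(g1$image))$records$n_foci
  c2 <- detect_foci(g2$image, segment_nuclei(g2$image))$records$n_foci
  expect_true(all(c2 >= c1))
})

test_that("per-condition statistics summarize counts and flag empty conditions", {
  records <- data.frame(condition = rep(c("vehicle", "combo"), each = 3),
                        field_id = "f1", nucleus = 1:6,
                        n_foci = c(3, 3, 3, 5, 7, 6))
  tab <- foci_statistics(records, conditions = c("vehicle", "combo", "empty"))
  expect_equal(tab$mean_foci[tab$condition == "vehicle"], 3)
  expect_equal(tab$sem_foci[tab$condition == "vehicle"], 0)
  expect_equal(tab$n_cells[tab$condition == "empty"], 0)
  expect_true(is.na(tab$mean_foci[tab$condition == "empty"]))

  one <- foci_statistics(records[1, , drop = FALSE])
  expect_true(is.na(one$sem_foci))
})

test_that("treated vs control generator regimes reproduce a ~3x foci ratio", {
  counts <- function(mean_foci, seed) {
    g <- gen_foci_image(n_nuclei = 6, foci_per_nucleus = mean_foci,
                        snr = 5, seed = seed)
    det <- detect_foci(g$image, segment_nuclei(g$image))
    mean(det$records$n_foci)
  }
  m_ctrl <- mean(vapply(1:3, function(i) counts(2, 70 + i), numeric(1)))
  m_trt <- mean(vapply(1:3, function(i) counts(6, 80 + i), numeric(1)))
  expect_gt(m_trt / m_ctrl, 2)
  expect_lt(m_trt / m_ctrl, 4)
})
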