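# one generated flatmount shared across tests in this file
sim0 <- generate_flatmount(flatmount_sim_spec(seed = 1))

test_that("vessel mask area matches the rendered tube footprint", {
  mask <- build_vessel_mask(sim0$image)
  expect_true(mask$fill_state)
  expect_equal(mask_area(mask), sim0$truth$tube_footprint_px *
                 sim0$image$pixel_size^2, tolerance = 0.02)
})

test_that("all-zero channel yields an empty mask with a warning", {
  img <- flatmount_image(list(CD31 = matrix(0, 32, 32)), pixel_size = 1)
  expect_warning(m <- build_vessel_mask(img), "all zero")
  expect_equal(mask_area(m), 0)
  expect_error(build_vessel_mask(img, channel = "nope"), "unknown channel")
})

test_that("hole filling closes a hollow lumen (flood-fill oracle)", {
  n <- 80
  g <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  r <- sqrt((g[, 1] - 40)^2 + (g[, 2] - 40)^2)
  ring <- matrix(abs(r - 12) <= 3, n, n)
  img <- mask_image(ring, "CD31")
  m <- build_vessel_mask(img)
  # oracle: holes = complement pixels not reachable from the border
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((!ring) * 1)))
  border_labs <- unique(c(comp[1, ], comp[n, ], comp[, 1], comp[, n]))
  filled_oracle <- ring | (comp > 0 & !(comp %in% border_labs))
  expect_gte(sum(m$mask), sum(filled_oracle) * 0.97)
  # interior centre pixel is part of the solid mask
  expect_true(m$mask[40, 40])
})

test_that("nucleus segmentation recovers disjoint nuclei and splits dumbbells", {
  nuc <- segment_nuclei(sim0$image)
  expect_equal(nrow(nuc), nrow(sim0$truth$nuclei))
  expect_true(all(nuc$area_um2 > 0))
  expect_true(all(nuc$circularity >= 0 & nuc$circularity <= 1))
  # blank channel
  blank <- flatmount_image(list(DAPI = matrix(3, 40, 40)), pixel_size = 1)
  expect_equal(nrow(segment_nuclei(blank)), 0)
  # dumbbell: two equal overlapping discs -> watershed yields 2 records;
  # oracle: the distance transform has two regional maxima
  db <- disc_mask(60, c(30, 24), 11) | disc_mask(60, c(30, 42), 11)
  # oracle: count regional maxima of the distance transform (disc-dilated
  # plateau comparison); the two disc centres each carry one maximum
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(db * 1)))
  pooled <- EBImage::imageData(EBImage::dilate(EBImage::Image(dm),
                                               EBImage::makeBrush(11, "disc")))
  peak_px <- which(dm > 8 & dm >= pooled - 1e-9, arr.ind = TRUE)
  n_maxima <- nrow(unique(round(peak_px / 8)))
  expect_equal(n_maxima, 2)
  expect_equal(nrow(segment_nuclei(mask_image(db))), n_maxima)
})

test_that("an ideal disc has circularity close to 1", {
  d <- disc_mask(221, c(111, 111), 90)
  nuc <- segment_nuclei(mask_image(d))
  expect_equal(nrow(nuc), 1)
  expect_gte(nuc$circularity, 0.9)
  expect_lte(nuc$circularity, 1.0)
})

test_that("cell classification follows the mask/circularity rule exactly", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, ] <- TRUE
  vm <- as_vessel_mask(mask)
  nuclei <- tibble::tibble(
    nucleus_id = 1:4,
    centroid_row = c(4, 15, 15, 15), centroid_col = c(10, 10, 10, 10),
    area_um2 = 30, perimeter_um = 20,
    circularity = c(0.9, 0.5, 0.61, 0.6)
  )
  cls <- classify_cells(nuclei, vm)
  expect_equal(as.character(cls$cell_class),
               c("endothelial",           # inside mask, any circularity
                 "pericyte",              # outside, 0.5 <= 0.6
                 "other_non_endothelial", # outside, 0.61 > 0.6
                 "pericyte"))             # boundary: rule is <=
})

test_that("classification is a partition on generated data", {
  mask <- build_vessel_mask(sim0$image)
  nuc <- classify_cells(segment_nuclei(sim0$image), mask)
  expect_equal(sum(table(nuc$cell_class)), nrow(nuc))
  expect_false(any(is.na(nuc$cell_class)))
})

test_that("nuclear marker quantification matches the direct formula", {
  n <- 64
  mask <- matrix(FALSE, n, n); mask[, 1:40] <- TRUE
  vm <- as_vessel_mask(mask)
  nuc_px <- list(disc_mask(n, c(20, 20), 4), disc_mask(n, c(44, 25), 4))
  lab <- matrix(0L, n, n)
  lab[nuc_px[[1]]] <- 1L; lab[nuc_px[[2]]] <- 2L
  nuclei <- tibble::tibble(nucleus_id = 1:2,
                           centroid_row = c(19, 43), centroid_col = c(19, 24),
                           area_um2 = c(sum(nuc_px[[1]]), sum(nuc_px[[2]])),
                           perimeter_um = 20, circularity = 0.9,
                           cell_class = factor(rep("endothelial", 2)))
  attr(nuclei, "label_matrix") <- lab
  bg <- 17.5
  S <- c(3.25, 9.5)   # per-pixel signal added over background
  marker <- matrix(bg, n, n)
  marker[nuc_px[[1]]] <- bg + S[1]
  marker[nuc_px[[2]]] <- bg + S[2]
  img <- flatmount_image(list(LEF1 = marker), pixel_size = 1)
  q <- quantify_nuclear_marker(img, "LEF1", nuclei, vm)
  expect_equal(q$background, bg, tolerance = 1e-9)
  expect_equal(q$nuclei$LEF1,
               c(S[1] * sum(nuc_px[[1]]), S[2] * sum(nuc_px[[2]])),
               tolerance = 1e-9)
  # uniform channel: every corrected intensity is exactly zero
  img0 <- flatmount_image(list(LEF1 = matrix(bg, n, n)), pixel_size = 1)
  q0 <- quantify_nuclear_marker(img0, "LEF1", nuclei, vm)
  expect_equal(q0$nuclei$LEF1, c(0, 0), tolerance = 1e-9)
  # per-flatmount summary is the median over nuclei of a class
  nuclei2 <- nuclei
  attr(nuclei2, "label_matrix") <- lab
  marker2 <- matrix(bg, n, n)
  marker2[nuc_px[[1]]] <- bg + 10 / sum(nuc_px[[1]])
  marker2[nuc_px[[2]]] <- bg + 30 / sum(nuc_px[[2]])
  img_med <- flatmount_image(list(LEF1 = marker2), pixel_size = 1)
  q2 <- quantify_nuclear_marker(img_med, "LEF1", nuclei2, vm)
  expect_equal(q2$summary$median_intensity[
    q2$summary$cell_class == "endothelial"], 20, tolerance = 1e-9)
  # empty background region errors
  vm_all <- as_vessel_mask(lab > 0)
  expect_error(quantify_nuclear_marker(img, "LEF1", nuclei, vm_all),
               "background")
})

test_that("membrane marker intensity is mean inside minus mean outside", {
  n <- 50
  mask <- matrix(FALSE, n, n); mask[1:25, ] <- TRUE
  vm <- as_vessel_mask(mask)
  b <- 12; s <- 34.5
  ch <- matrix(b, n, n); ch[mask] <- b + s
  img <- flatmount_image(list(VEC = ch), pixel_size = 1)
  expect_equal(quantify_membrane_marker(img, "VEC", vm), s, tolerance = 1e-9)
  img_const <- flatmount_image(list(VEC = matrix(b, n, n)), pixel_size = 1)
  expect_equal(quantify_membrane_marker(img_const, "VEC", vm), 0,
               tolerance = 1e-9)
  # noisy estimate within 3 sigma / sqrt(n) of the true contrast
  set.seed(21)
  sigma <- 5
  noisy <- pmax(ch + matrix(rnorm(n * n, 0, sigma), n, n), 0)
  imgn <- flatmount_image(list(VEC = noisy), pixel_size = 1)
  est <- quantify_membrane_marker(imgn, "VEC", vm)
  expect_lt(abs(est - s), 3 * sigma / sqrt(sum(mask)) * 2)
  # degenerate masks error
  expect_error(quantify_membrane_marker(img, "VEC",
                                        as_vessel_mask(matrix(TRUE, n, n))),
               "degenerate")
})

test_that("TUNEL puncta detection finds spots and splits touching pairs", {
  set.seed(22)
  n <- 128
  m <- matrix(3, n, n)
  centers <- cbind(sample(seq(15, n - 15, by = 22)),
                   sample(seq(15, n - 15, by = 22)))
  for (i in seq_len(nrow(centers))) m <- add_spot(m, centers[i, ])
  vm <- as_vessel_mask(matrix(TRUE, n, n))
  img <- flatmount_image(list(TUNEL = m), pixel_size = 1)
  p <- detect_tunel_puncta(img, "TUNEL", vm)
  expect_equal(nrow(p), nrow(centers))
  # blank channel
  img0 <- flatmount_image(list(TUNEL = matrix(3, n, n)), pixel_size = 1)
  expect_equal(nrow(detect_tunel_puncta(img0, "TUNEL", vm)), 0)
  # two touching spots with distinct maxima -> 2 after watershed
  m2 <- add_spot(add_spot(matrix(3, 60, 60), c(30, 26)), c(30, 36))
  img2 <- flatmount_image(list(TUNEL = m2), pixel_size = 1)
  p2 <- detect_tunel_puncta(img2, "TUNEL", as_vessel_mask(matrix(TRUE, 60, 60)))
  expect_equal(nrow(p2), 2)
})

test_that("positive area arithmetic, ratios and percent of control", {
  m <- matrix(0, 50, 50)
  m[1:25, 1:40] <- 100   # exactly 1000 positive pixels
  img <- flatmount_image(list(GPR124 = m, CD31 = m), pixel_size = 0.5)
  a <- positive_area(img, "GPR124")
  expect_equal(a$area_um2, 1000 * 0.25)  # 250 um^2 at 0.5 um/px
  # identical channel as numerator and denominator -> ratio 1
  r <- positive_area(img, "GPR124", denominator_channel = "CD31")
  expect_equal(r$ratio, 1.0)
  # ratio 0.1 vs control-group mean ratio 0.5 -> 20% of control
  m2 <- matrix(0, 50, 50); m2[1:5, 1:20] <- 100
  img2 <- flatmount_image(list(GPR124 = m2, CD31 = m), pixel_size = 0.5)
  pc <- positive_area(img2, "GPR124", denominator_channel = "CD31",
                      control_mean_ratio = 0.5)
  expect_equal(pc$percent_of_control, (0.1 / 0.5) * 100)
  # zero-denominator error
  img3 <- flatmount_image(list(GPR124 = m, CD31 = matrix(0, 50, 50)),
                          pixel_size = 0.5)
  expect_error(positive_area(img3, "GPR124", denominator_channel = "CD31"),
               "zero positive area")
})

test_that("positive area is monotone in the positive pixel set", {
  base <- matrix(0, 40, 40); base[10:20, 10:20] <- 100
  grown <- base; grown[10:25, 10:25] <- 100
  i1 <- flatmount_image(list(X = base), pixel_size = 1)
  i2 <- flatmount_image(list(X = grown), pixel_size = 1)
  expect_gte(positive_area(i2, "X")$area_um2, positive_area(i1, "X")$area_um2)
})

test_that("technical replicates average into biological replicates", {
  df <- tibble::tibble(animal = c("a", "a", "a", "b"),
                       genotype = c("ko", "ko", "ko", "wt"),
                       y = c(1, 2, 3, 7))
  agg <- aggregate_replicates(df, y, animal, genotype)
  expect_equal(agg$value[agg$animal == "a"], 2)
  expect_equal(agg$value[agg$animal == "b"], 7)  # identity for single value
  expect_equal(agg$n_replicates, c(3L, 1L))
  expect_warning(aggregate_replicates(
    tibble::tibble(animal = "a", y = NA_real_), y, animal), "no non-missing")
})

test_that("per-flatmount summaries are invariant to translation and rotation", {
  rot90 <- function(m) t(m)[, nrow(m):1]
  img_r <- flatmount_image(lapply(sim0$image$channels, rot90),
                           pixel_size = sim0$image$pixel_size)
  shift <- function(m, k = 7) {
    out <- matrix(m[1, 1], nrow(m), ncol(m))
    out[(k + 1):nrow(m), (k + 1):ncol(m)] <-
      m[1:(nrow(m) - k), 1:(ncol(m) - k)]
    out
  }
  img_t <- flatmount_image(lapply(sim0$image$channels, shift),
                           pixel_size = sim0$image$pixel_size)
  summarize <- function(img) {
    mask <- build_vessel_mask(img)
    nuc <- classify_cells(segment_nuclei(img), mask)
    p <- detect_tunel_puncta(img, "TUNEL", mask)
    c(area = mask_area(mask), n = nrow(nuc),
      as.vector(table(nuc$cell_class)), puncta = nrow(p))
  }
  s0 <- summarize(sim0$image)
  expect_equal(unname(summarize(img_r)), unname(s0), tolerance = 0.01)
  expect_equal(unname(summarize(img_t)), unname(s0), tolerance = 0.01)
})
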