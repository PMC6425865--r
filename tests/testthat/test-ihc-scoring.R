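# Scoring tables, stain separation, positivity and dichotomization.

test_that("digital score reproduces the printed interval anchors", {
  anchors <- c("0" = 0, "12.5" = 0, "12.6" = 1, "25" = 1, "26" = 2,
               "37.5" = 2, "37.6" = 3, "40" = 3, "50" = 3, "51" = 4,
               "62.5" = 4, "62.6" = 5, "75" = 5, "76" = 6, "87.5" = 6,
               "87.6" = 7, "100" = 7)
  expect_equal(digital_score(as.numeric(names(anchors))), unname(anchors))
  expect_equal(digital_score(25.4), 2)  # fractional inputs fall in (25, 37.5]
})

test_that("score mappings are total and monotone on a dense grid", {
  grid <- seq(0, 100, by = 0.1)
  ds <- digital_score(grid)
  expect_true(all(ds %in% 0:7))
  expect_true(all(diff(ds) >= 0))
  mc <- manual_composite(0, grid)
  expect_true(all(mc$proportion_bin %in% 0:4))
  expect_true(all(diff(mc$proportion_bin) >= 0))
  expect_error(digital_score(101), "0, 100")
  expect_error(digital_score(-1), "0, 100")
})

test_that("manual composite adds intensity and proportion bin", {
  expect_equal(manual_composite(3, 100)$composite, 7)
  expect_equal(manual_composite(0, 0)$composite, 0)
  mc <- manual_composite(2, 60)
  expect_equal(mc$proportion_bin, 3)
  expect_equal(mc$composite, 5)
  # printed integer anchors of the proportion bins
  expect_equal(manual_composite(0, c(0, 1, 25, 26, 50, 51, 75, 76, 100))$proportion_bin,
               c(0, 1, 1, 2, 2, 3, 3, 4, 4))
  # composite decomposes exactly
  withr::with_seed(1, {
    i <- sample(0:3, 50, replace = TRUE)
    p <- runif(50, 0, 100)
    mc <- manual_composite(i, p)
    expect_equal(mc$composite - mc$intensity, mc$proportion_bin)
    expect_true(all(mc$composite >= 0 & mc$composite <= 7))
  })
  expect_error(manual_composite(4, 50), "intensity")
})

test_that("dichotomization labels every score and honours the tie rule", {
  expect_equal(as.character(dichotomize(0:7, cutpoint = 4)),
               rep(c("low", "high"), each = 4))
  expect_equal(as.character(dichotomize(rep(3, 5))), rep("high", 5))  # median tie
  # the >50% / <50% proliferation-marker split
  expect_equal(as.character(dichotomize(c(10, 49, 51, 90), cutpoint = 51)),
               c("low", "low", "high", "high"))
  expect_error(dichotomize(numeric()), "non-empty")
  s <- withr::with_seed(2, sample(0:7, 30, replace = TRUE))
  expect_false(any(is.na(dichotomize(s))))  # partition: no record unlabeled
})

test_that("stain separation inverts the synthetic stain mixing", {
  # blank slide: white pixels carry no DAB
  white <- array(1, dim = c(8, 8, 3))
  sep <- separate_stains(white)
  expect_lt(max(sep$dab), 0.01)

  # pure DAB colour has (near-)zero haematoxylin after deconvolution
  sv <- stain_vectors_hdab()
  od <- 0.8 * sv["dab", ]
  v <- pmin(pmax(round(256 * 10^(-od)) - 1, 0), 255)
  dab_img <- array(rep(v / 255, each = 25), dim = c(5, 5, 3))
  sep <- separate_stains(dab_img)
  expect_lt(max(sep$hematoxylin), 0.02)
  expect_gt(min(sep$dab), 0.7)

  # noise-free synthetic core: recovered DAB map matches ground truth
  core <- gen_core_image(core_image_spec(2, 40, noise_sd = 0, seed = 7))
  sep <- separate_stains(core$image)
  expect_gt(cor(as.vector(sep$dab[core$tissue_mask]),
                as.vector(core$dab_od[core$tissue_mask])), 0.999)
  expect_error(separate_stains(matrix(1, 4, 4)), "RGB")
})

test_that("positivity counts tissue pixels above the OD threshold", {
  core <- gen_core_image(core_image_spec(2, 40, noise_sd = 0, seed = 11))
  sep <- separate_stains(core$image)
  pos <- positivity(sep$dab, core$tissue_mask)
  expect_lt(abs(pos - 40), 2)
  # ground-truth mask agrees with the measurement
  expect_equal(pos, 100 * sum(core$positive_mask) / sum(core$tissue_mask),
               tolerance = 0.02)
  # threshold above the maximum OD: nothing positive
  expect_equal(positivity(sep$dab, core$tissue_mask, od_threshold = 99), 0)
  # threshold 0 on fully stained tissue: everything positive
  full <- gen_core_image(core_image_spec(3, 100, seed = 2))
  sep_full <- separate_stains(full$image)
  expect_equal(positivity(sep_full$dab, full$tissue_mask, od_threshold = 0), 100)
  expect_error(positivity(sep$dab, core$tissue_mask & FALSE), "no tissue")
})

test_that("positivity is rotation invariant and tracks stained fraction", {
  core <- gen_core_image(core_image_spec(2, 35, noise_sd = 0, seed = 3))
  sep <- separate_stains(core$image)
  p1 <- positivity(sep$dab, core$tissue_mask)
  p2 <- positivity(rot90(sep$dab), rot90(core$tissue_mask))
  expect_equal(p1, p2)
  for (frac in c(0, 15, 60, 90)) {
    core <- gen_core_image(core_image_spec(2, frac, noise_sd = 0, seed = 5))
    sep <- separate_stains(core$image)
    expect_lt(abs(positivity(sep$dab, core$tissue_mask) - frac), 2)
  }
})

test_that("positivity recovery error grows with stain noise", {
  err_at <- function(noise_sd) {
    errs <- vapply(1:4, function(k) {
      core <- gen_core_image(core_image_spec(2, 40, noise_sd = noise_sd,
                                             seed = 20 + k))
      sep <- separate_stains(core$image)
      abs(positivity(sep$dab, core$tissue_mask) - 40)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0, 0.05, 0.25), err_at, numeric(1))
  expect_lt(errs[1], 0.5)
  expect_true(all(diff(errs) >= 0))
})

test_that("localization calls follow the ring/cytoplasm decision rule", {
  expect_equal(as.character(classify_localization(0, 0)), "negative")
  expect_equal(as.character(classify_localization(2, 1, ratio_threshold = 1.5)),
               "membranous")
  expect_equal(as.character(classify_localization(1, 1)), "cytoplasmic")
  expect_equal(as.character(classify_localization(0.5, 0)), "membranous")
  # membrane-only synthetic cells are all called membranous
  withr::with_seed(4, {
    ring <- runif(50, 0.5, 1.5)
    calls <- classify_localization(ring, rep(0, 50))
    expect_true(all(calls == "membranous"))
  })
  expect_error(classify_localization(-1, 0), "non-negative")
})

test_that("full-core scoring assembles digital and manual scores", {
  core <- gen_core_image(core_image_spec(2, 45, noise_sd = 0, seed = 9))
  row <- score_core_image(core$image, core$tissue_mask,
                          intensity = 2, proportion_pct = 45, core_id = "c1")
  expect_equal(row$digital_score, 3)   # 45% falls in (37.5, 50]
  expect_equal(row$composite, 4)       # intensity 2 + bin 2
  expect_equal(row$core_id, "c1")
})
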