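test_that("modality classification follows the paresthetic-descriptor rule", {
  expect_equal(classify_modality(c("vibration")), "naturalistic")
  expect_equal(classify_modality(c("electrical")), "paresthetic")
  expect_equal(classify_modality(c("pressure", "electrical")), "mixed")
  expect_equal(classify_modality(c("touch", "pressure")), "naturalistic")
  # sharp is paresthetic by rule despite sitting in the mechanical column
  expect_equal(classify_modality(c("sharp")), "paresthetic")
  # itch is not paresthetic by default, configurable
  expect_equal(classify_modality(c("itch")), "naturalistic")
  expect_equal(classify_modality(c("itch"), include_itch = TRUE), "paresthetic")
  # temperature counts as non-paresthetic content
  expect_equal(classify_modality(c("electrical", "temperature")), "mixed")
  expect_error(classify_modality(c("zap")), "zap")
  expect_error(classify_modality(character(0)), "no descriptors")
})

test_that("the three classes partition any report set", {
  vocab <- unlist(descriptor_vocabulary(), use.names = FALSE)
  set.seed(61)
  reports <- lapply(1:200, function(i)
    sample(vocab, sample(1:4, 1)))
  cls <- classify_modality(reports)
  expect_true(all(cls %in% c("paresthetic", "mixed", "naturalistic")))
  mf <- modality_fractions(reports)
  expect_equal(sum(mf$n), 200)
  expect_equal(sum(mf$fraction), 1)
})

test_that("modality fractions count constructed sets correctly", {
  reports <- c(rep(list(c("electrical")), 4),
               rep(list(c("electrical", "touch")), 4),
               rep(list(c("pressure")), 2))
  mf <- modality_fractions(reports)
  expect_equal(mf$fraction[mf$modality == "paresthetic"], 0.4)
  expect_equal(mf$fraction[mf$modality == "mixed"], 0.4)
  expect_equal(mf$fraction[mf$modality == "naturalistic"], 0.2)
  # all-touch reports: fully naturalistic, empty tingle annulus
  touch_only <- rep(list("touch"), 10)
  expect_equal(modality_fractions(touch_only)$fraction,
               c(0, 0, 1))
  sb <- sunburst_counts(touch_only)
  expect_equal(sb$n[sb$level == 1 & sb$tingle == "(none)"], 10)
  expect_false(any(sb$tingle %in% descriptor_vocabulary()$tingle))
})

test_that("sunburst nesting reproduces constructed hierarchy ratios", {
  # 761 reports with an electrical-tingle component, 245 of which also carry
  # sharp, 104 of which also carry vibration
  reports <- c(
    rep(list(c("electrical", "sharp", "vibration")), 104),
    rep(list(c("electrical", "sharp")), 245 - 104),
    rep(list(c("electrical")), 761 - 245))
  sb <- sunburst_counts(reports)
  n_tingle <- sb$n[sb$level == 1 & sb$tingle == "electrical"]
  n_sharp <- sb$n[sb$level == 2 & sb$mechanical == "sharp"]
  n_vib <- sb$n[sb$level == 3 & sb$movement == "vibration"]
  expect_equal(n_tingle, 761)
  expect_equal(n_sharp / n_tingle, 245 / 761)
  expect_equal(n_vib / n_sharp, 104 / 245)
})

test_that("sunburst child counts never exceed their parents", {
  set.seed(62)
  vocab <- unlist(descriptor_vocabulary(), use.names = FALSE)
  reports <- lapply(1:300, function(i) sample(vocab, sample(1:5, 1)))
  sb <- sunburst_counts(reports)
  for (i in which(sb$level == 2)) {
    parent <- sb$n[sb$level == 1 & sb$tingle == sb$tingle[i]]
    expect_lte(sb$n[i], parent)
  }
  for (i in which(sb$level == 3)) {
    parent <- sb$n[sb$level == 2 & sb$tingle == sb$tingle[i] &
                     sb$mechanical == sb$mechanical[i]]
    expect_lte(sb$n[i], parent)
  }
})

test_that("body-region assignment takes the maximal-overlap segment", {
  tpl <- arm_template()
  thumb_px <- which(tpl$labels == 1L, arr.ind = TRUE)
  m_thumb <- mask_from_pixels(tpl, thumb_px[1:20, 1], thumb_px[1:20, 2])
  expect_equal(assign_body_region(m_thumb), "thumb")
  # 60/40 split between forearm and wrist
  fore_px <- which(tpl$labels == 6L, arr.ind = TRUE)
  wrist_px <- which(tpl$labels == 5L, arr.ind = TRUE)
  m_mix <- mask_from_pixels(tpl,
                            c(fore_px[1:60, 1], wrist_px[1:40, 1]),
                            c(fore_px[1:60, 2], wrist_px[1:40, 2]))
  expect_equal(assign_body_region(m_mix), "forearm")
  # exact 50/50: wrist wins (distal-first order)
  m_tie <- mask_from_pixels(tpl,
                            c(fore_px[1:50, 1], wrist_px[1:50, 1]),
                            c(fore_px[1:50, 2], wrist_px[1:50, 2]))
  expect_equal(assign_body_region(m_tie), "wrist")
  # mask fully outside labeled regions
  bg <- which(tpl$labels == 0L, arr.ind = TRUE)
  m_bg <- mask_from_pixels(tpl, bg[1:5, 1], bg[1:5, 2])
  expect_warning(r <- assign_body_region(m_bg), "unassigned")
  expect_true(is.na(r))
})

test_that("dermatome proportions condition on region and sum to 1", {
  el <- tibble::tibble(electrode = c("A", "B", "C"),
                       spinal_level = c("C6", "C7", "C7"))
  pc <- tibble::tibble(electrode = c("A", "B", "C"),
                       region = c("thumb", "d2_d3", "d2_d3"),
                       laterality = "ipsilateral")
  dp <- dermatome_proportions(el, pc)
  expect_equal(dp$thumb[dp$spinal_level == "C6"], 1.0)
  expect_equal(dp$d2_d3[dp$spinal_level == "C7"], 1.0)
  expect_equal(sum(dp$d2_d3), 1)
  # never-evoked region: NA column, distinguishable from zero
  expect_true(all(is.na(dp$palm)))
  # contralateral-only electrode is excluded from the denominator
  pc2 <- dplyr::bind_rows(pc, tibble::tibble(
    electrode = "A", region = "thumb", laterality = "contralateral"))
  el2 <- dplyr::bind_rows(el, tibble::tibble(electrode = "D",
                                             spinal_level = "C8"))
  pc3 <- tibble::tibble(electrode = c("A", "D"), region = "thumb",
                        laterality = c("ipsilateral", "contralateral"))
  dp3 <- dermatome_proportions(el2, pc3)
  expect_equal(dp3$thumb[dp3$spinal_level == "C6"], 1.0)
  expect_equal(dp3$thumb[dp3$spinal_level == "C8"], 0)
  # electrode without a spinal level is excluded with a warning
  el_na <- tibble::tibble(electrode = c("A", "X"),
                          spinal_level = c("C6", NA))
  expect_warning(dermatome_proportions(el_na, pc[1, ]), "X")
})
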