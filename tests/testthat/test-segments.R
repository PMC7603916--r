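# 17-segment scoring, thresholds and protocol arithmetic.

score_map <- function(v) segment_map17(v, "score")

test_that("summed scores and their percent transform behave", {
  zeros <- score_map(rep(0, 17))
  s0 <- summed_scores(zeros, zeros)
  expect_equal(c(s0$SSS, s0$SRS, s0$SDS), c(0L, 0L, 0L))
  # saturation
  s_max <- summed_scores(score_map(rep(4, 17)), zeros)
  expect_equal(s_max$SSS, 68L)
  expect_equal(s_max$SDS, 68L)
  expect_equal(s_max$SSS_percent, 100)
  # two segments scored 2 -> SSS 4, abnormal at the SSS >= 4 rule
  v <- rep(0, 17); v[1:2] <- 2
  s4 <- summed_scores(score_map(v), zeros)
  expect_equal(s4$SSS, 4L)
  expect_equal(classify_sss(s4), "mildly_abnormal")
  # SDS = SSS - SRS always
  set.seed(1)
  for (i in 1:25) {
    stress <- score_map(sample(0:4, 17, replace = TRUE))
    rest_v <- pmin(as.numeric(stress), sample(0:4, 17, replace = TRUE))
    s <- summed_scores(stress, score_map(rest_v))
    expect_identical(s$SDS, s$SSS - s$SRS)
    expect_true(s$SSS_percent >= 0 && s$SSS_percent <= 100)
  }
  expect_error(summed_scores(segment_map17(rep(1.5, 17), "MFR"), zeros),
               class = "mbfpet_invalid_parameter")
  expect_error(score_map(rep(5, 17)), class = "mbfpet_invalid_parameter")
})

test_that("SSS classification follows the published bands and conventions", {
  mk <- function(sss) {
    v <- rep(0, 17)
    v[seq_len(ceiling(sss / 4))] <- c(rep(4, sss %/% 4), sss %% 4)[
      seq_len(ceiling(sss / 4))]
    summed_scores(score_map(v), score_map(rep(0, 17)))
  }
  expect_equal(classify_sss(mk(0)), "normal")
  expect_equal(classify_sss(mk(3)), "normal")
  expect_equal(classify_sss(mk(4)), "mildly_abnormal")
  expect_equal(classify_sss(mk(7)), "mildly_abnormal")
  expect_equal(classify_sss(mk(8)), "moderate_severe")
  expect_equal(classify_sss(mk(12)), "moderate_severe")
  # SSS = 3 is under 5% of the maximal myocardial score
  expect_lt(mk(3)$SSS_percent, 5)
  # stricter conventions
  expect_equal(classify_sss(mk(1), "hsiao"), "abnormal")
  expect_equal(classify_sss(mk(0), "hsiao"), "normal")
  expect_equal(classify_sss(mk(1), "dorbala"), "abnormal")  # 1/68 > 1%
  expect_error(classify_sss(mk(1), "nonsense"),
               class = "mbfpet_validation_error")
})

test_that("MFR maps are element-wise ratios with two global summaries", {
  rest <- segment_map17(rep(1, 17), "MBF_rest")
  stress <- segment_map17(rep(1, 17), "MBF_stress")
  expect_true(all(as.numeric(mfr(stress, rest)$map) == 1))
  stress3 <- segment_map17(rep(3, 17), "MBF_stress")
  expect_true(all(as.numeric(mfr(stress3, rest)$map) == 3))
  # heterogeneous toy map against hand-computed ratios
  rv <- c(rep(0.8, 8), rep(1.2, 9))
  sv <- c(rep(2.4, 8), rep(1.8, 9))
  out <- mfr(segment_map17(sv, "MBF_stress"), segment_map17(rv, "MBF_rest"))
  expect_equal(as.numeric(out$map), sv / rv)
  expect_equal(out$global_mean_of_ratios, mean(sv / rv))
  expect_equal(out$global_ratio_of_means, mean(sv) / mean(rv))
  # scale invariance under common scaling
  out2 <- mfr(segment_map17(2 * sv, "MBF_stress"),
              segment_map17(2 * rv, "MBF_rest"))
  expect_equal(as.numeric(out2$map), as.numeric(out$map))
  # zero rest flags the segment
  rv0 <- rv; rv0[3] <- 0
  out0 <- mfr(segment_map17(sv, "MBF_stress"), segment_map17(rv0, "MBF_rest"))
  expect_true(is.na(out0$map[3]))
  expect_equal(out0$undefined_segments, 3L)
})

test_that("the adjacency graph is symmetric and ring-consistent", {
  A <- aha17_adjacency()
  expect_true(isSymmetric(A))
  expect_false(any(diag(A)))
  expect_true(all(A[17, 13:16]))       # apex touches all apical segments
  expect_true(A[1, 2] && A[6, 1])      # basal ring closes
  expect_true(all(A[cbind(1:6, 7:12)]))  # radial basal-mid neighbours
  expect_false(A[1, 4])                # opposite walls are not adjacent
})

test_that("water abnormality rule matches a brute-force adjacent-pair scan", {
  A <- aha17_adjacency()
  rules <- interpretation_rules("water-pacific")
  expect_equal(rules$stress_mbf_cutoff, 2.30)
  brute <- function(vals) {
    low <- vals <= rules$stress_mbf_cutoff
    for (i in 1:16) for (j in (i + 1):17)
      if (A[i, j] && low[i] && low[j]) return(TRUE)
    FALSE
  }
  # directed cases
  all_normal <- segment_map17(rep(3, 17), "MBF_stress")
  expect_false(classify_water_abnormal(all_normal)$abnormal)
  two_adj <- rep(3, 17); two_adj[c(1, 2)] <- 2.2
  expect_true(classify_water_abnormal(
    segment_map17(two_adj, "MBF_stress"))$abnormal)
  two_far <- rep(3, 17); two_far[c(1, 4)] <- 2.2
  expect_false(classify_water_abnormal(
    segment_map17(two_far, "MBF_stress"))$abnormal)
  boundary <- rep(3, 17); boundary[c(7, 8)] <- 2.30  # inclusive cutoff
  expect_true(classify_water_abnormal(
    segment_map17(boundary, "MBF_stress"))$abnormal)
  # 1000 random maps against the oracle
  set.seed(99)
  for (i in seq_len(1000)) {
    vals <- stats::runif(17, 1.5, 3.5)
    got <- classify_water_abnormal(segment_map17(vals, "MBF_stress"))
    expect_identical(got$abnormal, brute(vals))
  }
})

test_that("territory means aggregate to the global mean", {
  set.seed(4)
  vals <- stats::runif(17, 0.5, 4)
  tm <- territory_means(segment_map17(vals, "MBF_stress"))
  sizes <- c(LAD = 7, RCA = 5, LCX = 5)
  expect_equal(sum(tm[names(sizes)] * sizes) / 17, unname(tm["global"]))
  expect_equal(unname(tm["global"]), mean(vals))
})

test_that("rate-pressure-product correction is proportional", {
  expect_equal(rpp_correct_rest_mbf(1.0, 100, 100), 1.0)   # RPP == reference
  expect_equal(rpp_correct_rest_mbf(1.0, 200, 100), 0.5)   # doubling halves
  expect_equal(rpp_correct_rest_mbf(1.2, 80, 150), 1.0)    # hand arithmetic
  expect_error(rpp_correct_rest_mbf(1, 0, 100),
               class = "mbfpet_invalid_parameter")
})

test_that("LVEF reserve classification follows the +/-5 unit rule", {
  up <- lvef_reserve_classify(55, 62)
  expect_equal(up$reserve, 7)
  expect_equal(up$category, "severe_cad_unlikely")
  down <- lvef_reserve_classify(54, 48)
  expect_equal(down$reserve, -6)
  expect_equal(down$category, "severe_cad_likely")
  expect_true(down$negative_reserve)
  flat <- lvef_reserve_classify(50, 50)
  expect_equal(flat$category, "indeterminate")
  expect_false(flat$negative_reserve)
  mild_drop <- lvef_reserve_classify(50, 47)
  expect_equal(mild_drop$category, "indeterminate")
  expect_true(mild_drop$negative_reserve)
  expect_error(lvef_reserve_classify(-5, 50),
               class = "mbfpet_invalid_parameter")
})
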