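# AHA 17-segment aggregation, semi-quantitative scoring and threshold-based
# interpretation.

#' 17-segment polar map
#'
#' Per-segment values on the standard AHA 17-segment left-ventricular
#' model: segments 1-6 basal, 7-12 mid-cavity, 13-16 apical, 17 apex.
#'
#' @param values numeric vector of exactly 17 values (segment order 1-17).
#' @param quantity what the values are: `"MBF_rest"`, `"MBF_stress"`,
#'   `"MFR"` or `"score"`. Scores must be integers in 0-4 (0 normal ...
#'   4 absent perfusion).
#' @return object of class `segment_map17`.
#' @export
segment_map17 <- function(values,
                          quantity = c("MBF_rest", "MBF_stress", "MFR",
                                       "score")) {
  quantity <- match.arg(quantity)
  if (length(values) != 17L)
    stop_invalid("a 17-segment map needs exactly 17 values, got %d",
                 length(values))
  values <- as.numeric(values)
  if (quantity == "score") {
    if (any(is.na(values)) || any(values != round(values)) ||
        any(values < 0) || any(values > 4))
      stop_invalid("scores must be integers in 0..4")
  }
  structure(stats::setNames(values, paste0("seg", 1:17)),
            quantity = quantity, class = "segment_map17")
}

#' @export
print.segment_map17 <- function(x, ...) {
  cat(sprintf("<segment_map17> %s\n", attr(x, "quantity")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

map_quantity <- function(map) attr(map, "quantity")

#' Summed perfusion scores
#'
#' Sums the per-segment 0-4 severity scores of the stress and rest maps:
#' SSS (summed stress score), SRS (summed rest score) and their difference
#' SDS = SSS - SRS, plus the percentage transform score / 68 * 100
#' (68 = 17 segments x maximal score 4).
#'
#' @param stress_scores,rest_scores score [segment_map17()]s.
#' @return object of class `score_summary` with fields `SSS`, `SRS`, `SDS`,
#'   `SSS_percent`, `SDS_percent`.
#' @export
summed_scores <- function(stress_scores, rest_scores) {
  for (m in list(stress_scores, rest_scores)) {
    if (!inherits(m, "segment_map17") || map_quantity(m) != "score")
      stop_invalid("summed_scores needs score maps")
  }
  sss <- sum(stress_scores); srs <- sum(rest_scores)
  structure(list(SSS = as.integer(sss), SRS = as.integer(srs),
                 SDS = as.integer(sss - srs),
                 SSS_percent = sss / 68 * 100,
                 SDS_percent = (sss - srs) / 68 * 100),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("SSS = %d (%.1f%%), SRS = %d, SDS = %d (%.1f%%)\n",
              x$SSS, x$SSS_percent, x$SRS, x$SDS, x$SDS_percent))
  invisible(x)
}

#' Classify a summed stress score
#'
#' Standard bands: SSS 0-3 normal (< 5% of the maximal myocardial score),
#' 4-7 mildly abnormal (5-10%), 8 and above moderately-to-severely
#' abnormal. The published bands leave SSS = 8 formally unassigned ("4-7"
#' then "> 8"); it is classified here as moderate/severe. Stricter
#' published conventions are selectable: `"hsiao"` calls any SSS > 0
#' abnormal; `"dorbala"` calls SSS% > 1% abnormal.
#'
#' @param summary a [summed_scores()] result.
#' @param convention `"standard"`, `"hsiao"` or `"dorbala"`.
#' @return for `"standard"`: one of `"normal"`, `"mildly_abnormal"`,
#'   `"moderate_severe"`; for the binary conventions: `"normal"` or
#'   `"abnormal"`.
#' @export
classify_sss <- function(summary, convention = "standard") {
  stopifnot(inherits(summary, "score_summary"))
  switch(convention,
    standard = if (summary$SSS <= 3) "normal"
               else if (summary$SSS <= 7) "mildly_abnormal"
               else "moderate_severe",
    hsiao = if (summary$SSS > 0) "abnormal" else "normal",
    dorbala = if (summary$SSS_percent > 1) "abnormal" else "normal",
    stop_validate("unknown scoring convention '%s'", convention))
}

#' Adjacency of the AHA 17 segments
#'
#' The standard model does not define segment adjacency; this package
#' ships an explicit adjacency graph: neighbours within each ring (1-6
#' basal, 7-12 mid, 13-16 apical, each cyclic), radial neighbours between
#' basal and mid rings (i and i+6), mid-to-apical radial neighbours
#' (13:7,8,12; 14:8,9; 15:9,10,11; 16:11,12) and the apex (17) adjacent to
#' all four apical segments.
#'
#' @return a symmetric 17 x 17 logical matrix.
#' @export
aha17_adjacency <- function() {
  A <- matrix(FALSE, 17, 17,
              dimnames = list(paste0("seg", 1:17), paste0("seg", 1:17)))
  link <- function(i, j) A[cbind(c(i, j), c(j, i))] <<- TRUE
  ring <- function(ids) for (k in seq_along(ids))
    link(ids[k], ids[k %% length(ids) + 1L])
  ring(1:6); ring(7:12); ring(13:16)
  for (i in 1:6) link(i, i + 6L)                       # basal - mid
  mid_ap <- list(`13` = c(7, 8, 12), `14` = c(8, 9),   # mid - apical
                 `15` = c(9, 10, 11), `16` = c(11, 12))
  for (ap in names(mid_ap)) for (m in mid_ap[[ap]])
    link(as.integer(ap), m)
  for (ap in 13:16) link(17L, ap)                      # apex
  A
}

#' Load an interpretation rule set
#'
#' Rule sets (tracer, stress-MBF cutoff, MFR cutoff, adjacency requirement,
#' SSS cutoff) are configuration, loaded from a YAML file; the shipped file
#' carries the published thresholds.
#'
#' @param name rule-set name (e.g. `"water-pacific"`) or a list already in
#'   rule-set form; `NULL` lists available names.
#' @param config_file YAML file path (default: shipped rule sets).
#' @return a list of class `interpretation_rules`.
#' @export
interpretation_rules <- function(name = NULL,
                                 config_file = system.file(
                                   "extdata", "rulesets.yaml",
                                   package = "mbfpet")) {
  if (is.list(name)) return(structure(name, class = "interpretation_rules"))
  cfg <- yaml::read_yaml(config_file)
  if (is.null(name)) return(names(cfg))
  rules <- cfg[[name]]
  if (is.null(rules))
    stop_validate("unknown rule set '%s'; available: %s", name,
                  paste(names(cfg), collapse = ", "))
  rules$name <- name
  structure(rules, class = "interpretation_rules")
}

#' Water-study abnormality by the adjacent-segment rule
#'
#' A stress (hyperaemic) MBF map is abnormal when at least two segments
#' that are adjacent on the 17-segment model both have stress MBF at or
#' below the cutoff (default 2.30 mL/min/g, inclusive).
#'
#' @param stress_map a `MBF_stress` [segment_map17()].
#' @param rules an [interpretation_rules()] (or name); only
#'   `stress_mbf_cutoff` is used.
#' @param adjacency adjacency matrix, default [aha17_adjacency()].
#' @return list with `abnormal` (logical), `segments` (integer ids of
#'   low-flow segments participating in an adjacent pair) and `cutoff`.
#' @export
classify_water_abnormal <- function(stress_map,
                                    rules = interpretation_rules("water-pacific"),
                                    adjacency = aha17_adjacency()) {
  stopifnot(inherits(stress_map, "segment_map17"))
  if (is.character(rules)) rules <- interpretation_rules(rules)
  cutoff <- rules$stress_mbf_cutoff
  low <- which(as.numeric(stress_map) <= cutoff)
  offending <- integer(0)
  if (length(low) >= 2L) {
    sub <- adjacency[low, low, drop = FALSE]
    hit <- rowSums(sub) > 0
    offending <- low[hit]
  }
  list(abnormal = length(offending) > 0, segments = offending,
       cutoff = cutoff)
}

#' Myocardial flow reserve map
#'
#' Element-wise ratio of stress to rest MBF. The global MFR is reported
#' both ways the literature uses: as the mean of the per-segment ratios
#' and as the ratio of the global (mean) stress and rest MBF values.
#'
#' @param map_stress,map_rest MBF [segment_map17()]s.
#' @return list with `map` (an MFR [segment_map17()], `NA` where rest MBF
#'   is zero), `global_mean_of_ratios` and `global_ratio_of_means`.
#' @export
mfr <- function(map_stress, map_rest) {
  stopifnot(inherits(map_stress, "segment_map17"),
            inherits(map_rest, "segment_map17"))
  s <- as.numeric(map_stress); r <- as.numeric(map_rest)
  ratio <- ifelse(r > 0, s / r, NA_real_)
  m <- segment_map17(ratio, "MFR")
  list(map = m,
       global_mean_of_ratios = mean(ratio, na.rm = TRUE),
       global_ratio_of_means = if (mean(r) > 0) mean(s) / mean(r)
                               else NA_real_,
       undefined_segments = which(!(r > 0)))
}

# Standard AHA coronary-territory assignment (configurable)
.default_territories <- list(
  LAD = c(1, 2, 7, 8, 13, 14, 17),
  RCA = c(3, 4, 9, 10, 15),
  LCX = c(5, 6, 11, 12, 16))

#' Coronary-territory means of a segment map
#'
#' @param map a [segment_map17()].
#' @param territories named list of segment-id vectors; default standard
#'   LAD/RCA/LCX assignment (configurable to the patient's own coronary
#'   distribution).
#' @return named numeric: one mean per territory plus `global` (mean of
#'   all 17 segments).
#' @export
territory_means <- function(map, territories = .default_territories) {
  stopifnot(inherits(map, "segment_map17"))
  v <- as.numeric(map)
  out <- vapply(territories, function(ids) mean(v[ids]), numeric(1))
  c(out, global = mean(v))
}

#' Rate-pressure-product correction of resting MBF
#'
#' Resting MBF scales with cardiac workload; when resting heart rate or
#' blood pressure is elevated it is normalized to a reference rate-pressure
#' product: `MBF_corrected = MBF * reference_RPP / (HR * SBP)`. The
#' reference RPP is a convention (not fixed by guidelines); the default is
#' 10,000.
#'
#' @param rest_MBF resting MBF (scalar or vector), mL/g/min.
#' @param heart_rate beats per minute (> 0).
#' @param systolic_BP mmHg (> 0).
#' @param reference_RPP reference rate-pressure product, default 1e4.
#' @return corrected resting MBF.
#' @export
rpp_correct_rest_mbf <- function(rest_MBF, heart_rate, systolic_BP,
                                 reference_RPP = 10000) {
  assert_scalar_num(heart_rate, "heart_rate", 0, strict_lower = TRUE)
  assert_scalar_num(systolic_BP, "systolic_BP", 0, strict_lower = TRUE)
  assert_scalar_num(reference_RPP, "reference_RPP", 0, strict_lower = TRUE)
  rest_MBF * reference_RPP / (heart_rate * systolic_BP)
}

#' Classify the LVEF reserve
#'
#' The LVEF reserve is the stress-minus-rest change in left-ventricular
#' ejection fraction (percentage units). A reserve above +5 units has a
#' very high negative predictive value for severe CAD; below -5 units, a
#' very high positive predictive value. Any negative reserve is
#' additionally flagged as most probably related to abnormal perfusion.
#'
#' @param LVEF_rest,LVEF_stress ejection fractions in percent, 0-100.
#' @return list with `reserve` (percentage units), `category` (one of
#'   `"severe_cad_unlikely"`, `"severe_cad_likely"`, `"indeterminate"`)
#'   and `negative_reserve` flag.
#' @export
lvef_reserve_classify <- function(LVEF_rest, LVEF_stress) {
  assert_scalar_num(LVEF_rest, "LVEF_rest", 0, 100)
  assert_scalar_num(LVEF_stress, "LVEF_stress", 0, 100)
  reserve <- LVEF_stress - LVEF_rest
  category <- if (reserve > 5) "severe_cad_unlikely"
              else if (reserve < -5) "severe_cad_likely"
              else "indeterminate"
  list(reserve = reserve, category = category,
       negative_reserve = reserve < 0)
}
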