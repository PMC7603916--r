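# Structured quantitative reporting: assembles the standard report scheme
# (administrative, patient, study, image/scoring, quantitative, gated,
# conclusion) from a results bundle, with machine-readable (JSON) and
# human-readable (Markdown) renderings.

seg_as_list <- function(map) as.list(stats::setNames(as.numeric(map),
                                                     names(map)))

#' Build a structured quantitative perfusion report
#'
#' Assembles a report following the standard quantitative PET reporting
#' scheme. The quantitative block (rest MBF, stress MBF, MFR, per territory
#' and global) is mandatory; administrative, patient, scoring and gated
#' sections are included when supplied. For water studies the
#' semi-quantitative score section is omitted (scores are not meaningful
#' without uptake images); supplying scores for water triggers a warning
#' and omission.
#'
#' @param results a list with elements:
#'   `study` (list: at least `tracer`; optionally `injected_activity_MBq`,
#'   `stress_agent`, `acquisition`, `haemodynamics` with `heart_rate` and
#'   `systolic_BP`),
#'   `quantitative` (required: list with `rest` and `stress`
#'   MBF [segment_map17()]s, optional `rules` rule-set name),
#'   and optionally `administrative`, `patient`,
#'   `scores` (list with `stress`/`rest` score maps) and
#'   `gated` (list with `LVEF_rest`, `LVEF_stress`).
#' @param rpp_correct apply rate-pressure-product correction to resting
#'   MBF when haemodynamics are supplied (default FALSE).
#' @return object of class `mbf_report` (a nested plain list, JSON-ready).
#' @export
build_report <- function(results, rpp_correct = FALSE) {
  q <- results$quantitative
  if (is.null(q) || is.null(q$rest) || is.null(q$stress))
    stop_validate(
      "results must contain a quantitative block with rest and stress MBF")
  stopifnot(inherits(q$rest, "segment_map17"),
            inherits(q$stress, "segment_map17"))
  tracer_name <- results$study$tracer
  if (is.null(tracer_name)) stop_validate("study$tracer is required")

  rest_map <- q$rest
  rpp_note <- NULL
  hemo <- results$study$haemodynamics
  if (rpp_correct) {
    if (is.null(hemo$heart_rate) || is.null(hemo$systolic_BP))
      stop_validate("RPP correction needs heart_rate and systolic_BP")
    corrected <- rpp_correct_rest_mbf(as.numeric(rest_map),
                                      hemo$heart_rate, hemo$systolic_BP)
    rest_map <- segment_map17(corrected, "MBF_rest")
    rpp_note <- sprintf("resting MBF corrected to RPP 10000 (HR %g, SBP %g)",
                        hemo$heart_rate, hemo$systolic_BP)
  }

  flow <- mfr(q$stress, rest_map)
  rules_name <- if (!is.null(q$rules)) q$rules
                else if (tracer_name == "water") "water-pacific" else NULL
  interp <- NULL
  if (!is.null(rules_name)) {
    rules <- interpretation_rules(rules_name)
    below <- which(as.numeric(q$stress) <= rules$stress_mbf_cutoff)
    interp <- list(rule_set = rules_name,
                   stress_mbf_cutoff = rules$stress_mbf_cutoff,
                   mfr_cutoff = rules$mfr_cutoff,
                   segments_below_cutoff = as.list(below))
    if (identical(tracer_name, "water")) {
      cls <- classify_water_abnormal(q$stress, rules)
      interp$abnormal <- cls$abnormal
      interp$offending_segments <- as.list(cls$segments)
    } else {
      interp$abnormal <- length(below) > 0
    }
  }

  scores_section <- NULL
  if (!is.null(results$scores)) {
    if (identical(tracer_name, "water")) {
      warning("semi-quantitative scores are omitted for water studies")
    } else {
      ss <- summed_scores(results$scores$stress, results$scores$rest)
      scores_section <- list(
        stress = seg_as_list(results$scores$stress),
        rest = seg_as_list(results$scores$rest),
        SSS = ss$SSS, SRS = ss$SRS, SDS = ss$SDS,
        SSS_percent = ss$SSS_percent, SDS_percent = ss$SDS_percent,
        classification = classify_sss(ss))
    }
  }

  gated_section <- NULL
  if (!is.null(results$gated)) {
    g <- results$gated
    lv <- lvef_reserve_classify(g$LVEF_rest, g$LVEF_stress)
    gated_section <- list(LVEF_rest = g$LVEF_rest,
                          LVEF_stress = g$LVEF_stress,
                          LVEF_reserve = lv$reserve,
                          category = lv$category,
                          negative_reserve = lv$negative_reserve)
  }

  dose <- NULL
  act <- results$study$injected_activity_MBq
  if (!is.null(act) && is.finite(tracer_spec(tracer_name)$
                                 dose_coefficient_mSv_per_GBq))
    dose <- effective_dose(unlist(act), tracer_name)

  report <- list(
    administrative = results$administrative,
    patient = results$patient,
    study = c(results$study,
              if (!is.null(dose)) list(effective_dose_mSv = dose)),
    image_reporting = scores_section,
    quantitative = list(
      rest_MBF = seg_as_list(rest_map),
      stress_MBF = seg_as_list(q$stress),
      MFR = seg_as_list(flow$map),
      territory_rest = as.list(territory_means(rest_map)),
      territory_stress = as.list(territory_means(q$stress)),
      territory_MFR = as.list(territory_means(flow$map)),
      global_MFR_mean_of_ratios = flow$global_mean_of_ratios,
      global_MFR_ratio_of_means = flow$global_ratio_of_means,
      rpp_correction = rpp_note,
      interpretation = interp),
    gated = gated_section,
    conclusion = results$conclusion)
  report <- report[!vapply(report, is.null, TRUE)]
  structure(report, class = "mbf_report")
}

#' Serialize a report to JSON text
#'
#' @param report an `mbf_report` (or the plain list parsed back from one).
#' @return a JSON string.
#' @export
report_to_json <- function(report) {
  # canonicalize through a parse cycle so freshly built and re-parsed
  # reports serialize to byte-identical text (lossless round trips)
  canon <- jsonlite::parse_json(
    jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                     null = "null"))
  jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' Parse a report back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return an `mbf_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io("report file not found: %s", path)
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "mbf_report")
}

#' Render a report as Markdown
#'
#' @param report an `mbf_report`.
#' @return a character vector of Markdown lines.
#' @export
render_report_markdown <- function(report) {
  fmt_num <- function(x) formatC(as.numeric(x), format = "g", digits = 4)
  lines <- c("# Quantitative myocardial perfusion PET report", "")
  kv_block <- function(title, x) {
    if (is.null(x) || length(x) == 0L) return(character(0))
    c(sprintf("## %s", title),
      vapply(names(x), function(nm) {
        val <- x[[nm]]
        val <- if (is.list(val) || length(val) > 1L)
          paste(unlist(val), collapse = ", ") else format(val)
        sprintf("- %s: %s", nm, val)
      }, character(1)), "")
  }
  lines <- c(lines,
             kv_block("Administrative data", report$administrative),
             kv_block("Patient", report$patient),
             kv_block("Study", report$study))
  if (!is.null(report$image_reporting)) {
    ir <- report$image_reporting
    lines <- c(lines, "## Image reporting (semi-quantitative)",
               sprintf("- SSS = %s (%s%%), SRS = %s, SDS = %s",
                       ir$SSS, fmt_num(ir$SSS_percent), ir$SRS, ir$SDS),
               sprintf("- Classification: %s", ir$classification), "")
  }
  q <- report$quantitative
  seg_table <- function(name, vals)
    sprintf("| %s | %s |", name,
            paste(fmt_num(unlist(vals)), collapse = " | "))
  lines <- c(lines, "## Quantitative analysis",
             paste0("| quantity | ", paste(paste0("s", 1:17),
                                           collapse = " | "), " |"),
             paste0("|", paste(rep("---", 18), collapse = "|"), "|"),
             seg_table("rest MBF", q$rest_MBF),
             seg_table("stress MBF", q$stress_MBF),
             seg_table("MFR", q$MFR), "",
             sprintf("- Territory rest MBF: %s",
                     paste(sprintf("%s %.3g", names(q$territory_rest),
                                   unlist(q$territory_rest)),
                           collapse = ", ")),
             sprintf("- Territory stress MBF: %s",
                     paste(sprintf("%s %.3g", names(q$territory_stress),
                                   unlist(q$territory_stress)),
                           collapse = ", ")),
             sprintf("- Global MFR: %.3g (mean of ratios), %.3g (ratio of means)",
                     q$global_MFR_mean_of_ratios,
                     q$global_MFR_ratio_of_means))
  if (!is.null(q$rpp_correction))
    lines <- c(lines, sprintf("- %s", q$rpp_correction))
  if (!is.null(q$interpretation)) {
    it <- q$interpretation
    lines <- c(lines,
               sprintf("- Interpretation (%s, stress MBF cutoff %.3g): %s",
                       it$rule_set, it$stress_mbf_cutoff,
                       if (isTRUE(it$abnormal)) "ABNORMAL" else "normal"))
    if (length(it$offending_segments))
      lines <- c(lines, sprintf("- Offending segments: %s",
                                paste(unlist(it$offending_segments),
                                      collapse = ", ")))
  }
  lines <- c(lines, "")
  if (!is.null(report$gated)) {
    g <- report$gated
    lines <- c(lines, "## Gated PET",
               sprintf("- LVEF rest %s%%, stress %s%%, reserve %s units: %s",
                       g$LVEF_rest, g$LVEF_stress, g$LVEF_reserve,
                       g$category), "")
  }
  lines <- c(lines, "## Conclusion",
             if (!is.null(report$conclusion)) as.character(report$conclusion)
             else "(to be completed by the reporting physician)")
  lines
}

#' Write a report to disk
#'
#' Writes `report.json` (machine-readable, losslessly re-parseable) and
#' `report.md` (human-readable) into a directory.
#'
#' @param report an `mbf_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io("cannot create directory %s", dir)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  writeLines(report_to_json(report), json_path)
  writeLines(render_report_markdown(report), md_path)
  invisible(c(json = json_path, md = md_path))
}
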