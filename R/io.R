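#' Read a judge panel from CSV
#'
#' Expects a UTF-8 CSV with header \code{judge_id,L,H} and an optional
#' \code{suggested} column; values are percents on \code{[0, scale_max]}
#' with "." as the decimal point. Blank suggested cells are allowed;
#' missing L or H is an error.
#'
#' @param path Path to the CSV file.
#' @param scale_max Maximum obtainable score, default 100.
#' @param label Exam identifier; defaults to the file name.
#' @param drop_inconsistent Passed to \code{\link{judge_panel}}.
#' @return A \code{\link{judge_panel}} carrying the input file's MD5 digest
#'   as attribute \code{"input_digest"} for audit.
#' @export
read_panel_csv <- function(path, scale_max = 100, label = basename(path),
                           drop_inconsistent = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("judge_id", "L", "H")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (field in c("L", "H", intersect("suggested", names(df)))) {
    v <- suppressWarnings(as.numeric(df[[field]]))
    bad_parse <- which(is.na(v) & !(is.na(df[[field]]) | df[[field]] == ""))
    if (length(bad_parse) > 0) {
      stop(sprintf("row %d: non-numeric %s value '%s'",
                   bad_parse[1], field, df[[field]][bad_parse[1]]),
           call. = FALSE)
    }
    bad_range <- which(!is.na(v) & (v < 0 | v > scale_max))
    if (length(bad_range) > 0) {
      stop(sprintf("row %d: %s = %g outside [0, %g]",
                   bad_range[1], field, v[bad_range[1]], scale_max),
           call. = FALSE)
    }
    df[[field]] <- v
  }
  panel <- judge_panel(df, scale_max = scale_max, label = label,
                       drop_inconsistent = drop_inconsistent)
  attr(panel, "input_digest") <- unname(tools::md5sum(path))
  panel
}

round_half_up <- function(x, digits) {
  # report rounding: ties away from zero, matching hand-rounded tables
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a cut-score result as a plain-text report
#'
#' The report mirrors how results of this method are narrated: Z from the
#' interface equation, the cut-score from both anchors, the confidence
#' level, the one-tailed p, the 95\% CI with its midpoint, and the plain
#' L/H midpoint — the last two deliberately side by side, because the CI
#' midpoint is generally not the cut-score (the CI combines two different
#' variances). Z is shown to 3 decimals, scores to 2, percentages to 1.
#'
#' @param result A \code{\link{compute_cut_score}} result.
#' @param baselines Optional named list with elements \code{angoff} and/or
#'   \code{suggested} (percent cut-scores) appended for comparison.
#' @return A character vector of report lines.
#' @export
format_report <- function(result, baselines = NULL) {
  stopifnot(inherits(result, "cut_score_result"))
  s <- result$summary
  f2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  lines <- c(
    "Anchored cut-score report",
    "=========================",
    if (nzchar(s$label)) paste0("exam: ", s$label),
    sprintf("judges: n = %d%s (SE method: %s)", s$n,
            if (length(s$trimmed) > 0)
              sprintf(", trimmed: %s", paste(s$trimmed, collapse = ", "))
            else "", s$se_method),
    sprintf("clear-fail anchor L: mean %s, SE %s", f2(s$mean_L), f2(s$se_L)),
    sprintf("clear-pass anchor H: mean %s, SE %s", f2(s$mean_H), f2(s$se_H)),
    sprintf("Z = %s", formatC(round_half_up(result$z, 3), format = "f", digits = 3)),
    sprintf("cut-score = %s (from L: %s; from H: %s)",
            f2(result$cut_score), f2(result$cut_score_from_L),
            f2(result$cut_score_from_H)),
    sprintf("confidence = %s%%",
            formatC(round_half_up(100 * result$confidence, 1),
                    format = "f", digits = 1)),
    sprintf("one-tailed p = %s",
            formatC(round_half_up(result$p_one_tailed, 2),
                    format = "f", digits = 2))
  )
  if (isTRUE(result$ci_applicable)) {
    lines <- c(lines,
      sprintf("95%% CI = (%s, %s); CI midpoint = %s",
              f2(result$ci_low), f2(result$ci_high),
              f2((result$ci_low + result$ci_high) / 2)))
  } else {
    lines <- c(lines, "95% CI: not applicable (|Z| >= 1.96)")
  }
  lines <- c(lines,
    sprintf("L/H midpoint = %s", f2((s$mean_L + s$mean_H) / 2)))
  if (result$anchors_inverted) {
    lines <- c(lines, "FLAG: anchors inverted (mean H < mean L)")
  }
  if (result$degenerate) {
    lines <- c(lines, "FLAG: degenerate panel (zero standard errors)")
  }
  if (!is.null(baselines)) {
    lines <- c(lines, "baselines:")
    if (!is.null(baselines$angoff)) {
      lines <- c(lines, sprintf("  classic Angoff = %s", f2(baselines$angoff)))
    }
    if (!is.null(baselines$suggested)) {
      lines <- c(lines,
                 sprintf("  direct suggested mean = %s", f2(baselines$suggested)))
    }
  }
  lines
}

#' Serialise a cut-score result
#'
#' Writes either the plain-text report of \code{\link{format_report}} or a
#' machine-readable JSON document containing the full-precision result
#' fields, the panel summary, flags, and provenance (input digest, trimmed
#' judges, seed) when available. Output is byte-deterministic for fixed
#' inputs.
#'
#' @param result A \code{\link{compute_cut_score}} result.
#' @param path Output file; when \code{NULL} the rendered report is
#'   returned invisibly as a character string.
#' @param format \code{"text"} or \code{"json"}.
#' @param baselines Optional baselines list, as in \code{\link{format_report}}.
#' @param provenance Optional named list (e.g. input digest, seed) embedded
#'   in the JSON output.
#' @return Invisibly, the rendered report as a single string.
#' @export
write_report <- function(result, path = NULL, format = c("text", "json"),
                         baselines = NULL, provenance = NULL) {
  stopifnot(inherits(result, "cut_score_result"))
  format <- match.arg(format)
  if (format == "text") {
    out <- paste(format_report(result, baselines), collapse = "\n")
  } else {
    payload <- result_to_list(result)
    if (!is.null(baselines)) payload$baselines <- baselines
    if (!is.null(provenance)) payload$provenance <- provenance
    out <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                            pretty = TRUE, na = "null")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(as.character(out))
}

result_to_list <- function(result) {
  s <- result$summary
  list(
    z = result$z,
    cut_score = result$cut_score,
    cut_score_from_L = result$cut_score_from_L,
    cut_score_from_H = result$cut_score_from_H,
    confidence = result$confidence,
    p_one_tailed = result$p_one_tailed,
    ci_low = result$ci_low, ci_high = result$ci_high,
    ci_applicable = result$ci_applicable,
    anchors_inverted = result$anchors_inverted,
    degenerate = result$degenerate,
    summary = list(
      n = s$n, mean_L = s$mean_L, sd_L = s$sd_L, se_L = s$se_L,
      mean_H = s$mean_H, sd_H = s$sd_H, se_H = s$se_H,
      mean_suggested = s$mean_suggested, sd_suggested = s$sd_suggested,
      se_suggested = s$se_suggested,
      scale_max = s$scale_max, label = s$label,
      trimmed = as.list(s$trimmed), se_method = s$se_method
    )
  )
}

#' Rebuild a cut-score result from its JSON serialisation
#'
#' Inverse of \code{\link{write_report}} with \code{format = "json"};
#' round-trips every numeric field exactly.
#'
#' @param path Path to a JSON report.
#' @return A \code{"cut_score_result"}.
#' @export
read_report_json <- function(path) {
  j <- jsonlite::read_json(path)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  s <- j$summary
  summary <- panel_summary(
    n = s$n, mean_L = num(s$mean_L), se_L = num(s$se_L),
    mean_H = num(s$mean_H), se_H = num(s$se_H),
    sd_L = num(s$sd_L), sd_H = num(s$sd_H),
    mean_suggested = num(s$mean_suggested),
    sd_suggested = num(s$sd_suggested), se_suggested = num(s$se_suggested),
    scale_max = num(s$scale_max), label = as.character(s$label),
    trimmed = as.character(unlist(s$trimmed)),
    se_method = as.character(s$se_method)
  )
  structure(
    list(z = num(j$z), cut_score = num(j$cut_score),
         cut_score_from_L = num(j$cut_score_from_L),
         cut_score_from_H = num(j$cut_score_from_H),
         confidence = num(j$confidence), p_one_tailed = num(j$p_one_tailed),
         ci_low = num(j$ci_low), ci_high = num(j$ci_high),
         ci_applicable = isTRUE(j$ci_applicable),
         anchors_inverted = isTRUE(j$anchors_inverted),
         degenerate = isTRUE(j$degenerate),
         summary = summary),
    class = "cut_score_result"
  )
}
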