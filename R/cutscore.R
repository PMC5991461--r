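#' Solve the anchor-interface Z equation
#'
#' The cut-score is defined as the point lying the same number of standard
#' errors above the mean clear-fail anchor as below the mean clear-pass
#' anchor. That common multiple Z solves
#' \deqn{Z \cdot SE_L + Z \cdot SE_H = \bar H - \bar L,}
#' i.e. \eqn{Z = (\bar H - \bar L) / (SE_L + SE_H)}.
#'
#' Z is negative when the anchors are inverted (mean H below mean L) and 0
#' when the means coincide. A panel with both SEs zero and distinct means
#' has no finite Z and is rejected as degenerate.
#'
#' @param summary A \code{\link{panel_summary}}.
#' @return The Z statistic at full floating precision.
#' @export
solve_z <- function(summary) {
  stopifnot(inherits(summary, "panel_summary"))
  denom <- summary$se_L + summary$se_H
  num <- summary$mean_H - summary$mean_L
  if (denom == 0) {
    if (num == 0) return(structure(0, degenerate = TRUE))
    stop("degenerate panel: zero standard errors with distinct anchor means",
         call. = FALSE)
  }
  num / denom
}

#' Confidence attached to a cut-score placement
#'
#' The confidence that the cut-score correctly separates the two anchor
#' distributions is the normal probability mass lying between the two
#' means at the interface point: \eqn{\max(0,\, 2\Phi(Z) - 1)}. This
#' reproduces the familiar 68\% / 95\% / 99.7\% levels at Z = 1, 2, 3.
#' Negative Z (inverted anchors) yields 0.
#'
#' @param z Z statistic from \code{\link{solve_z}}.
#' @return A proportion in [0, 1].
#' @export
confidence_level <- function(z) {
  stopifnot(is.finite(z))
  max(0, 2 * stats::pnorm(z) - 1)
}

#' One-tailed p-value of the Z statistic
#'
#' Returns \eqn{1 - \Phi(Z)}: the upper-tail standard normal probability,
#' read off a Z-table in classical practice.
#'
#' @param z Z statistic.
#' @return A proportion in [0, 1].
#' @export
one_tailed_p <- function(z) {
  stopifnot(is.finite(z))
  stats::pnorm(z, lower.tail = FALSE)
}

#' 95\% confidence interval of the cut-score
#'
#' Built from the two independent anchor variances: any score below
#' \eqn{\bar H - 1.96\,SE_H} falls below every plausible clear-pass anchor,
#' and any score above \eqn{\bar L + 1.96\,SE_L} lies above every plausible
#' clear-fail anchor, so the interval runs from the former (lower bound,
#' derived from H) to the latter (upper bound, derived from L). The
#' construction only makes sense while the two bands overlap, i.e. when
#' |Z| < 1.96; otherwise it self-inverts and the interval is reported as
#' not applicable rather than replaced by some other construction.
#'
#' @param summary A \code{\link{panel_summary}}.
#' @param z The Z statistic (computed from \code{summary} if omitted).
#' @return A list with \code{low}, \code{high} and \code{applicable};
#'   \code{low}/\code{high} are \code{NA} when not applicable.
#' @export
ci_95 <- function(summary, z = solve_z(summary)) {
  stopifnot(inherits(summary, "panel_summary"))
  if (abs(z) >= 1.96) {
    return(list(low = NA_real_, high = NA_real_, applicable = FALSE))
  }
  list(low = summary$mean_H - 1.96 * summary$se_H,
       high = summary$mean_L + 1.96 * summary$se_L,
       applicable = TRUE)
}

#' Compute the anchored cut-score and its inferential report
#'
#' Runs the whole method on a panel summary: solves for Z, places the
#' cut-score from each anchor (\eqn{\bar L + Z\,SE_L} and
#' \eqn{\bar H - Z\,SE_H}, identical by construction), and attaches the
#' confidence level, one-tailed p-value and the 95\% CI with its
#' applicability flag.
#'
#' Degenerate panels (both SEs zero) with coinciding means return the common
#' mean as the cut-score with confidence 0 and \code{degenerate = TRUE};
#' with distinct means they raise an error. A cut-score falling outside
#' \code{[0, scale_max]} (possible only with inverted anchors and unequal
#' SEs) is clamped with a warning.
#'
#' @param summary A \code{\link{panel_summary}}, or a
#'   \code{\link{judge_panel}} (summarised with analytic SEs first).
#' @return A \code{"cut_score_result"} list with elements \code{z},
#'   \code{cut_score}, \code{cut_score_from_L}, \code{cut_score_from_H},
#'   \code{confidence}, \code{p_one_tailed}, \code{ci_low}, \code{ci_high},
#'   \code{ci_applicable}, \code{anchors_inverted}, \code{degenerate} and
#'   \code{summary}.
#' @examples
#' s <- panel_summary(n = 17, mean_L = 62.65, se_L = 5.609,
#'                    mean_H = 65.35, se_H = 3.193)
#' res <- compute_cut_score(s)
#' round(res$z, 3)          # 0.307
#' round(res$cut_score, 2)  # 64.37
#' @export
compute_cut_score <- function(summary) {
  if (inherits(summary, "judge_panel")) summary <- summarize_panel(summary)
  stopifnot(inherits(summary, "panel_summary"))

  z <- solve_z(summary)
  degenerate <- isTRUE(attr(z, "degenerate"))
  z <- as.numeric(z)

  cs_L <- summary$mean_L + z * summary$se_L
  cs_H <- summary$mean_H - z * summary$se_H
  cs <- (cs_L + cs_H) / 2

  if (cs < 0 || cs > summary$scale_max) {
    warning(sprintf("cut-score %.4f outside [0, %g]; clamped",
                    cs, summary$scale_max), call. = FALSE)
    cs <- min(max(cs, 0), summary$scale_max)
  }

  ci <- ci_95(summary, z)
  structure(
    list(z = z,
         cut_score = cs,
         cut_score_from_L = cs_L,
         cut_score_from_H = cs_H,
         confidence = if (degenerate) 0 else confidence_level(z),
         p_one_tailed = one_tailed_p(z),
         ci_low = ci$low, ci_high = ci$high, ci_applicable = ci$applicable,
         anchors_inverted = summary$mean_H < summary$mean_L,
         degenerate = degenerate,
         summary = summary),
    class = "cut_score_result"
  )
}

#' @export
print.cut_score_result <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Classify an examinee score against a cut-score
#'
#' Every score at or above the cut-score passes; every score below it
#' fails. When the 95\% CI is applicable, scores inside it are additionally
#' annotated \code{within_ci = TRUE} as audit information — this never
#' creates a third outcome.
#'
#' @param score Examinee score in \code{[0, scale_max]}.
#' @param result A \code{\link{compute_cut_score}} result.
#' @return A list with \code{category} (\code{"pass"} or \code{"fail"}) and
#'   logical \code{within_ci}.
#' @export
classify_examinee <- function(score, result) {
  stopifnot(inherits(result, "cut_score_result"))
  scale_max <- result$summary$scale_max
  if (!is.finite(score) || score < 0 || score > scale_max) {
    stop(sprintf("score %s outside [0, %g]", score, scale_max), call. = FALSE)
  }
  list(
    category = if (score >= result$cut_score) "pass" else "fail",
    within_ci = isTRUE(result$ci_applicable) &&
      score >= result$ci_low && score <= result$ci_high
  )
}
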