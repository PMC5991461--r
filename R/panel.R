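#' Construct a judge panel
#'
#' A judge panel holds one row per judge with the two anchor scores the
#' method consumes: \code{L}, the highest whole-exam score that still
#' indicates the examinee is clearly incompetent (the clear-fail anchor),
#' and \code{H}, the lowest score indicating the examinee is clearly
#' competent (the clear-pass anchor). Judges may additionally supply a
#' directly suggested cut-score, used only by the
#' \code{\link{direct_suggested_mean}} baseline.
#'
#' Judges whose anchors are internally inconsistent (\code{L > H}) are
#' retained with a warning by default: the two anchor questions are asked
#' independently and dropping such judges silently would bias the panel.
#' Set \code{drop_inconsistent = TRUE} to exclude them instead.
#'
#' @param ratings A data frame with columns \code{judge_id}, \code{L},
#'   \code{H} and optionally \code{suggested}. Scores are percents on
#'   \code{[0, scale_max]}; \code{suggested} may contain \code{NA}.
#' @param scale_max Maximum obtainable score, default 100.
#' @param label Free-text exam identifier carried through to reports.
#' @param drop_inconsistent Drop judges with \code{L > H}? Default
#'   \code{FALSE} (retain with a warning).
#' @return An object of class \code{"judge_panel"}.
#' @examples
#' p <- judge_panel(data.frame(judge_id = c("a", "b"), L = c(60, 70),
#'                             H = c(72, 78)))
#' summarize_panel(p)
#' @export
judge_panel <- function(ratings, scale_max = 100, label = "",
                        drop_inconsistent = FALSE) {
  stopifnot(is.data.frame(ratings))
  required <- c("judge_id", "L", "H")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"suggested" %in% names(ratings)) {
    ratings$suggested <- rep(NA_real_, nrow(ratings))
  }
  ratings <- ratings[, c("judge_id", "L", "H", "suggested")]
  ratings$judge_id <- as.character(ratings$judge_id)
  ratings$L <- as.numeric(ratings$L)
  ratings$H <- as.numeric(ratings$H)
  ratings$suggested <- as.numeric(ratings$suggested)

  if (anyDuplicated(ratings$judge_id)) {
    dup <- unique(ratings$judge_id[duplicated(ratings$judge_id)])
    stop("duplicate judge_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (field in c("L", "H")) {
    v <- ratings[[field]]
    bad <- which(is.na(v) | v < 0 | v > scale_max)
    if (length(bad) > 0) {
      stop(sprintf("judge '%s': %s = %s outside [0, %g] (or missing)",
                   ratings$judge_id[bad[1]], field, v[bad[1]], scale_max),
           call. = FALSE)
    }
  }
  sv <- ratings$suggested
  bad <- which(!is.na(sv) & (sv < 0 | sv > scale_max))
  if (length(bad) > 0) {
    stop(sprintf("judge '%s': suggested = %s outside [0, %g]",
                 ratings$judge_id[bad[1]], sv[bad[1]], scale_max),
         call. = FALSE)
  }

  inconsistent <- ratings$L > ratings$H
  if (any(inconsistent)) {
    ids <- ratings$judge_id[inconsistent]
    if (drop_inconsistent) {
      warning("dropping ", length(ids), " judge(s) with L > H: ",
              paste(ids, collapse = ", "), call. = FALSE)
      ratings <- ratings[!inconsistent, , drop = FALSE]
    } else {
      warning("retaining ", length(ids), " judge(s) with L > H: ",
              paste(ids, collapse = ", "), call. = FALSE)
    }
  }
  rownames(ratings) <- NULL

  structure(
    list(ratings = ratings, scale_max = scale_max, label = label,
         trimmed = character(0)),
    class = "judge_panel"
  )
}

#' @export
print.judge_panel <- function(x, ...) {
  cat("Judge panel", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "with", nrow(x$ratings), "judges (scale 0-", x$scale_max, ")\n", sep = " ")
  if (length(x$trimmed) > 0) {
    cat("  trimmed judges:", paste(x$trimmed, collapse = ", "), "\n")
  }
  print(x$ratings, ...)
  invisible(x)
}

#' @export
nobs.judge_panel <- function(object, ...) nrow(object$ratings)

#' Summary statistics of a judge panel
#'
#' Computes the panel-level statistics the cut-score method consumes: the
#' number of judges n, and for each of L, H (and suggested, when every judge
#' supplied one) the mean, the sample standard deviation (n-1 denominator)
#' and the standard error of the mean SD/sqrt(n). With
#' \code{se_method = "bootstrap"}, the SEs of L and H are instead estimated
#' by \code{\link{bootstrap_se}}.
#'
#' @param panel A \code{\link{judge_panel}} with at least 2 judges.
#' @param se_method \code{"analytic"} (SD/sqrt(n), default) or
#'   \code{"bootstrap"}.
#' @param replicates Bootstrap replicates (used when
#'   \code{se_method = "bootstrap"}), default 2000.
#' @param seed Integer seed, required for the bootstrap.
#' @return A \code{"panel_summary"} object; see \code{\link{panel_summary}}.
#' @export
summarize_panel <- function(panel, se_method = c("analytic", "bootstrap"),
                            replicates = 2000, seed = NULL) {
  stopifnot(inherits(panel, "judge_panel"))
  se_method <- match.arg(se_method)
  r <- panel$ratings
  n <- nrow(r)
  if (n < 2) stop("insufficient panel: need at least 2 judges", call. = FALSE)

  stat3 <- function(v) {
    s <- stats::sd(v)
    c(mean = mean(v), sd = s, se = s / sqrt(length(v)))
  }
  sl <- stat3(r$L)
  sh <- stat3(r$H)

  if (se_method == "bootstrap") {
    if (is.null(seed)) stop("bootstrap SEs require an explicit seed", call. = FALSE)
    sl["se"] <- bootstrap_se(r$L, replicates = replicates, seed = seed)
    sh["se"] <- bootstrap_se(r$H, replicates = replicates, seed = seed + 1L)
  }

  has_suggested <- all(!is.na(r$suggested))
  ss <- if (has_suggested) stat3(r$suggested) else c(mean = NA_real_, sd = NA_real_, se = NA_real_)

  panel_summary(
    n = n,
    mean_L = sl[["mean"]], sd_L = sl[["sd"]], se_L = sl[["se"]],
    mean_H = sh[["mean"]], sd_H = sh[["sd"]], se_H = sh[["se"]],
    mean_suggested = ss[["mean"]], sd_suggested = ss[["sd"]],
    se_suggested = ss[["se"]],
    scale_max = panel$scale_max, label = panel$label,
    trimmed = panel$trimmed, se_method = se_method
  )
}

#' Construct a panel summary directly from statistics
#'
#' The cut-score engine operates on summary statistics only, so a summary
#' may be built directly from published values (e.g. a printed descriptive
#' table) without access to the raw judge scores. When SEs are taken from a
#' printed table they are used as given, not re-derived from rounded SDs.
#'
#' @param n Number of judges.
#' @param mean_L,se_L Mean and standard error of the clear-fail anchor (percent).
#' @param mean_H,se_H Mean and standard error of the clear-pass anchor (percent).
#' @param sd_L,sd_H Sample SDs (optional; \code{NA} when only SEs are known).
#' @param mean_suggested,sd_suggested,se_suggested Statistics of directly
#'   suggested cut-scores, if collected.
#' @param scale_max Maximum obtainable score, default 100.
#' @param label Exam identifier.
#' @param trimmed Character vector of trimmed judge ids (provenance).
#' @param se_method \code{"analytic"} or \code{"bootstrap"} (provenance label).
#' @return A \code{"panel_summary"} object.
#' @examples
#' # A pilot panel of 17 judges, from its printed descriptive table:
#' s <- panel_summary(n = 17, mean_L = 62.65, se_L = 5.609,
#'                    mean_H = 65.35, se_H = 3.193)
#' compute_cut_score(s)
#' @export
panel_summary <- function(n, mean_L, se_L, mean_H, se_H,
                          sd_L = NA_real_, sd_H = NA_real_,
                          mean_suggested = NA_real_, sd_suggested = NA_real_,
                          se_suggested = NA_real_,
                          scale_max = 100, label = "",
                          trimmed = character(0),
                          se_method = "analytic") {
  stopifnot(n >= 2, se_L >= 0, se_H >= 0)
  structure(
    list(n = as.integer(n),
         mean_L = mean_L, sd_L = sd_L, se_L = se_L,
         mean_H = mean_H, sd_H = sd_H, se_H = se_H,
         mean_suggested = mean_suggested, sd_suggested = sd_suggested,
         se_suggested = se_suggested,
         scale_max = scale_max, label = label,
         trimmed = trimmed, se_method = se_method),
    class = "panel_summary"
  )
}

#' @export
print.panel_summary <- function(x, digits = 2, ...) {
  cat("Panel summary (n =", x$n, "judges",
      if (length(x$trimmed) > 0) paste0("; ", length(x$trimmed), " trimmed") else "",
      "; SE method:", x$se_method, ")\n")
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits, format = "f"))
  m <- rbind(`L (clear fail)` = c(x$mean_L, x$sd_L, x$se_L),
             `H (clear pass)` = c(x$mean_H, x$sd_H, x$se_H))
  if (!is.na(x$mean_suggested)) {
    m <- rbind(m, `suggested CS` = c(x$mean_suggested, x$sd_suggested,
                                     x$se_suggested))
  }
  colnames(m) <- c("mean", "SD", "SE")
  print(apply(m, c(1, 2), fmt), quote = FALSE)
  invisible(x)
}

#' Trim extreme judges from a panel
#'
#' Removes the \code{k_per_side} judges with the lowest and the
#' \code{k_per_side} judges with the highest values of the chosen anchor.
#' Whole judges are removed (both their L and H), so the two anchor
#' distributions remain drawn from the same panel. Ties at the trim
#' boundary are broken by input order: among tied judges the earlier rows
#' are removed first on the low side and the later rows first on the high
#' side, as a stable sort on the anchor implies.
#'
#' @param panel A \code{\link{judge_panel}}.
#' @param k_per_side Non-negative integer count removed from each tail.
#' @param field Which anchor drives removal, \code{"L"} or \code{"H"}.
#' @return A new \code{judge_panel}; removed judge ids accumulate in the
#'   \code{trimmed} element. The input panel is unchanged.
#' @export
trim_extremes <- function(panel, k_per_side, field = c("L", "H")) {
  stopifnot(inherits(panel, "judge_panel"))
  field <- match.arg(field)
  k <- as.integer(k_per_side)
  if (k < 0) stop("k_per_side must be >= 0", call. = FALSE)
  if (k == 0) return(panel)
  r <- panel$ratings
  n <- nrow(r)
  if (n - 2L * k < 2) {
    stop(sprintf("trimming %d per side leaves %d judge(s); need at least 2",
                 k, max(n - 2L * k, 0L)), call. = FALSE)
  }
  ord <- order(r[[field]])          # stable: ties keep input order
  drop_idx <- c(ord[seq_len(k)], ord[seq(n - k + 1L, n)])
  removed <- r$judge_id[sort(drop_idx)]
  out <- panel
  out$ratings <- r[-drop_idx, , drop = FALSE]
  rownames(out$ratings) <- NULL
  out$trimmed <- c(panel$trimmed, removed)
  out
}

#' Bootstrap standard error of a mean
#'
#' Resamples the values with replacement \code{replicates} times (same size
#' as the input), computes the mean of each resample, and returns the sample
#' standard deviation (n-1 denominator) of those means. Fully reproducible
#' for a fixed seed.
#'
#' @param values Numeric vector of at least 2 scores.
#' @param replicates Number of bootstrap resamples, default 2000.
#' @param seed Integer seed (required; the bootstrap is audit-reproducible).
#' @return The bootstrap SE (a single non-negative number).
#' @export
bootstrap_se <- function(values, replicates = 2000, seed) {
  if (length(values) < 2) {
    stop("insufficient panel: need at least 2 values", call. = FALSE)
  }
  stopifnot(replicates >= 1)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  n <- length(values)
  means <- withr_seed(seed, {
    vapply(seq_len(replicates),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  if (replicates == 1) return(0)
  stats::sd(means)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Normality diagnostics for anchor scores
#'
#' The cut-score method assumes the judges' anchor scores are approximately
#' normally distributed. This reports sample skewness, excess kurtosis and a
#' Shapiro-Wilk p-value, with an advisory flag when |skewness| > 1 or
#' p < 0.05. The flag is advisory only: the engine never refuses data on
#' this basis, because with small panels the remedies (trimming, bootstrap
#' SEs, recruiting more judges) are a judgement call for the standard-setting
#' team.
#'
#' @param values Numeric vector of at least 3 scores.
#' @return A list with \code{n}, \code{skewness} (g1), \code{excess_kurtosis}
#'   (g2), \code{shapiro_p}, and logical \code{advisory}.
#' @export
normality_diagnostics <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values for diagnostics", call. = FALSE)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  skew <- if (m2 == 0) 0 else mean(d^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean(d^4) / m2^2 - 3
  sw_p <- if (m2 == 0 || n > 5000) NA_real_ else stats::shapiro.test(values)$p.value
  advisory <- abs(skew) > 1 || (!is.na(sw_p) && sw_p < 0.05)
  list(n = n, skewness = skew, excess_kurtosis = kurt,
       shapiro_p = sw_p, advisory = advisory)
}
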