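#' Classic Angoff baseline cut-score
#'
#' In the classic Angoff procedure each judge estimates, per item, the
#' proportion of minimally competent examinees who would answer correctly;
#' the grand mean of those proportions, on the percent scale, is the
#' cut-score. Items are weighted equally.
#'
#' @param proportions A judges-by-items numeric matrix (or data frame) of
#'   proportions in [0, 1]; complete (no missing cells).
#' @return The cut-score as a percent in [0, 100].
#' @examples
#' classic_angoff(matrix(c(0.5, 0.7, 0.6, 0.8), nrow = 2, byrow = TRUE))  # 65
#' @export
classic_angoff <- function(proportions) {
  m <- as.matrix(proportions)
  if (length(m) == 0) stop("empty item-rating matrix", call. = FALSE)
  if (!is.numeric(m) || anyNA(m)) {
    stop("item-rating matrix must be numeric and complete", call. = FALSE)
  }
  if (any(m < 0 | m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("proportion %g at [%d, %d] outside [0, 1]",
                 m[bad[1], bad[2]], bad[1], bad[2]), call. = FALSE)
  }
  100 * mean(m)
}

#' Direct-suggestion baseline cut-score
#'
#' The mean of the cut-scores the judges suggested directly for the whole
#' examination — the naive comparator against which the anchored method is
#' reported.
#'
#' @param panel A \code{\link{judge_panel}} in which every judge supplied a
#'   suggested cut-score.
#' @return The mean suggested cut-score (percent).
#' @export
direct_suggested_mean <- function(panel) {
  stopifnot(inherits(panel, "judge_panel"))
  s <- panel$ratings$suggested
  if (anyNA(s)) {
    stop("missing suggested cut-score for judge(s): ",
         paste(panel$ratings$judge_id[is.na(s)], collapse = ", "),
         call. = FALSE)
  }
  mean(s)
}

#' Read a judges-by-items Angoff proportion matrix from CSV
#'
#' Expects a header \code{judge_id,item_1,...,item_k} with proportions as
#' decimals in [0, 1].
#'
#' @param path Path to the CSV file.
#' @return A numeric matrix with judge ids as row names and item names as
#'   column names.
#' @export
read_item_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"judge_id" %in% names(df)) {
    stop("item matrix CSV must have a 'judge_id' column", call. = FALSE)
  }
  if (ncol(df) < 2) stop("item matrix CSV has no item columns", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "judge_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$judge_id)
  if (anyNA(m)) stop("item matrix contains missing or non-numeric cells",
                     call. = FALSE)
  m
}
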