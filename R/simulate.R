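#' Configure a synthetic judge panel
#'
#' Describes the population a simulated panel is drawn from: independent
#' (optionally skewed) normal distributions for the clear-fail and
#' clear-pass anchors, truncated to the score scale by redrawing, with an
#' optional contamination mechanism that shifts a fraction of judges'
#' values by a fixed offset to emulate extreme panellists.
#'
#' Skew is parameterised by the skew-normal shape; the location and scale
#' are re-solved so the stated mean and SD are preserved, which keeps skewed
#' and unskewed configurations comparable. This is a testing device for the
#' method's distributional assumption, not part of the method itself.
#'
#' @param n_judges Panel size, at least 2.
#' @param mu_L,mu_H Population anchor means (percent).
#' @param sigma_L,sigma_H Population anchor SDs (percent, >= 0).
#' @param bounds Truncation interval, default \code{c(0, 100)}.
#' @param skew_L,skew_H Optional skew-normal shape parameters (0 = none).
#' @param contamination Optional \code{list(proportion = , shift = )}:
#'   the stated proportion of judges have both anchors shifted by
#'   \code{shift} percent (clamped to \code{bounds}).
#' @param seed Integer master seed.
#' @return A \code{"simulation_config"} list.
#' @export
simulation_config <- function(n_judges, mu_L, mu_H, sigma_L, sigma_H,
                              bounds = c(0, 100), skew_L = 0, skew_H = 0,
                              contamination = NULL, seed = 1L) {
  stopifnot(n_judges >= 2, sigma_L >= 0, sigma_H >= 0,
            length(bounds) == 2, bounds[1] < bounds[2])
  if (!is.null(contamination)) {
    stopifnot(is.list(contamination),
              contamination$proportion >= 0, contamination$proportion < 1)
  }
  structure(
    list(n_judges = as.integer(n_judges), mu_L = mu_L, mu_H = mu_H,
         sigma_L = sigma_L, sigma_H = sigma_H, bounds = bounds,
         skew_L = skew_L, skew_H = skew_H,
         contamination = contamination, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Skew-normal draws standardised to mean 0, SD 1, then rescaled to
# (mu, sigma). shape = 0 reduces to N(mu, sigma^2).
rskewnorm_ms <- function(n, mu, sigma, shape) {
  if (shape == 0) return(stats::rnorm(n, mu, sigma))
  delta <- shape / sqrt(1 + shape^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  x <- delta * z0 + sqrt(1 - delta^2) * z1      # SN(0, 1, shape)
  m <- delta * sqrt(2 / pi)
  s <- sqrt(1 - 2 * delta^2 / pi)
  mu + sigma * (x - m) / s
}

# Draw n values from the (skew-)normal truncated to bounds by redraw.
draw_truncated <- function(n, mu, sigma, shape, bounds, max_attempts = 1000) {
  if (sigma == 0) {
    if (mu < bounds[1] || mu > bounds[2]) {
      stop("degenerate distribution lies outside the truncation bounds",
           call. = FALSE)
    }
    return(rep(mu, n))
  }
  out <- numeric(n)
  filled <- 0L
  for (attempt in seq_len(max_attempts)) {
    need <- n - filled
    x <- rskewnorm_ms(need, mu, sigma, shape)
    keep <- x[x >= bounds[1] & x <= bounds[2]]
    if (length(keep) > 0) {
      out[filled + seq_along(keep)] <- keep
      filled <- filled + length(keep)
    }
    if (filled == n) return(out)
  }
  stop(sprintf(
    "truncation redraw cap (%d) reached: bounds [%g, %g] exclude nearly all mass",
    max_attempts, bounds[1], bounds[2]), call. = FALSE)
}

# Deterministic substream seed from (master seed, replicate index, n);
# kept within the positive 32-bit integer range.
substream_seed <- function(seed, replicate, n) {
  as.integer((as.double(seed) * 48271 + replicate * 7919 + n * 104729) %%
               2147483647)
}

#' Simulate a judge panel
#'
#' Draws each judge's L and H independently from the configured populations
#' (truncated by redraw, not clipping, so the distributional shape within
#' the bounds is preserved), then applies contamination by shifting the
#' first \code{round(proportion * n)} judges' anchors by the configured
#' offset. Identical configurations (including seed) yield identical panels.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{judge_panel}}.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_judges
  panel <- withr_seed(config$seed, {
    L <- draw_truncated(n, config$mu_L, config$sigma_L, config$skew_L,
                        config$bounds)
    H <- draw_truncated(n, config$mu_H, config$sigma_H, config$skew_H,
                        config$bounds)
    if (!is.null(config$contamination)) {
      k <- round(config$contamination$proportion * n)
      if (k > 0) {
        idx <- seq_len(k)
        shift <- config$contamination$shift
        L[idx] <- pmin(pmax(L[idx] + shift, config$bounds[1]), config$bounds[2])
        H[idx] <- pmin(pmax(H[idx] + shift, config$bounds[1]), config$bounds[2])
      }
    }
    data.frame(judge_id = sprintf("sim_%03d", seq_len(n)), L = L, H = H)
  })
  suppressWarnings(
    judge_panel(panel, scale_max = max(config$bounds[2], 100),
                label = "simulated panel")
  )
}

#' Analytic population oracle for a simulated configuration
#'
#' Applies the cut-score engine to the population parameters directly
#' (mean_L = mu_L, se_L = sigma_L/sqrt(n), and likewise for H), yielding
#' the deterministic result that panel estimates converge to as the panel
#' grows. Only defined for clean configurations: no skew, no contamination,
#' and truncation bounds far enough out not to distort the populations
#' (configurations whose bounds remove more than 10\% of either anchor's
#' mass are refused; below that the oracle treats the populations as
#' untruncated normals and is mildly approximate).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{compute_cut_score}} result.
#' @export
population_result <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$sigma_L + config$sigma_H <= 0) {
    stop("no analytic oracle: sigma_L + sigma_H must be > 0", call. = FALSE)
  }
  if (config$skew_L != 0 || config$skew_H != 0 ||
      !is.null(config$contamination)) {
    stop("no analytic oracle for skewed or contaminated configurations",
         call. = FALSE)
  }
  # effective truncation (mass beyond the bounds) voids the normal oracle
  for (p in list(c(config$mu_L, config$sigma_L), c(config$mu_H, config$sigma_H))) {
    if (p[2] > 0) {
      outside <- stats::pnorm(config$bounds[1], p[1], p[2]) +
        stats::pnorm(config$bounds[2], p[1], p[2], lower.tail = FALSE)
      if (outside > 0.10) {
        stop("no analytic oracle: truncation bounds remove > 10% of the mass",
             call. = FALSE)
      }
    }
  }
  rn <- sqrt(config$n_judges)
  compute_cut_score(panel_summary(
    n = config$n_judges,
    mean_L = config$mu_L, sd_L = config$sigma_L, se_L = config$sigma_L / rn,
    mean_H = config$mu_H, sd_H = config$sigma_H, se_H = config$sigma_H / rn,
    scale_max = max(config$bounds[2], 100),
    label = "population oracle"
  ))
}

#' Confidence as a function of panel size
#'
#' For each panel size in \code{n_grid}, simulates \code{replicates} panels
#' (each on its own deterministic substream of the master seed), runs the
#' cut-score engine, and tabulates the mean and SD of the reported
#' confidence, alongside the analytic population confidence at that n.
#' Larger panels shrink both SEs, raising Z and hence the confidence.
#'
#' @param config A \code{\link{simulation_config}} supplying the population
#'   parameters and master seed (its \code{n_judges} is ignored).
#' @param n_grid Integer vector of panel sizes (each >= 2).
#' @param replicates Panels per grid point, default 500.
#' @return A data frame with columns \code{n}, \code{mean_confidence},
#'   \code{sd_confidence}, \code{analytic_confidence}.
#' @export
confidence_curve <- function(config, n_grid, replicates = 500) {
  stopifnot(inherits(config, "simulation_config"),
            all(n_grid >= 2), replicates >= 1)
  rows <- lapply(n_grid, function(n) {
    cfg_n <- config
    cfg_n$n_judges <- as.integer(n)
    conf <- vapply(seq_len(replicates), function(r) {
      cfg_r <- cfg_n
      cfg_r$seed <- substream_seed(config$seed, r, n)
      res <- compute_cut_score(summarize_panel(simulate_panel(cfg_r)))
      res$confidence
    }, numeric(1))
    analytic <- tryCatch(population_result(cfg_n)$confidence,
                         error = function(e) NA_real_)
    data.frame(n = n,
               mean_confidence = mean(conf),
               sd_confidence = stats::sd(conf),
               analytic_confidence = analytic)
  })
  do.call(rbind, rows)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{simulation_config}}.
#'
#' @param path Path to the YAML file.
#' @return A \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(simulation_config, y)
}
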