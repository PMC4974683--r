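#' Ordinary least-squares line with determination coefficient
#'
#' Simple linear regression with intercept; r^2 = 1 - SS_res / SS_tot. Used
#' for the pressure-drop-versus-helicity-intensity association.
#'
#' @param x,y numeric vectors (>= 3 points, x not constant).
#' @return list with \code{slope}, \code{intercept}, \code{r2}.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("linear_fit_r2: length mismatch")
  if (length(x) < 3) stopf("linear_fit_r2: need at least 3 points")
  if (stats::var(x) == 0) stopf("linear_fit_r2: zero variance in x")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

#' FFR differences between the largest and smallest bifurcation angle
#'
#' For each combination of side-branch stenosis and flow split, the
#' side-branch FFR at the smallest distal angle minus the FFR at the largest
#' angle, rounded to 2 decimals (exact ties rounded down, the display
#' convention of the reference table).
#'
#' @param results data frame with columns \code{sb_stenosis_pct},
#'   \code{alpha_deg}, \code{sb_flow_pct}, \code{ffr_sb} (e.g. from
#'   \code{\link{reference_results}} or \code{\link{run_study}}).
#' @return data frame with one row per (stenosis, split) pair: columns
#'   \code{sb_stenosis_pct}, \code{sb_flow_pct}, \code{ffr_small_angle},
#'   \code{ffr_large_angle}, \code{diff} (rounded), \code{diff_raw}.
#' @export
angle_difference_table <- function(results) {
  need <- c("sb_stenosis_pct", "alpha_deg", "sb_flow_pct", "ffr_sb")
  if (!all(need %in% names(results)))
    stopf("angle_difference_table: results must have columns %s",
          paste(need, collapse = ", "))
  a_min <- min(results$alpha_deg); a_max <- max(results$alpha_deg)
  if (a_min == a_max)
    stopf("angle_difference_table: need at least two distinct angles")
  combos <- unique(results[, c("sb_stenosis_pct", "sb_flow_pct")])
  combos <- combos[order(combos$sb_stenosis_pct, combos$sb_flow_pct), ]
  missing <- character(0)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sten <- combos$sb_stenosis_pct[i]; fl <- combos$sb_flow_pct[i]
    sel <- results$sb_stenosis_pct == sten & results$sb_flow_pct == fl
    f_lo <- results$ffr_sb[sel & results$alpha_deg == a_min]
    f_hi <- results$ffr_sb[sel & results$alpha_deg == a_max]
    if (length(f_lo) != 1 || length(f_hi) != 1) {
      missing <<- c(missing, sprintf("%g%% / %g%%sb", sten, fl))
      return(NULL)
    }
    data.frame(sb_stenosis_pct = sten, sb_flow_pct = fl,
               ffr_small_angle = f_lo, ffr_large_angle = f_hi,
               diff = round_half_down(f_lo - f_hi, 2),
               diff_raw = f_lo - f_hi)
  })
  if (length(missing))
    stopf("angle_difference_table: missing angle pairing for: %s",
          paste(missing, collapse = "; "))
  do.call(rbind, rows)
}
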