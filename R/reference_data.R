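#' Reference 27-case study results
#'
#' The published pressure drops and FFR values of the 27-case bifurcation
#' study (side-branch stenosis 40/60/80 %, distal angle 40/55/70 deg,
#' side-branch flow 25/35/45 % of the 120 mL/min hyperemic inlet flow;
#' proximal and distal main branch stenosis fixed at 60 %), kept verbatim as
#' printed. Used as the validation surface for the statistics layer and as
#' calibration targets for the synthetic stenotic-jet fixture. The FFR
#' columns are arithmetically consistent with the pressure-drop columns via
#' FFR = (100 - dP)/100 at 3 decimals, with one known print slip in the
#' main-branch FFR of the 60 %/40 deg/45 % case.
#'
#' @param inlet_flow inlet flow used to derive \code{q_sb_ml_min} (mL/min).
#' @return data frame with one row per case: \code{case_id},
#'   \code{sb_stenosis_pct}, \code{alpha_deg}, \code{sb_flow_pct},
#'   \code{q_sb_ml_min}, \code{dp_mb}, \code{ffr_mb}, \code{dp_sb},
#'   \code{ffr_sb}.
#' @export
reference_results <- function(inlet_flow = 120) {
  path <- system.file("extdata", "reference_results.csv", package = "stenoflow",
                      mustWork = TRUE)
  d <- utils::read.csv(path)
  d$q_sb_ml_min <- inlet_flow * d$sb_flow_pct / 100
  d$case_id <- case_id(d$sb_stenosis_pct, d$alpha_deg, d$sb_flow_pct)
  d[, c("case_id", "sb_stenosis_pct", "alpha_deg", "sb_flow_pct",
        "q_sb_ml_min", "dp_mb", "ffr_mb", "dp_sb", "ffr_sb")]
}
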