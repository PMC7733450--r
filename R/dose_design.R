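# Steady-state design calculators: synthesis rates required to hold a
# protein at its minimal working concentration against dilution, minimal DNA
# template inputs under proportional rate allocation, dilution fluxes, and
# molar/mass unit conversions.

#' Synthesis rate required to sustain a concentration against dilution
#'
#' At chemostat steady state, synthesis must balance dilution:
#' `rate = mu * c_min`.
#'
#' @param c_min minimum required concentration (> 0; nM or ug/mL — the
#'   result inherits the unit per minute).
#' @param mu dilution rate in 1/min (> 0).
#' @return Synthesis rate in concentration units per minute.
#' @examples
#' required_rate(100, dilution_rate(0.2, 15))
#' @export
required_rate <- function(c_min, mu) {
  if (any(c_min <= 0) || any(mu <= 0))
    stop("c_min and mu must be > 0", call. = FALSE)
  mu * c_min
}

#' Synthesis rate allocated to a gene by its DNA share
#'
#' Assumes every template is transcribed and translated at the same
#' per-template rate, so a gene at DNA concentration `d_target` receives
#' `rate_ref * d_target / d_ref` where `rate_ref` is the measured rate of a
#' reference gene at template concentration `d_ref`.
#'
#' @param rate_ref reference synthesis rate (concentration/min).
#' @param d_target DNA concentration of the target gene (>= 0).
#' @param d_ref DNA concentration of the reference gene (> 0).
#' @return Allocated synthesis rate, same units as `rate_ref`.
#' @export
allocated_rate <- function(rate_ref, d_target, d_ref) {
  if (any(d_ref <= 0)) stop("d_ref must be > 0", call. = FALSE)
  if (any(d_target < 0)) stop("d_target must be >= 0", call. = FALSE)
  rate_ref * d_target / d_ref
}

#' Minimal DNA template input for sustained self-regeneration
#'
#' The smallest DNA input whose allocated synthesis rate meets the
#' steady-state requirement: `d = d_ref * mu * c_min / rate_ref`, the exact
#' inverse of [allocated_rate()] composed with [required_rate()].
#'
#' @param c_min minimum required protein concentration (> 0).
#' @param mu dilution rate in 1/min (> 0).
#' @param rate_ref reference (e.g. reporter) synthesis rate (> 0), in the
#'   same concentration units as `c_min` per minute.
#' @param d_ref reference DNA concentration (> 0).
#' @return Minimal DNA concentration, same units as `d_ref`.
#' @examples
#' mu <- dilution_rate(0.2, 15)
#' min_dna_input(c_min = 100, mu = mu, rate_ref = 10, d_ref = 2)
#' @export
min_dna_input <- function(c_min, mu, rate_ref, d_ref) {
  if (any(c_min <= 0) || any(mu <= 0) || any(rate_ref <= 0) || any(d_ref <= 0))
    stop("all inputs must be > 0", call. = FALSE)
  d_ref * mu * c_min / rate_ref
}

#' Dilution flux of a species at steady state
#'
#' The amount removed from the reactor per minute when a species is held at
#' concentration `c`: `mu * c`.
#'
#' @param c working concentration (> 0).
#' @param mu dilution rate in 1/min (> 0).
#' @return Removal rate in concentration units per minute.
#' @export
dilution_flux <- function(c, mu) {
  if (any(c <= 0) || any(mu <= 0)) stop("c and mu must be > 0", call. = FALSE)
  mu * c
}

.UNIT_KIND <- c(nM = "molar", uM = "molar", `ug/mL` = "mass", `mg/mL` = "mass")
.UNIT_SCALE <- c(nM = 1, uM = 1000, `ug/mL` = 1, `mg/mL` = 1000)

normalize_unit <- function(unit) {
  u <- gsub("µ", "u", unit)  # micro sign -> u
  if (!u %in% names(.UNIT_KIND))
    stop(sprintf("unknown unit '%s' (use nM, uM, ug/mL, mg/mL)", unit), call. = FALSE)
  u
}

#' Convert between molar and mass concentration units
#'
#' Supported units: `nM`, `uM` (molar) and `ug/mL`, `mg/mL` (mass).
#' Crossing molar and mass requires the molecular weight in kDa
#' (1 uM of a W-kDa protein = W ug/mL). Conversions round-trip exactly.
#'
#' @param value numeric value(s).
#' @param from,to unit names.
#' @param molecular_weight molecular weight in kDa; required only when
#'   converting between molar and mass units.
#' @return Converted value(s).
#' @examples
#' convert_units(1, "uM", "ug/mL", molecular_weight = 99)   # 99
#' convert_units(2, "ug/mL", "nM", molecular_weight = 50)   # 40
#' @export
convert_units <- function(value, from, to, molecular_weight = NULL) {
  from <- normalize_unit(from); to <- normalize_unit(to)
  base <- value * .UNIT_SCALE[[from]]  # nM or ug/mL
  if (.UNIT_KIND[[from]] != .UNIT_KIND[[to]]) {
    if (is.null(molecular_weight))
      stop("molecular_weight (kDa) required to convert between molar and mass units",
           call. = FALSE)
    if (molecular_weight <= 0) stop("molecular_weight must be > 0", call. = FALSE)
    base <- if (.UNIT_KIND[[from]] == "molar") {
      base * molecular_weight / 1000        # nM -> ug/mL
    } else {
      base * 1000 / molecular_weight        # ug/mL -> nM
    }
  }
  base / .UNIT_SCALE[[to]]
}

#' Protein specification table
#'
#' Reads a delimited text table of proteins to be regenerated. Required
#' columns: `name`, `molecular_weight` (kDa), `c_min` (minimum required
#' concentration) and `unit` (`nM`, `uM`, `ug/mL` or `mg/mL`); optional
#' `working_concentration` in the same unit.
#'
#' @param path CSV file path.
#' @return Data frame of class `protein_spec`.
#' @export
read_protein_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "molecular_weight", "c_min", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("protein spec table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$molecular_weight <= 0) || any(df$c_min <= 0))
    stop("molecular weights and concentrations must be > 0", call. = FALSE)
  df$unit <- vapply(df$unit, normalize_unit, character(1))
  class(df) <- c("protein_spec", "data.frame")
  df
}

#' Dose-design table for a set of proteins
#'
#' For each protein: the synthesis rate required to sustain `c_min` against
#' dilution, the minimal DNA template input under proportional allocation
#' from a reference gene, and (when a working concentration is given) the
#' dilution flux at that concentration. Rates are computed in molar units
#' (nM/min) using each protein's molecular weight where the input is
#' mass-based.
#'
#' @param specs a `protein_spec` data frame (see [read_protein_specs()]).
#' @param schedule a [dilution_schedule()].
#' @param rate_ref reference synthesis rate in nM/min (e.g. the reporter's).
#' @param d_ref reference DNA concentration in nM.
#' @return Data frame with one row per protein: `c_min_nM`,
#'   `required_rate_nM_min`, `min_dna_nM`, and `dilution_flux` in the
#'   spec's own unit per minute when `working_concentration` is present.
#' @export
design_table <- function(specs, schedule = dilution_schedule(),
                         rate_ref, d_ref) {
  stopifnot(inherits(schedule, "dilution_schedule"))
  mu <- dilution_rate(schedule$replaced_fraction, schedule$cycle_interval)
  c_min_nM <- mapply(function(v, u, mw) convert_units(v, u, "nM", mw),
                     specs$c_min, specs$unit, specs$molecular_weight)
  out <- data.frame(name = specs$name,
                    c_min_nM = c_min_nM,
                    required_rate_nM_min = required_rate(c_min_nM, mu),
                    min_dna_nM = min_dna_input(c_min_nM, mu, rate_ref, d_ref),
                    stringsAsFactors = FALSE)
  if ("working_concentration" %in% names(specs)) {
    out$dilution_flux <- ifelse(is.na(specs$working_concentration), NA_real_,
                                specs$working_concentration * mu)
    out$flux_unit <- paste0(specs$unit, "/min")
  }
  attr(out, "mu_per_min") <- mu
  out
}
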