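#' DNA mass-conversion constants
#'
#' Average molar masses used to interconvert molecule counts and mass:
#' 330 g/mol per nucleotide of single-stranded DNA and 650 g/mol per base
#' pair of double-stranded DNA.
#'
#' @param ss_mass_per_nt Single-stranded DNA, g/mol per nt.
#' @param ds_mass_per_bp Double-stranded DNA, g/mol per bp.
#' @param avogadro Avogadro constant, 1/mol.
#' @return A list of class `mass_model`.
#' @export
mass_model <- function(ss_mass_per_nt = 330, ds_mass_per_bp = 650,
                       avogadro = 6.022e23) {
  stopifnot(ss_mass_per_nt > 0, ds_mass_per_bp > 0, avogadro > 0)
  structure(list(ss_mass_per_nt = ss_mass_per_nt,
                 ds_mass_per_bp = ds_mass_per_bp, avogadro = avogadro),
            class = "mass_model")
}

per_unit_mass <- function(strandedness, model) {
  strandedness <- match.arg(strandedness, c("ss", "ds"))
  if (strandedness == "ss") model$ss_mass_per_nt else model$ds_mass_per_bp
}

#' Convert between molecule counts and mass in picograms
#'
#' `molecules_to_mass()` gives the mass in pg of `n_molecules` DNA
#' molecules of a given length;
#' `mass = n * length * m / N_A * 1e12` with `m` the per-nt (ss) or per-bp
#' (ds) molar mass. `mass_to_molecules()` is its exact inverse. These are
#' the conversions behind minimal-library budgeting: 340,000 single-stranded
#' 700-nt molecules (one 1/8 picotiterplate region) weigh about 0.13 pg.
#'
#' @param n_molecules Number of molecules (>= 0).
#' @param mass_pg Mass in picograms (>= 0).
#' @param length Molecule length in nt (ss) or bp (ds).
#' @param strandedness `"ss"` or `"ds"`.
#' @param model A [mass_model()].
#' @return A single number: mass in pg, or molecule count.
#' @export
#' @examples
#' molecules_to_mass(340000, 700, "ss")   # ~0.13 pg
#' mass_to_molecules(0.13, 700, "ss")     # ~340,000 molecules
molecules_to_mass <- function(n_molecules, length, strandedness = c("ss", "ds"),
                              model = mass_model()) {
  if (n_molecules < 0 || length < 0) {
    stop("n_molecules and length must be nonnegative", call. = FALSE)
  }
  n_molecules * length * per_unit_mass(strandedness, model) /
    model$avogadro * 1e12
}

#' @rdname molecules_to_mass
#' @export
mass_to_molecules <- function(mass_pg, length, strandedness = c("ss", "ds"),
                              model = mass_model()) {
  if (mass_pg < 0) stop("mass_pg must be nonnegative", call. = FALSE)
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  mass_pg * 1e-12 * model$avogadro /
    (length * per_unit_mass(strandedness, model))
}

#' Percent DNA lost between protocol input and output
#'
#' @param input_mass_pg Input mass in pg (> 0).
#' @param output_mass_pg Output mass in pg (`<= input_mass_pg`).
#' @return Loss as a percentage of input.
#' @export
#' @examples
#' # 1 ug input yielding 8.4e9 ds 700-bp molecules loses ~99.4%
#' percent_loss(1e6, molecules_to_mass(8.4e9, 700, "ds"))
percent_loss <- function(input_mass_pg, output_mass_pg) {
  if (input_mass_pg <= 0) stop("input mass must be positive", call. = FALSE)
  if (output_mass_pg > input_mass_pg) {
    stop("output mass cannot exceed input mass", call. = FALSE)
  }
  100 * (input_mass_pg - output_mass_pg) / input_mass_pg
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 of the
#' starting molecule count over a serial dilution of a standard of known
#' concentration. The amplification efficiency derives from the slope as
#' `E = 10^(-1/slope) - 1` (E = 1 means perfect doubling per cycle, slope
#' -3.32).
#'
#' @param points Data frame with columns `n_molecules` (> 0) and `cq`.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_points`, `n_levels` and the
#'   underlying `lm` fit. [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' pts <- data.frame(n_molecules = 10^(6:3), cq = c(10, 13.32, 16.64, 19.97))
#' fit_standard_curve(pts)
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("n_molecules", "cq") %in% names(points)))
  if (any(points$n_molecules <= 0)) {
    stop("all n_molecules must be positive", call. = FALSE)
  }
  if (length(unique(points$n_molecules)) < 3) {
    stop("at least 3 distinct dilution levels required", call. = FALSE)
  }
  d <- tibble::tibble(log10_molecules = log10(points$n_molecules),
                      cq = points$cq)
  fit <- stats::lm(cq ~ log10_molecules, data = d)
  slope <- unname(stats::coef(fit)[["log10_molecules"]])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid calibration: slope must be negative", call. = FALSE)
  }
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = summary(fit)$r.squared,
    efficiency = 10^(-1 / slope) - 1,
    n_points = nrow(d),
    n_levels = length(unique(points$n_molecules)),
    fit = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.4f + %.4f * log10(molecules)\n  efficiency %.3f, r-squared %.4f (%d points, %d levels)\n",
    x$intercept, x$slope, x$efficiency, x$r_squared, x$n_points, x$n_levels))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted qPCR standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return `tidy()` returns the per-term coefficient tibble of the
#'   underlying linear fit; `glance()` a one-row tibble with `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `n_points`, `n_levels`.
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 efficiency = x$efficiency, r_squared = x$r_squared,
                 n_points = x$n_points, n_levels = x$n_levels)
}

#' Absolute quantification of a sample from Cq replicates
#'
#' Replicate Cq values are averaged in Cq space (standard qPCR practice),
#' inverted through the calibration line, and scaled by the dilution
#' factor to give molecules per microliter in the undiluted sample.
#'
#' @param curve A fitted [fit_standard_curve()] object.
#' @param cq_replicates Numeric vector of Cq values (>= 1 replicate).
#' @param dilution_factor Fold dilution applied before measurement
#'   (e.g. 10 for a 1:10 dilution).
#' @return One-row tibble: `molecules_per_ul`, `mean_cq`, `cq_spread`,
#'   `n_replicates`, `flag` (`"replicate spread > 1 Cq"` when replicates
#'   disagree by more than one cycle, else `NA`).
#' @export
quantify <- function(curve, cq_replicates, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"),
            length(cq_replicates) >= 1, dilution_factor > 0)
  spread <- diff(range(cq_replicates))
  flag <- NA_character_
  if (spread > 1.0) {
    flag <- "replicate spread > 1 Cq"
    warning(flag, call. = FALSE)
  }
  mean_cq <- mean(cq_replicates)
  molecules <- 10^((mean_cq - curve$intercept) / curve$slope) *
    dilution_factor
  tibble::tibble(molecules_per_ul = molecules, mean_cq = mean_cq,
                 cq_spread = spread, n_replicates = length(cq_replicates),
                 flag = flag)
}

#' Picotiterplate bead-budget configuration
#'
#' A picotiterplate (PTP) region holds a fixed number of enriched,
#' template-bearing beads; under the one-bead-one-molecule notion that
#' capacity is the number of library molecules needed. Only the 1/8 region
#' capacity (340,000 beads) is provided as a default; other regions must be
#' configured explicitly.
#'
#' @param region_beads Named numeric vector mapping region labels to
#'   enriched-bead capacities.
#' @param n_mids Number of multiplexed samples (MIDs) sharing the region.
#' @param enrichment_fraction Length-2 numeric, the recommended enrichment
#'   range (fractions in (0, 1)).
#' @return A list of class `ptp_config`.
#' @export
ptp_config <- function(region_beads = c("1/8" = 340000), n_mids = 1,
                       enrichment_fraction = c(0.05, 0.15)) {
  stopifnot(length(region_beads) >= 1, all(region_beads >= 1),
            !is.null(names(region_beads)),
            length(enrichment_fraction) == 2,
            all(enrichment_fraction > 0), all(enrichment_fraction < 1))
  if (n_mids < 1) stop("n_mids must be >= 1", call. = FALSE)
  structure(list(region_beads = region_beads, n_mids = n_mids,
                 enrichment_fraction = enrichment_fraction),
            class = "ptp_config")
}

#' Molecules required to fill a PTP region
#'
#' @param ptp A [ptp_config()].
#' @param region Region label present in `ptp$region_beads`.
#' @return One-row tibble: `region`, `total_molecules`,
#'   `molecules_per_mid`, `n_mids`.
#' @export
#' @examples
#' required_molecules(ptp_config(n_mids = 2), "1/8")  # 170,000 per MID
required_molecules <- function(ptp, region = "1/8") {
  stopifnot(inherits(ptp, "ptp_config"))
  if (!region %in% names(ptp$region_beads)) {
    stop(sprintf("unknown PTP region '%s'", region), call. = FALSE)
  }
  total <- unname(ptp$region_beads[[region]])
  tibble::tibble(region = region, total_molecules = total,
                 molecules_per_mid = total / ptp$n_mids,
                 n_mids = ptp$n_mids)
}

#' PCR cycles needed to reach a target molecule count
#'
#' Smallest integer `n` with `current * (1 + pcr_efficiency)^n >= target *
#' safety_margin`; 0 when the target is already met. A safety margin above
#' 1 plans for sub-nominal amplification and downstream losses; with the
#' default margin of 2 an under-quantified library of 41,043 molecules
#' needs 4 perfect-doubling cycles to cover a 170,000-molecule target.
#'
#' @param current Current molecule count (> 0).
#' @param target Required molecule count (> 0).
#' @param pcr_efficiency Per-cycle amplification efficiency in (0, 1].
#' @param safety_margin Multiplier applied to `target` (>= 1); 1 plans for
#'   the bare target.
#' @return Integer number of cycles.
#' @export
#' @examples
#' enrichment_cycles(41043, 170000, safety_margin = 1)  # 3
#' enrichment_cycles(41043, 170000)                     # 4 with 2x margin
enrichment_cycles <- function(current, target, pcr_efficiency = 1,
                              safety_margin = 2) {
  if (current <= 0 || target <= 0) {
    stop("current and target must be positive", call. = FALSE)
  }
  stopifnot(pcr_efficiency > 0, pcr_efficiency <= 1, safety_margin >= 1)
  goal <- target * safety_margin
  if (current >= goal) return(0L)
  as.integer(ceiling(log(goal / current) / log(1 + pcr_efficiency)))
}

#' Read qPCR tables from delimited text
#'
#' `read_curve_points()` expects columns `n_molecules` and `cq`;
#' `read_cq_replicates()` a column `cq` (optionally `sample`).
#'
#' @param path Path to a CSV or TSV file (delimiter auto-detected from the
#'   extension).
#' @return A tibble.
#' @export
read_curve_points <- function(path) {
  f <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  f(path, show_col_types = FALSE)
}

#' @rdname read_curve_points
#' @export
read_cq_replicates <- function(path) read_curve_points(path)

#' Plan a minimal-library preparation
#'
#' Combines qPCR quantification, PTP budgeting and enrichment planning in
#' one report: how many molecules the region needs per MID, how many the
#' sample holds, the mass this represents for the given fragment length,
#' and how many PCR cycles (if any) are required.
#'
#' @param current_molecules Quantified molecule count of the library.
#' @param ptp A [ptp_config()].
#' @param region PTP region label.
#' @param fragment_length Library fragment length in nt.
#' @param pcr_efficiency,safety_margin Passed to [enrichment_cycles()].
#' @return One-row tibble mirroring a budgeting worksheet.
#' @export
plan_library <- function(current_molecules, ptp = ptp_config(),
                         region = "1/8", fragment_length = 700,
                         pcr_efficiency = 1, safety_margin = 2) {
  req <- required_molecules(ptp, region)
  cycles <- enrichment_cycles(current_molecules, req$molecules_per_mid,
                              pcr_efficiency, safety_margin)
  dplyr::mutate(
    req,
    current_molecules = current_molecules,
    required_mass_pg = molecules_to_mass(.data$total_molecules,
                                         fragment_length, "ss"),
    enrichment_cycles = cycles,
    sufficient = current_molecules >= .data$molecules_per_mid
  )
}
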