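#' Flow-karyotype DNA-content estimation
#'
#' In a bivariate flow karyotype, chromosomes stained with Hoechst 33258
#' (AT-preferring, `HO`) and Chromomycin A3 (GC-preferring, `CA3`) form peaks
#' whose position along the "DNA line" -- a line through the origin at angle
#' `alpha` to the CA3 axis -- is proportional to DNA content. Projecting each
#' peak onto that line gives `D_n = HO * sin(alpha) + CA3 * cos(alpha)`;
#' calibrating `D_n` against peaks of known DNA content converts projections
#' to megabase contents, and the genome size is the copy-number-weighted sum
#' over chromosome peaks.
#'
#' @name flow_karyotype
NULL

#' Project flow peaks onto the DNA line
#'
#' @param peaks A data frame with numeric columns `HO` and `CA3` (mean peak
#'   fluorescence, arbitrary units).
#' @param alpha_degrees Angle of the DNA line to the CA3 (x) axis, in
#'   degrees, within `[0, 90]`.
#' @return The input as a tibble with a `dn` column appended.
#' @examples
#' dna_line_projection(data.frame(HO = 3, CA3 = 4), alpha_degrees = 50)
#' @export
dna_line_projection <- function(peaks, alpha_degrees = 50) {
  check_scalar_number(alpha_degrees, "alpha_degrees", min = 0, max = 90)
  peaks <- as_tibble(peaks)
  stopifnot(all(c("HO", "CA3") %in% names(peaks)))
  if (any(peaks$HO < 0, na.rm = TRUE) || any(peaks$CA3 < 0, na.rm = TRUE)) {
    abort("fluorescence intensities must be non-negative")
  }
  a <- alpha_degrees * pi / 180
  peaks |> mutate(dn = .data$HO * sin(a) + .data$CA3 * cos(a))
}

#' Calibrate the DNA line and estimate chromosomal contents and genome size
#'
#' Fits DNA content against the `D_n` projection on calibration peaks of
#' known content (by default through the origin, matching the construction of
#' the DNA line as a projection through the origin), predicts the content of
#' each query peak, and sums the per-peak contents -- each weighted by its
#' chromosome copy number -- into a genome size.
#'
#' @param calibration_peaks Data frame with `HO`, `CA3` and `known_content`
#'   (Mbp); at least two peaks with distinct projections.
#' @param query_peaks Data frame with `HO`, `CA3`, optional `label` and
#'   `copy_number` (defaults to 1 per peak).
#' @param alpha_degrees DNA-line angle, degrees.
#' @param through_origin Fit without an intercept (default)?
#' @return An object of class `flow_karyotype_fit`: list with `peaks`
#'   (query peaks plus `dn` and predicted `content`), `genome_size_mbp`,
#'   `fit` (the `lm`), `alpha_degrees`.
#' @examples
#' cal <- data.frame(HO = c(1, 3), CA3 = c(0, 0), known_content = c(100, 300))
#' qry <- data.frame(HO = 2, CA3 = 0)
#' calibrate_and_estimate(cal, qry, alpha_degrees = 90)
#' @export
calibrate_and_estimate <- function(calibration_peaks, query_peaks,
                                   alpha_degrees = 50,
                                   through_origin = TRUE) {
  cal <- dna_line_projection(calibration_peaks, alpha_degrees)
  if (!"known_content" %in% names(cal)) {
    abort("calibration peaks need a `known_content` column")
  }
  if (nrow(cal) < 2 || length(unique(cal$dn)) < 2) {
    abort("need >= 2 calibration peaks with distinct projections")
  }
  fit <- if (through_origin) {
    lm(known_content ~ 0 + dn, data = cal)
  } else {
    lm(known_content ~ dn, data = cal)
  }
  qry <- dna_line_projection(query_peaks, alpha_degrees)
  if (!"copy_number" %in% names(qry)) qry$copy_number <- 1
  qry$content <- unname(predict(fit, newdata = qry))
  out <- list(
    peaks = qry,
    genome_size_mbp = sum(qry$content * qry$copy_number),
    fit = fit,
    alpha_degrees = alpha_degrees
  )
  class(out) <- "flow_karyotype_fit"
  out
}

#' @export
print.flow_karyotype_fit <- function(x, ...) {
  cat(sprintf("<flow_karyotype_fit> %d peaks, genome size %.1f Mbp (alpha = %g deg)\n",
              nrow(x$peaks), x$genome_size_mbp, x$alpha_degrees))
  invisible(x)
}

#' @rdname calibrate_and_estimate
#' @param x A `flow_karyotype_fit`.
#' @param ... Unused.
#' @export
tidy.flow_karyotype_fit <- function(x, ...) as_tibble(x$peaks)

#' @rdname calibrate_and_estimate
#' @export
glance.flow_karyotype_fit <- function(x, ...) {
  tibble(
    genome_size_mbp = x$genome_size_mbp,
    n_peaks = nrow(x$peaks),
    slope = unname(coef(x$fit)[["dn"]]),
    alpha_degrees = x$alpha_degrees
  )
}

#' Genome size from propidium-iodide DNA-index measurements
#'
#' Cells stained with propidium iodide are measured against an internal
#' standard of chicken erythrocyte nuclei (CEN) of known DNA mass. The DNA
#' index -- the ratio of the sample peak mean to the CEN peak mean -- scales
#' the standard's genome mass, converted at 978 Mbp per picogram.
#'
#' @param sample_peak_mean Mean PI fluorescence of the sample G1 peak.
#' @param cen_peak_mean Mean PI fluorescence of the CEN peak (> 0).
#' @param cen_pg DNA mass of the CEN standard, picograms.
#' @param mbp_per_pg Conversion factor, Mbp per picogram.
#' @return Genome size in Mbp.
#' @examples
#' pi_genome_size(2.5, 1)   # DNA index 2.5
#' @export
pi_genome_size <- function(sample_peak_mean, cen_peak_mean,
                           cen_pg = 1.25, mbp_per_pg = 978) {
  check_scalar_number(sample_peak_mean, "sample_peak_mean", min = 0)
  if (!is.numeric(cen_peak_mean) || cen_peak_mean <= 0) {
    abort("`cen_peak_mean` must be positive")
  }
  cen_pg * (sample_peak_mean / cen_peak_mean) * mbp_per_pg
}
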