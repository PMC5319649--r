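#' Coniine SIM reference pattern
#'
#' The ion set monitored for coniine confirmation: m/z 56, 70, 80, 84 and
#' 126, of which 80, 84 (base peak) and 126 (molecular-ion mass peak) are
#' diagnostic; 56 and 70 are shared with many other molecules and are
#' recorded but never used for confirmation. `rel` holds intensities
#' relative to the base peak (84 = 1). Coniine elutes at a constant
#' retention time, 6.33 +/- 0.01 min, under the reference chromatographic
#' method.
#'
#' The packaged default intensity ratios
#' (`extdata/coniine_reference_pattern_synthetic.tsv`) are a synthetic
#' stand-in for a pure-standard spectrum and should be replaced by ratios
#' measured on the user's instrument.
#'
#' @param pattern_file optional TSV (`mz`, `rel_intensity`) overriding the
#'   packaged ratios.
#' @param rt_center,rt_tol retention-time window, minutes.
#' @return An object of class `coniine_reference`.
#' @export
coniine_reference <- function(pattern_file = NULL, rt_center = 6.33,
                              rt_tol = 0.01) {
  if (is.null(pattern_file))
    pattern_file <- system.file("extdata",
                                "coniine_reference_pattern_synthetic.tsv",
                                package = "sarrachem")
  pat <- utils::read.delim(pattern_file)
  stopifnot(all(c("mz", "rel_intensity") %in% names(pat)))
  rel <- stats::setNames(pat$rel_intensity, pat$mz)
  need <- c("56", "70", "80", "84", "126")
  if (!all(need %in% names(rel)))
    stop("pattern must cover m/z ", paste(need, collapse = ", "))
  if (abs(rel[["84"]] - 1) > 1e-9)
    stop("m/z 84 must be the base peak (relative intensity 1)")
  if (any(rel <= 0) || any(rel > 1))
    stop("relative intensities must lie in (0, 1]")
  structure(list(ions = c(56, 70, 80, 84, 126),
                 diagnostic = c(80, 84, 126),
                 rel = rel[need], rt_center = rt_center, rt_tol = rt_tol),
            class = "coniine_reference")
}

#' Sum SIM intensities per ion inside the retention-time window
#'
#' Points with rt in the closed interval `rt_center +/- rt_tol` are summed
#' per monitored ion; other ions are ignored. An empty window yields an
#' all-zero slice flagged `empty_window`.
#'
#' @param trace data frame with columns `rt`, `mz`, `intensity`.
#' @param ref a `coniine_reference`.
#' @return List with `intensity` (named by ion), `empty_window` flag.
#' @export
extract_window <- function(trace, ref) {
  stopifnot(all(c("rt", "mz", "intensity") %in% names(trace)))
  keep <- trace$rt >= ref$rt_center - ref$rt_tol &
    trace$rt <= ref$rt_center + ref$rt_tol &
    trace$mz %in% ref$ions
  slice <- stats::setNames(rep(0, length(ref$ions)), ref$ions)
  empty <- !any(trace$rt >= ref$rt_center - ref$rt_tol &
                  trace$rt <= ref$rt_center + ref$rt_tol)
  if (any(keep)) {
    sums <- tapply(trace$intensity[keep], as.character(trace$mz[keep]), sum)
    slice[names(sums)] <- sums
  }
  list(intensity = slice, empty_window = empty)
}

#' Qualifier codes for a diagnostic-ion pattern
#'
#' Classifies the relative intensities of the diagnostic ions 80, 84 and
#' 126 with the qualifier codes used when reporting coniine screening:
#' \describe{
#'   \item{G_proportions_ok}{80/84 and 126/84 each within `rel_tol`
#'     relative error of the reference ratios — the confirmatory pattern.}
#'   \item{H_80_gt_84}{intensity of 80 exceeds 84.}
#'   \item{I_equal}{all three ions of (pairwise) equal intensity within
#'     `rel_tol`.}
#'   \item{J_126_dominant}{126 is the most intense of the three.}
#'   \item{F_low_intensity}{some present ion sits below the low-intensity
#'     threshold.}
#' }
#' G excludes H/I/J (a pattern in correct proportions is not additionally
#' called anomalous); F is independent.
#'
#' @param slice result of [extract_window()].
#' @param ref a `coniine_reference`.
#' @param rel_tol relative tolerance for ratio agreement (default 0.30; no
#'   tighter value is defensible for "correct proportions" without an
#'   instrument calibration).
#' @param noise_floor intensity below which an ion counts as absent.
#' @param low_intensity threshold under which a present ion is flagged F.
#' @return Character vector of qualifier codes (possibly empty).
#' @export
classify_pattern <- function(slice, ref, rel_tol = 0.30, noise_floor = 0,
                             low_intensity = noise_floor * 3) {
  stopifnot(rel_tol > 0, rel_tol < 1)
  i80 <- slice$intensity[["80"]]
  i84 <- slice$intensity[["84"]]
  i126 <- slice$intensity[["126"]]
  present <- slice$intensity[as.character(ref$diagnostic)] > noise_floor
  qual <- character(0)
  rel_ok <- function(obs, expd) is.finite(obs) && abs(obs - expd) <= rel_tol * expd
  g <- i84 > noise_floor &&
    rel_ok(i80 / i84, ref$rel[["80"]] / ref$rel[["84"]]) &&
    rel_ok(i126 / i84, ref$rel[["126"]] / ref$rel[["84"]])
  if (g) {
    qual <- "G_proportions_ok"
  } else {
    if (i80 > i84 && i80 > noise_floor) qual <- c(qual, "H_80_gt_84")
    three <- c(i80, i84, i126)
    if (all(three > noise_floor)) {
      eq <- max(three) <= (1 + rel_tol) * min(three)
      if (eq) qual <- c(qual, "I_equal")
    }
    if (i126 > noise_floor && i126 > max(i80, i84)) # strictly the greatest
      qual <- c(qual, "J_126_dominant")
  }
  if (any(present & slice$intensity[as.character(ref$diagnostic)] < low_intensity))
    qual <- c(qual, "F_low_intensity")
  qual
}

#' Rule-based coniine detection call from a SIM window
#'
#' Verdicts: `absent` when no diagnostic ion rises above the noise floor;
#' `ion84_only` when only the base peak m/z 84 is present (an inconclusive
#' observation — 84 alone is compatible with other piperidines);
#' `detected` when 84 plus at least one further diagnostic ion is present,
#' or the full pattern qualifies as G; `detected` is downgraded to `trace`
#' when the strongest diagnostic ion stays below `trace_threshold`
#' (calibrated against the generator's spiked dilution series; on real
#' data it must be re-calibrated to the instrument's limit of detection).
#'
#' @param slice result of [extract_window()].
#' @param ref a `coniine_reference`.
#' @param thresholds list with `noise_floor`, `trace` and optionally
#'   `low_intensity`; see [sim_thresholds()] for the defaults.
#' @return An object of class `detection_call`: list with `verdict`,
#'   `qualifiers`, `present` (per diagnostic ion), `intensity`.
#' @export
detect_coniine <- function(slice, ref, thresholds = sim_thresholds()) {
  nf <- thresholds$noise_floor
  qual <- classify_pattern(slice, ref, noise_floor = nf,
                           low_intensity = thresholds$low_intensity)
  diag_int <- slice$intensity[as.character(ref$diagnostic)]
  present <- diag_int > nf
  verdict <- if (!any(present)) {
    "absent"
  } else if (present[["84"]] && sum(present) == 1) {
    "ion84_only"
  } else if (present[["84"]] || "G_proportions_ok" %in% qual) {
    "detected"
  } else {
    # diagnostic ions without the base peak: inconclusive, keep as trace
    "trace"
  }
  if (verdict == "detected" && max(diag_int) < thresholds$trace)
    verdict <- "trace"
  structure(list(verdict = verdict, qualifiers = qual, present = present,
                 intensity = slice$intensity),
            class = "detection_call")
}

#' Default SIM detection thresholds
#'
#' Calibrated against [simulate_sim_trace()]'s intensity scale, where an
#' `amount` of 1 corresponds to the limit of detection: an amount-1 peak
#' is called `trace`, amounts of ~2 and above are called `detected`, and
#' pure noise is `absent`.
#'
#' @return List with `noise_floor`, `trace`, `low_intensity`.
#' @export
sim_thresholds <- function() {
  list(noise_floor = 200, trace = 12000, low_intensity = 500)
}

#' @export
print.detection_call <- function(x, ...) {
  cat(sprintf("detection_call: %s%s\n", x$verdict,
              if (length(x$qualifiers))
                paste0(" [", paste(x$qualifiers, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Species-level coniine detection summary
#'
#' A species counts as coniine-positive if any of its accessions or
#' tissues yields a `detected` or `trace` verdict. Infraspecific taxa are
#' grouped under the parent binomial (genus + species epithet); `NA`
#' verdicts (tissue not analysed) are ignored.
#'
#' @param calls data frame with columns `species` (full name, possibly
#'   with infraspecific parts), `tissue`, `verdict`.
#' @return List with `n_positive_species` and a data frame `per_species`
#'   (`species`, `n_calls`, `positive`).
#' @export
species_detection_summary <- function(calls) {
  stopifnot(all(c("species", "verdict") %in% names(calls)))
  calls <- calls[!is.na(calls$verdict), , drop = FALSE]
  binomial <- vapply(strsplit(trimws(calls$species), "\\s+"),
                     function(w) paste(w[seq_len(min(2, length(w)))],
                                       collapse = " "), "")
  pos <- calls$verdict %in% c("detected", "trace")
  per <- data.frame(species = sort(unique(binomial)))
  per$n_calls <- vapply(per$species, function(s) sum(binomial == s), 0L)
  per$positive <- vapply(per$species, function(s) any(pos[binomial == s]),
                         FALSE)
  list(n_positive_species = sum(per$positive), per_species = per)
}

#' Published SIM screening marks for coniine
#'
#' The printed per-accession lid/pitcher detection marks from the targeted
#' coniine SIM screen of 17 Sarracenia accessions, transcribed as packaged
#' data: `x` detected, `x*` trace (close to the 1 ug/ml limit of
#' detection), `-` not detected, empty = tissue not analysed.
#'
#' @param as_verdicts if `TRUE`, return a long data frame with columns
#'   `species`, `tissue`, `verdict` suitable for
#'   [species_detection_summary()].
#' @return Data frame.
#' @export
coniine_detection_marks <- function(as_verdicts = FALSE) {
  df <- utils::read.delim(system.file("extdata",
                                      "coniine_sim_detection_marks.tsv",
                                      package = "sarrachem"),
                          colClasses = "character", na.strings = "")
  if (!as_verdicts) return(df)
  to_verdict <- function(m)
    ifelse(is.na(m), NA_character_,
           ifelse(m == "x", "detected",
                  ifelse(m == "x*", "trace", "absent")))
  rbind(
    data.frame(species = df$species, tissue = "lid",
               verdict = to_verdict(df$lid)),
    data.frame(species = df$species, tissue = "pitcher",
               verdict = to_verdict(df$pitcher))
  )
}
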