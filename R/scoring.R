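# Sample-level scoring: aggregate nucleus records into per-marker scores,
# apply the assay's quality-control gates, and call HRR status at the 10%
# RAD51-score cutoff.

#' Quality-control policy for sample scoring
#'
#' A sample is evaluable only with at least `min_geminin_cells`
#' geminin-positive cells and a gamma-H2AX score of at least
#' `min_gh2ax_score` percent (evidence of sufficient endogenous DNA damage).
#' Scoring targets the first `target_cells` geminin-positive cells drawn
#' from at least `min_areas` representative areas; too few areas is a
#' warning by default (`areas_hard_fail = TRUE` turns it into an exclusion).
#'
#' @param min_geminin_cells minimum geminin-positive cells (default 40).
#' @param min_gh2ax_score minimum gamma-H2AX score in percent (default 25).
#' @param min_areas minimum representative areas (default 3).
#' @param target_cells geminin-positive cells scored per sample (default 100).
#' @param areas_hard_fail treat too few areas as an exclusion.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_geminin_cells = 40, min_gh2ax_score = 25,
                      min_areas = 3, target_cells = 100,
                      areas_hard_fail = FALSE) {
  stopifnot(min_geminin_cells > 0, min_gh2ax_score > 0, min_areas > 0,
            target_cells > 0)
  structure(list(min_geminin_cells = min_geminin_cells,
                 min_gh2ax_score = min_gh2ax_score, min_areas = min_areas,
                 target_cells = target_cells,
                 areas_hard_fail = areas_hard_fail),
            class = "qc_policy")
}

# Geminin-positive records in canonical scoring order.
scored_subset <- function(records, policy) {
  g <- records[records$geminin %in% TRUE, , drop = FALSE]
  g <- g[order(g$area_id, g$field_id, g$nucleus_id), , drop = FALSE]
  head(g, policy$target_cells)
}

#' Compute one marker's score for a sample
#'
#' The score is the percentage of scored geminin-positive cells that are
#' focus-positive for the marker (>= 5 in-band foci by default, carried in
#' the `<marker>_pos` column). Geminin-positive records are ordered by
#' (area_id, field_id, nucleus_id) and the first `target_cells` form the
#' denominator; with fewer available, all of them are used.
#'
#' @param records nucleus records for one sample (see [quantify_field()]).
#' @param marker marker name, e.g. `"RAD51"`.
#' @param policy a [qc_policy()].
#' @return list(`score` in percent or `NA` when no geminin-positive cell is
#'   available, `n` = denominator used).
#' @export
compute_marker_score <- function(records, marker, policy = qc_policy()) {
  col <- paste0(marker, "_pos")
  if (!col %in% names(records))
    abort(sprintf("marker '%s' absent from records", marker))
  g <- scored_subset(records, policy)
  if (!nrow(g)) return(list(score = NA_real_, n = 0L))
  list(score = 100 * mean(g[[col]]), n = nrow(g))
}

#' Apply the scoring quality-control gates
#'
#' Gates are checked in order — geminin-positive cell count, gamma-H2AX
#' score, number of areas — and the first failure is reported. An absent
#' (`NA`) gamma-H2AX score skips that gate.
#'
#' @param n_geminin geminin-positive cells available.
#' @param gh2ax_score gamma-H2AX score in percent (may be `NA`).
#' @param n_areas number of representative areas scored.
#' @param policy a [qc_policy()].
#' @return list(`status` one of `"evaluable"`, `"fail_geminin_count"`,
#'   `"fail_gh2ax"`, `"fail_areas"`; `warnings` character vector).
#' @export
apply_qc <- function(n_geminin, gh2ax_score = NA, n_areas = Inf,
                     policy = qc_policy()) {
  warn <- character()
  if (n_geminin < policy$min_geminin_cells)
    return(list(status = "fail_geminin_count", warnings = warn))
  if (!is.na(gh2ax_score) && gh2ax_score < policy$min_gh2ax_score)
    return(list(status = "fail_gh2ax", warnings = warn))
  if (n_areas < policy$min_areas) {
    if (policy$areas_hard_fail)
      return(list(status = "fail_areas", warnings = warn))
    warn <- sprintf("only %d area(s) scored (< %d recommended)",
                    n_areas, policy$min_areas)
  }
  list(status = "evaluable", warnings = warn)
}

#' Call HRR status from a RAD51 score
#'
#' @param rad51_score RAD51 score in percent, from an evaluable sample.
#' @param cutoff cutoff in percent (default 10); scores at or below the
#'   cutoff are HRR-deficient (the cutoff is inclusive).
#' @return `"deficient"` or `"proficient"`.
#' @export
classify_hrr <- function(rad51_score, cutoff = 10) {
  if (length(rad51_score) != 1 || is.na(rad51_score))
    abort("RAD51 score unavailable (sample not evaluable)")
  if (rad51_score <= cutoff) "deficient" else "proficient"
}

#' Score one sample: marker scores, QC verdict and HRR call
#'
#' @param records nucleus records for one sample.
#' @param markers markers to score; the first is the HRR-call marker
#'   (RAD51). Any marker named in `gh2ax_marker` feeds the damage QC gate.
#' @param policy a [qc_policy()].
#' @param cutoff HRR-deficiency cutoff in percent.
#' @param gh2ax_marker name of the gamma-H2AX channel, if scored.
#' @return one-row data.frame: `sample_id`, `n_geminin_cells`, `n_areas`,
#'   one `<marker>_score` column per marker, `qc_status`, `hrr_call`
#'   (`"deficient"`, `"proficient"` or `"not_evaluable"`).
#' @export
score_sample <- function(records, markers = c("RAD51", "gH2AX"),
                         policy = qc_policy(), cutoff = 10,
                         gh2ax_marker = "gH2AX") {
  stopifnot(nrow(records) == 0 || length(unique(records$sample_id)) == 1)
  markers <- markers[paste0(markers, "_pos") %in% names(records)]
  n_gem <- sum(records$geminin %in% TRUE)
  n_areas <- length(unique(records$area_id))
  out <- data.frame(
    sample_id = if (nrow(records)) records$sample_id[1] else NA_character_,
    n_geminin_cells = n_gem, n_areas = n_areas, stringsAsFactors = FALSE)
  for (mk in markers)
    out[[paste0(mk, "_score")]] <- compute_marker_score(records, mk,
                                                        policy)$score
  gh2ax <- if (gh2ax_marker %in% markers)
    out[[paste0(gh2ax_marker, "_score")]] else NA_real_
  qc <- apply_qc(n_gem, gh2ax, n_areas, policy)
  out$qc_status <- qc$status
  for (w in qc$warnings) warning(w, call. = FALSE)
  rad51 <- out[[paste0(markers[1], "_score")]]
  out$hrr_call <- if (qc$status != "evaluable") "not_evaluable"
                  else classify_hrr(rad51, cutoff)
  out
}

#' Score every sample in a nucleus-record table
#'
#' @param records nucleus records from one or more samples.
#' @inheritParams score_sample
#' @return data.frame with one [score_sample()] row per sample.
#' @export
score_samples <- function(records, markers = c("RAD51", "gH2AX"),
                          policy = qc_policy(), cutoff = 10,
                          gh2ax_marker = "gH2AX") {
  out <- lapply(split(records, records$sample_id), score_sample,
                markers = markers, policy = policy, cutoff = cutoff,
                gh2ax_marker = gh2ax_marker)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id), , drop = FALSE]
}
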