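#' Union of per-treatment distribution masks
#'
#' Voxel-wise OR of the per-infusion Vd masks after nearest-neighbour
#' resampling onto the baseline lattice, giving the per-patient total
#' distribution volume (overlapping treatments are not double-counted).
#'
#' @param masks Nonempty list of [binary_mask()]s.
#' @param reference_lattice [image_volume()] or [binary_mask()] defining
#'   the output lattice; defaults to the first mask's lattice.
#' @return A [binary_mask()] on the reference lattice.
#' @export
union_vd <- function(masks, reference_lattice = NULL) {
  if (length(masks) == 0) abort("union_vd: empty mask list")
  ref <- reference_lattice %||% masks[[1]]
  identity_tr <- rigid_transform(diag(3), c(0, 0, 0))
  acc <- array(FALSE, dim = dim(ref$voxels))
  for (m in masks) {
    mm <- if (same_lattice(m, ref)) m else resample_image(m, identity_tr, ref, method = "nearest")
    acc <- acc | mm$voxels
  }
  binary_mask(acc, spacing_mm = ref$spacing_mm, origin_mm = ref$origin_mm)
}

#' Tumor coverage percentage
#'
#' @param tumor_covered_cm3 Tumor volume overlapped by the union of
#'   distribution masks, cm^3.
#' @param tumor_volume_cm3 Baseline tumor volume, cm^3 (> 0).
#' @return `100 * covered / tumor` at full precision (round with
#'   [round_half_up()] for presentation).
#' @examples
#' coverage_percent(7.5, 45.1)
#' @export
coverage_percent <- function(tumor_covered_cm3, tumor_volume_cm3) {
  if (isTRUE(any(tumor_volume_cm3 <= 0, na.rm = TRUE))) {
    abort("coverage_percent: tumor volume must be positive")
  }
  if (isTRUE(any(tumor_covered_cm3 < 0, na.rm = TRUE)) ||
      isTRUE(any(tumor_covered_cm3 > tumor_volume_cm3 + 1e-9, na.rm = TRUE))) {
    abort("coverage_percent: covered volume must lie in [0, tumor volume]")
  }
  100 * tumor_covered_cm3 / tumor_volume_cm3
}

#' Convection efficiency Vd/Vi
#'
#' Ratio of the tracer distribution volume to the infused volume
#' (cm^3 and mL are the same physical unit).
#'
#' @param vd_cm3 Distribution volume, cm^3.
#' @param vi_mL Infusion volume, mL (> 0).
#' @return `vd_cm3 / vi_mL`.
#' @export
vd_vi_ratio <- function(vd_cm3, vi_mL) {
  if (any(vi_mL <= 0)) abort("vd_vi_ratio: infusion volume must be positive")
  if (any(vd_cm3 < 0)) abort("vd_vi_ratio: Vd must be nonnegative")
  vd_cm3 / vi_mL
}

#' Mean and standard deviation of a cohort metric
#'
#' Published cohort tables mix the sample (n-1) and population (n)
#' standard-deviation conventions, so both are returned; the mean is the
#' quantity of record.
#'
#' @param values Numeric vector (length >= 2 for a defined sd).
#' @return One-row tibble: `n`, `mean`, `sd` (sample), `sd_population`.
#' @export
cohort_summary <- function(values) {
  if (length(values) == 0) abort("cohort_summary: empty value list")
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) >= 2) sd_sample(values) else NA_real_,
         sd_population = sd_population(values))
}

#' Per-patient coverage from masks
#'
#' Mask-based route: unions the per-treatment Vd masks on the tumor
#' lattice and intersects with the tumor mask.
#'
#' @param subject_id Identifier.
#' @param tumor_mask [binary_mask()] of the baseline tumor.
#' @param vd_masks List of per-treatment [binary_mask()]s.
#' @return One-row tibble with the `patient_coverage` schema:
#'   `subject_id`, `tumor_volume_cm3`, `total_vd_cm3`,
#'   `tumor_covered_cm3`, `coverage_percent`, `outside_tumor_cm3`.
#' @export
patient_coverage <- function(subject_id, tumor_mask, vd_masks) {
  total <- union_vd(vd_masks, reference_lattice = tumor_mask)
  covered <- binary_mask(total$voxels & tumor_mask$voxels,
                         spacing_mm = tumor_mask$spacing_mm,
                         origin_mm = tumor_mask$origin_mm)
  tumor_cm3 <- mask_volume_cm3(tumor_mask)
  total_cm3 <- mask_volume_cm3(total)
  covered_cm3 <- mask_volume_cm3(covered)
  tibble(subject_id = subject_id, tumor_volume_cm3 = tumor_cm3,
         total_vd_cm3 = total_cm3, tumor_covered_cm3 = covered_cm3,
         coverage_percent = coverage_percent(covered_cm3, tumor_cm3),
         outside_tumor_cm3 = total_cm3 - covered_cm3)
}

#' Build the per-patient coverage table and cohort summary
#'
#' Tabular route: takes the per-infusion records (one row per CED
#' treatment, with the per-patient totals carried on each subject's
#' first row, as in the published table) and assembles one
#' `patient_coverage` row per subject plus a cohort summary block with
#' mean/sd of tumor volume, per-infusion Vd, coverage percentage,
#' first-infusion Vd/Vi, outside-tumor volume and infusion duration.
#'
#' The cohort Vd/Vi statistic is computed over each patient's first CED
#' treatment by default (`vd_vi_basis = "first_infusion"`): the first
#' infusion is the only one whose distribution volume is attributable to
#' a single treatment, later unions overlap. The alternative bases
#' (all infusions, or per-patient total Vd over total Vi) are exposed as
#' options.
#'
#' @param records Tibble with columns `subject`, `ced_number`, `vi_mL`,
#'   `duration_min`, `tumor_cm3`, `vd_cm3`, and (first row per subject)
#'   `total_vd_cm3`, `covered_cm3` (see [pnoc009_infusions()]).
#' @param vd_vi_basis One of `"first_infusion"`, `"all_infusions"`,
#'   `"per_patient_total"`.
#' @return List of class `coverage_summary`: `patients` (one row per
#'   subject), `summary` (one row per metric), `vd_vi_basis`.
#' @examples
#' cov <- build_coverage_table(pnoc009_infusions())
#' cov$summary
#' @export
build_coverage_table <- function(records,
                                 vd_vi_basis = c("first_infusion", "all_infusions",
                                                 "per_patient_total")) {
  vd_vi_basis <- match.arg(vd_vi_basis)
  needed <- c("subject", "ced_number", "vi_mL", "duration_min", "tumor_cm3",
              "vd_cm3", "total_vd_cm3", "covered_cm3")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste("build_coverage_table: missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!"coverage_pct" %in% names(records)) records$coverage_pct <- NA_real_
  records <- dplyr::arrange(records, .data$subject, .data$ced_number)

  no_tumor <- records %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::summarise(ok = any(is.finite(.data$tumor_cm3)), .groups = "drop") %>%
    dplyr::filter(!.data$ok)
  if (nrow(no_tumor)) {
    abort(paste("build_coverage_table: no tumor volume for subject(s):",
                paste(no_tumor$subject, collapse = ", ")))
  }

  patients <- records %>%
    dplyr::group_by(subject_id = .data$subject) %>%
    dplyr::summarise(
      tumor_volume_cm3 = dplyr::first(.data$tumor_cm3[is.finite(.data$tumor_cm3)]),
      total_vd_cm3 = dplyr::first(.data$total_vd_cm3[is.finite(.data$total_vd_cm3)]),
      tumor_covered_cm3 = dplyr::first(.data$covered_cm3[is.finite(.data$covered_cm3)]),
      coverage_percent_printed = dplyr::first(.data$coverage_pct[is.finite(.data$coverage_pct)]),
      sum_vd_cm3 = sum(.data$vd_cm3),
      first_vd_vi = vd_vi_ratio(.data$vd_cm3[.data$ced_number == min(.data$ced_number)][1],
                                .data$vi_mL[.data$ced_number == min(.data$ced_number)][1]),
      total_vi_mL = sum(.data$vi_mL),
      n_treatments = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      coverage_percent = coverage_percent(.data$tumor_covered_cm3, .data$tumor_volume_cm3),
      outside_tumor_cm3 = .data$total_vd_cm3 - .data$tumor_covered_cm3
    )

  bad <- patients %>%
    dplyr::filter(.data$tumor_covered_cm3 > .data$total_vd_cm3 + 1e-9 |
                    .data$total_vd_cm3 > .data$sum_vd_cm3 + 1e-9 |
                    .data$outside_tumor_cm3 < -1e-9)
  if (nrow(bad)) {
    abort(paste("build_coverage_table: coverage invariants violated for:",
                paste(bad$subject_id, collapse = ", ")))
  }

  vd_vi_values <- switch(
    vd_vi_basis,
    first_infusion = patients$first_vd_vi,
    all_infusions = vd_vi_ratio(records$vd_cm3, records$vi_mL),
    per_patient_total = vd_vi_ratio(patients$total_vd_cm3, patients$total_vi_mL)
  )

  summary <- dplyr::bind_rows(
    dplyr::mutate(cohort_summary(patients$tumor_volume_cm3), metric = "tumor_volume_cm3"),
    dplyr::mutate(cohort_summary(records$vd_cm3), metric = "vd_per_infusion_cm3"),
    dplyr::mutate(cohort_summary(patients$coverage_percent), metric = "coverage_percent"),
    dplyr::mutate(cohort_summary(vd_vi_values), metric = "vd_vi_ratio"),
    dplyr::mutate(cohort_summary(patients$outside_tumor_cm3), metric = "outside_tumor_cm3"),
    dplyr::mutate(cohort_summary(records$duration_min), metric = "infusion_duration_min")
  ) %>%
    dplyr::relocate("metric")

  structure(list(patients = patients, summary = summary,
                 vd_vi_basis = vd_vi_basis,
                 n_treatments = nrow(records)),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary: %d patients, %d treatments, Vd/Vi basis '%s'>\n",
              nrow(x$patients), x$n_treatments, x$vd_vi_basis))
  print(dplyr::mutate(x$summary, dplyr::across(c("mean", "sd", "sd_population"),
                                               ~ round_half_up(.x, 1))))
  invisible(x)
}

#' @rdname build_coverage_table
#' @param x A `coverage_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coverage_summary <- function(x, ...) x$patients

#' @rdname build_coverage_table
#' @exportS3Method generics::glance
glance.coverage_summary <- function(x, ...) {
  wide <- x$summary %>%
    dplyr::select("metric", "mean") %>%
    tidyr::pivot_wider(names_from = "metric", values_from = "mean",
                       names_glue = "mean_{metric}")
  dplyr::mutate(wide, n_patients = nrow(x$patients),
                n_treatments = x$n_treatments,
                max_coverage_percent = max(x$patients$coverage_percent),
                .before = 1)
}
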