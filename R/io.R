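#' Write an image series as NIfTI plus a JSON sidecar
#'
#' The image stack is stored as a single 4-D NIfTI volume
#' (`series.nii.gz`) and the acquisition metadata (kind, TI or TE list in
#' ms, saturation time, water-fat offset, slice geometry) as
#' `series.json` alongside it.
#'
#' @param series an `image_series`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nii <- RNifti::asNifti(series$images,
                         pixdim = c(series$spacing_mm, series$spacing_mm,
                                    series$slice_thickness_mm +
                                      series$interslice_gap_mm, 1))
  RNifti::writeNifti(nii, file.path(dir, "series.nii.gz"))
  meta <- list(kind = series$kind,
               index_ms = series$index_ms,
               tsat_ms = series$tsat_ms,
               delta_f_hz = series$delta_f_hz,
               spacing_mm = series$spacing_mm,
               slice_thickness_mm = series$slice_thickness_mm,
               interslice_gap_mm = series$interslice_gap_mm)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an image series written by [write_series()]
#'
#' Validates that the metadata sidecar is present and consistent: the
#' TI/TE list must match the fourth image dimension and be strictly
#' increasing (volumes stored out of order are reordered by their
#' metadata).
#'
#' @param dir directory containing `series.nii.gz` and `series.json`.
#' @param kind optional expected kind (`"ir"`, `"dixon"`, `"in_opposed"`
#'   or the full kind names); mismatch is an error.
#' @return An `image_series`.
#' @export
read_series <- function(dir, kind = NULL) {
  nii_path <- file.path(dir, "series.nii.gz")
  json_path <- file.path(dir, "series.json")
  if (!file.exists(nii_path)) stop("missing image file: ", nii_path)
  if (!file.exists(json_path)) stop("missing metadata sidecar: ", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (fld in c("kind", "index_ms", "spacing_mm", "slice_thickness_mm",
                "interslice_gap_mm"))
    if (is.null(meta[[fld]])) stop("sidecar is missing field: ", fld)
  img <- array(as.numeric(RNifti::readNifti(nii_path)),
               dim = dim(RNifti::readNifti(nii_path)))
  if (length(dim(img)) == 3) dim(img) <- c(dim(img), 1)
  if (dim(img)[4] != length(meta$index_ms))
    stop("sidecar index_ms length (", length(meta$index_ms),
         ") contradicts the number of volumes (", dim(img)[4], ")")
  ord <- order(meta$index_ms)
  if (is.unsorted(meta$index_ms, strictly = TRUE)) {
    img <- img[, , , ord, drop = FALSE]
    meta$index_ms <- meta$index_ms[ord]
  }
  if (any(duplicated(meta$index_ms)))
    stop("sidecar index_ms contains duplicates")
  if (!is.null(kind)) {
    full <- c(ir = "inversion_recovery", dixon = "multiecho_dixon",
              in_opposed = "in_opposed")
    want <- if (kind %in% names(full)) full[[kind]] else kind
    if (!identical(meta$kind, want))
      stop("series kind is '", meta$kind, "', expected '", want, "'")
  }
  structure(list(images = img, kind = meta$kind, index_ms = meta$index_ms,
                 tsat_ms = meta$tsat_ms %||% NA_real_,
                 delta_f_hz = meta$delta_f_hz %||% NA_real_,
                 spacing_mm = meta$spacing_mm,
                 slice_thickness_mm = meta$slice_thickness_mm,
                 interslice_gap_mm = meta$interslice_gap_mm),
            class = "image_series")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write phantom ground truth (label map + tissue table)
#'
#' @param phantom a [make_phantom()] object.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(phantom$labels),
                     file.path(dir, "labels.nii.gz"))
  utils::write.csv(phantom$tissue_table, file.path(dir, "tissues.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(spacing_mm = phantom$spacing_mm,
         slice_thickness_mm = phantom$slice_thickness_mm,
         interslice_gap_mm = phantom$interslice_gap_mm,
         true_vat_volume_l = phantom$true_vat_volume_l),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# header keyword -> canonical parameter column
cohort_header_patterns <- function() {
  list(
    subject_id = c("subject", "patient", "^id$", "^pat"),
    bmi_kg_m2  = c("bmi"),
    v_vat_l    = c("v[._ ]?vat", "vat.*vol", "vol.*vat"),
    t1_vat_ms  = c("t1[._ ]?vat", "vat[._ ]?t1"),
    t1_sat_ms  = c("t1[._ ]?sat", "sat[._ ]?t1"),
    ff_vat_pct = c("ff[._ ]?vat", "vat[._ ]?ff"),
    ff_sat_pct = c("ff[._ ]?sat", "sat[._ ]?ff")
  )
}

map_header <- function(nm) {
  pats <- cohort_header_patterns()
  low <- tolower(nm)
  for (canon in names(pats))
    for (p in pats[[canon]])
      if (grepl(p, low)) return(canon)
  NA_character_
}

#' Read a per-subject cohort table (CSV or xlsx)
#'
#' Column headers are auto-mapped to the canonical parameter names by
#' keyword (BMI, VAT volume, T1/FF in VAT/SAT, subject id, timepoint).
#' Two layouts are accepted: long (a `timepoint` column with M0/M1 rows)
#' and wide (paired `<param>_m0` / `<param>_m1` columns). Unmappable or
#' incomplete tables fail with an explicit message.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @return Long-format data.frame as produced by [make_cohort()].
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package")
      as.data.frame(readxl::read_excel(path))
    },
    stop("unsupported cohort table format: .", ext))
  nms <- names(raw)
  tp_col <- nms[grepl("time ?point|^tp$|^visit", tolower(nms))][1]
  if (!is.na(tp_col)) {
    # long layout
    mapped <- vapply(nms, map_header, character(1))
    sid_col <- which(mapped == "subject_id")
    if (length(sid_col) == 0)
      stop("no subject-id column recognised in ", path)
    tpv <- toupper(trimws(as.character(raw[[tp_col]])))
    if (!all(tpv %in% c("M0", "M1")))
      stop("timepoint column must contain only M0/M1")
    out <- data.frame(subject_id = raw[[sid_col[1]]], timepoint = tpv)
    for (canon in setdiff(names(cohort_header_patterns()), "subject_id")) {
      j <- which(mapped == canon)
      if (length(j)) out[[canon]] <- as.numeric(raw[[j[1]]])
    }
    found <- intersect(names(cohort_parameters()), names(out))
    if (length(found) == 0)
      stop("no parameter columns recognised in ", path,
           "; headers were: ", paste(nms, collapse = ", "))
    return(as.data.frame(out))
  }
  # wide layout: <something>_m0 / _m1 per parameter
  base <- sub("[._ ]?m[01]$", "", tolower(nms))
  is_m0 <- grepl("m0$", tolower(nms)); is_m1 <- grepl("m1$", tolower(nms))
  if (!any(is_m0) || !any(is_m1))
    stop("could not recognise a long (timepoint column) or wide (_M0/_M1 ",
         "columns) layout in ", path, "; headers were: ",
         paste(nms, collapse = ", "))
  mapped <- vapply(base, map_header, character(1))
  sid_col <- which(mapped == "subject_id" & !is_m0 & !is_m1)
  sid <- if (length(sid_col)) raw[[sid_col[1]]] else seq_len(nrow(raw))
  out0 <- data.frame(subject_id = sid, timepoint = "M0")
  out1 <- data.frame(subject_id = sid, timepoint = "M1")
  found <- character(0)
  for (canon in setdiff(names(cohort_header_patterns()), "subject_id")) {
    j0 <- which(mapped == canon & is_m0); j1 <- which(mapped == canon & is_m1)
    if (length(j0) && length(j1)) {
      out0[[canon]] <- as.numeric(raw[[j0[1]]])
      out1[[canon]] <- as.numeric(raw[[j1[1]]])
      found <- c(found, canon)
    }
  }
  if (length(found) == 0)
    stop("no paired parameter columns recognised in ", path,
         "; headers were: ", paste(nms, collapse = ", "))
  rbind(out0, out1)
}

#' Run the full simulation-to-report pipeline
#'
#' Generates a phantom and cohort, simulates the three acquisition types,
#' fits ROI-level T1 and fat fraction, segments the dual-echo series and
#' computes the visceral fat volume, produces the cohort change report,
#' and writes every artifact plus a manifest with md5 checksums. Fixed
#' seeds give identical manifests.
#'
#' @param out_dir output directory.
#' @param seed master seed for phantom, noise and cohort.
#' @param n_subjects cohort size.
#' @param noise_sigma Rician noise scale.
#' @param phantom_args list of extra arguments to [make_phantom()].
#' @return Invisibly, the manifest (named md5 vector); written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_subjects = 23,
                         noise_sigma = 1.6, phantom_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- do.call(make_phantom, c(list(seed = seed), phantom_args))
  write_phantom(ph, file.path(out_dir, "phantom"))

  ir <- simulate_ir_series(ph, acquisition_spec("inversion_recovery",
                                                noise_sigma = noise_sigma,
                                                seed = seed))
  dx <- simulate_dixon_series(ph, acquisition_spec("multiecho_dixon",
                                                   noise_sigma = noise_sigma,
                                                   seed = seed))
  io <- simulate_in_opposed(ph, acquisition_spec("in_opposed",
                                                 noise_sigma = noise_sigma,
                                                 seed = seed))
  write_series(ir, file.path(out_dir, "ir"))
  write_series(dx, file.path(out_dir, "dixon"))
  write_series(io, file.path(out_dir, "in_opposed"))

  # ROI stats in the first slice's largest VAT blob and the SAT ring
  sl <- 1L
  vat_px <- which(ph$labels[, , sl] == 2L, arr.ind = TRUE) - 1L
  sat_px <- which(ph$labels[, , sl] == 1L, arr.ind = TRUE) - 1L
  roi_vat <- roi(0L, vat_px, "VAT")
  roi_sat <- roi(0L, sat_px, "SAT")
  t1_stats <- list(VAT = roi_t1(ir, roi_vat), SAT = roi_t1(ir, roi_sat))
  ff_stats <- list(VAT = roi_ff(dx, roi_vat), SAT = roi_ff(dx, roi_sat))
  roi_tab <- data.frame(
    tissue = c("VAT", "SAT"),
    mean_t1_ms = c(t1_stats$VAT$mean_t1_ms, t1_stats$SAT$mean_t1_ms),
    cv_t1_pct = c(t1_stats$VAT$cv_pct, t1_stats$SAT$cv_pct),
    mean_ff_pct = c(ff_stats$VAT$mean_ff_pct, ff_stats$SAT$mean_ff_pct))
  utils::write.csv(roi_tab, file.path(out_dir, "roi_stats.csv"),
                   row.names = FALSE)

  cs <- segment_slices(io, seed = seed)
  vol <- total_vat_volume(io, cs)
  utils::write.csv(
    data.frame(slice = seq_along(vol$per_slice_fat_area_cm2) - 1L,
               fat_area_cm2 = vol$per_slice_fat_area_cm2),
    file.path(out_dir, "fat_areas.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(total_vat_volume_l = vol$total_volume_l,
         true_vat_volume_l = ph$true_vat_volume_l),
    file.path(out_dir, "volumetry.json"), auto_unbox = TRUE, digits = NA)

  cohort <- make_cohort(n_subjects, seed = seed)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  summ <- cohort_summary(cohort)
  utils::write.csv(as.data.frame(summ), file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- tools::md5sum(sort(files))
  names(manifest) <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
                         normalizePath(names(manifest)))
  jsonlite::write_json(as.list(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
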