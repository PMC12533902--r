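# Readers and writers for every container: beat tables (headerless CSV,
# label last), record tables (CSV with header + JSON provenance sidecar),
# image sets (PNG + labels CSV), food databases and patient profiles
# (JSON), feature tables and selection scores (CSV), reports (JSON/CSV),
# configurations (YAML). Write/read round-trips are lossless: bit-exact for
# integers, within 1e-12 for floating point.

#' Write a beat table as headerless CSV (label in the last column)
#' @param bt a [beat_table]. @param path output file.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(bt, path) {
  stopifnot(inherits(bt, "beat_table"))
  df <- as.data.frame(cbind(bt$signals, bt$labels))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a headerless beat CSV (one beat per row, integer label last)
#' @param path input file. @param fs sampling frequency of the stored beats.
#' @return A [beat_table].
#' @export
read_beat_csv <- function(path, fs = 125) {
  df <- tryCatch(suppressWarnings(utils::read.csv(path, header = FALSE)),
                 error = function(e) stop_invalid("malformed CSV: ",
                                                  conditionMessage(e)))
  lab <- df[[ncol(df)]]
  if (any(lab != floor(lab)))
    stop_invalid("label column (last) must be integer; offending line ",
                 which(lab != floor(lab))[1])
  beat_table(as.matrix(df[, -ncol(df), drop = FALSE]), as.integer(lab), fs)
}

#' Write a record table as CSV with header (plus provenance sidecar)
#'
#' The target is stored in a `target` column; the provenance map goes to a
#' `<path>.provenance.json` sidecar so the planted-truth annotation follows
#' the data.
#'
#' @param rt a [record_table]. @param path output file.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(rt, path) {
  stopifnot(inherits(rt, "record_table"))
  df <- rt$data
  df$target <- rt$target
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(as.list(rt$provenance),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a record-table CSV written by [write_record_csv()]
#' @param path input file.
#' @return A [record_table] (provenance restored from the sidecar if present).
#' @export
read_record_csv <- function(path) {
  df <- tryCatch(suppressWarnings(utils::read.csv(path, stringsAsFactors = FALSE)),
                 error = function(e) stop_invalid("malformed CSV: ",
                                                  conditionMessage(e)))
  if (!"target" %in% names(df)) stop_invalid("no 'target' column in ", path)
  target <- df$target
  if (any(target != floor(target))) stop_invalid("target must be integer")
  df$target <- NULL
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side))
    unlist(jsonlite::read_json(side, simplifyVector = TRUE))
  else NULL
  record_table(df, as.integer(target), prov)
}

#' Write an image set as PNG files plus a labels CSV
#'
#' Images go to `img_0001.png`, ..., masks (if any) to `msk_0001.png`, and
#' `labels.csv` records the filename/label pairs.
#'
#' @param is an [image_set]. @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(is, dir) {
  stopifnot(inherits(is, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("img_%04d.png", seq_along(is$images))
  for (i in seq_along(is$images))
    png::writePNG(is$images[[i]] / (is$levels - 1L), file.path(dir, files[i]))
  if (!is.null(is$masks))
    for (i in seq_along(is$masks))
      png::writePNG(is$masks[[i]] * 1.0,
                    file.path(dir, sprintf("msk_%04d.png", i)))
  utils::write.csv(data.frame(file = files, label = is$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an image set written by [write_image_set()]
#' @param dir directory. @param levels gray-level count of the stored images.
#' @return An [image_set].
#' @export
read_image_set <- function(dir, levels = 256L) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  images <- lapply(lab$file, function(f) {
    m <- png::readPNG(file.path(dir, f))
    matrix(as.integer(round(m * (levels - 1L))), nrow(m), ncol(m))
  })
  mask_files <- sprintf("msk_%04d.png", seq_along(images))
  masks <- if (all(file.exists(file.path(dir, mask_files))))
    lapply(mask_files, function(f) png::readPNG(file.path(dir, f)) > 0.5)
  else NULL
  image_set(images, lab$label, masks, levels = levels)
}

#' Write / read a food database as JSON
#' @param db a food database. @param path file path.
#' @return `path` invisibly / a `food_db` list.
#' @export
write_food_db <- function(db, path) {
  jsonlite::write_json(lapply(db, function(it)
    list(id = it$id, nutrients = as.list(it$nutrients), cost = it$cost,
         tags = it$tags)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_food_db
#' @export
read_food_db <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(lapply(raw, function(it)
    food_item(it$id, unlist(it$nutrients), it$cost, unlist(it$tags))),
    class = "food_db")
}

#' Write / read a patient profile as JSON
#' @param profile a [patient_profile]. @param path file path.
#' @return `path` invisibly / a [patient_profile].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "patient_profile"))
  jsonlite::write_json(lapply(unclass(profile), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_profile(age = p$age, bmi = p$bmi, risk = p$risk,
                  prefs = list(required = as.character(unlist(p$prefs$required)),
                               forbidden = as.character(unlist(p$prefs$forbidden))),
                  exclusions = as.character(unlist(p$exclusions)),
                  lower = unlist(p$lower), upper = unlist(p$upper),
                  targets = unlist(p$targets), tol = unlist(p$tol),
                  gmax = unlist(p$gmax), risk_weights = unlist(p$risk_weights))
}

#' Write / read a feature table as CSV with header (label column last)
#' @param ft a [feature_table]. @param path file path.
#' @return `path` invisibly / a [feature_table].
#' @export
write_feature_csv <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- as.data.frame(ft$values)
  df$label <- ft$labels
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop_invalid("no 'label' column in ", path)
  lab <- df$label; df$label <- NULL
  feature_table(as.matrix(df), names(df), as.integer(lab))
}

#' Write selection scores as CSV / a report as JSON
#' @param scores a `selection_scores` frame. @param report a
#'   [classification_report()]. @param path file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(format(scores, digits = 17, trim = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
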