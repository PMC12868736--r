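# Reading and writing participant tables, morphometry tables, brain maps
# and result artifacts, with strict schema validation. Canonical on-disk
# dialect is TSV with a header; comma-separated files are autodetected.

.participant_required <- c("participant_id", "group", "pd_diagnosis",
                           "lrrk2_carrier", "age", "sex", "site",
                           "disease_duration")

#' @keywords internal
.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a participant table
#'
#' Reads a delimited text file of participant metadata and validates it
#' against the participant schema: mandatory columns present, unique ids,
#' parseable numeric fields, and the structural invariants
#' `pd_diagnosis = 1` iff the group is a PD group, `lrrk2_carrier = 1` iff
#' the group is a carrier group, and disease duration present iff the
#' participant has a PD diagnosis. Missing disease duration and SAA status
#' are preserved as `NA`, never imputed.
#'
#' @param path Path to a TSV (or CSV) file with a header row.
#' @return A data.frame of typed participant records.
#' @export
read_participants <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(.participant_required, names(df))
  if (length(missing_cols) > 0) {
    stop("participant schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) {
    dup <- df$participant_id[duplicated(df$participant_id)][1]
    stop(sprintf("participant schema error: duplicate participant_id '%s'", dup),
         call. = FALSE)
  }
  for (col in c("pd_diagnosis", "lrrk2_carrier", "age", "disease_duration",
                "tiv", "moca", "updrs3", "prs")) {
    if (!col %in% names(df)) next
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("participant schema error: unparseable value '%s' in column '%s', row %d",
                   df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age) > 0) {
    stop(sprintf("participant schema error: non-positive age in row %d", bad_age[1]),
         call. = FALSE)
  }
  pd_groups <- df$group %in% c("sPD", "LRRK2_PD")
  bad_pd <- which(df$pd_diagnosis != as.integer(pd_groups))
  if (length(bad_pd) > 0) {
    stop(sprintf("participant schema error: pd_diagnosis inconsistent with group in row %d",
                 bad_pd[1]), call. = FALSE)
  }
  bad_dur <- which(df$pd_diagnosis == 1 & is.na(df$disease_duration))
  if (length(bad_dur) > 0) {
    stop(sprintf("participant schema error: missing disease_duration for PD participant in row %d",
                 bad_dur[1]), call. = FALSE)
  }
  bad_dur0 <- which(df$pd_diagnosis == 0 & !is.na(df$disease_duration))
  if (length(bad_dur0) > 0) {
    stop(sprintf("participant schema error: disease_duration present for non-PD participant in row %d",
                 bad_dur0[1]), call. = FALSE)
  }
  df
}

#' Write a participant table as TSV
#'
#' @param participants Participant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.table(participants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide morphometry table
#'
#' Reads a participants x regions table and validates it against a region
#' registry: every registry region must be present exactly once, all values
#' must be positive, and columns are reordered to registry order so that
#' downstream code can rely on a fixed layout.
#'
#' @param path Path to a TSV/CSV file with a `participant_id` column plus
#'   one column per region.
#' @param registry Region registry (default [region_registry()]).
#' @return A data.frame: `participant_id` followed by the 82 region columns
#'   in registry order.
#' @export
read_morphometry <- function(path, registry = region_registry()) {
  assert_that(file.exists(path), paste("file not found:", path))
  validate_registry(registry)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  assert_that("participant_id" %in% names(df),
              "morphometry schema error: missing participant_id column")
  region_cols <- setdiff(names(df), "participant_id")
  absent <- setdiff(registry$name, region_cols)
  extra <- setdiff(region_cols, registry$name)
  if (length(absent) > 0 || length(extra) > 0) {
    stop("morphometry schema error: region columns do not match registry.",
         if (length(absent) > 0) paste0(" Missing: ",
                                        paste(absent, collapse = ", "), "."),
         if (length(extra) > 0) paste0(" Unexpected: ",
                                       paste(extra, collapse = ", "), "."),
         call. = FALSE)
  }
  out <- df[, c("participant_id", registry$name), drop = FALSE]
  vals <- as.matrix(out[, registry$name])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("morphometry schema error: non-positive or missing value in row %d, region '%s'",
                 bad[1], registry$name[bad[2]]), call. = FALSE)
  }
  out
}

#' Write a wide morphometry table as TSV
#' @param morphometry Morphometry data.frame (`participant_id` + regions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(morphometry, path) {
  utils::write.table(morphometry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a brain map
#'
#' A brain map is a named per-region scalar vector with value semantics,
#' the container used for diagnosis-beta maps, preservation maps and
#' regional correlation maps.
#'
#' @param values Named numeric vector (names = region names).
#' @param semantics One of `"beta"`, `"prediction_difference"`,
#'   `"correlation"`, `"r_squared"`, `"other"`.
#' @return A data.frame of class `brain_map` with columns `region`, `value`
#'   and a `semantics` attribute.
#' @export
brain_map <- function(values,
                      semantics = c("beta", "prediction_difference",
                                    "correlation", "r_squared", "other")) {
  semantics <- match.arg(semantics)
  assert_that(is.numeric(values) && !is.null(names(values)),
              "values must be a named numeric vector")
  out <- data.frame(region = names(values), value = as.numeric(values),
                    stringsAsFactors = FALSE)
  attr(out, "semantics") <- semantics
  class(out) <- c("brain_map", "data.frame")
  out
}

#' Write a brain map as a region/value TSV
#' @param map A [brain_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_brain_map <- function(map, path) {
  df <- as.data.frame(map)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a brain map TSV
#' @param path Path to a region/value TSV.
#' @param semantics Value semantics tag to attach.
#' @return A [brain_map()].
#' @export
read_brain_map <- function(path, semantics = "other") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("region", "value") %in% names(df)),
              "brain map file must have region and value columns")
  v <- df$value
  names(v) <- df$region
  brain_map(v, semantics)
}

#' Write result artifacts and a manifest
#'
#' Serializes a named list of artifacts into `outdir`: brain maps as
#' region/value TSV, data.frames as TSV, everything else as JSON. Returns a
#' manifest listing every file written; the manifest itself is written as
#' `manifest.json`.
#'
#' @param outdir Output directory (created if absent).
#' @param artifacts Named list of artifacts.
#' @param meta Optional named list of run metadata (seeds, caliper,
#'   covariates, matched ids, ...) embedded in the manifest.
#' @return The manifest, invisibly (list with `files` and `meta`).
#' @export
write_results <- function(outdir, artifacts, meta = list()) {
  assert_that(length(artifacts) == 0 ||
                (!is.null(names(artifacts)) && all(nzchar(names(artifacts)))),
              "artifacts must be a named list")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(outdir), paste("cannot create output directory:", outdir))
  files <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    if (inherits(a, "brain_map")) {
      f <- file.path(outdir, paste0(nm, ".tsv"))
      write_brain_map(a, f)
    } else if (is.data.frame(a)) {
      f <- file.path(outdir, paste0(nm, ".tsv"))
      utils::write.table(a, f, sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "")
    } else {
      f <- file.path(outdir, paste0(nm, ".json"))
      jsonlite::write_json(a, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
    }
    files <- c(files, basename(f))
  }
  manifest <- list(files = files, meta = meta)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(manifest)
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON; the format is chosen by file extension.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json", call. = FALSE)
  }
}
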