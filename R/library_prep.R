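#' Compound library curation
#'
#' Tools to parse compound libraries (CSV, SMILES, SDF) into a uniform
#' record table and to apply the standard screening-database curation
#' funnel: a molecular-weight window, canonical deduplication and an
#' activity-potency threshold. Each step updates a per-step count report so
#' the curation funnel is auditable.
#'
#' A curated library is a list with elements:
#' \describe{
#'   \item{records}{data.frame with columns \code{id}, \code{smiles},
#'     \code{canonical_key} (canonical SMILES of the desalted, neutralized
#'     parent), \code{mw} (g/mol, average atomic weights, desalted parent),
#'     \code{activity_value} (potency in uM, NA for unannotated drugs),
#'     \code{activity_type} (\code{"IC50"}, \code{"Ki"}, \code{"EC50"} or
#'     \code{"none"}) and \code{source_class}.}
#'   \item{report}{data.frame of per-step record counts.}
#'   \item{rejected}{data.frame of entries dropped at parse time, with
#'     reasons.}
#' }
#'
#' @name library_prep
NULL

.activity_types <- c("IC50", "Ki", "EC50", "none")
.source_classes <- c("PTP1B", "alpha_glucosidase", "PPAR_gamma", "drug")

.new_library <- function(records, report, rejected = NULL) {
  rownames(records) <- NULL
  if (is.null(rejected))
    rejected <- data.frame(id = character(0), reason = character(0))
  structure(list(records = records, report = report, rejected = rejected),
            class = "curated_library")
}

.add_step <- function(lib, step) {
  lib$report <- rbind(lib$report,
                      data.frame(step = step, n_records = nrow(lib$records)))
  lib
}

#' Build a compound library from identifiers and SMILES
#'
#' Computes, per record, the canonical key (canonical SMILES of the largest
#' organic fragment after charge neutralization) and the molecular weight of
#' that desalted parent. Unparsable structures are dropped into the
#' \code{rejected} table, not raised as errors.
#'
#' @param id character vector of compound identifiers.
#' @param smiles character vector of SMILES, same length as \code{id}.
#' @param activity_um numeric potency in micromolar (NA allowed).
#' @param activity_type character, one of \code{"IC50"}, \code{"Ki"},
#'   \code{"EC50"}, \code{"none"}.
#' @param source_class character, one of \code{"PTP1B"},
#'   \code{"alpha_glucosidase"}, \code{"PPAR_gamma"}, \code{"drug"}.
#' @return A \code{curated_library} (uncurated: only parsing applied).
#' @export
compound_library <- function(id, smiles,
                             activity_um = NA_real_,
                             activity_type = "none",
                             source_class = "drug") {
  stopifnot(length(id) == length(smiles))
  n <- length(id)
  if (n == 0L) stop("empty library: no input records")
  activity_um <- rep_len(as.numeric(activity_um), n)
  activity_type <- rep_len(as.character(activity_type), n)
  source_class <- rep_len(as.character(source_class), n)
  bad_type <- !activity_type %in% .activity_types
  if (any(bad_type)) {
    warning("unknown activity_type values set to 'none': ",
            paste(unique(activity_type[bad_type]), collapse = ", "))
    activity_type[bad_type] <- "none"
  }
  if (any(!source_class %in% .source_classes))
    warning("source_class contains values outside the documented set")
  if (any(activity_um < 0, na.rm = TRUE))
    stop("activity_um must be >= 0 where present")

  key <- ob_canonical_smiles(smiles, desalt = TRUE, neutralize = TRUE)
  mw <- ob_molecular_weight(key)
  ok <- !is.na(key) & !is.na(mw) & mw > 0
  rejected <- data.frame(id = as.character(id)[!ok],
                         reason = rep("unparsable structure", sum(!ok)))
  records <- data.frame(id = as.character(id)[ok],
                        smiles = as.character(smiles)[ok],
                        canonical_key = key[ok],
                        mw = mw[ok],
                        activity_value = activity_um[ok],
                        activity_type = activity_type[ok],
                        source_class = source_class[ok])
  if (nrow(records) == 0L) stop("empty library: no parsable records")
  report <- data.frame(step = c("input", "parsed"),
                       n_records = c(n, nrow(records)))
  .new_library(records, report, rejected)
}

#' Parse a compound library file
#'
#' @param path file path.
#' @param format \code{"csv"} (columns \code{id}, \code{smiles}, optional
#'   \code{activity_um}, \code{activity_type}, \code{source_class}),
#'   \code{"smiles"} (whitespace-delimited \code{SMILES id} lines) or
#'   \code{"sdf"} (V2000; molecule title used as id, auto-ids assigned where
#'   missing).
#' @return A \code{curated_library}; unparsable entries are logged in
#'   \code{$rejected}.
#' @export
parse_library <- function(path, format = c("csv", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
      stop("CSV must have columns 'id' and 'smiles'")
    return(compound_library(
      id = df$id, smiles = df$smiles,
      activity_um = if ("activity_um" %in% names(df)) df$activity_um else NA_real_,
      activity_type = if ("activity_type" %in% names(df)) df$activity_type else "none",
      source_class = if ("source_class" %in% names(df)) df$source_class else "drug"))
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty library: no input records")
    parts <- strsplit(lines, "[[:space:]]+")
    smi <- vapply(parts, `[`, "", 1L)
    id <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) >= 2L) paste(p[-1L], collapse = " ") else sprintf("mol%05d", i)
    }, "")
    return(compound_library(id = id, smiles = smi))
  }
  # SDF: convert each molecule to SMILES, then run the common pipeline
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) == 0L) stop("empty library: no input records")
  valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
  ids <- ChemmineR::sdfid(sdfset)
  ids <- trimws(ids)
  need_auto <- is.na(ids) | !nzchar(ids)
  ids[need_auto] <- sprintf("mol%05d", which(need_auto))
  smi <- rep(NA_character_, length(sdfset))
  if (any(valid)) {
    conv <- tryCatch(
      suppressWarnings(ChemmineR::sdf2smiles(sdfset[which(valid)])),
      error = function(e) NULL)
    if (!is.null(conv)) smi[which(valid)] <- as.character(conv)
  }
  ok <- !is.na(smi) & nzchar(smi)
  if (!any(ok)) stop("empty library: no parsable records")
  lib <- compound_library(id = ids[ok], smiles = smi[ok])
  # account for molecules the SDF reader itself rejected
  lib$report$n_records[lib$report$step == "input"] <- length(sdfset)
  if (any(!ok)) {
    lib$rejected <- rbind(
      data.frame(id = ids[!ok], reason = rep("unparsable structure", sum(!ok))),
      lib$rejected)
  }
  lib
}

#' Molecular-weight window filter
#'
#' Retains records with \code{min_mw <= mw <= max_mw} (inclusive bounds).
#'
#' @param lib a \code{curated_library}.
#' @param min_mw,max_mw window bounds in g/mol.
#' @return The filtered library with an updated report.
#' @export
filter_molecular_weight <- function(lib, min_mw = 160, max_mw = 1000) {
  stopifnot(inherits(lib, "curated_library"))
  if (min_mw > max_mw) stop("min_mw must not exceed max_mw")
  keep <- lib$records$mw >= min_mw & lib$records$mw <= max_mw
  lib$records <- lib$records[keep, , drop = FALSE]
  rownames(lib$records) <- NULL
  .add_step(lib, "mw_filter")
}

#' Canonical deduplication
#'
#' Collapses records sharing a canonical key to a single record. Among
#' duplicates carrying activity values the most potent (lowest value) is
#' kept; otherwise the first by input order. Survivors keep input order.
#'
#' @param lib a \code{curated_library}.
#' @return The deduplicated library with an updated report.
#' @export
deduplicate <- function(lib) {
  stopifnot(inherits(lib, "curated_library"))
  rec <- lib$records
  if (nrow(rec) > 1L) {
    keep_idx <- unlist(lapply(split(seq_len(nrow(rec)), rec$canonical_key), function(ix) {
      act <- rec$activity_value[ix]
      if (all(is.na(act))) ix[1L] else ix[which.min(replace(act, is.na(act), Inf))]
    }), use.names = FALSE)
    rec <- rec[sort(keep_idx), , drop = FALSE]
  }
  lib$records <- rec
  rownames(lib$records) <- NULL
  .add_step(lib, "deduplicate")
}

#' Activity-potency threshold filter
#'
#' Removes records whose activity value is strictly greater than
#' \code{threshold} (in micromolar). Records without an activity annotation
#' (e.g. approved drugs) are retained untouched.
#'
#' @param lib a \code{curated_library}.
#' @param threshold potency cutoff in uM.
#' @return The filtered library with an updated report.
#' @export
filter_activity <- function(lib, threshold = 100) {
  stopifnot(inherits(lib, "curated_library"))
  if (threshold < 0) stop("threshold must be non-negative")
  act <- lib$records$activity_value
  keep <- is.na(act) | act <= threshold
  lib$records <- lib$records[keep, , drop = FALSE]
  rownames(lib$records) <- NULL
  .add_step(lib, "activity_filter")
}

#' Full curation funnel
#'
#' Applies, in order, the molecular-weight window, canonical deduplication
#' and the activity threshold.
#'
#' @inheritParams filter_molecular_weight
#' @inheritParams filter_activity
#' @param apply_activity_filter set \code{FALSE} for libraries (approved
#'   drugs) exempt from the potency criterion.
#' @return The curated library.
#' @export
curate_library <- function(lib, min_mw = 160, max_mw = 1000, threshold = 100,
                           apply_activity_filter = TRUE) {
  lib <- filter_molecular_weight(lib, min_mw, max_mw)
  lib <- deduplicate(lib)
  if (apply_activity_filter) lib <- filter_activity(lib, threshold)
  lib
}

#' Write a curated library and its report
#'
#' @param lib a \code{curated_library}.
#' @param file output CSV path for the records.
#' @param report_file optional JSON path for the per-step count report.
#' @return \code{lib}, invisibly.
#' @export
write_library <- function(lib, file, report_file = NULL) {
  stopifnot(inherits(lib, "curated_library"))
  utils::write.csv(lib$records, file, row.names = FALSE)
  if (!is.null(report_file)) {
    counts <- as.list(stats::setNames(lib$report$n_records, lib$report$step))
    jsonlite::write_json(counts, report_file, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(lib)
}

#' @export
print.curated_library <- function(x, ...) {
  cat("Compound library:", nrow(x$records), "records\n")
  if (nrow(x$rejected)) cat("  rejected at parse time:", nrow(x$rejected), "\n")
  cat("Curation report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
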