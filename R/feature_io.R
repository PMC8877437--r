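#' Construct a molecular feature intensity matrix
#'
#' Holds LC-MS feature intensities over samples, cell (x, s) being the
#' intensity of molecular feature x in sample s, together with per-feature
#' precursor m/z and optional retention time.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param mz Numeric vector of precursor m/z (Da), one per feature.
#' @param rt Optional numeric vector of retention times (unit as supplied;
#'   treated as opaque), one per feature.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `mz` and `rt`.
#' @export
intensity_matrix <- function(values, mz, rt = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  if (length(mz) != nrow(values))
    stop("length of 'mz' (", length(mz), ") != number of features (",
         nrow(values), ")")
  if (!is.null(rt) && length(rt) != nrow(values))
    stop("length of 'rt' (", length(rt), ") != number of features (",
         nrow(values), ")")
  .check_nonnegative(values, "intensity")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids")
  structure(list(values = values, mz = as.numeric(mz),
                 rt = if (is.null(rt)) NULL else as.numeric(rt)),
            class = "intensity_matrix")
}

#' Construct a microbial feature count matrix
#'
#' Holds microbial feature abundances over samples: OTU counts
#' (`feature_kind = "taxon"`) or predicted enzyme abundances
#' (`feature_kind = "enzyme"`); presence/absence tables from shotgun data
#' are the same shape with 0/1 values.
#'
#' @param values Numeric matrix, features in rows, samples in columns,
#'   with row/column names as ids.
#' @param feature_kind Either `"taxon"` or `"enzyme"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, feature_kind = c("taxon", "enzyme")) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  .check_nonnegative(values, "count")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids")
  structure(list(values = values, feature_kind = feature_kind),
            class = "count_matrix")
}

.check_nonnegative <- function(values, what) {
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative ", what, " at feature '", rownames(values)[neg[1, 1]],
         "', sample '", colnames(values)[neg[1, 2]], "'")
  }
  invisible(TRUE)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("Intensity matrix:", nrow(x$values), "molecular features x",
      ncol(x$values), "samples\n")
  cat("  m/z range:", paste(signif(range(x$mz), 7), collapse = " - "), "Da\n")
  if (!is.null(x$rt)) cat("  retention time attached\n")
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix (", x$feature_kind, "): ", nrow(x$values),
      " microbial features x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers
#'
#' @param x An `intensity_matrix` or `count_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# ---------------------------------------------------------------------------
# CSV readers/writers.  Layout: first column = feature id; optional columns
# `mz` and `rt`; every remaining column = one sample.  Blank cells encode
# absence and are read as zero (count reported via message).

.read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("feature table needs an id column plus data columns: ", path)
  names(df) <- trimws(names(df))
  df[[1]] <- trimws(df[[1]])
  df
}

.parse_numeric_cols <- function(df, cols, path) {
  ids <- df[[1]]
  n_imputed <- 0L
  out <- matrix(0, nrow(df), length(cols), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    raw <- trimws(df[[cols[j]]])
    blank <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    n_imputed <- n_imputed + sum(blank)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(num))
    if (length(bad) > 0)
      stop("non-numeric cell in '", path, "' at feature '", ids[bad[1]],
           "', column '", cols[j], "': \"", raw[bad[1]], "\"")
    num[blank] <- 0
    out[, j] <- num
  }
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Read a molecular feature intensity matrix from CSV
#'
#' The expected layout has one row per molecular feature and one column per
#' sample; the first column holds feature ids, and a column with precursor
#' m/z (default name `"mz"`) is required. Blank cells are imputed as zero
#' intensity with a reported count. Row and column order are preserved.
#'
#' @param path Path to a UTF-8, comma-delimited CSV file.
#' @param mz_column Name of the precursor m/z column.
#' @param rt_column Optional name of a retention time column; `NULL` if absent.
#' @return An [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path, mz_column = "mz", rt_column = NULL) {
  df <- .read_feature_csv(path)
  if (!mz_column %in% names(df))
    stop("m/z column '", mz_column, "' not found in ", path)
  if (!is.null(rt_column) && !rt_column %in% names(df))
    stop("retention time column '", rt_column, "' not found in ", path)
  mz <- suppressWarnings(as.numeric(df[[mz_column]]))
  if (anyNA(mz)) {
    bad <- df[[1]][which(is.na(mz))[1]]
    stop("unparseable m/z for feature '", bad, "' in ", path)
  }
  rt <- NULL
  if (!is.null(rt_column)) {
    rt <- suppressWarnings(as.numeric(df[[rt_column]]))
    if (anyNA(rt)) stop("unparseable retention time in ", path)
  }
  meta <- c(names(df)[1], mz_column, rt_column)
  samples <- setdiff(names(df), meta)
  if (length(samples) == 0) stop("no sample columns in ", path)
  vals <- .parse_numeric_cols(df, samples, path)
  if (attr(vals, "n_imputed") > 0)
    message("read_intensity_matrix: ", attr(vals, "n_imputed"),
            " blank cell(s) imputed as zero")
  attr(vals, "n_imputed") <- NULL
  intensity_matrix(vals, mz = mz, rt = rt)
}

#' Read a microbial feature count matrix from CSV
#'
#' Same layout as [read_intensity_matrix()] without feature metadata
#' columns: first column = feature id, remaining columns = samples.
#'
#' @param path Path to a CSV file.
#' @param feature_kind `"taxon"` (OTU counts) or `"enzyme"` (predicted
#'   enzyme abundances).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_kind = c("taxon", "enzyme")) {
  feature_kind <- match.arg(feature_kind)
  df <- .read_feature_csv(path)
  samples <- names(df)[-1]
  vals <- .parse_numeric_cols(df, samples, path)
  if (attr(vals, "n_imputed") > 0)
    message("read_count_matrix: ", attr(vals, "n_imputed"),
            " blank cell(s) imputed as zero")
  attr(vals, "n_imputed") <- NULL
  count_matrix(vals, feature_kind = feature_kind)
}

#' Write feature matrices to CSV
#'
#' Inverse of the corresponding readers; `write` then `read` reproduces the
#' object (numeric values to full double precision).
#'
#' @param x An `intensity_matrix` or `count_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(feature_id = rownames(x$values), mz = x$mz,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$rt)) df$rt <- x$rt
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- cbind(data.frame(feature_id = rownames(x$values),
                         stringsAsFactors = FALSE),
              as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Filtering and alignment

#' Drop features observed in fewer than two samples
#'
#' A feature counts as present in a sample when its value is strictly
#' greater than zero. Survivor order is preserved; the result may be empty.
#' The operation is idempotent.
#'
#' @param m An `intensity_matrix` or `count_matrix`.
#' @param min_samples Minimum number of samples a feature must be present in.
#' @return Object of the same class restricted to surviving features.
#' @export
filter_rare_features <- function(m, min_samples = 2) {
  keep <- rowSums(m$values > 0) >= min_samples
  if (inherits(m, "intensity_matrix")) {
    structure(list(values = m$values[keep, , drop = FALSE],
                   mz = m$mz[keep],
                   rt = if (is.null(m$rt)) NULL else m$rt[keep]),
              class = "intensity_matrix")
  } else if (inherits(m, "count_matrix")) {
    structure(list(values = m$values[keep, , drop = FALSE],
                   feature_kind = m$feature_kind),
              class = "count_matrix")
  } else stop("unsupported class: ", paste(class(m), collapse = "/"))
}

#' Restrict two feature matrices to their shared samples
#'
#' Sample ids are matched by exact string equality (ids are whitespace
#' trimmed at read time); both outputs carry exactly the shared samples in
#' a single canonical (sorted) order. Correlation of feature pairs needs at
#' least 3 paired samples, so fewer than 3 shared ids is an error.
#'
#' @param a An `intensity_matrix`.
#' @param b A `count_matrix`.
#' @return A list with elements `molecules` and `microbes`.
#' @export
align_samples <- function(a, b) {
  shared <- sort(intersect(colnames(a$values), colnames(b$values)))
  if (length(shared) < 3)
    stop("only ", length(shared),
         " shared sample id(s); need at least 3 for correlation")
  a$values <- a$values[, shared, drop = FALSE]
  b$values <- b$values[, shared, drop = FALSE]
  list(molecules = a, microbes = b)
}

# ---------------------------------------------------------------------------
# Tandem mass spectra (MGF dialect)

#' Construct a tandem mass spectrum
#'
#' @param spectrum_id Identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z in Da; must be positive.
#' @param peaks Two-column matrix or data.frame of fragment (m/z, intensity);
#'   stored sorted ascending by m/z, intensities must be nonnegative.
#' @param cohort Cohort label, e.g. `"gut"` or `"food"`.
#' @param retention_time Optional retention time.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, peaks, cohort = NA_character_,
                     retention_time = NULL) {
  peaks <- as.matrix(peaks)
  storage.mode(peaks) <- "double"
  if (ncol(peaks) != 2) stop("'peaks' must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0) {
    if (any(peaks[, 2] < 0)) stop("negative peak intensity in '", spectrum_id, "'")
    peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive in '", spectrum_id, "'")
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 retention_time = retention_time,
                 cohort = as.character(cohort),
                 peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Spectrum '", x$spectrum_id, "': precursor m/z ",
      format(x$precursor_mz, digits = 8), ", ", nrow(x$peaks), " peaks",
      if (!is.na(x$cohort)) paste0(", cohort ", x$cohort), "\n", sep = "")
  invisible(x)
}

#' Read tandem mass spectra from an MGF file
#'
#' Parses BEGIN IONS/END IONS blocks; PEPMASS supplies the precursor m/z
#' (a second number on the line, the precursor intensity, is ignored),
#' TITLE the spectrum id (defaulting to `scan_<k>`), RTINSECONDS the
#' retention time. Peaks are returned sorted ascending by fragment m/z.
#' Scans lacking PEPMASS are skipped with a warning; the skip count is
#' available as `attr(result, "n_skipped")`.
#'
#' @param path Path to an MGF file.
#' @param cohort_tag Cohort label applied to every spectrum (e.g. `"gut"`).
#' @return A list of [spectrum()] objects.
#' @export
read_spectra <- function(path, cohort_tag = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin))
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS): ", path)
  out <- vector("list", length(begin))
  n_skipped <- 0L
  for (k in seq_along(begin)) {
    block <- lines[(begin[k] + 1):(end[k] - 1)]
    block <- block[nzchar(block)]
    is_param <- grepl("=", block, fixed = TRUE)
    params <- block[is_param]
    keys <- toupper(sub("=.*$", "", params))
    vals <- sub("^[^=]*=", "", params)
    pep <- vals[keys == "PEPMASS"]
    if (length(pep) == 0) {
      warning("MGF scan ", k, " in ", basename(path),
              " has no PEPMASS; skipped", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    prec <- as.numeric(strsplit(trimws(pep[1]), "[ \t]+")[[1]][1])
    title <- vals[keys == "TITLE"]
    sid <- if (length(title) > 0) trimws(title[1]) else paste0("scan_", k)
    rts <- vals[keys == "RTINSECONDS"]
    rt <- if (length(rts) > 0) as.numeric(rts[1]) else NULL
    peak_lines <- block[!is_param]
    if (length(peak_lines) > 0) {
      fields <- strsplit(peak_lines, "[ \t]+")
      pk <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
    } else pk <- matrix(numeric(0), 0, 2)
    out[[k]] <- spectrum(sid, prec, pk, cohort = cohort_tag,
                         retention_time = rt)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write tandem mass spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(paste0("PEPMASS=", format(s$precursor_mz, digits = 15)), con)
    if (!is.null(s$retention_time))
      writeLines(paste0("RTINSECONDS=", format(s$retention_time, digits = 15)), con)
    if (nrow(s$peaks) > 0)
      writeLines(paste(format(s$peaks[, 1], digits = 15, trim = TRUE),
                       format(s$peaks[, 2], digits = 15, trim = TRUE)), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
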