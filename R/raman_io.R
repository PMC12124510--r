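#' Construct a RamanSpectra object
#'
#' @param intensity numeric matrix, wavenumber x acquisition.
#' @param wavenumbers numeric, strictly increasing grid (cm-1).
#' @param meta data.frame with one row per acquisition and columns
#'   `sample_id`, `location`, `roi`, `point`, `replicate`, `pol_angle_deg`.
#'   Polarization angles are wrapped modulo 180.
#' @param procLog character, provenance of preprocessing steps.
#' @param checkAngles warn when polarization angles fall outside the
#'   standard 0-150 by 30 acquisition scheme (internal reconstructions and
#'   dense synthetic angle scans disable this).
#' @return A [RamanSpectra-class] object.
#' @examples
#' w <- seq(1400, 1800, by = 2)
#' m <- data.frame(sample_id = "s1", location = "CE", roi = 1L, point = 1L,
#'                 replicate = 1L, pol_angle_deg = 0)
#' rs <- RamanSpectra(matrix(rnorm(length(w)), ncol = 1), w, m)
#' @export
RamanSpectra <- function(intensity, wavenumbers, meta,
                         procLog = character(0), checkAngles = TRUE) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == length(wavenumbers))
  meta <- as.data.frame(meta)
  if (nrow(meta) != ncol(intensity))
    stop("meta must have one row per spectrum (column of intensity)")
  miss <- setdiff(.meta_cols, colnames(meta))
  if (length(miss))
    stop("meta is missing columns: ", paste(miss, collapse = ", "))
  meta$pol_angle_deg <- meta$pol_angle_deg %% 180
  odd <- setdiff(unique(meta$pol_angle_deg), .std_angles)
  if (checkAngles && length(odd))
    warning("non-standard polarization angle(s): ",
            paste(format(odd), collapse = ", "))
  if (any(!nzchar(as.character(meta$sample_id))) ||
      any(!nzchar(as.character(meta$location))))
    stop("sample_id and location must be non-empty")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = unname(intensity)),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(meta))
  new("RamanSpectra", se, procLog = procLog)
}

#' @describeIn RamanSpectra Wavenumber grid (cm-1).
#' @param x a `RamanSpectra` object.
#' @export
wavenumbers <- function(x) SummarizedExperiment::rowData(x)$wavenumber

#' @describeIn RamanSpectra Intensity matrix (wavenumber x acquisition).
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn RamanSpectra Acquisition metadata as a data.frame.
#' @export
acquisitionMeta <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn RamanSpectra Polarization angles (degrees, in `[0, 180)`).
#' @export
polAngles <- function(x) SummarizedExperiment::colData(x)$pol_angle_deg

setMethod("show", "RamanSpectra", function(object) {
  w <- wavenumbers(object)
  cat("RamanSpectra:", ncol(object), "spectra on",
      nrow(object), "wavenumbers")
  if (nrow(object))
    cat(sprintf(" [%.1f, %.1f] cm-1", min(w), max(w)))
  cat("\n")
  if (ncol(object)) {
    md <- acquisitionMeta(object)
    cat("  locations:", paste(sort(unique(md$location)), collapse = ", "),
        "| angles:", paste(sort(unique(md$pol_angle_deg)), collapse = ", "),
        "\n")
  }
  if (length(object@procLog))
    cat("  processed:", paste(object@procLog, collapse = " -> "), "\n")
})

.read_xy_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(w) || anyNA(y))
    stop("non-numeric value in ", path)
  list(wavenumber = w, intensity = y)
}

#' Read polarized Raman acquisitions from a manifest
#'
#' The manifest is a CSV with header
#' `file,sample_id,location,roi,point,replicate,pol_angle_deg`; each `file`
#' is a two-column plain-text spectrum (wavenumber, intensity; whitespace or
#' comma delimited, `#` comments allowed) relative to `dataDir`.  All
#' spectra must share one wavenumber grid (use [resampleSpectra()] first
#' otherwise).
#'
#' @param manifest path to the manifest CSV.
#' @param dataDir directory containing the spectrum files.
#' @return A [RamanSpectra-class] object with one column per manifest row.
#' @export
readSpectra <- function(manifest, dataDir = dirname(manifest)) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("file", .meta_cols)
  miss <- setdiff(need, colnames(man))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(man)) stop("manifest is empty")
  key <- do.call(paste, c(man[, c("location", "roi", "point", "replicate",
                                  "pol_angle_deg")], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate acquisition key in manifest row ",
         which(duplicated(key))[1])
  grid <- NULL
  cols <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dataDir, man$file[i])
    if (!file.exists(f))
      stop("manifest row ", i, ": spectrum file not found: ", f)
    xy <- .read_xy_file(f)
    if (any(diff(xy$wavenumber) <= 0))
      stop("manifest row ", i, ": wavenumbers not strictly increasing in ", f)
    if (is.null(grid)) grid <- xy$wavenumber
    else if (length(xy$wavenumber) != length(grid) ||
             any(xy$wavenumber != grid))
      stop("manifest row ", i, ": wavenumber grid differs from first file; ",
           "resample explicitly")
    cols[[i]] <- xy$intensity
  }
  RamanSpectra(do.call(cbind, cols), grid, man[, .meta_cols])
}

#' Write spectra back to two-column text files plus a manifest
#'
#' Inverse of [readSpectra()]: values are printed with full precision
#' (`%.17g`) so a write/read round trip is bit-exact.
#'
#' @param x a [RamanSpectra-class] object.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name written inside `dir`.
#' @return The manifest path, invisibly.
#' @export
writeSpectra <- function(x, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- acquisitionMeta(x)
  w <- wavenumbers(x)
  ints <- intensities(x)
  files <- sprintf("spec_%04d.txt", seq_len(ncol(x)))
  for (i in seq_len(ncol(x))) {
    writeLines(sprintf("%.17g %.17g", w, ints[, i]),
               file.path(dir, files[i]))
  }
  man <- cbind(data.frame(file = files), md[, .meta_cols])
  path <- file.path(dir, manifest)
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Partition spectra by metadata fields
#'
#' @param x a [RamanSpectra-class] object.
#' @param keys character, metadata field names to group by (any of
#'   `sample_id`, `location`, `roi`, `point`, `replicate`, `pol_angle_deg`).
#' @return A named list of `RamanSpectra`, one per observed key combination;
#'   group sizes always sum to `ncol(x)`.
#' @export
groupSpectra <- function(x, keys) {
  bad <- setdiff(keys, .meta_cols)
  if (length(bad))
    stop("unknown metadata key(s): ", paste(bad, collapse = ", "))
  if (ncol(x) == 0) return(structure(list(), names = character(0)))
  md <- acquisitionMeta(x)
  kc <- interaction(md[keys], drop = TRUE, sep = "|", lex.order = TRUE)
  idx <- split(seq_len(ncol(x)), kc)
  lapply(idx, function(i) x[, i])
}

#' Resample spectra onto a new wavenumber grid
#'
#' Linear interpolation; the new grid must lie within the support of the
#' current grid (no extrapolation).
#'
#' @param x a [RamanSpectra-class] object.
#' @param grid numeric, strictly increasing target grid (cm-1).
#' @return A [RamanSpectra-class] object on `grid`.
#' @export
resampleSpectra <- function(x, grid) {
  w <- wavenumbers(x)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < min(w) || max(grid) > max(w))
    stop("target grid extends beyond spectrum support")
  ints <- intensities(x)
  out <- apply(ints, 2, function(y) approx(w, y, xout = grid)$y)
  RamanSpectra(matrix(out, nrow = length(grid)), grid, acquisitionMeta(x),
               procLog = c(x@procLog, "resample"), checkAngles = FALSE)
}
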