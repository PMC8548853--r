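#' Construct a squiggle (one nanopore read's raw signal)
#'
#' A squiggle bundles the raw digitizer readings of a single read with the
#' channel calibration metadata needed to convert them to picoamperes, plus
#' an optional class label.
#'
#' @param read_id Character scalar, unique read identifier.
#' @param raw Integer (or integer-valued numeric) vector of raw DAC readings.
#' @param offset Calibration offset, in DAC units.
#' @param range_pA Calibration range, in picoamperes.
#' @param digitisation Number of DAC quantisation levels; must be positive.
#' @param sampling_rate Sampling frequency in Hz; must be positive.
#' @param label Optional class label (kept as character).
#'
#' @return An object of class `"squiggle"`: a list with the fields above.
#' @examples
#' sq <- squiggle("r1", c(480L, 502L, 497L), offset = 10, range_pA = 1402.882,
#'                digitisation = 8192, sampling_rate = 4000)
#' current_pA(sq)[1:3]
#' @export
squiggle <- function(read_id, raw, offset, range_pA, digitisation,
                     sampling_rate, label = NULL) {
  if (!is.character(read_id) || length(read_id) != 1L || !nzchar(read_id))
    stop("'read_id' must be a non-empty character scalar")
  if (length(raw) < 1L)
    stop("'raw' must be non-empty")
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("'raw' must be finite numeric (DAC counts)")
  if (!is.numeric(digitisation) || digitisation <= 0)
    stop("'digitisation' must be > 0")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be > 0")
  structure(list(read_id = read_id,
                 raw = as.integer(round(raw)),
                 offset = as.numeric(offset),
                 range_pA = as.numeric(range_pA),
                 digitisation = as.numeric(digitisation),
                 sampling_rate = as.numeric(sampling_rate),
                 label = if (is.null(label)) NULL else as.character(label)),
            class = "squiggle")
}

#' @export
print.squiggle <- function(x, ...) {
  cat(sprintf("<squiggle> %s: %d samples @ %g Hz%s\n", x$read_id,
              length(x$raw), x$sampling_rate,
              if (!is.null(x$label)) paste0(", label=", x$label) else ""))
  invisible(x)
}

#' Convert raw DAC readings to picoamperes
#'
#' Applies the standard nanopore channel calibration
#' `pA = (raw + offset) * range / digitisation`.
#'
#' @param raw Numeric vector of raw DAC readings.
#' @param offset,range_pA,digitisation Channel calibration values.
#' @return Numeric vector of currents in pA.
#' @examples
#' dac_to_pa(500, offset = 10, range_pA = 1500, digitisation = 8192)
#' @export
dac_to_pa <- function(raw, offset, range_pA, digitisation) {
  if (!is.numeric(digitisation) || length(digitisation) != 1L ||
      !is.finite(digitisation) || digitisation <= 0)
    stop("'digitisation' must be a positive scalar")
  (as.numeric(raw) + offset) * range_pA / digitisation
}

#' Calibrated current trace of a squiggle
#'
#' @param x A [squiggle()].
#' @return Numeric vector of currents in pA.
#' @export
current_pA <- function(x) {
  stopifnot(inherits(x, "squiggle"))
  dac_to_pa(x$raw, x$offset, x$range_pA, x$digitisation)
}

# channel_id attribute names expected in a FAST5 container
.chan_attrs <- c("digitisation", "offset", "range", "sampling_rate")

.read_chan_attrs <- function(attrs, where) {
  miss <- setdiff(.chan_attrs, names(attrs))
  if (length(miss))
    stop(sprintf("FAST5 format error in '%s': missing channel attribute(s) %s",
                 where, paste(miss, collapse = ", ")))
  lapply(attrs[.chan_attrs], as.numeric)
}

#' Read squiggles from a FAST5 (HDF5) container
#'
#' Supports both the multi-read layout (top-level `read_<id>` groups, each
#' with `Raw/Signal` and a `channel_id` subgroup carrying the calibration
#' attributes) and the single-read layout (`/Raw/Reads/Read_<n>/Signal` with
#' `/UniqueGlobalKey/channel_id`). A `label` attribute on the read group, as
#' written by [write_fast5()], is restored when present. Reads with an empty
#' signal are skipped with a warning; missing calibration attributes are a
#' format error. Reads are returned in lexicographic `read_id` order.
#'
#' @param path Path to an HDF5 file.
#' @return A named list of [squiggle()] objects, sorted by `read_id`.
#' @seealso [write_fast5()]
#' @export
read_fast5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open '%s': no such file", path))
  if (!rhdf5::H5Fis_hdf5(path))
    stop(sprintf("cannot read '%s': not an HDF5 file", path))
  top <- rhdf5::h5ls(path, recursive = FALSE)
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)

  out <- list()
  if ("Raw" %in% top$name) {                      # single-read layout
    cal <- .read_chan_attrs(
      rhdf5::h5readAttributes(fid, "UniqueGlobalKey/channel_id"),
      "UniqueGlobalKey/channel_id")
    reads <- rhdf5::h5ls(rhdf5::H5Gopen(fid, "Raw/Reads"), recursive = FALSE)
    for (nm in reads$name) {
      grp <- paste0("Raw/Reads/", nm)
      ats <- rhdf5::h5readAttributes(fid, grp)
      rid <- if (!is.null(ats$read_id)) as.character(ats$read_id) else nm
      raw <- as.vector(rhdf5::h5read(fid, paste0(grp, "/Signal")))
      if (length(raw) < 1L) { warning(sprintf("read '%s' skipped: empty signal", rid)); next }
      out[[rid]] <- squiggle(rid, raw, cal$offset, cal$range, cal$digitisation,
                             cal$sampling_rate,
                             label = if (is.null(ats$label)) NULL else as.character(ats$label))
    }
  } else {                                        # multi-read layout
    grps <- top$name[top$otype == "H5I_GROUP"]
    for (nm in grps) {
      rid <- sub("^read_", "", nm)
      ats <- rhdf5::h5readAttributes(fid, nm)
      cal <- .read_chan_attrs(
        rhdf5::h5readAttributes(fid, paste0(nm, "/channel_id")),
        paste0(nm, "/channel_id"))
      raw <- as.vector(rhdf5::h5read(fid, paste0(nm, "/Raw/Signal")))
      if (length(raw) < 1L) { warning(sprintf("read '%s' skipped: empty signal", rid)); next }
      out[[rid]] <- squiggle(rid, raw, cal$offset, cal$range, cal$digitisation,
                             cal$sampling_rate,
                             label = if (is.null(ats$label)) NULL else as.character(ats$label))
    }
  }
  out[order(names(out), method = "radix")]
}

#' Write squiggles to a multi-read FAST5 (HDF5) container
#'
#' Writes one `read_<id>` group per squiggle with an integer `Raw/Signal`
#' dataset and a `channel_id` subgroup holding the calibration attributes
#' (`digitisation`, `offset`, `range`, `sampling_rate`). Class labels, when
#' present, are stored as a `label` attribute on the read group so that a
#' round trip through [read_fast5()] is lossless.
#'
#' @param squiggles A non-empty list of [squiggle()] objects with unique ids.
#' @param path Output file path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_fast5 <- function(squiggles, path) {
  if (length(squiggles) == 0L) stop("'squiggles' must be non-empty")
  if (!all(vapply(squiggles, inherits, logical(1), "squiggle")))
    stop("all elements must be squiggle objects")
  ids <- vapply(squiggles, `[[`, character(1), "read_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate read_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (file.exists(path)) unlink(path)
  fid <- rhdf5::H5Fcreate(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (sq in squiggles) {
    gname <- paste0("read_", sq$read_id)
    gid <- rhdf5::H5Gcreate(fid, gname)
    if (!is.null(sq$label))
      rhdf5::h5writeAttribute(sq$label, gid, "label")
    rgid <- rhdf5::H5Gcreate(gid, "Raw")
    rhdf5::h5writeDataset(sq$raw, rgid, "Signal")
    rhdf5::H5Gclose(rgid)
    cid <- rhdf5::H5Gcreate(gid, "channel_id")
    rhdf5::h5writeAttribute(sq$digitisation, cid, "digitisation")
    rhdf5::h5writeAttribute(sq$offset, cid, "offset")
    rhdf5::h5writeAttribute(sq$range_pA, cid, "range")
    rhdf5::h5writeAttribute(sq$sampling_rate, cid, "sampling_rate")
    rhdf5::H5Gclose(cid)
    rhdf5::H5Gclose(gid)
  }
  invisible(path)
}

#' Read or write a read-label manifest
#'
#' The manifest is a 3-column tab-separated table with header
#' `read_id  label  source_file`, mapping every read to its class label and
#' the signal container it lives in.
#'
#' @param path Path to a TSV file.
#' @return For `read_manifest`, a data.frame with columns `read_id`, `label`
#'   and `source_file`; labels are kept as character.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("read_id", "label", "source_file")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  validate_manifest(m[need])
}

#' @param manifest A data.frame with columns `read_id`, `label`, `source_file`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("read_id", "label", "source_file") %in% names(manifest)))
  if (anyDuplicated(manifest$read_id))
    stop("manifest read_ids must be unique")
  if (length(unique(manifest$label)) < 2L)
    stop("manifest must contain at least 2 classes")
  manifest
}
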