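# Spectrum ingestion, normalization, binning and group averaging.

.BIN_MIN <- 39.714
.BIN_MAX <- 3000
.N_BINS <- 2048L

#' Width of one m/z bin
#'
#' 2048 equal-sized windows over [39.714, 3000) give a nominal resolution of
#' about 1.45 Da; the per-bin remainder channel restores sub-bin peak location.
#'
#' @return Bin width in Da.
#' @export
binWidth <- function() (.BIN_MAX - .BIN_MIN) / .N_BINS

# Categorical codebooks for the experimental metadata embeddings. Fixed integer
# enumerations; 0 codes "unknown".
.META_CODEBOOKS <- list(
  glycan_class = c(O = 1L, N = 2L, free = 3L, lipid = 4L),
  ion_mode     = c(negative = 1L, positive = 2L),
  trap         = c(linear = 1L, orbitrap = 2L, amazon = 3L, QTOF = 4L),
  lc_type      = c(PGC = 1L, C18 = 2L, HILIC = 3L),
  modification = c(reduced = 1L, permethylated = 2L, native = 3L, labeled = 4L)
)

#' Encode experimental metadata as integer codes
#'
#' @param glycan_class,ion_mode,trap,lc_type,modification Category names; see
#'   \code{glycrunch:::.META_CODEBOOKS} for the enumerations. Unknown values
#'   code as 0.
#' @return Integer vector of length 5, in the order glycan_class, ion_mode,
#'   trap, lc_type, modification.
#' @export
metaCodes <- function(glycan_class = "O", ion_mode = "negative",
                      trap = "linear", lc_type = "PGC",
                      modification = "reduced") {
  vals <- c(glycan_class = glycan_class, ion_mode = ion_mode, trap = trap,
            lc_type = lc_type, modification = modification)
  out <- integer(5L)
  for (k in seq_along(vals)) {
    code <- .META_CODEBOOKS[[k]][vals[k]]
    out[k] <- if (is.na(code)) 0L else code
  }
  out
}

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z; when more than 1000 peaks are supplied only the
#' 1000 most intense are kept.
#'
#' @param mz,intensity Numeric peak vectors.
#' @param precursor_mz Precursor ion m/z.
#' @param rt Retention time in minutes (\code{NA} when missing).
#' @param meta Integer metadata codes from \code{\link{metaCodes}}.
#' @return A \linkS4class{Spectrum}.
#' @export
spectrum <- function(mz, intensity, precursor_mz, rt = NA_real_,
                     meta = metaCodes()) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1000L) {
    keep <- order(intensity, decreasing = TRUE)[seq_len(1000L)]
    mz <- mz[keep]; intensity <- intensity[keep]
  }
  o <- order(mz)
  new("Spectrum", mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      precursorMz = as.numeric(precursor_mz), rt = as.numeric(rt),
      meta = as.integer(meta))
}

#' Load MS2 spectra from a raw file or peak-list TSV
#'
#' Supported formats: mzML/mzXML (read through the mzR package) and a plain
#' TSV dialect with columns \code{scan_id, precursor_mz, rt_min, mz, intensity}
#' (one row per peak; \code{rt_min} may be \code{NA}). Only MS2-level spectra
#' are returned; per spectrum the 1000 most intense peaks are kept, and spectra
#' eluting before 2 minutes are dropped as noise (spectra with missing
#' retention time are kept).
#'
#' @param path Path to an mzML, mzXML or TSV file.
#' @param meta Metadata codes attached to every spectrum.
#' @param min_rt Minimum retention time in minutes (default 2).
#' @return List of \linkS4class{Spectrum} objects (possibly empty, with a
#'   warning when the file holds no MS2 scans).
#' @export
loadSpectra <- function(path, meta = metaCodes(), min_rt = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    spectra <- .loadSpectraTSV(path, meta)
  } else if (ext %in% c("mzml", "mzxml")) {
    spectra <- .loadSpectraMzML(path, meta)
  } else {
    stop("unsupported spectrum file format: '.", ext,
         "' (expected mzML, mzXML or TSV)", call. = FALSE)
  }
  if (length(spectra) == 0L) {
    warning("no MS2 spectra found in ", path)
    return(list())
  }
  keep <- vapply(spectra, function(s) is.na(s@rt) || s@rt >= min_rt, logical(1))
  spectra[keep]
}

.loadSpectraTSV <- function(path, meta) {
  if (file.size(path) == 0L) return(list())
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "precursor_mz", "rt_min", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("TSV spectrum file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$scan_id), function(scan) {
    spectrum(scan$mz, scan$intensity, scan$precursor_mz[1L],
             rt = scan$rt_min[1L], meta = meta)
  })
}

.loadSpectraMzML <- function(path, meta) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML/mzXML requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2L)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    rt <- hdr$retentionTime[i] / 60  # seconds -> minutes
    spectrum(pk[, 1L], pk[, 2L], hdr$precursorMZ[i], rt = rt, meta = meta)
  })
}

#' Normalize peak intensities to total-ion fractions
#'
#' Divides every intensity by the total intensity of the spectrum, so the
#' intensities sum to 1. Idempotent; an all-zero spectrum is returned unchanged
#' with a warning.
#'
#' @param s A \linkS4class{Spectrum}.
#' @return The normalized \linkS4class{Spectrum}.
#' @export
normalizeIntensities <- function(s) {
  tot <- sum(s@intensity)
  if (length(s@intensity) == 0L) return(s)
  if (tot == 0) {
    warning("spectrum has zero total intensity; left unchanged")
    return(s)
  }
  s@intensity <- s@intensity / tot
  s
}

#' Normalize a retention time
#'
#' Divides by the run's maximum retention time, floored at 30 minutes; missing
#' retention times map to 0.
#'
#' @param rt Retention time(s) in minutes; \code{NA} allowed.
#' @param max_rt Maximum retention time observed in the run.
#' @return Normalized retention time(s) in [0, 1].
#' @export
normalizeRT <- function(rt, max_rt) {
  stopifnot(max_rt >= 0)
  if (any(rt < 0, na.rm = TRUE)) stop("negative retention time", call. = FALSE)
  out <- rt / max(max_rt, 30)
  out[is.na(rt)] <- 0
  pmin(out, 1)
}

#' Bin a spectrum into the fixed 2048-channel representation
#'
#' Intensities are summed into half-open bins
#' \eqn{[39.714 + b w, 39.714 + (b+1) w)} with \eqn{w} = \code{\link{binWidth}};
#' per bin, the remainder channel records the offset of the bin's
#' highest-intensity peak from the left bin edge. Peaks outside [39.714, 3000)
#' are discarded (their count is returned as the \code{"dropped"} attribute).
#' Intensities are normalized first (idempotent for already-normalized input).
#'
#' @param s A \linkS4class{Spectrum}.
#' @param max_rt Maximum retention time of the run, for
#'   \code{\link{normalizeRT}} (default 30).
#' @return A \linkS4class{BinnedSpectrum}.
#' @export
binSpectrum <- function(s, max_rt = 30) {
  s <- suppressWarnings(normalizeIntensities(s))
  w <- binWidth()
  idx <- floor((s@mz - .BIN_MIN) / w)
  inRange <- idx >= 0 & idx < .N_BINS & s@mz >= .BIN_MIN
  dropped <- sum(!inRange)
  idx <- idx[inRange]
  mzIn <- s@mz[inRange]
  intIn <- s@intensity[inRange]
  intensities <- numeric(.N_BINS)
  remainders <- numeric(.N_BINS)
  if (length(idx) > 0L) {
    agg <- rowsum(intIn, idx)
    intensities[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    for (b in unique(idx)) {
      sel <- which(idx == b)
      top <- sel[which.max(intIn[sel])]
      remainders[b + 1L] <- mzIn[top] - (.BIN_MIN + b * w)
    }
    tot <- sum(intensities)
    if (tot > 0) intensities <- intensities / tot
  }
  out <- new("BinnedSpectrum", intensities = intensities,
             remainders = remainders,
             rtNorm = normalizeRT(s@rt, max_rt),
             precursorMz = s@precursorMz, meta = s@meta)
  attr(out, "dropped") <- dropped
  out
}

#' Average a group of co-eluting spectra
#'
#' Operates on the 2048-bin grid, which makes the result independent of peak
#' order and list lengths: the averaged spectrum is the bin-wise mean of the
#' members' binned intensities (renormalized), and the representative "median
#' spectrum" takes the bin-wise median intensity, with each surviving bin's m/z
#' reconstructed as the left bin edge plus the median remainder of the members
#' populating that bin. The precursor m/z of both outputs is the member median.
#'
#' @param group Non-empty list of \linkS4class{Spectrum} objects sharing a
#'   precursor/retention group.
#' @param max_rt Maximum retention time of the run (for rt normalization).
#' @return List with \code{averaged} (\linkS4class{BinnedSpectrum}),
#'   \code{median} (\linkS4class{Spectrum}), \code{precursor_mz} and
#'   \code{rt_window} (range of member retention times, minutes).
#' @export
averageSpectra <- function(group, max_rt = 30) {
  if (length(group) == 0L) stop("empty spectrum group", call. = FALSE)
  binned <- lapply(group, binSpectrum, max_rt = max_rt)
  mats <- vapply(binned, function(b) b@intensities, numeric(.N_BINS))
  rems <- vapply(binned, function(b) b@remainders, numeric(.N_BINS))
  if (is.null(dim(mats))) { mats <- matrix(mats, ncol = 1L); rems <- matrix(rems, ncol = 1L) }
  avg <- rowMeans(mats)
  if (sum(avg) > 0) avg <- avg / sum(avg)
  med <- apply(mats, 1L, stats::median)
  precursor <- stats::median(vapply(group, function(s) s@precursorMz, numeric(1)))
  rts <- vapply(group, function(s) s@rt, numeric(1))
  rtWindow <- if (all(is.na(rts))) c(NA_real_, NA_real_) else range(rts, na.rm = TRUE)
  # averaged remainder: intensity-weighted mean of member remainders per bin
  wsum <- rowSums(mats)
  avgRem <- ifelse(wsum > 0, rowSums(rems * mats) / pmax(wsum, .Machine$double.eps), 0)
  avgBinned <- new("BinnedSpectrum", intensities = avg, remainders = avgRem,
                   rtNorm = normalizeRT(stats::median(rts), max_rt),
                   precursorMz = precursor, meta = group[[1L]]@meta)
  nonEmpty <- which(med > 0)
  w <- binWidth()
  medMz <- vapply(nonEmpty, function(b) {
    members <- which(mats[b, ] > 0)
    .BIN_MIN + (b - 1L) * w + stats::median(rems[b, members])
  }, numeric(1))
  medInt <- med[nonEmpty]
  medianSpec <- spectrum(medMz, medInt / max(sum(medInt), .Machine$double.eps),
                         precursor, rt = stats::median(rts),
                         meta = group[[1L]]@meta)
  list(averaged = avgBinned, median = medianSpec,
       precursor_mz = precursor, rt_window = rtWindow)
}

#' Write spectra to the package's TSV peak-list dialect
#'
#' One row per peak with columns \code{scan_id, precursor_mz, rt_min, mz,
#' intensity}; the format \code{\link{loadSpectra}} reads back.
#'
#' @param spectra List of \linkS4class{Spectrum} objects.
#' @param path Output file path.
#' @return Invisible path.
#' @export
writeSpectraTSV <- function(spectra, path) {
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(scan_id = i, precursor_mz = s@precursorMz, rt_min = s@rt,
               mz = s@mz, intensity = s@intensity)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
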