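#' @import methods
NULL

.LINKAGE_RE <- "^[\u03b1\u03b2?][12]-[1-9?]$"

#' GlycanGraph: a glycan as a rooted labeled tree
#'
#' Nodes are monosaccharides (labels may carry site modifications such as
#' \code{"GlcNAc6S"}); each non-root node is joined to its parent by a glycosidic
#' linkage label such as \code{"β1-3"} or \code{"?1-?"}. The root is the
#' reducing-end residue. Node 1 is always the root; \code{parent} is
#' \code{NA} for the root and \code{linkage[i]} labels the edge
#' \code{parent[i] -> i}.
#'
#' @slot label character vector of monosaccharide labels, one per node.
#' @slot parent integer vector of parent node indices (\code{NA} for the root).
#' @slot linkage character vector of linkage labels (\code{NA} for the root).
#' @slot reduced logical; reducing end reduced to an alditol.
#'
#' @seealso \code{\link{parseIUPAC}}, \code{\link{serializeIUPAC}}
#' @export
setClass("GlycanGraph",
  representation(label = "character", parent = "integer",
                 linkage = "character", reduced = "logical"),
  prototype(label = character(0), parent = integer(0),
            linkage = character(0), reduced = FALSE)
)

setValidity("GlycanGraph", function(object) {
  n <- length(object@label)
  if (n == 0L) return("glycan must have at least one residue")
  if (length(object@parent) != n || length(object@linkage) != n) {
    return("label, parent and linkage must have equal length")
  }
  roots <- which(is.na(object@parent))
  if (length(roots) != 1L) return("exactly one root (NA parent) required")
  if (roots != 1L) return("the root must be node 1")
  if (n > 1L) {
    p <- object@parent[-1L]
    if (any(p < 1L | p > n | p == seq.int(2L, n))) {
      return("parent indices out of range")
    }
    # acyclicity: every node must reach the root
    for (i in seq.int(2L, n)) {
      seen <- logical(n); v <- i
      while (!is.na(v)) {
        if (seen[v]) return("cycle detected")
        seen[v] <- TRUE
        v <- object@parent[v]
      }
    }
    bad <- !grepl(.LINKAGE_RE, object@linkage[-1L])
    if (any(bad)) {
      return(paste0("malformed linkage label: '",
                    object@linkage[-1L][bad][1L], "'"))
    }
  }
  if (!is.na(object@linkage[1L])) return("root must have NA linkage")
  TRUE
})

#' IonSpec: ion mode, adduct and charge state
#'
#' @slot mode "negative" or "positive".
#' @slot charge positive integer.
#' @slot adduct "none", "acetate" or "sodium".
#' @seealso \code{\link{ionSpec}}
#' @export
setClass("IonSpec",
  representation(mode = "character", charge = "integer", adduct = "character"),
  prototype(mode = "negative", charge = 1L, adduct = "none")
)

setValidity("IonSpec", function(object) {
  if (!object@mode %in% c("negative", "positive")) return("invalid mode")
  if (object@charge < 1L) return("charge must be >= 1")
  if (!object@adduct %in% c("none", "acetate", "sodium")) return("invalid adduct")
  if (object@mode == "positive" && object@adduct == "acetate") {
    return("acetate adduct only supported in negative mode")
  }
  TRUE
})

#' Spectrum: one MS/MS scan
#'
#' Peaks are stored sorted by m/z; at most 1000 peaks are retained (highest
#' intensity first when truncating).
#'
#' @slot mz numeric vector of peak m/z values (sorted ascending).
#' @slot intensity non-negative numeric vector, same length.
#' @slot precursorMz precursor ion m/z.
#' @slot rt retention time in minutes (\code{NA} when missing).
#' @slot meta integer codes: glycan_class, ion_mode, trap, lc_type, modification.
#' @seealso \code{\link{spectrum}}, \code{\link{loadSpectra}}
#' @export
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric",
                 precursorMz = "numeric", rt = "numeric", meta = "integer")
)

setValidity("Spectrum", function(object) {
  if (length(object@mz) != length(object@intensity)) {
    return("mz and intensity must have equal length")
  }
  if (length(object@mz) > 1000L) return("at most 1000 peaks per spectrum")
  if (any(object@intensity < 0)) return("intensities must be non-negative")
  if (is.unsorted(object@mz)) return("peaks must be sorted by m/z")
  if (length(object@meta) != 5L) return("meta must hold 5 integer codes")
  TRUE
})

#' BinnedSpectrum: fixed-length model input
#'
#' Intensities summed into 2048 equal-width m/z bins over [39.714, 3000), with a
#' remainder channel giving, per bin, the offset of the bin's highest-intensity
#' peak from the left bin edge.
#'
#' @slot intensities numeric vector, length 2048, summing to 1 (or all zero).
#' @slot remainders numeric vector, length 2048, each in [0, bin width).
#' @slot rtNorm normalized retention time in [0, 1].
#' @slot precursorMz precursor m/z.
#' @slot meta integer codes as in \linkS4class{Spectrum}.
#' @seealso \code{\link{binSpectrum}}
#' @export
setClass("BinnedSpectrum",
  representation(intensities = "numeric", remainders = "numeric",
                 rtNorm = "numeric", precursorMz = "numeric", meta = "integer")
)

setValidity("BinnedSpectrum", function(object) {
  if (length(object@intensities) != 2048L) return("2048 intensity bins required")
  if (length(object@remainders) != 2048L) return("2048 remainder bins required")
  s <- sum(object@intensities)
  if (s > 0 && abs(s - 1) > 1e-6) return("intensities must sum to 1 (or 0)")
  w <- binWidth()
  if (any(object@remainders < 0 | object@remainders >= w)) {
    return("remainders must lie in [0, bin width)")
  }
  if (object@rtNorm < 0 || object@rtNorm > 1) return("rtNorm must be in [0,1]")
  TRUE
})

setMethod("show", "GlycanGraph", function(object) {
  cat("GlycanGraph with", length(object@label), "residues",
      if (object@reduced) "(reduced)\n" else "\n")
  cat("  ", serializeIUPAC(object), "\n", sep = "")
})

setMethod("show", "IonSpec", function(object) {
  cat(ionLabel(object), "\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d peaks, precursor m/z %.4f, rt %s min\n",
              length(object@mz), object@precursorMz,
              if (is.na(object@rt)) "NA" else sprintf("%.2f", object@rt)))
})

setMethod("show", "BinnedSpectrum", function(object) {
  cat(sprintf("BinnedSpectrum: %d non-empty bins, precursor m/z %.4f, rtNorm %.3f\n",
              sum(object@intensities > 0), object@precursorMz, object@rtNorm))
})

#' Render the conventional ion label, e.g. "[M-2H]2-"
#'
#' @param ion An \linkS4class{IonSpec}.
#' @return Character label.
#' @export
ionLabel <- function(ion) {
  z <- ion@charge
  zs <- if (z == 1L) "" else as.character(z)
  ad <- switch(ion@adduct, none = "", acetate = "+CH3COO", sodium = "+Na-H")
  if (ion@mode == "negative") {
    core <- if (ion@adduct == "acetate") paste0("M", ad)
            else paste0("M", ad, "-", if (z > 1L) z else "", "H")
    paste0("[", core, "]", zs, "-")
  } else {
    paste0("[M", ad, "+", if (z > 1L) z else "", "H]", zs, "+")
  }
}

# --- accessors -------------------------------------------------------------

#' Accessors for GlycanGraph and Spectrum objects
#'
#' @param x The object.
#' @return \code{glyLabels}: residue labels; \code{glyParents}: parent indices;
#'   \code{glyLinkages}: linkage labels; \code{glyRoot}: root index;
#'   \code{isReduced}: logical; \code{nResidues}: node count;
#'   \code{glyChildren}: list of child index vectors; \code{glyLeaves}: indices
#'   of terminal residues; \code{peakTable}: two-column matrix of m/z and
#'   intensity.
#' @name accessors
NULL

#' @rdname accessors
#' @export
glyLabels <- function(x) x@label

#' @rdname accessors
#' @export
glyParents <- function(x) x@parent

#' @rdname accessors
#' @export
glyLinkages <- function(x) x@linkage

#' @rdname accessors
#' @export
glyRoot <- function(x) 1L

#' @rdname accessors
#' @export
isReduced <- function(x) x@reduced

#' @rdname accessors
#' @export
nResidues <- function(x) length(x@label)

#' @rdname accessors
#' @export
glyChildren <- function(x) {
  n <- length(x@label)
  kids <- vector("list", n)
  if (n > 1L) {
    for (i in seq.int(2L, n)) kids[[x@parent[i]]] <- c(kids[[x@parent[i]]], i)
  }
  kids
}

#' @rdname accessors
#' @export
glyLeaves <- function(x) {
  n <- length(x@label)
  setdiff(seq_len(n), unique(x@parent[!is.na(x@parent)]))
}

#' @rdname accessors
#' @export
peakTable <- function(x) {
  cbind(mz = x@mz, intensity = x@intensity)
}

#' @rdname accessors
#' @export
precursorMz <- function(x) x@precursorMz

#' @rdname accessors
#' @export
retentionTime <- function(x) x@rt
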