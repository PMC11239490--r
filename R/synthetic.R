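# Synthetic glycan libraries and in-silico fragmented LC-MS/MS spectra.
#
# The simulator samples peaks from the glycan's own theoretical fragment list
# (glycosidic cleavages up to order 2, water-loss satellites), so every
# downstream stage -- annotation, binning, grouping, classification -- can be
# exercised offline against a known ground truth.

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Biosynthetically plausible single-residue extensions per glycan class:
# parent label -> data.frame(child, linkage). Terminal decorations (Fuc,
# sialic acids) are not extended further.
.GROWTH_RULES <- list(
  O = list(
    GalNAc = data.frame(
      child = c("Gal", "GlcNAc", "GlcNAc", "Neu5Ac"),
      linkage = c("b1-3", "b1-6", "b1-3", "a2-6"),
      stringsAsFactors = FALSE),
    Gal = data.frame(
      child = c("Neu5Ac", "Neu5Gc", "Fuc", "GlcNAc"),
      linkage = c("a2-3", "a2-3", "a1-2", "b1-3"),
      stringsAsFactors = FALSE),
    GlcNAc = data.frame(
      child = c("Gal", "Gal", "Fuc"),
      linkage = c("b1-4", "b1-3", "a1-3"),
      stringsAsFactors = FALSE)
  ),
  free = list(
    Glc = data.frame(child = "Gal", linkage = "b1-4", stringsAsFactors = FALSE),
    Gal = data.frame(
      child = c("GlcNAc", "Fuc", "Neu5Ac"),
      linkage = c("b1-3", "a1-2", "a2-3"),
      stringsAsFactors = FALSE),
    GlcNAc = data.frame(
      child = c("Gal", "Fuc"),
      linkage = c("b1-4", "a1-3"),
      stringsAsFactors = FALSE)
  )
)

.CLASS_CORES <- c(O = "GalNAc", free = "Glc")

#' Generate a synthetic glycan library
#'
#' Structures are grown from the class-specific reducing-end core (GalNAc for
#' O-glycans, Glc for free oligosaccharides) by repeated biosynthetically
#' plausible single-monosaccharide additions; at most two children per residue
#' and no two identical child labels on the same residue, so antennae stay
#' mass-distinguishable. All returned structures are distinct by canonical
#' form. Deterministic under \code{seed}.
#'
#' @param n Number of structures (>= 1).
#' @param glycan_class \code{"O"} or \code{"free"}.
#' @param min_size,max_size Residue-count range to draw from (default 3..7).
#' @param reduced Reducing-end alditol flag applied to all structures.
#' @param seed Integer seed (\code{NULL} uses the current RNG state).
#' @return List of \code{n} \linkS4class{GlycanGraph} objects.
#' @export
generateLibrary <- function(n, glycan_class = "O", min_size = 3L,
                            max_size = 7L, reduced = TRUE, seed = NULL) {
  stopifnot(n >= 1L, min_size >= 1L, max_size >= min_size)
  rules <- .GROWTH_RULES[[glycan_class]]
  if (is.null(rules)) {
    stop("no growth rules for glycan class '", glycan_class, "'", call. = FALSE)
  }
  core <- .CLASS_CORES[[glycan_class]]
  .withSeed(seed, {
    out <- list()
    seen <- character(0)
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 200L * n) {
        stop("could not generate ", n, " distinct structures; ",
             "increase max_size", call. = FALSE)
      }
      size <- sample(seq.int(min_size, max_size), 1L)
      label <- core
      parent <- NA_integer_
      linkage <- NA_character_
      while (length(label) < size) {
        kidsOf <- split(seq_along(label)[-1], parent[-1])
        eligible <- which(vapply(seq_along(label), function(v) {
          base <- .splitLabel(label[v])$base
          if (!base %in% names(rules)) return(FALSE)
          ch <- kidsOf[[as.character(v)]]
          length(ch) < 2L
        }, logical(1)))
        if (length(eligible) == 0L) break
        v <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        opts <- rules[[.splitLabel(label[v])$base]]
        ch <- kidsOf[[as.character(v)]]
        if (!is.null(ch)) opts <- opts[!opts$child %in% label[ch], , drop = FALSE]
        if (nrow(opts) == 0L) next
        pick <- opts[sample(nrow(opts), 1L), ]
        label <- c(label, pick$child)
        parent <- c(parent, v)
        lnk <- sub("^a", "\u03b1", sub("^b", "\u03b2", pick$linkage))
        linkage <- c(linkage, lnk)
      }
      if (length(label) < min_size) next
      g <- new("GlycanGraph", label = label, parent = parent,
               linkage = linkage, reduced = reduced)
      key <- serializeIUPAC(g)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- g
      }
    }
    out
  })
}

#' Simulation parameters
#'
#' @param n_noise_peaks Number of uniform decoy peaks per spectrum.
#' @param noise_intensity_frac Decoy intensity as a fraction of the median true
#'   fragment intensity.
#' @param mz_jitter_sd Gaussian m/z jitter of true fragment peaks (Da).
#' @param fragment_keep_prob Probability of observing each theoretical
#'   fragment.
#' @param intensity_model \code{"exponential"} (intensity decays with cleavage
#'   count; single-cleavage ions strongest) or \code{"uniform"}.
#' @param rt_mean,rt_sd Per-glycan elution model: Gaussian mean and sd
#'   (minutes).
#' @return A list of class \code{"SimParams"}.
#' @export
simParams <- function(n_noise_peaks = 5L, noise_intensity_frac = 0.05,
                      mz_jitter_sd = 0.005, fragment_keep_prob = 0.7,
                      intensity_model = c("exponential", "uniform"),
                      rt_mean = 10, rt_sd = 0.1) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(fragment_keep_prob >= 0, fragment_keep_prob <= 1,
            mz_jitter_sd >= 0, noise_intensity_frac >= 0, rt_sd >= 0)
  structure(list(n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_frac = noise_intensity_frac,
                 mz_jitter_sd = mz_jitter_sd,
                 fragment_keep_prob = fragment_keep_prob,
                 intensity_model = intensity_model,
                 rt_mean = rt_mean, rt_sd = rt_sd),
            class = "SimParams")
}

# Theoretical fragment list used by the simulator: singly charged negative-mode
# glycosidic fragments up to two cleavages, with water-loss satellites.
# Memoized per canonical structure.
.SIM_CACHE <- new.env(parent = emptyenv())

simulationFragments <- function(g, mode = "negative") {
  key <- paste(serializeIUPAC(g), g@reduced, mode)
  hit <- .SIM_CACHE[[key]]
  if (!is.null(hit)) return(hit)
  fr <- enumerateFragments(g, ions = list(ionSpec(mode, 1L)),
                           max_cleavages = 2L, allow_cross_ring = FALSE,
                           global_mods = "-H2O")
  # one species per m/z: mass-degenerate fragment assignments (e.g. Z vs
  # Y - H2O) are the same observable peak; keep the minimal-tier representative
  o <- order(fr$n_cleav, nzchar(fr$global_mod), fr$dc_name, method = "radix")
  fr <- fr[o, , drop = FALSE]
  fr <- fr[!duplicated(round(fr$theo_mz, 6L)), , drop = FALSE]
  fr <- fr[order(fr$theo_mz), , drop = FALSE]
  rownames(fr) <- NULL
  .SIM_CACHE[[key]] <- fr
  fr
}

#' Simulate one MS/MS spectrum of a glycan
#'
#' Peaks are the theoretical singly charged glycosidic fragment m/z values of
#' \code{g} (each kept with \code{fragment_keep_prob} and jittered by
#' \code{mz_jitter_sd}) plus uniform decoy peaks. Intensities follow the
#' configured model and are normalized to sum 1. The precursor m/z is the exact
#' [M-H]- (or [M-2H]2- above 1500 Da) of the glycan before jitter; the
#' retention time is drawn from the per-glycan Gaussian.
#'
#' The returned Spectrum carries a \code{"truth"} attribute: a data.frame with
#' one row per peak (\code{mz}, \code{is_decoy}, \code{frag_row},
#' \code{dc_name}) identifying the generating fragment of every non-decoy peak.
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @param params A \code{\link{simParams}} object.
#' @param mode Ion mode (default negative).
#' @param meta Metadata codes for the spectrum.
#' @param seed Integer seed (\code{NULL} uses the current RNG state).
#' @return A \linkS4class{Spectrum}.
#' @export
simulateSpectrum <- function(g, params = simParams(), mode = "negative",
                             meta = metaCodes(), seed = NULL) {
  stopifnot(is(g, "GlycanGraph"), inherits(params, "SimParams"))
  fr <- simulationFragments(g, mode)
  .withSeed(seed, {
    keep <- stats::runif(nrow(fr)) <= params$fragment_keep_prob
    if (!any(keep)) keep[which.max(fr$n_cleav == 1L)] <- TRUE
    fk <- fr[keep, , drop = FALSE]
    base <- switch(params$intensity_model,
      exponential = exp(-1.5 * (fk$n_cleav + (fk$global_mod != ""))),
      uniform = rep(1, nrow(fk)))
    intensity <- base * exp(stats::rnorm(nrow(fk), 0, 0.3))
    mz <- fk$theo_mz + stats::rnorm(nrow(fk), 0, params$mz_jitter_sd)
    truth <- data.frame(mz = mz, is_decoy = FALSE,
                        frag_row = which(keep),
                        dc_name = fk$dc_name, stringsAsFactors = FALSE)
    if (params$n_noise_peaks > 0L) {
      noiseMz <- stats::runif(params$n_noise_peaks, 100,
                              max(fk$theo_mz) + 50)
      noiseInt <- params$noise_intensity_frac * stats::median(intensity) *
        stats::runif(params$n_noise_peaks, 0.2, 1)
      mz <- c(mz, noiseMz)
      intensity <- c(intensity, noiseInt)
      truth <- rbind(truth, data.frame(
        mz = noiseMz, is_decoy = TRUE, frag_row = NA_integer_,
        dc_name = NA_character_, stringsAsFactors = FALSE))
    }
    M <- glycanMass(g)
    z <- if (M > 1500) 2L else 1L
    prec <- ionMz(M, ionSpec(mode, z))
    rt <- stats::rnorm(1L, params$rt_mean, params$rt_sd)
    o <- order(mz)
    s <- spectrum(mz[o], intensity[o] / sum(intensity), prec,
                  rt = max(rt, 0), meta = meta)
    attr(s, "truth") <- truth[o, , drop = FALSE]
    attr(s, "glycan") <- serializeIUPAC(g)
    s
  })
}

#' Simulate a labeled dataset with a sample-level split
#'
#' Spectra are organized into pseudo-samples ("runs"): each run contains one
#' spectrum of every library glycan, all sharing an rt axis on which glycan i
#' elutes around \code{3 + 0.7 i} minutes (plus a small per-run shift), so the
#' precursor/retention grouping logic is exercised. The train/test split
#' assigns whole runs to one side, never splitting a run.
#'
#' @param library List of \linkS4class{GlycanGraph} objects.
#' @param spectra_per_glycan Number of runs (one spectrum per glycan per run).
#' @param params \code{\link{simParams}} noise settings; its \code{rt_mean} is
#'   overridden by the per-glycan elution schedule.
#' @param train_frac Fraction of runs assigned to training (default 0.8).
#' @param mode,meta Passed to \code{\link{simulateSpectrum}}.
#' @param seed Integer seed.
#' @return List with \code{spectra} (list of Spectrum), \code{label} (integer
#'   class index into \code{library}), \code{sample} (run id), \code{split}
#'   ("train"/"test" per spectrum), \code{library}, and a \code{class_balance}
#'   table.
#' @export
makeDataset <- function(library, spectra_per_glycan = 10L,
                        params = simParams(), train_frac = 0.8,
                        mode = "negative", meta = metaCodes(), seed = 1L) {
  stopifnot(length(library) >= 1L, spectra_per_glycan >= 1L)
  nG <- length(library)
  .withSeed(seed, {
    rtSchedule <- 3 + 0.7 * seq_len(nG)
    spectra <- vector("list", nG * spectra_per_glycan)
    label <- integer(length(spectra))
    sampleId <- integer(length(spectra))
    k <- 0L
    for (run in seq_len(spectra_per_glycan)) {
      runShift <- stats::rnorm(1L, 0, 0.05)
      for (i in seq_len(nG)) {
        k <- k + 1L
        p <- params
        p$rt_mean <- rtSchedule[i] + runShift
        spectra[[k]] <- simulateSpectrum(library[[i]], p, mode = mode,
                                         meta = meta)
        label[k] <- i
        sampleId[k] <- run
      }
    }
    nTrain <- max(1L, round(train_frac * spectra_per_glycan))
    trainRuns <- sample(spectra_per_glycan, nTrain)
    split <- ifelse(sampleId %in% trainRuns, "train", "test")
    list(spectra = spectra, label = label, sample = sampleId, split = split,
         library = library,
         class_balance = table(label = label, split = split))
  })
}
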