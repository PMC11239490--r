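# Raw file -> ranked structure table: grouping, prediction, domain filters,
# biosynthetic rescoring, zero-shot extension, abundance estimation.

#' Inference pipeline configuration
#'
#' Defaults follow the reference workflow: 25 initial candidates per spectrum
#' entity, a 0.01 score floor, cross-class candidates kept only above 0.2,
#' precursor groups split at m/z discontinuities larger than 0.5 Da, retention
#' isomers resolved in 0.5-min chunks, logits calibrated by a 1.15 Platt
#' factor, 5 test-time-augmentation rounds, a 0.1 score bonus per observed
#' biosynthetic precursor, and up to 5 reported candidates.
#'
#' @param topk_initial,topk_final Candidate list sizes before/after curation.
#' @param score_floor Minimum candidate score.
#' @param cross_class_override Score above which wrong-class candidates are
#'   kept.
#' @param precursor_gap m/z discontinuity that separates precursor groups (Da).
#' @param rt_chunk Retention-time chunk width (minutes).
#' @param platt_factor Single-parameter Platt scaling divisor for logits.
#' @param tta_rounds Test-time augmentation rounds.
#' @param precursor_bonus Score bonus per distinct observed biosynthetic
#'   precursor.
#' @param mass_tolerance Precursor mass-match tolerance (Da).
#' @param max_charge Maximum charge state considered in mass filters.
#' @return List of class \code{"InferenceConfig"}.
#' @export
inferenceConfig <- function(topk_initial = 25L, score_floor = 0.01,
                            cross_class_override = 0.2, precursor_gap = 0.5,
                            rt_chunk = 0.5, platt_factor = 1.15,
                            tta_rounds = 5L, precursor_bonus = 0.1,
                            topk_final = 5L, mass_tolerance = 0.5,
                            max_charge = 3L) {
  cfg <- list(topk_initial = as.integer(topk_initial),
              score_floor = score_floor,
              cross_class_override = cross_class_override,
              precursor_gap = precursor_gap, rt_chunk = rt_chunk,
              platt_factor = platt_factor, tta_rounds = as.integer(tta_rounds),
              precursor_bonus = precursor_bonus,
              topk_final = as.integer(topk_final),
              mass_tolerance = mass_tolerance,
              max_charge = as.integer(max_charge))
  stopifnot(all(vapply(cfg, function(x) x > 0, logical(1))),
            cfg$topk_final <= cfg$topk_initial)
  structure(cfg, class = "InferenceConfig")
}

#' Group spectra by precursor m/z discontinuities
#'
#' Spectra are sorted by precursor m/z; a new group starts wherever the gap to
#' the previous precursor exceeds \code{gap} (strictly).
#'
#' @param spectra List of \linkS4class{Spectrum} objects.
#' @param gap Discontinuity threshold in Da (default 0.5).
#' @return List of integer index vectors into \code{spectra}.
#' @export
groupPrecursors <- function(spectra, gap = 0.5) {
  if (length(spectra) == 0L) return(list())
  mz <- vapply(spectra, function(s) s@precursorMz, numeric(1))
  o <- order(mz)
  breaks <- c(0L, which(diff(mz[o]) > gap), length(o))
  lapply(seq_len(length(breaks) - 1L), function(i) {
    o[seq.int(breaks[i] + 1L, breaks[i + 1L])]
  })
}

#' Partition a precursor group into retention-time chunks
#'
#' Chunk index is \code{floor(rt / chunk)}; spectra with missing retention time
#' fall into chunk 0. Empty chunks are dropped.
#'
#' @param spectra List of \linkS4class{Spectrum} (one precursor group).
#' @param indices Which elements to partition (default all).
#' @param chunk Chunk width in minutes (default 0.5).
#' @return List of integer index vectors, ordered by chunk.
#' @export
groupRT <- function(spectra, indices = seq_along(spectra), chunk = 0.5) {
  if (length(indices) == 0L) return(list())
  rt <- vapply(indices, function(i) {
    r <- spectra[[i]]@rt
    if (is.na(r)) 0 else r
  }, numeric(1))
  bins <- floor(rt / chunk)
  split(indices, bins)
}

# Glycan class inferred from the reducing-end residue.
glycanClassOf <- function(g) {
  base <- .splitLabel(g@label[1L])$base
  switch(base, GalNAc = "O", GlcNAc = "N", Glc = "free", Gal = "free", "other")
}

#' Diagnostic fragment ions per structural motif
#'
#' Shipped table (inst/extdata/diagnostic_ions.csv) mapping composition motifs
#' to the fragment m/z whose presence corroborates them in negative mode
#' (sialic acid B1 oxocarbenium-type ions, the fucose B1 ion, the bisulfate
#' marker for sulfated glycans).
#'
#' @return data.frame with columns \code{motif}, \code{mz}, \code{tolerance}.
#' @export
diagnosticIons <- function() {
  path <- system.file("extdata", "diagnostic_ions.csv", package = "glycrunch")
  if (!nzchar(path)) path <- "inst/extdata/diagnostic_ions.csv"
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Motifs of a candidate composition that require diagnostic-ion support.
.requiredDiagnostics <- function(comp, diag) {
  need <- character(0)
  if (comp[["Neu5Ac"]] > 0) need <- c(need, "Neu5Ac")
  if (comp[["Neu5Gc"]] > 0) need <- c(need, "Neu5Gc")
  if (comp[["dHex"]] > 0) need <- c(need, "Fuc")
  if (comp[["S"]] > 0) need <- c(need, "sulfate")
  diag[diag$motif %in% need, , drop = FALSE]
}

.hasPeakNear <- function(spec, mz, tol) {
  any(abs(spec@mz - mz) <= tol)
}

# Empty prediction table with the right columns.
.emptyPredictionTable <- function() {
  out <- data.frame(precursor_mz = numeric(0), rt_start = numeric(0),
                    rt_end = numeric(0), charge = integer(0),
                    composition = character(0), evidence = character(0),
                    abundance = numeric(0), stringsAsFactors = FALSE)
  out$candidates <- list()
  out$spectrum <- list()
  class(out) <- c("PredictionTable", "data.frame")
  out
}

.newPredictionRow <- function(precursor_mz, rt_window, candidates, evidence,
                              spectrum = NULL, charge = NA_integer_,
                              composition = NA_character_) {
  out <- data.frame(precursor_mz = precursor_mz, rt_start = rt_window[1],
                    rt_end = rt_window[2], charge = charge,
                    composition = composition, evidence = evidence,
                    abundance = NA_real_, stringsAsFactors = FALSE)
  out$candidates <- list(candidates)
  out$spectrum <- list(spectrum)
  class(out) <- c("PredictionTable", "data.frame")
  out
}

.bindRows <- function(rows) {
  if (length(rows) == 0L) return(.emptyPredictionTable())
  out <- do.call(rbind, rows)
  class(out) <- c("PredictionTable", "data.frame")
  out
}

# Candidate lists are data.frames with columns glycan (canonical string),
# score; glycans are parsed on demand (cached).
.GLYCAN_PARSE_CACHE <- new.env(parent = emptyenv())
.parseCached <- function(iupac, reduced = TRUE) {
  key <- paste0(iupac, "|", reduced)
  hit <- .GLYCAN_PARSE_CACHE[[key]]
  if (is.null(hit)) {
    hit <- parseIUPAC(iupac, reduced = reduced)
    .GLYCAN_PARSE_CACHE[[key]] <- hit
  }
  hit
}

#' Apply domain-knowledge filters to prediction candidates
#'
#' Removes candidates that (1) score below the floor, (2) belong to the wrong
#' glycan class -- unless their score exceeds the cross-class override, since
#' e.g. O-glycan preparations often carry remnant N-glycans, (3) cannot match
#' the precursor mass at any charge state up to \code{max_charge} within the
#' tolerance, or (4) contain a motif whose diagnostic fragment ion is absent
#' from the row's representative spectrum. Rows keep their (possibly empty)
#' filtered candidate lists.
#'
#' @param rows A PredictionTable.
#' @param cfg An \code{\link{inferenceConfig}}.
#' @param expected_class Glycan class of the run ("O", "N", "free").
#' @param mode Ion mode.
#' @param reduced Reducing-end flag of the candidate structures.
#' @param check_diagnostics Apply filter (4) (needs per-row spectra).
#' @return The filtered PredictionTable.
#' @export
applyDomainFilters <- function(rows, cfg = inferenceConfig(),
                               expected_class = "O", mode = "negative",
                               reduced = TRUE, check_diagnostics = TRUE) {
  if (nrow(rows) == 0L) return(rows)
  diag <- diagnosticIons()
  for (r in seq_len(nrow(rows))) {
    cand <- rows$candidates[[r]]
    if (is.null(cand) || nrow(cand) == 0L) next
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      sc <- cand$score[i]
      if (sc < cfg$score_floor) next
      g <- .parseCached(cand$glycan[i], reduced)
      cls <- glycanClassOf(g)
      if (cls != expected_class && sc <= cfg$cross_class_override) next
      comp <- toComposition(g)
      m <- compositionMatch(rows$precursor_mz[r], list(comp),
                            tolerance = cfg$mass_tolerance,
                            max_charge = cfg$max_charge, mode = mode,
                            reduced = reduced)
      if (nrow(m) == 0L) next
      if (check_diagnostics && !is.null(rows$spectrum[[r]])) {
        req <- .requiredDiagnostics(comp, diag)
        ok <- TRUE
        for (k in seq_len(nrow(req))) {
          if (!.hasPeakNear(rows$spectrum[[r]], req$mz[k], req$tolerance[k])) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
      }
      keep[i] <- TRUE
    }
    kept <- cand[keep, , drop = FALSE]
    if (nrow(kept) > 0L && is.na(rows$charge[r])) {
      g1 <- .parseCached(kept$glycan[1L], reduced)
      m1 <- compositionMatch(rows$precursor_mz[r], list(toComposition(g1)),
                             tolerance = cfg$mass_tolerance,
                             max_charge = cfg$max_charge, mode = mode,
                             reduced = reduced)
      if (nrow(m1) > 0L) rows$charge[r] <- m1$charge[1L]
    }
    rows$candidates[[r]] <- kept
  }
  rows
}

#' Biosynthetic rescoring of ranked predictions
#'
#' Every candidate's score gains \code{bonus} for each distinct lower-mass
#' top-1 prediction (from rows whose evidence is in \code{bonus_sources}) that
#' is a biosynthetic precursor of it, i.e. embeds as a rooted subgraph
#' (wildcard linkages honored). Candidates are then re-sorted, scores
#' renormalized to sum 1, and the top \code{topk_final} kept.
#'
#' @param rows A PredictionTable.
#' @param bonus Score bonus per precursor hit (default 0.1).
#' @param topk_final Candidates kept per row after rescoring.
#' @param bonus_sources Evidence categories whose top-1 predictions may donate
#'   bonuses (default "strong").
#' @param reduced Reducing-end flag for parsing.
#' @return The rescored PredictionTable.
#' @export
canonicalizeBiosynthesis <- function(rows, bonus = 0.1, topk_final = 5L,
                                     bonus_sources = "strong",
                                     reduced = TRUE) {
  if (nrow(rows) == 0L) return(rows)
  # pool of top-1 predictions (pre-update), with neutral masses
  pool <- list()
  for (r in seq_len(nrow(rows))) {
    cand <- rows$candidates[[r]]
    if (is.null(cand) || nrow(cand) == 0L) next
    if (!rows$evidence[r] %in% bonus_sources) next
    top <- cand$glycan[which.max(cand$score)]
    g <- .parseCached(top, reduced)
    pool[[length(pool) + 1L]] <- list(iupac = serializeIUPAC(g), g = g,
                                      mass = glycanMass(g))
  }
  poolKey <- vapply(pool, `[[`, character(1), "iupac")
  dedup <- !duplicated(poolKey)
  pool <- pool[dedup]

  # process rows from the largest top-1 mass downward
  rowMass <- vapply(seq_len(nrow(rows)), function(r) {
    cand <- rows$candidates[[r]]
    if (is.null(cand) || nrow(cand) == 0L) return(-Inf)
    max(vapply(cand$glycan, function(s)
      glycanMass(.parseCached(s, reduced)), numeric(1)))
  }, numeric(1))
  for (r in order(-rowMass)) {
    cand <- rows$candidates[[r]]
    if (is.null(cand) || nrow(cand) == 0L) next
    for (i in seq_len(nrow(cand))) {
      g <- .parseCached(cand$glycan[i], reduced)
      m <- glycanMass(g)
      hits <- 0L
      for (p in pool) {
        if (p$mass < m - 1e-6 && p$iupac != serializeIUPAC(g) &&
            subgraphOf(p$g, g, wildcards = TRUE)) {
          hits <- hits + 1L
        }
      }
      cand$score[i] <- cand$score[i] + bonus * hits
    }
    cand <- cand[order(-cand$score), , drop = FALSE]
    cand$score <- cand$score / sum(cand$score)
    rows$candidates[[r]] <- utils::head(cand, topk_final)
  }
  rows
}

#' Estimate relative abundances from precursor (MS1) intensities
#'
#' Each row's abundance is the summed precursor intensity of MS1 features
#' falling inside its precursor tolerance and retention window, normalized so
#' the sample's abundances sum to 1. Without MS1 data all abundances stay
#' missing.
#'
#' @param rows A PredictionTable.
#' @param ms1 data.frame with columns \code{mz}, \code{rt}, \code{intensity},
#'   or \code{NULL}.
#' @param mz_tol Precursor matching tolerance (Da).
#' @return The PredictionTable with an \code{abundance} column filled in.
#' @export
estimateAbundance <- function(rows, ms1 = NULL, mz_tol = 0.5) {
  if (nrow(rows) == 0L || is.null(ms1)) return(rows)
  raw <- vapply(seq_len(nrow(rows)), function(r) {
    sel <- abs(ms1$mz - rows$precursor_mz[r]) <= mz_tol &
      (is.na(rows$rt_start[r]) |
         (ms1$rt >= rows$rt_start[r] - 0.25 & ms1$rt <= rows$rt_end[r] + 0.25))
    sum(ms1$intensity[sel])
  }, numeric(1))
  tot <- sum(raw)
  rows$abundance <- if (tot > 0) raw / tot else NA_real_
  rows
}

# Merge adjacent rows with identical ordered candidate lists and precursors
# within one gap width.
.deduplicateRows <- function(rows, gap = 0.5) {
  if (nrow(rows) <= 1L) return(rows)
  o <- order(rows$precursor_mz, rows$rt_start)
  rows <- rows[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(rows))
  for (r in seq.int(2L, nrow(rows))) {
    prev <- max(which(keep[seq_len(r - 1L)]))
    sameCand <- identical(rows$candidates[[r]]$glycan,
                          rows$candidates[[prev]]$glycan)
    closeMz <- abs(rows$precursor_mz[r] - rows$precursor_mz[prev]) <= gap
    if (sameCand && closeMz && length(rows$candidates[[r]]$glycan) > 0L) {
      keep[r] <- FALSE
      rows$rt_end[prev] <- max(rows$rt_end[prev], rows$rt_end[r], na.rm = TRUE)
      rows$rt_start[prev] <- min(rows$rt_start[prev], rows$rt_start[r],
                                 na.rm = TRUE)
      rows$candidates[[prev]]$score <-
        (rows$candidates[[prev]]$score + rows$candidates[[r]]$score) / 2
    }
  }
  out <- rows[keep, , drop = FALSE]
  class(out) <- c("PredictionTable", "data.frame")
  out
}

#' Zero-shot extension of predictions beyond the model library
#'
#' Three routes add candidates for rows left unexplained by the classifier:
#' (a) biosynthetic-network intermediates of the strong top-1 predictions
#' (iterated leaf deletions) whose mass matches the unexplained precursor at
#' any charge within tolerance, added with evidence \code{"medium"};
#' (b) single Neu5Ac<->Neu5Gc substitutions (16 Da each) of predicted
#' structures and, for O-glycans, GlcNAc<->GlcNAc6S swaps, added with evidence
#' \code{"weak"} when the swapped motif's diagnostic ion is present;
#' (c) reference-library structures whose composition matches the precursor,
#' added with evidence \code{"weak"}. All additions then pass the domain
#' filters.
#'
#' @param rows A PredictionTable (post-filtering).
#' @param reference Optional list of \linkS4class{GlycanGraph} for route (c).
#' @param cfg An \code{\link{inferenceConfig}}.
#' @param expected_class,mode,reduced As in \code{\link{applyDomainFilters}}.
#' @return The extended PredictionTable.
#' @export
zeroShotExtend <- function(rows, reference = NULL, cfg = inferenceConfig(),
                           expected_class = "O", mode = "negative",
                           reduced = TRUE) {
  if (nrow(rows) == 0L) return(rows)
  unexplained <- which(vapply(rows$candidates, function(c)
    is.null(c) || nrow(c) == 0L, logical(1)))
  if (length(unexplained) == 0L) return(rows)
  strongTop <- list()
  for (r in seq_len(nrow(rows))) {
    cand <- rows$candidates[[r]]
    if (!is.null(cand) && nrow(cand) > 0L && rows$evidence[r] == "strong") {
      strongTop[[length(strongTop) + 1L]] <-
        .parseCached(cand$glycan[which.max(cand$score)], reduced)
    }
  }
  # (a) all biosynthetic intermediates of strong top-1s
  intermediates <- list()
  seen <- character(0)
  frontier <- strongTop
  while (length(frontier) > 0L) {
    nxt <- list()
    for (g in frontier) {
      for (p in biosyntheticPrecursors(g)) {
        key <- serializeIUPAC(p)
        if (!key %in% seen) {
          seen <- c(seen, key)
          intermediates[[length(intermediates) + 1L]] <- p
          nxt[[length(nxt) + 1L]] <- p
        }
      }
    }
    frontier <- nxt
  }
  # (b) substitution variants of predicted structures
  variants <- list()
  for (g in strongTop) {
    variants <- c(variants, .substitutionVariants(g, expected_class))
  }
  addCandidates <- function(r, glycans, evidence) {
    hits <- Filter(function(g) {
      nrow(compositionMatch(rows$precursor_mz[r], list(toComposition(g)),
                            tolerance = cfg$mass_tolerance,
                            max_charge = cfg$max_charge, mode = mode,
                            reduced = reduced)) > 0L
    }, glycans)
    if (length(hits) == 0L) return(FALSE)
    iupacs <- unique(vapply(hits, serializeIUPAC, character(1)))
    cand <- data.frame(glycan = iupacs, score = rep(1 / length(iupacs),
                                                    length(iupacs)),
                       stringsAsFactors = FALSE)
    rows$candidates[[r]] <<- cand
    rows$evidence[r] <<- evidence
    TRUE
  }
  for (r in unexplained) {
    done <- addCandidates(r, intermediates, "medium")
    if (!done) done <- addCandidates(r, variants, "weak")
    if (!done && !is.null(reference)) addCandidates(r, reference, "weak")
  }
  # additions must survive the same domain filters (score floor does not
  # apply to uniform zero-shot scores below it only when a single candidate;
  # keep the paper's rule and filter on mass/class/diagnostics)
  cfgZS <- cfg
  cfgZS$score_floor <- min(cfg$score_floor, 1e-9)
  rows <- applyDomainFilters(rows, cfgZS, expected_class = expected_class,
                             mode = mode, reduced = reduced)
  rows$evidence[vapply(rows$candidates, function(c)
    is.null(c) || nrow(c) == 0L, logical(1))] <- NA_character_
  rows
}

# Single-site substitution variants: Neu5Ac <-> Neu5Gc everywhere; for
# O-glycans also GlcNAc <-> GlcNAc6S.
.substitutionVariants <- function(g, expected_class = "O") {
  out <- list()
  swaps <- list(c("Neu5Ac", "Neu5Gc"), c("Neu5Gc", "Neu5Ac"))
  if (expected_class == "O") {
    swaps <- c(swaps, list(c("GlcNAc", "GlcNAc6S"), c("GlcNAc6S", "GlcNAc")))
  }
  for (sw in swaps) {
    at <- which(g@label == sw[1])
    for (v in at) {
      g2 <- g
      g2@label[v] <- sw[2]
      out[[length(out) + 1L]] <- g2
    }
  }
  out
}

#' Cosine-similarity baseline predictor
#'
#' A training-free predictor implementing the same interface as the neural
#' classifier: each library glycan is represented by the binned intensities of
#' its noiseless simulated spectrum, and a query spectrum is scored by cosine
#' similarity against every template (normalized to a probability-like vector).
#'
#' @param library List of \linkS4class{GlycanGraph} objects (the class space).
#' @param mode Ion mode for the templates.
#' @return A predictor: list with \code{labels} (canonical strings) and
#'   \code{scores(binned)} returning a normalized score vector.
#' @export
cosineBaselinePredictor <- function(library, mode = "negative") {
  labels <- vapply(library, serializeIUPAC, character(1))
  noiseless <- simParams(n_noise_peaks = 0L, mz_jitter_sd = 0,
                         fragment_keep_prob = 1)
  templates <- vapply(library, function(g) {
    s <- simulateSpectrum(g, noiseless, mode = mode, seed = 0L)
    binSpectrum(s)@intensities
  }, numeric(2048L))
  tnorm <- sqrt(colSums(templates^2))
  list(
    labels = labels,
    library = library,
    scores = function(binned) {
      v <- binned@intensities
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(rep(1 / length(labels), length(labels)))
      sim <- as.numeric(crossprod(templates, v)) / (tnorm * nv)
      sim[sim < 0] <- 0
      if (sum(sim) == 0) rep(1 / length(labels), length(labels))
      else sim / sum(sim)
    }
  )
}

#' End-to-end inference: raw file to ranked structure table
#'
#' Loads spectra (or takes a list), groups them by precursor m/z and retention
#' time, averages each group, scores the averaged spectrum with the predictor,
#' keeps the top candidates, applies the domain filters, deduplicates, rescores
#' against the biosynthetic network, optionally extends zero-shot, and
#' estimates abundances when MS1 intensities are supplied.
#'
#' @param x Path to a raw/TSV file, or a list of \linkS4class{Spectrum}.
#' @param predictor Predictor interface (see
#'   \code{\link{cosineBaselinePredictor}} and \code{\link{nnPredictor}}).
#' @param cfg An \code{\link{inferenceConfig}}.
#' @param expected_class,mode,reduced Sample-level settings.
#' @param reference Optional reference library for zero-shot extension.
#' @param zero_shot Run the zero-shot extension (default FALSE).
#' @param ms1 Optional MS1 feature table for \code{\link{estimateAbundance}}.
#' @param meta Metadata codes used when loading from file.
#' @return A PredictionTable sorted by precursor m/z then retention time.
#' @export
wrapInference <- function(x, predictor, cfg = inferenceConfig(),
                          expected_class = "O", mode = "negative",
                          reduced = TRUE, reference = NULL,
                          zero_shot = FALSE, ms1 = NULL, meta = metaCodes()) {
  spectra <- if (is.character(x)) loadSpectra(x, meta = meta) else x
  if (length(spectra) == 0L) return(.emptyPredictionTable())
  rts <- vapply(spectra, function(s) s@rt, numeric(1))
  maxRt <- if (all(is.na(rts))) 30 else max(rts, na.rm = TRUE)

  rows <- list()
  for (pg in groupPrecursors(spectra, cfg$precursor_gap)) {
    for (rg in groupRT(spectra, pg, cfg$rt_chunk)) {
      avg <- averageSpectra(spectra[rg], max_rt = maxRt)
      sc <- predictor$scores(avg$averaged)
      k <- min(cfg$topk_initial, length(sc))
      topIdx <- order(-sc)[seq_len(k)]
      cand <- data.frame(glycan = predictor$labels[topIdx],
                         score = sc[topIdx], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- .newPredictionRow(
        avg$precursor_mz, avg$rt_window, cand, "strong",
        spectrum = avg$median)
    }
  }
  tab <- .bindRows(rows)
  tab <- applyDomainFilters(tab, cfg, expected_class = expected_class,
                            mode = mode, reduced = reduced)
  tab <- .deduplicateRows(tab, gap = cfg$precursor_gap)
  tab$evidence[vapply(tab$candidates, function(c)
    is.null(c) || nrow(c) == 0L, logical(1))] <- NA_character_
  tab <- canonicalizeBiosynthesis(tab, bonus = cfg$precursor_bonus,
                                  topk_final = cfg$topk_final,
                                  bonus_sources = "strong", reduced = reduced)
  if (zero_shot) {
    tab$evidence[is.na(tab$evidence)] <- ""
    tab$evidence[tab$evidence == ""] <- NA_character_
    tab <- zeroShotExtend(tab, reference = reference, cfg = cfg,
                          expected_class = expected_class, mode = mode,
                          reduced = reduced)
    tab <- canonicalizeBiosynthesis(tab, bonus = cfg$precursor_bonus,
                                    topk_final = cfg$topk_final,
                                    bonus_sources = "strong",
                                    reduced = reduced)
  }
  tab <- estimateAbundance(tab, ms1, mz_tol = cfg$mass_tolerance)
  # fill compositions from the top candidate
  for (r in seq_len(nrow(tab))) {
    cand <- tab$candidates[[r]]
    if (!is.null(cand) && nrow(cand) > 0L) {
      g <- .parseCached(cand$glycan[1L], reduced)
      tab$composition[r] <- compositionString(toComposition(g))
    }
  }
  o <- order(tab$precursor_mz, tab$rt_start)
  out <- tab[o, , drop = FALSE]
  class(out) <- c("PredictionTable", "data.frame")
  out
}

#' Flatten a PredictionTable for CSV export
#'
#' One row per precursor/retention entity with top1..top5 glycan and score
#' columns, mirroring the standard output table layout.
#'
#' @param tab A PredictionTable.
#' @return Plain data.frame without list columns.
#' @export
flattenPredictions <- function(tab) {
  k <- 5L
  base <- tab[, c("precursor_mz", "rt_start", "rt_end", "charge",
                  "composition", "evidence", "abundance"), drop = FALSE]
  for (i in seq_len(k)) {
    base[[paste0("top", i)]] <- vapply(tab$candidates, function(c) {
      if (!is.null(c) && nrow(c) >= i) c$glycan[i] else NA_character_
    }, character(1))
    base[[paste0("score", i)]] <- vapply(tab$candidates, function(c) {
      if (!is.null(c) && nrow(c) >= i) c$score[i] else NA_real_
    }, numeric(1))
  }
  rownames(base) <- NULL
  as.data.frame(base)
}
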