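# Exhaustive theoretical fragmentation and Domon-Costello annotation.
#
# Every induced connected subgraph of the glycan tree is a potential fragment
# skeleton. Its boundary bonds are the cleavages: the bond above the subgraph's
# top residue breaks as B/C (or cross-ring A through the top residue), every
# bond to an excluded child breaks as Y/Z (or cross-ring X through the excluded
# residue). Neutral fragment masses follow the convention
#   base = sum(residue masses) + H2O (+ 2H if the reducing end is in the
#          fragment and reduced),
# with B and Z subtracting one water relative to C and Y, so that
# mass(B) + mass(Y_complement) = mass(intact) for every glycosidic bond.

.GREEK <- c("\u03b1", "\u03b2", "\u03b3", "\u03b4", "\u03b5", "\u03b6", "\u03b7")

# Reducing-side retained mass (Da) of a residue split by a cross-ring cleavage,
# by ring-bond pair. A = C-ion - value; X = Y-ion + value. Package convention
# (configurable); the pairs follow common usage for hexose rings.
.CROSS_RING_X <- c(
  "0,2" = 60.021130,   # C2H4O2
  "0,3" = 90.031694,   # C3H6O3
  "2,4" = 120.042259,  # C4H8O4
  "1,5" = 30.010565    # CH2O
)

# Parent-side carbon positions still present on the non-reducing (A) part,
# used to filter physically impossible ring cleavages given child linkages.
.CROSS_RING_RETAINED <- list(
  "0,2" = c("3", "4", "6", "?"),
  "0,3" = c("4", "6", "?"),
  "2,4" = c("6", "?"),
  "1,5" = c("2", "3", "4", "6", "?")
)

# Ring pairs admissible per residue class.
.CROSS_RING_PAIRS <- function(cls) {
  if (cls %in% c("Neu5Ac", "Neu5Gc", "Kdn")) "0,2" else names(.CROSS_RING_X)
}

.DEFAULT_GLOBAL_MODS <- c("-H2O", "-CO2", "-2H2O")

.globalModDelta <- function(mod) {
  if (!nzchar(mod)) return(0)
  switch(mod,
    "-H2O" = -.WATER,
    "-2H2O" = -2 * .WATER,
    "-CO2" = -.CO2,
    stop("unknown global modification: '", mod, "'", call. = FALSE))
}

#' Enumerate all induced connected subgraphs of a glycan tree
#'
#' Deterministic exhaustive enumeration: for each node v, all connected node
#' sets whose topmost node is v are built as the cartesian product of
#' "include or exclude" choices over the subtrees of v's children, memoized per
#' node. Every induced connected subgraph is produced exactly once.
#'
#' @param g A \linkS4class{GlycanGraph} with at most 25 residues.
#' @return List of integer vectors (node-id sets), sorted within each set.
#' @examples
#' length(enumerateConnectedSubgraphs(parseIUPAC("Neu5Aca2-3Galb1-3GalNAc")))  # 6
#' @export
enumerateConnectedSubgraphs <- function(g) {
  n <- nResidues(g)
  if (n > 25L) stop("glycan too large (> 25 residues)", call. = FALSE)
  kids <- glyChildren(g)
  memo <- vector("list", n)
  topped <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    sets <- list(v)
    for (c in kids[[v]]) {
      cs <- topped(c)
      grown <- list()
      for (s in sets) {
        for (t in cs) grown[[length(grown) + 1L]] <- c(s, t)
      }
      sets <- c(sets, grown)
    }
    memo[[v]] <<- sets
    sets
  }
  out <- list()
  for (v in seq_len(n)) out <- c(out, topped(v))
  lapply(out, function(s) sort(as.integer(s)))
}

# Boundary of a node set: the top node, whether the bond above it is cleaved,
# and the excluded children (bottom cleavages).
.boundary <- function(g, nodes) {
  inSet <- logical(nResidues(g)); inSet[nodes] <- TRUE
  topMask <- is.na(g@parent[nodes]) | !inSet[g@parent[nodes]]
  top <- nodes[topMask]
  stopifnot(length(top) == 1L)
  kids <- glyChildren(g)
  bottom <- integer(0)
  for (v in nodes) {
    ch <- kids[[v]]
    bottom <- c(bottom, ch[!inSet[ch]])
  }
  list(top = top, topCleaved = !is.na(g@parent[top]), bottom = bottom)
}

#' Enumerate theoretical fragment ions of a glycan
#'
#' Walks every induced connected subgraph, assigns every admissible combination
#' of cleavage types to its boundary bonds (B/C and optionally cross-ring A at
#' the bond above the fragment; Y/Z and optionally cross-ring X at each bond to
#' an excluded residue), applies each global modification, and computes the
#' theoretical m/z for every requested ion species. Ring cleavages incompatible
#' with the linkage positions of retained children are filtered out.
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @param ions List of \code{\link{ionSpec}} objects (default: negative mode,
#'   charges 1 and 2).
#' @param max_cleavages Maximum simultaneous cleavages per fragment (default 2).
#' @param allow_cross_ring Include A/X ring cleavages (default TRUE).
#' @param global_mods Character vector of global modifications out of
#'   \code{"-H2O"}, \code{"-2H2O"}, \code{"-CO2"} (the latter only applied to
#'   fragments containing a sialic acid). The unmodified fragment is always
#'   included.
#' @param scan_range Length-2 numeric m/z window; fragments outside are dropped
#'   (\code{NULL} keeps everything).
#' @return data.frame with one row per fragment ion: \code{nodes} (list of
#'   node ids), \code{n_cleav}, \code{cross_ring}, \code{cleavages} (list of
#'   per-cleavage records), \code{global_mod}, \code{neutral}, \code{charge},
#'   \code{adduct}, \code{theo_mz}, \code{dc_name}, \code{iupac_name}.
#' @export
enumerateFragments <- function(g, ions = list(ionSpec("negative", 1L),
                                              ionSpec("negative", 2L)),
                               max_cleavages = 2L, allow_cross_ring = TRUE,
                               global_mods = .DEFAULT_GLOBAL_MODS,
                               scan_range = c(39.714, 3000)) {
  stopifnot(is(g, "GlycanGraph"), max_cleavages >= 1L)
  if (inherits(ions, "IonSpec")) ions <- list(ions)
  n <- nResidues(g)
  kids <- glyChildren(g)
  resMass <- vapply(g@label, residueMass, numeric(1))
  classes <- vapply(g@label, .residueClass, character(1))
  sialic <- classes %in% c("Neu5Ac", "Neu5Gc", "Kdn")
  subs <- enumerateConnectedSubgraphs(g)

  rows <- list()
  addRow <- function(nodes, cleav, deltas, crossRing) {
    base <- sum(resMass[nodes]) + .WATER +
      if (1L %in% nodes && g@reduced) .REDUCTION else 0
    neutral0 <- base + sum(deltas)
    mods <- ""
    for (m in global_mods) {
      if (m == "-CO2" && !any(sialic[nodes])) next
      mods <- c(mods, m)
    }
    for (m in mods) {
      neutral <- neutral0 + .globalModDelta(m)
      if (neutral <= 0) next
      for (ion in ions) {
        mz <- ionMz(neutral, ion)
        if (!is.null(scan_range) && (mz < scan_range[1] || mz >= scan_range[2])) next
        rows[[length(rows) + 1L]] <<- list(
          nodes = nodes, n_cleav = length(cleav), cross_ring = crossRing,
          cleavages = cleav, global_mod = m, neutral = neutral,
          charge = ion@charge, adduct = ion@adduct, mode = ion@mode,
          theo_mz = mz)
      }
    }
  }

  for (S in subs) {
    b <- .boundary(g, S)
    nCl <- as.integer(b$topCleaved) + length(b$bottom)
    if (nCl > max_cleavages) next

    # options for the top bond
    topOpts <- list(NULL)
    if (b$topCleaved) {
      t <- b$top
      topOpts <- list(list(kind = "B", node = t, pair = NA_character_,
                           delta = -.WATER),
                      list(kind = "C", node = t, pair = NA_character_,
                           delta = 0))
      if (allow_cross_ring) {
        childPos <- substr(g@linkage[intersect(kids[[t]], S)], 4L, 4L)
        for (p in .CROSS_RING_PAIRS(classes[t])) {
          if (all(childPos %in% .CROSS_RING_RETAINED[[p]])) {
            topOpts[[length(topOpts) + 1L]] <-
              list(kind = "A", node = t, pair = p, delta = -.CROSS_RING_X[[p]])
          }
        }
      }
    }
    # options per bottom bond (indexed by excluded child)
    bottomOpts <- lapply(b$bottom, function(c) {
      opts <- list(list(kind = "Y", node = c, pair = NA_character_, delta = 0),
                   list(kind = "Z", node = c, pair = NA_character_,
                        delta = -.WATER))
      if (allow_cross_ring) {
        for (p in .CROSS_RING_PAIRS(classes[c])) {
          opts[[length(opts) + 1L]] <-
            list(kind = "X", node = c, pair = p, delta = .CROSS_RING_X[[p]])
        }
      }
      opts
    })

    combos <- list(list())
    for (opts in c(if (b$topCleaved) list(topOpts) else NULL, bottomOpts)) {
      grown <- list()
      for (cmb in combos) {
        for (o in opts) grown[[length(grown) + 1L]] <- c(cmb, list(o))
      }
      combos <- grown
    }
    for (cmb in combos) {
      deltas <- vapply(cmb, function(x) x$delta, numeric(1))
      crossRing <- any(vapply(cmb, function(x) x$kind %in% c("A", "X"),
                              logical(1)))
      addRow(S, cmb, deltas, crossRing)
    }
  }

  if (length(rows) == 0L) {
    return(data.frame())
  }
  out <- data.frame(
    n_cleav = vapply(rows, `[[`, integer(1), "n_cleav"),
    cross_ring = vapply(rows, `[[`, logical(1), "cross_ring"),
    global_mod = vapply(rows, `[[`, character(1), "global_mod"),
    neutral = vapply(rows, `[[`, numeric(1), "neutral"),
    charge = vapply(rows, `[[`, integer(1), "charge"),
    adduct = vapply(rows, `[[`, character(1), "adduct"),
    mode = vapply(rows, `[[`, character(1), "mode"),
    theo_mz = vapply(rows, `[[`, numeric(1), "theo_mz"),
    stringsAsFactors = FALSE
  )
  out$nodes <- lapply(rows, `[[`, "nodes")
  out$cleavages <- lapply(rows, `[[`, "cleavages")
  out$dc_name <- vapply(seq_len(nrow(out)), function(i) {
    .dcNameFromCleavages(g, out$cleavages[[i]])
  }, character(1))
  out$iupac_name <- vapply(out$nodes, function(nd) {
    serializeIUPAC(.inducedSubgraph(g, nd))
  }, character(1))
  out[order(out$theo_mz), , drop = FALSE]
}

# --- Domon-Costello naming ---------------------------------------------------

.nodeDepth <- function(g, v) {
  d <- 0L
  while (!is.na(v)) { d <- d + 1L; v <- g@parent[v] }
  d
}

.nodeHeight <- function(g, kids, v) {
  ch <- kids[[v]]
  if (length(ch) == 0L) return(1L)
  1L + max(vapply(ch, function(c) .nodeHeight(g, kids, c), integer(1)))
}

.subtreeMass <- function(g, kids, v) {
  resMass <- residueMass(g@label[v])
  ch <- kids[[v]]
  if (length(ch) == 0L) return(resMass)
  resMass + sum(vapply(ch, function(c) .subtreeMass(g, kids, c), numeric(1)))
}

# Greek branch designator of a node: at every branching point on the path from
# the root, branches are ranked by decreasing subtree mass (ties by canonical
# string) and the rank letter of the branch taken is appended.
.branchDesignator <- function(g, kids, v) {
  path <- integer(0); u <- v
  while (!is.na(u)) { path <- c(u, path); u <- g@parent[u] }
  letters_ <- character(0)
  for (k in seq_along(path)[-length(path)]) {
    node <- path[k]; nxt <- path[k + 1L]
    ch <- kids[[node]]
    if (length(ch) >= 2L) {
      mass <- vapply(ch, function(c) .subtreeMass(g, kids, c), numeric(1))
      canon <- vapply(ch, function(c) .canonSub(g, kids, c), character(1))
      o <- order(-mass, canon, method = "radix")
      rank <- which(ch[o] == nxt)
      letters_ <- c(letters_, .GREEK[rank])
    }
  }
  paste0(letters_, collapse = "")
}

.dcNameFromCleavages <- function(g, cleavages) {
  if (length(cleavages) == 0L) return("M")
  kids <- glyChildren(g)
  entries <- lapply(cleavages, function(cl) {
    kind <- cl$kind
    v <- cl$node
    if (kind %in% c("B", "C", "A")) {
      idx <- .nodeHeight(g, kids, v)
      des <- .branchDesignator(g, kids, v)
    } else {
      idx <- if (kind == "X") .nodeDepth(g, v) else .nodeDepth(g, g@parent[v])
      des <- .branchDesignator(g, kids, v)
    }
    prefix <- if (kind %in% c("A", "X")) cl$pair else ""
    list(name = paste0(prefix, kind, idx, des),
         side = if (kind %in% c("A", "B", "C")) 0L else 1L, idx = idx)
  })
  o <- order(vapply(entries, `[[`, integer(1), "side"),
             vapply(entries, `[[`, integer(1), "idx"),
             vapply(entries, `[[`, character(1), "name"))
  paste(vapply(entries[o], `[[`, character(1), "name"), collapse = "/")
}

#' Domon-Costello name of a fragment
#'
#' B/C/A ions are indexed from the non-reducing terminus of their branch
#' (the height of the cleaved residue in the parent tree); Y/Z ions from the
#' reducing end (depth of the residue retaining the bond); X ions carry the
#' depth of the split residue. A/X names are prefixed with their cleaved
#' ring-bond pair ("0,2A2"); branch designators are Greek letters ranked by
#' decreasing branch mass; simultaneous cleavages are joined by "/". The
#' intact glycan is named "M".
#'
#' @param fragment One row of the data.frame returned by
#'   \code{\link{enumerateFragments}} (or a list with a \code{cleavages} field).
#' @param parent The parent \linkS4class{GlycanGraph} the fragment came from.
#' @return Character name.
#' @export
domonCostelloName <- function(fragment, parent) {
  cl <- if (is.data.frame(fragment)) fragment$cleavages[[1L]] else fragment$cleavages
  if (is.null(cl)) stop("fragment lacks cleavage records", call. = FALSE)
  for (c_ in cl) {
    if (c_$node > nResidues(parent)) {
      stop("fragment is not derived from this parent glycan", call. = FALSE)
    }
  }
  .dcNameFromCleavages(parent, cl)
}

#' Parse a Domon-Costello fragment name
#'
#' Inverse of the naming convention used by \code{\link{domonCostelloName}}:
#' returns one record per cleavage with kind, index, ring-bond pair and branch
#' designator.
#'
#' @param name Fragment name, e.g. \code{"0,2A2/Y1a"} or \code{"M"}.
#' @return data.frame with columns \code{kind}, \code{index}, \code{pair},
#'   \code{branch}; zero rows for \code{"M"}.
#' @export
parseDomonCostello <- function(name) {
  if (identical(name, "M")) {
    return(data.frame(kind = character(0), index = integer(0),
                      pair = character(0), branch = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  re <- paste0("^(?:([0-9],[0-9]))?([ABCXYZ])([0-9]+)([",
               paste(.GREEK, collapse = ""), "]*)$")
  recs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec(re, p))[[1]]
    if (length(m) == 0L) stop("malformed fragment name: '", p, "'", call. = FALSE)
    data.frame(kind = m[3], index = as.integer(m[4]),
               pair = if (nzchar(m[2])) m[2] else NA_character_,
               branch = m[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# --- peak matching and prioritization ---------------------------------------

#' Match observed peaks against theoretical fragments
#'
#' Each peak is annotated with every fragment within \code{tolerance} Da;
#' candidates are ranked by \code{\link{prioritizeFragments}}. Peaks with no
#' candidate are retained with zero candidate rows so the caller can see what
#' stayed unexplained.
#'
#' @param fragments data.frame from \code{\link{enumerateFragments}}.
#' @param peaks Two-column matrix/data.frame (m/z, intensity) or a
#'   \linkS4class{Spectrum}.
#' @param tolerance Matching tolerance in Da (default 0.5).
#' @param prioritize Rank multiple explanations of the same peak (default TRUE;
#'   when FALSE, candidates are ordered by absolute mass error).
#' @return data.frame with columns \code{peak}, \code{observed_mz},
#'   \code{intensity}, \code{rank}, \code{theo_mz}, \code{mass_error},
#'   \code{dc_name}, \code{iupac_name}, \code{charge}, \code{global_mod},
#'   \code{n_cleav}, \code{cross_ring}, \code{frag_row}. Unexplained peaks have
#'   \code{rank = NA}.
#' @export
matchPeaks <- function(fragments, peaks, tolerance = 0.5, prioritize = TRUE) {
  stopifnot(tolerance > 0)
  if (is(peaks, "Spectrum")) peaks <- peakTable(peaks)
  peaks <- as.matrix(peaks)
  if (nrow(peaks) == 0L) return(data.frame())
  nFrag <- if (is.null(nrow(fragments))) 0L else nrow(fragments)

  # corroboration context: which fragments are matched by any peak at all
  matchedRows <- integer(0)
  hits <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (nFrag > 0L) {
      err <- fragments$theo_mz - peaks[i, 1]
      hits[[i]] <- which(abs(err) <= tolerance)
      matchedRows <- union(matchedRows, hits[[i]])
    } else {
      hits[[i]] <- integer(0)
    }
  }

  out <- list()
  for (i in seq_len(nrow(peaks))) {
    cand <- hits[[i]]
    if (length(cand) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        peak = i, observed_mz = peaks[i, 1], intensity = peaks[i, 2],
        rank = NA_integer_, theo_mz = NA_real_, mass_error = NA_real_,
        dc_name = NA_character_, iupac_name = NA_character_,
        charge = NA_integer_, global_mod = NA_character_,
        n_cleav = NA_integer_, cross_ring = NA, frag_row = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    if (prioritize) {
      ord <- prioritizeFragments(fragments, cand,
                                 context_rows = setdiff(matchedRows, cand),
                                 observed_mz = peaks[i, 1])
    } else {
      ord <- cand[order(abs(fragments$theo_mz[cand] - peaks[i, 1]))]
    }
    out[[length(out) + 1L]] <- data.frame(
      peak = i, observed_mz = peaks[i, 1], intensity = peaks[i, 2],
      rank = seq_along(ord), theo_mz = fragments$theo_mz[ord],
      mass_error = fragments$theo_mz[ord] - peaks[i, 1],
      dc_name = fragments$dc_name[ord],
      iupac_name = fragments$iupac_name[ord],
      charge = fragments$charge[ord], global_mod = fragments$global_mod[ord],
      n_cleav = fragments$n_cleav[ord], cross_ring = fragments$cross_ring[ord],
      frag_row = ord, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rank competing fragment explanations of one peak
#'
#' Stable tiered ranking: (1) fewer cleavages; (2) glycosidic before
#' cross-ring; (3) fewer global modifications; (4) higher corroboration, i.e.
#' the number of other matched fragments in the spectrum that are complementary
#' to, contained in, or containing this fragment's residue set; (5) smaller
#' absolute mass error; (6) name, as a deterministic tie-break.
#'
#' @param fragments Fragment data.frame from \code{\link{enumerateFragments}}.
#' @param candidate_rows Integer row indices competing for one peak.
#' @param context_rows Row indices of fragments matched elsewhere in the
#'   spectrum (corroboration evidence).
#' @param observed_mz The peak m/z (for the mass-error tier; optional).
#' @return \code{candidate_rows} reordered best-first.
#' @export
prioritizeFragments <- function(fragments, candidate_rows,
                                context_rows = integer(0),
                                observed_mz = NA_real_) {
  if (length(candidate_rows) == 0L) stop("no candidates to rank", call. = FALSE)
  allNodes <- sort(unique(unlist(fragments$nodes)))
  corro <- vapply(candidate_rows, function(r) {
    s <- fragments$nodes[[r]]
    comp <- setdiff(allNodes, s)
    n <- 0L
    for (cr in context_rows) {
      o <- fragments$nodes[[cr]]
      if (setequal(o, comp) || all(o %in% s) || all(s %in% o)) n <- n + 1L
    }
    n
  }, integer(1))
  err <- if (is.na(observed_mz)) rep(0, length(candidate_rows)) else
    abs(fragments$theo_mz[candidate_rows] - observed_mz)
  nmods <- nchar(fragments$global_mod[candidate_rows]) > 0L
  o <- order(fragments$n_cleav[candidate_rows],
             fragments$cross_ring[candidate_rows],
             nmods, -corro, err, fragments$dc_name[candidate_rows],
             method = "radix")
  candidate_rows[o]
}

#' Annotate an observed spectrum with a candidate glycan
#'
#' Convenience wrapper: enumerate the candidate's theoretical fragments and
#' match them against the peaks.
#'
#' @param g Candidate \linkS4class{GlycanGraph}.
#' @param peaks Peak matrix or \linkS4class{Spectrum}.
#' @param tolerance Matching tolerance in Da.
#' @param ... Passed to \code{\link{enumerateFragments}}.
#' @return Annotation data.frame as from \code{\link{matchPeaks}}.
#' @export
annotateSpectrum <- function(g, peaks, tolerance = 0.5, ...) {
  frags <- enumerateFragments(g, ...)
  matchPeaks(frags, peaks, tolerance = tolerance)
}
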