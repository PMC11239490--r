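# Composition, motif fingerprints, distances, subgraph tests and biosynthetic
# precursors.

.COMP_CLASSES <- c("Hex", "HexNAc", "dHex", "Neu5Ac", "Neu5Gc", "Pen", "Kdn",
                   "S", "P")

#' Base composition of a glycan
#'
#' Counts residues by class (Hex, HexNAc, dHex, Neu5Ac, Neu5Gc, Pen, Kdn) and
#' tallies sulfate/phosphate site modifications into the S/P slots (a
#' \code{"Gal3S"} contributes one Hex and one S).
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @return Named integer vector over the composition classes.
#' @examples
#' toComposition(parseIUPAC("Gal3Sb1-3GalNAc"))  # Hex 1, HexNAc 1, S 1
#' @export
toComposition <- function(g) {
  stopifnot(is(g, "GlycanGraph"))
  counts <- stats::setNames(integer(length(.COMP_CLASSES)), .COMP_CLASSES)
  for (lab in g@label) {
    parts <- .splitLabel(lab)
    cls <- .residueClass(lab)
    counts[cls] <- counts[cls] + 1L
    for (mod in parts$mods) counts[mod] <- counts[mod] + 1L
  }
  counts
}

#' Compact string form of a composition, e.g. "Hex1HexNAc1S1"
#' @param comp Named integer composition vector.
#' @return Character scalar ("" for all-zero).
#' @export
compositionString <- function(comp) {
  nz <- comp[comp > 0]
  paste0(names(nz), nz, collapse = "")
}

# Motif strings of a glycan: every node label, plus every linkage-typed
# disaccharide written child-linkage-parent (IUPAC order).
.motifStrings <- function(g) {
  mono <- g@label
  di <- character(0)
  if (nResidues(g) > 1L) {
    idx <- seq.int(2L, nResidues(g))
    di <- paste0(g@label[idx], g@linkage[idx], g@label[g@parent[idx]])
  }
  c(mono, di)
}

#' Build a motif vocabulary from a glycan library
#'
#' The vocabulary is the sorted union of all monosaccharide labels and
#' linkage-typed disaccharide motifs occurring in the library. It is built once
#' at pipeline start and then frozen: motifs outside the vocabulary are ignored
#' when fingerprinting, keeping the distance geometry stable.
#'
#' @param library List of \linkS4class{GlycanGraph} objects.
#' @return Character vector of motif strings.
#' @export
motifVocabulary <- function(library) {
  sort(unique(unlist(lapply(library, .motifStrings))), method = "radix")
}

#' Motif fingerprint of a glycan
#'
#' Counts of each monosaccharide and each linkage-typed disaccharide motif
#' against a fixed vocabulary.
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @param vocab Character vocabulary from \code{\link{motifVocabulary}}; when
#'   \code{NULL}, the vocabulary of \code{g} itself is used (fit mode).
#' @return Named integer vector of motif counts (length = vocabulary size).
#' @examples
#' fingerprint(parseIUPAC("Galb1-3GalNAc"))
#' @export
fingerprint <- function(g, vocab = NULL) {
  motifs <- .motifStrings(g)
  if (is.null(vocab)) vocab <- sort(unique(motifs), method = "radix")
  tab <- table(factor(motifs, levels = vocab))
  stats::setNames(as.integer(tab), vocab)
}

#' Cosine distance between glycan motif fingerprints
#'
#' \eqn{1 - \cos(f_1, f_2)} over a shared vocabulary. A glycan whose
#' fingerprint is the zero vector (fully out of vocabulary) is defined to have
#' distance 0 to a structurally identical glycan and 1 to anything else.
#'
#' @param g1,g2 \linkS4class{GlycanGraph} objects.
#' @param vocab Shared motif vocabulary; when \code{NULL}, built from both
#'   inputs.
#' @return Distance in [0, 1]; symmetric, zero on the diagonal.
#' @export
structureDistance <- function(g1, g2, vocab = NULL) {
  if (is.null(vocab)) vocab <- motifVocabulary(list(g1, g2))
  f1 <- fingerprint(g1, vocab)
  f2 <- fingerprint(g2, vocab)
  .cosineDistance(f1, f2, identical(serializeIUPAC(g1), serializeIUPAC(g2)))
}

#' Cosine distance between base compositions
#'
#' @param g1,g2 \linkS4class{GlycanGraph} objects.
#' @return Distance in [0, 1].
#' @export
compositionDistance <- function(g1, g2) {
  c1 <- toComposition(g1)
  c2 <- toComposition(g2)
  .cosineDistance(c1, c2, identical(c1, c2))
}

.cosineDistance <- function(v1, v2, sameObject) {
  n1 <- sqrt(sum(as.numeric(v1)^2))
  n2 <- sqrt(sum(as.numeric(v2)^2))
  if (n1 == 0 || n2 == 0) {
    return(if (sameObject) 0 else 1)
  }
  d <- 1 - sum(as.numeric(v1) * as.numeric(v2)) / (n1 * n2)
  min(max(d, 0), 1)
}

# Linkage compatibility: exact match, or per-field wildcard when enabled.
.linkageMatches <- function(sub, sup, wildcards) {
  if (identical(sub, sup)) return(TRUE)
  if (!wildcards) return(FALSE)
  a <- strsplit(sub, "", fixed = TRUE)[[1]]
  b <- strsplit(sup, "", fixed = TRUE)[[1]]
  # fields: anomeric, child carbon, '-', parent carbon(s)
  an <- a[1] == b[1] || a[1] == "?" || b[1] == "?"
  c1 <- a[2] == b[2] || a[2] == "?" || b[2] == "?"
  p1 <- a[4] == b[4] || a[4] == "?" || b[4] == "?"
  an && c1 && p1
}

#' Rooted subgraph test between glycans
#'
#' Tests whether \code{sub} embeds injectively into \code{sup}, preserving
#' residue labels and parent-child edges with their linkages. The embedding may
#' root anywhere in \code{sup} (any residue of \code{sup} can host the root of
#' \code{sub}); \code{"?"} linkage fields match anything when
#' \code{wildcards = TRUE}.
#'
#' @param sub,sup \linkS4class{GlycanGraph} objects.
#' @param wildcards Honor \code{"?"} wildcards in linkage labels (default TRUE).
#' @return Logical.
#' @examples
#' subgraphOf(parseIUPAC("Galb1-3GalNAc"), parseIUPAC("Neu5Aca2-3Galb1-3GalNAc"))
#' @export
subgraphOf <- function(sub, sup, wildcards = TRUE) {
  kidsSub <- glyChildren(sub)
  kidsSup <- glyChildren(sup)
  # canMap[i, j]: subtree of sub rooted at i embeds at sup node j
  nS <- nResidues(sub); nP <- nResidues(sup)
  canMap <- matrix(NA, nS, nP)
  embed <- function(i, j) {
    if (!is.na(canMap[i, j])) return(canMap[i, j])
    ok <- FALSE
    if (sub@label[i] == sup@label[j]) {
      sc <- kidsSub[[i]]
      if (length(sc) == 0L) {
        ok <- TRUE
      } else {
        pc <- kidsSup[[j]]
        if (length(pc) >= length(sc)) {
          # backtracking assignment of sub children to distinct sup children
          assign_ <- function(k, used) {
            if (k > length(sc)) return(TRUE)
            for (m in seq_along(pc)) {
              if (used[m]) next
              if (!.linkageMatches(sub@linkage[sc[k]], sup@linkage[pc[m]],
                                   wildcards)) next
              if (!embed(sc[k], pc[m])) next
              used[m] <- TRUE
              if (assign_(k + 1L, used)) return(TRUE)
              used[m] <- FALSE
            }
            FALSE
          }
          ok <- assign_(1L, logical(length(pc)))
        }
      }
    }
    canMap[i, j] <<- ok
    ok
  }
  any(vapply(seq_len(nP), function(j) embed(1L, j), logical(1)))
}

#' Biosynthetic precursors by single leaf deletion
#'
#' All structures obtained by removing exactly one terminal monosaccharide
#' (a leaf that is not the root), deduplicated by canonical form. Biosynthesis
#' extends glycans one monosaccharide at a time, so these are the immediate
#' upstream intermediates.
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @return List of \linkS4class{GlycanGraph} (empty for a single residue).
#' @export
biosyntheticPrecursors <- function(g) {
  n <- nResidues(g)
  if (n < 2L) return(list())
  leaves <- setdiff(glyLeaves(g), 1L)
  out <- list()
  seen <- character(0)
  for (leaf in leaves) {
    sub <- .inducedSubgraph(g, setdiff(seq_len(n), leaf), reduced = g@reduced)
    key <- serializeIUPAC(sub)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sub
    }
  }
  out
}
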