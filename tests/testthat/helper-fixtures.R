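# Shared fixtures and independent oracles used across test files.

ALPHA <- "\u03b1"
BETA <- "\u03b2"

gBranch <- function() parseIUPAC("GlcNAcb1-3(Neu5Aca2-6)GalNAc", reduced = TRUE)
gChain <- function() parseIUPAC("Neu5Aca2-3Galb1-3GalNAc", reduced = TRUE)
gDisac <- function() parseIUPAC("Galb1-3GalNAc", reduced = TRUE)

# Random labeled rooted tree with n nodes (uniform random attachment).
randomTree <- function(n, reduced = TRUE) {
  labels <- c("Gal", "GalNAc", "GlcNAc", "Fuc", "Neu5Ac", "Man", "Xyl")
  linkset <- c(paste0(ALPHA, "2-3"), paste0(ALPHA, "2-6"),
               paste0(BETA, "1-3"), paste0(BETA, "1-4"),
               paste0(BETA, "1-6"), "?1-?")
  label <- sample(labels, n, replace = TRUE)
  parent <- c(NA_integer_,
              if (n > 1L) vapply(2:n, function(i) sample.int(i - 1L, 1L),
                                 integer(1)))
  linkage <- c(NA_character_,
               if (n > 1L) sample(linkset, n - 1L, replace = TRUE))
  new("GlycanGraph", label = label, parent = parent, linkage = linkage,
      reduced = reduced)
}

# Independent oracle: all connected induced subgraphs by brute force over all
# non-empty node subsets plus a BFS connectivity check on the induced edges.
bruteForceConnectedSubgraphs <- function(g) {
  n <- nResidues(g)
  out <- list()
  for (code in seq_len(2^n - 1L)) {
    nodes <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    if (length(nodes) == 1L) {
      out[[length(out) + 1L]] <- nodes
      next
    }
    # induced edges: parent links whose both ends are in the set
    adj <- lapply(nodes, function(v) integer(0))
    names(adj) <- nodes
    for (v in nodes) {
      p <- glyParents(g)[v]
      if (!is.na(p) && p %in% nodes) {
        adj[[as.character(v)]] <- c(adj[[as.character(v)]], p)
        adj[[as.character(p)]] <- c(adj[[as.character(p)]], v)
      }
    }
    seen <- nodes[1L]
    queue <- nodes[1L]
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[as.character(v)]]) {
        if (!w %in% seen) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    if (length(seen) == length(nodes)) {
      out[[length(out) + 1L]] <- sort(nodes)
    }
  }
  out
}

# Independent oracle: injective label/linkage-preserving embedding by explicit
# enumeration of all candidate node maps (no shared code with subgraphOf).
bruteForceSubgraphOf <- function(sub, sup, wildcards = TRUE) {
  ns <- nResidues(sub); np <- nResidues(sup)
  if (ns > np) return(FALSE)
  linkOk <- function(a, b) {
    if (identical(a, b)) return(TRUE)
    if (!wildcards) return(FALSE)
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    all(mapply(function(x, y) x == y || x == "?" || y == "?",
               ca[c(1, 2, 4)], cb[c(1, 2, 4)]))
  }
  maps <- list(integer(0))
  for (i in seq_len(ns)) {
    nxt <- list()
    for (m in maps) {
      for (j in seq_len(np)) {
        if (j %in% m) next
        if (glyLabels(sub)[i] != glyLabels(sup)[j]) next
        pi <- glyParents(sub)[i]
        if (!is.na(pi)) {
          pj <- glyParents(sup)[j]
          if (is.na(pj) || m[pi] != pj) next
          if (!linkOk(glyLinkages(sub)[i], glyLinkages(sup)[j])) next
        }
        nxt[[length(nxt) + 1L]] <- c(m, j)
      }
    }
    maps <- nxt
    if (length(maps) == 0L) return(FALSE)
  }
  TRUE
}

# Canonical key for comparing sets of node sets.
nodeSetKey <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))

# Small TSV raw-file fixture writer.
writeFixtureTSV <- function(path, scans) {
  rows <- do.call(rbind, lapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    data.frame(scan_id = i, precursor_mz = sc$precursor_mz, rt_min = sc$rt,
               mz = sc$mz, intensity = sc$intensity)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
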