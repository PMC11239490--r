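# IUPAC-condensed parsing and canonical serialization.
#
# Grammar: a glycan string is read right-to-left; the rightmost residue is the
# reducing end (tree root). Everything before it is one optional unparenthesized
# "main chain" branch plus any number of parenthesized branches, each branch
# being a subglycan followed by the linkage that joins it to the residue on its
# right, e.g. "GlcNAcβ1-3(Neu5Acα2-6)GalNAc".

.ALPHA <- "\u03b1"
.BETA <- "\u03b2"

# Tokenize into residues, linkages and parentheses. ASCII anomeric letters
# ("a"/"b" directly before a linkage, as in "Galb1-3") are normalized to Greek.
.tokenizeIUPAC <- function(s) {
  s <- gsub("a(?=[12]-[1-9?])", .ALPHA, s, perl = TRUE)
  s <- gsub("b(?=[12]-[1-9?])", .BETA, s, perl = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c(.ALPHA, .BETA, "?")) {
      if (i + 3L > n || !chars[i + 1L] %in% c("1", "2") ||
          chars[i + 2L] != "-" || !chars[i + 3L] %in% c(as.character(1:9), "?")) {
        stop("malformed linkage token at position ", i, " in '", s, "'",
             call. = FALSE)
      }
      toks[[length(toks) + 1L]] <- list(
        type = "linkage", text = paste(chars[i:(i + 3L)], collapse = ""), pos = i)
      i <- i + 4L
    } else if (grepl("[A-Za-z]", ch)) {
      j <- i
      while (j < n && grepl("[A-Za-z0-9]", chars[j + 1L]) &&
             !chars[j + 1L] %in% c(.ALPHA, .BETA)) {
        # stop the residue run where a linkage begins: a/b + digit + '-'
        if (chars[j + 1L] %in% c("a", "b") && j + 2L <= n &&
            chars[j + 2L] %in% c("1", "2") && j + 3L <= n && chars[j + 3L] == "-") {
          break
        }
        j <- j + 1L
      }
      toks[[length(toks) + 1L]] <- list(
        type = "residue", text = paste(chars[i:j], collapse = ""), pos = i)
      i <- j + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i, " in '", s, "'",
           call. = FALSE)
    }
  }
  toks
}

# Parse a token segment into a nested list: list(label=, children=list of
# list(linkage=, node=)), children in left-to-right string order.
.parseSegment <- function(toks, s) {
  n <- length(toks)
  if (n == 0L) stop("empty glycan segment in '", s, "'", call. = FALSE)
  last <- toks[[n]]
  if (last$type != "residue") {
    stop("expected a residue at position ", last$pos, " in '", s, "'",
         call. = FALSE)
  }
  node <- list(label = last$text, children = list())
  rest <- if (n > 1L) toks[seq_len(n - 1L)] else list()
  parenKids <- list()
  while (length(rest) > 0L && rest[[length(rest)]]$type == ")") {
    depth <- 0L
    open <- NA_integer_
    for (k in rev(seq_along(rest))) {
      t <- rest[[k]]$type
      if (t == ")") depth <- depth + 1L
      if (t == "(") {
        depth <- depth - 1L
        if (depth == 0L) { open <- k; break }
      }
    }
    if (is.na(open)) {
      stop("unbalanced parentheses in '", s, "'", call. = FALSE)
    }
    inner <- rest[seq.int(open + 1L, length(rest) - 1L)]
    parenKids <- c(list(.parseBranch(inner, s)), parenKids)
    rest <- if (open > 1L) rest[seq_len(open - 1L)] else list()
  }
  if (length(rest) > 0L && rest[[length(rest)]]$type == "(") {
    stop("unbalanced parentheses in '", s, "'", call. = FALSE)
  }
  if (length(rest) > 0L) {
    node$children <- c(list(.parseBranch(rest, s)), parenKids)
  } else {
    node$children <- parenKids
  }
  node
}

.parseBranch <- function(toks, s) {
  n <- length(toks)
  if (n < 2L || toks[[n]]$type != "linkage") {
    pos <- if (n > 0L) toks[[n]]$pos else 1L
    stop("expected a linkage before position ", pos + 1L, " in '", s, "'",
         call. = FALSE)
  }
  list(linkage = toks[[n]]$text,
       node = .parseSegment(toks[seq_len(n - 1L)], s))
}

# Flatten the nested-list tree into parallel vectors, root first (preorder).
.flattenTree <- function(tree) {
  label <- character(0); parent <- integer(0); linkage <- character(0)
  rec <- function(node, parentId, link) {
    label <<- c(label, node$label)
    parent <<- c(parent, parentId)
    linkage <<- c(linkage, link)
    myId <- length(label)
    for (ch in node$children) rec(ch$node, myId, ch$linkage)
  }
  rec(tree, NA_integer_, NA_character_)
  list(label = label, parent = parent, linkage = linkage)
}

#' Parse an IUPAC-condensed glycan string
#'
#' The rightmost residue is the reducing end and becomes the tree root;
#' parenthesized branches attach to the residue following them. Linkages follow
#' the grammar \code{[αβ?][12]-[1-9?]}; ASCII \code{a}/\code{b} anomeric letters
#' are accepted and normalized.
#'
#' @param s IUPAC-condensed string, e.g. \code{"GlcNAcb1-3(Neu5Aca2-6)GalNAc"}.
#' @param reduced Logical; reducing end reduced to an alditol (default FALSE).
#' @return A \linkS4class{GlycanGraph}.
#' @examples
#' g <- parseIUPAC("GlcNAcb1-3(Neu5Aca2-6)GalNAc")
#' nResidues(g)  # 3
#' @export
parseIUPAC <- function(s, reduced = FALSE) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop("s must be a non-empty string", call. = FALSE)
  }
  toks <- .tokenizeIUPAC(s)
  tree <- .parseSegment(toks, s)
  flat <- .flattenTree(tree)
  new("GlycanGraph", label = flat$label, parent = flat$parent,
      linkage = flat$linkage, reduced = isTRUE(reduced))
}

# Canonical string of the subtree rooted at v: children ordered by
# (linkage label, child canonical string).
.canonSub <- function(g, kids, v) {
  ch <- kids[[v]]
  if (length(ch) == 0L) return(g@label[v])
  sub <- vapply(ch, function(c) .canonSub(g, kids, c), character(1))
  lnk <- g@linkage[ch]
  o <- order(lnk, sub, method = "radix")
  sub <- sub[o]; lnk <- lnk[o]
  main <- paste0(sub[1L], lnk[1L])
  others <- if (length(ch) > 1L) {
    paste0(vapply(seq.int(2L, length(ch)), function(k) {
      paste0("(", sub[k], lnk[k], ")")
    }, character(1)), collapse = "")
  } else ""
  paste0(main, others, g@label[v])
}

#' Serialize a GlycanGraph to canonical IUPAC-condensed form
#'
#' Children of every residue are ordered by (linkage label, canonical subtree
#' string), so two structurally identical glycans always serialize identically;
#' \code{parseIUPAC(serializeIUPAC(g))} reproduces \code{g} up to node
#' numbering.
#'
#' @param g A \linkS4class{GlycanGraph}.
#' @return Canonical IUPAC-condensed string.
#' @export
serializeIUPAC <- function(g) {
  stopifnot(is(g, "GlycanGraph"))
  .canonSub(g, glyChildren(g), 1L)
}

#' Canonical form and structural identity
#'
#' \code{canonicalForm} is an alias of \code{\link{serializeIUPAC}};
#' \code{glycanEqual} compares two glycans by canonical form and reduced flag.
#'
#' @param g,g1,g2 \linkS4class{GlycanGraph} objects.
#' @return \code{canonicalForm}: character; \code{glycanEqual}: logical.
#' @export
canonicalForm <- function(g) serializeIUPAC(g)

#' @rdname canonicalForm
#' @export
glycanEqual <- function(g1, g2) {
  identical(serializeIUPAC(g1), serializeIUPAC(g2)) &&
    identical(g1@reduced, g2@reduced)
}

#' Read / write a reference glycan library
#'
#' Plain UTF-8 text, one IUPAC-condensed structure per line; blank lines and
#' lines starting with \code{#} are ignored. Writing emits canonical forms.
#'
#' @param path File path.
#' @param reduced Logical applied to every structure on read.
#' @param library For writing: a list of \linkS4class{GlycanGraph} objects.
#' @return \code{readGlycanLibrary}: list of \linkS4class{GlycanGraph};
#'   \code{writeGlycanLibrary}: invisible path.
#' @export
readGlycanLibrary <- function(path, reduced = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parseIUPAC, reduced = reduced)
}

#' @rdname readGlycanLibrary
#' @export
writeGlycanLibrary <- function(library, path) {
  writeLines(vapply(library, serializeIUPAC, character(1)), path,
             useBytes = FALSE)
  invisible(path)
}

# Extract the subtree induced by a node-id set (must be connected) as a new
# GlycanGraph; the topmost node becomes the root. Used by the fragmenter.
.inducedSubgraph <- function(g, nodes, reduced = NULL) {
  nodes <- sort(unique(as.integer(nodes)))
  inSet <- logical(nResidues(g)); inSet[nodes] <- TRUE
  top <- nodes[!(g@parent[nodes] %in% nodes) | is.na(g@parent[nodes])]
  if (length(top) != 1L) stop("node set is not connected", call. = FALSE)
  # preorder from top
  kids <- glyChildren(g)
  order_ <- integer(0)
  stack <- top
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    order_ <- c(order_, v)
    ch <- kids[[v]]
    stack <- c(ch[inSet[ch]], stack)
  }
  newId <- integer(nResidues(g)); newId[order_] <- seq_along(order_)
  parent <- vapply(order_, function(v) {
    p <- g@parent[v]
    if (is.na(p) || !inSet[p]) NA_integer_ else newId[p]
  }, integer(1))
  linkage <- ifelse(is.na(parent), NA_character_, g@linkage[order_])
  if (is.null(reduced)) reduced <- g@reduced && inSet[1L]
  new("GlycanGraph", label = g@label[order_], parent = parent,
      linkage = linkage, reduced = reduced)
}
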