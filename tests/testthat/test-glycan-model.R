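# Glycan parsing, canonical serialization, composition, fingerprints,
# distances, subgraph tests and biosynthetic precursors.

test_that("parseIUPAC builds the documented trees", {
  g <- gBranch()
  expect_equal(nResidues(g), 3L)
  expect_equal(glyLabels(g)[1L], "GalNAc")  # root = reducing end
  expect_setequal(glyLabels(g)[2:3], c("GlcNAc", "Neu5Ac"))
  expect_equal(glyParents(g)[2:3], c(1L, 1L))

  single <- parseIUPAC("GalNAc")
  expect_equal(nResidues(single), 1L)
  expect_equal(length(biosyntheticPrecursors(single)), 0L)

  chain <- gChain()
  expect_equal(glyLabels(chain), c("GalNAc", "Gal", "Neu5Ac"))
  expect_equal(glyParents(chain), c(NA_integer_, 1L, 2L))
  expect_equal(glyLinkages(chain)[3L], paste0(ALPHA, "2-3"))
})

test_that("malformed strings raise informative parse errors", {
  expect_error(parseIUPAC("Galb1-3"), "residue")
  expect_error(parseIUPAC("Gal("), "parenthes|residue")
  expect_error(parseIUPAC("(Galb1-3"), "parenthes|residue|linkage")
  expect_error(parseIUPAC("Gal\u03b21"), "malformed linkage")
  expect_error(parseIUPAC(""), "non-empty")
  expect_error(parseIUPAC("Gal Gal"), "unexpected character")
})

test_that("parse/serialize round-trip is the identity on canonical forms", {
  lib <- generateLibrary(60, seed = 101, max_size = 8L)
  extra <- lapply(c(4L, 5L, 6L, 7L, 8L), function(n) {
    set.seed(n * 13L)
    replicate(10, randomTree(n), simplify = FALSE)
  })
  all_g <- c(lib, unlist(extra, recursive = FALSE))
  expect_gte(length(all_g), 100L)
  for (g in all_g) {
    s <- serializeIUPAC(g)
    expect_identical(serializeIUPAC(parseIUPAC(s, reduced = isReduced(g))), s)
  }
})

test_that("toComposition counts residue classes and site modifications", {
  expect_equal(toComposition(gBranch())[c("HexNAc", "Neu5Ac")],
               c(HexNAc = 2L, Neu5Ac = 1L))
  comp <- toComposition(parseIUPAC("Gal3Sb1-3GalNAc"))
  expect_equal(comp[c("Hex", "HexNAc", "S")], c(Hex = 1L, HexNAc = 1L, S = 1L))
  expect_equal(toComposition(parseIUPAC("Gal"))[["Hex"]], 1L)
  expect_error(toComposition(new("GlycanGraph", label = "Xyz",
                                 parent = NA_integer_,
                                 linkage = NA_character_, reduced = FALSE)),
               "Xyz")
})

test_that("fingerprints count mono- and linkage-typed disaccharide motifs", {
  f <- fingerprint(gDisac())
  expect_equal(f[["Gal"]], 1L)
  expect_equal(f[["GalNAc"]], 1L)
  expect_equal(f[[paste0("Gal", BETA, "1-3GalNAc")]], 1L)
  expect_equal(sum(f), 3L)

  f1 <- fingerprint(parseIUPAC("Gal"))
  expect_equal(sum(f1), 1L)

  fc <- fingerprint(gChain())
  expect_equal(sum(fc), 5L)  # 3 monosaccharides + 2 disaccharides
  # out-of-vocabulary motifs are ignored under a frozen vocabulary
  vocab <- motifVocabulary(list(gDisac()))
  ff <- fingerprint(gChain(), vocab)
  expect_equal(length(ff), length(vocab))
  expect_true(all(ff >= 0))
})

test_that("structureDistance is cosine-based, symmetric, zero on identity", {
  g <- gBranch()
  expect_equal(structureDistance(g, g), 0)
  d <- structureDistance(parseIUPAC("Fuca1-2Gal"), parseIUPAC("Xylb1-3Man"))
  expect_equal(d, 1)  # disjoint motif sets
  # hand cosine: fingerprints (1,1,0,1,0) vs (1,0,1,0,1) over the shared
  # 5-motif vocabulary -> similarity 1/3
  d2 <- structureDistance(parseIUPAC("Galb1-3GalNAc"),
                          parseIUPAC("Galb1-3GlcNAc"))
  expect_equal(d2, 1 - 1 / 3, tolerance = 1e-12)
  lib <- generateLibrary(8, seed = 7)
  vocab <- motifVocabulary(lib)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(structureDistance(lib[[i]], lib[[j]], vocab),
                 structureDistance(lib[[j]], lib[[i]], vocab))
  }
})

test_that("subgraphOf matches the documented embeddings", {
  expect_true(subgraphOf(gDisac(), gChain()))
  expect_true(subgraphOf(gBranch(), gBranch()))
  expect_false(subgraphOf(parseIUPAC("Neu5Aca2-6GalNAc"), gChain()))
  # wildcard linkages
  expect_true(subgraphOf(parseIUPAC("Gal?1-?GalNAc"), gChain(),
                         wildcards = TRUE))
  expect_false(subgraphOf(parseIUPAC("Gal?1-?GalNAc"), gChain(),
                          wildcards = FALSE))
})

test_that("subgraphOf agrees with brute-force enumeration on small trees", {
  set.seed(424)
  for (rep in 1:40) {
    sup <- randomTree(sample(3:6, 1))
    sub <- randomTree(sample(2:4, 1))
    expect_identical(subgraphOf(sub, sup), bruteForceSubgraphOf(sub, sup))
    # a genuine subtree must always embed
    nodes <- seq_len(sample(nResidues(sup), 1L))  # preorder prefix: connected
    sub2 <- glycrunch:::.inducedSubgraph(sup, nodes)
    expect_true(subgraphOf(sub2, sup))
  }
})

test_that("biosyntheticPrecursors deletes exactly one terminal residue", {
  pre <- biosyntheticPrecursors(gBranch())
  expect_setequal(vapply(pre, serializeIUPAC, character(1)),
                  c(paste0("GlcNAc", BETA, "1-3GalNAc"),
                    paste0("Neu5Ac", ALPHA, "2-6GalNAc")))
  expect_equal(length(biosyntheticPrecursors(gChain())), 1L)
  expect_equal(length(biosyntheticPrecursors(parseIUPAC("GalNAc"))), 0L)
})

test_that("precursor count equals distinct canonical single-leaf deletions", {
  set.seed(77)
  for (rep in 1:20) {
    g <- randomTree(sample(3:7, 1))
    leaves <- setdiff(glyLeaves(g), 1L)
    keys <- unique(vapply(leaves, function(leaf) {
      serializeIUPAC(glycrunch:::.inducedSubgraph(
        g, setdiff(seq_len(nResidues(g)), leaf), reduced = isReduced(g)))
    }, character(1)))
    expect_equal(length(biosyntheticPrecursors(g)), length(keys))
  }
})

test_that("glycan library files round-trip through read/write", {
  lib <- generateLibrary(10, seed = 3)
  path <- tempfile(fileext = ".txt")
  writeGlycanLibrary(lib, path)
  lib2 <- readGlycanLibrary(path)
  expect_equal(vapply(lib2, serializeIUPAC, character(1)),
               vapply(lib, serializeIUPAC, character(1)))
  # comments and blank lines are skipped
  writeLines(c("# comment", "", serializeIUPAC(lib[[1]])), path)
  expect_equal(length(readGlycanLibrary(path)), 1L)
})
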