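# Monoisotopic mass bookkeeping: elements, residues, derivatization, adducts.

#' Monoisotopic element masses (Da)
#'
#' IUPAC/CODATA monoisotopic masses of the elements occurring in glycans,
#' plus the proton mass used for charge-state arithmetic.
#'
#' @format Named numeric vector (Da).
#' @keywords internal
.ELEMENTS <- c(
  C  = 12.000000,
  H  = 1.007825,
  O  = 15.994915,
  N  = 14.003074,
  S  = 31.972071,
  P  = 30.973762,
  Na = 22.989770
)

.PROTON <- 1.007276

# Elemental formulas of dehydrated residues (as incorporated in a chain).
.RESIDUE_FORMULAS <- list(
  Hex    = c(C = 6,  H = 10, O = 5),
  HexNAc = c(C = 8,  H = 13, O = 5, N = 1),
  dHex   = c(C = 6,  H = 10, O = 4),
  Neu5Ac = c(C = 11, H = 17, O = 8, N = 1),
  Neu5Gc = c(C = 11, H = 17, O = 9, N = 1),
  Pen    = c(C = 5,  H = 8,  O = 4),
  Kdn    = c(C = 9,  H = 14, O = 8)
)

# Site-modification masses: sulfate (SO3) and phosphate (HPO3) as neutral adducts
# on a hydroxyl.
.MOD_FORMULAS <- list(
  S = c(S = 1, O = 3),
  P = c(H = 1, P = 1, O = 3)
)

# Free hydroxyl/amine sites gaining a methyl group under permethylation,
# counted for a chain-internal residue.
.PERMETHYL_SITES <- c(
  Hex = 3, HexNAc = 3, dHex = 2, Neu5Ac = 5, Neu5Gc = 6, Pen = 2, Kdn = 5
)

# Monosaccharide label -> residue class. Generic class names map to themselves.
.RESIDUE_CLASSES <- c(
  Glc = "Hex", Gal = "Hex", Man = "Hex", Hex = "Hex", All = "Hex", Ido = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc", ManNAc = "HexNAc", HexNAc = "HexNAc",
  Fuc = "dHex", Rha = "dHex", Qui = "dHex", dHex = "dHex",
  Neu5Ac = "Neu5Ac", Neu5Gc = "Neu5Gc", Kdn = "Kdn",
  Xyl = "Pen", Ara = "Pen", Rib = "Pen", Pen = "Pen"
)

.formulaMass <- function(formula) {
  sum(.ELEMENTS[names(formula)] * formula)
}

.WATER     <- .formulaMass(c(H = 2, O = 1))       # 18.010565
.REDUCTION <- .formulaMass(c(H = 2))              # alditol reducing end, +2 H
.METHYL    <- .formulaMass(c(C = 1, H = 2))       # CH2 increment per methylation
.CO2       <- .formulaMass(c(C = 1, O = 2))

# Neutral adduct mass shifts entering ion m/z. Acetate: +CH3COOH combined with
# deprotonation gives [M+CH3COO]-; sodium: Na-for-H exchange.
.ADDUCT_SHIFTS <- c(
  none    = 0,
  acetate = .formulaMass(c(C = 2, H = 4, O = 2)), # 60.021130
  sodium  = .ELEMENTS[["Na"]] - .ELEMENTS[["H"]]  # 21.981944
)

#' Split a monosaccharide label into base residue and site modifications
#'
#' Labels may carry trailing site modifications such as \code{"6S"}, \code{"3S"}
#' or \code{"6P"} (e.g. \code{"GlcNAc6S"}, \code{"Gal3S"}). The optional site
#' digit is retained for bookkeeping; masses depend only on the S/P type.
#'
#' @param label Monosaccharide label, e.g. \code{"GlcNAc6S"}.
#' @return List with \code{base} (character) and \code{mods} (character vector
#'   of \code{"S"}/\code{"P"} codes, one per modification).
#' @keywords internal
.splitLabel <- function(label) {
  m <- regmatches(label, regexpr("(?:[1-9]?[SP])+$", label))
  if (length(m) == 0L || m == label) {
    return(list(base = label, mods = character(0)))
  }
  base <- substr(label, 1L, nchar(label) - nchar(m))
  mods <- regmatches(m, gregexpr("[1-9]?[SP]", m))[[1]]
  list(base = base, mods = gsub("[1-9]", "", mods))
}

.residueClass <- function(label) {
  base <- .splitLabel(label)$base
  cls <- .RESIDUE_CLASSES[base]
  if (is.na(cls)) {
    stop("unknown monosaccharide label: '", label, "'", call. = FALSE)
  }
  unname(cls)
}

#' Monoisotopic mass of a dehydrated residue
#'
#' @param label Monosaccharide label (specific, like \code{"GalNAc"}, or a
#'   residue class like \code{"HexNAc"}), optionally with site modifications
#'   (\code{"Gal3S"}).
#' @param derivatization \code{"none"} or \code{"permethylated"}. Permethylation
#'   adds one methyl increment (CH2, 14.01565 Da) per free hydroxyl/amine site;
#'   each sulfate/phosphate consumes one site.
#' @return Monoisotopic residue mass in Da.
#' @examples
#' residueMass("Hex")                     # 162.0528
#' residueMass("Neu5Gc") - residueMass("Neu5Ac")  # ~16
#' @export
residueMass <- function(label, derivatization = c("none", "permethylated")) {
  derivatization <- match.arg(derivatization)
  parts <- .splitLabel(label)
  cls <- .residueClass(label)
  mass <- .formulaMass(.RESIDUE_FORMULAS[[cls]])
  for (mod in parts$mods) {
    mass <- mass + .formulaMass(.MOD_FORMULAS[[mod]])
  }
  if (derivatization == "permethylated") {
    sites <- max(.PERMETHYL_SITES[[cls]] - length(parts$mods), 0)
    mass <- mass + sites * .METHYL
  }
  mass
}

#' Neutral monoisotopic mass of an intact glycan
#'
#' The mass is composition-determined: the sum of dehydrated residue masses plus
#' one water, plus 2 H if the reducing end is an alditol (reductive
#' beta-elimination workup). Permethylated glycans additionally gain one methyl
#' at the anomeric position (two when reduced, for the opened ring).
#'
#' @param x A \linkS4class{GlycanGraph} or a composition (named integer vector /
#'   output of \code{\link{toComposition}}).
#' @param reduced Logical; reducing end reduced to an alditol. For a
#'   GlycanGraph input, defaults to the object's \code{reduced} slot.
#' @param derivatization \code{"none"} or \code{"permethylated"}.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' g <- parseIUPAC("Galβ1-3GalNAc", reduced = TRUE)
#' glycanMass(g)  # 385.1585
#' @export
glycanMass <- function(x, reduced = NULL,
                       derivatization = c("none", "permethylated")) {
  derivatization <- match.arg(derivatization)
  if (is(x, "GlycanGraph")) {
    if (is.null(reduced)) reduced <- x@reduced
    labels <- x@label
    mass <- sum(vapply(labels, residueMass, numeric(1),
                       derivatization = derivatization))
  } else {
    if (is.null(reduced)) reduced <- FALSE
    comp <- x[x > 0]
    if (length(comp) == 0L) stop("empty composition", call. = FALSE)
    modM <- 0
    res <- comp[!names(comp) %in% c("S", "P")]
    for (mod in c("S", "P")) {
      if (!is.na(comp[mod])) modM <- modM + comp[[mod]] * .formulaMass(.MOD_FORMULAS[[mod]])
    }
    if (length(res) == 0L) stop("composition has no residues", call. = FALSE)
    mass <- sum(vapply(names(res), residueMass, numeric(1),
                       derivatization = derivatization) * res) + modM
    if (derivatization == "permethylated" && !is.na(comp["S"]) && comp[["S"]] > 0) {
      mass <- mass - comp[["S"]] * .METHYL  # sites consumed by sulfation
    }
  }
  mass <- mass + .WATER
  if (isTRUE(reduced)) mass <- mass + .REDUCTION
  if (derivatization == "permethylated") {
    mass <- mass + .METHYL + if (isTRUE(reduced)) .METHYL else 0
  }
  mass
}

#' Ion species specification
#'
#' @param mode \code{"negative"} or \code{"positive"}.
#' @param charge Positive integer charge state.
#' @param adduct \code{"none"}, \code{"acetate"} (negative mode only) or
#'   \code{"sodium"} (Na-for-H exchange).
#' @return An \code{IonSpec} object.
#' @examples
#' ionSpec("negative", 2)            # [M-2H]2-
#' ionSpec("negative", 1, "acetate") # [M+CH3COO]-
#' @export
ionSpec <- function(mode = c("negative", "positive"), charge = 1L,
                    adduct = c("none", "acetate", "sodium")) {
  mode <- match.arg(mode)
  adduct <- match.arg(adduct)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer", call. = FALSE)
  if (mode == "positive" && adduct == "acetate") {
    stop("acetate adducts are supported in negative mode only", call. = FALSE)
  }
  new("IonSpec", mode = mode, charge = charge, adduct = adduct)
}

#' Theoretical m/z of an ion
#'
#' Negative mode: \eqn{(M - z \cdot m_p + \Delta_{adduct}) / z}; positive mode:
#' \eqn{(M + z \cdot m_p + \Delta_{adduct}) / z}. Adduct shifts: acetate
#' +60.021130 Da (acetic acid, i.e. [M+CH3COO]- after deprotonation), sodium
#' +21.981944 Da (Na-for-H exchange).
#'
#' @param neutral Neutral monoisotopic mass (Da), > 0.
#' @param ion An \code{\link{ionSpec}} object.
#' @return m/z value.
#' @examples
#' ionMz(385.1585, ionSpec("negative", 1))  # 384.1512
#' @export
ionMz <- function(neutral, ion) {
  stopifnot(is(ion, "IonSpec"))
  if (any(neutral <= 0)) stop("neutral mass must be positive", call. = FALSE)
  z <- ion@charge
  shift <- .ADDUCT_SHIFTS[[ion@adduct]]
  if (ion@mode == "negative") {
    (neutral - z * .PROTON + shift) / z
  } else {
    (neutral + z * .PROTON + shift) / z
  }
}

#' Match an observed precursor m/z against candidate compositions
#'
#' Tries every candidate composition at every charge state 1..\code{max_charge}
#' (and the listed adducts) and keeps matches with absolute m/z error at or
#' below \code{tolerance}, sorted by absolute error.
#'
#' @param observed_mz Observed m/z.
#' @param candidates A list of compositions (named integer vectors as returned
#'   by \code{\link{toComposition}}); a single composition is also accepted.
#' @param tolerance Matching tolerance in Da (default 0.5).
#' @param max_charge Maximum charge state to consider (default 3).
#' @param mode Ion mode.
#' @param reduced Whether the glycans carry an alditol reducing end.
#' @param adducts Adducts to consider (default \code{"none"}).
#' @return data.frame with columns \code{candidate} (index), \code{charge},
#'   \code{adduct}, \code{theo_mz}, \code{error}; zero rows when nothing
#'   matches.
#' @export
compositionMatch <- function(observed_mz, candidates, tolerance = 0.5,
                             max_charge = 3L, mode = "negative",
                             reduced = TRUE, adducts = "none") {
  stopifnot(tolerance > 0, max_charge >= 1L)
  if (!is.list(candidates)) candidates <- list(candidates)
  out <- list()
  for (i in seq_along(candidates)) {
    neutral <- glycanMass(candidates[[i]], reduced = reduced)
    for (z in seq_len(max_charge)) {
      for (ad in adducts) {
        mz <- ionMz(neutral, ionSpec(mode, z, ad))
        err <- mz - observed_mz
        if (abs(err) <= tolerance) {
          out[[length(out) + 1L]] <- data.frame(
            candidate = i, charge = z, adduct = ad,
            theo_mz = mz, error = err, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(candidate = integer(0), charge = integer(0),
                      adduct = character(0), theo_mz = numeric(0),
                      error = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(abs(res$error)), , drop = FALSE]
}
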