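.NOMINAL_MASS <- c(C = 12L, H = 1L, O = 16L, N = 14L, S = 32L, P = 31L)
.MONO_MASS <- c(C = 12, H = 1.0078250319, O = 15.9949146221,
                N = 14.0030740052, S = 31.97207069, P = 30.97376151)
.PROTON_MASS <- 1.00727646

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like element-count string (e.g. `"C15H10O5"`) into
#' a [MolecularFormula].  Supported elements: C, H, O, N, S, P.
#'
#' @param text Formula string.
#' @param label Optional provenance label (default the input text).
#' @return A [MolecularFormula].
#' @examples
#' parseFormula("C15H10O5", "apigenin")
#' @export
parseFormula <- function(text, label = text) {
    if (length(text) != 1L || !is.character(text) || is.na(text))
        stop("parse error: formula must be a single string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
    tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
    if (!length(tokens) || paste(tokens, collapse = "") != text)
        stop("parse error: malformed formula '", text, "'")
    elems <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Z][a-z]?", "", tokens)
    counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
    if (any(is.na(counts)))
        stop("parse error: malformed count in '", text, "'")
    unknown <- setdiff(elems, names(.NOMINAL_MASS))
    if (length(unknown))
        stop("parse error: unknown element symbol '",
             paste(unknown, collapse = "', '"), "' in '", text, "'")
    cnt <- tapply(counts, factor(elems, levels = unique(elems)), sum)
    counts <- stats::setNames(as.integer(cnt), names(cnt))
    new("MolecularFormula", counts = counts, label = as.character(label))
}

.asFormula <- function(f) {
    if (is(f, "MolecularFormula")) f else parseFormula(f)
}

#' Render a formula back to Hill-like notation
#'
#' @param f A [MolecularFormula].
#' @return Character formula string (C first, then H, then others).
#' @export
formulaString <- function(f) {
    cnt <- f@counts[f@counts > 0L]
    ord <- c(intersect(c("C", "H"), names(cnt)),
             sort(setdiff(names(cnt), c("C", "H"))))
    paste0(ord, ifelse(cnt[ord] == 1L, "", cnt[ord]), collapse = "")
}

#' Nominal (integer) molecular mass
#'
#' Sum of integer atomic masses (C=12, H=1, O=16, ...), the scale on which
#' unit-resolution mass spectra are read.
#'
#' @param f A [MolecularFormula] or formula string.
#' @return Integer mass in Da.
#' @examples
#' nominalMass("C15H10O5")   # apigenin, 270
#' @export
nominalMass <- function(f) {
    f <- .asFormula(f)
    sum(f@counts * .NOMINAL_MASS[names(f@counts)])
}

#' Monoisotopic molecular mass
#'
#' @param f A [MolecularFormula] or formula string.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(f) {
    f <- .asFormula(f)
    sum(f@counts * .MONO_MASS[names(f@counts)])
}

#' m/z of the singly deprotonated ([M-H]-) ion
#'
#' Negative-mode electrospray of flavonoids yields the singly deprotonated
#' molecular ion; on the nominal scale its m/z is the neutral mass minus 1.
#'
#' @param f A [MolecularFormula] or formula string; must contain hydrogen.
#' @param monoisotopic Use monoisotopic masses (subtracting a proton mass)
#'   instead of the nominal scale.
#' @return m/z of `[M-H]-`.
#' @examples
#' deprotonatedMz("C15H10O5")    # apigenin, 269
#' deprotonatedMz("C21H18O11")   # apigenin-7-glucuronide, 445
#' @export
deprotonatedMz <- function(f, monoisotopic = FALSE) {
    f <- .asFormula(f)
    if (is.na(f@counts["H"]) || f@counts[["H"]] < 1L)
        stop("chemistry error: cannot deprotonate a hydrogen-free formula")
    if (monoisotopic) monoisotopicMass(f) - .PROTON_MASS
    else nominalMass(f) - 1L
}

#' Table of glycosyl/acyl residue neutral losses
#'
#' Nominal masses of the neutral losses produced when common sugar or acyl
#' residues detach from a flavonoid glycoside in MS/MS: glucuronyl 176
#' (dehydrated glucuronic acid, C6H8O6), hexosyl 162 (C6H10O5),
#' deoxyhexosyl 146, pentosyl 132, malonyl 86.
#'
#' @return `data.frame` with columns `residue`, `formula`, `mass`.
#' @examples
#' residueTable()
#' @export
residueTable <- function() {
    data.frame(
        residue = c("glucuronyl", "hexosyl", "deoxyhexosyl", "pentosyl",
                    "malonyl"),
        formula = c("C6H8O6", "C6H10O5", "C6H10O4", "C5H8O4", "C3H2O3"),
        mass = c(176L, 162L, 146L, 132L, 86L),
        stringsAsFactors = FALSE)
}

#' Decompose a precursor-to-product mass difference into residue losses
#'
#' @param parentMz,fragmentMz Observed precursor and product m/z;
#'   `parentMz` must exceed `fragmentMz`.
#' @param table A residue table (see [residueTable()]).
#' @param tolerance Allowed |difference - residue mass| (default 0).
#' @return Character vector of matching residue names (possibly empty).
#' @examples
#' neutralLoss(445, 269)   # glucuronyl
#' @export
neutralLoss <- function(parentMz, fragmentMz, table = residueTable(),
                        tolerance = 0) {
    diff <- parentMz - fragmentMz
    if (diff <= 0)
        stop("usage error: parent m/z must exceed fragment m/z")
    table$residue[abs(table$mass - diff) <= tolerance]
}

#' Retro-Diels-Alder cleavage scheme of the flavonoid C ring
#'
#' The 1,3 scheme cleaves the O1-C2 and C3-C4 bonds of a flavanone/flavone C
#' ring, splitting the skeleton into an A-side (ring A plus O1 and the C4
#' carbonyl; for the 5,7-dihydroxy A ring this is C7H4O4, 152 Da neutral)
#' and the complementary B-side (ring B plus C2-C3).  The partition is
#' encoded as explicit element formulas; the B-side is obtained by
#' element-wise subtraction from the parent, so complementarity holds by
#' construction.
#'
#' @param name Scheme label.
#' @param aSide A-side neutral formula (default `"C7H4O4"`).
#' @return A list with elements `name` and `aSide`.
#' @export
rda13Scheme <- function(name = "1,3 RDA", aSide = "C7H4O4") {
    list(name = name, aSide = .asFormula(aSide))
}

.subtractFormula <- function(parent, part) {
    els <- union(names(parent@counts), names(part@counts))
    pc <- stats::setNames(rep(0L, length(els)), els)
    pc[names(parent@counts)] <- parent@counts
    qc <- stats::setNames(rep(0L, length(els)), els)
    qc[names(part@counts)] <- part@counts
    pc - qc
}

#' Retro-Diels-Alder fragment ions of an aglycone
#'
#' Applies a C-ring cleavage scheme to an aglycone formula and returns the
#' neutral masses and singly deprotonated m/z of both complementary sides.
#' For naringenin (C15H12O5) the 1,3 scheme yields the 151 (A-side) and 119
#' (B-side) ions.
#'
#' @param aglycone A [MolecularFormula] or formula string.
#' @param scheme A cleavage scheme (see [rda13Scheme()]).
#' @return A list: `aNeutral`, `bNeutral` ([MolecularFormula]),
#'   `aNeutralMass`, `bNeutralMass`, `aIonMz`, `bIonMz`.
#' @examples
#' rdaFragments("C15H12O5")   # naringenin: ions 151 and 119
#' @export
rdaFragments <- function(aglycone, scheme = rda13Scheme()) {
    parent <- .asFormula(aglycone)
    bCounts <- .subtractFormula(parent, scheme$aSide)
    if (any(bCounts < 0L) || sum(bCounts) < 1L)
        stop("chemistry error: aglycone '", formulaString(parent),
             "' is not consistent with the ", scheme$name, " skeleton")
    bSide <- new("MolecularFormula", counts = bCounts[bCounts > 0L],
                 label = paste(parent@label, "B-side"))
    aSide <- scheme$aSide
    aSide@label <- paste(parent@label, "A-side")
    list(aNeutral = aSide, bNeutral = bSide,
         aNeutralMass = nominalMass(aSide), bNeutralMass = nominalMass(bSide),
         aIonMz = deprotonatedMz(aSide), bIonMz = deprotonatedMz(bSide))
}

#' Annotate a peak list against a compound library
#'
#' Each peak is matched, in rule precedence, to (i) a molecular ion of a
#' library species (the deprotonated `[M-H]-` ion, or the radical anion at
#' the neutral nominal mass, as seen after homolytic glycosidic cleavage),
#' (ii) the species minus combinations of up to two of its attached
#' residues, or (iii) a retro-Diels-Alder fragment of the aglycone.
#' Unmatched peaks are reported as `unassigned`.  Output is ordered by m/z
#' then rule precedence, so annotation is deterministic.
#'
#' @param peaks Numeric vector of observed m/z values (non-empty).
#' @param library List of species; each a list with `name`, `formula`
#'   (aglycone), and optionally `residues` (character vector of residue
#'   names attached to the aglycone).
#' @param table Residue table (see [residueTable()]).
#' @param schemes List of cleavage schemes applied to each aglycone.
#' @param tolerance Allowed |observed - expected| m/z (default 0).
#' @return `data.frame` with columns `mz`, `species`, `formula`, `ion`,
#'   `rule`, `loss`, `expected_mz`, `error`.
#' @examples
#' lib <- list(list(name = "apigenin-7-glucuronide", formula = "C15H10O5",
#'                  residues = "glucuronyl"))
#' annotateSpectrum(c(445, 269), lib)
#' @export
annotateSpectrum <- function(peaks, library, table = residueTable(),
                             schemes = list(rda13Scheme()), tolerance = 0) {
    if (!length(peaks))
        stop("usage error: peak list is empty")
    if (!length(library))
        stop("usage error: compound library is empty")

    resMass <- stats::setNames(table$mass, table$residue)
    cand <- list()
    for (sp in library) {
        agly <- .asFormula(sp$formula)
        residues <- if (is.null(sp$residues)) character(0) else sp$residues
        unknown <- setdiff(residues, names(resMass))
        if (length(unknown))
            stop("usage error: unknown residue '", unknown[1], "' for species '",
                 sp$name, "'")
        fullMass <- nominalMass(agly) + sum(resMass[residues])
        ## rule i: molecular ion of the full (glycosylated) species
        cand[[length(cand) + 1L]] <- data.frame(
            species = sp$name, formula = formulaString(agly),
            ion = "[M-H]-", rule = "molecular ion", loss = NA_character_,
            expected_mz = fullMass - 1L, prec = 1L, stringsAsFactors = FALSE)
        cand[[length(cand) + 1L]] <- data.frame(
            species = sp$name, formula = formulaString(agly),
            ion = "[M]-.", rule = "molecular ion", loss = NA_character_,
            expected_mz = fullMass, prec = 1.5, stringsAsFactors = FALSE)
        ## rule ii: neutral loss of 1..2 attached residues
        if (length(residues)) {
            combos <- c(lapply(seq_along(residues), function(i) residues[i]))
            if (length(residues) >= 2L)
                combos <- c(combos, utils::combn(residues, 2L, simplify = FALSE))
            for (cb in combos) {
                lost <- sum(resMass[cb])
                for (ionDelta in c(1L, 0L))
                    cand[[length(cand) + 1L]] <- data.frame(
                        species = sp$name, formula = formulaString(agly),
                        ion = if (ionDelta == 1L) "[M-H]-" else "[M]-.",
                        rule = "neutral loss",
                        loss = paste(cb, collapse = "+"),
                        expected_mz = fullMass - lost - ionDelta,
                        prec = 2L + (1L - ionDelta) / 10, stringsAsFactors = FALSE)
            }
        }
        ## rule iii: RDA fragments of the aglycone
        for (sc in schemes) {
            fr <- tryCatch(rdaFragments(agly, sc), error = function(e) NULL)
            if (is.null(fr)) next
            cand[[length(cand) + 1L]] <- data.frame(
                species = sp$name, formula = formulaString(fr$aNeutral),
                ion = "[A-H]-", rule = sc$name, loss = NA_character_,
                expected_mz = fr$aIonMz, prec = 3L, stringsAsFactors = FALSE)
            cand[[length(cand) + 1L]] <- data.frame(
                species = sp$name, formula = formulaString(fr$bNeutral),
                ion = "[B-H]-", rule = sc$name, loss = NA_character_,
                expected_mz = fr$bIonMz, prec = 3L, stringsAsFactors = FALSE)
        }
    }
    cand <- do.call(rbind, cand)

    out <- lapply(sort(peaks), function(mz) {
        hit <- cand[abs(cand$expected_mz - mz) <= tolerance, , drop = FALSE]
        if (!nrow(hit))
            return(data.frame(mz = mz, species = NA_character_,
                              formula = NA_character_, ion = NA_character_,
                              rule = "unassigned", loss = NA_character_,
                              expected_mz = NA_real_, error = NA_real_,
                              stringsAsFactors = FALSE))
        hit <- hit[order(hit$prec, abs(hit$expected_mz - mz)), , drop = FALSE][1L, ]
        data.frame(mz = mz, species = hit$species, formula = hit$formula,
                   ion = hit$ion, rule = hit$rule, loss = hit$loss,
                   expected_mz = hit$expected_mz,
                   error = mz - hit$expected_mz, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
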