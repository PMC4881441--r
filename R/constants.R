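# Shared physical constants, residue tables and DS119 segment definitions.

#' Boltzmann constant in kcal/(mol K)
#'
#' Single source of truth for converting bin probabilities to free energies.
#'
#' @return A length-one numeric, 0.0019872041 kcal mol^-1 K^-1.
#' @export
kB <- 0.0019872041

#' The DS119 amino-acid sequence
#'
#' The 36-residue one-letter sequence of the designed beta-alpha-beta
#' mini-protein DS119. Residue 1 is Gly; the alpha-helix spans residues
#' 14-27 and the two parallel beta-strands span residues 5-10 and 29-34.
#'
#' @return A length-one character string of 36 letters.
#' @examples
#' nchar(ds119_sequence())
#' @export
ds119_sequence <- function() "GSGQVRTIWVGGTPEELKKLKEEAKKANIRVTFWGD"

#' DS119 secondary-structure segment ranges
#'
#' Inclusive 1-based residue ranges of the designed fold: the alpha-helix
#' (14-27) and the two beta-strands (5-10 and 29-34). These are the atom
#' sets behind the whole-protein RMSD, alpha-RMSD and beta-RMSD order
#' parameters.
#'
#' @return A named list with elements `helix` (one range) and `sheet`
#'   (two ranges), each a two-column matrix of (start, end) rows.
#' @export
ds119_segments <- function() {
  list(
    helix = matrix(c(14L, 27L), ncol = 2,
                   dimnames = list(NULL, c("start", "end"))),
    sheet = matrix(c(5L, 29L, 10L, 34L), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  )
}

#' Hydrophobic-core residue set of DS119
#'
#' The eight residues whose solvent-accessible surface area is summed into
#' the `core_sasa` order parameter: Ile8, Val10, Leu17, Leu20, Ala24,
#' Ile29, Val31 and Phe33.
#'
#' @param validate_against Optional one-letter sequence; when supplied, the
#'   residue identities at the core positions are checked against the
#'   expected amino acids and a mismatch is an error.
#' @return An integer vector of 1-based residue indices.
#' @examples
#' core_definition(validate_against = ds119_sequence())
#' @export
core_definition <- function(validate_against = NULL) {
  core <- c(8L, 10L, 17L, 20L, 24L, 29L, 31L, 33L)
  expected <- c("I", "V", "L", "L", "A", "I", "V", "F")
  if (!is.null(validate_against)) {
    got <- strsplit(validate_against, "")[[1]][core]
    if (!identical(got, expected)) {
      abort(sprintf(
        "core residue identities %s do not match expected %s",
        paste(got, collapse = ""), paste(expected, collapse = "")))
    }
  }
  core
}

# one-letter <-> three-letter amino acid tables (standard 20)
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa1 <- setNames(names(.aa3), .aa3)

# atomic masses (g/mol) and van der Waals radii (Angstrom) for protein
# heavy atoms plus hydrogen
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
.vdw_radius <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

# indole ring heavy atoms of tryptophan, used for the W9-W34 distance
.trp_ring_atoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                     "CZ2", "CZ3", "CH2")

# infer the element symbol from a (protein) atom name
infer_element <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  el <- substr(stripped, 1, 1)
  bad <- !el %in% names(.element_mass)
  if (any(bad)) {
    abort(sprintf("cannot infer element for atom name(s): %s",
                  paste(unique(name[bad]), collapse = ", ")))
  }
  el
}
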