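#' @include AllClasses.R
NULL

.aminoAcids3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                  "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                  "TYR", "VAL", "MSE", "SEC", "PYL")
.dnaResidues <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "T", "U", "I")

## Average residue masses (Da) of amino-acid residues in a chain (monomer mass
## minus water); used for chain mass book-keeping of PDB inputs.
.aaResidueMass <- c(
  ALA = 71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886, CYS = 103.1388,
  GLN = 128.1307, GLU = 129.1155, GLY = 57.0519, HIS = 137.1411, ILE = 113.1594,
  LEU = 113.1594, LYS = 128.1741, MET = 131.1926, PHE = 147.1766, PRO = 97.1167,
  SER = 87.0782, THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326,
  MSE = 178.1250, SEC = 150.0379, PYL = 237.3018)

#' Extract protein and DNA particle clouds from a PDB file
#'
#' Reads ATOM records (via bio3d), keeps heavy atoms only (hydrogens dropped),
#' retains the first alternate location, excludes waters and heteroatoms, and
#' splits particles into protein and DNA clouds by residue name. Coordinates
#' are converted from Angstrom to nm.
#'
#' @param path PDB file path.
#' @param chains optional character vector of chain ids to keep.
#' @param includeDna logical; if `FALSE` the DNA cloud is `NULL`.
#' @return list with elements `protein` and `dna` ([ParticleCloud-class] or
#'   `NULL` when a class has no atoms).
#' @export
readPdbParticles <- function(path, chains = NULL, includeDna = TRUE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("readPdbParticles: no ATOM records in ", path)
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!nrow(at)) stop("readPdbParticles: no ATOM records left after chain filter")
  ## first alternate location only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ## heavy atoms: drop hydrogens by element symbol, falling back to atom name
  elt <- toupper(trimws(at$elesy))
  noElt <- is.na(elt) | elt == ""
  elt[noElt] <- substr(gsub("^[0-9]*", "", toupper(trimws(at$elety[noElt]))), 1, 1)
  at <- at[!elt %in% c("H", "D"), , drop = FALSE]
  resid <- toupper(trimws(at$resid))
  isProt <- resid %in% .aminoAcids3
  isDna <- resid %in% .dnaResidues
  unknown <- unique(resid[!isProt & !isDna])
  if (length(unknown))
    warning("readPdbParticles: excluding unknown residues: ",
            paste(unknown, collapse = ", "))
  mk <- function(rows, role) {
    if (!any(rows)) return(NULL)
    a <- at[rows, , drop = FALSE]
    new("ParticleCloud",
        positions = cbind(a$x, a$y, a$z) / 10,
        labels = data.frame(chain = a$chain, resid = a$resno, resname = a$resid,
                            atom = trimws(a$elety), stringsAsFactors = FALSE),
        role = role)
  }
  list(protein = mk(isProt, "protein"),
       dna = if (includeDna) mk(isDna, "dna") else NULL)
}

#' Protein chain mass from residue composition
#'
#' Sums average amino-acid residue masses over one chain of a protein particle
#' cloud (one residue counted once) and adds one water for the termini.
#'
#' @param cloud a protein [ParticleCloud-class] from [readPdbParticles()].
#' @param chain chain id; default the first chain present.
#' @return mass in kDa.
#' @export
proteinChainMass <- function(cloud, chain = NULL) {
  stopifnot(is(cloud, "ParticleCloud"), cloud@role == "protein")
  lab <- cloud@labels
  if (is.null(chain)) chain <- lab$chain[1]
  lab <- lab[lab$chain == chain, , drop = FALSE]
  res <- lab$resname[!duplicated(lab$resid)]
  known <- res %in% names(.aaResidueMass)
  if (!all(known))
    warning("proteinChainMass: unknown residues skipped: ",
            paste(unique(res[!known]), collapse = ", "))
  (sum(.aaResidueMass[res[known]]) + 18.0153) / 1000
}

#' Per-nucleotide anchor points of a crystal duplex
#'
#' Collapses each DNA residue to one anchor (mean of its heavy atoms), grouped
#' and ordered by chain and residue number.
#'
#' @param dna a DNA [ParticleCloud-class].
#' @return list with `anchors` (m x 3 matrix) and `info` (data.frame chain, resid).
#' @export
dnaResidueAnchors <- function(dna) {
  stopifnot(is(dna, "ParticleCloud"), dna@role == "dna")
  key <- paste(dna@labels$chain, dna@labels$resid, sep = "|")
  ord <- order(dna@labels$chain, dna@labels$resid)
  ukey <- unique(key[ord])
  anchors <- t(vapply(ukey, function(k) {
    colMeans(dna@positions[key == k, , drop = FALSE])
  }, numeric(3)))
  parts <- strsplit(ukey, "\\|")
  list(anchors = anchors,
       info = data.frame(chain = vapply(parts, `[`, "", 1),
                         resid = as.integer(vapply(parts, `[`, "", 2)),
                         stringsAsFactors = FALSE))
}
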