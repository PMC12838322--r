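#' @import methods
NULL

# Central atom table column set; one row per heavy atom of the polymer.
.ATOM_COLS <- c("chain", "resno", "ins", "resid", "elety", "elem",
                "x", "y", "z", "o", "het")

#' ProteinStructure: chains of residues of heavy atoms, plus bound metal ions
#'
#' The core container every analysis in the package consumes. Atoms are held
#' as a flat data.frame (one row per heavy atom) with author residue
#' numbering preserved verbatim; bound metal ions (Ca, Zn, Na, Mg, K
#' HETATM records) live in a separate table so that polymer analyses and
#' ion-centred analyses never mix them up.
#'
#' @slot atoms data.frame with columns \code{chain} (character),
#'   \code{resno} (integer, author numbering), \code{ins} (insertion code,
#'   "" if none), \code{resid} (3-letter residue name), \code{elety}
#'   (PDB atom name, e.g. "OD1"), \code{elem} (element symbol), \code{x,y,z}
#'   (Angstrom), \code{o} (occupancy), \code{het} (logical, HETATM origin).
#' @slot ions data.frame with columns \code{elem}, \code{x}, \code{y},
#'   \code{z} for bound metal ions.
#' @slot title character(1), free text.
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(atoms = "data.frame",
                        ions = "data.frame",
                        title = "character"),
         prototype(atoms = data.frame(),
                   ions = data.frame(elem = character(), x = numeric(),
                                     y = numeric(), z = numeric()),
                   title = ""))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return("structure contains no atoms")
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss))
    return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite atom coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  if (any(!nzchar(a$elety)))
    return("empty atom name")
  key <- paste(a$chain, a$resno, a$ins, a$elety)
  if (anyDuplicated(key))
    return("duplicate atom (chain, resno, ins, name) after altloc resolution")
  TRUE
})

#' @describeIn ProteinStructure atom table accessor
#' @param x,object a \code{ProteinStructure}
#' @export
atoms <- function(x) x@atoms

#' @describeIn ProteinStructure bound metal-ion table accessor
#' @export
ions <- function(x) x@ions

#' Per-residue index of a structure
#'
#' One row per polymer residue, in file order: chain, resno, ins, resid and
#' a residue key used throughout the package ("chain/resno" or
#' "chain/resno^ins" when an insertion code is present).
#'
#' @param x a \code{ProteinStructure}
#' @return data.frame with columns \code{key}, \code{chain}, \code{resno},
#'   \code{ins}, \code{resid}
#' @export
residueTable <- function(x) {
  a <- atoms(x)
  key <- residueKey(a$chain, a$resno, a$ins)
  idx <- !duplicated(key)
  data.frame(key = key[idx], chain = a$chain[idx], resno = a$resno[idx],
             ins = a$ins[idx], resid = a$resid[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Residue key string ("chain/resno" with optional "^ins" suffix)
#' @param chain,resno,ins vectors of chain id, residue number, insertion code
#' @export
residueKey <- function(chain, resno, ins = "") {
  if (length(chain) == 0L || length(resno) == 0L) return(character(0))
  paste0(chain, "/", resno, ifelse(nzchar(ins), paste0("^", ins), ""))
}

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  ch <- unique(rt$chain)
  cat("ProteinStructure:",
      if (nzchar(object@title)) object@title else "<untitled>", "\n")
  cat("  ", nrow(rt), " residues in ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ", nrow(object@atoms),
      " heavy atoms, ", nrow(object@ions), " bound ion(s)\n", sep = "")
})

#' SasaResult: solvent-accessible surface areas and relative accessibility
#'
#' Returned by \code{\link{computeSasa}}. Per-atom areas are in Angstrom^2;
#' per-residue totals are exact sums of the residue's atom areas. RASA
#' (percent) is filled in by \code{\link{computeRasa}} and may exceed 100
#' for conformations more exposed than the extended Gly-X-Gly reference.
#'
#' @slot atomArea numeric, one entry per row of the structure's atom table.
#' @slot residues data.frame: key, chain, resno, ins, resid, area_total,
#'   area_sidechain, rasa (NA until computed, NaN never), rasa_defined.
#' @slot probeRadius numeric(1), Angstrom.
#' @slot nSpherePoints integer(1).
#'
#' @exportClass SasaResult
setClass("SasaResult",
         representation(atomArea = "numeric",
                        residues = "data.frame",
                        probeRadius = "numeric",
                        nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@atomArea < 0)) return("negative atom area")
  r <- object@residues
  if (any(r$area_total < -1e-9)) return("negative residue area")
  TRUE
})

setMethod("show", "SasaResult", function(object) {
  r <- object@residues
  cat("SasaResult: ", nrow(r), " residues, probe ", object@probeRadius,
      " A, ", object@nSpherePoints, " sphere points\n", sep = "")
  cat("  total SASA ", format(sum(object@atomArea), digits = 6), " A^2\n",
      sep = "")
})

#' @describeIn SasaResult per-residue area/RASA table accessor
#' @param x a \code{SasaResult}
#' @export
residueAreas <- function(x) x@residues

#' @describeIn SasaResult per-atom area accessor
#' @export
atomAreas <- function(x) x@atomArea
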