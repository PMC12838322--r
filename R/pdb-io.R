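# Fixed-width PDB v3.3 reader/writer with the package's atom policy:
# hydrogens and waters discarded, altlocs resolved to the highest-occupancy
# copy (ties -> alphabetically first altloc id), metal HETATMs routed to the
# ions table. Author residue numbering is preserved verbatim.

.METAL_ELEMS <- c("CA", "ZN", "NA", "MG", "K")
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.guessElement <- function(name, resid, het) {
  nm <- gsub("[0-9']", "", trimws(name))
  if (!nzchar(nm)) return("")
  up <- toupper(nm)
  if (het && up %in% .METAL_ELEMS && toupper(trimws(resid)) %in% .METAL_ELEMS)
    return(up)
  first <- substr(up, 1L, 1L)
  if (first %in% c("H", "D") && !het) return("H")
  first
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records from PDB text. Hydrogens and waters are
#' discarded; alternate locations are resolved to the highest-occupancy copy
#' (ties broken by the alphabetically first altloc id); metal HETATM records
#' (Ca, Zn, Na, Mg, K) are routed to the ion table of the returned object.
#'
#' @param file path to a PDB file, or \code{NULL} if \code{text} is given
#' @param text character vector of PDB lines (or a single string with
#'   embedded newlines), used instead of \code{file}
#' @return a \code{\linkS4class{ProteinStructure}}
#' @examples
#' gly <- c(
#'  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C")
#' readPDB(text = gly)
#' @export
readPDB <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0L) stop("no atoms: empty PDB input")

  rec <- substr(lines, 1L, 6L)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(sel) == 0L) stop("no atoms: input contains no ATOM/HETATM records")

  ln <- lines[sel]
  num <- function(lo, hi, what) {
    s <- trimws(substr(ln, lo, hi))
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!nzchar(s) | is.na(v))
    if (what %in% c("x", "y", "z") && length(bad))
      stop(sprintf("parse error at line %d: malformed %s coordinate field",
                   sel[bad[1L]], what))
    v
  }
  title <- trimws(substr(lines[rec == "TITLE "][1L], 11L, 80L))
  if (is.na(title) || !length(title)) title <- ""

  a <- data.frame(
    chain = substr(ln, 22L, 22L),
    resno = suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L)))),
    ins = trimws(substr(ln, 27L, 27L)),
    resid = trimws(substr(ln, 18L, 20L)),
    elety = trimws(substr(ln, 13L, 16L)),
    alt = trimws(substr(ln, 17L, 17L)),
    elem = toupper(trimws(substr(ln, 77L, 78L))),
    x = num(31L, 38L, "x"), y = num(39L, 46L, "y"), z = num(47L, 54L, "z"),
    o = num(55L, 60L, "occupancy"),
    het = substr(ln, 1L, 6L) == "HETATM",
    stringsAsFactors = FALSE)
  if (anyNA(a$resno))
    stop(sprintf("parse error at line %d: malformed residue number",
                 sel[which(is.na(a$resno))[1L]]))
  a$o[is.na(a$o)] <- 1
  noel <- !nzchar(a$elem)
  if (any(noel))
    a$elem[noel] <- mapply(.guessElement, a$elety[noel], a$resid[noel],
                           a$het[noel])

  a <- a[!(a$elem %in% c("H", "D")), , drop = FALSE]
  a <- a[!(toupper(a$resid) %in% .WATER_NAMES), , drop = FALSE]

  is_ion <- a$het & a$elem %in% .METAL_ELEMS &
    toupper(a$resid) %in% .METAL_ELEMS
  ions <- data.frame(elem = a$elem[is_ion], x = a$x[is_ion], y = a$y[is_ion],
                     z = a$z[is_ion], stringsAsFactors = FALSE)
  a <- a[!is_ion, , drop = FALSE]
  if (nrow(a) == 0L && nrow(ions) == 0L)
    stop("no atoms: all records discarded by policy")

  # altloc resolution: highest occupancy wins; ties -> first altloc id
  if (any(nzchar(a$alt))) {
    key <- paste(a$chain, a$resno, a$ins, a$elety)
    ord <- order(key, -a$o, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$ins, a$elety)), , drop = FALSE]
    a <- a[order(match(paste(a$chain, a$resno, a$ins, a$elety), unique(key))), ,
           drop = FALSE]
  }
  a$alt <- NULL
  rownames(a) <- NULL
  new("ProteinStructure", atoms = a, ions = ions, title = title)
}

.fmtAtomName <- function(name, elem) {
  # column 13 is blank for 1-letter elements with short names (PDB v3.3)
  if (nchar(elem) == 1L && nchar(name) <= 3L) sprintf(" %-3s", name)
  else sprintf("%-4s", name)
}

#' Write a structure as PDB text
#'
#' Emits fixed-width ATOM records (plus HETATM records for bound ions and
#' TER/END) such that \code{readPDB(text = writePDB(s))} reproduces residue
#' and atom identities and coordinates to the PDB precision of 0.001 A.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param file optional path; when given, lines are also written to it
#' @return character vector of PDB lines (invisibly when \code{file} given)
#' @export
writePDB <- function(structure, file = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- atoms(structure)
  if (nrow(a) == 0L) stop("cannot write an empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000))
    stop("coordinate outside the PDB fixed-width field (|x| >= 10000 A)")

  out <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    ai <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (ai$het[i]) "HETATM" else "ATOM", serial,
        .fmtAtomName(ai$elety[i], ai$elem[i]), "", ai$resid[i],
        ch, ai$resno[i], ai$ins[i], ai$x[i], ai$y[i], ai$z[i], ai$o[i], 0,
        ai$elem[i]))
    }
    last <- ai[nrow(ai), ]
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s", serial,
                          last$resid, ch, last$resno, last$ins))
  }
  io <- ions(structure)
  for (i in seq_len(nrow(io))) {
    serial <- serial + 1L
    out <- c(out, sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "HETATM", serial, io$elem[i], "", io$elem[i], "I", 900L + i, "",
      io$x[i], io$y[i], io$z[i], 1, 0, io$elem[i]))
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
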