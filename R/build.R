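# Synthetic peptide builder: sequential internal-coordinate (NeRF) chain
# extension with ideal covalent geometry. Used to plant ground-truth
# features (turns, salt bridges, burial, coordination shells) for tests.

#' Per-residue dihedral specification for the backbone builder
#'
#' @param resid character vector of 3-letter residue names
#' @param phi,psi backbone dihedrals in degrees, range (-180, 180]; the
#'   first residue's phi and the last residue's psi may be \code{NA}
#' @param omega peptide-bond dihedral preceding each residue (degrees),
#'   default trans (180); the first residue's omega is ignored
#' @return data.frame consumed by \code{\link{buildBackbone}}
#' @export
dihedralSpec <- function(resid, phi, psi, omega = 180) {
  n <- length(resid)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  ok <- function(v) all(is.na(v) | (v > -180 & v <= 180))
  if (!ok(phi) || !ok(psi) || !ok(omega))
    stop("dihedral angles must lie in (-180, 180]")
  if (!all(toupper(resid) %in% .AA3))
    stop("unknown residue name in spec: ",
         paste(setdiff(toupper(resid), .AA3), collapse = ", "))
  data.frame(resid = toupper(resid), phi = phi, psi = psi, omega = omega,
             stringsAsFactors = FALSE)
}

#' Build backbone coordinates from a dihedral specification
#'
#' Places N/CA/C/O for each residue by sequential NeRF extension with ideal
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 A; angles
#' N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.7 deg; carbonyl O in the peptide
#' plane). Measuring phi/psi/omega on the result reproduces the spec.
#'
#' @param spec data.frame from \code{\link{dihedralSpec}}
#' @param chain chain identifier for the emitted residues
#' @param startResno first residue number
#' @return a \code{\linkS4class{ProteinStructure}} (backbone only)
#' @export
buildBackbone <- function(spec, chain = "A", startResno = 1L) {
  n <- nrow(spec)
  if (is.null(n) || n < 2L) stop("backbone spec needs at least 2 residues")
  if (anyNA(spec$psi[-n])) stop("psi required for all but the last residue")
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.BB$b_N_CA, 0, 0)
  th <- .BB$a_N_CA_C * pi / 180
  C[1L, ] <- CA[1L, ] + .BB$b_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ] <- .placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         .BB$b_C_N, .BB$a_CA_C_N, spec$psi[i - 1L])
    CA[i, ] <- .placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          .BB$b_N_CA, .BB$a_C_N_CA, spec$omega[i])
    phi <- spec$phi[i]
    if (is.na(phi)) phi <- -140
    C[i, ] <- .placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                         .BB$b_CA_C, .BB$a_N_CA_C, phi)
  }
  for (i in seq_len(n)) {
    psi <- spec$psi[i]
    if (is.na(psi)) psi <- 180
    tors <- psi + 180
    if (tors > 180) tors <- tors - 360
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                         .BB$b_C_O, .BB$a_CA_C_O, tors)
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(chain = chain, resno = startResno + i - 1L, ins = "",
               resid = spec$resid[i], elety = c("N", "CA", "C", "O"),
               elem = c("N", "C", "C", "O"),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               o = 1, het = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  new("ProteinStructure", atoms = rows, title = "synthetic backbone")
}

#' Measure backbone dihedrals of a structure
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @return data.frame with key, chain, resno, resid, phi, psi, omega
#'   (degrees; NA where the flanking residue is absent)
#' @export
measureBackboneDihedrals <- function(structure) {
  a <- atoms(structure)
  rt <- residueTable(structure)
  get <- function(i, name) {
    sel <- a$chain == rt$chain[i] & a$resno == rt$resno[i] &
      a$ins == rt$ins[i] & a$elety == name
    if (!any(sel)) return(NULL)
    as.numeric(a[which(sel)[1L], c("x", "y", "z")])
  }
  n <- nrow(rt)
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    prev_ok <- i > 1L && rt$chain[i - 1L] == rt$chain[i]
    next_ok <- i < n && rt$chain[i + 1L] == rt$chain[i]
    if (prev_ok) {
      Cp <- get(i - 1L, "C"); CAp <- get(i - 1L, "CA")
      if (!is.null(Cp)) phi[i] <- dihedralAngle(Cp, Ni, CAi, Ci)
      if (!is.null(Cp) && !is.null(CAp))
        omega[i] <- dihedralAngle(CAp, Cp, Ni, CAi)
    }
    if (next_ok) {
      Nn <- get(i + 1L, "N")
      if (!is.null(Nn)) psi[i] <- dihedralAngle(Ni, CAi, Ci, Nn)
    }
  }
  cbind(rt, phi = phi, psi = psi, omega = omega)
}

.residueCoords <- function(a, chain, resno, ins = "") {
  sel <- a$chain == chain & a$resno == resno & a$ins == ins
  sub <- a[sel, , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$elety
  m
}

#' Attach an ideal-geometry side chain to a residue
#'
#' Places side-chain atoms from the canonical rigid rotamer template of the
#' residue's type, oriented on its backbone frame (CB tetrahedral off
#' N-CA-C with L-chirality). Atom names follow PDB conventions.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param chain,resno,ins residue identifier
#' @param chi optional named numeric of torsion overrides, keyed by the
#'   side-chain atom the torsion places (e.g. \code{c(CG = -60)})
#' @return the structure with the side-chain atoms appended
#' @export
attachSidechain <- function(structure, chain, resno, ins = "", chi = NULL) {
  a <- atoms(structure)
  sel <- a$chain == chain & a$resno == resno & a$ins == ins
  if (!any(sel)) stop("residue not found: ", residueKey(chain, resno, ins))
  resname <- toupper(a$resid[which(sel)[1L]])
  if (resname == "GLY") stop("GLY has no side chain to attach")
  if (!resname %in% .AA3) stop("no side-chain template for ", resname)
  bb <- .residueCoords(a, chain, resno, ins)
  if (!all(c("N", "CA", "C") %in% rownames(bb)))
    stop("residue lacks complete backbone N/CA/C")
  have <- rownames(bb)
  pos <- list(N = bb["N", ], CA = bb["CA", ], C = bb["C", ])
  newAtoms <- list()
  if (!"CB" %in% have) {
    pos$CB <- .placeAtom(pos$N, pos$C, pos$CA, .BB$b_CA_CB, .BB$a_C_CA_CB,
                         .BB$t_N_C_CA_CB)
    newAtoms$CB <- pos$CB
  } else pos$CB <- bb["CB", ]
  zm <- .SIDECHAIN_ZMAT[[resname]]
  if (!is.null(zm)) {
    for (j in seq_len(nrow(zm))) {
      tors <- zm$chi[j]
      if (!is.null(chi) && zm$name[j] %in% names(chi))
        tors <- unname(chi[zm$name[j]])
      pos[[zm$name[j]]] <- .placeAtom(pos[[zm$a[j]]], pos[[zm$b[j]]],
                                      pos[[zm$c[j]]], zm$r[j], zm$theta[j],
                                      tors)
      if (!zm$name[j] %in% have) newAtoms[[zm$name[j]]] <- pos[[zm$name[j]]]
    }
  }
  if (length(newAtoms)) {
    xyz <- do.call(rbind, newAtoms)
    add <- data.frame(chain = chain, resno = resno, ins = ins,
                      resid = resname, elety = names(newAtoms),
                      elem = vapply(names(newAtoms), .elemFromName, ""),
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      o = 1, het = FALSE, stringsAsFactors = FALSE)
    # keep residue atoms contiguous in file order
    last <- max(which(sel))
    a <- rbind(a[seq_len(last), , drop = FALSE], add,
               if (last < nrow(a)) a[(last + 1L):nrow(a), , drop = FALSE])
    rownames(a) <- NULL
  }
  initialize(structure, atoms = a)
}

#' Build a peptide with side chains from a dihedral specification
#'
#' Convenience wrapper: \code{\link{buildBackbone}} followed by
#' \code{\link{attachSidechain}} on every non-Gly residue.
#'
#' @inheritParams buildBackbone
#' @return a \code{\linkS4class{ProteinStructure}}
#' @export
buildPeptide <- function(spec, chain = "A", startResno = 1L) {
  s <- buildBackbone(spec, chain = chain, startResno = startResno)
  for (i in seq_len(nrow(spec))) {
    if (toupper(spec$resid[i]) != "GLY")
      s <- attachSidechain(s, chain, startResno + i - 1L)
  }
  s
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param rotation 3x3 rotation matrix (default identity)
#' @param translation numeric 3-vector (default zero)
#' @return the transformed structure (polymer atoms and ions)
#' @export
transformStructure <- function(structure, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
  a$x <- xyz[, 1L] + translation[1L]
  a$y <- xyz[, 2L] + translation[2L]
  a$z <- xyz[, 3L] + translation[3L]
  io <- ions(structure)
  if (nrow(io)) {
    ixyz <- as.matrix(io[, c("x", "y", "z")]) %*% t(rotation)
    io$x <- ixyz[, 1L] + translation[1L]
    io$y <- ixyz[, 2L] + translation[2L]
    io$z <- ixyz[, 3L] + translation[3L]
  }
  initialize(structure, atoms = a, ions = io)
}

# uniform random rotation (seeded callers' responsibility)
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
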