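# Ground-truth fixture generators. Each returns a structure plus a planted
# feature log ({kind, residues, target, achieved}) so downstream detectors
# can be tested against known geometry without any external data.

.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

#' Combine structures into one
#'
#' Atom tables are concatenated in order; chains must not collide on
#' (chain, resno, ins).
#'
#' @param ... \code{ProteinStructure} objects
#' @return a single \code{\linkS4class{ProteinStructure}}
#' @export
combineStructures <- function(...) {
  xs <- list(...)
  a <- do.call(rbind, lapply(xs, atoms))
  io <- do.call(rbind, lapply(xs, ions))
  rownames(a) <- NULL
  new("ProteinStructure", atoms = a, ions = io,
      title = "combined synthetic structure")
}

.featureEntry <- function(kind, residues, target, achieved) {
  list(kind = kind, residues = residues, target = target, achieved = achieved)
}

#' Write a planted-feature log as JSON
#'
#' @param log list of feature entries from the fixture generators
#' @param path output path
#' @export
writeFeatureLog <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# extended single residue with side chain, centred frame
.singleResidue <- function(resname, chain = "A", resno = 1L) {
  spec <- dihedralSpec(c(resname, "GLY"), phi = c(NA, -140),
                       psi = c(135, NA))
  s <- buildBackbone(spec, chain = chain, startResno = resno)
  if (toupper(resname) != "GLY") s <- attachSidechain(s, chain, resno)
  a <- atoms(s)
  a <- a[a$resno == resno, , drop = FALSE]
  rownames(a) <- NULL
  initialize(s, atoms = a)
}

.minCrossDistance <- function(A, B, namesA = NULL, namesB = NULL) {
  selA <- if (is.null(namesA)) rep(TRUE, nrow(A)) else A$elety %in% namesA
  selB <- if (is.null(namesB)) rep(TRUE, nrow(B)) else B$elety %in% namesB
  xa <- as.matrix(A[selA, c("x", "y", "z"), drop = FALSE])
  xb <- as.matrix(B[selB, c("x", "y", "z"), drop = FALSE])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  ij <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(min(d2)),
       a = xa[ij[1L], ], b = xb[ij[2L], ])
}

#' Salt-bridge / ion-pair fixture at a prescribed charged-atom distance
#'
#' Builds two Gly-X-Gly tripeptides (X = the acidic and the basic residue)
#' and rigidly translates the basic fragment along the inter-fragment axis
#' until the minimum acidic-O to basic-N distance equals the target within
#' 0.05 Angstrom.
#'
#' @param acid "ASP" or "GLU"
#' @param base "LYS" or "ARG"
#' @param targetMinON target minimum O-N distance in Angstrom, in [2.5, 15]
#' @return list(structure, log)
#' @export
makeSaltBridgeFixture <- function(acid = "ASP", base = "LYS",
                                  targetMinON = 3.5) {
  acid <- toupper(acid); base <- toupper(base)
  stopifnot(acid %in% c("ASP", "GLU"), base %in% c("LYS", "ARG"))
  if (targetMinON < 2.5 || targetMinON > 15)
    stop("target O-N distance must lie in [2.5, 15] Angstrom")
  fragA <- buildPeptide(dihedralSpec(c("GLY", acid, "GLY"),
                                     phi = -140, psi = 135), chain = "A")
  fragB <- buildPeptide(dihedralSpec(c("GLY", base, "GLY"),
                                     phi = -140, psi = 135), chain = "B")
  aA <- atoms(fragA)
  onA <- .ACIDIC_ATOMS[[acid]]
  onB <- .BASIC_ATOMS[[base]]
  # face the charged groups head-on so the backbones stay apart
  grp <- function(at, names) colMeans(as.matrix(
    at[at$resno == 2L & at$elety %in% names, c("x", "y", "z"), drop = FALSE]))
  ca <- function(at) as.numeric(
    at[at$resno == 2L & at$elety == "CA", c("x", "y", "z")])
  vA <- .unit(grp(aA, onA) - ca(aA))
  aB0 <- atoms(fragB)
  vB <- .unit(grp(aB0, onB) - ca(aB0))
  fragB <- transformStructure(fragB, .rotationBetween(vB, -vA))
  aB0 <- atoms(fragB)
  fragB <- transformStructure(
    fragB, translation = grp(aA, onA) + vA * (targetMinON + 6) - grp(aB0, onB))
  for (iter in seq_len(200L)) {
    aB <- atoms(fragB)
    mc <- .minCrossDistance(aA[aA$resno == 2L, ], aB[aB$resno == 2L, ],
                            onA, onB)
    if (abs(mc$dist - targetMinON) < 1e-6) break
    u <- (mc$b - mc$a) / mc$dist
    fragB <- transformStructure(fragB,
                                translation = u * (targetMinON - mc$dist))
  }
  aB <- atoms(fragB)
  achieved <- .minCrossDistance(aA[aA$resno == 2L, ],
                                aB[aB$resno == 2L, ], onA, onB)$dist
  if (abs(achieved - targetMinON) > 0.05)
    stop("could not reach target O-N distance")
  if (.minCrossDistance(aA, aB)$dist < 2.5)
    stop("unreachable target: steric clash (< 2.5 Angstrom contact)")
  s <- combineStructures(fragA, fragB)
  kind <- if (targetMinON <= 4) "salt_bridge"
          else if (targetMinON <= 8) "long_range_pair" else "non_pair"
  log <- list(.featureEntry(kind, c(residueKey("A", 2L), residueKey("B", 2L)),
                            targetMinON, achieved))
  list(structure = s, log = log)
}

#' Burial fixture: a centre residue inside an occluding shell
#'
#' The centre residue sits at the middle of an extended Gly-X-Gly
#' tripeptide translated so its side chain is at the origin; \code{shell}
#' alanine residues are laid tangentially on a sphere around it (residue
#' centroids at \code{shellRadius}, atoms spanning roughly 5-7.5 Angstrom).
#' With \code{shell = 0} the centre side chain is maximally exposed; a
#' dense shell (>= 30 residues at the default radius) buries it below 5\%
#' RASA.
#'
#' @param center 3-letter residue name of the centre residue
#' @param shell number of surrounding alanine residues (>= 0)
#' @param shellRadius length-2 range of shell centroid distances (Angstrom)
#' @param seed integer seed for the deterministic shell arrangement
#' @return list(structure, log)
#' @export
makeBurialFixture <- function(center = "ASP", shell = 30L,
                              shellRadius = c(6, 6), seed = 0L) {
  stopifnot(shell >= 0L)
  center <- toupper(center)
  host <- buildPeptide(dihedralSpec(c("GLY", center, "GLY"),
                                    phi = -140, psi = 135), chain = "A")
  a <- atoms(host)
  sideSel <- a$resno == 2L & !(a$elety %in% .BACKBONE_ATOMS)
  if (!any(sideSel)) sideSel <- a$resno == 2L & a$elety == "CA"
  ctr <- colMeans(as.matrix(a[sideSel, c("x", "y", "z")]))
  host <- transformStructure(host, translation = -ctr)
  parts <- list(host)
  log <- list(.featureEntry("buried_residue", residueKey("A", 2L),
                            if (shell > 0L) shell else 0, NA))
  if (shell > 0L) {
    dirs <- .fibSphere(shell)
    set.seed(seed)
    radii <- stats::runif(shell, shellRadius[1L], shellRadius[2L])
    for (k in seq_len(shell)) {
      dummy <- .singleResidue("ALA", chain = "S", resno = k)
      da <- atoms(dummy)
      xyz <- as.matrix(da[, c("x", "y", "z")])
      cen <- colMeans(xyz)
      dummy <- transformStructure(dummy, translation = -cen)
      # lie the residue flat on the shell: its thinnest principal axis
      # points radially, so the atoms tile the sphere tangentially
      ev <- eigen(stats::cov(sweep(xyz, 2L, cen)), symmetric = TRUE)
      normal <- ev$vectors[, 3L]
      dummy <- transformStructure(dummy, .rotationBetween(normal, dirs[k, ]))
      spin <- stats::runif(1, -pi, pi)
      axis <- dirs[k, ]
      K <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                    -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
      Rspin <- diag(3) + sin(spin) * K + (1 - cos(spin)) * K %*% K
      dummy <- transformStructure(dummy, Rspin, dirs[k, ] * radii[k])
      parts[[k + 1L]] <- dummy
    }
  }
  list(structure = do.call(combineStructures, parts), log = log)
}

.rotationBetween <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  w <- .cross(u, v)
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross(u, p))
    K <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                  -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -w[3L], w[2L], w[3L], 0, -w[1L], -w[2L], w[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Toy metal-coordination fixture
#'
#' Places \code{nLigands} serine hydroxyl oxygens on near-octahedral
#' directions at \code{ionDistance} from a calcium ion at the origin, each
#' attached to its own host residue pointing radially outward.
#'
#' @param nLigands number of coordinating oxygens, in [1, 8]
#' @param ionDistance ligand-ion distance in Angstrom
#' @return list(structure, ion = c(0,0,0), log)
#' @export
makeCoordinationFixture <- function(nLigands = 6L, ionDistance = 2.4) {
  if (nLigands < 1L || nLigands > 8L)
    stop("nLigands must lie in [1, 8]")
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 1) / sqrt(3), c(-1, -1, -1) / sqrt(3))
  parts <- vector("list", nLigands)
  for (k in seq_len(nLigands)) {
    host <- .singleResidue("SER", chain = "L", resno = k)
    ha <- atoms(host)
    og <- as.numeric(ha[ha$elety == "OG", c("x", "y", "z")])
    cb <- as.numeric(ha[ha$elety == "CB", c("x", "y", "z")])
    # OG-to-CB bond radially outward so OG is the innermost oxygen
    R <- .rotationBetween(cb - og, dirs[k, ])
    host <- transformStructure(host, translation = -og)
    host <- transformStructure(host, R, dirs[k, ] * ionDistance)
    parts[[k]] <- host
  }
  s <- do.call(combineStructures, parts)
  s@ions <- data.frame(elem = "CA", x = 0, y = 0, z = 0,
                       stringsAsFactors = FALSE)
  log <- list(.featureEntry("coordination_shell",
                            residueKey("L", seq_len(nLigands)),
                            ionDistance, ionDistance))
  list(structure = s, ion = c(0, 0, 0), log = log)
}
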