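# Solvent-accessible surface area by the sphere-point (Shrake-Rupley style)
# method with a deterministic Fibonacci-spiral point set, and relative
# solvent accessibility (RASA) against extended Gly-X-Gly references.

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.ION_RADII <- c(CA = 2.31, ZN = 1.39, "NA" = 2.27, MG = 1.73, K = 2.75)
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Deterministic per-atom spin of the sphere-point lattice, hashed from the
# atom's own coordinates. Using one shared lattice orientation makes the
# occlusion-boundary quantization of neighbouring atoms correlate, which
# shows up as an orientation-dependent bias of summed areas; a
# coordinate-hashed spin decorrelates it while keeping results a pure
# function of the coordinates (so disjoint fragments are exactly additive).
.latticeSpin <- function(ci) {
  h <- function(k, off) {
    v <- sin(sum(ci * k) + off) * 43758.5453
    v - floor(v)
  }
  z <- 2 * h(c(12.9898, 78.2330, 37.7190), 1) - 1
  th <- 2 * pi * h(c(39.3468, 11.1351, 83.1550), 2)
  ang <- 2 * pi * h(c(26.6519, 63.7743, 9.1189), 3)
  s <- sqrt(max(0, 1 - z^2))
  ax <- c(s * cos(th), s * sin(th), z)
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L],
                -ax[2L], ax[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

# quasi-uniform points on the unit sphere; deterministic, no RNG
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of a structure
#'
#' Sphere-point method: for each heavy atom, the fraction of quasi-uniform
#' points on a sphere of radius (r_vdw + probe) that fall inside no
#' neighbouring expanded sphere, times the sphere area. The point set is a
#' deterministic Fibonacci spiral, so results are bitwise reproducible.
#' Bound metal ions are excluded from both the surface and the occlusion
#' set unless \code{includeIons = TRUE}.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param probe probe radius in Angstrom (water = 1.4)
#' @param nPoints sphere points per atom; 960 converges to ~1\% per residue
#' @param includeIons also treat bound metal ions as occluding spheres
#' @return a \code{\linkS4class{SasaResult}}
#' @export
computeSasa <- function(structure, probe = 1.4, nPoints = 960L,
                        includeIons = FALSE) {
  stopifnot(is(structure, "ProteinStructure"), probe >= 0, nPoints >= 12L)
  a <- atoms(structure)
  if (nrow(a) == 0L) stop("structure has no heavy atoms")
  unknown <- setdiff(unique(a$elem), names(.VDW_RADII))
  if (length(unknown)) {
    bad <- a[a$elem %in% unknown, ][1L, ]
    stop(sprintf("no van der Waals radius for atom %s/%s %s (element '%s')",
                 bad$chain, bad$resno, bad$elety, bad$elem))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- unname(.VDW_RADII[a$elem]) + probe
  nSurf <- nrow(xyz)
  if (includeIons && nrow(ions(structure))) {
    io <- ions(structure)
    bad <- setdiff(io$elem, names(.ION_RADII))
    if (length(bad)) stop("no radius for ion element ", bad[1L])
    xyz <- rbind(xyz, as.matrix(io[, c("x", "y", "z")]))
    rad <- c(rad, unname(.ION_RADII[io$elem]) + probe)
  }
  pts <- .fibSphere(as.integer(nPoints))
  nAll <- nrow(xyz)
  area <- numeric(nAll)
  for (i in seq_len(nAll)) {
    ci <- xyz[i, ]
    d2 <- rowSums(sweep(xyz, 2L, ci)^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(nAll) != i)
    P <- (pts %*% t(.latticeSpin(ci))) * rad[i]
    P <- sweep(P, 2L, ci, "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- sweep(P[free, , drop = FALSE], 2L, xyz[j, ])
      free[free] <- rowSums(dj^2) >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / nPoints
  }
  atomArea <- area[seq_len(nSurf)]
  key <- residueKey(a$chain, a$resno, a$ins)
  rt <- residueTable(structure)
  tot <- tapply(atomArea, factor(key, levels = rt$key), sum)
  isSide <- !(a$elety %in% .BACKBONE_ATOMS) |
    (a$resid == "GLY" & a$elety == "CA")
  side <- tapply(ifelse(isSide, atomArea, 0), factor(key, levels = rt$key),
                 sum)
  res <- cbind(rt,
               area_total = as.numeric(tot),
               area_sidechain = as.numeric(side),
               rasa = NA_real_,
               rasa_defined = as.logical(tapply(isSide,
                                                factor(key, levels = rt$key),
                                                any)))
  rownames(res) <- NULL
  new("SasaResult", atomArea = atomArea, residues = res,
      probeRadius = probe, nSpherePoints = as.integer(nPoints))
}

.refCache <- new.env(parent = emptyenv())

#' Random-coil reference side-chain area of a residue type
#'
#' Side-chain SASA of residue X at the centre of an extended Gly-X-Gly
#' tripeptide (phi = -140, psi = 135, canonical rotamer) at the given probe
#' radius. For Gly the C-alpha atom serves as the side-chain proxy. Values
#' are computed once per (residue, probe, nPoints) and cached, so repeated
#' calls are bitwise identical.
#'
#' @param resid 3-letter residue name
#' @param probe probe radius in Angstrom
#' @param nPoints sphere points per atom (must match the SASA run being
#'   normalised)
#' @return reference area in Angstrom^2
#' @export
referenceArea <- function(resid, probe = 1.4, nPoints = 960L) {
  resid <- toupper(resid)
  if (!resid %in% .AA3 || !resid %in% names(.AA3TO1))
    stop("no reference area for nonstandard residue ", resid)
  keyStr <- paste(resid, format(probe, digits = 12), nPoints, sep = "|")
  if (!is.null(.refCache[[keyStr]])) return(.refCache[[keyStr]])
  spec <- dihedralSpec(c("GLY", resid, "GLY"), phi = -140, psi = 135)
  pep <- buildPeptide(spec)
  sr <- computeSasa(pep, probe = probe, nPoints = nPoints)
  val <- residueAreas(sr)$area_sidechain[2L]
  .refCache[[keyStr]] <- val
  val
}

#' Relative solvent accessibility (RASA) per residue
#'
#' RASA(res) = 100 x side-chain area / reference area of the residue type,
#' where the reference is the extended Gly-X-Gly value at the same probe
#' radius and point count (\code{\link{referenceArea}}). Side chain = all
#' atoms except backbone N/CA/C/O (Gly: CA only). Residues whose
#' side-chain atoms are all missing are flagged undefined and excluded
#' from exposure calls.
#'
#' @param result a \code{\linkS4class{SasaResult}}
#' @return the result with the \code{rasa} column of
#'   \code{\link{residueAreas}} filled in (percent)
#' @export
computeRasa <- function(result) {
  stopifnot(is(result, "SasaResult"))
  r <- result@residues
  std <- r$resid %in% names(.AA3TO1)
  refs <- vapply(unique(r$resid[std]), function(nm)
    referenceArea(nm, probe = result@probeRadius,
                  nPoints = result@nSpherePoints), numeric(1))
  r$rasa <- NA_real_
  ok <- std & r$rasa_defined
  r$rasa[ok] <- 100 * r$area_sidechain[ok] / unname(refs[r$resid[ok]])
  result@residues <- r
  result
}

#' Named per-residue RASA vector
#'
#' @param result a \code{\linkS4class{SasaResult}} after
#'   \code{\link{computeRasa}}
#' @return numeric vector of RASA percentages named by residue key
#' @export
rasaVector <- function(result) {
  r <- residueAreas(result)
  stats::setNames(r$rasa, r$key)
}
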