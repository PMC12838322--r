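# Beta-turn detection/typing from backbone dihedrals, i+1 proline candidate
# proposal, calcium-site coordination analysis and graft verification.

.TURN_IDEALS <- list(
  I = c(-60, -30, -90, 0),
  II = c(-60, 120, 80, 0),
  "I'" = c(60, 30, 90, 0),
  "II'" = c(60, -120, -80, 0),
  VIII = c(-60, -30, -120, 120))

.angDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Classify a beta-turn from its central dihedrals
#'
#' Standard dihedral-window taxonomy: a turn matches a type when all four
#' central angles (phi/psi of residues i+1 and i+2) are within 30 degrees
#' of the type's ideal values, with at most one angle allowed up to 45
#' degrees off. Types are tried in the order I, II, I', II', VIII; the
#' first match wins, otherwise the turn is "IV" (other).
#'
#' @param phi1,psi1 dihedrals of residue i+1 (degrees)
#' @param phi2,psi2 dihedrals of residue i+2 (degrees)
#' @return type label: "I", "II", "I'", "II'", "VIII" or "IV"
#' @export
classifyTurnType <- function(phi1, psi1, phi2, psi2) {
  ang <- c(phi1, psi1, phi2, psi2)
  stopifnot(all(is.finite(ang)))
  for (ty in names(.TURN_IDEALS)) {
    dev <- .angDiff(ang, .TURN_IDEALS[[ty]])
    if (all(dev <= 45) && sum(dev > 30) <= 1L) return(ty)
  }
  "IV"
}

#' Detect beta-turns in a structure
#'
#' Scans every window of four consecutive residues (same chain, residue
#' numbers increasing by one, complete backbones). A window is a turn when
#' the C-alpha(i) to C-alpha(i+3) distance is at most \code{caCutoff} and
#' its two central residues are not part of a helix. The helix veto marks
#' a residue helical when its (phi, psi) lies within \code{helixWindow}
#' degrees of (-63, -42) and it sits in a run of at least four such
#' consecutive residues. Overlapping turns are all reported.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param caCutoff maximum C-alpha(i)-C-alpha(i+3) distance (Angstrom)
#' @param helixWindow half-width of the helix (phi, psi) window (degrees);
#'   set to 0 to disable the veto
#' @return data.frame, one row per turn: chain, resno_i, keys of i..i+3,
#'   residue names, phi1, psi1, phi2, psi2, ca_dist, type
#' @export
detectBetaTurns <- function(structure, caCutoff = 7.0, helixWindow = 40) {
  dih <- measureBackboneDihedrals(structure)
  a <- atoms(structure)
  out <- list()
  for (ch in unique(dih$chain)) {
    di <- dih[dih$chain == ch, , drop = FALSE]
    n <- nrow(di)
    if (n < 4L) next
    helical <- rep(FALSE, n)
    if (helixWindow > 0) {
      near <- !is.na(di$phi) & !is.na(di$psi) &
        .angDiff(di$phi, -63) <= helixWindow &
        .angDiff(di$psi, -42) <= helixWindow
      r <- rle(near)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$lengths))
        if (r$values[k] && r$lengths[k] >= 4L)
          helical[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
    }
    caOf <- function(i) {
      sel <- a$chain == ch & a$resno == di$resno[i] & a$ins == di$ins[i] &
        a$elety == "CA"
      if (!any(sel)) return(NULL)
      as.numeric(a[which(sel)[1L], c("x", "y", "z")])
    }
    for (i in seq_len(n - 3L)) {
      idx <- i:(i + 3L)
      if (!all(diff(di$resno[idx]) == 1L) || any(nzchar(di$ins[idx]))) next
      if (anyNA(c(di$phi[i + 1L], di$psi[i + 1L],
                  di$phi[i + 2L], di$psi[i + 2L]))) next
      ca1 <- caOf(i); ca4 <- caOf(i + 3L)
      if (is.null(ca1) || is.null(ca4)) next
      cad <- atomDistance(ca1, ca4)
      if (cad > caCutoff) next
      if (helical[i + 1L] && helical[i + 2L]) next
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resno_i = di$resno[i],
        key_i = di$key[i], key_i1 = di$key[i + 1L],
        key_i2 = di$key[i + 2L], key_i3 = di$key[i + 3L],
        resid_i = di$resid[i], resid_i1 = di$resid[i + 1L],
        resid_i2 = di$resid[i + 2L], resid_i3 = di$resid[i + 3L],
        phi1 = di$phi[i + 1L], psi1 = di$psi[i + 1L],
        phi2 = di$phi[i + 2L], psi2 = di$psi[i + 2L],
        ca_dist = cad,
        type = classifyTurnType(di$phi[i + 1L], di$psi[i + 1L],
                                di$phi[i + 2L], di$psi[i + 2L]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), resno_i = integer(),
                      key_i = character(), key_i1 = character(),
                      key_i2 = character(), key_i3 = character(),
                      resid_i = character(), resid_i1 = character(),
                      resid_i2 = character(), resid_i3 = character(),
                      phi1 = numeric(), psi1 = numeric(), phi2 = numeric(),
                      psi2 = numeric(), ca_dist = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Propose i+1 proline substitutions in Type I beta-turns
#'
#' Proline at the i+1 position of a Type I beta-turn lowers the entropy of
#' the unfolded state and commonly stabilizes proteins. For every Type I
#' turn whose i+1 residue is not already proline and is not excluded
#' (e.g. metal-ligand or catalytic residues), a X->P candidate is emitted,
#' deduplicated by position.
#'
#' @param turns data.frame from \code{\link{detectBetaTurns}}
#' @param exclusions character vector of residue keys that must not be
#'   mutated
#' @return data.frame: position (resno), key, wt (1-letter), mut ("P"),
#'   category "turn_pro"
#' @export
proposeProlineCandidates <- function(turns, exclusions = character()) {
  sel <- turns$type == "I" & turns$resid_i1 != "PRO" &
    !(turns$key_i1 %in% exclusions)
  t1 <- turns[sel, , drop = FALSE]
  t1 <- t1[!duplicated(t1$key_i1), , drop = FALSE]
  if (nrow(t1) == 0L)
    return(data.frame(position = integer(), key = character(),
                      wt = character(), mut = character(),
                      category = character(), stringsAsFactors = FALSE))
  resno <- as.integer(sub("^.*/(\\d+).*$", "\\1", t1$key_i1))
  out <- data.frame(position = resno, key = t1$key_i1,
                    wt = unname(.AA3TO1[t1$resid_i1]), mut = "P",
                    category = "turn_pro", stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analyze the coordination shell of a metal ion
#'
#' Reports every oxygen atom within \code{cutoff} of the given ion
#' coordinate, labelled \code{side_chain} (atom name starting OD/OE/OG/OH)
#' or \code{main_chain_carbonyl} (atom name "O"), sorted by distance.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param ionCoord numeric 3-vector, Angstrom
#' @param cutoff coordination distance cutoff (Angstrom); typical Ca-O
#'   bonds are 2.3-2.6
#' @param label free-text site label carried into the result
#' @return list with \code{label}, \code{ion} and \code{ligands}
#'   (data.frame: key, resid, resno, elety, dist, role)
#' @export
analyzeCaSite <- function(structure, ionCoord, cutoff = 3.0,
                          label = "site") {
  stopifnot(length(ionCoord) == 3L, all(is.finite(ionCoord)))
  a <- atoms(structure)
  isO <- a$elem == "O"
  d <- sqrt((a$x - ionCoord[1L])^2 + (a$y - ionCoord[2L])^2 +
              (a$z - ionCoord[3L])^2)
  sel <- which(isO & d <= cutoff)
  role <- ifelse(a$elety[sel] == "O", "main_chain_carbonyl",
                 ifelse(grepl("^(OD|OE|OG|OH)", a$elety[sel]), "side_chain",
                        "other"))
  lig <- data.frame(key = residueKey(a$chain[sel], a$resno[sel], a$ins[sel]),
                    resid = a$resid[sel], resno = a$resno[sel],
                    elety = a$elety[sel], dist = d[sel], role = role,
                    stringsAsFactors = FALSE)
  lig <- lig[order(lig$dist), , drop = FALSE]
  rownames(lig) <- NULL
  list(label = label, ion = ionCoord, ligands = lig)
}

#' Verify a grafted metal site against its expected ligand set
#'
#' Compares the observed coordination shell of a site (computed on a model
#' carrying the graft mutations) with the expected (residue number, atom
#' name, role) triples of the graft design. The verdict is "satisfied"
#' exactly when no expected ligand is missing; extra observed ligands are
#' listed but do not fail the graft.
#'
#' @param site result of \code{\link{analyzeCaSite}}
#' @param expected data.frame with columns resno, elety, role
#' @param structure optional structure used to check that expected
#'   positions exist
#' @return list(satisfied, missing, extra, matched)
#' @export
checkGraft <- function(site, expected, structure = NULL) {
  stopifnot(all(c("resno", "elety", "role") %in% names(expected)))
  if (!is.null(structure)) {
    rt <- residueTable(structure)
    absent <- setdiff(expected$resno, rt$resno)
    if (length(absent))
      stop("graft positions absent from structure: ",
           paste(absent, collapse = ", "))
  }
  obs <- site$ligands
  trip <- function(df) paste(df$resno, df$elety, df$role)
  expT <- trip(expected); obsT <- trip(obs)
  missing <- expected[!(expT %in% obsT), , drop = FALSE]
  extra <- obs[!(obsT %in% expT), , drop = FALSE]
  matched <- obs[obsT %in% expT, , drop = FALSE]
  rownames(missing) <- rownames(extra) <- rownames(matched) <- NULL
  list(satisfied = nrow(missing) == 0L, missing = missing, extra = extra,
       matched = matched)
}
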