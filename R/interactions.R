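# Ion-pair detection (salt bridges and long-range pairs), ionic-network
# assembly over the residue-pair graph, exposure annotation and unpaired
# basic residues.
#
# A pair's distance is the minimum over side-chain charged-atom pairs
# (Asp OD1/OD2, Glu OE1/OE2 vs Lys NZ, Arg NE/NH1/NH2); a residue pair is
# one ion pair regardless of how many O-N contacts it makes.

.chargedAtomTable <- function(structure, includeHis = FALSE) {
  a <- atoms(structure)
  acid <- (a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
          (a$resid == "GLU" & a$elety %in% c("OE1", "OE2"))
  basicNames <- .BASIC_ATOMS[c("LYS", "ARG", if (includeHis) "HIS")]
  basic <- rep(FALSE, nrow(a))
  for (nm in names(basicNames))
    basic <- basic | (a$resid == nm & a$elety %in% basicNames[[nm]])
  list(acid = a[acid, , drop = FALSE], basic = a[basic, , drop = FALSE])
}

#' Detect salt bridges and long-range ion pairs
#'
#' For every acidic (Asp/Glu) x basic (Lys/Arg) residue pair, the minimum
#' distance over side-chain charged atoms is computed; pairs at or below
#' \code{saltCutoff} are salt bridges, pairs above it but at or below
#' \code{longCutoff} are long-range ion pairs (both boundaries inclusive).
#' Residues whose charged side-chain atoms are missing are skipped.
#' Histidine is excluded by default.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param saltCutoff salt-bridge distance limit (Angstrom)
#' @param longCutoff long-range ion-pair distance limit (Angstrom)
#' @param includeHis also treat His ND1/NE2 as basic charged atoms
#' @return data.frame with one row per ion pair, sorted by (acidic resno,
#'   basic resno): acid_key, acid_resid, acid_resno, base_key, base_resid,
#'   base_resno, min_dist, category ("salt_bridge" or "long_range"),
#'   pair_rasa (NA), exposed (NA)
#' @export
detectIonPairs <- function(structure, saltCutoff = 4.0, longCutoff = 8.0,
                           includeHis = FALSE) {
  stopifnot(saltCutoff > 0, saltCutoff <= longCutoff)
  ch <- .chargedAtomTable(structure, includeHis)
  empty <- data.frame(acid_key = character(), acid_resid = character(),
                      acid_resno = integer(), base_key = character(),
                      base_resid = character(), base_resno = integer(),
                      min_dist = numeric(), category = character(),
                      pair_rasa = numeric(), exposed = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(ch$acid) == 0L || nrow(ch$basic) == 0L) return(empty)
  xa <- as.matrix(ch$acid[, c("x", "y", "z")])
  xb <- as.matrix(ch$basic[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  keyA <- residueKey(ch$acid$chain, ch$acid$resno, ch$acid$ins)
  keyB <- residueKey(ch$basic$chain, ch$basic$resno, ch$basic$ins)
  d <- sqrt(d2)
  rows <- list()
  for (ka in unique(keyA)) for (kb in unique(keyB)) {
    md <- min(d[keyA == ka, keyB == kb])
    if (md > longCutoff) next
    ia <- which(keyA == ka)[1L]; ib <- which(keyB == kb)[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      acid_key = ka, acid_resid = ch$acid$resid[ia],
      acid_resno = ch$acid$resno[ia],
      base_key = kb, base_resid = ch$basic$resid[ib],
      base_resno = ch$basic$resno[ib],
      min_dist = md,
      category = if (md <= saltCutoff) "salt_bridge" else "long_range",
      pair_rasa = NA_real_, exposed = NA,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$acid_resno, out$base_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble ionic networks from ion pairs
#'
#' Connected components of the residue graph whose edges are the ion
#' pairs. Components containing at least two pairs are ionic networks;
#' single isolated pairs are reported separately. Assembly is independent
#' of the input pair order.
#'
#' @param pairs data.frame from \code{\link{detectIonPairs}}
#' @return list with \code{pairs} (the input plus a \code{network_id}
#'   column, NA for singleton pairs), \code{networks} (list of
#'   \code{list(residues, pair_rows, n_pairs)} sorted by smallest member
#'   residue number) and \code{singletons} (row indices of isolated pairs)
#' @export
buildIonicNetworks <- function(pairs) {
  pairs$network_id <- NA_integer_
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, networks = list(), singletons = integer()))
  g <- igraph::graph_from_data_frame(
    pairs[, c("acid_key", "base_key")], directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  edgeComp <- memb[pairs$acid_key]
  nets <- list()
  for (ci in seq_len(comp$no)) {
    rows <- which(edgeComp == ci)
    if (length(rows) < 2L) next
    resk <- sort(unique(c(pairs$acid_key[rows], pairs$base_key[rows])))
    minres <- min(c(pairs$acid_resno[rows], pairs$base_resno[rows]))
    nets[[length(nets) + 1L]] <- list(residues = resk, pair_rows = rows,
                                      n_pairs = length(rows),
                                      min_resno = minres)
  }
  if (length(nets)) {
    nets <- nets[order(vapply(nets, `[[`, numeric(1), "min_resno"))]
    for (i in seq_along(nets)) pairs$network_id[nets[[i]]$pair_rows] <- i
  }
  singles <- which(is.na(pairs$network_id))
  list(pairs = pairs, networks = nets, singletons = singles)
}

#' Annotate ion pairs with exposure
#'
#' The RASA of an ion pair is the arithmetic mean of its two members'
#' RASA values; a pair is exposed when that mean is at or above the
#' threshold (inclusive). Pairs with a missing member RASA are flagged
#' unknown (NA).
#'
#' @param pairs data.frame from \code{\link{detectIonPairs}}
#' @param rasa named numeric of per-residue RASA percentages keyed by
#'   residue key (see \code{\link{rasaVector}})
#' @param threshold exposure threshold in percent
#' @return the pairs with \code{pair_rasa} and \code{exposed} filled in
#' @export
annotateExposure <- function(pairs, rasa, threshold = 20) {
  if (nrow(pairs) == 0L) return(pairs)
  ra <- unname(rasa[pairs$acid_key])
  rb <- unname(rasa[pairs$base_key])
  pairs$pair_rasa <- (ra + rb) / 2
  pairs$exposed <- pairs$pair_rasa >= threshold
  pairs
}

#' Basic residues outside any ion pair
#'
#' All Lys/Arg residues of the structure that appear in no detected ion
#' pair (either category), sorted by residue number. In thermostable
#' subtilases these are prime anchors for engineering new surface pairs.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param pairs data.frame from \code{\link{detectIonPairs}}
#' @param includeHis also count His as basic
#' @return data.frame key, chain, resno, ins, resid
#' @export
unpairedBasicResidues <- function(structure, pairs, includeHis = FALSE) {
  rt <- residueTable(structure)
  basics <- rt[rt$resid %in% c("LYS", "ARG", if (includeHis) "HIS"), ,
               drop = FALSE]
  out <- basics[!(basics$key %in% pairs$base_key), , drop = FALSE]
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
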