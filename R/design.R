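# Candidate generation and aggregation: multi-predictor consensus selection,
# surface Asp/Glu substitution scan, and the unified report.

#' Parse and merge stability-predictor mutation tables
#'
#' Each predictor exports a TSV with header columns \code{wt},
#' \code{position}, \code{mut} (1-letter codes, mature-chain numbering).
#' Records are merged across tools by (position, wt, mut); the support of
#' a record is the number of distinct tools proposing it. Tools that
#' disagree on the wild-type residue at a position indicate mismatched
#' numbering and raise an error.
#'
#' @param tables named list: tool name -> TSV text (single string or
#'   character vector of lines) or a file path
#' @return data.frame: position, wt, mut, tools (comma-joined), support,
#'   category "consensus"; sorted by (position, mut)
#' @export
parsePredictorTables <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L,
            !is.null(names(tables)), !anyDuplicated(names(tables)))
  recs <- list()
  for (tool in names(tables)) {
    txt <- tables[[tool]]
    if (length(txt) == 1L && !grepl("\n", txt) && file.exists(txt))
      txt <- readLines(txt, warn = FALSE)
    else txt <- unlist(strsplit(txt, "\n", fixed = TRUE), use.names = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (!length(txt)) stop("empty predictor table for tool ", tool)
    df <- tryCatch(
      utils::read.table(text = txt, header = TRUE, sep = "\t",
                        colClasses = "character",
                        stringsAsFactors = FALSE),
      error = function(e) stop("malformed table for tool ", tool, ": ",
                               conditionMessage(e)))
    need <- c("wt", "position", "mut")
    if (!all(need %in% names(df)))
      stop("tool ", tool, ": header must contain wt, position, mut")
    bad <- which(!grepl("^[A-Z]$", df$wt) | !grepl("^[A-Z]$", df$mut) |
                   is.na(suppressWarnings(as.integer(df$position))))
    if (length(bad))
      stop(sprintf("tool %s: malformed row at line %d", tool, bad[1L] + 1L))
    if (any(df$wt == df$mut))
      stop("tool ", tool, ": wt equal to mut at position ",
           df$position[df$wt == df$mut][1L])
    df$position <- as.integer(df$position)
    df$tool <- tool
    recs[[tool]] <- df[, c("position", "wt", "mut", "tool")]
  }
  all <- do.call(rbind, recs)
  wtByPos <- tapply(all$wt, all$position, function(x) length(unique(x)))
  if (any(wtByPos > 1L)) {
    p <- names(wtByPos)[wtByPos > 1L][1L]
    stop("predictor tables disagree on the wild-type residue at position ", p)
  }
  keyOf <- paste(all$position, all$wt, all$mut)
  merged <- lapply(split(all, keyOf), function(g)
    data.frame(position = g$position[1L], wt = g$wt[1L], mut = g$mut[1L],
               tools = paste(sort(unique(g$tool)), collapse = ","),
               support = length(unique(g$tool)),
               category = "consensus", stringsAsFactors = FALSE))
  out <- do.call(rbind, merged)
  out <- out[order(out$position, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select consensus mutations by minimum predictor support
#'
#' Keeps records proposed by at least \code{minSupport} distinct tools,
#' sorted by support (descending), then position, then substitution.
#'
#' @param records data.frame from \code{\link{parsePredictorTables}}
#' @param minSupport minimum number of supporting tools (>= 1)
#' @return the filtered, re-sorted records
#' @export
consensusSelect <- function(records, minSupport = 2L) {
  stopifnot(minSupport >= 1L)
  out <- records[records$support >= minSupport, , drop = FALSE]
  out <- out[order(-out$support, out$position, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation notation helper ("S182A")
#'
#' @param wt,mut 1-letter codes
#' @param position integer position
#' @export
mutationLabel <- function(wt, position, mut) paste0(wt, position, mut)

# Cbeta-to-carboxylate-oxygen reach of the proposed residue in an extended
# rotamer; permissive feasibility screen, not a rotamer search.
.REACH <- c(ASP = 2.5, GLU = 3.9)

#' Scan exposed residues for Asp/Glu substitutions forming new ion pairs
#'
#' For every basic residue B of the structure, every exposed residue T
#' (RASA at or above \code{rasaThreshold}; not Gly/Pro/Cys, not already
#' acidic, not excluded) whose C-beta lies within
#' \code{longCutoff + reach} of B's nearest charged nitrogen is emitted as
#' a candidate T->Asp and/or T->Glu. Basic residues that currently sit in
#' no ion pair are flagged as priority partners. The screen is
#' deliberately permissive: it shortlists geometrically feasible new
#' surface pairs for human triage.
#'
#' @param structure a \code{\linkS4class{ProteinStructure}}
#' @param rasa named RASA vector (\code{\link{rasaVector}})
#' @param pairs ion pairs from \code{\link{detectIonPairs}} (used to flag
#'   unpaired partners)
#' @param rasaThreshold exposure threshold (percent)
#' @param longCutoff long-range ion-pair limit (Angstrom)
#' @param exclusions residue keys never proposed (catalytic, metal ligands)
#' @return data.frame: key, resno, resid, wt, proposed ("ASP"/"GLU"), mut,
#'   partner_key, partner_resno, cb_to_charge, partner_unpaired, category
#'   "surface_acidic"; sorted by (partner resno, distance)
#' @export
scanSurfaceAcidicCandidates <- function(structure, rasa, pairs,
                                        rasaThreshold = 20,
                                        longCutoff = 8.0,
                                        exclusions = character()) {
  a <- atoms(structure)
  rt <- residueTable(structure)
  unpaired <- unpairedBasicResidues(structure, pairs)
  basics <- rt[rt$resid %in% c("LYS", "ARG"), , drop = FALSE]
  out <- list()
  for (bi in seq_len(nrow(basics))) {
    bkey <- basics$key[bi]
    bn <- .BASIC_ATOMS[[basics$resid[bi]]]
    bsel <- a$chain == basics$chain[bi] & a$resno == basics$resno[bi] &
      a$ins == basics$ins[bi] & a$elety %in% bn
    if (!any(bsel)) next
    bxyz <- as.matrix(a[bsel, c("x", "y", "z"), drop = FALSE])
    for (ti in seq_len(nrow(rt))) {
      tkey <- rt$key[ti]
      if (tkey == bkey || tkey %in% exclusions) next
      tres <- rt$resid[ti]
      if (tres %in% c("GLY", "PRO", "CYS", "ASP", "GLU")) next
      if (!tres %in% names(.AA3TO1)) next
      rv <- rasa[tkey]
      if (is.na(rv) || rv < rasaThreshold) next
      cbsel <- a$chain == rt$chain[ti] & a$resno == rt$resno[ti] &
        a$ins == rt$ins[ti] & a$elety == "CB"
      if (!any(cbsel)) next
      cb <- as.numeric(a[which(cbsel)[1L], c("x", "y", "z")])
      dmin <- sqrt(min(rowSums(sweep(bxyz, 2L, cb)^2)))
      for (prop in names(.REACH)) {
        if (dmin > longCutoff + .REACH[[prop]]) next
        out[[length(out) + 1L]] <- data.frame(
          key = tkey, resno = rt$resno[ti], resid = tres,
          wt = unname(.AA3TO1[tres]), proposed = prop,
          mut = unname(.AA3TO1[prop]),
          partner_key = bkey, partner_resno = basics$resno[bi],
          cb_to_charge = dmin,
          partner_unpaired = bkey %in% unpaired$key,
          category = "surface_acidic", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(key = character(), resno = integer(),
                      resid = character(), wt = character(),
                      proposed = character(), mut = character(),
                      partner_key = character(), partner_resno = integer(),
                      cb_to_charge = numeric(), partner_unpaired = logical(),
                      category = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$key, res$proposed, res$partner_key)), ,
             drop = FALSE]
  res <- res[order(res$partner_resno, res$cb_to_charge, res$resno), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Unified candidate report
#'
#' Bundles the outputs of the analysis stages into one deterministic
#' report carrying each candidate's category and the parameters it was
#' derived with. Optionally written as pretty JSON plus a flat TSV of
#' candidates.
#'
#' @param ionPairs annotated pair table (with networks applied), or NULL
#' @param networks result of \code{\link{buildIonicNetworks}}, or NULL
#' @param unpairedBasics from \code{\link{unpairedBasicResidues}}, or NULL
#' @param turns from \code{\link{detectBetaTurns}}, or NULL
#' @param turnProCandidates from \code{\link{proposeProlineCandidates}},
#'   or NULL
#' @param caSites list of \code{\link{analyzeCaSite}} results, or NULL
#' @param graftReports list of \code{\link{checkGraft}} results, or NULL
#' @param surfaceAcidic from \code{\link{scanSurfaceAcidicCandidates}},
#'   or NULL
#' @param consensus from \code{\link{consensusSelect}}, or NULL
#' @param parameters named list of the parameters used upstream
#' @param jsonPath,tsvPath optional output paths
#' @return the report (a named list), invisibly when written to disk
#' @export
generateReport <- function(ionPairs = NULL, networks = NULL,
                           unpairedBasics = NULL, turns = NULL,
                           turnProCandidates = NULL, caSites = NULL,
                           graftReports = NULL, surfaceAcidic = NULL,
                           consensus = NULL, parameters = list(),
                           jsonPath = NULL, tsvPath = NULL) {
  sections <- list(ion_pairs = ionPairs, networks = networks,
                   unpaired_basic_residues = unpairedBasics, turns = turns,
                   turn_pro_candidates = turnProCandidates,
                   ca_sites = caSites, graft_reports = graftReports,
                   surface_acidic_candidates = surfaceAcidic,
                   consensus_mutations = consensus)
  if (all(vapply(sections, is.null, logical(1))))
    stop("at least one stage output must be supplied")
  cand <- list()
  if (!is.null(turnProCandidates) && nrow(turnProCandidates))
    cand$turn_pro <- data.frame(
      mutation = mutationLabel(turnProCandidates$wt,
                               turnProCandidates$position,
                               turnProCandidates$mut),
      category = "turn_pro",
      rationale = "Pro at i+1 of a Type I beta-turn lowers unfolding entropy",
      stringsAsFactors = FALSE)
  if (!is.null(surfaceAcidic) && nrow(surfaceAcidic))
    cand$surface_acidic <- data.frame(
      mutation = mutationLabel(surfaceAcidic$wt, surfaceAcidic$resno,
                               surfaceAcidic$mut),
      category = "surface_acidic",
      rationale = paste0("exposed residue within ion-pair reach of basic ",
                         "partner ", surfaceAcidic$partner_key),
      stringsAsFactors = FALSE)
  if (!is.null(consensus) && nrow(consensus))
    cand$consensus <- data.frame(
      mutation = mutationLabel(consensus$wt, consensus$position,
                               consensus$mut),
      category = "consensus",
      rationale = paste0("predicted by ", consensus$support,
                         " tool(s): ", consensus$tools),
      stringsAsFactors = FALSE)
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(mutation = character(), category = character(),
               rationale = character(), stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  report <- list(sections = sections, candidates = candidates,
                 parameters = parameters)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
  if (!is.null(tsvPath))
    utils::write.table(candidates, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath) || !is.null(tsvPath)) invisible(report) else report
}
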