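# Reading, standardizing, pairing and writing screening tables, and the
# benchmark bookkeeping rules: a hit that is inactive or inconclusive in the
# confirmatory screen is a ground-truth false positive; campaigns qualify
# for benchmarking only with more than `minHits` confirmed hits and a false
# positive fraction inside [0.05, 0.95].

#' Read a primary-screen table
#'
#' Loads a screening table from CSV (RFC-4180, header required, lines
#' starting with \code{#} ignored), whitespace-separated SMILES
#' (\code{.smi}: structure then id) or SDF. Rows whose structures fail to
#' parse are dropped and counted in the load report (stored in metadata and
#' logged to stderr). A structure column is optional for CSV: without one
#' the records are structure-free (simulated screens).
#'
#' @param path input file.
#' @param columnMap named list mapping roles to column names for CSV input:
#'   \code{id}, \code{readout}, \code{label} are mandatory, \code{smiles}
#'   and \code{confirmatory} optional.
#' @param format \code{"csv"}, \code{"smi"} or \code{"sdf"}; default guessed
#'   from the file extension.
#' @param readoutOrientation orientation of the readout column as stored in
#'   the file; \code{"lower_more_active"} (e.g. inhibition assays reported
#'   as residual activity) is sign-flipped at load.
#' @param name campaign name.
#' @return A \linkS4class{ScreenSet}; \code{screenMetadata(x)$loadReport}
#'   holds row/rejection counts.
#' @export
readScreenTable <- function(path,
                            columnMap = list(id = "compound_id",
                                             smiles = "smiles",
                                             readout = "readout",
                                             label = "primary_active"),
                            format = c("auto", "csv", "smi", "sdf"),
                            readoutOrientation = "higher_more_active",
                            name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("smi", "sdf")) ext else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#")
    if (nrow(tab) == 0L) stop("empty dataset: ", path, call. = FALSE)
    for (role in c("id", "readout", "label")) {
      col <- columnMap[[role]]
      if (is.null(col) || !col %in% colnames(tab))
        stop(sprintf("configuration error: missing mandatory column '%s' (role %s)",
                     if (is.null(col)) role else col, role), call. = FALSE)
    }
    smiCol <- columnMap$smiles
    smi <- if (!is.null(smiCol) && smiCol %in% colnames(tab))
      as.character(tab[[smiCol]]) else rep(NA_character_, nrow(tab))
    conf <- rep("untested", nrow(tab))
    confCol <- columnMap$confirmatory
    if (!is.null(confCol) && confCol %in% colnames(tab)) {
      v <- as.character(tab[[confCol]])
      v[is.na(v) | !nzchar(v)] <- "untested"
      conf <- v
    }
    lab <- tab[[columnMap$label]]
    if (is.character(lab)) lab <- lab %in% c("1", "TRUE", "true", "active")
    raw <- list(id = as.character(tab[[columnMap$id]]), smiles = smi,
                readout = as.numeric(tab[[columnMap$readout]]),
                label = as.logical(lab), conf = conf)
  } else if (format == "smi") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty dataset: ", path, call. = FALSE)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    raw <- list(
      id = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], ""),
      smiles = vapply(parts, `[`, "", 1L),
      readout = rep(0, length(lines)),
      label = rep(FALSE, length(lines)),
      conf = rep("untested", length(lines)))
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    if (length(sdfs) == 0L) stop("empty dataset: ", path, call. = FALSE)
    smi <- as.character(ChemmineR::sdf2smiles(sdfs))
    ids <- ChemmineR::sdfid(sdfs)
    raw <- list(id = as.character(ids), smiles = smi,
                readout = rep(0, length(smi)),
                label = rep(FALSE, length(smi)),
                conf = rep("untested", length(smi)))
  }
  n0 <- length(raw$id)
  hasStructure <- !all(is.na(raw$smiles))
  rejected <- 0L
  if (hasStructure) {
    can <- canonicalSmiles(raw$smiles)
    bad <- is.na(can)
    rejected <- sum(bad)
    if (rejected > 0L)
      .log("readScreenTable: dropped %d row(s) with unparseable structures",
           rejected)
    raw <- lapply(raw, function(v) v[!bad])
  }
  sset <- ScreenSet(compoundId = raw$id, smiles = raw$smiles,
                    readout = raw$readout, primaryActive = raw$label,
                    confirmatoryOutcome = raw$conf, name = name,
                    readoutOrientation = readoutOrientation,
                    metadata = list(loadReport = list(
                      rowsRead = n0, rejectedStructures = rejected,
                      kept = n0 - rejected)))
  sset
}

#' Standardize compound structures
#'
#' Canonicalizes every structure, keeps the largest organic fragment
#' (salt stripping), and merges duplicate canonical structures. Records
#' whose duplicates disagree on the primary activity call are handled by
#' \code{mergePolicy}: \code{"drop_conflicts"} (default) removes all of
#' them as unreliable; \code{"keep_first"} keeps the first occurrence.
#' Agreeing duplicates always collapse to the first occurrence. Failures
#' are reported in metadata, never raised. Structure-free datasets are
#' returned unchanged.
#'
#' @param sset a \linkS4class{ScreenSet}.
#' @param mergePolicy duplicate-conflict policy.
#' @return A standardized \linkS4class{ScreenSet} with a
#'   \code{standardizationReport} in its metadata.
#' @export
standardizeCompounds <- function(sset,
                                 mergePolicy = c("drop_conflicts",
                                                 "keep_first")) {
  mergePolicy <- match.arg(mergePolicy)
  smi <- compoundSmiles(sset)
  if (all(is.na(smi))) {
    sset@metadata$standardizationReport <-
      list(structureFree = TRUE, merged = 0L, conflictsDropped = 0L)
    return(sset)
  }
  can <- canonicalSmiles(smi)
  parsedOK <- !is.na(can)
  can[parsedOK] <- vapply(can[parsedOK], .largestOrganicFragment, "")
  # re-canonicalize stripped fragments so equal structures compare equal
  can[parsedOK] <- canonicalSmiles(can[parsedOK])
  keep <- parsedOK
  rec <- sset@records
  grp <- match(can, can)  # first-occurrence index per canonical structure
  merged <- 0L
  conflictsDropped <- 0L
  for (g in unique(grp[keep])) {
    members <- which(keep & grp == g)
    if (length(members) <= 1L) next
    calls <- rec$primaryActive[members]
    if (length(unique(calls)) > 1L && mergePolicy == "drop_conflicts") {
      keep[members] <- FALSE
      conflictsDropped <- conflictsDropped + length(members)
    } else {
      keep[members[-1L]] <- FALSE
      merged <- merged + length(members) - 1L
    }
  }
  out <- sset[keep]
  out@records$smiles <- can[keep]
  out@metadata$standardizationReport <-
    list(structureFree = FALSE,
         unparseable = sum(!parsedOK),
         merged = merged, conflictsDropped = conflictsDropped,
         mergePolicy = mergePolicy, kept = sum(keep))
  if (merged + conflictsDropped > 0L)
    .log("standardizeCompounds: merged %d duplicate(s), dropped %d conflicting record(s)",
         merged, conflictsDropped)
  out
}

# Largest organic fragment of a dot-disconnected canonical SMILES: the
# fragment with the most heavy atoms among those containing carbon (falls
# back to most heavy atoms overall for fully inorganic records).
.largestOrganicFragment <- function(can) {
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(frags) <= 1L) return(can)
  heavy <- vapply(frags, .heavyAtomCountSmiles, numeric(1))
  organic <- grepl("C|c", vapply(frags, function(f)
    gsub("Cl|Ca|Cd|Cu|Co|Cr|Cs", "", f), ""))
  cand <- if (any(organic)) which(organic) else seq_along(frags)
  frags[cand[which.max(heavy[cand])]]
}

.heavyAtomCountSmiles <- function(s) {
  # strip bracket-atom hydrogens and count element tokens
  toks <- gregexpr("Cl|Br|Si|Se|Li|Na|Mg|Al|Ca|Fe|Zn|Cu|Mn|[BCNOSPFIbcnosp]",
                   s)[[1]]
  if (toks[1] == -1) 0 else length(toks)
}

#' Attach confirmatory-screen outcomes to primary hits
#'
#' Joins a confirmatory table onto the primary screen by compound id (or by
#' canonical structure when \code{by = "structure"}). Every primary hit
#' found in the table gains its outcome; hits absent from the table stay
#' \code{"untested"} and are counted in the report (they are excluded from
#' evaluation, not treated as false positives). Entries for non-hits are
#' ignored with a report count, since confirmatory data exist only for
#' hits in this design.
#'
#' @param primary a \linkS4class{ScreenSet}.
#' @param confirmatory a data.frame with columns \code{compound_id} and
#'   \code{outcome} (\code{active}/\code{inactive}/\code{inconclusive}),
#'   or a CSV path to one.
#' @param by join key: \code{"id"} or \code{"structure"}.
#' @return The primary \linkS4class{ScreenSet} with outcomes assigned and a
#'   \code{confirmatoryReport} in its metadata.
#' @export
assignConfirmatoryOutcomes <- function(primary, confirmatory,
                                       by = c("id", "structure")) {
  by <- match.arg(by)
  if (is.character(confirmatory) && length(confirmatory) == 1L)
    confirmatory <- utils::read.csv(confirmatory, stringsAsFactors = FALSE,
                                    comment.char = "#")
  if (!all(c("compound_id", "outcome") %in% colnames(confirmatory)))
    stop("confirmatory table needs columns compound_id, outcome",
         call. = FALSE)
  outcome <- as.character(confirmatory$outcome)
  if (!all(outcome %in% c("active", "inactive", "inconclusive")))
    stop("confirmatory outcomes must be active/inactive/inconclusive",
         call. = FALSE)
  key <- if (by == "id") compoundIds(primary)
         else canonicalSmiles(compoundSmiles(primary))
  tabKey <- as.character(confirmatory$compound_id)
  if (by == "structure") tabKey <- canonicalSmiles(tabKey)
  idx <- match(key, tabKey)
  hit <- isHit(primary)
  assigned <- hit & !is.na(idx)
  rec <- primary@records
  rec$confirmatoryOutcome[assigned] <- outcome[idx[assigned]]
  untested <- sum(hit & is.na(idx))
  ignoredNonHits <- sum(!hit & !is.na(idx))
  if (untested > 0L)
    .log("assignConfirmatoryOutcomes: %d hit(s) absent from confirmatory table -> untested",
         untested)
  if (ignoredNonHits > 0L)
    .log("assignConfirmatoryOutcomes: ignored %d table entr(ies) matching non-hits",
         ignoredNonHits)
  primary@records <- rec
  primary@metadata$confirmatoryReport <-
    list(assigned = sum(assigned), untestedHits = untested,
         ignoredNonHits = ignoredNonHits)
  methods::validObject(primary)
  primary
}

#' Check benchmark eligibility of a paired screen
#'
#' A campaign qualifies for method benchmarking when more than
#' \code{minHits} hits carry confirmatory outcomes and the confirmed false
#' positive fraction lies inside \code{fpBounds} (campaigns almost entirely
#' composed of false positives, or almost none, cannot discriminate
#' ranking methods). The verdict is a pure function of the confirmed hit
#' count and the false-positive fraction.
#'
#' @param sset a \linkS4class{ScreenSet} with confirmatory outcomes.
#' @param minHits minimum confirmed-hit count (strictly more required;
#'   default 200).
#' @param fpBounds inclusive false-positive-fraction bounds
#'   (default \code{c(0.05, 0.95)}).
#' @return list with \code{eligible}, \code{nConfirmedHits},
#'   \code{fpFraction}, \code{reasons}.
#' @export
checkBenchmarkEligibility <- function(sset, minHits = 200,
                                      fpBounds = c(0.05, 0.95)) {
  confirmed <- isHit(sset) & confirmatoryOutcomes(sset) != "untested"
  nConf <- sum(confirmed)
  reasons <- character(0)
  if (nConf == 0L)
    return(list(eligible = FALSE, nConfirmedHits = 0L, fpFraction = NA_real_,
                reasons = "no confirmed hits"))
  fpFrac <- sum(isFalsePositive(sset)) / nConf
  if (nConf <= minHits)
    reasons <- c(reasons, sprintf("too few hits (%d <= %d)", nConf, minHits))
  if (fpFrac < fpBounds[1] || fpFrac > fpBounds[2])
    reasons <- c(reasons,
                 sprintf("false positive fraction %.3f outside [%g, %g]",
                         fpFrac, fpBounds[1], fpBounds[2]))
  list(eligible = length(reasons) == 0L, nConfirmedHits = nConf,
       fpFraction = fpFrac, reasons = reasons)
}

#' Write a ScreenSet to CSV
#'
#' Emits the package CSV dialect (columns \code{compound_id},
#' \code{smiles}, \code{readout}, \code{primary_active},
#' \code{confirmatory_outcome}), readable back by
#' \code{\link{readScreenTable}} bit-exactly.
#'
#' @param sset a \linkS4class{ScreenSet}.
#' @param path output file.
#' @export
writeScreenTable <- function(sset, path) {
  df <- data.frame(compound_id = compoundIds(sset),
                   smiles = compoundSmiles(sset),
                   readout = sprintf("%.17g", readouts(sset)),
                   primary_active = as.integer(isHit(sset)),
                   confirmatory_outcome = confirmatoryOutcomes(sset),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a triage report
#'
#' CSV with one row per ranked hit: \code{compound_id}, \code{smiles},
#' \code{readout}, \code{mvsa_score}, \code{rank} (1-based, rank 1 =
#' highest score) and \code{flag} in \{likely_FP, likely_TP, unflagged\}.
#' A leading \code{#} comment line stamps the run's config hash and seed
#' for provenance. Deterministic: identical inputs yield byte-identical
#' files.
#'
#' @param triage a \linkS4class{TriageResult}.
#' @param sset the \linkS4class{ScreenSet} the triage was computed from.
#' @param path output file.
#' @param provenance optional named list merged into the provenance stamp.
#' @export
writeTriageReport <- function(triage, sset, path, provenance = list()) {
  tb <- triageTable(triage)
  idx <- match(tb$compoundId, compoundIds(sset))
  if (any(is.na(idx)))
    stop("alignment error: triage ids missing from dataset", call. = FALSE)
  stamp <- c(list(config_hash = configHash(c(provenance,
                                             fraction = triage@fraction)),
                  fraction = triage@fraction), provenance)
  header <- paste0("# ", paste(names(stamp), unlist(lapply(stamp, format)),
                               sep = "=", collapse = " "))
  lines <- c(header,
             "compound_id,smiles,readout,mvsa_score,rank,flag",
             sprintf("%s,%s,%.17g,%.17g,%d,%s",
                     tb$compoundId,
                     ifelse(is.na(compoundSmiles(sset)[idx]), "",
                            compoundSmiles(sset)[idx]),
                     readouts(sset)[idx], tb$score, tb$rank, tb$flag))
  if (nrow(tb) == 0L) lines <- lines[1:2]
  writeLines(lines, path)
  invisible(path)
}
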