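# Structure handling and featurization. SMILES parsing, canonicalization and
# physicochemical properties go through ChemmineR/ChemmineOB (OpenBabel);
# hashed circular fingerprints and Bemis-Murcko scaffold extraction are
# computed here on the parsed molecular graph.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form in one batch. Strings that
#' fail to parse are returned as \code{NA} (the batch is title-indexed so
#' alignment survives parser drop-outs).
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, \code{NA} where unparseable.
#' @export
#' @examples
#' canonicalSmiles(c("OCC", "C1CC", "c1ccccc1C"))
canonicalSmiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(smiles[idx], "\tm", idx, "\n", collapse = "")
  res <- ChemmineOB::convertFormat(
    "SMI", "CAN", src,
    options = data.frame(names = "e", args = "", stringsAsFactors = FALSE))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    cans <- vapply(parts, `[`, "", 1L)
    ids <- as.integer(sub("^m", "", vapply(parts, `[`, "", 2L)))
    keep <- !is.na(ids) & nzchar(cans)
    out[ids[keep]] <- cans[keep]
  }
  out
}

# Parse canonical SMILES into simple molecular graphs. Returns a list per
# molecule: symbols (element per atom), bonds (matrix a1,a2,order), and the
# originating SDF (kept for subgraph export). Errors if any string fails to
# parse; callers are expected to have standardized structures already.
.molGraphs <- function(smiles) {
  if (any(is.na(smiles)))
    stop("unparseable structure(s): standardize/canonicalize first",
         call. = FALSE)
  if (length(smiles) == 0L) return(list())
  nm <- paste0("m", seq_along(smiles))
  # single-atom molecules (e.g. water) have no bond block and trip
  # ChemmineR's SDF validity warning; their graphs are still usable
  sdfs <- withCallingHandlers(
    ChemmineR::smiles2sdf(stats::setNames(smiles, nm)),
    warning = function(w) {
      if (grepl("invalid SDFs", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lapply(seq_along(smiles), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (!is.matrix(bb)) bb <- matrix(bb, ncol = max(length(bb), 1))
    symbols <- sub("_[0-9]+$", "", rownames(ab))
    bonds <- if (nrow(bb) > 0 && ncol(bb) >= 3)
      cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
            order = as.integer(bb[, 3]))
    else
      matrix(integer(0), 0, 3, dimnames = list(NULL, c("a1", "a2", "order")))
    list(symbols = symbols, bonds = bonds, sdf = sdf)
  })
}

# Atom indices forming the molecular framework: iteratively prune atoms of
# degree <= 1 until a fixpoint; what remains is ring systems plus linkers.
.frameworkAtoms <- function(g) {
  nA <- length(g$symbols)
  alive <- rep(TRUE, nA)
  b <- g$bonds
  repeat {
    if (!any(alive)) break
    keepEdge <- alive[b[, 1]] & alive[b[, 2]]
    deg <- tabulate(c(b[keepEdge, 1], b[keepEdge, 2]), nbins = nA)
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}

# Deterministic bit position for an atom-environment identifier string.
.fpBit <- function(ident, nBits) .hashString(ident) %% nBits

#' Hashed circular (Morgan-style) fingerprints
#'
#' Computes atom-centered circular substructure fingerprints on the
#' molecular graph: each atom starts from an invariant built from its
#' element, degree, total bond order and framework membership; for each
#' radius step the invariant is re-hashed together with the sorted
#' (bond order, neighbor invariant) list, and every identifier at every
#' radius sets one bit of a fixed-width binary vector. Input SMILES are
#' canonicalized first, so different spellings of the same molecule yield
#' identical rows. Deterministic for fixed parameters across platforms.
#'
#' @param smiles character vector of structures.
#' @param radius maximum circular radius (default 2, ECFP4-like).
#' @param nBits fingerprint width; a power of two, at least 256
#'   (default 1024).
#' @param ids row identifiers (default: names of \code{smiles} or index).
#' @return A \linkS4class{FeatureMatrix} with 0/1 entries.
#' @export
#' @examples
#' fp <- circularFingerprints(c("CCO", "c1ccccc1"), radius = 1)
#' rowSums(featureValues(fp))
circularFingerprints <- function(smiles, radius = 2L, nBits = 1024L,
                                 ids = NULL) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (nBits < 256 || bitwAnd(nBits, nBits - 1L) != 0)
    stop("nBits must be a power of two >= 256", call. = FALSE)
  if (is.null(ids))
    ids <- if (!is.null(names(smiles))) names(smiles)
           else as.character(seq_along(smiles))
  can <- canonicalSmiles(smiles)
  graphs <- .molGraphs(can)
  vals <- matrix(0, length(smiles), nBits)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    nA <- length(g$symbols)
    b <- g$bonds
    deg <- tabulate(c(b[, 1], b[, 2]), nbins = nA)
    bos <- numeric(nA)
    if (nrow(b) > 0) {
      for (k in seq_len(nrow(b))) {
        bos[b[k, 1]] <- bos[b[k, 1]] + b[k, 3]
        bos[b[k, 2]] <- bos[b[k, 2]] + b[k, 3]
      }
    }
    ring <- seq_len(nA) %in% .frameworkAtoms(g)
    inv <- paste(g$symbols, deg, bos, as.integer(ring), sep = ",")
    nbr <- vector("list", nA)
    if (nrow(b) > 0) {
      for (k in seq_len(nrow(b))) {
        nbr[[b[k, 1]]] <- rbind(nbr[[b[k, 1]]], c(b[k, 2], b[k, 3]))
        nbr[[b[k, 2]]] <- rbind(nbr[[b[k, 2]]], c(b[k, 1], b[k, 3]))
      }
    }
    for (r in 0:radius) {
      bits <- .fpBit(paste0("r", r, "|", inv), nBits)
      vals[i, bits + 1L] <- 1
      if (r == radius) break
      inv <- vapply(seq_len(nA), function(a) {
        ns <- nbr[[a]]
        if (is.null(ns)) return(paste0("(", inv[a], ")"))
        parts <- paste0(ns[, 2], ":", inv[ns[, 1]])
        paste0("(", inv[a], ";", paste(sort(parts), collapse = "|"), ")")
      }, character(1))
    }
  }
  FeatureMatrix(vals, rowIds = ids, featureKind = "circular_fp",
                params = list(radius = radius, nBits = nBits))
}

.DESCRIPTOR_REGISTRY <- c("MW", "logP", "TPSA", "HBA", "HBD", "MR", "nF",
                          "rings", "heavyAtoms")

#' Physicochemical descriptors
#'
#' Real-valued molecular descriptors from a documented registry:
#' molecular weight (\code{MW}, g/mol), octanol/water partition estimate
#' (\code{logP}), topological polar surface area (\code{TPSA}, A^2),
#' hydrogen-bond acceptor and donor counts (\code{HBA}, \code{HBD}),
#' molar refractivity (\code{MR}), fluorine count (\code{nF}), smallest
#' set of rings count (\code{rings}, circuit rank) and heavy-atom count
#' (\code{heavyAtoms}). Failed values are imputed with the column median
#' and reported.
#'
#' @param smiles character vector of structures.
#' @param descriptorSet subset of the registry, in registry order.
#' @param ids row identifiers.
#' @return A \linkS4class{FeatureMatrix} of kind \code{"physchem"} with an
#'   \code{imputed} count in its params.
#' @export
physchemDescriptors <- function(smiles, descriptorSet = .DESCRIPTOR_REGISTRY,
                                ids = NULL) {
  descriptorSet <- .DESCRIPTOR_REGISTRY[.DESCRIPTOR_REGISTRY %in% descriptorSet]
  if (length(descriptorSet) == 0L)
    stop("descriptorSet must name registry descriptors", call. = FALSE)
  if (is.null(ids))
    ids <- if (!is.null(names(smiles))) names(smiles)
           else as.character(seq_along(smiles))
  can <- canonicalSmiles(smiles)
  if (any(is.na(can)))
    stop("unparseable structure(s): standardize/canonicalize first",
         call. = FALSE)
  graphs <- .molGraphs(can)
  prList <- ChemmineOB::forEachMol("SMILES",
                                   paste0(can, "\n", collapse = ""),
                                   function(mol) ChemmineOB::prop_OB(mol))
  pr <- do.call(rbind, prList)
  ringCount <- vapply(graphs, function(g)
    nrow(g$bonds) - length(g$symbols) + .nComponents(g), numeric(1))
  heavy <- vapply(graphs, function(g) length(g$symbols), numeric(1))
  cols <- list(MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA, HBA = pr$HBA1,
               HBD = pr$HBD, MR = pr$MR, nF = pr$nF, rings = ringCount,
               heavyAtoms = heavy)
  vals <- do.call(cbind, cols[descriptorSet])
  nImputed <- 0L
  for (j in seq_len(ncol(vals))) {
    bad <- !is.finite(vals[, j])
    if (any(bad)) {
      med <- stats::median(vals[!bad, j])
      if (!is.finite(med)) med <- 0
      vals[bad, j] <- med
      nImputed <- nImputed + sum(bad)
    }
  }
  if (nImputed > 0L)
    .log("physchemDescriptors: imputed %d failed values with column medians",
         nImputed)
  colnames(vals) <- descriptorSet
  FeatureMatrix(vals, rowIds = ids, featureKind = "physchem",
                params = list(descriptorSet = descriptorSet,
                              imputed = nImputed))
}

# Number of connected components of the molecular graph (union-find);
# used for the circuit-rank ring count: rings = bonds - atoms + components.
.nComponents <- function(g) {
  nA <- length(g$symbols)
  if (nA == 0L) return(0L)
  comp <- seq_len(nA)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
      ra <- a; while (comp[ra] != ra) ra <- comp[ra]
      rb <- b; while (comp[rb] != rb) rb <- comp[rb]
      if (ra != rb) comp[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nA), function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }, integer(1))
  length(unique(roots))
}

#' Bemis-Murcko scaffold
#'
#' Extracts the molecular framework - ring systems plus the linkers
#' connecting them - by iteratively pruning terminal atoms, then restoring
#' atoms attached to the framework by a double (or higher-order) bond
#' (e.g. carbonyl oxygens on a ring). The scaffold is emitted as canonical
#' SMILES; acyclic molecules map to the empty-scaffold sentinel \code{""},
#' which counts as one shared scaffold class in diversity computations.
#'
#' @param smiles character vector of parseable structures.
#' @return character vector of canonical scaffold SMILES (\code{""} for
#'   acyclic molecules).
#' @export
#' @examples
#' murckoScaffold(c("Cc1ccccc1", "CCCC"))
murckoScaffold <- function(smiles) {
  can <- canonicalSmiles(smiles)
  if (any(is.na(can)))
    stop("unparseable structure(s) passed to murckoScaffold", call. = FALSE)
  graphs <- .molGraphs(can)
  out <- character(length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    fw <- .frameworkAtoms(g)
    if (length(fw) == 0L) { out[i] <- ""; next }
    # restore terminal atoms multiply bonded to the framework
    b <- g$bonds
    extra <- integer(0)
    if (nrow(b) > 0) {
      for (k in seq_len(nrow(b))) {
        if (b[k, 3] >= 2L) {
          if (b[k, 1] %in% fw && !(b[k, 2] %in% fw)) extra <- c(extra, b[k, 2])
          if (b[k, 2] %in% fw && !(b[k, 1] %in% fw)) extra <- c(extra, b[k, 1])
        }
      }
    }
    keep <- sort(unique(c(fw, extra)))
    if (length(keep) == length(g$symbols)) {
      out[i] <- can[i]
      next
    }
    sub <- ChemmineR::atomsubset(g$sdf, atomrows = keep)
    sset <- methods::new("SDFset", SDF = list(sub), ID = "scaffold")
    smi <- as.character(ChemmineR::sdf2smiles(sset))
    out[i] <- canonicalSmiles(smi)
  }
  out
}
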