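#' Parse a protein structure (PDB or mmCIF)
#'
#' Reads a coordinate file into a flat atom table. Only the first model
#' of multi-model files is kept; when alternate locations are present,
#' the highest-occupancy altloc of each atom is retained. Hetero records
#' (ions, waters, ligands) are kept.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return Object of class `structure_model`: a list with `atoms` (a
#'   data.frame with columns `type`, `eleno`, `elety`, `alt`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `elesy`) and
#'   `source` (the input path).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)),
    error = function(e) stop("could not parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  ## first model only: bio3d already restricts $atom to model 1 when
  ## multi = FALSE, but coordinates may still be NA-padded; drop those
  at <- at[is.finite(at$x) & is.finite(at$y) & is.finite(at$z), , drop = FALSE]

  ## altloc policy: keep the highest-occupancy altloc per atom site
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.finite(at$o), at$o, 1)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  ## resolve elements: use the element column, fall back on atom names
  elesy <- toupper(trimws(as.character(at$elesy)))
  missing_el <- is.na(elesy) | !nzchar(elesy)
  if (any(missing_el)) {
    warning(sprintf("element column missing for %d atom(s); inferring from atom names",
                    sum(missing_el)))
    elesy[missing_el] <- .element_from_name(at$elety[missing_el],
                                            at$resid[missing_el],
                                            at$type[missing_el])
  }
  at$elesy <- elesy
  rownames(at) <- NULL
  cols <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "elesy")
  structure(list(atoms = at[, intersect(cols, names(at)), drop = FALSE],
                 source = path),
            class = "structure_model")
}

## Name-based element inference: hetero atoms whose residue name equals
## the atom name and is a known ion are that ion; otherwise the first
## alphabetic character of the stripped atom name.
.element_from_name <- function(elety, resid, type) {
  elety <- toupper(trimws(elety)); resid <- toupper(trimws(resid))
  out <- character(length(elety))
  ion <- type == "HETATM" & resid == elety & elety %in% .ION_ELEMENTS
  out[ion] <- elety[ion]
  rest <- !ion
  stripped <- gsub("[^A-Z]", "", elety[rest])
  out[rest] <- substr(stripped, 1L, 1L)
  out
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure model: %d atoms (%d hetero), %d chain(s)\n",
              nrow(a), sum(a$type == "HETATM"),
              length(unique(a$chain))))
  invisible(x)
}

#' Side-chain pseudo-atom vectors of acidic residues
#'
#' Each Asp/Glu side chain is reduced to a two-point vector: for Asp
#' from Cbeta to the midpoint of Odelta1/Odelta2, and (by analogy, for
#' the DEDD/3D1E variants) for Glu from Cgamma to the midpoint of
#' Oepsilon1/Oepsilon2. Residues with missing side-chain atoms, or whose
#' vector length falls outside the 1.0-3.5 A sanity window, are skipped
#' with a warning.
#'
#' @param structure A [parse_structure()] result.
#' @param residues Optional data.frame with columns `chain` and `resno`
#'   (and optionally `insert`) restricting — and ordering — the residues
#'   used.
#' @return data.frame of class `sidechain_vectors` with one row per
#'   residue: `chain`, `resno`, `insert`, `resid`, base coordinates
#'   `bx`, `by`, `bz` and tip coordinates `tx`, `ty`, `tz` (Angstrom).
#' @export
sidechain_vectors <- function(structure, residues = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  acid <- at[at$resid %in% c("ASP", "GLU") & at$type == "ATOM", , drop = FALSE]
  key <- unique(acid[, c("chain", "resno", "insert", "resid")])
  if (!is.null(residues)) {
    if (is.null(residues$insert)) residues$insert <- ""
    idx <- match(paste(residues$chain, residues$resno, residues$insert),
                 paste(key$chain, key$resno, key$insert))
    if (anyNA(idx))
      stop("requested residue(s) not found as Asp/Glu in the structure: ",
           paste(paste0(residues$chain, ":", residues$resno)[is.na(idx)],
                 collapse = ", "))
    key <- key[idx, , drop = FALSE]
  }
  rows <- vector("list", nrow(key))
  skipped <- character(0)
  for (i in seq_len(nrow(key))) {
    res <- acid[acid$chain == key$chain[i] & acid$resno == key$resno[i] &
                  acid$insert == key$insert[i], , drop = FALSE]
    names_needed <- if (key$resid[i] == "ASP") c("CB", "OD1", "OD2")
                    else c("CG", "OE1", "OE2")
    coords <- lapply(names_needed, function(nm) {
      r <- res[res$elety == nm, , drop = FALSE]
      if (nrow(r) == 0L) NULL else c(r$x[1L], r$y[1L], r$z[1L])
    })
    if (any(vapply(coords, is.null, logical(1L)))) {
      skipped <- c(skipped, paste0(key$chain[i], ":", key$resno[i]))
      next
    }
    base <- coords[[1L]]
    tip <- (coords[[2L]] + coords[[3L]]) / 2
    len <- sqrt(sum((tip - base)^2))
    if (len < 1.0 || len > 3.5) {
      skipped <- c(skipped, paste0(key$chain[i], ":", key$resno[i],
                                   sprintf(" (vector %.2f A)", len)))
      next
    }
    rows[[i]] <- data.frame(chain = key$chain[i], resno = key$resno[i],
                            insert = key$insert[i], resid = key$resid[i],
                            bx = base[1L], by = base[2L], bz = base[3L],
                            tx = tip[1L], ty = tip[2L], tz = tip[3L])
  }
  if (length(skipped))
    warning("skipped residue(s) with missing/abnormal side chains: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      bx = numeric(0), by = numeric(0), bz = numeric(0),
                      tx = numeric(0), ty = numeric(0), tz = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("sidechain_vectors", "data.frame")
  out
}

#' Construct a motif query from side-chain vectors
#'
#' @param vectors A `sidechain_vectors` data.frame (>= 3 residues), in
#'   the residue order defining the query.
#' @param source Free-text provenance label (structure id + residues).
#' @return Object of class `motif_query`.
#' @export
motif_query <- function(vectors, source = "") {
  if (nrow(vectors) < 3L) stop("a motif query needs at least 3 residues")
  B <- as.matrix(vectors[, c("bx", "by", "bz")])
  if (max(stats::dist(B)) > 20)
    warning("pairwise base distances exceed 20 A; query is unusually spread out")
  structure(list(vectors = vectors, source = as.character(source)[1L]),
            class = "motif_query")
}

#' @export
print.motif_query <- function(x, ...) {
  cat(sprintf("Motif query%s: %s\n",
              if (nzchar(x$source)) paste0(" [", x$source, "]") else "",
              paste(paste0(x$vectors$chain, ":", x$vectors$resid,
                           x$vectors$resno), collapse = ", ")))
  invisible(x)
}

## Interleave base/tip rows of a vector table into a 2N x 3 matrix.
.pseudo_atoms <- function(vectors) {
  n <- nrow(vectors)
  M <- matrix(NA_real_, 2L * n, 3L)
  M[seq(1L, 2L * n, by = 2L), ] <- as.matrix(vectors[, c("bx", "by", "bz")])
  M[seq(2L, 2L * n, by = 2L), ] <- as.matrix(vectors[, c("tx", "ty", "tz")])
  M
}

## Mirror a vector table through the x = 0 plane.
.mirror_vectors <- function(vectors) {
  vectors$bx <- -vectors$bx
  vectors$tx <- -vectors$tx
  vectors
}

#' Least-squares rigid superposition of pseudo-atom sets
#'
#' Kabsch superposition of the candidate points onto the query points
#' using a proper rotation only (mirror solutions are never returned
#' silently; chirality is handled upstream by mirroring the query).
#'
#' @param query_coords,candidate_coords Numeric matrices of identical
#'   dimension (2N x 3), pseudo-atoms in matching row order.
#' @return List with `rmsd` (Angstrom, over all point pairs), `rotation`
#'   (3x3 proper rotation applied to the centered candidate) and
#'   `translation` so that `candidate %*% rotation + translation`
#'   superposes onto the query.
#' @export
superpose_rmsd <- function(query_coords, candidate_coords) {
  X <- as.matrix(query_coords); Y <- as.matrix(candidate_coords)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stop("coordinate sets must be matrices of identical 2N x 3 dimension")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Yc, Xc)                    # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate (collinear) point set: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)               # proper rotation, det = +1
  Yr <- Yc %*% R
  rmsd <- sqrt(mean(rowSums((Yr - Xc)^2)))
  list(rmsd = rmsd, rotation = R, translation = cx - cy %*% R)
}

#' Search a structure for a side-chain vector motif
#'
#' Enumerates candidate residue sets of the query's residue types whose
#' pairwise base-atom distances match the query's within a pruning
#' tolerance, superposes each type-consistent pairing of the 2N
#' pseudo-atoms, and keeps hits at or below the RMSD cutoff. Because the
#' motif is chiral, the left-handed search applies the identical
#' procedure to the mirrored query (x -> -x); left-handed hits carry an
#' explicit `handedness = "left"` flag rather than an improper rotation.
#' Hits sharing the same residue set (within one handedness) are
#' deduplicated keeping the best-RMSD pairing, and results are sorted by
#' RMSD.
#'
#' @param structure A [parse_structure()] result (or path).
#' @param query A [motif_query()].
#' @param rmsd_cutoff RMSD cutoff in Angstrom (default 2.5).
#' @param handedness `"both"` (default), `"right"` or `"left"`.
#' @param prune_tol Base-distance pruning tolerance in Angstrom
#'   (default 3.5). Pruning is guaranteed never to discard a hit (or a
#'   better pairing of one) only when `prune_tol >=
#'   sqrt(4 * N) * rmsd_cutoff`, since after superposition a single
#'   base-pair distance can deviate by up to that factor times the RMSD;
#'   the default is a practical compromise that cannot miss near-exact
#'   motif copies but bounds the combinatorics.
#' @param max_candidates Abort with an error when the enumeration
#'   exceeds this many candidate assignments (default 1e6).
#' @return Object of class `motif_hits`: a list of hits, each with
#'   `residues` (data.frame in pairing order), `handedness`, `rmsd`,
#'   `rotation`, `translation`, `mirrored`.
#' @export
search_motif <- function(structure, query, rmsd_cutoff = 2.5,
                         handedness = c("both", "right", "left"),
                         prune_tol = 3.5, max_candidates = 1e6) {
  handedness <- match.arg(handedness)
  if (rmsd_cutoff <= 0) stop("'rmsd_cutoff' must be > 0")
  if (is.character(structure)) structure <- parse_structure(structure)
  stopifnot(inherits(query, "motif_query"))
  vecs <- suppressWarnings(sidechain_vectors(structure))
  hands <- switch(handedness, both = c("right", "left"),
                  right = "right", left = "left")
  hits <- list()
  for (hand in hands) {
    qv <- if (hand == "left") .mirror_vectors(query$vectors) else query$vectors
    hits <- c(hits, .search_one_hand(vecs, qv, hand, rmsd_cutoff,
                                     prune_tol, max_candidates))
  }
  ord <- order(vapply(hits, `[[`, numeric(1L), "rmsd"))
  structure(hits[ord], class = "motif_hits")
}

.search_one_hand <- function(vecs, qv, hand, cutoff, tol, max_candidates) {
  nq <- nrow(qv)
  if (nrow(vecs) < nq) return(list())
  QB <- as.matrix(qv[, c("bx", "by", "bz")])
  D <- as.matrix(stats::dist(QB))
  CB <- as.matrix(vecs[, c("bx", "by", "bz")])
  CD <- as.matrix(stats::dist(CB))
  cand_by_pos <- lapply(seq_len(nq), function(p)
    which(vecs$resid == qv$resid[p]))
  n_assign <- 0L
  assigns <- list()

  recurse <- function(pos, chosen) {
    if (pos > nq) {
      n_assign <<- n_assign + 1L
      if (n_assign > max_candidates)
        stop("more than ", format(max_candidates, scientific = FALSE),
             " candidate sets after pruning; tighten 'prune_tol'")
      assigns[[n_assign]] <<- chosen
      return(invisible())
    }
    for (r in cand_by_pos[[pos]]) {
      if (r %in% chosen) next
      ok <- TRUE
      for (q in seq_len(pos - 1L)) {
        if (abs(CD[r, chosen[q]] - D[pos, q]) > tol) { ok <- FALSE; break }
      }
      if (ok) recurse(pos + 1L, c(chosen, r))
    }
    invisible()
  }
  recurse(1L, integer(0))

  Q <- .pseudo_atoms(qv)
  hits <- list()
  for (a in assigns) {
    C <- .pseudo_atoms(vecs[a, , drop = FALSE])
    sp <- tryCatch(superpose_rmsd(Q, C), error = function(e) NULL)
    if (is.null(sp) || sp$rmsd > cutoff) next
    hits[[length(hits) + 1L]] <- list(
      residues = vecs[a, c("chain", "resno", "insert", "resid")],
      handedness = hand, rmsd = sp$rmsd,
      rotation = sp$rotation, translation = sp$translation,
      mirrored = hand == "left")
  }
  ## deduplicate by unordered residue set, keep best pairing
  if (length(hits) > 1L) {
    keyset <- vapply(hits, function(h)
      paste(sort(paste(h$residues$chain, h$residues$resno,
                       h$residues$insert)), collapse = "|"), character(1L))
    rmsds <- vapply(hits, `[[`, numeric(1L), "rmsd")
    best <- tapply(seq_along(hits), keyset, function(idx) idx[which.min(rmsds[idx])])
    hits <- hits[sort(unlist(best))]
  }
  hits
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("%d motif hit(s)\n", length(x)))
  for (i in seq_len(min(length(x), 10L))) {
    h <- x[[i]]
    cat(sprintf("  %2d. rmsd %6.3f A  %-5s  %s\n", i, h$rmsd, h$handedness,
                paste(paste0(h$residues$chain, ":", h$residues$resid,
                             h$residues$resno), collapse = " ")))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.motif_hits <- function(x, ...) {
  if (!length(x))
    return(data.frame(rank = integer(0), rmsd = numeric(0),
                      handedness = character(0), residues = character(0)))
  data.frame(
    rank = seq_along(x),
    rmsd = vapply(x, `[[`, numeric(1L), "rmsd"),
    handedness = vapply(x, `[[`, character(1L), "handedness"),
    residues = vapply(x, function(h)
      paste(paste0(h$residues$chain, ":", h$residues$resno),
            collapse = ","), character(1L)))
}

#' Overlay two motifs and report the RMSD
#'
#' Convenience wrapper: builds the side-chain vectors of the listed
#' residues in both structures, in the given order, and superposes them.
#'
#' @param structA,structB [parse_structure()] results (or paths).
#' @param residuesA,residuesB Residue lists, either data.frames with
#'   `chain`/`resno` columns or character vectors like `"A:326"`.
#' @param metric `"pseudoatom"` (default): RMSD over the 2N superposed
#'   pseudo-atom positions. `"vector"`: after the same superposition,
#'   RMSD of the differences between corresponding side-chain vectors
#'   (tip - base). Both are reported by structure-comparison servers;
#'   they need not agree exactly.
#' @return The RMSD in Angstrom, with the full superposition in the
#'   `"superposition"` attribute.
#' @export
overlay_motifs <- function(structA, residuesA, structB, residuesB,
                           metric = c("pseudoatom", "vector")) {
  metric <- match.arg(metric)
  if (is.character(structA)) structA <- parse_structure(structA)
  if (is.character(structB)) structB <- parse_structure(structB)
  ra <- .parse_residue_list(residuesA)
  rb <- .parse_residue_list(residuesB)
  va <- suppressWarnings(sidechain_vectors(structA, ra))
  vb <- suppressWarnings(sidechain_vectors(structB, rb))
  if (nrow(va) != nrow(vb))
    stop("residue lists resolve to different numbers of usable side chains")
  sp <- superpose_rmsd(.pseudo_atoms(va), .pseudo_atoms(vb))
  out <- if (metric == "pseudoatom") {
    sp$rmsd
  } else {
    VA <- as.matrix(va[, c("tx", "ty", "tz")]) -
          as.matrix(va[, c("bx", "by", "bz")])
    VB <- (as.matrix(vb[, c("tx", "ty", "tz")]) -
           as.matrix(vb[, c("bx", "by", "bz")])) %*% sp$rotation
    sqrt(mean(rowSums((VA - VB)^2)))
  }
  attr(out, "superposition") <- sp
  out
}

.parse_residue_list <- function(residues) {
  if (is.data.frame(residues)) {
    if (is.null(residues$insert)) residues$insert <- ""
    return(residues)
  }
  parts <- strsplit(as.character(residues), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("residues must be 'chain:resno' strings or a data.frame")
  data.frame(chain = vapply(parts, `[`, character(1L), 1L),
             resno = as.integer(vapply(parts, `[`, character(1L), 2L)),
             insert = "")
}

#' Select an atom's coordinates from a structure
#'
#' @param structure A [parse_structure()] result.
#' @param chain,resno,elety,resid Optional filters; all supplied filters
#'   must match. Exactly one atom must remain.
#' @return Numeric length-3 coordinates (Angstrom).
#' @export
select_atom <- function(structure, chain = NULL, resno = NULL,
                        elety = NULL, resid = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(resno)) at <- at[at$resno == resno, , drop = FALSE]
  if (!is.null(elety)) at <- at[at$elety == elety, , drop = FALSE]
  if (!is.null(resid)) at <- at[at$resid == resid, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atom matches the selection")
  if (nrow(at) > 1L) stop("selection matches ", nrow(at), " atoms; refine it")
  c(at$x, at$y, at$z)
}

#' Distance between two selected atoms
#'
#' Plain atom-atom distance utility, e.g. from a bound metal ion to the
#' catalytic serine O-gamma.
#'
#' @param structure A [parse_structure()] result.
#' @param sel1,sel2 Lists of arguments for [select_atom()] (e.g.
#'   `list(resid = "MG")`, `list(chain = "A", resno = 200, elety = "OG")`).
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(structure, sel1, sel2) {
  p1 <- do.call(select_atom, c(list(structure), sel1))
  p2 <- do.call(select_atom, c(list(structure), sel2))
  sqrt(sum((p1 - p2)^2))
}
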