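#' Annotate ion and water occupancy of a matched motif pocket
#'
#' Inventories the hetero atoms inside a matched 4-carboxylate pocket.
#' An ion belongs to the pocket when it lies within `ion_cutoff` of any
#' motif carboxylate oxygen, or is linked to one via a bridging water
#' lying within `water_cutoff` of both. For each ion the motif residues
#' are split into direct contacts (a carboxylate O within `ion_cutoff`)
#' and water-mediated contacts (bridged by a water). Waters are counted
#' when within `water_cutoff` of at least one carboxylate oxygen.
#'
#' @param structure A [parse_structure()] result.
#' @param hit A single hit from [search_motif()] (or any list with a
#'   `residues` data.frame of `chain`/`resno`/`insert`).
#' @param ion_cutoff Direct ion-oxygen contact cutoff, Angstrom
#'   (default 3.0).
#' @param water_cutoff Water hydrogen-bond cutoff, Angstrom
#'   (default 3.5).
#' @return Object of class `pocket_occupancy`: list with `ions` (a list
#'   of per-ion records: `element`, `coords`, `direct`, `water_mediated`
#'   residue labels), `water_count`, and `classification` in
#'   `"unoccupied"`, `"monovalent"`, `"divalent"`, `"multi_ion"`.
#' @export
annotate_pocket <- function(structure, hit, ion_cutoff = 3.0,
                            water_cutoff = 3.5) {
  stopifnot(inherits(structure, "structure_model"))
  res <- hit$residues
  if (is.null(res)) stop("'hit' must carry a 'residues' data.frame")
  if (is.null(res$insert)) res$insert <- ""
  at <- structure$atoms

  ## carboxylate oxygens of the motif residues, tagged by residue
  sel <- paste(at$chain, at$resno, at$insert) %in%
    paste(res$chain, res$resno, res$insert)
  ox <- at[sel & at$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
  if (nrow(ox) == 0L) stop("hit residues have no carboxylate oxygens in the structure")
  ox_res <- paste0(ox$chain, ":", ox$resno, ox$insert)
  OX <- as.matrix(ox[, c("x", "y", "z")])

  het <- at[at$type == "HETATM", , drop = FALSE]
  is_water <- het$resid %in% .WATER_RESIDUES
  ions <- het[!is_water & het$elesy %in% .ION_ELEMENTS, , drop = FALSE]
  waters <- het[is_water & het$elesy == "O", , drop = FALSE]
  W <- as.matrix(waters[, c("x", "y", "z")])

  dmat <- function(P, Q) {
    ## pairwise distances between rows of P and rows of Q
    if (nrow(P) == 0L || nrow(Q) == 0L)
      return(matrix(numeric(0), nrow(P), nrow(Q)))
    outer(seq_len(nrow(P)), seq_len(nrow(Q)),
          Vectorize(function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))))
  }

  ## waters H-bonded to the pocket
  w_ox <- dmat(W, OX)
  pocket_water <- if (nrow(waters)) apply(w_ox <= water_cutoff, 1L, any) else logical(0)

  ion_records <- list()
  if (nrow(ions)) {
    I <- as.matrix(ions[, c("x", "y", "z")])
    i_ox <- dmat(I, OX)
    i_w <- dmat(I, W)
    for (i in seq_len(nrow(ions))) {
      direct_ox <- i_ox[i, ] <= ion_cutoff
      ## waters bridging this ion to a carboxylate O
      bridges <- if (nrow(waters))
        which(i_w[i, ] <= water_cutoff & pocket_water) else integer(0)
      mediated_ox <- rep(FALSE, nrow(ox))
      for (b in bridges)
        mediated_ox <- mediated_ox | (w_ox[b, ] <= water_cutoff)
      if (!any(direct_ox) && !any(mediated_ox)) next
      direct_res <- sort(unique(ox_res[direct_ox]))
      mediated_res <- setdiff(sort(unique(ox_res[mediated_ox])), direct_res)
      ion_records[[length(ion_records) + 1L]] <- list(
        element = ions$elesy[i],
        coords = unname(I[i, ]),
        direct = direct_res,
        water_mediated = mediated_res)
    }
  }

  classification <- if (length(ion_records) == 0L) {
    "unoccupied"
  } else if (length(ion_records) > 1L) {
    "multi_ion"
  } else if (ion_records[[1L]]$element %in% .DIVALENT_ELEMENTS) {
    "divalent"
  } else {
    "monovalent"
  }
  structure(list(ions = ion_records,
                 water_count = sum(pocket_water),
                 classification = classification,
                 ion_cutoff = ion_cutoff, water_cutoff = water_cutoff),
            class = "pocket_occupancy")
}

#' @export
print.pocket_occupancy <- function(x, ...) {
  cat(sprintf("Pocket occupancy: %s (%d ion(s), %d pocket water(s))\n",
              x$classification, length(x$ions), x$water_count))
  for (ion in x$ions)
    cat(sprintf("  %s  direct: %s | water-mediated: %s\n", ion$element,
                paste(ion$direct, collapse = " "),
                if (length(ion$water_mediated))
                  paste(ion$water_mediated, collapse = " ") else "-"))
  invisible(x)
}
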