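## Run a generator under a fixed seed without disturbing the caller's
## RNG stream: every generator is a pure function of (spec, seed).
.with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  fn()
}

#' Generate a synthetic mono-exponential inactivation decay
#'
#' A(t_i) = A0 * exp(-k t_i) * (1 + eps_i), eps ~ N(0, noise_rel^2):
#' multiplicative noise, matching the roughly constant coefficient of
#' variation of replicate activity assays. By default the time course
#' covers three half-lives.
#'
#' @param k True first-order rate constant, min^-1 (> 0).
#' @param n_points Number of time points (default 20).
#' @param t_max Last time point, minutes (default 3 half-lives).
#' @param noise_rel Relative noise SD (default 0.02).
#' @param seed Integer seed (generators are pure functions of their
#'   arguments and the seed).
#' @param A0 Initial activity (default 1).
#' @param label Curve label.
#' @return A [decay_curve()].
#' @export
gen_decay <- function(k, n_points = 20L, t_max = NULL, noise_rel = 0.02,
                      seed = 1L, A0 = 1, label = "") {
  if (k <= 0) stop("'k' must be > 0")
  if (is.null(t_max)) t_max <- 3 * log(2) / k
  times <- seq(0, t_max, length.out = n_points)
  .with_seed(seed, function() {
    eps <- if (noise_rel > 0) stats::rnorm(n_points, 0, noise_rel) else 0
    decay_curve(times, pmax(A0 * exp(-k * times) * (1 + eps), 0), label)
  })
}

#' Generate a synthetic EPR-style titration series
#'
#' For each total ligand concentration the free concentration is found
#' by solving the mass balance c_free + protein_total * nu(c_free) =
#' ligand_total (a monotone scalar root), and the observed signal is
#' I = gamma * (c_free + alpha * c_bound) * (1 + eps), with
#' multiplicative noise. Defaults mirror the standard design: 20 uM
#' catalytic subunits titrated with 4-280 uM divalent ion, bound signal
#' amplitude 5% of free.
#'
#' @param model A [binding_model()].
#' @param protein_total Catalytic-subunit concentration, M.
#' @param ligand_totals Total ligand concentrations, M (default 25
#'   geometrically spaced points spanning 4e-6 to 2.8e-4 M, the usual
#'   titration practice of roughly constant-ratio additions, which
#'   samples the high-affinity transition densely).
#' @param alpha Bound-signal amplitude fraction (default 0.05).
#' @param gamma Signal per M free ligand (default 1e5).
#' @param noise_rel Relative signal noise SD (default 0).
#' @param seed Integer seed.
#' @return A [titration_series()].
#' @export
gen_titration <- function(model, protein_total = 2e-5,
                          ligand_totals = NULL, alpha = 0.05,
                          gamma = 1e5, noise_rel = 0, seed = 1L) {
  stopifnot(inherits(model, "binding_model"))
  if (is.null(ligand_totals))
    ligand_totals <- exp(seq(log(4e-6), log(2.8e-4), length.out = 25L))
  c_free <- vapply(ligand_totals, function(L) {
    f <- function(cf) cf + protein_total * nu_bound(model, cf) - L
    r <- tryCatch(
      stats::uniroot(f, c(0, L), tol = 1e-16 * max(1, L / 1e-6))$root,
      error = function(e) stop("mass-balance root finding failed: ",
                               conditionMessage(e)))
    r
  }, numeric(1L))
  c_bound <- ligand_totals - c_free
  signal <- gamma * (c_free + alpha * c_bound)
  .with_seed(seed, function() {
    if (noise_rel > 0)
      signal <- signal * (1 + stats::rnorm(length(signal), 0, noise_rel))
    titration_series(ligand_totals, protein_total, signal,
                     alpha = alpha, gamma = gamma)
  })
}

#' Generate a synthetic DSC thermogram
#'
#' The ideal kinetic transition of [excess_heat_capacity()] plus an
#' optional linear instrumental baseline and additive Gaussian noise
#' (instrument noise on a DSC trace is additive, not proportional).
#'
#' @param params An [arrhenius_params()].
#' @param scan_rate Scan rate, K min^-1 (default 1).
#' @param grid Temperature grid, K (default T* - 25 to T* + 15 in
#'   0.1 K steps).
#' @param noise_abs Additive noise SD, kcal mol^-1 K^-1 (default 0).
#' @param baseline Optional `c(slope, intercept)` of a linear baseline
#'   added to the trace.
#' @param seed Integer seed.
#' @return A [thermogram()].
#' @export
gen_thermogram <- function(params, scan_rate = 1, grid = NULL,
                           noise_abs = 0, baseline = NULL, seed = 1L) {
  stopifnot(inherits(params, "arrhenius_params"))
  if (is.null(grid))
    grid <- seq(params$T_star - 25, params$T_star + 15, by = 0.1)
  tg <- excess_heat_capacity(params, grid, scan_rate)
  cp <- tg$Cp_ex
  if (!is.null(baseline))
    cp <- cp + baseline[1L] * grid + baseline[2L]
  .with_seed(seed, function() {
    if (noise_abs > 0)
      cp <- cp + stats::rnorm(length(cp), 0, noise_abs)
    thermogram(grid, cp, scan_rate)
  })
}

#' Built-in chiral 4-aspartate motif template
#'
#' A synthetic 4D pocket: four Asp side-chain vectors whose tips point
#' inward toward a common center, with tangential twists that make the
#' arrangement markedly chiral (its mirror image cannot be superposed
#' onto it by a proper rotation within typical search cutoffs, under any
#' residue pairing). Residue numbers follow the classical pocket
#' (326/389/392/393) purely as a mnemonic; the geometry is synthetic.
#'
#' @return A [motif_query()].
#' @export
default_4d_template <- function() {
  ## frozen geometry: its mirror image cannot be proper-superposed onto
  ## it below 3.2 A RMSD under any of the 24 residue pairings
  bases <- rbind(c(3.591, -0.496, 2.144),
                 c(-6.393, -6.297, 1.116),
                 c(4.530, -5.973, -3.978),
                 c(-6.484, 0.006, 3.358))
  tips <- rbind(c(4.614, 1.182, 2.940),
                c(-7.146, -6.485, 3.089),
                c(5.536, -4.694, -5.337),
                c(-6.972, 1.697, 2.176))
  v <- data.frame(chain = "A", resno = c(326L, 389L, 392L, 393L),
                  insert = "", resid = "ASP",
                  bx = bases[, 1L], by = bases[, 2L], bz = bases[, 3L],
                  tx = tips[, 1L], ty = tips[, 2L], tz = tips[, 3L])
  class(v) <- c("sidechain_vectors", "data.frame")
  motif_query(v, source = "synthetic 4D template")
}

## Build full-atom Asp/Glu records around a base->tip pseudo-atom vector.
## Ideal geometry: C-C 1.52 A, C-O 1.25 A, O-C-O 123 deg; only the
## pseudo-atoms matter to the vector search.
.build_acidic_atoms <- function(base, tip, resid) {
  u <- tip - base
  len <- sqrt(sum(u^2)); u <- u / len
  a <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- pracma::cross(u, a); p <- p / sqrt(sum(p^2))
  q <- pracma::cross(u, p)
  carb <- base + min(1.52, len - 0.3) * u          # carboxylate carbon
  rp <- sqrt(sum((tip - carb)^2))
  d <- sqrt(max(1.25^2 - rp^2, 0.09))
  o1 <- tip + d * p
  o2 <- tip - d * p
  ca <- base + 1.53 * (( -u + 0.8 * q) / sqrt(sum((-u + 0.8 * q)^2)))
  n <- ca + 1.46 * (-u)
  if (resid == "ASP") {
    nm <- c("N", "CA", "CB", "CG", "OD1", "OD2")
    xyz <- rbind(n, ca, base, carb, o1, o2)
  } else {
    cb <- base - 1.52 * u
    nm <- c("N", "CA", "CB", "CG", "CD", "OE1", "OE2")
    xyz <- rbind(n, ca, cb, base, carb, o1, o2)
  }
  el <- substr(nm, 1L, 1L)
  list(elety = nm, xyz = xyz, elesy = el)
}

#' Generate a synthetic structure with a planted carboxylate motif
#'
#' Writes a single-model PDB containing the template motif's residues
#' (full Asp side chains reconstructed around each pseudo-atom vector,
#' optionally jittered), `n_decoys` randomly placed and oriented decoy
#' Asp/Glu residues at least `min_separation` apart, and optional ions
#' and waters. With `mirror = TRUE` every coordinate is reflected
#' through the x = 0 plane, producing a motif that only a left-handed
#' search can retrieve.
#'
#' @param template A [motif_query()] (default [default_4d_template()]).
#' @param n_decoys Number of decoy acidic residues (default 30).
#' @param jitter_sigma Per-coordinate Gaussian jitter SD applied to
#'   every motif atom, Angstrom (default 0).
#' @param ions Optional data.frame with columns `element`, `x`, `y`, `z`
#'   for hetero ion records.
#' @param waters Either an integer count of waters to scatter 2.4-3.2 A
#'   from the motif tip centroid, or a data.frame with `x`, `y`, `z`.
#' @param mirror Reflect all coordinates through x = 0 (default FALSE).
#' @param seed Integer seed.
#' @param file Output PDB path (default a tempfile).
#' @param box Edge length of the cube in which decoys are placed
#'   (default 50 A, centered on the origin).
#' @param min_separation Minimum distance between residue anchor points,
#'   Angstrom (default 8).
#' @return The PDB path, invisibly, with the planted motif's residue
#'   table in the `"motif_residues"` attribute.
#' @export
gen_structure <- function(template = default_4d_template(), n_decoys = 30L,
                          jitter_sigma = 0, ions = NULL, waters = 0,
                          mirror = FALSE, seed = 1L,
                          file = tempfile(fileext = ".pdb"),
                          box = 50, min_separation = 8) {
  stopifnot(inherits(template, "motif_query"))
  tv <- template$vectors
  .with_seed(seed, function() {
    recs <- list()
    add <- function(type, chain, resno, resid, elety, xyz, elesy) {
      recs[[length(recs) + 1L]] <<- data.frame(
        type = type, chain = chain, resno = resno, resid = resid,
        elety = elety, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        elesy = elesy)
    }

    ## planted motif
    anchors <- as.matrix(tv[, c("bx", "by", "bz")])
    for (i in seq_len(nrow(tv))) {
      at <- .build_acidic_atoms(unlist(tv[i, c("bx", "by", "bz")]),
                                unlist(tv[i, c("tx", "ty", "tz")]),
                                tv$resid[i])
      if (jitter_sigma > 0)
        at$xyz <- at$xyz + matrix(stats::rnorm(length(at$xyz), 0, jitter_sigma),
                                  ncol = 3L)
      add("ATOM", tv$chain[i], tv$resno[i], tv$resid[i],
          at$elety, at$xyz, at$elesy)
    }

    ## decoys: random positions >= min_separation apart, random orientation
    attempts <- 0L
    placed <- 0L
    while (placed < n_decoys) {
      attempts <- attempts + 1L
      if (attempts > 1e4L)
        stop("decoy placement failed after 10000 attempts; ",
             "enlarge 'box' or reduce 'n_decoys'")
      pos <- stats::runif(3L, -box / 2, box / 2)
      if (nrow(anchors) &&
          min(sqrt(rowSums(sweep(anchors, 2L, pos)^2))) < min_separation)
        next
      anchors <- rbind(anchors, pos)
      placed <- placed + 1L
      u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
      resid <- sample(c("ASP", "GLU"), 1L)
      at <- .build_acidic_atoms(pos, pos + 2.12 * u, resid)
      add("ATOM", "A", 500L + placed, resid, at$elety, at$xyz, at$elesy)
    }

    ## hetero records
    hetno <- 900L
    if (!is.null(ions)) {
      for (i in seq_len(nrow(ions))) {
        el <- toupper(ions$element[i])
        add("HETATM", "A", hetno, el, el,
            matrix(c(ions$x[i], ions$y[i], ions$z[i]), 1L), el)
        hetno <- hetno + 1L
      }
    }
    wat <- if (is.data.frame(waters)) {
      as.matrix(waters[, c("x", "y", "z")])
    } else if (is.numeric(waters) && waters >= 1) {
      ctr <- colMeans(as.matrix(tv[, c("tx", "ty", "tz")]))
      t(vapply(seq_len(as.integer(waters)), function(i) {
        u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
        ctr + stats::runif(1L, 2.4, 3.2) * u
      }, numeric(3L)))
    } else NULL
    if (!is.null(wat) && nrow(wat)) {
      for (i in seq_len(nrow(wat))) {
        add("HETATM", "A", hetno, "HOH", "O", wat[i, , drop = FALSE], "O")
        hetno <- hetno + 1L
      }
    }

    atoms <- do.call(rbind, recs)
    if (mirror) atoms$x <- -atoms$x
    xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
    bio3d::write.pdb(file = file, xyz = xyz, type = atoms$type,
                     resno = atoms$resno, resid = atoms$resid,
                     eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                     chain = atoms$chain, o = rep(1, nrow(atoms)),
                     b = rep(0, nrow(atoms)), elesy = atoms$elesy)
    out <- file
    attr(out, "motif_residues") <- tv[, c("chain", "resno", "insert", "resid")]
    invisible(out)
  })
}
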