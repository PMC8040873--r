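test_that("PDB parsing resolves atoms, models and altlocs correctly", {
  f <- write_single_asp_pdb(tempfile(fileext = ".pdb"))
  s <- parse_structure(f)
  expect_equal(nrow(s$atoms), 8)
  expect_equal(s$atoms$elesy[s$atoms$elety == "OD1"], "O")

  ## two-model file: only model 1 is kept
  fm <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line("ATOM", 1, "CB", "ASP", "A", 10, 0, 0, 0),
    pdb_line("ATOM", 2, "OD1", "ASP", "A", 10, 1, 1, 0),
    pdb_line("ATOM", 3, "OD2", "ASP", "A", 10, 1, -1, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "CB", "ASP", "A", 10, 50, 0, 0),
    pdb_line("ATOM", 2, "OD1", "ASP", "A", 10, 51, 1, 0),
    pdb_line("ATOM", 3, "OD2", "ASP", "A", 10, 51, -1, 0),
    "ENDMDL", "END"), fm)
  sm <- parse_structure(fm)
  expect_equal(nrow(sm$atoms), 3)
  expect_true(all(sm$atoms$x < 10))

  ## altloc A/B: highest occupancy wins
  fa <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "CB", "ASP", "A", 10, 0, 0, 0),
    pdb_line("ATOM", 2, "OD1", "ASP", "A", 10, 1.0, 1, 0, occ = 0.4, alt = "A"),
    pdb_line("ATOM", 3, "OD1", "ASP", "A", 10, 1.2, 1, 0, occ = 0.6, alt = "B"),
    pdb_line("ATOM", 4, "OD2", "ASP", "A", 10, 1, -1, 0),
    "END"), fa)
  sa <- parse_structure(fa)
  od1 <- sa$atoms[sa$atoms$elety == "OD1", ]
  expect_equal(nrow(od1), 1)
  expect_equal(od1$x, 1.2)
  expect_equal(od1$o, 0.6)

  expect_error(parse_structure(tempfile(fileext = ".pdb")), "parse")
})

test_that("side-chain vectors use the carboxylate midpoint", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "CB", "ASP", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "OD1", "ASP", "A", 1, 1, 1, 0),
    pdb_line("ATOM", 3, "OD2", "ASP", "A", 1, 1, -1, 0),
    ## same residue with swapped oxygen labels
    pdb_line("ATOM", 4, "CB", "ASP", "A", 2, 0, 0, 5),
    pdb_line("ATOM", 5, "OD2", "ASP", "A", 2, 1, 1, 5),
    pdb_line("ATOM", 6, "OD1", "ASP", "A", 2, 1, -1, 5),
    ## glutamate analog: CG -> midpoint(OE1, OE2)
    pdb_line("ATOM", 7, "CG", "GLU", "A", 3, 10, 0, 0),
    pdb_line("ATOM", 8, "OE1", "GLU", "A", 3, 11.5, 1, 0),
    pdb_line("ATOM", 9, "OE2", "GLU", "A", 3, 11.5, -1, 0),
    ## incomplete side chain: must be skipped with a warning
    pdb_line("ATOM", 10, "CB", "ASP", "A", 4, 20, 0, 0),
    "END"), f)
  s <- parse_structure(f)
  expect_warning(v <- sidechain_vectors(s), "skipped")
  expect_equal(nrow(v), 3)
  expect_equal(unlist(v[1, c("bx", "by", "bz")]), c(bx = 0, by = 0, bz = 0))
  expect_equal(unlist(v[1, c("tx", "ty", "tz")]), c(tx = 1, ty = 0, tz = 0))
  ## label swap leaves the tip unchanged
  expect_equal(unlist(v[2, c("tx", "ty")]), c(tx = 1, ty = 0))
  ## GLU base is CG, tip the OE midpoint
  expect_equal(unlist(v[3, c("bx", "tx", "ty")]), c(bx = 10, tx = 11.5, ty = 0))
})

test_that("superposition is exact under rigid motion and matches the quaternion oracle", {
  q <- default_4d_template()
  Q <- pseudo_atoms(q$vectors)

  expect_equal(superpose_rmsd(Q, Q)$rmsd, 0, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    ## random proper rotation + translation
    M <- matrix(rnorm(9), 3)
    sv <- svd(M)
    R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    tr <- rnorm(3, sd = 10)
    Y <- Q %*% R + matrix(tr, nrow(Q), 3, byrow = TRUE)
    expect_lt(superpose_rmsd(Q, Y)$rmsd, 1e-8)

    ## jittered copies: SVD result equals Horn quaternion oracle
    Yj <- Y + matrix(rnorm(length(Q), sd = 0.4), ncol = 3)
    r_pkg <- superpose_rmsd(Q, Yj)$rmsd
    r_oracle <- quaternion_superpose_rmsd(Q, Yj)
    expect_lt(abs(r_pkg - r_oracle), 1e-6)
    ## symmetry: A onto B equals B onto A
    expect_lt(abs(superpose_rmsd(Yj, Q)$rmsd - r_pkg), 1e-9)
  }

  ## collinear points are degenerate
  line <- cbind(1:6, 2 * (1:6), -(1:6))
  expect_error(superpose_rmsd(line, line), "degenerate")
})

test_that("self-search returns the planted motif at zero RMSD, right-handed", {
  q <- default_4d_template()
  f <- gen_structure(q, n_decoys = 20, jitter_sigma = 0, seed = 3)
  s <- parse_structure(f)
  hits <- search_motif(s, q, rmsd_cutoff = 2.5, handedness = "both")
  expect_gte(length(hits), 1)
  top <- hits[[1]]
  expect_lt(top$rmsd, 1e-6)
  expect_identical(top$handedness, "right")
  expect_setequal(top$residues$resno, q$vectors$resno)
})

test_that("a mirrored motif is found only by the left-handed search", {
  q <- default_4d_template()
  f <- gen_structure(q, n_decoys = 10, jitter_sigma = 0, mirror = TRUE, seed = 4)
  s <- parse_structure(f)
  right <- search_motif(s, q, rmsd_cutoff = 2.5, handedness = "right")
  left <- search_motif(s, q, rmsd_cutoff = 2.5, handedness = "left")
  expect_length(right, 0)
  expect_gte(length(left), 1)
  expect_lt(left[[1]]$rmsd, 1e-6)
  expect_true(left[[1]]$mirrored)
  ## both = union of the single-handed searches
  both <- search_motif(s, q, rmsd_cutoff = 2.5, handedness = "both")
  sig_both <- vapply(both, function(h)
    hit_signature(h$residues, h$handedness, h$rmsd), character(1))
  sig_union <- vapply(c(right, left), function(h)
    hit_signature(h$residues, h$handedness, h$rmsd), character(1))
  expect_setequal(sig_both, sig_union)
})

test_that("pruned search equals brute-force enumeration", {
  ## prune_tol = sqrt(4N) * cutoff guarantees pruning is lossless, so
  ## the hit sets must agree exactly
  q <- default_4d_template()
  for (seed in c(21, 22, 23)) {
    f <- gen_structure(q, n_decoys = 5, jitter_sigma = 0.4, seed = seed)
    s <- parse_structure(f)
    hits <- search_motif(s, q, rmsd_cutoff = 3.0, handedness = "both",
                         prune_tol = 4 * 3.0)
    brute <- brute_force_search(s, q, cutoff = 3.0)
    vecs <- suppressWarnings(sidechain_vectors(s))
    sig_pkg <- sort(vapply(hits, function(h)
      hit_signature(h$residues, h$handedness, h$rmsd), character(1)))
    sig_bf <- sort(vapply(brute, function(h)
      hit_signature(vecs[h$set, ], h$handedness, h$rmsd), character(1)))
    expect_identical(sig_pkg, sig_bf)
  }
})

test_that("pocket occupancy classifies ions and bridging waters", {
  ## convergent pocket: two near aspartates (direct) and two remote ones
  ## reachable only through bridging waters, metal at the center
  bases <- rbind(c(4.2, 0, 0), c(-4.2, 0, 0), c(0, 6.5, 0), c(0, -6.5, 0))
  tips <- rbind(c(2.08, 0, 0), c(-2.08, 0, 0), c(0, 4.38, 0), c(0, -4.38, 0))
  q <- motif_query(make_vectors(bases, tips))
  hit <- list(residues = data.frame(chain = "A", resno = 1:4, insert = "",
                                    resid = "ASP"))

  f <- gen_structure(q, n_decoys = 0, seed = 1,
                     ions = data.frame(element = "MG", x = 0, y = 0, z = 0),
                     waters = data.frame(x = c(0, 0), y = c(3, -3), z = c(0, 0)))
  s <- parse_structure(f)
  occ <- annotate_pocket(s, hit)
  expect_identical(occ$classification, "divalent")
  expect_length(occ$ions, 1)
  expect_setequal(occ$ions[[1]]$direct, c("A:1", "A:2"))
  expect_setequal(occ$ions[[1]]$water_mediated, c("A:3", "A:4"))
  expect_equal(occ$water_count, 2)

  ## atom-order invariance
  s_shuf <- s
  set.seed(9)
  s_shuf$atoms <- s$atoms[sample(nrow(s$atoms)), ]
  occ2 <- annotate_pocket(s_shuf, hit)
  expect_identical(occ2$classification, occ$classification)
  expect_setequal(occ2$ions[[1]]$direct, occ$ions[[1]]$direct)

  ## sodium: monovalent
  fna <- gen_structure(q, n_decoys = 0, seed = 1,
                       ions = data.frame(element = "NA", x = 0, y = 0, z = 0))
  expect_identical(annotate_pocket(parse_structure(fna), hit)$classification,
                   "monovalent")

  ## no hetero atoms: unoccupied
  f0 <- gen_structure(q, n_decoys = 0, seed = 1)
  expect_identical(annotate_pocket(parse_structure(f0), hit)$classification,
                   "unoccupied")

  ## two ions: multi-ion
  f2 <- gen_structure(q, n_decoys = 0, seed = 1,
                      ions = data.frame(element = c("MG", "CA"),
                                        x = c(0, 1), y = 0, z = 0))
  expect_identical(annotate_pocket(parse_structure(f2), hit)$classification,
                   "multi_ion")
})

test_that("motif overlay reports superposition RMSD and atom distances work", {
  q <- default_4d_template()
  f <- gen_structure(q, n_decoys = 0, jitter_sigma = 0, seed = 5)
  s <- parse_structure(f)
  resids <- paste0("A:", q$vectors$resno)

  ## a structure overlaid on itself is exact
  r_self <- overlay_motifs(s, resids, s, resids)
  expect_lt(as.numeric(r_self), 1e-9)

  ## jittered copy: overlay equals the independent quaternion oracle
  f2 <- gen_structure(q, n_decoys = 0, jitter_sigma = 0.5, seed = 6)
  s2 <- parse_structure(f2)
  r <- overlay_motifs(s, resids, s2, resids)
  va <- sidechain_vectors(s, data.frame(chain = "A", resno = q$vectors$resno))
  vb <- sidechain_vectors(s2, data.frame(chain = "A", resno = q$vectors$resno))
  expect_lt(abs(as.numeric(r) -
                quaternion_superpose_rmsd(pseudo_atoms(va), pseudo_atoms(vb))),
            1e-6)
  ## the vector-difference metric is finite and non-negative too
  rv <- overlay_motifs(s, resids, s2, resids, metric = "vector")
  expect_gte(as.numeric(rv), 0)

  ## plain atom-atom distance utility
  fi <- gen_structure(q, n_decoys = 0, seed = 1,
                      ions = data.frame(element = "MG", x = 0, y = 0, z = 0))
  si <- parse_structure(fi)
  d <- atom_distance(si, list(resid = "MG"),
                     list(chain = "A", resno = q$vectors$resno[1], elety = "CB"))
  expect_equal(d, sqrt(sum(unlist(q$vectors[1, c("bx", "by", "bz")])^2)),
               tolerance = 0.01)
})

test_that("alignment scan maps reference positions through gaps", {
  aln <- c(ref = "MKDDLDDKA", seq2 = "MKDDLDDKA", seq3 = "MKDELDDKA",
           gapped = "MK-DLDDKA")
  res <- alignment_motif_scan(aln, "ref", c(3, 4, 6, 7))
  expect_identical(res$residues, c("DDDD", "DDDD", "DEDD", "-DDD"))
  expect_identical(res$present, c(TRUE, TRUE, FALSE, FALSE))

  ## variant pattern: DEDD present where strict DDDD is absent
  res2 <- alignment_motif_scan(aln, "ref", c(3, 4, 6, 7), pattern = "DEDD")
  expect_true(res2$present[res2$id == "seq3"])
  expect_false(res2$present[res2$id == "ref"])

  ## gaps in the reference shift the column map correctly (round trip)
  aln_g <- c(ref = "MK--DDLDD", other = "MKXXDDLDD")
  resg <- alignment_motif_scan(aln_g, "ref", c(3, 4))
  expect_identical(resg$residues[resg$id == "ref"], "DD")
  ## reference ungapped position 3 is alignment column 5
  expect_identical(resg$residues[resg$id == "other"], "DD")

  expect_error(alignment_motif_scan(aln, "ref", c(3, 99)), "beyond")
  expect_error(alignment_motif_scan(aln, "nope", 3), "not found")
})
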