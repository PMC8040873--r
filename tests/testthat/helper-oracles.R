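# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the code under test.

# Horn's closed-form quaternion solution for optimal proper rotation:
# an independent check on the Kabsch/SVD superposition.
quaternion_superpose_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Yc, Xc)  # S[i,j] = sum_k Yc[k,i] * Xc[k,j]
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  # R rotates Yc row-vectors as Yc %*% t(R)
  Yr <- Yc %*% t(R)
  sqrt(mean(rowSums((Yr - Xc)^2)))
}

# Interleaved base/tip pseudo-atom matrix of a side-chain vector table
# (re-implemented here so tests do not depend on package internals).
pseudo_atoms <- function(v) {
  n <- nrow(v)
  M <- matrix(NA_real_, 2 * n, 3)
  M[seq(1, 2 * n, by = 2), ] <- as.matrix(v[, c("bx", "by", "bz")])
  M[seq(2, 2 * n, by = 2), ] <- as.matrix(v[, c("tx", "ty", "tz")])
  M
}

make_vectors <- function(bases, tips, resid = "ASP", resno = seq_len(nrow(bases))) {
  v <- data.frame(chain = "A", resno = resno, insert = "", resid = resid,
                  bx = bases[, 1], by = bases[, 2], bz = bases[, 3],
                  tx = tips[, 1], ty = tips[, 2], tz = tips[, 3])
  class(v) <- c("sidechain_vectors", "data.frame")
  v
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Brute-force motif search: enumerate every ordered type-consistent
# residue tuple with no distance pruning, superpose, keep hits <= cutoff,
# deduplicate by residue set keeping the best pairing.
brute_force_search <- function(structure, query, cutoff,
                               handedness = c("right", "left")) {
  vecs <- suppressWarnings(sidechain_vectors(structure))
  out <- list()
  for (hand in handedness) {
    qv <- query$vectors
    if (hand == "left") { qv$bx <- -qv$bx; qv$tx <- -qv$tx }
    Q <- pseudo_atoms(qv)
    nq <- nrow(qv)
    idx_by_type <- lapply(seq_len(nq), function(p) which(vecs$resid == qv$resid[p]))
    tuples <- list(integer(0))
    for (p in seq_len(nq)) {
      tuples <- do.call(c, lapply(tuples, function(tp)
        lapply(setdiff(idx_by_type[[p]], tp), function(r) c(tp, r))))
    }
    best <- list()
    for (tp in tuples) {
      C <- pseudo_atoms(vecs[tp, , drop = FALSE])
      r <- tryCatch(superpose_rmsd(Q, C)$rmsd, error = function(e) Inf)
      if (r > cutoff) next
      key <- paste(sort(tp), collapse = "-")
      if (is.null(best[[key]]) || r < best[[key]]$rmsd)
        best[[key]] <- list(set = sort(tp), rmsd = r, handedness = hand)
    }
    out <- c(out, unname(best))
  }
  out
}

# Canonical summary of a hit list for set comparison: sorted residue set
# + handedness + rounded rmsd.
hit_signature <- function(residue_df, handedness, rmsd) {
  paste(paste(sort(paste0(residue_df$chain, ":", residue_df$resno)),
              collapse = ","), handedness, sprintf("%.6f", rmsd))
}

# Damped fixed-point iteration oracle for the titration mass balance
# (damping keeps the map contractive when protein_total * K > 1).
fixed_point_free <- function(model, protein_total, L, iter = 4000,
                             damping = 0.05) {
  cf <- L
  for (i in seq_len(iter))
    cf <- (1 - damping) * cf +
      damping * pmax(L - protein_total * nu_bound(model, cf), 0)
  cf
}

# Minimal handcrafted PDB text fixtures.
pdb_line <- function(type, serial, name, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(gsub("[^A-Z]", "", name), 1, 1),
                     alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, b, element)
}

write_single_asp_pdb <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, "N",   "ASP", "A", 10, 0.0, 1.4, 0.0),
    pdb_line("ATOM", 2, "CA",  "ASP", "A", 10, 0.0, 0.0, 0.0),
    pdb_line("ATOM", 3, "C",   "ASP", "A", 10, 1.4, -0.7, 0.0),
    pdb_line("ATOM", 4, "O",   "ASP", "A", 10, 2.4, 0.0, 0.0),
    pdb_line("ATOM", 5, "CB",  "ASP", "A", 10, -1.2, -0.8, 0.0),
    pdb_line("ATOM", 6, "CG",  "ASP", "A", 10, -2.5, -0.1, 0.0),
    pdb_line("ATOM", 7, "OD1", "ASP", "A", 10, -3.3, -0.4, 0.9),
    pdb_line("ATOM", 8, "OD2", "ASP", "A", 10, -2.8, 0.8, -0.9),
    "END")
  writeLines(lines, path)
  path
}
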