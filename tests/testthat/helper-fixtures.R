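# Shared fixtures and independent oracles used across the test files.

# standard toy complex: residues at nominal distances from the duplex
toy_complex <- function(dists = c(2, 4, 6, 8, 20),
                        resn = NULL, strand = NULL, resi = NULL) {
  dup <- make_bdna_duplex()
  pl <- data.frame(
    resn = resn %||% rep_len(c("LYS", "ALA", "ASP", "SER", "ARG"),
                             length(dists)),
    dist = dists,
    strand = strand %||% rep_len(c("P", "T"), length(dists)))
  if (!is.null(resi)) pl$resi <- resi
  make_toy_complex(dup, pl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(N^2) brute-force minimum heavy-atom distance (independent of the
# vectorised implementation under test)
brute_min_dist <- function(model, chain, resi, target_chains) {
  at <- model$atoms[!(model$atoms$elem %in% c("H", "D")), ]
  res <- at[at$chain == chain & at$resi == resi, ]
  tgt <- at[at$chain %in% target_chains, ]
  best <- Inf
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(tgt))) {
    d <- sqrt((res$x[i] - tgt$x[j])^2 + (res$y[i] - tgt$y[j])^2 +
                (res$z[i] - tgt$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# brute-force contact shell from the distance oracle
brute_shell <- function(model, cutoff) {
  prot <- names(model$chain_roles)[model$chain_roles == "protein"]
  nuc <- names(model$chain_roles)[model$chain_roles == "nucleic"]
  out <- NULL
  for (ch in prot) {
    for (ri in unique(model$atoms$resi[model$atoms$chain == ch])) {
      d <- brute_min_dist(model, ch, ri, nuc)
      if (d <= cutoff)
        out <- rbind(out, data.frame(chain = ch, resi = ri, min_dist = d))
    }
  }
  if (is.null(out)) data.frame(chain = character(0), resi = integer(0),
                               min_dist = numeric(0))
  else out[order(out$chain, out$resi), ]
}

# rigid-body transform: rotate by Euler-ish angles then translate
rigid_transform <- function(model, angles = c(0.3, -1.1, 2.0),
                            shift = c(5, -7, 11)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, byrow = TRUE)
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  structure_model(at, chain_roles = model$chain_roles)
}

# independent plain-loop reference for the pairwise MM score (same physical
# conventions, none of the vectorised code)
brute_energy <- function(model, protein_chains, dna_chain, params,
                         eps0 = 4, cutoff = 12, vdw = TRUE) {
  at <- model$atoms[!(model$atoms$elem %in% c("H", "D")), ]
  q <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (at$resn[i] %in% c("DA", "DC", "DG", "DT") && at$atom[i] == "P")
      q[i] <- params$dna_phosphate_charge
  }
  for (ch in protein_chains) {
    for (ri in unique(at$resi[at$chain == ch])) {
      idx <- which(at$chain == ch & at$resi == ri)
      qc <- params$charges[at$resn[idx][1]]
      if (is.na(qc) || qc == 0) next
      cb <- idx[at$atom[idx] == "CB"]
      if (!length(cb)) cb <- idx[at$atom[idx] == "CA"]
      q[cb[1]] <- qc
    }
  }
  A <- which(at$chain %in% protein_chains)
  B <- which(at$chain == dna_chain)
  elec <- 0; lj <- 0
  for (i in A) for (j in B) {
    r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (r > cutoff || r == 0) next
    if (q[i] * q[j] != 0)
      elec <- elec + params$coulomb_k * q[i] * q[j] / (eps0 * r^2)
    if (vdw) {
      ii <- match(at$elem[i], params$vdw$elem)
      jj <- match(at$elem[j], params$vdw$elem)
      sij <- (params$vdw$sigma[ii] + params$vdw$sigma[jj]) / 2
      eij <- sqrt(params$vdw$eps[ii] * params$vdw$eps[jj])
      lj <- lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  list(E_elec = elec, E_vdW = lj, total = elec + lj)
}

# dense 2-D grid-search RSS minimiser for the hyperbola y = ymax x/(k + x)
grid_search_hyperbola <- function(x, y, k_range, ymax_range, n = 201) {
  ks <- seq(k_range[1], k_range[2], length.out = n)
  ys <- seq(ymax_range[1], ymax_range[2], length.out = n)
  best <- c(NA, NA); best_rss <- Inf
  for (k in ks) {
    pred <- outer(x / (k + x), ys)
    rss <- colSums((y - pred)^2)
    i <- which.min(rss)
    if (rss[i] < best_rss) { best_rss <- rss[i]; best <- c(k, ys[i]) }
  }
  list(k = best[1], ymax = best[2], rss = best_rss,
       cell = c(diff(ks[1:2]), diff(ys[1:2])))
}
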