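# Deterministic molecular-mechanics surrogate for protein-DNA binding
# energies, per-DNA-chain bookkeeping and mutant-WT ddG aggregation.
#
# The scorer is a single-conformation pairwise sum (screened Coulomb with a
# distance-dependent dielectric + Lennard-Jones with Lorentz-Berthelot
# mixing). It reproduces the decomposition bookkeeping of an MM-PBSA style
# workflow, not the absolute magnitudes of an MD-ensemble calculation; an
# external solver can be wired in through the `scorer` argument of
# per_chain_binding().

#' Load the molecular-mechanics parameter table
#'
#' Reads the plain-text key/value parameter file shipped with the package
#' (per-element Lennard-Jones sigma/epsilon, integer formal residue charges,
#' the Coulomb constant and the nucleotide phosphate charge).
#'
#' @param path parameter file; default the table under
#'   \code{system.file("extdata", "ff_params.txt", package = "polbind")}.
#' @return list with components \code{vdw} (data frame \code{elem},
#'   \code{sigma}, \code{eps}), \code{charges} (named numeric),
#'   \code{coulomb_k}, \code{dna_phosphate_charge}.
#' @export
load_ff_params <- function(path = system.file("extdata", "ff_params.txt",
                                              package = "polbind")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "[[:space:]]+")
  vdw <- do.call(rbind, lapply(Filter(function(t) t[1] == "vdw", tok),
                               function(t) data.frame(elem = t[2],
                                                      sigma = as.numeric(t[3]),
                                                      eps = as.numeric(t[4]))))
  ch <- Filter(function(t) t[1] == "charge", tok)
  charges <- setNames(vapply(ch, function(t) as.numeric(t[3]), numeric(1)),
                      vapply(ch, `[`, character(1), 2))
  scalar <- function(key, default) {
    hit <- Filter(function(t) t[1] == key, tok)
    if (length(hit)) as.numeric(hit[[1]][2]) else default
  }
  list(vdw = vdw, charges = charges,
       coulomb_k = scalar("coulomb_k", 332.06),
       dna_phosphate_charge = scalar("dna_phosphate_charge", -1))
}

#' Construct an energy decomposition
#'
#' @param E_elec,E_vdW,G_polar,G_nonpolar components in kcal/mol.
#' @param chain which DNA chain the score is against (\code{"P"},
#'   \code{"T"} or \code{"complex"}).
#' @return object of class \code{energy_decomposition}; \code{total} is the
#'   exact component sum (the entropy term is identically zero by
#'   construction).
#' @export
energy_decomposition <- function(E_elec, E_vdW, G_polar = 0, G_nonpolar = 0,
                                 chain = "complex") {
  structure(list(E_elec = E_elec, E_vdW = E_vdW, G_polar = G_polar,
                 G_nonpolar = G_nonpolar,
                 total = E_elec + E_vdW + G_polar + G_nonpolar,
                 chain = chain),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf(
    "energy_decomposition [%s]: total %.4f kcal/mol\n  E_elec %.4f  E_vdW %.4f  G_polar %.4f  G_nonpolar %.4f\n",
    x$chain, x$total, x$E_elec, x$E_vdW, x$G_polar, x$G_nonpolar))
  invisible(x)
}

# Per-atom partial charges under the integer-formal-charge convention:
# residue charge on CB (CA when no CB is present, e.g. Gly); DNA backbone
# charge on the P atom; everything else neutral.
.atom_charges <- function(atoms, params) {
  q <- numeric(nrow(atoms))
  role <- .residue_role(atoms$resn)
  q[role == "nucleic" & atoms$atom == "P"] <- params$dna_phosphate_charge
  prot <- which(role == "protein")
  if (length(prot)) {
    key <- paste(atoms$chain, atoms$resi, sep = "|")
    for (res in unique(key[prot])) {
      i <- prot[key[prot] == res]
      qc <- params$charges[atoms$resn[i][1L]]
      if (is.na(qc) || qc == 0) next
      at <- i[atoms$atom[i] == "CB"]
      if (!length(at)) at <- i[atoms$atom[i] == "CA"]
      if (!length(at)) at <- i[1L]
      q[at[1L]] <- qc
    }
  }
  q
}

#' Protein–DNA interaction energy of a single conformation
#'
#' Pairwise molecular-mechanics score between the protein chains and one DNA
#' chain, over heavy-atom pairs within \code{cutoff}:
#' \deqn{E_{elec} = \sum k\, q_i q_j / (\epsilon_0 r_{ij}^2)}
#' (distance-dependent dielectric \eqn{\epsilon(r) = \epsilon_0 r}), plus a
#' Lennard-Jones term \eqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12} -
#' (\sigma_{ij}/r)^6]} with Lorentz–Berthelot combination. Polar solvation is
#' 0 by default and the nonpolar term is \eqn{\gamma \times} a
#' buried-contact-area surrogate (off at \eqn{\gamma = 0}).
#'
#' @param model a \code{\link{structure_model}}.
#' @param protein_chains protein chain ids.
#' @param dna_chain one nucleic chain id (disjoint from
#'   \code{protein_chains}).
#' @param params parameter list from \code{\link{load_ff_params}}.
#' @param eps0 dielectric prefactor (default 4.0).
#' @param cutoff pair cutoff in Å (default 12; pairs beyond contribute
#'   exactly 0).
#' @param gamma nonpolar surface coefficient in kcal/mol/Å² (default 0).
#' @param vdw include the Lennard-Jones term (default TRUE).
#' @return an \code{\link{energy_decomposition}}.
#' @export
interaction_energy <- function(model, protein_chains, dna_chain,
                               params = load_ff_params(), eps0 = 4.0,
                               cutoff = 12.0, gamma = 0, vdw = TRUE) {
  if (length(dna_chain) != 1L) stop("dna_chain must be a single chain id")
  if (dna_chain %in% protein_chains)
    stop("protein and DNA chain sets overlap: ", dna_chain)
  at <- .heavy(model$atoms)
  A <- at[at$chain %in% protein_chains, , drop = FALSE]
  B <- at[at$chain == dna_chain, , drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("empty atom set for the requested chains")
  known <- params$vdw$elem
  for (set in list(A, B)) {
    bad <- setdiff(unique(set$elem), known)
    if (vdw && length(bad))
      stop("parameterization error: no vdW parameters for element(s) ",
           paste(bad, collapse = ", "))
  }
  qA <- .atom_charges(A, params)
  qB <- .atom_charges(B, params)
  d2 <- .cross_dist2(as.matrix(A[, c("x", "y", "z")]),
                     as.matrix(B[, c("x", "y", "z")]))
  within <- d2 <= cutoff^2 & d2 > 0
  # electrostatics: k q_i q_j / (eps0 r^2)
  qq <- outer(qA, qB)
  sel <- within & qq != 0
  E_elec <- if (any(sel))
    sum(params$coulomb_k * qq[sel] / (eps0 * d2[sel])) else 0
  # Lennard-Jones
  E_vdW <- 0
  G_nonpolar <- 0
  if (vdw || gamma != 0) {
    sigA <- params$vdw$sigma[match(A$elem, known)]
    epsA <- params$vdw$eps[match(A$elem, known)]
    sigB <- params$vdw$sigma[match(B$elem, known)]
    epsB <- params$vdw$eps[match(B$elem, known)]
    sij <- outer(sigA, sigB, "+") / 2
    eij <- sqrt(outer(epsA, epsB))
    if (vdw && any(within)) {
      sr6 <- (sij[within]^2 / d2[within])^3
      E_vdW <- sum(4 * eij[within] * (sr6^2 - sr6))
    }
    if (gamma != 0) {
      # crude buried-contact-area surrogate: pi*sigma_ij^2/4 per close pair
      close <- d2 <= 4.5^2 & d2 > 0
      G_nonpolar <- gamma * sum(pi * sij[close]^2 / 4)
    }
  }
  energy_decomposition(E_elec, E_vdW, 0, G_nonpolar, chain = dna_chain)
}

#' Per-DNA-chain binding energies of a variant
#'
#' Scores the protein against the primer (P) and template (T) strands
#' separately, optionally after applying a mutation to the model in coarse
#' mode (residue relabelled, side chain truncated at Cβ, new formal charge
#' applied there).
#'
#' @param model a \code{\link{structure_model}} whose two nucleic chains are
#'   (or map to) P and T.
#' @param mutant optional \code{\link{mutation_spec}} applied via
#'   \code{\link{relabel_mutant}}.
#' @param params,scorer scoring parameters and a plug-in scorer with the
#'   signature \code{function(model, protein_chains, dna_chain, params, ...)}
#'   returning an \code{\link{energy_decomposition}}
#'   (default \code{\link{interaction_energy}}).
#' @param chain_map named character vector mapping \code{c(P = , T = )} to
#'   the model's nucleic chain ids.
#' @param ... passed to the scorer.
#' @return named numeric vector \code{c(P = , T = )} of ΔG totals (kcal/mol),
#'   with the full decompositions in \code{attr(, "decomposition")}.
#' @export
per_chain_binding <- function(model, mutant = NULL, params = load_ff_params(),
                              scorer = interaction_energy,
                              chain_map = c(P = "P", T = "T"), ...) {
  nuc <- .chains_by_role(model, "nucleic")
  if (!all(chain_map %in% nuc))
    stop("cannot identify the P and T DNA strands: nucleic chains are ",
         paste(nuc, collapse = ", "))
  if (!is.null(mutant)) model <- relabel_mutant(model, mutant)
  prot <- .chains_by_role(model, "protein")
  if (length(prot) == 0L) stop("model has no protein chain")
  dec <- lapply(chain_map, function(ch) scorer(model, prot, ch, params, ...))
  out <- vapply(dec, `[[`, numeric(1), "total")
  names(out) <- names(chain_map)
  attr(out, "decomposition") <- setNames(dec, names(chain_map))
  out
}

#' Coarse in-place mutant model
#'
#' Applies a \code{\link{mutation_spec}} to a structure at the residue-label
#' level: the residue name is replaced by the new amino acid and side-chain
#' atoms beyond Cβ are dropped (Cβ itself is dropped for a glycine target).
#' No side-chain rebuilding is attempted; the coarse energy mode scores the
#' new formal charge at the retained Cβ/Cα position.
#'
#' @param model a \code{\link{structure_model}}.
#' @param spec a \code{\link{mutation_spec}} in the protein chain's residue
#'   numbering.
#' @param chain protein chain to mutate; default the first protein chain.
#' @return the mutated \code{structure_model}.
#' @export
relabel_mutant <- function(model, spec, chain = NULL) {
  chain <- chain %||% .chains_by_role(model, "protein")[1L]
  at <- model$atoms
  backbone <- c("N", "CA", "C", "O", "CB")
  drop <- logical(nrow(at))
  for (k in seq_along(spec$pos)) {
    i <- which(at$chain == chain & at$resi == spec$pos[k])
    if (!length(i)) stop("residue ", spec$pos[k], " not found in chain ", chain)
    wt3 <- at$resn[i][1L]
    wt1 <- bio3d::aa321(wt3)
    if (!identical(wt1, spec$wt[k]))
      stop("wt mismatch at position ", spec$pos[k], ": structure has ", wt1,
           ", spec says ", spec$wt[k])
    new3 <- bio3d::aa123(spec$new[k])
    at$resn[i] <- new3
    drop[i[!(at$atom[i] %in% backbone)]] <- TRUE
    if (new3 == "GLY") drop[i[at$atom[i] == "CB"]] <- TRUE
  }
  structure_model(at[!drop, , drop = FALSE], chain_roles = model$chain_roles)
}

#' Aggregate a mutant−WT binding-energy difference
#'
#' \deqn{\Delta\Delta G = \sum_{c \in \{P,T\}} (\Delta G_{mut,c} -
#' \Delta G_{wt,c})}
#' Negative values indicate strengthened binding.
#'
#' @param wt,mut named numeric vectors with components \code{P} and \code{T}
#'   (kcal/mol).
#' @param label mutant label.
#' @return object of class \code{ddg_record} with fields \code{label},
#'   \code{wt}, \code{mut}, \code{ddg}.
#' @export
aggregate_ddg <- function(wt, mut, label) {
  for (v in list(wt, mut))
    if (!all(c("P", "T") %in% names(v)))
      stop("per-chain mapping must have both P and T components")
  ddg <- sum(mut[c("P", "T")] - wt[c("P", "T")])
  structure(list(label = label, wt = wt[c("P", "T")], mut = mut[c("P", "T")],
                 ddg = unname(ddg)),
            class = "ddg_record")
}

#' @export
print.ddg_record <- function(x, ...) {
  cat(sprintf("ddg_record %s: ddG = %+.2f kcal/mol (P %+.2f, T %+.2f)\n",
              x$label, x$ddg, x$mut["P"] - x$wt["P"], x$mut["T"] - x$wt["T"]))
  invisible(x)
}

#' Rank mutants by binding-energy change
#'
#' Ascending ΔΔG (most strengthening first), ties broken by label.
#'
#' @param records list of \code{ddg_record}s.
#' @return the reordered list, with a summary data frame in
#'   \code{attr(, "summary")}.
#' @export
rank_mutants <- function(records) {
  ddg <- vapply(records, `[[`, numeric(1), "ddg")
  lab <- vapply(records, `[[`, character(1), "label")
  ord <- order(ddg, lab)
  out <- records[ord]
  attr(out, "summary") <- data.frame(label = lab[ord], ddg = ddg[ord],
                                     stringsAsFactors = FALSE)
  out
}
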