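# Structure models and the DNA contact shell.

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","SEC","PYL")
.NUC <- c("DA","DC","DG","DT","DU","DI","A","C","G","U","I")
.WATER <- c("HOH","WAT","DOD","H2O")

.residue_role <- function(resn) {
  ifelse(resn %in% .AA3, "protein", ifelse(resn %in% .NUC, "nucleic", "other"))
}

#' Construct a structure model
#'
#' A light container for an atomic model of a protein–DNA complex: a table of
#' atoms and a per-chain role (\code{protein}, \code{nucleic} or \code{other}).
#' Roles are inferred from the residue-name vocabulary (standard amino acids
#' vs. deoxy/ribo nucleotides) by per-chain majority vote; ties give
#' \code{other}.
#'
#' @param atoms data frame with columns \code{chain}, \code{resi} (integer),
#'   \code{resn}, \code{atom}, \code{elem}, \code{x}, \code{y}, \code{z} (Å).
#' @param chain_roles optional named character vector chain id → role,
#'   overriding the vocabulary inference.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, chain_roles = NULL) {
  need <- c("chain", "resi", "resn", "atom", "elem", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resi <- as.integer(atoms$resi)
  atoms$resn <- toupper(as.character(atoms$resn))
  atoms$atom <- as.character(atoms$atom)
  atoms$elem <- toupper(as.character(atoms$elem))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure model")
  # residue indices must be non-decreasing in file order within a chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resi[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices not sorted within chain ", ch)
  }
  if (is.null(chain_roles)) {
    chain_roles <- vapply(split(atoms$resn, atoms$chain), function(resn) {
      roles <- .residue_role(unique(resn))
      tab <- sort(table(roles), decreasing = TRUE)
      if (length(tab) > 1L && tab[1L] == tab[2L]) "other" else names(tab)[1L]
    }, character(1))
  } else {
    chain_roles <- chain_roles[unique(atoms$chain)]
    names(chain_roles) <- unique(atoms$chain)
  }
  structure(list(atoms = atoms, chain_roles = chain_roles),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(x$chain_roles), "chains\n")
  for (ch in names(x$chain_roles)) {
    n <- sum(x$atoms$chain == ch)
    cat(sprintf("  chain %s (%s): %d atoms, %d residues\n", ch,
                x$chain_roles[ch], n,
                length(unique(x$atoms$resi[x$atoms$chain == ch]))))
  }
  invisible(x)
}

.infer_element <- function(elety) {
  # fall back for files without an element column: strip digits/primes,
  # take the leading letter(s) of the atom name
  e <- gsub("[0-9']", "", toupper(elety))
  two <- substr(e, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
         two, substr(e, 1, 1))
}

#' Read a protein–DNA complex structure
#'
#' Parses PDB or mmCIF coordinates (via \pkg{bio3d}) into a
#' \code{\link{structure_model}}. Waters are excluded; for alternate
#' locations the highest-occupancy conformer is kept (ties broken
#' alphabetically by altloc id).
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"mmcif"}.
#' @return A \code{structure_model}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- obj$atom
  at <- at[!(toupper(at$resid) %in% .WATER), , drop = FALSE]
  if (nrow(at) == 0L) stop("no non-water atoms in ", path)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  # altloc: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "|")), ,
             drop = FALSE]
    at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- .infer_element(at$elety)
  else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- .infer_element(at$elety[miss])
  }
  structure_model(data.frame(
    chain = at$chain, resi = at$resno, resn = at$resid, atom = at$elety,
    elem = elem, x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write a structure model as a PDB file
#'
#' @param model a \code{structure_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resi, resid = at$resn, chain = at$chain,
                   elety = at$atom, elesy = at$elem,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

.chains_by_role <- function(model, role) {
  names(model$chain_roles)[model$chain_roles == role]
}

.heavy <- function(atoms) atoms[!(atoms$elem %in% c("H", "D")), , drop = FALSE]

# squared-distance cross matrix between two coordinate matrices
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

#' Minimum heavy-atom distance from a residue to target chains
#'
#' @param model a \code{structure_model}.
#' @param chain,resi residue identifier.
#' @param target_chains chain ids whose atoms define the target set.
#' @return minimum Euclidean heavy-atom distance, in Å.
#' @export
min_residue_distance <- function(model, chain, resi, target_chains) {
  at <- model$atoms
  res <- .heavy(at[at$chain == chain & at$resi == resi, , drop = FALSE])
  if (nrow(res) == 0L)
    stop("residue ", chain, ":", resi, " not found (or has no heavy atoms)")
  if (length(target_chains) == 0L) stop("target chain set is empty")
  tgt <- .heavy(at[at$chain %in% target_chains, , drop = FALSE])
  if (nrow(tgt) == 0L) stop("no heavy atoms in target chains")
  sqrt(min(.cross_dist2(as.matrix(res[, c("x", "y", "z")]),
                        as.matrix(tgt[, c("x", "y", "z")]))))
}

#' DNA contact shell of a protein–DNA complex
#'
#' Returns every protein residue whose minimum heavy-atom distance to any
#' nucleic-chain heavy atom is at or below \code{cutoff} (inclusive). Residues
#' within ~6 Å of the duplex are the conventional pol/DNA interaction shell.
#'
#' @param model a \code{structure_model} with at least one protein and one
#'   nucleic chain.
#' @param cutoff shell radius in Å (default 6.0, compared inclusively).
#' @param target_chains nucleic chains defining the DNA; default all of them.
#' @return A data frame of class \code{contact_shell} with columns
#'   \code{chain}, \code{resi}, \code{resn}, \code{min_dist}, sorted by
#'   (chain, resi); the cutoff is kept in \code{attr(, "cutoff")}.
#' @export
contact_shell <- function(model, cutoff = 6.0, target_chains = NULL) {
  prot <- .chains_by_role(model, "protein")
  nuc <- .chains_by_role(model, "nucleic")
  if (length(prot) == 0L) stop("model has no protein chain")
  if (length(nuc) == 0L) stop("model has no nucleic chain")
  target_chains <- target_chains %||% nuc
  if (!all(target_chains %in% nuc))
    stop("target_chains must be nucleic chains")
  at <- .heavy(model$atoms)
  pa <- at[at$chain %in% prot, , drop = FALSE]
  da <- at[at$chain %in% target_chains, , drop = FALSE]
  d2 <- .cross_dist2(as.matrix(pa[, c("x", "y", "z")]),
                     as.matrix(da[, c("x", "y", "z")]))
  mind <- sqrt(tapply(apply(d2, 1L, min),
                      paste(pa$chain, pa$resi, sep = "|"), min))
  key <- do.call(rbind, strsplit(names(mind), "|", fixed = TRUE))
  shell <- data.frame(chain = key[, 1L], resi = as.integer(key[, 2L]),
                      min_dist = as.numeric(mind), stringsAsFactors = FALSE)
  rn <- unique(pa[, c("chain", "resi", "resn")])
  shell <- merge(shell, rn, by = c("chain", "resi"), sort = FALSE)
  shell <- shell[shell$min_dist <= cutoff, c("chain", "resi", "resn", "min_dist")]
  shell <- shell[order(shell$chain, shell$resi), , drop = FALSE]
  rownames(shell) <- NULL
  attr(shell, "cutoff") <- cutoff
  class(shell) <- c("contact_shell", "data.frame")
  shell
}

#' Write / read a contact shell as TSV
#'
#' Columns: \code{chain}, \code{resi}, \code{resn}, \code{min_dist_A}.
#' @param shell a \code{contact_shell}.
#' @param path file path.
#' @return \code{path} / a \code{contact_shell}.
#' @export
write_contact_shell <- function(shell, path) {
  out <- as.data.frame(shell)
  names(out)[names(out) == "min_dist"] <- "min_dist_A"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_shell
#' @param cutoff cutoff to record on the re-read shell.
#' @export
read_contact_shell <- function(path, cutoff = NA_real_) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "min_dist_A"] <- "min_dist"
  attr(x, "cutoff") <- cutoff
  class(x) <- c("contact_shell", "data.frame")
  x
}
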