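# Alignment handling, conservation classification, substitution frequencies.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an alignment object
#'
#' @param seqs named character vector of aligned sequences (residues +
#'   \code{"-"} gaps), all the same length.
#' @param ref_id name of the designated reference sequence.
#' @return An object of class \code{msa_alignment}.
#' @export
msa_alignment <- function(seqs, ref_id) {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("ragged alignment: sequence lengths differ")
  bad <- grepl(paste0("[^", paste(.AA1, collapse = ""), "-]"), seqs)
  if (any(bad))
    stop("alphabet error: sequence(s) ", paste(names(seqs)[bad], collapse = ", "),
         " contain characters outside the 20 amino acids + gap")
  if (!ref_id %in% names(seqs))
    stop("reference id '", ref_id, "' not present in alignment")
  structure(list(seqs = seqs, ref_id = ref_id, width = len),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("msa_alignment:", length(x$seqs), "sequences x", x$width,
      "columns; reference:", x$ref_id, "\n")
  invisible(x)
}

#' Read / write an aligned FASTA file
#'
#' @param path aligned FASTA path.
#' @param ref_id reference sequence id (must be present).
#' @return \code{read_alignment}: an \code{msa_alignment};
#'   \code{write_alignment}: \code{path}, invisibly.
#' @export
read_alignment <- function(path, ref_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty FASTA file")
  fa <- tryCatch(bio3d::read.fasta(path, rm.dup = FALSE),
                 error = function(e) stop("format error reading '", path,
                                          "': ", conditionMessage(e)))
  seqs <- apply(fa$ali, 1L, paste, collapse = "")
  names(seqs) <- rownames(fa$ali)
  msa_alignment(seqs, ref_id)
}

#' @rdname read_alignment
#' @param aln an \code{msa_alignment}.
#' @export
write_alignment <- function(aln, path) {
  bio3d::write.fasta(seqs = do.call(rbind, strsplit(aln$seqs, "")),
                     ids = names(aln$seqs), file = path)
  invisible(path)
}

#' Pairwise identity between two aligned sequences
#'
#' Fraction of matching residues over columns where neither sequence has a
#' gap; 0 when no such column exists.
#'
#' @param a,b aligned sequences of equal length (strings).
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  keep <- av != "-" & bv != "-"
  if (!any(keep)) return(0)
  sum(av[keep] == bv[keep]) / sum(keep)
}

#' Keep homologs above an identity threshold to the reference
#'
#' Retains the reference plus every record whose pairwise identity to the
#' reference is strictly greater than \code{min_identity}.
#'
#' @param aln an \code{msa_alignment}.
#' @param min_identity identity threshold (default 0.40, strict \code{>}).
#' @return A filtered \code{msa_alignment}.
#' @export
filter_homologs <- function(aln, min_identity = 0.40) {
  ref <- aln$seqs[[aln$ref_id]]
  keep <- vapply(aln$seqs, function(s) pairwise_identity(s, ref),
                 numeric(1)) > min_identity
  keep[aln$ref_id] <- TRUE
  msa_alignment(aln$seqs[keep], aln$ref_id)
}

#' Per-position residue profiles over the ungapped reference
#'
#' One profile per ungapped reference position: the reference residue, the
#' residue counts among the non-reference sequences at that alignment column,
#' and the gap count. Columns where the reference is gapped produce no
#' profile.
#'
#' @param aln an \code{msa_alignment}.
#' @return A list of \code{column_profile} objects (each with fields
#'   \code{position}, \code{ref_aa}, \code{counts}, \code{gap_count},
#'   \code{n_other}).
#' @export
column_profiles <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(mat) <- names(aln$seqs)
  ref <- mat[aln$ref_id, ]
  oth <- mat[rownames(mat) != aln$ref_id, , drop = FALSE]
  cols <- which(ref != "-")
  if (length(cols) == 0L) stop("reference sequence is all gaps")
  lapply(seq_along(cols), function(i) {
    col <- oth[, cols[i]]
    gaps <- sum(col == "-")
    res <- col[col != "-"]
    counts <- if (length(res)) table(res) else integer(0)
    counts <- setNames(as.integer(counts), names(counts))
    structure(list(position = i, ref_aa = unname(ref[cols[i]]),
                   counts = counts, gap_count = gaps, n_other = nrow(oth)),
              class = "column_profile")
  })
}

#' @export
print.column_profile <- function(x, ...) {
  subs <- ranked_substitutions(x)
  cat(sprintf("position %d (%s): %s; gaps %d\n", x$position, x$ref_aa,
              if (nrow(subs)) paste(subs$residue, subs$count, sep = "/",
                                    collapse = ", ") else "-",
              x$gap_count))
  invisible(x)
}

#' Classify a position as conserved or non-conserved
#'
#' A position is conserved when the fraction of non-reference, non-gap
#' residues that differ from the reference residue is at most
#' \code{max_nonref_frac}. All-gap columns carry no evidence of variation and
#' are classified conserved.
#'
#' @param profile a \code{column_profile}.
#' @param max_nonref_frac tolerated differing fraction (default 0.05).
#' @return logical: \code{TRUE} if conserved.
#' @export
classify_conservation <- function(profile, max_nonref_frac = 0.05) {
  nongap <- sum(profile$counts)
  if (nongap == 0L) return(TRUE)
  differing <- nongap - sum(profile$counts[profile$ref_aa], na.rm = TRUE)
  (differing / nongap) <= max_nonref_frac
}

#' Ranked substitutions at a position
#'
#' Non-reference residues observed among homologs, sorted by count
#' (descending, ties alphabetical). The reference residue is never listed.
#'
#' @param profile a \code{column_profile}.
#' @return data frame with columns \code{residue}, \code{count} (possibly
#'   zero rows).
#' @export
ranked_substitutions <- function(profile) {
  counts <- profile$counts
  counts <- counts[names(counts) != profile$ref_aa & counts > 0L]
  if (length(counts) == 0L)
    return(data.frame(residue = character(0), count = integer(0)))
  ord <- order(-counts, names(counts))
  data.frame(residue = names(counts)[ord], count = unname(counts[ord]),
             stringsAsFactors = FALSE)
}

# "R/25, I/1, V/2" rendering used in the candidate table TSV
.subs_text <- function(subs) {
  if (nrow(subs) == 0L) return("")
  paste(subs$residue, subs$count, sep = "/", collapse = ", ")
}

#' Reference sequence reconstructed from profiles
#'
#' @param profiles list of \code{column_profile}s.
#' @return the ungapped reference sequence as a string.
#' @export
profiles_reference <- function(profiles) {
  paste(vapply(profiles, `[[`, character(1), "ref_aa"), collapse = "")
}
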