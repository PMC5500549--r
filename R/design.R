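# Candidate-site intersection, block candidates, mutation and fusion building.

#' Construct a mutation specification
#'
#' A set of single-site substitutions in reference (1-based) coordinates.
#'
#' @param pos integer positions (unique, ascending).
#' @param wt wild-type residues (1-letter) at those positions.
#' @param new replacement residues (1-letter).
#' @param label display label; derived from the substitutions when omitted
#'   (\code{"M76I"} for a point mutant, \code{"KSKIP(241-245)RVRKS"} for a
#'   contiguous block).
#' @param reference optional reference sequence; when given, \code{wt} is
#'   validated against it.
#' @return An object of class \code{mutation_spec}.
#' @export
mutation_spec <- function(pos, wt, new, label = NULL, reference = NULL) {
  pos <- as.integer(pos)
  if (length(pos) != length(wt) || length(pos) != length(new))
    stop("pos, wt and new must have equal length")
  if (anyDuplicated(pos) || is.unsorted(pos, strictly = TRUE))
    stop("positions must be unique and ascending")
  wt <- toupper(wt); new <- toupper(new)
  if (!is.null(reference)) {
    refv <- strsplit(reference, "")[[1]]
    bad <- which(refv[pos] != wt)
    if (length(bad))
      stop("wt mismatch at position ", pos[bad[1L]], ": reference has ",
           refv[pos[bad[1L]]], ", spec says ", wt[bad[1L]])
  }
  if (is.null(label)) {
    label <- if (length(pos) > 1L && all(diff(pos) == 1L))
      sprintf("%s(%d-%d)%s", paste(wt, collapse = ""), pos[1L],
              pos[length(pos)], paste(new, collapse = ""))
    else paste0(wt, pos, new, collapse = "+")
  }
  structure(list(pos = pos, wt = wt, new = new, label = label),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation_spec:", x$label, sprintf("(%d substitution%s)\n",
      length(x$pos), if (length(x$pos) == 1L) "" else "s"))
  invisible(x)
}

#' Parse a mutation label
#'
#' Accepts point-mutant labels (\code{"M76I"}, possibly joined by \code{+})
#' and block labels (\code{"KSKIP(241-245)RVRKS"}; an en dash is accepted in
#' place of the hyphen).
#'
#' @param label label text.
#' @return A \code{mutation_spec}.
#' @export
parse_mutation_label <- function(label) {
  x <- gsub("\u2013", "-", trimws(label))  # en dash tolerated on input
  m <- regmatches(x, regexec("^([A-Z]+)\\((\\d+)-(\\d+)\\)([A-Z]+)$", x))[[1]]
  if (length(m) == 5L) {
    from <- as.integer(m[3L]); to <- as.integer(m[4L])
    wt <- strsplit(m[2L], "")[[1]]; new <- strsplit(m[5L], "")[[1]]
    if (to - from + 1L != length(wt) || length(wt) != length(new))
      stop("block label '", label, "': run length does not match residues")
    return(mutation_spec(from:to, wt, new, label = x))
  }
  parts <- strsplit(x, "+", fixed = TRUE)[[1]]
  mm <- regmatches(parts, regexec("^([A-Z])(\\d+)([A-Z])$", parts))
  if (any(lengths(mm) != 4L)) stop("cannot parse mutation label '", label, "'")
  mm <- do.call(rbind, mm)
  mutation_spec(as.integer(mm[, 3L]), mm[, 2L], mm[, 4L], label = x)
}

#' Intersect the contact shell with non-conserved positions
#'
#' The candidate mutation sites are exactly the reference positions that are
#' (a) in the DNA contact shell and (b) non-conserved in the homolog
#' alignment. Each candidate carries its ranked substitutions and its minimum
#' DNA distance.
#'
#' @param shell a \code{\link{contact_shell}}.
#' @param profiles list of \code{column_profile}s in reference coordinates.
#' @param max_nonref_frac conservation threshold passed to
#'   \code{\link{classify_conservation}}.
#' @param mapping optional named integer vector mapping structure residue
#'   numbers to reference positions (names = structure \code{resi});
#'   identity by default.
#' @return A data frame of class \code{candidate_table} with columns
#'   \code{position}, \code{wt}, \code{top_sub}, \code{top_count},
#'   \code{subs_txt}, \code{min_dist}, plus a list column \code{subs} of
#'   ranked-substitution data frames.
#' @export
candidate_sites <- function(shell, profiles, max_nonref_frac = 0.05,
                            mapping = NULL) {
  positions <- vapply(profiles, `[[`, integer(1), "position")
  shell_pos <- shell$resi
  if (!is.null(mapping)) {
    hit <- match(as.character(shell_pos), names(mapping))
    if (anyNA(hit))
      stop("mapping error: structure residue(s) ",
           paste(shell_pos[is.na(hit)], collapse = ", "),
           " absent from the numbering map")
    shell_pos <- as.integer(mapping[hit])
  }
  miss <- setdiff(shell_pos, positions)
  if (length(miss))
    stop("mapping error: shell position(s) ", paste(miss, collapse = ", "),
         " absent from the alignment profiles")
  idx <- match(shell_pos, positions)
  keep <- !vapply(profiles[idx], classify_conservation, logical(1),
                  max_nonref_frac = max_nonref_frac)
  rows <- order(shell_pos[keep])
  pos <- shell_pos[keep][rows]
  prof <- profiles[idx[keep]][rows]
  subs <- lapply(prof, ranked_substitutions)
  out <- data.frame(
    position = pos,
    wt = vapply(prof, `[[`, character(1), "ref_aa"),
    top_sub = vapply(subs, function(s) if (nrow(s)) s$residue[1L] else NA_character_,
                     character(1)),
    top_count = vapply(subs, function(s) if (nrow(s)) s$count[1L] else 0L,
                       integer(1)),
    subs_txt = vapply(subs, .subs_text, character(1)),
    min_dist = shell$min_dist[keep][rows],
    stringsAsFactors = FALSE)
  out$subs <- subs
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  cols <- c("position", "wt", "top_sub", "top_count", "subs_txt", "min_dist")
  print(as.data.frame(x)[, cols], ...)
  invisible(x)
}

#' Write a candidate table as TSV
#'
#' Columns mirror the frequency-table layout: position, wild-type residue,
#' ranked \code{"AA/count"} substitutions, minimum DNA distance.
#' @param table a \code{candidate_table}.
#' @param path file path.
#' @export
write_candidates <- function(table, path) {
  out <- as.data.frame(table)[, c("position", "wt", "subs_txt", "min_dist")]
  names(out) <- c("position", "wt_aa", "substitutions", "min_dist_A")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contiguous-block mutation candidates
#'
#' Finds maximal runs of consecutive candidate positions of at least
#' \code{min_run} residues and emits each as one block
#' \code{\link{mutation_spec}} whose replacements are the per-position top
#' substitutions.
#'
#' @param table a \code{candidate_table} (sorted by position).
#' @param min_run minimum run length (default 2).
#' @return list of \code{mutation_spec}s (possibly empty).
#' @export
block_candidates <- function(table, min_run = 2L) {
  if (nrow(table) == 0L) return(list())
  pos <- table$position
  if (is.unsorted(pos, strictly = TRUE)) stop("candidate table must be sorted")
  runs <- split(seq_along(pos), cumsum(c(1L, diff(pos) != 1L)))
  runs <- Filter(function(i) length(i) >= min_run, runs)
  unname(lapply(runs, function(i)
    mutation_spec(pos[i], table$wt[i], table$top_sub[i])))
}

#' Apply substitutions to a reference sequence
#'
#' @param sequence reference amino-acid sequence (string).
#' @param spec a \code{mutation_spec}; every \code{wt} residue must match
#'   the sequence (guards against coordinate drift).
#' @return the mutated sequence (same length).
#' @export
apply_mutations <- function(sequence, spec) {
  v <- strsplit(sequence, "")[[1]]
  if (length(spec$pos) == 0L) return(sequence)
  if (any(spec$pos > length(v)))
    stop("position ", max(spec$pos), " beyond sequence length ", length(v))
  bad <- which(v[spec$pos] != spec$wt)
  if (length(bad))
    stop("wt mismatch at position ", spec$pos[bad[1L]], ": sequence has ",
         v[spec$pos[bad[1L]]], ", spec says ", spec$wt[bad[1L]])
  v[spec$pos] <- spec$new
  paste(v, collapse = "")
}

#' Build a linker fusion construct
#'
#' Expands linker notation of the form \code{PREFIX(UNIT)_k_SUFFIX} (e.g.
#' \code{"SS(GGGGS)_3_GM"}; a plain residue string is also accepted) and
#' concatenates N-terminal domain + linker + C-terminal domain.
#'
#' @param n_domain N-terminal domain sequence.
#' @param linker linker notation or plain sequence.
#' @param c_domain C-terminal domain sequence.
#' @return An object of class \code{fusion_design} with fields
#'   \code{n_domain}, \code{linker_notation}, \code{linker},
#'   \code{c_domain}, \code{fused}.
#' @export
build_fusion <- function(n_domain, linker, c_domain) {
  m <- regmatches(linker,
                  regexec("^([A-Z]*)\\(([A-Z]+)\\)_(\\d+)_([A-Z]*)$", linker))[[1]]
  if (length(m) == 5L) {
    expanded <- paste0(m[2L], strrep(m[3L], as.integer(m[4L])), m[5L])
  } else if (grepl("^[A-Z]*$", linker)) {
    expanded <- linker
  } else stop("malformed linker notation: '", linker, "'")
  structure(list(n_domain = n_domain, linker_notation = linker,
                 linker = expanded, c_domain = c_domain,
                 fused = paste0(n_domain, expanded, c_domain)),
            class = "fusion_design")
}

#' @export
print.fusion_design <- function(x, ...) {
  cat(sprintf("fusion_design: %d aa = N(%d) + linker %s (%d aa) + C(%d)\n",
              nchar(x$fused), nchar(x$n_domain), x$linker_notation,
              nchar(x$linker), nchar(x$c_domain)))
  invisible(x)
}
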