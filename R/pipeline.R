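# End-to-end orchestration: design runs with manifests, and report tables
# with recomputed derived columns.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.manifest <- function(command, params, inputs, outputs = character(0),
                      seed = NA_integer_) {
  hashes <- vapply(inputs, function(p)
    if (is.character(p) && length(p) == 1L && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_, character(1))
  list(command = command, params = params, seed = seed,
       inputs = inputs, input_md5 = hashes,
       package_version = as.character(utils::packageVersion("polbind")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

#' Run the mutation-design pipeline
#'
#' Composes the design stages: contact shell of the structure → column
#' profiles of the (identity-filtered) alignment → candidate sites → block
#' candidates, and returns them with a run manifest (inputs, md5 hashes,
#' parameters, package version).
#'
#' @param structure a \code{\link{structure_model}} or a PDB/mmCIF path.
#' @param alignment an \code{msa_alignment} or an aligned FASTA path.
#' @param ref_id reference id (required when \code{alignment} is a path).
#' @param cutoff contact-shell cutoff (Å).
#' @param min_identity homolog identity threshold (strict \code{>}).
#' @param max_nonref_frac conservation threshold.
#' @param min_run minimum block run length.
#' @param mapping optional structure→reference numbering map (see
#'   \code{\link{candidate_sites}}).
#' @return list with \code{shell}, \code{profiles}, \code{candidates},
#'   \code{blocks}, \code{manifest}.
#' @export
run_design <- function(structure, alignment, ref_id = NULL, cutoff = 6.0,
                       min_identity = 0.40, max_nonref_frac = 0.05,
                       min_run = 2L, mapping = NULL) {
  inputs <- list()
  if (is.character(structure)) {
    inputs$structure <- structure
    structure <- .stage("read_structure", read_structure(structure))
  }
  if (is.character(alignment)) {
    inputs$alignment <- alignment
    if (is.null(ref_id)) stop("ref_id is required when alignment is a path")
    alignment <- .stage("read_alignment", read_alignment(alignment, ref_id))
  }
  shell <- .stage("contact_shell", contact_shell(structure, cutoff = cutoff))
  aln <- .stage("filter_homologs",
                filter_homologs(alignment, min_identity = min_identity))
  profiles <- .stage("column_profiles", column_profiles(aln))
  candidates <- .stage("candidate_sites",
                       candidate_sites(shell, profiles,
                                       max_nonref_frac = max_nonref_frac,
                                       mapping = mapping))
  blocks <- .stage("block_candidates",
                   block_candidates(candidates, min_run = min_run))
  list(shell = shell, profiles = profiles, candidates = candidates,
       blocks = blocks,
       manifest = .manifest("design",
                            params = list(cutoff = cutoff,
                                          min_identity = min_identity,
                                          max_nonref_frac = max_nonref_frac,
                                          min_run = min_run),
                            inputs = inputs))
}

#' Regenerate the derived columns of the binding-energy and kinetics tables
#'
#' Recomputes, never hand-enters, the derived quantities of the two summary
#' tables: the per-mutant ΔΔG (mutant − WT, summed over the P and T chains)
#' from per-chain binding energies, and the catalytic-efficiency column
#' (\eqn{V_{max}/K_m}, \eqn{K_m} in mM, 2 significant figures) from the
#' kinetic parameters — flagging any printed value that disagrees with its
#' own row's parameters.
#'
#' @param energies data frame with columns \code{label}, \code{chain}
#'   (\code{P}/\code{T}), \code{dG_bind} (kcal/mol) and optionally
#'   \code{ddg_printed}; the WT rows carry \code{label == wt_label}.
#' @param kinetics data frame with columns \code{variant},
#'   \code{template_base}, \code{dntp}, \code{km}, \code{vmax} and
#'   optionally \code{eff_printed}.
#' @param wt_label label of the wild-type rows in \code{energies}
#'   (default \code{"WTDbh"}).
#' @param baseline variant against which V_max fold changes are computed
#'   (default \code{"Dbh"}).
#' @param ddg_tol printed-vs-computed ΔΔG tolerance in kcal/mol
#'   (default 0.05, half a unit in the last printed decimal).
#' @return list of data frames: \code{ddg} (label, per-chain ΔG, computed
#'   ΔΔG, printed value, flag), \code{efficiency} (per condition, computed
#'   vs printed, flag), \code{folds} (V_max fold change of every variant
#'   vs the baseline per condition) and \code{misinsertion}
#'   (dATP/dCTP efficiency ratio per variant and template base).
#' @export
run_report <- function(energies = NULL, kinetics = NULL, wt_label = "WTDbh",
                       baseline = "Dbh", ddg_tol = 0.05) {
  out <- list()
  if (!is.null(energies)) {
    energies <- as.data.frame(energies)
    need <- c("label", "chain", "dG_bind")
    if (!all(need %in% names(energies)))
      stop("schema error: energies needs columns ",
           paste(need, collapse = ", "))
    if (nrow(energies) == 0L) {
      out$ddg <- data.frame(label = character(0), dG_P = numeric(0),
                            dG_T = numeric(0), ddg = numeric(0),
                            ddg_printed = numeric(0), flag = character(0))
    } else {
      grab <- function(lab) {
        rows <- energies[energies$label == lab, ]
        setNames(rows$dG_bind, rows$chain)
      }
      wt <- grab(wt_label)
      labs <- setdiff(unique(energies$label), wt_label)
      recs <- lapply(labs, function(l) aggregate_ddg(wt, grab(l), l))
      printed <- if ("ddg_printed" %in% names(energies))
        vapply(labs, function(l)
          energies$ddg_printed[energies$label == l][1L], numeric(1))
      else rep(NA_real_, length(labs))
      ddg <- vapply(recs, `[[`, numeric(1), "ddg")
      out$ddg <- data.frame(
        label = labs,
        dG_P = vapply(recs, function(r) unname(r$mut["P"]), numeric(1)),
        dG_T = vapply(recs, function(r) unname(r$mut["T"]), numeric(1)),
        ddg = ddg, ddg_printed = printed,
        flag = ifelse(!is.na(printed) & abs(ddg - printed) > ddg_tol,
                      "printed ddG inconsistent with per-chain values", ""),
        stringsAsFactors = FALSE)
      out$ddg <- out$ddg[order(out$ddg$ddg), ]
      rownames(out$ddg) <- NULL
    }
  }
  if (!is.null(kinetics)) {
    kin <- as.data.frame(kinetics)
    need <- c("variant", "template_base", "dntp", "km", "vmax")
    if (!all(need %in% names(kin)))
      stop("schema error: kinetics needs columns ", paste(need, collapse = ", "))
    if (!"eff_printed" %in% names(kin)) kin$eff_printed <- NA_real_
    eff <- kin$vmax / (kin$km / 1000)
    out$efficiency <- data.frame(
      kin[, c("variant", "template_base", "dntp", "km", "vmax")],
      eff = eff, eff_2sf = signif(eff, 2), eff_printed = kin$eff_printed,
      flag = ifelse(!is.na(kin$eff_printed) &
                      signif(eff, 2) != kin$eff_printed,
                    "printed efficiency inconsistent with row parameters", ""),
      stringsAsFactors = FALSE)
    if (nrow(kin)) {
      fits <- lapply(seq_len(nrow(kin)), function(i)
        mm_params(kin$km[i], kin$vmax[i], variant = kin$variant[i],
                  template_base = kin$template_base[i], dntp = kin$dntp[i]))
      key <- paste(kin$template_base, kin$dntp)
      folds <- do.call(rbind, lapply(which(kin$variant != baseline), function(i) {
        j <- which(kin$variant == baseline & key == key[i])
        if (length(j) != 1L) return(NULL)
        data.frame(variant = kin$variant[i],
                   template_base = kin$template_base[i], dntp = kin$dntp[i],
                   vmax_fold = fold_change(fits[[i]], fits[[j]], "vmax"),
                   stringsAsFactors = FALSE)
      }))
      out$folds <- folds
      mis <- do.call(rbind, lapply(unique(kin$variant), function(v) {
        do.call(rbind, lapply(unique(kin$template_base), function(tb) {
          i <- which(kin$variant == v & kin$template_base == tb & kin$dntp == "dCTP")
          j <- which(kin$variant == v & kin$template_base == tb & kin$dntp == "dATP")
          if (length(i) != 1L || length(j) != 1L) return(NULL)
          data.frame(variant = v, template_base = tb,
                     misinsertion = misinsertion_ratio(fits[[i]], fits[[j]]),
                     stringsAsFactors = FALSE)
        }))
      }))
      out$misinsertion <- mis
    } else {
      out$folds <- data.frame(variant = character(0),
                              template_base = character(0),
                              dntp = character(0), vmax_fold = numeric(0))
      out$misinsertion <- data.frame(variant = character(0),
                                     template_base = character(0),
                                     misinsertion = numeric(0))
    }
  }
  out
}

#' Printed summary tables shipped with the package
#'
#' Convenience readers for the plain-text copies of the published
#' binding-energy and kinetics tables under \code{inst/extdata} (inputs to
#' \code{\link{run_report}}).
#'
#' @return data frames (see \code{\link{run_report}} for the schemas).
#' @export
published_energies <- function() {
  utils::read.delim(system.file("extdata", "table2_energies.tsv",
                                package = "polbind"),
                    stringsAsFactors = FALSE)
}

#' @rdname published_energies
#' @export
published_kd <- function() {
  utils::read.delim(system.file("extdata", "table2_kd.tsv",
                                package = "polbind"),
                    stringsAsFactors = FALSE)
}

#' @rdname published_energies
#' @export
published_kinetics <- function() {
  utils::read.delim(system.file("extdata", "table3_kinetics.tsv",
                                package = "polbind"),
                    stringsAsFactors = FALSE)
}
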