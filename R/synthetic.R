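# Seeded synthetic-data generators: coarse B-DNA duplexes, toy complexes,
# designed alignments, titration/velocity curves and gel lanes. These
# emulate the statistical and geometric structure of the real inputs so the
# whole pipeline is testable without external data.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Coarse ideal B-form DNA duplex
#'
#' Builds a two-pseudo-atom-per-nucleotide duplex around a straight helical
#' axis: one backbone phosphate pseudo-atom (atom \code{P}, carries the −1
#' backbone charge in the energy model) and one base-centroid pseudo-atom
#' per base, with a 3.4 Å rise and 36°/step twist. The input sequence is the
#' template strand (chain \code{T}); the generated complementary strand is
#' the primer (chain \code{P}). Coordinates are rounded to 0.001 Å so PDB
#' round trips are exact.
#'
#' @param sequence template DNA sequence over A/C/G/T; the default is the
#'   13-mer duplex sequence used throughout the package fixtures.
#' @param rise,twist helix rise (Å/bp) and twist (degrees/bp).
#' @param r_backbone,r_base radial positions (Å) of the phosphate and base
#'   pseudo-atoms.
#' @return a \code{\link{structure_model}} with nucleic chains \code{T}
#'   and \code{P}.
#' @export
make_bdna_duplex <- function(sequence = "GAAGCCGGCGGAA", rise = 3.4,
                             twist = 36, r_backbone = 8.9, r_base = 3.0) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2L) stop("sequence must have length >= 2")
  if (any(!bases %in% names(.COMPLEMENT)))
    stop("alphabet error: sequence must be over A/C/G/T")
  n <- length(bases)
  comp <- unname(.COMPLEMENT[bases])
  rows <- list()
  add <- function(chain, resi, base, theta, z) {
    th <- theta * pi / 180
    # second strand backbone offset across the minor groove
    th2 <- th + 120 * pi / 180
    bb <- if (chain == "T") th else th2
    bc <- if (chain == "T") th else th + pi
    rbind(
      data.frame(chain = chain, resi = resi, resn = paste0("D", base),
                 atom = "P", elem = "P",
                 x = r_backbone * cos(bb), y = r_backbone * sin(bb), z = z),
      data.frame(chain = chain, resi = resi, resn = paste0("D", base),
                 atom = "BC", elem = "C",
                 x = r_base * cos(bc), y = r_base * sin(bc), z = z))
  }
  for (i in seq_len(n)) {
    theta <- twist * (i - 1)
    z <- rise * (i - 1)
    rows[[length(rows) + 1L]] <- add("T", i, bases[i], theta, z)
  }
  # antiparallel complement: residue j of P pairs template base n+1-j
  for (j in seq_len(n)) {
    i <- n + 1L - j
    theta <- twist * (i - 1)
    z <- rise * (i - 1)
    rows[[length(rows) + 1L]] <- add("P", j, comp[i], theta, z)
  }
  at <- do.call(rbind, rows)
  at[, c("x", "y", "z")] <- round(at[, c("x", "y", "z")], 3)
  structure_model(at)
}

#' Toy protein–DNA complex with controlled contact distances
#'
#' Places two-pseudo-atom protein residues (Cα + Cβ) around a duplex so that
#' each residue's minimum heavy-atom distance to the duplex equals its
#' nominal distance to within 0.01 Å (solved by bisection along an outward
#' radial ray through a backbone anchor atom).
#'
#' @param duplex a duplex from \code{\link{make_bdna_duplex}}.
#' @param placements data frame with columns \code{resn} (3-letter residue
#'   name), \code{dist} (nominal minimum distance, Å > 0), \code{strand}
#'   (\code{"P"} or \code{"T"}: which strand the residue approaches) and
#'   optionally \code{resi} (protein residue numbers; default 1, 2, ...).
#' @param chain protein chain id (default \code{"A"}).
#' @return a \code{\link{structure_model}} with the protein chain appended.
#' @export
make_toy_complex <- function(duplex, placements, chain = "A") {
  placements <- as.data.frame(placements)
  if (nrow(placements) == 0L) {
    return(duplex)
  }
  if (any(placements$dist <= 0))
    stop("geometry error: placement distances must be > 0")
  if (!"resi" %in% names(placements))
    placements$resi <- seq_len(nrow(placements))
  dat <- .heavy(duplex$atoms)
  D <- as.matrix(dat[, c("x", "y", "z")])
  mind <- function(p) sqrt(min(.cross_dist2(matrix(p, 1L), D)))
  rows <- list()
  for (k in seq_len(nrow(placements))) {
    strand <- placements$strand[k]
    anchors <- which(dat$chain == strand & dat$atom == "P")
    if (!length(anchors)) stop("strand ", strand, " not found in duplex")
    # spread anchors along the strand
    a <- anchors[1L + ((k - 1L) %% length(anchors))]
    ax <- D[a, ]
    dir <- c(ax[1L], ax[2L], 0)
    dir <- dir / sqrt(sum(dir^2))
    # solve 2 mA below nominal so 0.001-A coordinate rounding cannot push a
    # residue placed exactly at a shell cutoff beyond it
    target <- placements$dist[k] - 0.002
    f <- function(t) mind(ax + t * dir) - target
    lo <- target
    hi <- target + 20
    while (f(hi) < 0) hi <- hi + 20
    t_cb <- if (f(lo) >= 0) lo else uniroot(f, c(lo, hi), tol = 1e-9)$root
    cb <- ax + t_cb * dir
    if (abs(mind(cb) - placements$dist[k]) > 0.01)
      stop("geometry error: could not realise placement ", k,
           " at ", target, " A")
    ca <- cb + 1.53 * dir
    rows[[k]] <- data.frame(
      chain = chain, resi = placements$resi[k], resn = placements$resn[k],
      atom = c("CA", "CB"), elem = "C",
      x = c(ca[1L], cb[1L]), y = c(ca[2L], cb[2L]), z = c(ca[3L], cb[3L]))
  }
  prot <- do.call(rbind, rows)
  prot <- prot[order(prot$resi), ]
  prot[, c("x", "y", "z")] <- round(prot[, c("x", "y", "z")], 3)
  structure_model(rbind(duplex$atoms, prot))
}

#' Designed multiple sequence alignment
#'
#' Generates an alignment of \code{n} sequences over an ungapped reference
#' whose per-column residue compositions among the non-reference sequences
#' match \code{column_specs} exactly; unspecified positions copy the
#' reference. Which homolog carries which residue is shuffled per column
#' under the seed.
#'
#' @param reference reference amino-acid sequence (string).
#' @param column_specs named list: \code{list(`337` = c(R = 28))} puts 28 R
#'   residues (and leaves the rest as the reference residue) at reference
#'   position 337; use residue name \code{"-"} for designed gaps.
#' @param n total number of sequences including the reference.
#' @param seed RNG seed.
#' @param ref_id,id_prefix sequence ids.
#' @return an \code{msa_alignment}.
#' @export
make_alignment <- function(reference, column_specs = list(), n, seed = 1,
                           ref_id = "REF", id_prefix = "HOM") {
  refv <- strsplit(toupper(reference), "")[[1]]
  width <- length(refv)
  m <- n - 1L
  if (m < 0L) stop("n must be >= 1")
  mat <- matrix(rep(refv, each = m), nrow = m)
  with_seed(seed, {
    for (ps in names(column_specs)) {
      p <- as.integer(ps)
      if (is.na(p) || p < 1L || p > width)
        stop("column spec position out of range: ", ps)
      comp <- column_specs[[ps]]
      if (sum(comp) > m)
        stop("spec error: composition at position ", ps, " exceeds n-1 = ", m)
      who <- sample.int(m)
      i <- 1L
      for (r in names(comp)) {
        cnt <- comp[[r]]
        if (cnt > 0L) {
          mat[who[i:(i + cnt - 1L)], p] <- r
          i <- i + cnt
        }
      }
    }
  })
  seqs <- c(setNames(paste(refv, collapse = ""), ref_id),
            setNames(apply(mat, 1L, paste, collapse = ""),
                     sprintf("%s%03d", id_prefix, seq_len(m))))
  msa_alignment(seqs, ref_id)
}

#' Simulate an equilibrium titration
#'
#' Hyperbolic binding signal \eqn{F_{max}[pol]/(K_d+[pol])} plus i.i.d.
#' Gaussian noise, with an optional linear protein-background term that is
#' also recorded as a matched control series (as measured with an unlabelled
#' probe).
#'
#' @param kd dissociation constant (nM, > 0).
#' @param fmax saturating fluorescence (negative for a quenching probe).
#' @param concentrations polymerase concentrations (nM); the default grid
#'   spans the 0–1000 nM titration range.
#' @param noise_sd Gaussian noise s.d. (a.u.) of a single measurement, or
#'   the fractional error when \code{heteroscedastic}.
#' @param replicates repeated measurements averaged per recorded point
#'   (default 4, the bench protocol for these titrations).
#' @param seed RNG seed.
#' @param background_slope protein-background fluorescence per nM.
#' @param probe_conc probe concentration (nM).
#' @param heteroscedastic if TRUE, \code{noise_sd} is interpreted as a
#'   fractional error and the noise s.d. is \code{noise_sd} times the local
#'   model signal.
#' @return a \code{\link{titration_dataset}} (control present when
#'   \code{background_slope} is non-zero).
#' @export
simulate_titration <- function(kd, fmax, concentrations = c(0, 5, 10, 20, 40,
                                                            60, 80, 100, 150,
                                                            200, 300, 400, 600,
                                                            800, 1000),
                               noise_sd = 0, replicates = 4, seed = NULL,
                               background_slope = 0, probe_conc = 100,
                               heteroscedastic = FALSE) {
  stopifnot(kd > 0)
  conc <- sort(unique(concentrations))
  model <- fmax * conc / (kd + conc)
  bg <- background_slope * conc
  with_seed(seed, {
    sdv <- if (heteroscedastic) noise_sd * abs(model) else rep(noise_sd,
                                                               length(conc))
    # each recorded point is the mean of `replicates` repeated measurements
    noise <- rowMeans(matrix(rnorm(length(conc) * replicates, 0, sdv),
                             nrow = length(conc)))
    fl <- model + bg + noise
    ctrl <- if (background_slope != 0)
      data.frame(conc = conc,
                 fluor = bg + rowMeans(matrix(
                   rnorm(length(conc) * replicates, 0, noise_sd),
                   nrow = length(conc))))
    else NULL
    titration_dataset(data.frame(conc = conc, fluor = fl), control = ctrl,
                      probe_conc = probe_conc)
  })
}

#' Simulate single-nucleotide insertion velocities
#'
#' Michaelis–Menten rates plus Gaussian noise, in the duplicate structure of
#' the bench assay; noisy rates are truncated at zero (a measured rate
#' cannot be negative).
#'
#' @param km,vmax Michaelis constant (µM, > 0) and limiting rate (nM/min).
#' @param concentrations dNTP concentrations (µM).
#' @param noise_sd Gaussian noise s.d. (nM/min), or the fractional error
#'   when \code{heteroscedastic}.
#' @param replicates replicate count (default 2).
#' @param heteroscedastic if TRUE the noise s.d. is \code{noise_sd} times
#'   the local model rate (proportional measurement error, the realistic
#'   model for quantified gel-band intensities).
#' @param seed RNG seed.
#' @param variant,template_base,dntp metadata carried on the dataset.
#' @return a \code{\link{velocity_dataset}}.
#' @export
simulate_velocities <- function(km, vmax,
                                concentrations = c(5, 10, 25, 50, 100, 200, 400),
                                noise_sd = 0, replicates = 2, seed = NULL,
                                variant = NA_character_,
                                template_base = NA_character_,
                                dntp = NA_character_,
                                heteroscedastic = FALSE) {
  stopifnot(km > 0)
  conc <- sort(unique(concentrations))
  model <- vmax * conc / (km + conc)
  with_seed(seed, {
    sdv <- if (heteroscedastic) noise_sd * model else noise_sd
    pts <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      v <- pmax(model + rnorm(length(conc), 0, sdv), 0)
      data.frame(conc = conc, v = v, replicate = r)
    }))
    velocity_dataset(pts, variant = variant, template_base = template_base,
                     dntp = dntp)
  })
}

# normalise an extension spec to a data.frame(extension, weight)
.extension_weights <- function(spec) {
  if (is.data.frame(spec)) return(spec[, c("extension", "weight")])
  switch(spec$type,
         point = data.frame(extension = spec$at, weight = 1),
         geometric = {
           ext <- seq_len(spec$max %||% 400)
           data.frame(extension = ext,
                      weight = (1 - spec$p)^(ext - 1L) * spec$p)
         },
         stop("unknown extension spec type: ", spec$type))
}

#' Analytic quantile of a discrete extension spec
#'
#' Smallest extension whose cumulative weight reaches \code{p} — the
#' generator-side oracle for the gel pipeline.
#'
#' @param spec an extension spec (see \code{\link{simulate_gel_lanes}}).
#' @param p cumulative fraction.
#' @return extension length in nt.
#' @export
extension_quantile <- function(spec, p = 0.85) {
  w <- .extension_weights(spec)
  w <- w[order(w$extension), ]
  cum <- cumsum(w$weight) / sum(w$weight)
  w$extension[which(cum >= p - 1e-12)[1L]]
}

#' Simulate a sample gel lane and its marker ladder
#'
#' Renders bands as Gaussians in the migration coordinate under the
#' log-linear mobility model \eqn{migration = a - b\log(L)}. Sample-lane
#' products carry the fluorophore mobility offset (apparent length = true
#' length + \code{offset}); the unlabelled ladder does not. A fraction of
#' the primer is left unextended.
#'
#' @param extension extension-length spec: \code{list(type = "point", at =
#'   100)}, \code{list(type = "geometric", p = 0.02, max = 400)}, or a data
#'   frame with \code{extension}, \code{weight}.
#' @param primer_length true primer length (nt, default 36).
#' @param ladder_lengths marker fragment lengths (nt).
#' @param a,b mobility model intercept/slope.
#' @param offset fluorophore mobility offset (nt, default 44).
#' @param unextended_frac fraction of lane intensity left in the primer
#'   band.
#' @param band_sd Gaussian band width in migration units.
#' @param noise_sd baseline noise s.d. (folded to keep intensities ≥ 0).
#' @param seed RNG seed.
#' @return list with elements \code{sample} and \code{ladder}, both
#'   \code{\link{lane_trace}}s on a common migration grid.
#' @export
simulate_gel_lanes <- function(extension, primer_length = 36,
                               ladder_lengths = c(25, 50, 100, 200, 400, 800),
                               a = 600, b = 80, offset = 44,
                               unextended_frac = 0.4, band_sd = 0.5,
                               noise_sd = 0, seed = NULL) {
  if (b <= 0) stop("mobility model must be monotone (b > 0)")
  w <- .extension_weights(extension)
  true_len <- c(primer_length, primer_length + w$extension)
  weight <- c(unextended_frac,
              (1 - unextended_frac) * w$weight / sum(w$weight))
  app_len <- true_len + offset
  mig_bands <- a - b * log(app_len)
  mig_ladder <- a - b * log(ladder_lengths)
  grid <- seq(min(c(mig_bands, mig_ladder)) - 8,
              max(c(mig_bands, mig_ladder)) + 8, by = 0.25)
  render <- function(centres, weights) {
    y <- numeric(length(grid))
    for (i in seq_along(centres))
      y <- y + weights[i] * stats::dnorm(grid, centres[i], band_sd)
    y
  }
  with_seed(seed, {
    samp <- render(mig_bands, weight)
    lad <- render(mig_ladder, rep(1, length(mig_ladder)))
    if (noise_sd > 0) {
      samp <- samp + abs(rnorm(length(grid), 0, noise_sd))
      lad <- lad + abs(rnorm(length(grid), 0, noise_sd))
    }
    list(sample = lane_trace(grid, samp, label = "sample", role = "sample"),
         ladder = lane_trace(grid, lad, label = "ladder", role = "ladder"))
  })
}
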