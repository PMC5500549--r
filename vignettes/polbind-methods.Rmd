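---
title: "Designing and evaluating DNA-binding-enhanced polymerase variants with polbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating DNA-binding-enhanced polymerase variants with polbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polbind)
```

## Scope and model

Y-family (translesion) DNA polymerases such as Dbh trade fidelity and
processivity for a loose, damage-tolerant active site. One engineering route
to better processivity is tighter, sequence-nonspecific DNA binding —
through fusion to a small dsDNA-binding domain (Sso7d) and through point
mutations at the protein–DNA interface. `polbind` implements the desk-scale
computational arm of that workflow, plus the analysis of the three
quantitative assays used to evaluate the resulting variants:

1. **Interface shell.** Protein residues whose minimum heavy-atom distance
   to any DNA heavy atom is ≤ 6 Å form the contact shell — the conventional
   definition of the pol/DNA interaction zone.
2. **Mutability.** A homolog multiple sequence alignment is reduced to
   per-position residue counts; positions are *non-conserved* when more than
   a threshold fraction (default 5%) of non-gap homolog residues differ from
   the reference. Candidate sites are the non-conserved shell positions, and
   the suggested substitution at each is the most frequent homolog residue.
3. **Binding-energy ranking.** Wild type and mutants are scored against each
   DNA strand (primer P and template T) separately and compared by
   \(\Delta\Delta G = \sum_{c\in\{P,T\}}(\Delta G_{mut,c}-\Delta G_{wt,c})\),
   negative meaning strengthened binding.
4. **Assay analysis.** Hyperbolic titration fits
   \(F = F_{max}[pol]/(K_d+[pol])\), Michaelis–Menten insertion kinetics
   \(v = V_{max}[dNTP]/(K_m+[dNTP])\) with catalytic efficiency
   \(V_{max}/K_m\) (\(K_m\) in mM), and gel-densitometry processivity
   reported as the 85th percentile of the extended-product length
   distribution under single-hit (trap) conditions.

## The surrogate energy scorer

A full MM-PBSA treatment needs an MD ensemble and a Poisson–Boltzmann
solver; neither belongs in a deterministic analysis package. `polbind`
instead scores a *single conformation* with a pairwise molecular-mechanics
sum over protein×DNA heavy-atom pairs within 12 Å:

* electrostatics with a distance-dependent dielectric
  \(\varepsilon(r)=\varepsilon_0 r\) (so
  \(E_{elec} = \sum k\,q_iq_j/(\varepsilon_0 r_{ij}^2)\), with
  \(k = 332.06\) kcal·Å/(mol·e²) and \(\varepsilon_0 = 4\) by default, the
  common protein-interior choice);
* a Lennard-Jones term with per-element σ/ε and Lorentz–Berthelot mixing;
* polar solvation 0 by default and a nonpolar buried-contact-area surrogate
  switched off by default (γ = 0).

Charges are integer formal charges: Asp/Glu −1, Lys/Arg +1, His 0, −1 on
each nucleotide backbone phosphorus, termini neutral. The residue charge
sits on Cβ (Cα for Gly), which is exactly the information still present in
a *coarse mutant model* — a relabelled wild-type backbone with side chains
truncated past Cβ — so wild type and mutants are scored on the same
footing without side-chain rebuilding.

Two consequences are deliberate and documented rather than hidden:

* **Absolute magnitudes are not comparable to MD-ensemble MM-PBSA values.**
  What the package reproduces exactly is the *bookkeeping*: per-chain
  decomposition (the total is identically
  \(E_{elec}+E_{vdW}+G_{polar}+G_{nonpolar}\); the entropy term is zero by
  construction), the P/T aggregation, and the mutant ranking.
* The scorer is a **plug-in seam**: `per_chain_binding(scorer = ...)`
  accepts any function with the same signature, so an external PB solver
  can be wired in without touching the bookkeeping.

When the published per-chain energies are fed through `aggregate_ddg`, the
printed difference column is regenerated for 7 of 8 mutants. The L250V row
is internally inconsistent in the source table (per-chain values sum to
−308.3, printed −318.3 kcal/mol); `run_report` reports the computed value
and flags the row. Likewise two printed efficiency cells are a factor of 10
smaller than their own row's \(V_{max}/K_m\); they are flagged, never
matched.

## Fitting conventions

Both fits are unweighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm::nlsLM`, convergence tolerances 1e−13) on replicate-averaged
data, initialised from the data (plateau ← max signal, midpoint ←
concentration at half-max). Standard errors come from the fit covariance.
Non-convergence, degenerate designs (e.g. saturation-only velocities, for
which \(K_m\) is unidentifiable) and non-positive parameters yield a
*flagged* fit object, never a silent fallback.

* `fit_kd` treats the concentration as total added polymerase — the
  standard hyperbolic reporting convention for these titrations — even
  though the probe (100 nM) is comparable to \(K_d\); a depletion-corrected
  quadratic model is available via `model = "quadratic"`. The binding signal
  may rise or quench; the dominant direction is inferred from the data and
  \(F_{max}\) is reported signed.
* `catalytic_efficiency` converts \(K_m\) to mM, the only unit reading
  consistent with the published efficiency column (e.g. 1.0 nM·min⁻¹ at
  88.2 µM → 11); its nominal "(min)" column unit is treated as a
  typographical artifact. Full precision is kept internally; 2 significant
  figures are used for table display.

## Processivity percentile

Denaturing-PAGE mobility is modelled as affine in log length,
\(m = a - b\log L\), fitted by least squares to ladder band peaks (detected
as local maxima above a noise floor and matched in order: longest fragment
migrates least). Sample-lane intensities are mapped through the inverse
model, shifted by the fluorophore mobility offset (default 44 nt: a 36-nt
fluorescein-labelled primer runs at an apparent ~80 nt), and re-binned to
integer nucleotides conserving total intensity.

The percentile is computed over *extended products only* (lengths strictly
above the primer): including the unextended primer band would conflate
binding with extension. The estimate is the smallest extension whose
cumulative normalised intensity reaches the percentile (default 0.85, no
interpolation); a lane with no intensity above the primer band returns a
"no extension" estimate of 0 rather than an error. Both the percentile and
the primer-inclusion rule are explicit arguments because the source
convention is ambiguous.

## Synthetic data: what it does and does not emulate

Every input has a seeded generator, byte-deterministic under a fixed seed:

* `make_bdna_duplex` — a coarse ideal B-form duplex (3.4 Å rise, 36°/step
  twist, one phosphate and one base-centroid pseudo-atom per nucleotide;
  default sequence the 13-mer duplex used throughout the fixtures), with
  the template strand labelled T and its complement P.
* `make_toy_complex` — two-pseudo-atom protein residues placed so each
  realises a *nominal* minimum distance to the duplex within 0.01 Å
  (bisection along an outward radial ray). Distance contracts can therefore
  be tested against construction, not just against a second implementation.
* `make_alignment` — alignments whose per-column residue compositions are
  hit *exactly*, so frequency-table rows (e.g. a position where 28 of 33
  homologs carry Arg against a Lys reference) are reproduced by
  construction.
* `simulate_titration` / `simulate_velocities` — hyperbolae plus Gaussian
  noise. Titration points are averages of four repeated measurements (the
  bench protocol); velocities come in duplicate and are truncated at zero
  (a measured rate cannot be negative). Noise is homoscedastic by default;
  `heteroscedastic = TRUE` makes the s.d. proportional to the local signal,
  the realistic error model for quantified gel-band intensities.
* `simulate_gel_lanes` — Gaussian bands in migration coordinate under the
  log-linear mobility model, with the fluorophore offset applied to the
  sample lane only and an analytic quantile oracle
  (`extension_quantile`) for end-to-end checks.

These generators test geometry, bookkeeping and statistics — not structure
realism. Passing tests show the pipeline recovers what it is fed under the
stated error models; they do not show that the 6 Å shell of a coarse
duplex matches a crystal structure's, nor that the surrogate scorer ranks
real mutants as MD would.

## Recovery-study design and problem sizes

The parameter-recovery studies (also run by `scripts/acceptance.R`) use:
200 seeded datasets per condition; titrations on the default 15-point
0–1000 nM grid with 5% proportional noise and 4-fold averaging; velocity
curves on 12 log-spaced concentrations bracketing \(K_m\) (0.1–10×, the
textbook Michaelis–Menten design chosen from a pilot estimate) in
duplicate with 5% proportional noise. Under these conditions the median
relative errors are ~3% for \(K_d\), ~4% for \(K_m\) and ~1.5% for
\(V_{max}\); noiseless data are recovered to 1e−6 relative. With strictly
homoscedastic noise of 5% of the saturating rate, no realistic
duplicate design determines \(K_m\) to a 5% median error — proportional
error is both the realistic densitometry model and the regime in which the
estimator's advertised precision holds. Brute-force shell equivalence is
checked on toy complexes of ≤ 500 atoms, and gel-pipeline percentile
recovery on single-lane renderings of point-mass and geometric(p = 0.02)
extension distributions (±2 nt at 1-nt binning).

## Numerical and design choices

* The 6 Å shell uses heavy atoms only and an inclusive comparison; both
  choices are explicit arguments. Structure-to-reference numbering is an
  explicit mapping table (identity by default).
* Homolog inclusion is strict (> 40% identity to the reference); gaps never
  count as substitutions and are excluded from identity denominators;
  substitution frequencies are raw counts, as in the published table.
* Ranked substitutions break count ties alphabetically; mutant ranking
  breaks \(\Delta\Delta G\) ties by label — both total orders are
  deterministic under permutation of the input.
* Block candidates are maximal runs of consecutive candidate positions
  (length ≥ 2), labelled `WTRUN(start-end)NEWRUN`; an en dash is accepted
  on input, ASCII is stored.
* All-gap alignment columns carry no evidence of variation and classify as
  conserved.
* Generator coordinates are rounded to 0.001 Å so PDB round trips are
  byte-exact; toy placements solve 0.002 Å below nominal so rounding can
  never push a residue placed exactly at a cutoff outside the shell.

## Known limitations

* The surrogate scorer's absolute energies are not physical binding free
  energies; only differences and rankings computed under the same scorer
  are meaningful, and even those are single-conformation estimates.
* Coarse mutant models cannot capture steric effects of a larger side
  chain (only the charge and truncation are represented).
* The exact homolog set behind the published frequency table is not
  available, so those counts are reproduced from designed alignments, not
  re-derived from a database search.
* Published processivity values derive from gel images that are not
  available numerically; the gel pipeline is validated against its own
  generators instead.
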