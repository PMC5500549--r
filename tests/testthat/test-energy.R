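# Surrogate MM scorer, per-chain bookkeeping, ddG aggregation and ranking.

params <- load_ff_params()

# two-atom fixture: one charged protein residue CB at distance r from one
# DNA phosphate
charge_pair_model <- function(r, resn = "ASP") {
  structure_model(data.frame(
    chain = c("B", "A", "A"), resi = c(1L, 1L, 1L),
    resn = c("DG", resn, resn), atom = c("P", "CA", "CB"),
    elem = c("P", "C", "C"),
    x = c(0, r + 1.53, r), y = 0, z = 0))
}

test_that("screened Coulomb term matches the closed form", {
  # unit opposite charges at 3.5 A, eps0 = 4, vdW off:
  # 332.06 * (+1)(-1) / (4 * 3.5^2) kcal/mol
  m <- charge_pair_model(3.5, resn = "LYS")
  e <- interaction_energy(m, "A", "B", params, eps0 = 4, vdw = FALSE)
  expect_equal(e$E_elec, 332.06 * (1 * -1) / (4 * 3.5^2), tolerance = 1e-12)
  expect_equal(e$E_elec, -6.78, tolerance = 1e-3)
  expect_equal(e$E_vdW, 0)
  # negative-charge residue repels the phosphate
  e2 <- interaction_energy(charge_pair_model(3.5, "ASP"), "A", "B", params,
                           eps0 = 4, vdw = FALSE)
  expect_equal(e2$E_elec, -e$E_elec, tolerance = 1e-12)
})

test_that("vectorised scorer equals the unoptimised all-pairs reference", {
  cx <- toy_complex(dists = c(2.5, 4, 7), resn = c("LYS", "ASP", "ARG"),
                    strand = c("P", "T", "P"))
  expect_lte(nrow(cx$atoms), 60)
  for (ch in c("P", "T")) {
    got <- interaction_energy(cx, "A", ch, params)
    ref <- brute_energy(cx, "A", ch, params)
    expect_equal(got$E_elec, ref$E_elec, tolerance = 1e-9)
    expect_equal(got$E_vdW, ref$E_vdW, tolerance = 1e-9)
    expect_equal(got$total, ref$total, tolerance = 1e-9)
  }
})

test_that("decomposition identity holds exactly and is rigid-motion invariant", {
  cx <- toy_complex()
  e <- interaction_energy(cx, "A", "P", params)
  expect_identical(e$total, e$E_elec + e$E_vdW + e$G_polar + e$G_nonpolar)
  moved <- rigid_transform(cx)
  e2 <- interaction_energy(moved, "A", "P", params)
  expect_equal(e2$total, e$total, tolerance = 1e-9)
  expect_equal(e2$E_elec, e$E_elec, tolerance = 1e-9)
})

test_that("energy vanishes beyond the pair cutoff", {
  cx <- toy_complex(dists = c(3, 5))
  at <- cx$atoms
  at[at$chain == "A", c("x", "y")] <- at[at$chain == "A", c("x", "y")] + 100
  far <- structure_model(at, chain_roles = cx$chain_roles)
  for (ch in c("P", "T")) {
    e <- interaction_energy(far, "A", ch, params)
    expect_identical(e$total, 0)  # exactly zero beyond 12 A
  }
  # and a residue just inside the cutoff still contributes
  near <- toy_complex(dists = 11.5, resn = "LYS", strand = "P")
  expect_gt(abs(interaction_energy(near, "A", "P", params)$total), 0)
})

test_that("missing vdW parameters raise a parameterization error", {
  m <- charge_pair_model(3.5)
  m$atoms$elem[2] <- "ZN"
  expect_error(interaction_energy(m, "A", "B", params), "parameterization")
})

test_that("per-chain binding is symmetric for a mirror-symmetric complex", {
  # two identical single-nucleotide strands at x = +/-6, protein on the axis
  at <- data.frame(
    chain = c("P", "P", "T", "T", "A", "A"),
    resi = c(1L, 1L, 1L, 1L, 1L, 1L),
    resn = c("DG", "DG", "DG", "DG", "LYS", "LYS"),
    atom = c("P", "BC", "P", "BC", "CA", "CB"),
    elem = c("P", "C", "P", "C", "C", "C"),
    x = c(-6, -3, 6, 3, 0, 0), y = c(0, 0, 0, 0, 1.5, 0), z = 0)
  m <- structure_model(at)
  pc <- per_chain_binding(m, params = params)
  expect_equal(unname(pc["P"]), unname(pc["T"]), tolerance = 1e-12)
  # swapping the P/T labels swaps the mapping values
  cx <- toy_complex(dists = c(2.5, 4), resn = c("LYS", "ASP"),
                    strand = c("P", "P"))
  fwd <- per_chain_binding(cx, params = params)
  swp <- per_chain_binding(cx, params = params, chain_map = c(P = "T", T = "P"))
  expect_equal(unname(fwd["P"]), unname(swp["T"]), tolerance = 1e-12)
  expect_equal(unname(fwd["T"]), unname(swp["P"]), tolerance = 1e-12)
})

test_that("a charge-introducing mutation near the primer strand strengthens its chain score", {
  cx <- toy_complex(dists = 4.5, resn = "ALA", strand = "P")
  wt <- per_chain_binding(cx, params = params)
  mut <- per_chain_binding(cx, mutant = mutation_spec(1, "A", "K"),
                           params = params)
  expect_lt(mut["P"] - wt["P"], 0)  # +1 near backbone: more negative
  expect_lt(abs(mut["T"] - wt["T"]), abs(mut["P"] - wt["P"]))
})

test_that("coarse mutant models relabel and truncate past C-beta", {
  pdbtxt <- c(
    "ATOM      1  N   LYS A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  LYS A  10       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  LYS A  10       2.000   1.200   0.000  1.00  0.00           C",
    "ATOM      4  CG  LYS A  10       3.400   1.500   0.000  1.00  0.00           C",
    "ATOM      5  NZ  LYS A  10       4.600   2.000   0.000  1.00  0.00           N",
    "ATOM      6  P    DG B   1       0.000   5.000   0.000  1.00  0.00           P",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdbtxt, f)
  m <- read_structure(f)
  mut <- relabel_mutant(m, mutation_spec(10, "K", "R"))
  a <- mut$atoms[mut$atoms$chain == "A", ]
  expect_setequal(a$atom, c("N", "CA", "CB"))
  expect_true(all(a$resn == "ARG"))
  gly <- relabel_mutant(m, mutation_spec(10, "K", "G"))
  expect_setequal(gly$atoms$atom[gly$atoms$chain == "A"], c("N", "CA"))
  expect_error(relabel_mutant(m, mutation_spec(10, "A", "R")), "wt mismatch")
})

test_that("ddG aggregation reproduces the published difference column", {
  wt <- c(P = -2251.8, T = -3465.7)
  kskip <- aggregate_ddg(wt, c(P = -2579.5, T = -3670.2),
                         "KSKIP(241-245)RVRKS")
  expect_equal(kskip$ddg, -532.2, tolerance = 1e-9)
  k337r <- aggregate_ddg(wt, c(P = -2554.6, T = -3120.5), "K337R")
  expect_equal(k337r$ddg, 42.4, tolerance = 1e-9)
  expect_equal(aggregate_ddg(wt, wt, "self")$ddg, 0)
  expect_error(aggregate_ddg(wt, c(P = -1), "x"), "both P and T")
})

test_that("mutants rank ascending by ddG with deterministic ties", {
  en <- published_energies()
  wt <- setNames(en$dG_bind[en$label == "WTDbh"], en$chain[en$label == "WTDbh"])
  labs <- setdiff(unique(en$label), "WTDbh")
  recs <- lapply(labs, function(l)
    aggregate_ddg(wt, setNames(en$dG_bind[en$label == l],
                               en$chain[en$label == l]), l))
  ranked <- rank_mutants(recs)
  expect_equal(vapply(ranked, `[[`, character(1), "label"),
               c("KSKIP(241-245)RVRKS", "M76I", "L250V", "T37F", "A221S",
                 "I62V", "K337R", "Y249I"))
  # permutation of the input leaves the output order unchanged
  set.seed(1)
  ranked2 <- rank_mutants(sample(recs))
  expect_equal(attr(ranked2, "summary"), attr(ranked, "summary"))
})
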