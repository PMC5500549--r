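# Candidate intersection, block candidates, mutation application, fusions.

fake_shell <- function(pos, dist = NULL) {
  sh <- data.frame(chain = rep("A", length(pos)), resi = as.integer(pos),
                   resn = rep("ALA", length(pos)),
                   min_dist = dist %||% rep(3, length(pos)))
  class(sh) <- c("contact_shell", "data.frame")
  sh
}

fake_profile <- function(pos, ref, counts, gaps = 0L) {
  structure(list(position = as.integer(pos), ref_aa = ref, counts = counts,
                 gap_count = gaps, n_other = sum(counts) + gaps),
            class = "column_profile")
}

test_that("candidate sites are the shell x non-conserved intersection", {
  profs <- list(
    fake_profile(5, "A", c(A = 33L)),            # conserved
    fake_profile(7, "K", c(R = 30L, K = 3L)),    # non-conserved
    fake_profile(9, "L", c(V = 20L, L = 13L)),   # non-conserved
    fake_profile(12, "T", c(F = 25L, T = 8L)))   # non-conserved, not in shell
  tab <- candidate_sites(fake_shell(c(5, 7, 9)), profs)
  expect_equal(tab$position, c(7L, 9L))
  expect_equal(tab$top_sub, c("R", "V"))
  expect_equal(tab$subs_txt[1], "R/30")
  expect_equal(nrow(candidate_sites(fake_shell(integer(0)), profs)), 0L)
  expect_error(candidate_sites(fake_shell(99), profs), "mapping error")
})

test_that("randomised candidate tables match a brute-force set/argmax oracle", {
  set.seed(13)
  for (rep in 1:3) {
    npos <- 200
    profs <- lapply(seq_len(npos), function(p) {
      ref <- sample(LETTERS[c(1, 3:9)], 1)
      nmut <- sample(0:30, 1)
      muts <- if (nmut > 0) table(sample(setdiff(c("A","C","D","E","K","R","V"),
                                                 ref), nmut, TRUE))
      counts <- c(setNames(as.integer(33 - nmut), ref),
                  setNames(as.integer(muts), names(muts)))
      fake_profile(p, ref, counts[counts > 0])
    })
    shell_pos <- sort(sample(npos, 60))
    tab <- candidate_sites(fake_shell(shell_pos), profs)
    # oracle: direct intersection + per-row argmax (ties alphabetical)
    nonconserved <- which(vapply(seq_len(npos), function(p) {
      cnt <- profs[[p]]$counts
      diff <- sum(cnt) - sum(cnt[profs[[p]]$ref_aa], na.rm = TRUE)
      diff / sum(cnt) > 0.05
    }, logical(1)))
    expected <- sort(intersect(shell_pos, nonconserved))
    expect_equal(tab$position, expected)
    for (i in seq_len(nrow(tab))) {
      cnt <- profs[[tab$position[i]]]$counts
      cnt <- cnt[names(cnt) != profs[[tab$position[i]]]$ref_aa]
      best <- sort(names(cnt)[cnt == max(cnt)])[1]
      expect_equal(tab$top_sub[i], best)
    }
    # containment both ways
    expect_true(all(tab$position %in% shell_pos))
    expect_true(all(tab$position %in% nonconserved))
  }
})

test_that("block candidates find maximal consecutive runs with top-pick replacements", {
  # the published contiguous interdomain-linker run 241-245
  wt <- c("K", "S", "K", "I", "P")
  top <- c("R", "V", "R", "K", "S")
  counts <- list(c(R = 24L), c(V = 19L, E = 5L, I = 2L, T = 1L, Q = 1L, K = 1L),
                 c(R = 25L, V = 2L, I = 1L), c(K = 25L, V = 2L, T = 1L, S = 1L, H = 1L),
                 c(S = 18L, H = 6L, N = 3L))
  profs <- lapply(1:5, function(i) fake_profile(240 + i, wt[i], counts[[i]]))
  tab <- candidate_sites(fake_shell(241:245), profs)
  blocks <- block_candidates(tab)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$label, "KSKIP(241-245)RVRKS")
  expect_equal(blocks[[1]]$new, top)
  # non-consecutive candidates yield no block
  profs2 <- lapply(c(10, 12, 14), function(p) fake_profile(p, "K", c(R = 30L)))
  expect_length(block_candidates(candidate_sites(fake_shell(c(10, 12, 14)),
                                                 profs2)), 0L)
  # two separate runs yield two blocks, partitioning without overlap
  profs3 <- lapply(c(1:3, 7:8), function(p) fake_profile(p, "K", c(R = 30L)))
  blocks3 <- block_candidates(candidate_sites(fake_shell(c(1:3, 7:8)), profs3))
  expect_length(blocks3, 2L)
  expect_equal(lapply(blocks3, `[[`, "pos"), list(1:3, 7:8))
  expect_equal(anyDuplicated(unlist(lapply(blocks3, `[[`, "pos"))), 0L)
})

test_that("mutations apply, validate wild types and revert cleanly", {
  ref <- paste(rep("K", 340), collapse = "")
  expect_equal(apply_mutations(ref, mutation_spec(integer(0), character(0),
                                                  character(0))), ref)
  mut <- apply_mutations(ref, mutation_spec(337, "K", "R"))
  expect_equal(substring(mut, 337, 337), "R")
  expect_equal(sum(strsplit(mut, "")[[1]] != strsplit(ref, "")[[1]]), 1L)
  # block: 5 positions changed
  ref2 <- paste0(strrep("A", 240), "KSKIP", strrep("A", 95))
  spec <- parse_mutation_label("KSKIP(241-245)RVRKS")
  mut2 <- apply_mutations(ref2, spec)
  expect_equal(sum(strsplit(mut2, "")[[1]] != strsplit(ref2, "")[[1]]), 5L)
  # revert restores the original
  revert <- mutation_spec(spec$pos, spec$new, spec$wt)
  expect_equal(apply_mutations(mut2, revert), ref2)
  expect_error(apply_mutations(ref2, mutation_spec(3, "K", "R")),
               "wt mismatch at position 3")
})

test_that("mutation labels parse in both point and block forms", {
  s <- parse_mutation_label("M76I")
  expect_equal(list(s$pos, s$wt, s$new), list(76L, "M", "I"))
  b <- parse_mutation_label("KSKIP(241–245)RVRKS")  # en dash accepted
  expect_equal(b$pos, 241:245)
  expect_equal(b$label, "KSKIP(241-245)RVRKS")
  expect_error(parse_mutation_label("KSKIP(241-244)RVRKS"), "run length")
  expect_error(parse_mutation_label("not-a-label"), "cannot parse")
})

test_that("linker notation expands and fuses domains", {
  fus <- build_fusion(strrep("M", 63), "SS(GGGGS)_3_GM", strrep("D", 354))
  expect_equal(fus$linker, "SSGGGGSGGGGSGGGGSGM")
  expect_equal(nchar(fus$linker), 19L)
  expect_equal(fus$fused, paste0(fus$n_domain, fus$linker, fus$c_domain))
  expect_equal(nchar(fus$fused), 63 + 19 + 354)
  expect_equal(build_fusion("", "(A)_0_B", "")$linker, "B")
  expect_equal(build_fusion("M", "GSGS", "D")$linker, "GSGS")  # plain linker
  expect_error(build_fusion("M", "SS(GGGGS_3_GM", "D"), "malformed")
})
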