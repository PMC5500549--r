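# Alignment I/O, identity filtering, conservation and substitution profiles.

test_that("aligned FASTA round-trips and bad inputs are rejected", {
  aln <- msa_alignment(c(REF = "ACDEFG", H1 = "ACDEYG", H2 = "A-DEFG"), "REF")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, "REF")
  expect_equal(back$seqs, aln$seqs)
  expect_error(msa_alignment(c(A = "ACDX", B = "ACDE"), "A"), "alphabet")
  expect_error(msa_alignment(c(A = "ACD", B = "ACDE"), "A"), "ragged")
  expect_error(msa_alignment(c(A = "ACDE"), "missing"), "not present")
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty, "REF"), "empty")
})

test_that("pairwise identity counts matches over mutually ungapped columns", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 5 / 6)
  expect_equal(pairwise_identity("A-CD", "AEC-"), 1.0)  # only cols 1,3 compare
  expect_equal(pairwise_identity("----", "AC-D"), 0)    # nothing comparable
  expect_error(pairwise_identity("AC", "ACD"), "length")
})

test_that("pairwise identity agrees with an independent implementation", {
  set.seed(7)
  aln <- make_alignment(paste(sample(c("A","C","D","E","K","R"), 60, TRUE),
                              collapse = ""),
                        column_specs = setNames(
                          lapply(1:7, function(i) c(V = i)),
                          as.character(seq(3, 39, by = 6))),
                        n = 8, seed = 7)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  ref_id <- aln$ref_id
  ident <- bio3d::seqidentity(bio3d::read.fasta(f))
  for (id in names(aln$seqs))  # bio3d reports identities rounded to 3 dp
    expect_lt(abs(pairwise_identity(aln$seqs[[id]], aln$seqs[[ref_id]]) -
                    ident[id, ref_id]), 5e-4 + 1e-12)
})

test_that("homolog filter keeps strictly-above-threshold records and is idempotent", {
  ref <- strrep("A", 100)
  mk <- function(k) paste0(strrep("V", k), strrep("A", 100 - k))
  # identities 0.2 .. 0.9 plus boundary cases 0.39, 0.40, 0.41
  ids <- c(seq(20, 90, by = 10), 39, 40, 41)
  seqs <- c(REF = ref, setNames(vapply(100 - ids, mk, character(1)),
                                paste0("H", ids)))
  aln <- msa_alignment(seqs, "REF")
  kept <- filter_homologs(aln, 0.40)
  planted <- ids / 100
  expect_setequal(names(kept$seqs),
                  c("REF", paste0("H", ids)[planted > 0.40]))
  expect_false("H40" %in% names(kept$seqs))  # exactly 0.40 is dropped
  expect_true("H41" %in% names(kept$seqs))
  expect_equal(filter_homologs(kept, 0.40)$seqs, kept$seqs)  # idempotent
})

test_that("column profiles obey count conservation and skip reference gaps", {
  set.seed(11)
  n <- 50; width <- 200
  alphabet <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","-")
  mat <- matrix(sample(alphabet, n * width, TRUE, prob = c(rep(1, 20), 4)),
                nrow = n)
  mat[1, ] <- sample(alphabet[1:20], width, TRUE)  # ungapped reference
  mat[1, 7] <- "-"                                 # one reference gap
  seqs <- setNames(apply(mat, 1, paste, collapse = ""),
                   c("REF", paste0("H", seq_len(n - 1))))
  aln <- msa_alignment(seqs, "REF")
  profiles <- column_profiles(aln)
  expect_length(profiles, width - 1L)  # reference-gap column dropped
  for (p in profiles)
    expect_equal(sum(p$counts) + p$gap_count, n - 1L)
  # position mapping is bijective onto the reference residues
  expect_equal(profiles_reference(profiles),
               gsub("-", "", seqs[["REF"]], fixed = TRUE))
})

test_that("designed high-frequency column reproduces the K337R profile shape", {
  ref <- paste(rep("K", 340), collapse = "")
  aln <- make_alignment(ref, column_specs = list(`337` = c(R = 28)),
                        n = 34, seed = 5)
  profiles <- column_profiles(aln)
  p <- profiles[[337]]
  expect_equal(p$ref_aa, "K")
  expect_equal(unname(p$counts["R"]), 28L)
  expect_equal(sum(p$counts) + p$gap_count, 33L)
  expect_false(classify_conservation(p))  # 28/33 differ >> 5%
  subs <- ranked_substitutions(p)
  expect_equal(subs$residue[1], "R")
  expect_equal(subs$count[1], 28L)
})

test_that("conservation classification follows the non-reference fraction rule", {
  prof <- function(counts, ref = "K", gaps = 0)
    structure(list(position = 1L, ref_aa = ref, counts = counts,
                   gap_count = gaps, n_other = sum(counts) + gaps),
              class = "column_profile")
  expect_true(classify_conservation(prof(c(K = 33))))          # all match
  expect_false(classify_conservation(prof(c(K = 5, R = 28))))  # 28/33 differ
  expect_true(classify_conservation(prof(c(K = 5, R = 28)),
                                    max_nonref_frac = 1.0))    # vacuous rule
  expect_true(classify_conservation(prof(c(K = 96, R = 4))))   # 4% <= 5%
  expect_false(classify_conservation(prof(c(K = 94, R = 6))))  # 6% > 5%
  expect_true(classify_conservation(prof(setNames(integer(0), character(0)),
                                         gaps = 33)))          # all-gap column
})

test_that("ranked substitutions sort by count with alphabetical ties, reference excluded", {
  prof <- structure(list(position = 243L, ref_aa = "K",
                         counts = c(R = 25L, I = 1L, V = 2L, K = 5L),
                         gap_count = 0L, n_other = 33L),
                    class = "column_profile")
  subs <- ranked_substitutions(prof)
  expect_equal(subs$residue, c("R", "V", "I"))  # K (reference) never listed
  expect_equal(subs$count, c(25L, 2L, 1L))
  tie <- structure(list(position = 1L, ref_aa = "K",
                        counts = c(C = 3L, A = 3L), gap_count = 0L,
                        n_other = 6L), class = "column_profile")
  expect_equal(ranked_substitutions(tie)$residue, c("A", "C"))
  none <- structure(list(position = 1L, ref_aa = "K", counts = c(K = 10L),
                         gap_count = 0L, n_other = 10L),
                    class = "column_profile")
  expect_equal(nrow(ranked_substitutions(none)), 0L)
})
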