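test_that("global alignment is optimal against exhaustive enumeration", {
  pa <- global_align("ACGT", "ACGT")
  expect_equal(pa$aligned_a, "ACGT")
  expect_equal(pa$score, 0)

  pa <- global_align("ACGT", "AGT")
  expect_equal(pa$score, 1)
  expect_equal(nchar(pa$aligned_a), 4L)

  expect_error(global_align("", "ACGT"), "nonempty")
  pa <- global_align("A", "G")
  expect_equal(pa$score, 1)
  expect_equal(pa$aligned_a, "A")
  expect_equal(pa$aligned_b, "G")

  set.seed(17)
  for (trial in 1:40) {
    a <- random_dna(sample(1:7, 1))
    b <- random_dna(sample(1:7, 1))
    got <- global_align(a, b)$score
    expect_equal(got, brute_align_cost(a, b), info = paste(a, b))
  }
})

test_that("alignment degapping reproduces inputs with no all-gap columns", {
  set.seed(23)
  for (trial in 1:20) {
    a <- random_dna(sample(5:60, 1))
    b <- random_dna(sample(5:60, 1))
    pa <- global_align(a, b)
    expect_equal(gsub("-", "", pa$aligned_a), a)
    expect_equal(gsub("-", "", pa$aligned_b), b)
    av <- strsplit(pa$aligned_a, "")[[1]]
    bv <- strsplit(pa$aligned_b, "")[[1]]
    expect_false(any(av == "-" & bv == "-"))
  }
})

test_that("edit distance counts columns or gap-run events", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0)
  expect_equal(edit_distance("ACGT", "ACGT", "single_event"), 0)
  expect_equal(edit_distance("A--T", "ACGT"), 2)
  expect_equal(edit_distance("A--T", "ACGT", "single_event"), 1)
  expect_equal(edit_distance("ACGT", "TCGA"), 2)
  expect_equal(edit_distance("ACGT", "TCGA", "single_event"), 2)
  expect_error(edit_distance("ACGT", "ACG"), "length")
  # intersecting IUPAC sets contribute nothing
  expect_equal(edit_distance("ANRT", "AGGT"), 0)
})

test_that("per-column edit distance is a metric on gapped rows", {
  set.seed(29)
  alphabet <- c("A", "C", "G", "T", "-")
  for (trial in 1:50) {
    n <- sample(5:20, 1)
    rows <- replicate(3, paste(sample(alphabet, n, TRUE), collapse = ""))
    dab <- edit_distance(rows[1], rows[2])
    dba <- edit_distance(rows[2], rows[1])
    dac <- edit_distance(rows[1], rows[3])
    dbc <- edit_distance(rows[2], rows[3])
    expect_equal(dab, dba)
    expect_equal(edit_distance(rows[1], rows[1]), 0)
    expect_true(dac <= dab + dbc)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and exact", {
  aln <- mt_alignment(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(unname(distance_matrix(aln)), matrix(0, 2, 2))

  aln <- mt_alignment(c("a", "b", "c"), c("ACGTACGT", "TCGTACGT", "ACGTACGA"))
  d <- distance_matrix(aln)
  expect_equal(unname(d["a", "b"]), 1)
  expect_equal(unname(d["a", "c"]), 1)
  expect_equal(unname(d["b", "c"]), 2)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_error(distance_matrix(mt_alignment("a", "ACGT")), "2 rows")

  # skip_ambiguous drops columns where either row is ambiguous
  aln <- mt_alignment(c("a", "b"), c("NCGT", "ACGA"))
  expect_equal(unname(distance_matrix(aln, skip_ambiguous = TRUE)[1, 2]), 1)
})

test_that("group outliers flag exactly the planted divergent sequences", {
  # homogeneous group: no flags; one planted outlier: exactly that id
  set.seed(37)
  hits <- 0L
  for (trial in 1:25) {
    spec <- synth_spec(seed = 100 + trial, n_outlier = 1L)
    g <- generate_dataset(spec)
    ds <- g$dataset$sequences
    aln <- mt_alignment(ds$id, ds$residues)
    d <- distance_matrix(aln)
    grp <- setNames(rep("synthetic", nrow(ds)), ds$id)
    out <- group_outliers(d, grp)
    expect_equal(out$flagged,
                 g$registry$id[g$registry$defect == "divergent"])
    hits <- hits + 1L
  }
  expect_equal(hits, 25L)

  # clean groups yield no flags
  spec <- synth_spec(seed = 55, n_leaves = 12)
  g <- generate_dataset(spec)
  aln <- mt_alignment(g$dataset$sequences$id, g$dataset$sequences$residues)
  d <- distance_matrix(aln)
  out <- group_outliers(d, setNames(rep("g", 12), g$dataset$sequences$id))
  expect_length(out$flagged, 0L)

  # undersized groups are reported, not scored
  out <- group_outliers(d[1:2, 1:2],
                        setNames(rep("tiny", 2), rownames(d)[1:2]))
  expect_equal(out$small_groups, "tiny")
})

test_that("two synthetic species clusters are reported as separated", {
  spec1 <- synth_spec(seed = 61, n_leaves = 8, sub_rate = 10)
  g1 <- generate_dataset(spec1)
  s1 <- g1$dataset$sequences
  # sister species: the same population carrying one shared block of fixed
  # differences, applied identically to every member
  set.seed(63)
  s2 <- s1
  fixed <- sample(nchar(s2$residues[1]), 150)
  refv <- strsplit(g1$annotation$reference, "")[[1]]
  s2$residues <- vapply(s2$residues, function(s) {
    v <- strsplit(s, "")[[1]]
    v[fixed] <- chartr("ACGT", "TGCA", refv[fixed])
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ids <- c(paste0("a_", s1$id), paste0("b_", s2$id))
  aln <- mt_alignment(ids, c(s1$residues, s2$residues))
  d <- distance_matrix(aln)
  grp <- setNames(rep(c("sp1", "sp2"), each = 8), ids)
  out <- group_outliers(d, grp)
  expect_true(out$separation$separated)
  expect_true(out$separation$min_inter > out$separation$max_intra)
})

test_that("rotation detection matches an exhaustive scan and inverts", {
  set.seed(41)
  ref <- random_dna(600)
  # exhaustive-scan oracle over all rotations
  oracle <- function(s, ref) {
    ids <- vapply(0:(nchar(s) - 1), function(o) {
      cand <- mtphylo::correct_rotation(s, o)
      mean(strsplit(cand, "")[[1]] == strsplit(ref, "")[[1]])
    }, numeric(1))
    which.max(ids) - 1L
  }
  for (off in c(100L, 13L, 599L)) {
    rotated <- correct_rotation(ref, nchar(ref) - off)  # rotate left by off
    expect_equal(oracle(rotated, ref), off)
    expect_equal(detect_rotation(rotated, ref), off)
    expect_equal(correct_rotation(rotated, off), ref)
  }
  # unrotated with 1% substitutions: offset 0 wins
  sv <- strsplit(ref, "")[[1]]
  at <- sample(600, 6)
  sv[at] <- vapply(sv[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  expect_equal(detect_rotation(paste(sv, collapse = ""), ref), 0L)
  # unrelated sequence: identity gain below margin
  expect_equal(detect_rotation(random_dna(600), ref), 0L)
})

test_that("rotation correction is the inverse of rotation for all offsets", {
  set.seed(43)
  s <- random_dna(200)
  for (o in c(0L, 1L, 57L, 199L)) {
    rotated <- correct_rotation(s, (nchar(s) - o) %% nchar(s))
    expect_equal(correct_rotation(rotated, o), s)
  }
  expect_equal(correct_rotation(s, 0L), s)
})
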