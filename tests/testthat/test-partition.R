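test_that("splitting the reference against itself recovers the annotation", {
  ann <- tiny_annotation()
  sp <- split_by_units(ann$reference, ann)
  expect_equal(sp$residues,
               substring(ann$reference, ann$units$start, ann$units$end))
  expect_false(any(sp$empty))
})

test_that("a planted insertion stays within its gene's slice", {
  ann <- tiny_annotation()
  ref <- ann$reference
  # insert 3 bp in the middle of gene1 (7..24)
  mutant <- paste0(substr(ref, 1, 15), "TTT", substr(ref, 16, nchar(ref)))
  sp <- split_by_units(mutant, ann)
  base <- split_by_units(ref, ann)
  expect_equal(nchar(sp$residues[2]) - nchar(base$residues[2]), 3L)
  expect_equal(sp$residues[-2], base$residues[-2])
})

test_that("a sequence lacking the control region yields empty flagged slices", {
  ann <- tiny_annotation()
  noCR <- substr(ann$reference, 7, 48)   # coding region only
  sp <- split_by_units(noCR, ann)
  expect_true(all(sp$empty[sp$kind == "control_region_part"]))
  expect_false(any(sp$empty[sp$kind != "control_region_part"]))
})

test_that("unit alignment of identical or near-identical slices is gap-free", {
  ann <- tiny_annotation()
  gene <- substr(ann$reference, 7, 24)
  ua <- align_unit(c(x = gene, y = gene, z = gene), gene, unit_start = 7L)
  expect_equal(ua$ncols, nchar(gene))
  expect_false(any(grepl("-", ua$rows)))
  expect_equal(ua$colmap, 7:24)

  var <- gene
  substr(var, 5, 5) <- if (substr(gene, 5, 5) == "A") "C" else "A"
  ua2 <- align_unit(c(x = gene, y = var), gene, unit_start = 7L)
  expect_false(any(grepl("-", ua2$rows)))
  diffcols <- sum(vapply(seq_len(ua2$ncols), function(j)
    substr(ua2$rows[1], j, j) != substr(ua2$rows[2], j, j), logical(1)))
  expect_equal(diffcols, 1L)

  expect_error(align_unit(c(x = gene), gene), "2 nonempty")
})

test_that("a missing external aligner is an actionable error", {
  expect_error(
    align_unit(c(a = "ACGT", b = "ACGT"), "ACGT",
               engine = "no_such_aligner_xyz"),
    "internal")
})

test_that("internal unit alignments are competitive with an external engine", {
  sp_cost <- function(aln) {
    # sum-of-pairs per-column distance
    n <- length(aln$ids)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + edit_distance(aln$rows[i], aln$rows[j])
    tot
  }
  set.seed(71)
  for (trial in 1:3) {
    ref <- random_dna(120)
    slices <- vapply(1:8, function(i) {
      v <- strsplit(ref, "")[[1]]
      at <- sample(120, 6)
      v[at] <- sample(c("A", "C", "G", "T"), 6, TRUE)
      if (runif(1) < 0.5) v <- v[-sample(120, 2)]  # small deletion
      paste(v, collapse = "")
    }, character(1))
    names(slices) <- paste0("s", 1:8)
    internal <- align_unit(slices, ref)
    external <- align_unit(slices, ref, engine = "mafft --quiet --auto")
    expect_lte(sp_cost(internal), 1.2 * sp_cost(external) + 1e-9)
  }
})

test_that("indel calls follow the codon-boundary rule", {
  # toy 9-bp coding gene starting at reference position 1
  unit <- data.frame(name = "g", kind = "gene", start = 1L, end = 9L,
                     coding = TRUE, frame = 0L, stringsAsFactors = FALSE)
  mk <- function(row) mt_alignment(c("ref", "x"), c("ACGTTGCAA", row), 1:9)
  calls <- classify_indels(mk("ACG---CAA"), unit)   # codon 2 deleted
  expect_equal(calls$kind[calls$id == "x"], "codon_full")
  expect_equal(calls$ref_pos[calls$id == "x"], 4L)

  calls <- classify_indels(mk("ACGT--CAA"), unit)   # 2 bp: frameshift
  expect_equal(calls$kind[calls$id == "x"], "frameshift")

  calls <- classify_indels(mk("AC---GCAA"), unit)   # 3 bp mid-codon
  expect_equal(calls$kind[calls$id == "x"], "frameshift")

  nc <- data.frame(name = "n", kind = "noncoding_gap", start = 1L, end = 9L,
                   coding = FALSE, frame = 0L, stringsAsFactors = FALSE)
  calls <- classify_indels(mk("ACG---CAA"), nc)
  expect_equal(calls$kind[calls$id == "x"], "noncoding")

  # partition property: every maximal gap run receives exactly one call
  aln <- mt_alignment(c("a", "b", "c"),
                      c("AC--TGC-A", "ACGTTG--A", "ACGTTGCAA"), 1:9)
  calls <- classify_indels(aln, unit)
  runs <- sum(vapply(aln$rows, function(r) {
    m <- gregexpr("-+", r)[[1]]; if (m[1] == -1) 0L else length(m)
  }, integer(1)))
  expect_equal(nrow(calls), runs)
})

test_that("merging disjoint units concatenates and pads missing rows", {
  u1 <- mt_alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"), 1:10)
  u2 <- mt_alignment(c("a", "b"), c(strrep("G", 20), strrep("G", 20)), 11:30)
  merged <- merge_units(list(first = u1, second = u2), NULL)
  expect_equal(merged$ncols, 30L)
  expect_equal(merged$colmap, 1:30)

  u2b <- mt_alignment("a", strrep("G", 20), 11:30)
  merged <- merge_units(list(first = u1, second = u2b), NULL)
  expect_equal(substr(merged$rows[match("b", merged$ids)], 11, 30),
               strrep("?", 20))
  expect_equal(attr(merged, "padded")$id, "b")
})

test_that("overlap reconciliation keeps left columns and verifies residues", {
  # units 1..10 and 8..17 share reference positions 8..10
  u1 <- mt_alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGAAC"), 1:10)
  u2 <- mt_alignment(c("a", "b"), c("TACGGGGGGG", "AACGGGGGGG"), 8:17)
  merged <- merge_units(list(left = u1, right = u2), NULL)
  expect_equal(merged$ncols, 17L)
  expect_equal(gsub("[?-]", "", merged$rows[1]), "ACGTACGTACGGGGGGG")

  # disagreement in the shared interval is a hard error naming the pair
  u2bad <- mt_alignment(c("a", "b"), c("CCCGGGGGGG", "AACGGGGGGG"), 8:17)
  expect_error(merge_units(list(left = u1, right = u2bad), NULL),
               "'a'.*left.*right")
})

test_that("split-align-merge round trip is residue-exact", {
  for (seed in c(81, 82, 83)) {
    spec <- synth_spec(seed = seed, n_leaves = 8, indel_rate = 0.3)
    g <- generate_dataset(spec)
    aln <- partition_align(g$dataset, g$annotation)
    seqs <- g$dataset$sequences
    for (i in seq_len(nrow(seqs))) {
      row <- aln$rows[match(seqs$id[i], aln$ids)]
      expect_equal(gsub("[?-]", "", row), seqs$residues[i],
                   info = paste("seed", seed, seqs$id[i]))
    }
    # merged width is at least the reference span
    expect_gte(aln$ncols, nchar(g$annotation$reference))
    # indel calls partition all gap runs of the unit alignments
    ind <- attr(aln, "indels")
    expect_true(all(ind$kind %in% c("codon_full", "frameshift", "noncoding")))
  }
})
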