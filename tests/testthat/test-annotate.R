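test_that("conservation alpha uses the unambiguous, non-gap denominator", {
  aln <- mt_alignment(letters[1:4], c("A", "A", "A", "A"))
  p <- conservation_profile(aln)
  expect_equal(p$alpha, 1)
  expect_equal(p$depth, 4)

  aln <- mt_alignment(sprintf("s%02d", 1:10),
                      c(rep("A", 9), "C"))
  expect_equal(conservation_profile(aln)$alpha, 0.9)

  aln <- mt_alignment(letters[1:4], c("A", "A", "N", "-"))
  p <- conservation_profile(aln)
  expect_equal(p$alpha, 1)
  expect_equal(p$depth, 2)

  # all-gap column: alpha undefined, flagged as NA
  aln <- mt_alignment(letters[1:2], c("-A", "-A"))
  p <- conservation_profile(aln)
  expect_true(is.na(p$alpha[1]))
  expect_equal(p$alpha[2], 1)
})

test_that("Fitch labeling matches hand-worked small cases", {
  tr <- ape::read.tree(text = "((l1,l2),(l3,l4));")
  lab <- fitch_label(tr, mt_alignment(paste0("l", 1:4), c("A", "A", "A", "A")))
  expect_equal(lab$score, 0)
  expect_true(all(lab$states == "A"))

  lab <- fitch_label(tr, mt_alignment(paste0("l", 1:4), c("A", "C", "A", "G")))
  expect_equal(lab$score, 2)

  # ambiguity resolves implicitly: R contains A
  lab <- fitch_label(ape::read.tree(text = "((l1,l2),l3);"),
                     mt_alignment(paste0("l", 1:3), c("A", "A", "R")))
  expect_equal(lab$score, 0)

  expect_error(fitch_label(tr, mt_alignment("l1", "A")), "missing")
})

test_that("Fitch score equals the exhaustive minimum on random instances", {
  set.seed(121)
  alphabet <- c("A", "C", "G", "T", "-", "N", "R", "Y")
  for (trial in 1:60) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    ncols <- sample(1:4, 1)
    rows <- replicate(n, paste(sample(alphabet, ncols, TRUE), collapse = ""))
    aln <- mt_alignment(tr$tip.label, rows)
    lab <- fitch_label(tr, aln)
    oracle <- brute_fitch_score(tr, mtphylo:::.aln_masks(aln)[tr$tip.label, ,
                                                             drop = FALSE])
    expect_equal(lab$score, oracle, info = paste("trial", trial))
  }
})

test_that("events per column equal the column parsimony score", {
  set.seed(131)
  for (trial in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    rows <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), 12, TRUE),
                               collapse = ""))
    aln <- mt_alignment(tr$tip.label, rows)
    lab <- fitch_label(tr, aln)
    ev <- extract_events(lab, aln)
    per_col <- table(factor(ev$column, levels = 1:12))
    expect_equal(as.numeric(per_col), lab$per_column_score)
    expect_equal(nrow(ev), lab$score)
    expect_true(all(ev$from != ev$to))
  }

  # zero-change labeling yields no events
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  aln <- mt_alignment(c("a", "b", "c", "d"), rep("ACGT", 4))
  expect_equal(nrow(extract_events(fitch_label(tr, aln), aln)), 0L)
})

test_that("back-mutations are recognized along the root path", {
  # caterpillar (((l1,l2),l3),l4) with column states A,C,A at the marked
  # leaves forces root A -> x C -> leaf A restoration
  tr <- ape::read.tree(text = "(((l1,l2),l3),l4);")
  aln <- mt_alignment(paste0("l", 1:4), c("A", "C", "C", "C"))
  lab <- fitch_label(tr, aln)
  prof <- conservation_profile(aln)
  ev <- flag_events(extract_events(lab, aln), lab, prof)
  # root resolves to C; the branch into l1 carries C -> A
  expect_equal(nrow(ev), 1L)
  expect_false(any(ev$back_mutation))

  # an explicit restoration: states change A -> C -> A down one path
  tr2 <- caterpillar(c("x4", "x3", "x2", "x1"))  # ((((x4,x3),x2),x1)
  aln2 <- mt_alignment(c("x1", "x2", "x3", "x4"), c("A", "C", "C", "A"))
  lab2 <- fitch_label(tr2, aln2)
  ev2 <- flag_events(extract_events(lab2, aln2), lab2,
                     conservation_profile(aln2))
  expect_equal(sum(ev2$back_mutation), 1L)
  restored <- ev2[ev2$back_mutation, ]
  expect_equal(restored$to, "A")

  # no back-mutation when the change moves to a third state
  aln3 <- mt_alignment(c("x1", "x2", "x3", "x4"), c("A", "C", "C", "G"))
  lab3 <- fitch_label(tr2, aln3)
  ev3 <- flag_events(extract_events(lab3, aln3), lab3,
                     conservation_profile(aln3))
  expect_false(any(ev3$back_mutation))

  # root-state-only scope is stricter than path scope
  ev2root <- flag_events(extract_events(lab2, aln2), lab2,
                         conservation_profile(aln2), scope = "root")
  expect_lte(sum(ev2root$back_mutation), sum(ev2$back_mutation))
})

test_that("conserved and indel flags follow their definitions", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  rows <- c("AAAAAAAAAAC", "AAAAAAAAAAA", "AAAAAAAAAAA", "AAAAAAAAAA-")
  aln <- mt_alignment(c("a", "b", "c", "d"), rows)
  lab <- fitch_label(tr, aln)
  prof <- conservation_profile(aln)
  # the variant column has alpha 2/3: conserved at a 0.5 threshold only
  ev <- flag_events(extract_events(lab, aln), lab, prof,
                    alpha_threshold = 0.5)
  expect_true(all(ev$conserved))
  ev95 <- flag_events(extract_events(lab, aln), lab, prof,
                      alpha_threshold = 0.95)
  expect_false(any(ev95$conserved))
  expect_true(any(ev$indel))
  expect_true(all(ev$indel == (ev$from == "-" | ev$to == "-")))
})

test_that("events into ambiguous leaf symbols carry the ambiguity flag", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  aln <- mt_alignment(c("a", "b", "c", "d"), c("Y", "A", "A", "A"))
  lab <- fitch_label(tr, aln)
  ev <- flag_events(extract_events(lab, aln), lab,
                    conservation_profile(aln))
  expect_equal(nrow(ev), 1L)
  expect_true(ev$ambiguous)
  expect_equal(ev$to_code, "Y")

  # plain polymorphic columns are not ambiguous
  aln2 <- mt_alignment(c("a", "b", "c", "d"), c("A", "A", "C", "C"))
  lab2 <- fitch_label(tr, aln2)
  ev2 <- flag_events(extract_events(lab2, aln2), lab2,
                     conservation_profile(aln2))
  expect_false(any(ev2$ambiguous))
})

test_that("cross-tab identities hold for arbitrary flag sets", {
  set.seed(141)
  for (trial in 1:50) {
    n <- sample(0:60, 1)
    ev <- data.frame(parent = rep(9L, n), child = rep(1L, n),
                     column = seq_len(n), ref_pos = seq_len(n),
                     from = rep("A", n), to = rep("C", n),
                     from_code = rep("A", n), to_code = rep("C", n),
                     conserved = sample(c(TRUE, FALSE), n, TRUE),
                     back_mutation = sample(c(TRUE, FALSE), n, TRUE),
                     ambiguous = sample(c(TRUE, FALSE), n, TRUE),
                     indel = sample(c(TRUE, FALSE), n, TRUE))
    tab <- crosstab(ev)
    for (r in rownames(tab))
      expect_equal(tab[r, "total"],
                   category_total(tab[r, "conserved"], tab[r, "back_mutation"],
                                  tab[r, "conserved_bm"], tab[r, "remaining"]))
    expect_equal(tab["unambiguous", "total"] + tab["ambiguous", "total"],
                 tab["total", "total"])
    expect_equal(tab["total", "total"], n)
    for (cl in colnames(tab))
      expect_equal(tab["total", cl],
                   tab["unambiguous", cl] + tab["ambiguous", cl])
  }
  expect_true(all(crosstab(ev[0, ]) == 0))
})

test_that("branch statistics count, flag and conserve totals", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  aln <- mt_alignment(c("a", "b", "c", "d"),
                      c("CAAA", "ACAA", "AACA", "AAAC"))
  lab <- fitch_label(star, aln)
  ev <- extract_events(lab, aln)
  bs <- branch_stats(ev, star)
  expect_true(all(bs$per_branch$count == 1L))
  expect_length(bs$outliers, 0L)
  expect_equal(sum(bs$per_branch$count), nrow(ev))

  # a planted divergent leaf exceeds the review threshold on its pendant edge
  spec <- synth_spec(seed = 151, n_leaves = 12, n_outlier = 1L)
  g <- generate_dataset(spec)
  ds <- g$dataset$sequences
  aln <- mt_alignment(ds$id, ds$residues)
  rooted <- root_by_outgroup(neighbor_joining(distance_matrix(aln)),
                             ds$id[1])
  ann <- annotate_tree(rooted, aln)
  bad <- g$registry$id[g$registry$defect == "divergent"]
  out_tips <- rooted$tip.label[ann$branch$outliers[
    ann$branch$outliers <= length(rooted$tip.label)]]
  expect_true(bad %in% out_tips)
})

test_that("generation points count distinct branches per mutation type", {
  ev <- data.frame(parent = c(9, 9, 10, 10, 11), child = c(1, 2, 3, 4, 5),
                   column = c(1, 1, 1, 2, 2), ref_pos = NA,
                   from = c("A", "A", "A", "C", "C"),
                   to = c("G", "G", "G", "T", "A"),
                   from_code = "A", to_code = "G",
                   conserved = FALSE, back_mutation = FALSE,
                   ambiguous = FALSE, indel = FALSE)
  by_pos <- generation_points(ev, "by_position")
  by_full <- generation_points(ev, "by_position_and_states")
  expect_equal(sort(by_pos$counts$generation_points, TRUE), c(3L, 2L))
  # the same A->G at one column on 3 branches counts 3 under both groupings
  expect_equal(by_full$counts$generation_points[
    by_full$counts$mutation == "1:A>G"], 3L)
  # by_position is never finer than by_position_and_states
  for (col in unique(ev$column)) {
    p <- by_pos$counts$generation_points[by_pos$counts$mutation == col]
    f <- sum(by_full$counts$generation_points[
      grepl(paste0("^", col, ":"), by_full$counts$mutation)])
    expect_gte(f, p)
  }
})

test_that("the perfect-phylogeny bound is sharp without homoplasy", {
  expect_equal(perfect_phylogeny_bound(
    mt_alignment(c("a", "b"), c("ACGT", "ACGT"))), 0L)
  expect_equal(perfect_phylogeny_bound(
    mt_alignment(c("a", "b", "c"), c("A", "C", "G"))), 2L)
  # ambiguity codes are suppressed; gap is a symbol
  expect_equal(perfect_phylogeny_bound(
    mt_alignment(c("a", "b", "c"), c("A", "N", "-"))), 1L)

  set.seed(161)
  for (trial in 1:40) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    rows <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), 10, TRUE),
                               collapse = ""))
    aln <- mt_alignment(tr$tip.label, rows)
    expect_lte(perfect_phylogeny_bound(aln), fitch_label(tr, aln)$score)
  }
})

test_that("summary rates reproduce simple ratios and handle empties", {
  r <- summary_rates(67900, 7390, 16832)
  expect_equal(r$per_leaf, 9.19)
  expect_equal(r$per_character, 4.03)
  expect_equal(summary_rates(0, 10, 10)$per_leaf, 0)
  expect_error(summary_rates(10, 0, 5), "positive")
})

test_that("a leaf ambiguity only perturbs states on its own pendant path", {
  set.seed(171)
  for (trial in 1:15) {
    n <- 8
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    rows <- replicate(n, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                               collapse = ""))
    aln <- mt_alignment(tr$tip.label, rows)
    lab0 <- fitch_label(tr, aln)
    victim <- sample(n, 1)
    rows2 <- rows
    substr(rows2[victim], 3, 3) <- "N"
    lab1 <- fitch_label(tr, mt_alignment(tr$tip.label, rows2))
    # candidate sets can differ only on the victim's root path: no other
    # node's bottom-up inputs change
    par <- mtphylo:::.parents(tr)
    path <- victim
    node <- victim
    while (par[node] != 0L) { node <- par[node]; path <- c(path, node) }
    changed_sets <- which(lab0$sets[, 3] != lab1$sets[, 3])
    expect_true(all(changed_sets %in% path), info = paste("trial", trial))
    # widening a leaf's state set can never raise the parsimony score
    expect_lte(lab1$score, lab0$score)
  }
})
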