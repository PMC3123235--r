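# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive global-alignment cost: enumerate every alignment of a and b
# by recursion over (consume a, consume b, consume both); linear gap costs
brute_align_cost <- function(a, b, match = 0, mismatch = 1, gap = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(av) && j > length(bv)) 0
    else {
      best <- Inf
      if (i <= length(av) && j <= length(bv)) {
        sub <- if (av[i] == bv[j]) match else mismatch
        best <- min(best, sub + rec(i + 1L, j + 1L))
      }
      if (i <= length(av)) best <- min(best, gap + rec(i + 1L, j))
      if (j <= length(bv)) best <- min(best, gap + rec(i, j + 1L))
      best
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L)
}

# exhaustive Fitch parsimony score: minimize total state changes over every
# assignment of internal-node states; leaves are free within their symbol
# sets (an edge into a leaf is free iff the parent state is in the set)
brute_fitch_score <- function(tree, leaf_masks) {
  ntip <- length(tree$tip.label)
  states <- c(1L, 2L, 4L, 8L, 16L)
  grid <- as.matrix(do.call(expand.grid, rep(list(states), tree$Nnode)))
  edges <- tree$edge
  total <- 0L
  for (col in seq_len(ncol(leaf_masks))) {
    lm <- leaf_masks[, col]
    cost <- integer(nrow(grid))
    for (e in seq_len(nrow(edges))) {
      p <- grid[, edges[e, 1] - ntip]
      child <- edges[e, 2]
      cost <- cost + if (child <= ntip) {
        as.integer(bitwAnd(lm[child], p) == 0L)
      } else {
        as.integer(grid[, child - ntip] != p)
      }
    }
    total <- total + min(cost)
  }
  total
}

# frequency of a split (given as a tip-label subset) among unrooted trees
split_frequency <- function(trees, side, all_tips) {
  key <- function(s) paste(sort(s), collapse = "|")
  anchor <- min(all_tips)
  target <- key(if (anchor %in% side) setdiff(all_tips, side) else side)
  hits <- vapply(trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    any(vapply(pp, function(cl) {
      tips <- labs[cl]
      s <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
      key(s) == target
    }, logical(1)))
  }, logical(1))
  mean(hits)
}

# small rooted caterpillar tree over given labels
caterpillar <- function(labels) {
  nwk <- labels[1]
  for (l in labels[-1]) nwk <- paste0("(", nwk, ",", l, ")")
  ape::read.tree(text = paste0(nwk, ";"))
}

tiny_annotation <- function() {
  # 60 bp reference: CR1 1..6, gene1 7..24 (coding), gap1 25..30,
  # gene2 31..48 (coding), CR2 49..60
  ref <- "ACGTACGGATCCGATTACAGGCTATTTACCGGATCAGGCATCGATCGGATATCCGGAATT"
  units <- data.frame(
    name = c("CR1", "gene1", "gap1", "gene2", "CR2"),
    kind = c("control_region_part", "gene", "noncoding_gap", "gene",
             "control_region_part"),
    start = c(1L, 7L, 25L, 31L, 49L),
    end = c(6L, 24L, 30L, 48L, 60L),
    coding = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    frame = 0L, stringsAsFactors = FALSE)
  mt_annotation("tinyref", ref, units, circular = TRUE)
}
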