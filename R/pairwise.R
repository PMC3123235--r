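# Global pairwise alignment, parsimony edit distances, distance matrices,
# group-wise outlier detection and circular start-point correction.

#' Scoring scheme for global alignment (distance orientation)
#'
#' All penalties are nonnegative costs; a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`. The default (match 0, mismatch 1,
#' gap 1 linear) makes the optimal alignment score equal the per-column
#' parsimony edit distance; the affine preset `scoring_scheme(gap_open = 3)`
#' approximates treating each indel as a single event.
#'
#' @param match,mismatch,gap_open,gap_extend nonnegative costs.
#' @param indel_mode how downstream distance computations count gap runs.
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 0, mismatch = 1, gap_open = 1,
                           gap_extend = 1,
                           indel_mode = c("per_column", "single_event")) {
  stopifnot(mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 indel_mode = match.arg(indel_mode)),
            class = "scoring_scheme")
}

# substitution matrix over the IUPAC alphabet: intersecting symbol sets
# cost `match`, disjoint sets cost `mismatch` (negated for maximization)
.subst_matrix <- function(scoring) {
  syms <- .RAW_ALPHABET
  masks <- symbol_to_mask(syms)
  m <- outer(masks, masks, function(a, b) bitwAnd(a, b) > 0L)
  mat <- ifelse(m, -scoring$match, -scoring$mismatch)
  dimnames(mat) <- list(syms, syms)
  mat
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under the (affine) cost scheme,
#' computed with `Biostrings::pairwiseAlignment`. Columns whose IUPAC
#' symbol sets intersect are treated as matches.
#'
#' @param a,b nonempty residue strings.
#' @param scoring a [scoring_scheme].
#' @return list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score` (the total
#'   alignment cost; smaller is closer).
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  .global_align_many(a, b, scoring)[[1]]
}

# batched global alignment of many patterns against one subject (one
# Biostrings call; far cheaper than per-pair S4 dispatch). The clipped
# core strings from pattern()/subject() are completed with the end
# overhangs, which Biostrings represents outside the aligned range.
.global_align_many <- function(patterns, subject, scoring = scoring_scheme()) {
  patterns <- toupper(chartr("Uu", "TT", patterns))
  subject <- toupper(chartr("Uu", "TT", subject))
  if (any(!nzchar(patterns)) || !nzchar(subject))
    stop("sequences must be nonempty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend,
    type = "global")
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  core_a <- as.character(pat); core_b <- as.character(sub)
  ps <- Biostrings::start(pat); pe <- Biostrings::end(pat)
  ss <- Biostrings::start(sub); se <- Biostrings::end(sub)
  sc <- -as.numeric(Biostrings::score(pa))
  nb <- nchar(subject)
  out <- lapply(seq_along(patterns), function(i) {
    lead_a <- substr(patterns[i], 1L, ps[i] - 1L)
    lead_b <- substr(subject, 1L, ss[i] - 1L)
    trail_a <- substr(patterns[i], pe[i] + 1L, nchar(patterns[i]))
    trail_b <- substr(subject, se[i] + 1L, nb)
    structure(list(
      aligned_a = paste0(lead_a, strrep("-", nchar(lead_b)), core_a[i],
                         trail_a, strrep("-", nchar(trail_b))),
      aligned_b = paste0(strrep("-", nchar(lead_a)), lead_b, core_b[i],
                         strrep("-", nchar(trail_a)), trail_b),
      score = sc[i]), class = "pairwise_alignment")
  })
  names(out) <- names(patterns)
  out
}

# maximal runs of '-' in a gapped row: data.frame(start, length)
.gap_runs <- function(row) {
  m <- gregexpr("-+", row)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), length = integer()))
  data.frame(start = as.integer(m), length = attr(m, "match.length"))
}

#' Parsimony edit distance between two aligned rows
#'
#' `per_column` counts columns whose symbols differ (IUPAC sets disjoint)
#' and are not both gaps; `single_event` counts substitution columns plus
#' one event per maximal gap run. Unsequenced padding (`?`) never
#' contributes.
#'
#' @param row_a,row_b equal-length gapped rows, or a `pairwise_alignment`.
#' @param indel_mode `"per_column"` or `"single_event"`.
#' @return a number.
#' @export
edit_distance <- function(row_a, row_b = NULL,
                          indel_mode = c("per_column", "single_event")) {
  if (inherits(row_a, "pairwise_alignment")) {
    row_b <- row_a$aligned_b; row_a <- row_a$aligned_a
  }
  indel_mode <- match.arg(indel_mode)
  if (nchar(row_a) != nchar(row_b)) stop("aligned rows differ in length")
  ma <- symbol_to_mask(strsplit(row_a, "")[[1]])
  mb <- symbol_to_mask(strsplit(row_b, "")[[1]])
  differ <- bitwAnd(ma, mb) == 0L
  if (indel_mode == "per_column") return(sum(differ))
  gap_a <- ma == 16L; gap_b <- mb == 16L
  subs <- sum(differ & !gap_a & !gap_b)
  runs <- function(g, other_mask) {
    # a maximal run of gaps facing sequence (not padding) = one event
    r <- rle(g & bitwAnd(other_mask, 16L) == 0L & other_mask != 31L)
    sum(r$values)
  }
  subs + runs(gap_a, mb) + runs(gap_b, ma)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln an [mt_alignment] with at least two rows.
#' @param indel_mode passed to the per-pair distance.
#' @param skip_ambiguous drop, for each pair, the columns where either row
#'   carries an ambiguity symbol (restriction "to unambiguous sequences").
#' @param columns optional column subset (e.g. coding-region columns for
#'   comparability with control-region-missing rows).
#' @return square symmetric numeric matrix with zero diagonal, labelled by
#'   row ids.
#' @export
distance_matrix <- function(aln, indel_mode = c("per_column", "single_event"),
                            skip_ambiguous = FALSE, columns = NULL) {
  indel_mode <- match.arg(indel_mode)
  n <- length(aln$ids)
  if (n < 2L) stop("distance matrix needs at least 2 rows")
  M <- .aln_masks(aln)
  if (!is.null(columns)) M <- M[, columns, drop = FALSE]
  ambig <- matrix(FALSE, n, ncol(M))
  if (skip_ambiguous) {
    pop <- function(x) (bitwAnd(x, 1L) > 0) + (bitwAnd(x, 2L) > 0) +
      (bitwAnd(x, 4L) > 0) + (bitwAnd(x, 8L) > 0) + (bitwAnd(x, 16L) > 0)
    ambig <- matrix(pop(M) > 1L, n, ncol(M))
  }
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- !(ambig[i, ] | ambig[j, ])
    a <- M[i, keep]; b <- M[j, keep]
    if (indel_mode == "per_column") {
      d[i, j] <- d[j, i] <- sum(bitwAnd(a, b) == 0L)
    } else {
      differ <- bitwAnd(a, b) == 0L
      ga <- a == 16L; gb <- b == 16L
      subs <- sum(differ & !ga & !gb)
      ev <- function(g, o) {
        r <- rle(g & bitwAnd(o, 16L) == 0L & o != 31L); sum(r$values)
      }
      d[i, j] <- d[j, i] <- subs + ev(ga, b) + ev(gb, a)
    }
  }
  d
}

#' Group-wise distance outliers
#'
#' Within each labelled group (of at least 3 members), a sequence is
#' flagged when its median intra-group distance exceeds the group median of
#' those medians by more than `k` robust spreads. Because parsimony
#' distances are counts, tightly clustered groups can drive the MAD below
#' the counting-noise scale; the spread is therefore floored at
#' `sqrt(median)` (the Poisson scale) so that only genuinely divergent
#' sequences are flagged. A between-group separation report (minimum
#' inter-group vs maximum intra-group distance) accompanies the flags.
#'
#' @param d distance matrix with id dimnames.
#' @param groups named character vector: id -> group label.
#' @param k robust multiplier (default 5).
#' @return list with `flagged` (ids), `per_group` medians table,
#'   `small_groups` (groups too small to score) and `separation`.
#' @export
group_outliers <- function(d, groups, k = 5) {
  ids <- rownames(d)
  if (is.null(names(groups))) names(groups) <- ids
  if (!all(ids %in% names(groups))) stop("every id must be labelled")
  flagged <- character()
  per_group <- list()
  small <- character()
  for (g in unique(groups[ids])) {
    mem <- ids[groups[ids] == g]
    if (length(mem) < 3L) { small <- c(small, g); next }
    sub <- d[mem, mem, drop = FALSE]
    med <- vapply(seq_along(mem),
                  function(i) stats::median(sub[i, -i]), numeric(1))
    names(med) <- mem
    ctr <- stats::median(med)
    spread <- max(stats::mad(med), sqrt(max(ctr, 1)))
    thr <- ctr + k * spread
    flagged <- c(flagged, mem[med > thr])
    per_group[[g]] <- data.frame(id = mem, median_distance = med,
                                 threshold = thr, row.names = NULL)
  }
  gl <- unique(groups[ids])
  separation <- NULL
  if (length(gl) > 1L) {
    intra <- max(unlist(lapply(gl, function(g) {
      mem <- ids[groups[ids] == g]
      if (length(mem) < 2L) return(0)
      max(d[mem, mem])
    })))
    inter <- min(unlist(lapply(utils::combn(gl, 2, simplify = FALSE),
                               function(p) {
      min(d[ids[groups[ids] == p[1]], ids[groups[ids] == p[2]]])
    })))
    separation <- list(max_intra = intra, min_inter = inter,
                       separated = inter > intra)
  }
  list(flagged = sort(unique(flagged)), per_group = per_group,
       small_groups = small, separation = separation)
}

# positional identity of two strings over their common prefix length
.identity_frac <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  mean(av == bv)
}

.rotate_left <- function(s, o) {
  n <- nchar(s); o <- o %% n
  if (o == 0L) return(s)
  paste0(substr(s, o + 1L, n), substr(s, 1L, o))
}

#' Detect a circular start-point displacement
#'
#' A circular genome linearized at a non-canonical point places canonical
#' position 1 in the middle of the string. Candidate displacements are
#' collected by k-mer seeding against the reference and verified by
#' ungapped positional identity of the corresponding rotation; the best
#' offset is reported only when its identity beats the unrotated identity
#' by at least `margin`.
#'
#' @param residues sequence string (length within ~20% of the reference).
#' @param reference reference residue string.
#' @param k seed k-mer length (default 12).
#' @param margin minimal identity improvement over offset 0 (default 0.05).
#' @param step spacing of sampled reference seeds.
#' @return integer displacement (`0` means no rotation detected).
#' @export
detect_rotation <- function(residues, reference, k = 12L, margin = 0.05,
                            step = 37L) {
  n <- nchar(residues); m <- nchar(reference)
  if (abs(n - m) > 0.2 * m) stop("sequence and reference lengths differ by >20%")
  if (n <= k) return(0L)
  seq_kmers <- substring(residues, 1:(n - k + 1L), k:n)
  kmer_pos <- split(seq_len(n - k + 1L), seq_kmers)
  offsets <- integer()
  for (p in seq(1L, m - k + 1L, by = step)) {
    km <- substr(reference, p, p + k - 1L)
    qs <- kmer_pos[[km]]
    if (is.null(qs) || length(qs) > 4L) next   # skip repetitive seeds
    offsets <- c(offsets, (p - qs) %% n)
  }
  if (!length(offsets)) return(0L)
  votes <- sort(table(offsets), decreasing = TRUE)
  cand <- as.integer(names(votes))[seq_len(min(3L, length(votes)))]
  cand <- unique(c(cand, 0L))
  id <- vapply(cand, function(o)
    .identity_frac(.rotate_left(residues, (n - o) %% n), reference), numeric(1))
  id0 <- id[match(0L, cand)]
  best <- cand[which.max(id)]
  if (best == 0L || max(id) - id0 < margin) return(0L)
  best
}

#' Correct a start-point displacement
#'
#' Rotates the residues so canonical position 1 leads; the inverse of
#' rotating left by `offset`.
#'
#' @param residues sequence string.
#' @param offset displacement returned by [detect_rotation].
#' @return the corrected residue string.
#' @export
correct_rotation <- function(residues, offset) {
  n <- nchar(residues)
  stopifnot(offset >= 0L, offset < n)
  .rotate_left(residues, (n - offset) %% n)
}
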