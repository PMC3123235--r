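# Generalized Fitch parsimony labeling, per-branch mutation events with
# classification (conservation, back-mutation, ambiguity, indel), tree
# statistics and tree-driven outlier detection.

#' Per-column conservation profile
#'
#' For every column, the dominant fraction alpha is the count of the most
#' frequent unambiguous, non-gap base divided by the effective depth (the
#' number of rows carrying an unambiguous base there). Columns with zero
#' effective depth have undefined alpha (NA, flagged). Optionally the
#' denominator can count all rows instead.
#'
#' @param aln an [mt_alignment] with at least 2 rows.
#' @param denominator `"unambiguous"` (default) or `"all_rows"`.
#' @return list of class `conservation_profile`: `alpha`, `dominant`,
#'   `depth` (per column), `mean_alpha`, `sd_alpha` (over defined columns).
#' @export
conservation_profile <- function(aln, denominator = c("unambiguous", "all_rows")) {
  denominator <- match.arg(denominator)
  if (length(aln$ids) < 2L) stop("conservation profile needs >= 2 rows")
  m <- .aln_matrix(aln)
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, c("A", "C", "G", "T")))
  depth <- rowSums(counts)
  top <- apply(counts, 1L, max)
  dominant <- c("A", "C", "G", "T")[apply(counts, 1L, which.max)]
  denom <- if (denominator == "unambiguous") depth else rep(nrow(m), ncol(m))
  alpha <- ifelse(depth > 0, top / denom, NA_real_)
  dominant[depth == 0] <- NA_character_
  structure(list(alpha = alpha, dominant = dominant, depth = depth,
                 mean_alpha = mean(alpha, na.rm = TRUE),
                 sd_alpha = stats::sd(alpha, na.rm = TRUE)),
            class = "conservation_profile")
}

# parent of every node (0 for the root) from a phylo edge table
.parents <- function(tree) {
  ntip <- length(tree$tip.label)
  p <- integer(ntip + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Generalized Fitch parsimony labeling of a tree
#'
#' Bottom-up pass: an internal node's candidate set is the intersection of
#' its children's sets when nonempty, else their union at the cost of one
#' change. Top-down pass: the root resolves to the first member of its set
#' in the fixed order A < C < G < T < `-`; every child resolves to its
#' parent's state when that state is in its set, else to its own first
#' member. Leaf IUPAC codes expand to base subsets, `N` to all four bases,
#' `-` is a fifth character state, and unsequenced padding `?` expands to
#' the full five-state set (it can never force a change). The total score
#' is the minimum number of state changes over the tree.
#'
#' @param tree a rooted `ape::phylo` tree whose tip labels are alignment
#'   row ids. Polytomies are folded child-by-child in label order.
#' @param aln an [mt_alignment] covering every leaf.
#' @return list of class `fitch_labeling`: `tree`, `sets` (bitmask matrix,
#'   nodes x columns), `states` (resolved character matrix), `score`,
#'   `per_column_score`.
#' @export
fitch_label <- function(tree, aln) {
  ntip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, aln$ids)
  if (length(missing)) stop("leaves missing from the alignment: ",
                            paste(missing, collapse = ", "))
  nnode <- ntip + tree$Nnode
  ncols <- aln$ncols
  M <- .aln_masks(aln)
  S <- matrix(0L, nnode, ncols)
  S[seq_len(ntip), ] <- M[match(tree$tip.label, aln$ids), , drop = FALSE]
  changes <- numeric(ncols)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    acc <- S[parent, ]; ch <- S[child, ]
    first <- acc == 0L
    inter <- bitwAnd(acc, ch)
    un <- bitwOr(acc, ch)
    newacc <- ifelse(first, ch, ifelse(inter > 0L, inter, un))
    changes <- changes + (!first & inter == 0L)
    S[parent, ] <- newacc
  }
  # top-down resolution
  states <- matrix(NA_character_, nnode, ncols)
  root <- ntip + 1L
  rootbits <- .lowest_bit(S[root, ])
  res_bits <- matrix(0L, nnode, ncols)
  res_bits[root, ] <- rootbits
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]; child <- pre[e, 2]
    pb <- res_bits[parent, ]
    keep <- bitwAnd(S[child, ], pb) > 0L
    res_bits[child, ] <- ifelse(keep, pb, .lowest_bit(S[child, ]))
  }
  states[] <- .mask_to_state[as.character(res_bits)]
  structure(list(tree = tree, sets = S, states = states,
                 score = sum(changes), per_column_score = changes),
            class = "fitch_labeling")
}

#' Extract mutation events from a labeling
#'
#' One event per branch per column where the parent's and child's resolved
#' states differ. Event endpoints are reported both as resolved states
#' (`from`, `to`) and as codes (`from_code`, `to_code`) that expose
#' ambiguity: a leaf endpoint keeps its observed IUPAC symbol, so an event
#' into an ambiguously sequenced position is visibly ambiguous, while
#' internal endpoints are resolved concrete states.
#'
#' @param labeling a [fitch_label] result.
#' @param aln optional alignment supplying reference positions via its
#'   colmap.
#' @return data frame with columns `parent`, `child`, `column`, `ref_pos`,
#'   `from`, `to`, `from_code`, `to_code` and all-FALSE flag columns
#'   `conserved`, `back_mutation`, `ambiguous`, `indel`.
#' @export
extract_events <- function(labeling, aln = NULL) {
  tree <- labeling$tree
  st <- labeling$states
  out <- list()
  ntip <- length(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    cols <- which(st[parent, ] != st[child, ])
    if (!length(cols)) next
    to_code <- if (child <= ntip)
      .mask_to_code(labeling$sets[child, cols]) else st[child, cols]
    out[[length(out) + 1L]] <- data.frame(
      parent = parent, child = child, column = cols,
      from = st[parent, cols], to = st[child, cols],
      from_code = st[parent, cols], to_code = to_code,
      stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(parent = integer(), child = integer(), column = integer(),
               from = character(), to = character(),
               from_code = character(), to_code = character(),
               stringsAsFactors = FALSE)
  ev$ref_pos <- if (!is.null(aln) && !is.null(aln$colmap))
    aln$colmap[ev$column] else rep(NA_integer_, nrow(ev))
  ev$conserved <- ev$back_mutation <- ev$ambiguous <- ev$indel <-
    rep(FALSE, nrow(ev))
  rownames(ev) <- NULL
  ev[, c("parent", "child", "column", "ref_pos", "from", "to",
         "from_code", "to_code", "conserved", "back_mutation", "ambiguous",
         "indel")]
}

#' Classify mutation events
#'
#' Sets the four flags: `conserved` when the column's dominant fraction
#' exceeds `alpha_threshold`; `back_mutation` when, at the same column,
#' some earlier event on the root-to-branch path replaced the state this
#' event restores (`scope = "path"`, default) or when the event restores
#' the root's state (`scope = "root"`); `indel` when either resolved state
#' is a gap; `ambiguous` when either endpoint's candidate set is not a
#' single concrete state (the event involves an ambiguous position).
#'
#' @param events from [extract_events].
#' @param labeling the [fitch_label] result the events came from.
#' @param profile a [conservation_profile] of the same alignment.
#' @param alpha_threshold conservation cutoff (default 0.95).
#' @param scope back-mutation definition, `"path"` or `"root"`.
#' @return the events data frame with flags filled in.
#' @export
flag_events <- function(events, labeling, profile,
                        alpha_threshold = 0.95, scope = c("path", "root")) {
  scope <- match.arg(scope)
  if (!nrow(events)) return(events)
  alpha <- profile$alpha[events$column]
  events$conserved <- !is.na(alpha) & alpha > alpha_threshold
  events$indel <- events$from == "-" | events$to == "-"
  single <- c("A", "C", "G", "T", "-")
  events$ambiguous <- !(events$from_code %in% single) |
    !(events$to_code %in% single)

  par <- .parents(labeling$tree)
  ntip <- length(labeling$tree$tip.label)
  root <- ntip + 1L
  # events indexed by (child, column) for path walking
  key <- paste(events$child, events$column)
  from_by_key <- stats::setNames(events$from, key)
  for (i in seq_len(nrow(events))) {
    if (scope == "root") {
      events$back_mutation[i] <-
        events$to[i] == labeling$states[root, events$column[i]] &&
        events$from[i] != events$to[i]
      next
    }
    node <- events$parent[i]
    while (node != root && node != 0L) {
      f <- from_by_key[paste(node, events$column[i])]
      if (!is.na(f) && f == events$to[i]) {
        events$back_mutation[i] <- TRUE
        break
      }
      node <- par[node]
    }
  }
  events
}

#' Cross-tabulated mutation statistics
#'
#' Rows: `unambiguous` (events without the ambiguity flag), `ungapped`
#' (the unambiguous events without the indel flag, a sub-row), `ambiguous`,
#' and their total. Columns: `conserved`, `back_mutation`, their
#' intersection, `remaining` (neither) and the row total, which satisfies
#' the inclusion-exclusion identity
#' `total = conserved + back_mutation - both + remaining`.
#'
#' @param events flagged events from [flag_events].
#' @return integer matrix of class `mutation_crosstab` (4 rows x 5 columns).
#' @export
crosstab <- function(events) {
  cells <- function(sub) {
    cons <- sum(sub$conserved)
    back <- sum(sub$back_mutation)
    both <- sum(sub$conserved & sub$back_mutation)
    rem <- sum(!sub$conserved & !sub$back_mutation)
    c(conserved = cons, back_mutation = back, conserved_bm = both,
      remaining = rem, total = cons + back - both + rem)
  }
  unamb <- events[!events$ambiguous, , drop = FALSE]
  tab <- rbind(
    unambiguous = cells(unamb),
    ungapped = cells(unamb[!unamb$indel, , drop = FALSE]),
    ambiguous = cells(events[events$ambiguous, , drop = FALSE]))
  tab <- rbind(tab, total = tab["unambiguous", ] + tab["ambiguous", ])
  structure(tab, class = c("mutation_crosstab", class(tab)))
}

#' Row total of a mutation category cross-tab
#'
#' The inclusion-exclusion identity relating the four category counts of a
#' cross-tab row to its total.
#'
#' @param conserved,back_mutation,both,remaining category counts (`both` =
#'   conserved back-mutations).
#' @return `conserved + back_mutation - both + remaining`.
#' @export
category_total <- function(conserved, back_mutation, both, remaining) {
  conserved + back_mutation - both + remaining
}

#' Category shares of a cross-tab
#'
#' Percentage of all events that are ambiguous, affect conserved positions,
#' or are back-mutations, as printed in mutation-statistics reports.
#'
#' @param tab a [crosstab] result.
#' @param digits rounding for the report (default 2).
#' @return named numeric vector (`pct_ambiguous`, `pct_conserved`,
#'   `pct_back_mutation`).
#' @export
mutation_shares <- function(tab, digits = 2L) {
  total <- tab["total", "total"]
  round(c(pct_ambiguous = 100 * tab["ambiguous", "total"] / total,
          pct_conserved = 100 * tab["total", "conserved"] / total,
          pct_back_mutation = 100 * tab["total", "back_mutation"] / total),
        digits)
}

#' Per-branch event counts and outliers
#'
#' Histogram of events per branch (including empty branches), the fraction
#' of empty branches, and flags for branches carrying more than `threshold`
#' events — in curated data such nodes are almost always single divergent
#' leaves and should be reviewed.
#'
#' @param events flagged events.
#' @param tree the annotated tree.
#' @param threshold review threshold (default 50).
#' @return list with `per_branch` (data frame parent/child/count/outlier),
#'   `empty_fraction`, `outliers` (child node ids), `mean`, `sd`.
#' @export
branch_stats <- function(events, tree, threshold = 50L) {
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
  cnt <- table(factor(events$child, levels = edges$child))
  edges$count <- as.integer(cnt[as.character(edges$child)])
  edges$outlier <- edges$count > threshold
  list(per_branch = edges,
       empty_fraction = mean(edges$count == 0L),
       outliers = edges$child[edges$outlier],
       mean = mean(edges$count), sd = stats::sd(edges$count))
}

#' Generation points per mutation type
#'
#' A mutation type is an alignment position (`by_position`) or a position
#' plus its from/to states (`by_position_and_states`); its generation
#' points are the distinct branches on which it arises. More than one
#' generation point indicates homoplasy.
#'
#' @param events flagged events.
#' @param grouping `"by_position"` or `"by_position_and_states"`.
#' @return list with `counts` (data frame mutation/generation_points) and
#'   `histogram` (table of generation-point counts).
#' @export
generation_points <- function(events,
                              grouping = c("by_position",
                                           "by_position_and_states")) {
  grouping <- match.arg(grouping)
  key <- if (grouping == "by_position") as.character(events$column)
  else paste0(events$column, ":", events$from, ">", events$to)
  branch <- paste(events$parent, events$child)
  counts <- vapply(split(branch, key), function(b) length(unique(b)),
                   integer(1))
  df <- data.frame(mutation = names(counts),
                   generation_points = as.integer(counts),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(counts = df, histogram = table(df$generation_points))
}

#' Perfect-phylogeny lower bound on mutation events
#'
#' Sum over columns of (number of distinct unambiguous symbols - 1), with
#' gap counted as a symbol and ambiguity codes (and unsequenced padding)
#' suppressed. A perfect phylogeny gives every occurring symbol a single
#' generation point except the root's, so no tree can need fewer events.
#'
#' @param aln an [mt_alignment].
#' @return integer lower bound.
#' @export
perfect_phylogeny_bound <- function(aln) {
  m <- .aln_matrix(aln)
  sum(apply(m, 2L, function(col) {
    k <- length(unique(col[col %in% c("A", "C", "G", "T", "-")]))
    max(k - 1L, 0L)
  }))
}

#' Summary mutation rates
#'
#' Per-leaf and per-character rates of the event total, with per-branch
#' mean/sd and empty-branch fraction when branch counts are supplied.
#' Report values are rounded to 2 decimals.
#'
#' @param total_events total number of point mutation events (or a
#'   [crosstab], whose grand total is used).
#' @param n_leaves,n_columns positive denominators.
#' @param branch_counts optional per-branch event counts.
#' @return list with `per_leaf`, `per_character`, and optionally
#'   `per_branch_mean`, `per_branch_sd`, `empty_fraction`.
#' @export
summary_rates <- function(total_events, n_leaves, n_columns,
                          branch_counts = NULL) {
  if (inherits(total_events, "mutation_crosstab"))
    total_events <- total_events["total", "total"]
  if (n_leaves <= 0 || n_columns <= 0) stop("denominators must be positive")
  out <- list(per_leaf = round(total_events / n_leaves, 2L),
              per_character = round(total_events / n_columns, 2L))
  if (!is.null(branch_counts)) {
    out$per_branch_mean <- round(mean(branch_counts), 2L)
    out$per_branch_sd <- round(stats::sd(branch_counts), 2L)
    out$empty_fraction <- round(mean(branch_counts == 0L), 4L)
  }
  out
}

#' Annotate a tree with classified mutation events
#'
#' Driver: Fitch labeling, event extraction, conservation profiling,
#' flagging, cross-tab, branch statistics and rates in one call.
#'
#' @param tree rooted tree with tips matching alignment rows.
#' @param aln an [mt_alignment].
#' @param alpha_threshold conservation cutoff.
#' @param branch_threshold branch-outlier cutoff.
#' @param scope back-mutation scope.
#' @return list of class `tree_annotation`: `labeling`, `events`,
#'   `profile`, `crosstab`, `branch`, `rates`, `bound`.
#' @export
annotate_tree <- function(tree, aln, alpha_threshold = 0.95,
                          branch_threshold = 50L, scope = "path") {
  lab <- fitch_label(tree, aln)
  prof <- conservation_profile(aln)
  ev <- flag_events(extract_events(lab, aln), lab, prof,
                    alpha_threshold, scope)
  tab <- crosstab(ev)
  br <- branch_stats(ev, tree, branch_threshold)
  structure(list(labeling = lab, events = ev, profile = prof,
                 crosstab = tab, branch = br,
                 rates = summary_rates(tab, length(tree$tip.label),
                                       aln$ncols, br$per_branch$count),
                 bound = perfect_phylogeny_bound(aln)),
            class = "tree_annotation")
}

#' @export
print.tree_annotation <- function(x, ...) {
  cat("<tree_annotation> ", nrow(x$events), " events, score ",
      x$labeling$score, ", perfect-phylogeny bound ", x$bound, "\n", sep = "")
  print(unclass(x$crosstab))
  cat("per leaf:", x$rates$per_leaf, "| per character:",
      x$rates$per_character, "| empty branches:",
      x$branch$empty_fraction, "\n")
  invisible(x)
}
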