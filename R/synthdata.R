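# Seeded generator of mtDNA-like datasets with a known phylogeny, known
# per-branch mutation events and injected curation defects, so every
# pipeline stage can be validated against exact ground truth.

#' Synthetic-data specification
#'
#' Defaults describe a miniature circular genome that is structurally
#' faithful to the mitochondrial scheme (genes, non-coding gaps and a
#' control region split in two by the numbering origin) while staying
#' small enough for exhaustive oracles. Substitution counts per branch are
#' Poisson(`sub_rate` x branch length) under a uniform-rate model; indels
#' respect unit structure (codon-length or frameshift in coding genes).
#' Background ambiguity injection is capped at the QC ambiguity threshold
#' so that only deliberately injected defects cross curation thresholds.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param ref_length reference genome length (default 2000).
#' @param control_region_length total control-region length, split 1/3 at
#'   the genome start and 2/3 at the end (default 300).
#' @param n_genes,n_gaps gene and non-coding-gap counts in the coding span.
#' @param sub_rate expected substitutions per unit branch length.
#' @param branch_mean mean of the exponential branch lengths.
#' @param indel_rate expected indels per unit branch length.
#' @param recurrent allow a position to mutate more than once.
#' @param force_revert force one x->y / y->x event pair on a root path.
#' @param ambiguity_rate per-base probability of replacing a leaf base with
#'   an IUPAC ambiguity code (capped at `ambiguity_cap` per sequence).
#' @param ambiguity_cap cap on injected ambiguities per sequence.
#' @param n_rotation,rotation_offset count and displacement of circular
#'   start-point defects.
#' @param n_truncate control-region truncations (flexible sequences).
#' @param n_nrun,nrun_length N-run injections and their length.
#' @param n_dup exact duplicate copies.
#' @param n_outlier,outlier_subs divergent intrusions and the number of
#'   extra substitutions each receives.
#' @param n_overlong,overlong_extra overlong intrusions and the inserted
#'   junk length.
#' @param seed integer seed; a fixed seed makes every output bit-identical.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_leaves = 30L, ref_length = 2000L,
                       control_region_length = 300L,
                       n_genes = 6L, n_gaps = 2L,
                       sub_rate = 20, branch_mean = 0.1,
                       indel_rate = 0, recurrent = TRUE,
                       force_revert = FALSE,
                       ambiguity_rate = 0, ambiguity_cap = 5L,
                       n_rotation = 0L, rotation_offset = 100L,
                       n_truncate = 0L, n_nrun = 0L, nrun_length = 25L,
                       n_dup = 0L, n_outlier = 0L, outlier_subs = 60L,
                       n_overlong = 0L, overlong_extra = 150L,
                       seed = 1L) {
  stopifnot(n_leaves >= 3L, ref_length >= 200L, sub_rate >= 0,
            indel_rate >= 0, ambiguity_rate >= 0, ambiguity_rate <= 1)
  structure(as.list(environment()), class = "synth_spec")
}

#' QC configuration matched to a synthetic genome
#'
#' Scales the mitochondrial length rules to the synthetic reference: the
#' strict band brackets the reference length (wide enough for the
#' generator's indels), the vacuum spans the control-region deficit, and
#' the ceiling sits just above the strict band.
#'
#' @param spec a [synth_spec].
#' @return a [qc_config].
#' @export
synth_qc_config <- function(spec) {
  L <- spec$ref_length
  qc_config(strict_length_range = c(L - 40L, L + 60L),
            max_length = L + 60L,
            control_region_vacuum = c(L - spec$control_region_length, L - 40L),
            review_ranges = list(),
            ambiguity_threshold = spec$ambiguity_cap,
            n_run_min = 10L)
}

#' Simulate a random rooted binary tree (Yule process)
#'
#' Starting from two lineages, a uniformly chosen tip is split until `n`
#' leaves exist; branch lengths are exponential with mean
#' `branch_mean`. Deterministic under the seed.
#'
#' @param n number of leaves (>= 3).
#' @param seed integer seed.
#' @param branch_mean mean branch length.
#' @return a rooted binary `ape::phylo` tree with tips `s01`, `s02`, ...
#' @export
simulate_tree <- function(n, seed = 1L, branch_mean = 0.1) {
  if (n < 3L) stop("a tree needs at least 3 leaves")
  set.seed(seed)
  # grow a nested-list topology by splitting random tips
  tips <- 2L
  topo <- list(1L, 2L)
  nxt <- 3L
  while (tips < n) {
    path <- .sample_tip_path(topo)
    topo <- .split_tip(topo, path, nxt)
    nxt <- nxt + 1L
    tips <- tips + 1L
  }
  lab <- sprintf("s%02d", seq_len(n))
  nwk <- .topo_newick(topo, lab)
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_mean)
  tr
}

.sample_tip_path <- function(topo, path = integer()) {
  if (!is.list(topo)) return(path)
  # count tips in each child to sample uniformly over tips
  sizes <- vapply(topo, .count_tips, integer(1))
  pick <- sample.int(2L, 1L, prob = sizes)
  .sample_tip_path(topo[[pick]], c(path, pick))
}

.count_tips <- function(topo) {
  if (!is.list(topo)) return(1L)
  sum(vapply(topo, .count_tips, integer(1)))
}

.split_tip <- function(topo, path, new_id) {
  if (!length(path)) return(list(topo, new_id))
  topo[[path[1]]] <- .split_tip(topo[[path[1]]], path[-1], new_id)
  topo
}

.topo_newick <- function(topo, lab) {
  if (!is.list(topo)) return(lab[topo])
  paste0("(", .topo_newick(topo[[1]], lab), ",",
         .topo_newick(topo[[2]], lab), ")")
}

#' Synthetic reference annotation
#'
#' Builds the miniature genome described by the spec: control region part 1
#' at the genome start, a coding span of alternating genes and non-coding
#' gaps, and control region part 2 at the end. Coding gene lengths are
#' multiples of 3.
#'
#' @param spec a [synth_spec].
#' @return an [mt_annotation].
#' @export
synth_annotation <- function(spec) {
  set.seed(spec$seed + 101L)
  L <- spec$ref_length
  cr1 <- floor(spec$control_region_length / 3)
  cr2 <- spec$control_region_length - cr1
  coding_span <- L - spec$control_region_length
  ng <- spec$n_genes; nn <- spec$n_gaps
  gap_w <- rep(10L, nn)
  gene_span <- coding_span - sum(gap_w)
  w <- rep(gene_span %/% ng, ng)
  w[1] <- w[1] + gene_span - sum(w)
  w <- 3L * (w %/% 3L)
  slack <- gene_span - sum(w)
  gap_w[1] <- gap_w[1] + slack
  # interleave: g1 gap g2 g3 gap g4 ... (gaps after genes 1 and ng-2)
  units <- list(data.frame(name = "CR1", kind = "control_region_part",
                           start = 1L, end = cr1, coding = FALSE, frame = 0L))
  pos <- cr1 + 1L
  gap_after <- unique(pmin(ng - 1L, c(1L, seq(2L, by = 2L,
                                              length.out = max(nn - 1L, 0L)))))
  gap_after <- gap_after[seq_len(nn)]
  gi <- 1L
  for (g in seq_len(ng)) {
    coding <- g %% 3L != 0L  # two of every three genes are protein-coding
    units[[length(units) + 1L]] <- data.frame(
      name = paste0("gene", g), kind = "gene", start = pos,
      end = pos + w[g] - 1L, coding = coding, frame = 0L)
    pos <- pos + w[g]
    if (g %in% gap_after && gi <= nn) {
      units[[length(units) + 1L]] <- data.frame(
        name = paste0("gap", gi), kind = "noncoding_gap", start = pos,
        end = pos + gap_w[gi] - 1L, coding = FALSE, frame = 0L)
      pos <- pos + gap_w[gi]
      gi <- gi + 1L
    }
  }
  units[[length(units) + 1L]] <- data.frame(
    name = "CR2", kind = "control_region_part", start = pos, end = L,
    coding = FALSE, frame = 0L)
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
  mt_annotation("synthetic_ref", ref, do.call(rbind, units), circular = TRUE)
}

#' Evolve sequences along a tree
#'
#' The root carries the reference; each branch receives
#' Poisson(`sub_rate` x length) substitutions and, if enabled,
#' Poisson(`indel_rate` x length) unit-respecting indels (codon-length at
#' codon boundaries or 1-2 bp frameshifts in coding genes, 1-3 bp in
#' non-coding units). Every applied event is recorded with its reference
#' position; leaves are emitted gap-free. With `recurrent = FALSE` every
#' reference position mutates at most once in the whole tree, so the Fitch
#' score of the true tree equals the number of generated events. With
#' `force_revert = TRUE` one x->y / y->x pair is forced onto a root path
#' and recorded in the registry.
#'
#' @param tree rooted binary tree from [simulate_tree].
#' @param annotation from [synth_annotation].
#' @param spec a [synth_spec].
#' @return list of class `synth_truth`: `dataset` ([mt_dataset]), `tree`,
#'   `events` (data frame branch/ref_pos/from/to/type), `annotation`.
#' @export
evolve_sequences <- function(tree, annotation, spec) {
  set.seed(spec$seed + 202L)
  L <- nchar(annotation$reference)
  refv <- strsplit(annotation$reference, "")[[1]]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # genotype: per reference position, a string ("" = deleted,
  # "XY" = original plus insertion after it)
  geno <- list()
  geno[[root]] <- refv
  events <- list()
  avail <- seq_len(L)  # for recurrent = FALSE
  units <- annotation$units
  bases <- c("A", "C", "G", "T")

  po <- ape::reorder.phylo(tree, "postorder")
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]

  # forced reverting pair: first root-child edge and a pendant edge below it
  forced <- NULL
  if (spec$force_revert) {
    e1 <- which(pre[, 1] == root)[1]
    child1 <- pre[e1, 2]
    desc <- .clade_tips(tree, child1)
    leaf <- desc[1]
    e2 <- which(pre[, 2] == leaf)[1]
    pos <- sample(avail, 1L)
    from <- refv[pos]
    to <- sample(setdiff(bases, from), 1L)
    forced <- list(e1 = e1, e2 = e2, pos = pos, from = from, to = to)
    avail <- setdiff(avail, pos)
  }

  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]; child <- pre[e, 2]
    g <- geno[[parent]]
    nsub <- stats::rpois(1L, spec$sub_rate * elen[e])
    single <- which(nchar(g) == 1L & g != "")
    pool <- if (spec$recurrent) single else intersect(single, avail)
    nsub <- min(nsub, length(pool))
    if (nsub > 0L) {
      at <- sample(pool, nsub)
      if (!spec$recurrent) avail <- setdiff(avail, at)
      for (p in at) {
        old <- g[p]
        new <- sample(setdiff(bases, old), 1L)
        g[p] <- new
        events[[length(events) + 1L]] <- data.frame(
          parent = parent, child = child, ref_pos = p, from = old, to = new,
          type = "sub", stringsAsFactors = FALSE)
      }
    }
    nind <- stats::rpois(1L, spec$indel_rate * elen[e])
    for (k in seq_len(nind)) {
      u <- sample.int(nrow(units), 1L,
                      prob = units$end - units$start + 1L)
      coding <- units$coding[u]
      len <- if (coding) {
        if (stats::runif(1) < 0.7) 3L else sample(1:2, 1L)
      } else sample(1:3, 1L)
      del <- stats::runif(1) < 0.5
      if (del) {
        lo <- units$start[u]; hi <- units$end[u] - len + 1L
        if (hi < lo) next
        p0 <- if (coding && len %% 3L == 0L) {
          starts <- seq(lo + units$frame[u], hi, by = 3L)
          sample(starts, 1L)
        } else sample(lo:hi, 1L)
        span <- p0:(p0 + len - 1L)
        if (any(nchar(g[span]) != 1L)) next  # keep events non-nested
        events[[length(events) + 1L]] <- data.frame(
          parent = parent, child = child, ref_pos = p0,
          from = paste(g[span], collapse = ""), to = "-", type = "del",
          stringsAsFactors = FALSE)
        g[span] <- ""
      } else {
        p0 <- sample(units$start[u]:units$end[u], 1L)
        if (nchar(g[p0]) != 1L) next
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        events[[length(events) + 1L]] <- data.frame(
          parent = parent, child = child, ref_pos = p0, from = "-",
          to = ins, type = "ins", stringsAsFactors = FALSE)
        g[p0] <- paste0(g[p0], ins)
      }
    }
    if (!is.null(forced) && e %in% c(forced$e1, forced$e2)) {
      p <- forced$pos
      if (e == forced$e1 && nchar(g[p]) == 1L && g[p] != forced$to) {
        events[[length(events) + 1L]] <- data.frame(
          parent = parent, child = child, ref_pos = p, from = g[p],
          to = forced$to, type = "sub_forced", stringsAsFactors = FALSE)
        g[p] <- forced$to
      } else if (e == forced$e2 && identical(g[p], forced$to)) {
        events[[length(events) + 1L]] <- data.frame(
          parent = parent, child = child, ref_pos = p, from = forced$to,
          to = forced$from, type = "sub_forced", stringsAsFactors = FALSE)
        g[p] <- forced$from
      }
    }
    geno[[child]] <- g
  }
  # guarantee distinct leaves: densely sampled real data contain exact
  # duplicates, but the defect registry must be the only source of
  # duplication for ground-truth recovery, so coincident leaves receive a
  # recorded private substitution on their pendant branch
  parent_of <- .parents(tree)
  residues <- vapply(seq_len(ntip),
                     function(i) paste(geno[[i]], collapse = ""), character(1))
  repeat {
    dup <- if (spec$sub_rate > 0) which(duplicated(residues)) else integer()
    if (!length(dup)) break
    for (i in dup) {
      g <- geno[[i]]
      single <- which(nchar(g) == 1L & g != "")
      pool <- if (spec$recurrent) single else intersect(single, avail)
      p <- if (length(pool)) sample(pool, 1L) else sample(single, 1L)
      if (!spec$recurrent) avail <- setdiff(avail, p)
      new <- sample(setdiff(bases, g[p]), 1L)
      events[[length(events) + 1L]] <- data.frame(
        parent = parent_of[i], child = i, ref_pos = p, from = g[p],
        to = new, type = "sub", stringsAsFactors = FALSE)
      g[p] <- new
      geno[[i]] <- g
      residues[i] <- paste(g, collapse = "")
    }
  }
  ds <- mt_dataset(tree$tip.label, residues, species = "synthetic",
                   source = "generator")
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(parent = integer(), child = integer(), ref_pos = integer(),
               from = character(), to = character(), type = character(),
               stringsAsFactors = FALSE)
  structure(list(dataset = ds, tree = tree, events = ev,
                 annotation = annotation), class = "synth_truth")
}

#' Inject curation defects into a clean dataset
#'
#' Applies the requested count of each defect kind to randomly chosen,
#' distinct sequences and returns the exact registry. Duplicate copies are
#' appended with ids sorting after their originals so that duplicate
#' compression keeps the original as representative. Background ambiguity
#' injection (a rate, not a defect) is applied to all non-victim sequences,
#' capped below the QC ambiguity threshold.
#'
#' @param truth a `synth_truth` from [evolve_sequences] (or an
#'   [mt_dataset]).
#' @param spec a [synth_spec].
#' @return list of class `synth_defects`: `dataset`, `registry` (data
#'   frame id/defect/parameter).
#' @export
inject_defects <- function(truth, spec) {
  ds <- if (inherits(truth, "synth_truth")) truth$dataset else truth
  set.seed(spec$seed + 303L)
  seqs <- ds$sequences
  n_def <- spec$n_rotation + spec$n_truncate + spec$n_nrun +
    spec$n_outlier + spec$n_overlong + spec$n_dup
  if (n_def > nrow(seqs))
    stop("more defects requested (", n_def, ") than sequences (",
         nrow(seqs), ")")
  victims <- sample(seqs$id, n_def)
  protected <- victims  # defect victims (and their copies) get no background noise
  reg <- list()
  take <- function(k) {
    if (k == 0L) return(character(0))
    v <- victims[seq_len(k)]; victims <<- victims[-seq_len(k)]; v
  }
  bases <- c("A", "C", "G", "T")
  amb_codes <- c("R", "Y", "M", "K", "S", "W", "N")

  for (id in take(spec$n_rotation)) {
    i <- match(id, seqs$id)
    seqs$residues[i] <- .rotate_left(seqs$residues[i], spec$rotation_offset)
    reg[[length(reg) + 1L]] <- data.frame(id = id, defect = "rotation",
                                          parameter = spec$rotation_offset)
  }
  for (id in take(spec$n_truncate)) {
    i <- match(id, seqs$id)
    cut <- spec$control_region_length + 20L
    seqs$residues[i] <- substr(seqs$residues[i], 1L,
                               nchar(seqs$residues[i]) - cut)
    reg[[length(reg) + 1L]] <- data.frame(id = id, defect = "truncation",
                                          parameter = cut)
  }
  for (id in take(spec$n_nrun)) {
    i <- match(id, seqs$id)
    s <- seqs$residues[i]
    at <- sample.int(nchar(s) - spec$nrun_length, 1L)
    seqs$residues[i] <- paste0(substr(s, 1L, at - 1L),
                               strrep("N", spec$nrun_length),
                               substr(s, at + spec$nrun_length, nchar(s)))
    reg[[length(reg) + 1L]] <- data.frame(id = id, defect = "n_run",
                                          parameter = spec$nrun_length)
  }
  for (id in take(spec$n_outlier)) {
    i <- match(id, seqs$id)
    sv <- strsplit(seqs$residues[i], "")[[1]]
    at <- sample(which(sv %in% bases), spec$outlier_subs)
    for (p in at) sv[p] <- sample(setdiff(bases, sv[p]), 1L)
    seqs$residues[i] <- paste(sv, collapse = "")
    reg[[length(reg) + 1L]] <- data.frame(id = id, defect = "divergent",
                                          parameter = spec$outlier_subs)
  }
  for (id in take(spec$n_overlong)) {
    i <- match(id, seqs$id)
    junk <- paste(sample(bases, spec$overlong_extra, replace = TRUE),
                  collapse = "")
    seqs$residues[i] <- paste0(seqs$residues[i], junk)
    reg[[length(reg) + 1L]] <- data.frame(id = id, defect = "overlong",
                                          parameter = spec$overlong_extra)
  }
  dup_src <- take(spec$n_dup)
  for (k in seq_along(dup_src)) {
    src <- dup_src[k]
    new_id <- paste0(src, "_dup")
    seqs <- rbind(seqs, seqs[match(src, seqs$id), ])
    seqs$id[nrow(seqs)] <- new_id
    reg[[length(reg) + 1L]] <- data.frame(id = new_id, defect = "duplicate",
                                          parameter = NA_integer_)
  }
  protected <- c(protected,
                 if (length(reg)) vapply(reg, `[[`, character(1), "id"))
  if (spec$ambiguity_rate > 0) {
    for (i in seq_len(nrow(seqs))) {
      if (seqs$id[i] %in% protected) next
      k <- min(stats::rpois(1L, spec$ambiguity_rate * nchar(seqs$residues[i])),
               spec$ambiguity_cap)
      if (k == 0L) next
      sv <- strsplit(seqs$residues[i], "")[[1]]
      at <- sample(which(sv %in% bases), k)
      sv[at] <- sample(amb_codes, k, replace = TRUE)
      seqs$residues[i] <- paste(sv, collapse = "")
    }
  }
  out <- ds
  out$sequences <- seqs
  rownames(out$sequences) <- NULL
  registry <- if (length(reg)) do.call(rbind, reg) else
    data.frame(id = character(), defect = character(), parameter = integer(),
               stringsAsFactors = FALSE)
  out <- .log_action(out, "inject_defects", "generator",
                     paste(nrow(registry), "defects injected"))
  structure(list(dataset = out, registry = registry),
            class = "synth_defects")
}

#' Generate a complete synthetic study
#'
#' Tree, annotation, evolved sequences and injected defects in one call.
#'
#' @param spec a [synth_spec].
#' @return list with `spec`, `annotation`, `tree`, `truth`
#'   (`synth_truth`), `dataset` (defective), `registry`.
#' @export
generate_dataset <- function(spec = synth_spec()) {
  ann <- synth_annotation(spec)
  tree <- simulate_tree(spec$n_leaves, seed = spec$seed,
                        branch_mean = spec$branch_mean)
  truth <- evolve_sequences(tree, ann, spec)
  def <- inject_defects(truth, spec)
  list(spec = spec, annotation = ann, tree = tree, truth = truth,
       dataset = def$dataset, registry = def$registry)
}
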