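# Workflow orchestration: storage stages interleaved with algorithmic and
# restrictive stages, with feedback of flagged items into the curation log.

#' Workflow configuration
#'
#' @param qc a [qc_config].
#' @param scoring a [scoring_scheme].
#' @param engine unit-alignment engine (`"internal"` or a command).
#' @param indel_mode distance mode.
#' @param outlier_k robust multiplier for distance outliers.
#' @param bootstrap number of bootstrap replicates (0 disables).
#' @param consensus_threshold majority-rule threshold.
#' @param outgroup optional tip ids used to root the tree.
#' @param alpha_threshold conservation cutoff for event flagging.
#' @param branch_threshold branch-outlier cutoff.
#' @param auto_exclude drop flagged distance outliers before tree building
#'   (off by default: low-risk corrections such as rotation and duplicate
#'   compression are automatic, exclusions require opting in).
#' @param seed integer seed for the bootstrap.
#' @return a list of class `workflow_config`.
#' @export
workflow_config <- function(qc = qc_config(),
                            scoring = scoring_scheme(gap_open = 3),
                            engine = "internal",
                            indel_mode = "per_column", outlier_k = 5,
                            bootstrap = 0L, consensus_threshold = 0.5,
                            outgroup = NULL, alpha_threshold = 0.95,
                            branch_threshold = 50L, auto_exclude = FALSE,
                            seed = 1L) {
  structure(list(qc = qc, scoring = scoring, engine = engine,
                 indel_mode = indel_mode, outlier_k = outlier_k,
                 bootstrap = as.integer(bootstrap),
                 consensus_threshold = consensus_threshold,
                 outgroup = outgroup, alpha_threshold = alpha_threshold,
                 branch_threshold = as.integer(branch_threshold),
                 auto_exclude = isTRUE(auto_exclude), seed = as.integer(seed)),
            class = "workflow_config")
}

#' Run the full curation-to-annotation pipeline
#'
#' Stages, in order: quality control -> duplicate compression -> rotation
#' detection and automatic correction -> reference-partitioned alignment
#' and merge -> distance matrix and group-wise outliers -> neighbor-joining
#' tree (optionally bootstrapped with a majority-rule consensus) ->
#' outgroup rooting -> Fitch labeling, event classification and tree
#' statistics. Restrictive stages feed their flags back into the dataset's
#' provenance log; flagged sequences are retained unless `auto_exclude` is
#' set. When `out_dir` is given, every stage writes its artifact (FASTA,
#' TSV, JSON, newick, phyloXML) and cached reference alignments are reused
#' on re-runs.
#'
#' @param dataset an [mt_dataset] of raw sequences.
#' @param annotation an [mt_annotation].
#' @param config a [workflow_config].
#' @param out_dir optional artifact directory.
#' @return list of class `pipeline_result` with elements `qc`, `dedup`,
#'   `rotations`, `alignment`, `distances`, `outliers`, `tree`,
#'   `consensus`, `annotation_stats`, `flags` (data frame id/stage/flag)
#'   and `dataset` (final, with full provenance log).
#' @export
run_pipeline <- function(dataset, annotation, config = workflow_config(),
                         out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  flags <- list()
  note <- function(id, stage, flag) {
    flags[[length(flags) + 1L]] <<- data.frame(id = id, stage = stage,
                                               flag = flag,
                                               stringsAsFactors = FALSE)
  }

  # --- quality control (restrictive) ---------------------------------
  qc <- run_qc(dataset, config$qc)
  ds <- qc$dataset
  for (i in seq_len(nrow(qc$report$per_sequence))) {
    r <- qc$report$per_sequence[i, ]
    if (nzchar(r$flags))
      for (f in strsplit(r$flags, ",")[[1]]) note(r$id, "qc", f)
    if (r$tier == "excluded") note(r$id, "qc", "excluded")
    if (r$tier == "flexible") note(r$id, "qc", "flexible")
  }

  # --- duplicate compression (automatic) -----------------------------
  dedup <- qc$report$duplicates
  members <- unlist(lapply(dedup$expansion, function(g) g[-1]),
                    use.names = FALSE)
  for (m in members) note(m, "dedup", "duplicate_member")

  working <- ds$sequences[ds$sequences$tier == "strict" &
                            !(ds$sequences$id %in% members), , drop = FALSE]

  # --- rotation detection and correction (automatic) -----------------
  rotations <- data.frame(id = character(), offset = integer(),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(working))) {
    o <- detect_rotation(working$residues[i], annotation$reference)
    if (o != 0L) {
      working$residues[i] <- correct_rotation(working$residues[i], o)
      ds <- .log_action(ds, "rotation_corrected", working$id[i],
                        paste("offset", o))
      note(working$id[i], "rotation", paste0("corrected_offset_", o))
      rotations <- rbind(rotations, data.frame(id = working$id[i], offset = o,
                                               stringsAsFactors = FALSE))
    }
  }

  # --- partitioned alignment (algorithmic, cached) -------------------
  wds <- structure(list(sequences = working, log = .empty_log()),
                   class = "mt_dataset")
  cache <- art("ref_alignments.rds")
  ref_alns <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    cached <- readRDS(cache)
    if (identical(cached$digest, working$residues[order(working$id)]))
      ref_alns <- cached$alignments
  }
  if (is.null(ref_alns)) {
    ref_alns <- .global_align_many(
      stats::setNames(working$residues, working$id),
      annotation$reference, config$scoring)
    if (!is.null(cache))
      saveRDS(list(digest = working$residues[order(working$id)],
                   alignments = ref_alns), cache)
  }
  aln <- partition_align(wds, annotation, engine = config$engine,
                         scoring = config$scoring, ref_alignments = ref_alns)
  if (!is.null(out_dir)) {
    write_fasta(aln, art("alignment.fasta"))
    utils::write.table(
      data.frame(column = seq_len(aln$ncols),
                 ref = ifelse(is.na(aln$colmap), "ins", aln$colmap)),
      art("colmap.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # --- distances and outliers (restrictive) --------------------------
  distances <- outliers <- NULL
  if (length(aln$ids) >= 3L) {
    distances <- distance_matrix(aln, indel_mode = config$indel_mode)
    grp <- stats::setNames(working$species[match(rownames(distances),
                                                 working$id)],
                           rownames(distances))
    outliers <- group_outliers(distances, grp, k = config$outlier_k)
    for (id in outliers$flagged) {
      note(id, "distance", "divergent")
      ds <- .log_action(ds, "distance_outlier", id, "flagged")
    }
    if (!is.null(out_dir))
      utils::write.table(distances, art("distances.tsv"), sep = "\t",
                         quote = FALSE)
  }

  keep_ids <- aln$ids
  if (config$auto_exclude && !is.null(outliers))
    keep_ids <- setdiff(keep_ids, outliers$flagged)

  # --- tree building -------------------------------------------------
  tree <- consensus <- ann_stats <- NULL
  if (length(keep_ids) >= 3L && !is.null(distances)) {
    d <- distances[keep_ids, keep_ids]
    tree <- neighbor_joining(d)
    if (config$bootstrap > 0L) {
      sub <- mt_alignment(keep_ids, aln$rows[match(keep_ids, aln$ids)],
                          aln$colmap)
      reps <- bootstrap_replicates(sub, config$bootstrap, config$seed)
      btrees <- lapply(reps, function(r)
        neighbor_joining(distance_matrix(r, indel_mode = config$indel_mode)))
      consensus <- majority_consensus(btrees, config$consensus_threshold)
    }
    rooted <- if (!is.null(config$outgroup) &&
                  all(config$outgroup %in% tree$tip.label)) {
      root_by_outgroup(tree, config$outgroup)
    } else {
      # midpoint-free default: root on the first tip's pendant edge
      root_by_outgroup(tree, tree$tip.label[1])
    }
    sub <- mt_alignment(keep_ids, aln$rows[match(keep_ids, aln$ids)],
                        aln$colmap)
    ann_stats <- annotate_tree(rooted, sub,
                               alpha_threshold = config$alpha_threshold,
                               branch_threshold = config$branch_threshold)
    for (ch in ann_stats$branch$outliers)
      note(if (ch <= length(rooted$tip.label)) rooted$tip.label[ch]
           else paste0("node_", ch), "tree", "branch_outlier")
    if (!is.null(out_dir)) {
      write_newick(tree, art("tree.nwk"))
      if (!is.null(consensus)) write_newick(consensus, art("consensus.nwk"))
      write_phyloxml(rooted, art("annotated.xml"), ann_stats$events)
      jsonlite::write_json(
        list(crosstab = as.data.frame(unclass(ann_stats$crosstab)),
             rates = ann_stats$rates,
             perfect_phylogeny_bound = ann_stats$bound,
             empty_branch_fraction = ann_stats$branch$empty_fraction),
        art("stats.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(id = character(), stage = character(), flag = character(),
               stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    utils::write.table(ds$log, art("provenance.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(flags, art("flags.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  structure(list(qc = qc$report, dedup = dedup, rotations = rotations,
                 alignment = aln, distances = distances, outliers = outliers,
                 tree = tree, consensus = consensus,
                 annotation_stats = ann_stats, flags = flags, dataset = ds),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  sequences:", nrow(x$dataset$sequences),
      "| flags:", nrow(x$flags), "\n")
  if (!is.null(x$alignment))
    cat("  alignment:", length(x$alignment$ids), "x", x$alignment$ncols, "\n")
  if (!is.null(x$annotation_stats))
    cat("  events:", nrow(x$annotation_stats$events), "(score",
        x$annotation_stats$labeling$score, ")\n")
  invisible(x)
}
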