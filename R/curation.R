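# Single-sequence quality tests and dataset classification into
# strict/flexible tiers with an auditable provenance log.

#' Quality-control configuration
#'
#' Length thresholds follow the empirical structure of complete human mtDNA
#' submissions: essentially all full genomes fall in a narrow band around
#' the reference length, none exceed a hard ceiling, and genomes lacking
#' the control region are separated from full ones by a length "vacuum" in
#' which no coherent sequence occurs. Lengths inside the vacuum or in a
#' review range are retained but flagged for inspection.
#'
#' @param strict_length_range closed interval of accepted full-genome
#'   lengths (default `c(16550, 16600)`).
#' @param max_length hard upper bound; longer sequences are rejected.
#' @param control_region_vacuum half-open interval `[lo, hi)` in which no
#'   coherent sequence is expected; lengths below `lo` are classified as
#'   control-region-missing ("flexible").
#' @param review_ranges list of half-open `[lo, hi)` intervals whose
#'   members are retained but flagged as outliers.
#' @param ambiguity_threshold maximum tolerated count of ambiguous
#'   positions before a sequence is flagged (default 5, which covered 99%
#'   of a large public snapshot; a threshold of 1 covered 95%).
#' @param ambiguity_fraction optional fractional alternative to the count.
#' @param n_run_min minimal length of a run of `N` to be flagged as an
#'   unsequenced stretch (default 10).
#' @param strict_exclude drop review-range outliers instead of flagging.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(strict_length_range = c(16550L, 16600L),
                      max_length = 16600L,
                      control_region_vacuum = c(15600L, 16300L),
                      review_ranges = list(c(16300L, 16550L)),
                      ambiguity_threshold = 5L,
                      ambiguity_fraction = NULL,
                      n_run_min = 10L,
                      strict_exclude = FALSE) {
  stopifnot(length(strict_length_range) == 2L,
            strict_length_range[1] <= strict_length_range[2],
            control_region_vacuum[1] <= control_region_vacuum[2],
            ambiguity_threshold >= 0L, n_run_min >= 1L)
  structure(list(strict_length_range = as.integer(strict_length_range),
                 max_length = as.integer(max_length),
                 control_region_vacuum = as.integer(control_region_vacuum),
                 review_ranges = lapply(review_ranges, as.integer),
                 ambiguity_threshold = as.integer(ambiguity_threshold),
                 ambiguity_fraction = ambiguity_fraction,
                 n_run_min = as.integer(n_run_min),
                 strict_exclude = isTRUE(strict_exclude)),
            class = "qc_config")
}

#' Classify a sequence length
#'
#' Total function on raw sequences: `strict_ok` inside the closed strict
#' range, `reject_overlong` above the hard ceiling,
#' `flexible_no_control_region` below the vacuum's lower bound, and
#' `review_outlier` inside the vacuum or a review range.
#'
#' @param length sequence length (or a vector of lengths).
#' @param cfg a [qc_config].
#' @return character vector of length classes.
#' @export
classify_length <- function(length, cfg = qc_config()) {
  out <- character(length(length))
  out[length > cfg$max_length] <- "reject_overlong"
  strict <- length >= cfg$strict_length_range[1] &
    length <= cfg$strict_length_range[2] & out == ""
  out[strict] <- "strict_ok"
  for (rr in cfg$review_ranges) {
    hit <- out == "" & length >= rr[1] & length < rr[2]
    out[hit] <- "review_outlier"
  }
  vac <- out == "" & length >= cfg$control_region_vacuum[1] &
    length < cfg$control_region_vacuum[2]
  out[vac] <- "review_outlier"
  out[out == "" & length < cfg$control_region_vacuum[1]] <-
    "flexible_no_control_region"
  # lengths above every named range but within max: reviewable
  out[out == ""] <- "review_outlier"
  out
}

#' Count ambiguous positions in a sequence
#'
#' Number of residues not in `{A,C,G,T}`. Gaps are not expected in raw
#' sequences and are excluded from the count.
#'
#' @param residues residue string(s).
#' @return integer vector of counts.
#' @export
count_ambiguities <- function(residues) {
  nchar(gsub("[ACGT?-]", "", toupper(residues)))
}

#' Ambiguity covering fraction
#'
#' Fraction of sequences whose ambiguity count is at most `t`; the covering
#' curve is nondecreasing in `t` and reaches 1 at the maximal count.
#'
#' @param dataset an [mt_dataset].
#' @param t integer threshold (vectorized).
#' @return numeric vector of fractions.
#' @export
ambiguity_covering <- function(dataset, t) {
  n <- nrow(dataset$sequences)
  if (n == 0L) stop("empty dataset")
  counts <- count_ambiguities(dataset$sequences$residues)
  vapply(t, function(ti) mean(counts <= ti), numeric(1))
}

#' Find runs of unknown positions
#'
#' Maximal runs of consecutive `N` of length at least `n_run_min`,
#' reported as 1-based (start, length) pairs, non-overlapping and sorted.
#'
#' @param residues a residue string.
#' @param n_run_min minimal run length.
#' @return data frame with columns `start`, `length`.
#' @export
find_n_runs <- function(residues, n_run_min = 10L) {
  stopifnot(n_run_min >= 1L)
  m <- gregexpr("N+", residues)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), length = integer()))
  len <- attr(m, "match.length")
  keep <- len >= n_run_min
  data.frame(start = as.integer(m[keep]), length = as.integer(len[keep]))
}

#' Compress exact duplicate sequences
#'
#' Partitions the dataset by exact equality of raw residue strings; each
#' group's representative is its lexicographically smallest id. The
#' expansion map lets final outputs restore all members. Ambiguity-aware
#' equality (N matching anything) is deliberately not used.
#'
#' @param dataset an [mt_dataset].
#' @return list with `groups` (list of id vectors), `representatives`
#'   (character), and `expansion` (named list: representative -> members).
#' @export
deduplicate <- function(dataset) {
  seqs <- dataset$sequences
  groups <- split(seqs$id, factor(seqs$residues, levels = unique(seqs$residues)))
  groups <- unname(lapply(groups, function(g) sort(g)))
  reps <- vapply(groups, `[`, character(1), 1L)
  ord <- order(reps)
  groups <- groups[ord]; reps <- reps[ord]
  list(groups = groups, representatives = reps,
       expansion = stats::setNames(groups, reps))
}

#' Run all single-sequence quality tests
#'
#' Assigns every sequence a tier and writes one provenance-log entry per
#' applied rule per affected sequence. Review-range outliers are retained
#' but flagged (set `strict_exclude` in the config to drop them);
#' overlong sequences are excluded; sequences below the vacuum are tiered
#' `flexible`. Re-running on its own output changes nothing: the QC log is
#' recomputed, not appended.
#'
#' @param dataset an [mt_dataset].
#' @param cfg a [qc_config].
#' @return list of class `qc_result` with elements `dataset` (tiered, with
#'   log) and `report` (class `qc_report`): per-sequence table, length
#'   histogram, covering curve, duplicate groups.
#' @export
run_qc <- function(dataset, cfg = qc_config()) {
  seqs <- dataset$sequences
  n <- nrow(seqs)
  len <- nchar(seqs$residues)
  lc <- classify_length(len, cfg)
  amb <- count_ambiguities(seqs$residues)
  nrun <- vapply(seqs$residues, function(s) {
    r <- find_n_runs(s, 1L)
    if (nrow(r)) max(r$length) else 0L
  }, integer(1), USE.NAMES = FALSE)

  amb_limit <- cfg$ambiguity_threshold
  if (!is.null(cfg$ambiguity_fraction))
    amb_limit <- pmax(amb_limit, floor(cfg$ambiguity_fraction * len))
  flags <- vector("list", n)
  for (i in seq_len(n)) {
    f <- character()
    if (lc[i] == "review_outlier") f <- c(f, "review_length")
    if (amb[i] > amb_limit[min(i, length(amb_limit))]) f <- c(f, "ambiguity_excess")
    if (nrun[i] >= cfg$n_run_min) f <- c(f, "n_run")
    flags[[i]] <- f
  }

  tier <- rep("strict", n)
  tier[lc == "flexible_no_control_region"] <- "flexible"
  tier[lc == "reject_overlong"] <- "excluded"
  if (cfg$strict_exclude) tier[lc == "review_outlier"] <- "excluded"

  dup <- deduplicate(dataset)
  dup_members <- unlist(lapply(dup$expansion, function(g) g[-1]), use.names = FALSE)
  for (i in seq_len(n))
    if (seqs$id[i] %in% dup_members) flags[[i]] <- c(flags[[i]], "duplicate")

  # fresh, deterministic log (idempotent under re-runs)
  log <- .empty_log()
  addlog <- function(rule, id, decision) {
    log <<- rbind(log, data.frame(rule = rule, id = id, decision = decision,
                                  stringsAsFactors = FALSE))
  }
  for (i in seq_len(n)) {
    if (lc[i] == "reject_overlong") addlog("reject_overlong", seqs$id[i], "excluded")
    if (lc[i] == "flexible_no_control_region")
      addlog("flexible_no_control_region", seqs$id[i], "tier flexible")
    for (f in flags[[i]]) addlog(f, seqs$id[i],
                                 if (cfg$strict_exclude && f == "review_length")
                                   "excluded" else "flagged")
  }

  out <- dataset
  out$sequences$tier <- tier
  keep <- !(out$log$rule %in% c("reject_overlong", "flexible_no_control_region",
                                "review_length", "ambiguity_excess", "n_run",
                                "duplicate"))
  out$log <- rbind(out$log[keep, , drop = FALSE], log)
  rownames(out$log) <- NULL

  per_seq <- data.frame(id = seqs$id, length = len, length_class = lc,
                        ambiguity_count = amb, max_n_run = nrun,
                        tier = tier,
                        flags = vapply(flags, paste, character(1), collapse = ","),
                        stringsAsFactors = FALSE)
  tmax <- max(amb, 0L)
  report <- structure(list(
    per_sequence = per_seq,
    length_histogram = table(len),
    covering = data.frame(threshold = 0:tmax,
                          fraction = ambiguity_covering(dataset, 0:tmax)),
    duplicates = dup), class = "qc_report")
  structure(list(dataset = out, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x$per_sequence), " sequences\n", sep = "")
  print(table(x$per_sequence$length_class))
  flagged <- sum(nzchar(x$per_sequence$flags))
  cat("flagged:", flagged, "| duplicate groups >1:",
      sum(lengths(x$duplicates$groups) > 1L), "\n")
  invisible(x)
}
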