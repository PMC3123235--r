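# Reference-guided decomposition into structural units, per-unit multiple
# alignment, indel classification in coding units, and overlapped merge.

# assign every column of a pairwise (sequence vs reference) alignment to a
# reference position: columns on a reference residue get its position,
# insertion columns get the position of the residue to their left (0 for
# insertions before position 1)
.column_ref_index <- function(ref_row) {
  chars <- strsplit(ref_row, "")[[1]]
  cumsum(chars != "-")
}

#' Split a sequence into structural-unit slices
#'
#' Maps each unit's reference interval through a cached global pairwise
#' alignment of the sequence with the reference, extracting the homologous
#' residues (insertion columns are assigned to the unit of the reference
#' residue on their left; insertions before position 1 go to the first
#' unit). A unit entirely deleted or unsequenced in the sequence yields an
#' empty, flagged slice.
#'
#' @param residues raw sequence string.
#' @param annotation an [mt_annotation].
#' @param ref_alignment optional precomputed [global_align] of the sequence
#'   against the reference (computed once and reusable).
#' @param scoring scheme used when `ref_alignment` is NULL.
#' @return data frame with columns `unit`, `kind`, `start`, `end`,
#'   `coding`, `frame`, `residues`, `empty`.
#' @export
split_by_units <- function(residues, annotation, ref_alignment = NULL,
                           scoring = scoring_scheme(gap_open = 3)) {
  if (is.null(ref_alignment))
    ref_alignment <- global_align(residues, annotation$reference, scoring)
  seq_chars <- strsplit(ref_alignment$aligned_a, "")[[1]]
  refidx <- .column_ref_index(ref_alignment$aligned_b)
  units <- annotation$units
  first_start <- units$start[1]
  out <- units
  out$residues <- ""
  out$empty <- FALSE
  for (i in seq_len(nrow(units))) {
    lo <- units$start[i]; hi <- units$end[i]
    sel <- refidx >= lo & refidx <= hi
    if (i == 1L) sel <- sel | refidx < first_start
    res <- paste(seq_chars[sel & seq_chars != "-"], collapse = "")
    out$residues[i] <- res
    out$empty[i] <- !nzchar(res)
  }
  out
}

# reference-anchored merge of pairwise alignments: each row is aligned to
# the same anchor; rows are expressed as (per-anchor-position symbol,
# per-junction insertion strings), then padded to common insertion widths
.anchor_decompose <- function(aligned_row, aligned_anchor) {
  refidx <- .column_ref_index(aligned_anchor)
  chars <- strsplit(aligned_row, "")[[1]]
  on_ref <- strsplit(aligned_anchor, "")[[1]] != "-"
  L <- max(refidx)
  sym <- character(L)
  sym[refidx[on_ref]] <- chars[on_ref]
  ins <- vapply(0:L, function(p) {
    paste(chars[!on_ref & refidx == p], collapse = "")
  }, character(1))
  list(sym = sym, ins = ins)  # ins[p + 1] follows anchor position p
}

#' Multiple alignment of one unit's slices
#'
#' The internal engine is a reference-anchored star alignment: every slice
#' is globally aligned to the unit's reference residues and the pairwise
#' results are merged on the shared anchor coordinates, padding per-row
#' insertions to a common width. The external engine writes a FASTA
#' (including the reference as an anchor row), invokes the configured
#' aligner as a subprocess and re-parses its FASTA output.
#'
#' @param slices named character vector of nonempty slice residues
#'   (at least 2).
#' @param reference_unit the unit's reference residues (anchor).
#' @param unit_start reference position of the unit's first residue (used
#'   for the column map).
#' @param engine `"internal"` or an external command (e.g. `"mafft"`).
#' @param scoring scheme for the internal engine.
#' @return an [mt_alignment] with a colmap into reference coordinates
#'   (`NA` for insertion columns).
#' @export
align_unit <- function(slices, reference_unit, unit_start = 1L,
                       engine = "internal", scoring = scoring_scheme(gap_open = 3)) {
  slices <- slices[nzchar(slices)]
  if (length(slices) < 2L) stop("align_unit needs at least 2 nonempty slices")
  if (is.null(names(slices))) names(slices) <- paste0("s", seq_along(slices))
  if (identical(engine, "internal")) {
    pas <- .global_align_many(slices, reference_unit, scoring)
    dec <- lapply(pas, function(pa)
      .anchor_decompose(pa$aligned_a, pa$aligned_b))
    L <- nchar(reference_unit)
    ins_w <- vapply(seq_len(L + 1L), function(j)
      max(vapply(dec, function(d) nchar(d$ins[j]), integer(1))), integer(1))
    rows <- vapply(dec, function(d) {
      ins <- paste0(d$ins, strrep("-", ins_w - nchar(d$ins)))
      paste0(paste0(ins[seq_len(L)], d$sym, collapse = ""), ins[L + 1L])
    }, character(1))
    colmap <- integer(0)
    for (p in 0:L) {
      colmap <- c(colmap, rep(NA_integer_, ins_w[p + 1L]),
                  if (p < L) unit_start + p)
    }
    return(mt_alignment(names(slices), unname(rows), colmap))
  }
  # external adapter: FASTA in / FASTA out subprocess
  cmd <- strsplit(engine, "\\s+")[[1]][1]
  if (Sys.which(cmd) == "")
    stop("external aligner '", cmd, "' not found; fall back to the ",
         "internal engine (engine = \"internal\")")
  td <- tempfile("unitaln"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  infa <- file.path(td, "in.fasta"); outfa <- file.path(td, "out.fasta")
  anchor_id <- "__reference__"
  con <- file(infa, "w")
  writeLines(c(paste0(">", anchor_id), reference_unit), con)
  for (i in seq_along(slices))
    writeLines(c(paste0(">", names(slices)[i]), slices[i]), con)
  close(con)
  args <- c(strsplit(engine, "\\s+")[[1]][-1], infa)
  res <- suppressWarnings(system2(cmd, args, stdout = outfa, stderr = FALSE))
  if (res != 0L || !file.size(outfa))
    stop("external aligner '", cmd, "' failed (exit ", res, ")")
  set <- Biostrings::readDNAStringSet(outfa)
  ids <- sub("\\s.*$", "", names(set))
  rows <- toupper(as.character(set))
  anchor_row <- rows[ids == anchor_id]
  refidx <- .column_ref_index(anchor_row)
  on_ref <- strsplit(anchor_row, "")[[1]] != "-"
  colmap <- ifelse(on_ref, unit_start - 1L + refidx, NA_integer_)
  keep <- ids != anchor_id
  mt_alignment(ids[keep], rows[keep], colmap)
}

#' Classify the indels of a unit alignment
#'
#' Every maximal gap run in every row is classified: in coding units, a run
#' is `codon_full` when its length is a multiple of 3 and it starts on a
#' codon boundary (per the unit's reading-frame offset), otherwise
#' `frameshift`; runs in non-coding units are `noncoding`. Unsequenced
#' padding (`?`) is not an indel.
#'
#' @param unit_aln an [mt_alignment] of one unit, with colmap.
#' @param unit one row of an annotation's `units` table.
#' @return data frame with columns `id`, `unit`, `ref_pos`, `length`,
#'   `kind`.
#' @export
classify_indels <- function(unit_aln, unit) {
  out <- list()
  colmap <- unit_aln$colmap
  # reference position associated with a column (insertions -> left residue)
  left_pos <- colmap
  last <- unit$start - 1L
  for (i in seq_along(left_pos)) {
    if (is.na(left_pos[i])) left_pos[i] <- last else last <- left_pos[i]
  }
  for (r in seq_along(unit_aln$ids)) {
    runs <- .gap_runs(unit_aln$rows[r])
    for (j in seq_len(nrow(runs))) {
      st <- runs$start[j]; len <- runs$length[j]
      pos <- if (!is.na(colmap[st])) colmap[st] else left_pos[st] + 1L
      kind <- if (!unit$coding) "noncoding"
      else if (len %% 3L == 0L &&
               (pos - unit$start - unit$frame) %% 3L == 0L) "codon_full"
      else "frameshift"
      out[[length(out) + 1L]] <- data.frame(
        id = unit_aln$ids[r], unit = unit$name, ref_pos = pos,
        length = len, kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), unit = character(),
                      ref_pos = integer(), length = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Merge unit alignments into a full alignment
#'
#' Concatenates the per-unit alignments in unit order. Rows absent from a
#' unit are padded with unsequenced markers (`?`) and flagged. Where
#' adjacent units overlap, the left unit's columns are kept and the right
#' unit's overlapping columns are dropped after verifying that each row's
#' residues agree; disagreement is an error naming the sequence and the
#' unit pair.
#'
#' @param unit_alns named list of [mt_alignment]s, one per unit, in
#'   annotation unit order.
#' @param annotation the [mt_annotation] that defined the units.
#' @return an [mt_alignment] spanning all reference positions, with a
#'   `padded` attribute (data frame id/unit) listing the gap-filled spans.
#' @export
merge_units <- function(unit_alns, annotation) {
  stopifnot(length(unit_alns) >= 1L)
  all_ids <- sort(unique(unlist(lapply(unit_alns, `[[`, "ids"))))
  rows <- stats::setNames(rep("", length(all_ids)), all_ids)
  colmap <- integer(0)
  padded <- list()
  covered_to <- 0L
  unames <- names(unit_alns)
  for (u in seq_along(unit_alns)) {
    ua <- unit_alns[[u]]
    ucm <- ua$colmap
    if (is.null(ucm)) stop("unit alignment '", unames[u], "' lacks a colmap")
    keep <- is.na(ucm) | ucm > covered_to
    # never keep leading insertion columns that precede dropped reference
    # columns (they belong to the overlapped region)
    if (any(!keep)) {
      last_drop <- max(which(!keep))
      keep[seq_len(last_drop)] <- ucm[seq_len(last_drop)] > covered_to &
        !is.na(ucm[seq_len(last_drop)])
      # verify residue agreement in the overlap, row by row
      drop_cols <- which(!keep)
      ref_drop <- ucm[drop_cols]
      for (id in ua$ids) {
        right <- .degap(paste(strsplit(ua$rows[match(id, ua$ids)], "")[[1]][drop_cols],
                              collapse = ""))
        left_cols <- which(colmap %in% ref_drop)
        if (id %in% names(rows) && nzchar(rows[id]) && length(left_cols)) {
          left <- .degap(paste(strsplit(rows[id], "")[[1]][left_cols],
                               collapse = ""))
          if (!identical(left, right))
            stop("overlap disagreement for sequence '", id, "' between units '",
                 unames[u - 1L], "' and '", unames[u], "'")
        }
      }
    }
    ncols_kept <- sum(keep)
    for (id in all_ids) {
      i <- match(id, ua$ids)
      piece <- if (is.na(i)) {
        padded[[length(padded) + 1L]] <- data.frame(id = id, unit = unames[u],
                                                    stringsAsFactors = FALSE)
        strrep("?", ncols_kept)
      } else {
        paste(strsplit(ua$rows[i], "")[[1]][keep], collapse = "")
      }
      rows[id] <- paste0(rows[id], piece)
    }
    colmap <- c(colmap, ucm[keep])
    covered_to <- max(covered_to, ucm[!is.na(ucm)])
  }
  aln <- mt_alignment(all_ids, unname(rows), colmap)
  attr(aln, "padded") <- if (length(padded)) do.call(rbind, padded)
  else data.frame(id = character(), unit = character(), stringsAsFactors = FALSE)
  aln
}

#' Partitioned alignment of a dataset against a reference
#'
#' Convenience driver: splits every sequence by structural units (reusing
#' cached reference alignments when supplied), aligns each unit and merges
#' the results.
#'
#' @param dataset an [mt_dataset] (raw sequences).
#' @param annotation an [mt_annotation].
#' @param engine passed to [align_unit].
#' @param scoring a [scoring_scheme].
#' @param ref_alignments optional named list of cached [global_align]
#'   results (id -> alignment against the reference).
#' @return the merged [mt_alignment]; unit alignments are attached as the
#'   `units` attribute and indel calls as the `indels` attribute.
#' @export
partition_align <- function(dataset, annotation, engine = "internal",
                            scoring = scoring_scheme(gap_open = 3),
                            ref_alignments = NULL) {
  seqs <- dataset$sequences
  units <- annotation$units
  slices <- matrix("", nrow(seqs), nrow(units),
                   dimnames = list(seqs$id, units$name))
  for (i in seq_len(nrow(seqs))) {
    ra <- ref_alignments[[seqs$id[i]]]
    sp <- split_by_units(seqs$residues[i], annotation, ra, scoring)
    slices[i, ] <- sp$residues
  }
  unit_alns <- list()
  indels <- list()
  for (j in seq_len(nrow(units))) {
    sl <- slices[, j]
    nonempty <- sl[nzchar(sl)]
    ref_unit <- substr(annotation$reference, units$start[j], units$end[j])
    ua <- if (length(nonempty) >= 2L) {
      align_unit(nonempty, ref_unit, unit_start = units$start[j],
                 engine = engine, scoring = scoring)
    } else if (length(nonempty) == 1L) {
      pa <- global_align(nonempty[[1]], ref_unit, scoring)
      d <- .anchor_decompose(pa$aligned_a, pa$aligned_b)
      cm <- integer(0); row <- character(0)
      L <- nchar(ref_unit)
      for (p in 0:L) {
        row <- c(row, d$ins[p + 1L], if (p < L) d$sym[p + 1L])
        cm <- c(cm, rep(NA_integer_, nchar(d$ins[p + 1L])),
                if (p < L) units$start[j] + p)
      }
      mt_alignment(names(nonempty), paste(row, collapse = ""), cm)
    } else {
      mt_alignment(character(0), character(0), NULL)
    }
    if (length(ua$ids)) {
      unit_alns[[units$name[j]]] <- ua
      indels[[units$name[j]]] <- classify_indels(ua, units[j, ])
    }
  }
  merged <- merge_units(unit_alns, annotation)
  attr(merged, "units") <- unit_alns
  attr(merged, "indels") <- do.call(rbind, unname(indels))
  merged
}
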