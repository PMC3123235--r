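# Domain containers: sequence datasets, reference annotations, alignments.
# Coordinates are 1-based inclusive in reference ("canonical") space.

# IUPAC nucleotide alphabet. U is normalized to T on input; '-' only occurs
# in aligned rows; '?' marks unsequenced padding (never a biological symbol).
.IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)
.RAW_ALPHABET  <- names(.IUPAC_SETS)
.ALN_ALPHABET  <- c(.RAW_ALPHABET, "-", "?")

# Bitmask encoding over the 5-state Fitch alphabet {A,C,G,T,-}:
# A=1, C=2, G=4, T=8, '-'=16; '?' (unsequenced) expands to all 5 states.
.STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.symbol_masks <- local({
  m <- integer(length(.ALN_ALPHABET))
  names(m) <- .ALN_ALPHABET
  for (s in names(.IUPAC_SETS)) {
    bases <- strsplit(.IUPAC_SETS[[s]], "")[[1]]
    m[s] <- sum(.STATE_BITS[bases])
  }
  m["-"] <- 16L
  m["?"] <- 31L
  m
})

#' Convert residue symbols to Fitch state bitmasks
#'
#' Each IUPAC symbol maps to the set of bases it denotes (`N` to all four),
#' `-` to the gap state and `?` (unsequenced padding) to the full five-state
#' set so that it can never force a change.
#'
#' @param symbols character vector of single residue symbols.
#' @return integer vector of bitmasks (A=1, C=2, G=4, T=8, gap=16).
#' @keywords internal
symbol_to_mask <- function(symbols) {
  m <- .symbol_masks[symbols]
  if (anyNA(m)) {
    bad <- unique(symbols[is.na(m)])
    stop("symbols outside the alignment alphabet: ", paste(bad, collapse = ", "))
  }
  unname(m)
}

.mask_to_state <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T", `16` = "-")

# Lowest set bit in the deterministic resolution order A < C < G < T < '-'.
.lowest_bit <- function(mask) {
  out <- integer(length(mask))
  for (b in c(1L, 2L, 4L, 8L, 16L)) {
    hit <- out == 0L & bitwAnd(mask, b) > 0L
    out[hit] <- b
  }
  out
}

# IUPAC-style code of a state set (used to report ambiguous event endpoints);
# sets mixing gap and bases have no IUPAC code and are written "<code>/-".
.mask_to_code <- local({
  codes <- character(31)
  base_masks <- vapply(names(.IUPAC_SETS), function(s) {
    sum(.STATE_BITS[strsplit(.IUPAC_SETS[[s]], "")[[1]]])
  }, integer(1))
  for (i in seq_along(base_masks)) codes[base_masks[i]] <- names(base_masks)[i]
  for (m in 1:31) {
    if (m == 16L) codes[m] <- "-"
    else if (m > 16L) codes[m] <- paste0(codes[m - 16L], "/-")
  }
  function(mask) codes[mask]
})

.validate_residues <- function(residues, ids, aligned = FALSE) {
  pat <- if (aligned) "[^ACGTMRWSYKVHDBN?-]" else "[^ACGTMRWSYKVHDBN]"
  bad <- grepl(pat, residues)
  if (any(bad)) {
    stop("sequence '", ids[which(bad)[1]], "' contains symbols outside the ",
         if (aligned) "alignment" else "raw IUPAC", " alphabet")
  }
  invisible(TRUE)
}

#' Construct a sequence dataset
#'
#' A dataset couples raw (ungapped) sequences with a provenance log of
#' curation actions. Residues are uppercased and `U` is normalized to `T`;
#' gaps are rejected because they have no meaning in raw sequences.
#'
#' @param id,residues character vectors of equal length.
#' @param species,source optional per-sequence labels.
#' @param tier curation tier, one of `"strict"`, `"flexible"`, `"excluded"`,
#'   `"unclassified"`.
#' @return an object of class `mt_dataset`: a list with elements
#'   `sequences` (data frame: id, residues, species, source, tier) and
#'   `log` (data frame: rule, id, decision).
#' @export
mt_dataset <- function(id, residues, species = "synthetic", source = "",
                       tier = "unclassified") {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  residues <- chartr("u", "t", residues)
  residues <- toupper(residues)
  residues <- chartr("U", "T", residues)
  if (any(!nzchar(residues))) stop("residues must be non-empty")
  .validate_residues(residues, id, aligned = FALSE)
  seqs <- data.frame(id = id, residues = residues,
                     species = rep_len(as.character(species), length(id)),
                     source = rep_len(as.character(source), length(id)),
                     tier = rep_len(match.arg(tier, c("strict", "flexible",
                                                      "excluded", "unclassified"),
                                              several.ok = FALSE), length(id)),
                     stringsAsFactors = FALSE)
  structure(list(sequences = seqs, log = .empty_log()), class = "mt_dataset")
}

.empty_log <- function() {
  data.frame(rule = character(), id = character(), decision = character(),
             stringsAsFactors = FALSE)
}

.log_action <- function(dataset, rule, id, decision) {
  dataset$log <- rbind(dataset$log,
                       data.frame(rule = rule, id = id, decision = decision,
                                  stringsAsFactors = FALSE))
  dataset
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat("<mt_dataset> ", nrow(x$sequences), " sequences, ",
      nrow(x$log), " logged curation actions\n", sep = "")
  tab <- table(x$sequences$tier)
  cat("  tiers:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a reference annotation
#'
#' Ordered structural units (genes, non-coding gaps in the coding region and
#' the two control-region parts created by the circular numbering origin)
#' over a linear reference in canonical coordinates. Unit intervals must
#' cover every reference position; only adjacent units may overlap.
#'
#' @param reference_id,reference_residues the reference genome.
#' @param units data frame with columns `name`, `kind` (one of `gene`,
#'   `noncoding_gap`, `control_region_part`), `start`, `end` (1-based
#'   inclusive), `coding` (logical) and `frame` (0..2, coding units only).
#' @param circular logical; the molecule is circular and downstream
#'   algorithms operate on rotation-corrected linearizations.
#' @return an object of class `mt_annotation`.
#' @export
mt_annotation <- function(reference_id, reference_residues, units,
                          circular = TRUE) {
  reference_residues <- toupper(chartr("Uu", "TT", reference_residues))
  n <- nchar(reference_residues)
  stopifnot(is.data.frame(units),
            all(c("name", "kind", "start", "end", "coding") %in% names(units)))
  if (is.null(units$frame)) units$frame <- 0L
  units <- units[order(units$start, units$end), , drop = FALSE]
  rownames(units) <- NULL
  if (any(units$start < 1L) || any(units$end > n) || any(units$start > units$end))
    stop("unit intervals must satisfy 1 <= start <= end <= reference length")
  if (any(units$coding & units$kind != "gene"))
    stop("only gene units may be coding")
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(units))) covered[units$start[i]:units$end[i]] <- TRUE
  if (!all(covered))
    stop("unit intervals do not cover the reference (first uncovered position ",
         which(!covered)[1], ")")
  # non-adjacent units must not overlap
  if (nrow(units) > 2L) {
    for (i in seq_len(nrow(units) - 2L)) {
      later <- units[(i + 2L):nrow(units), , drop = FALSE]
      clash <- later$start <= units$end[i]
      if (any(clash))
        stop("non-adjacent units overlap: ", units$name[i], " and ",
             later$name[which(clash)[1]])
    }
  }
  structure(list(reference_id = reference_id,
                 reference = reference_residues,
                 units = units, circular = circular,
                 false_gap_positions = integer()),
            class = "mt_annotation")
}

#' @export
print.mt_annotation <- function(x, ...) {
  cat("<mt_annotation> reference ", x$reference_id, " (",
      nchar(x$reference), " bp), ", nrow(x$units), " structural units: ",
      sum(x$units$kind == "gene"), " genes, ",
      sum(x$units$kind == "noncoding_gap"), " non-coding gaps, ",
      sum(x$units$kind == "control_region_part"), " control-region parts\n",
      sep = "")
  invisible(x)
}

#' Construct a multiple alignment
#'
#' Equal-length gapped rows plus a column map into reference coordinates.
#' `colmap[i]` is the canonical reference position of column `i`, or `NA`
#' for an insertion column; reference positions are strictly increasing
#' where present.
#'
#' @param ids sequence identifiers (unique).
#' @param rows gapped residue strings, all the same length.
#' @param colmap integer vector of length `ncols`, or `NULL` when the
#'   alignment is not anchored to a reference.
#' @return an object of class `mt_alignment` with elements `ids`, `rows`,
#'   `ncols`, `colmap`.
#' @export
mt_alignment <- function(ids, rows, colmap = NULL) {
  ids <- unname(as.character(ids))
  rows <- unname(toupper(chartr("Uu", "TT", rows)))
  if (anyDuplicated(ids)) stop("row ids must be unique")
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  ncols <- unique(nchar(rows))
  if (length(ncols) > 1L) stop("alignment rows must all have the same length")
  .validate_residues(rows, ids, aligned = TRUE)
  if (!is.null(colmap)) {
    if (length(colmap) != ncols) stop("colmap length must equal ncols")
    refp <- colmap[!is.na(colmap)]
    if (is.unsorted(refp, strictly = TRUE))
      stop("reference positions in colmap must be strictly increasing")
  }
  structure(list(ids = ids, rows = rows, ncols = as.integer(ncols),
                 colmap = if (is.null(colmap)) NULL else as.integer(colmap)),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("<mt_alignment> ", length(x$ids), " rows x ", x$ncols, " columns",
      if (!is.null(x$colmap))
        paste0(" (", sum(is.na(x$colmap)), " insertion columns)"),
      "\n", sep = "")
  invisible(x)
}

# Character matrix view of an alignment (rows x columns).
.aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$rows, ""), use.names = FALSE),
              nrow = length(aln$ids), ncol = aln$ncols, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

# Bitmask matrix view of an alignment.
.aln_masks <- function(aln) {
  m <- .aln_matrix(aln)
  mm <- matrix(symbol_to_mask(m), nrow = nrow(m))
  rownames(mm) <- aln$ids
  mm
}

.degap <- function(s) gsub("[-?]", "", s)
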