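# Readers and writers for the standard formats the pipeline touches:
# FASTA, GenBank feature tables, newick and phyloXML.

#' Read a FASTA file into a dataset
#'
#' Residues are uppercased and `U` normalized to `T`; every record enters
#' with tier `unclassified`. Records containing symbols outside the IUPAC
#' DNA alphabet are a parse error.
#'
#' @param path path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param species,source optional provenance labels applied to all records.
#' @return an [mt_dataset].
#' @export
read_fasta <- function(path, species = "", source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    d <- structure(list(sequences = data.frame(id = character(),
                                               residues = character(),
                                               species = character(),
                                               source = character(),
                                               tier = character(),
                                               stringsAsFactors = FALSE),
                        log = .empty_log()), class = "mt_dataset")
    return(.log_action(d, "read_fasta", path, "empty file"))
  }
  # BStringSet keeps residues verbatim (readDNAStringSet would silently
  # drop U); normalization and alphabet checks happen in mt_dataset
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  residues <- unname(as.character(set))
  mt_dataset(ids, residues, species = species,
             source = if (is.null(source)) path else source)
}

#' Write a dataset or alignment to FASTA
#'
#' @param x an [mt_dataset] or [mt_alignment].
#' @param path output path.
#' @param width line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "mt_dataset")) {
    ids <- x$sequences$id; rows <- x$sequences$residues
  } else if (inherits(x, "mt_alignment")) {
    ids <- x$ids; rows <- x$rows
  } else stop("x must be an mt_dataset or mt_alignment")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- rows[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenBank flat-file feature table

# Parse one GenBank location string. Returns a data frame of (start, end)
# spans; "join(16024..16569,1..576)" style origin-spanning locations yield
# two spans. Complement strand is irrelevant for partitioning.
.parse_gb_location <- function(loc) {
  loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3L) return(c(as.integer(m[2]), as.integer(m[3])))
    if (grepl("^\\d+$", p)) return(rep(as.integer(p), 2L))
    stop("cannot parse GenBank location: ", loc)
  })
  data.frame(start = vapply(out, `[`, integer(1), 1L),
             end = vapply(out, `[`, integer(1), 2L))
}

# Minimal GenBank flat-file reader: LOCUS length, FEATURES table and the
# optional ORIGIN sequence block. No installed R package parses this format.
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  ref_len <- if (length(locus))
    as.integer(sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1", locus[1]))
  else NA_integer_
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("GenBank record has no FEATURES table: ", path)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]
  # a feature starts with a key in columns 6-20
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  feats <- list()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1L] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    quals <- block[-1]
    # continuation lines of the location have no '='
    while (length(quals) && !grepl("^\\s+/", quals[1])) {
      loc <- paste0(loc, trimws(quals[1]))
      quals <- quals[-1]
    }
    getq <- function(name) {
      pat <- paste0("^\\s+/", name, "=\"?([^\"]*)\"?\\s*$")
      hit <- grep(pat, quals, value = TRUE)
      if (length(hit)) sub(pat, "\\1", hit[1]) else NA_character_
    }
    feats[[j]] <- list(key = key, location = loc,
                       gene = getq("gene"), product = getq("product"),
                       note = getq("note"))
  }
  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) min(oend[oend > ostart[1]]) - 1L else length(lines)
    seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[(ostart[1] + 1L):oend],
                                               collapse = "")))
    seq <- chartr("U", "T", seq)
  }
  list(length = ref_len, features = feats, sequence = seq,
       accession = {
         acc <- grep("^ACCESSION", lines, value = TRUE)
         if (length(acc)) sub("^ACCESSION\\s+(\\S+).*$", "\\1", acc[1]) else "reference"
       })
}

#' Read a reference annotation from a GenBank flat file
#'
#' Builds the ordered structural-unit table used for partitioned alignment:
#' all annotated genes (one unit per `gene` feature, `coding` when a CDS
#' shares its span), one `noncoding_gap` unit per maximal unannotated
#' interval inside the coding region, and the control region (D-loop) split
#' into the two parts created by the canonical numbering origin. Applied to
#' the human rCRS record this yields 50 units (37 genes, 11 gaps, 2
#' control-region parts).
#'
#' @param path GenBank flat file with a feature table; the sequence block is
#'   optional if `reference_fasta` supplies the residues.
#' @param reference_fasta optional FASTA file providing the reference
#'   residues when the GenBank record has no ORIGIN block.
#' @return an [mt_annotation].
#' @export
read_reference_annotation <- function(path, reference_fasta = NULL) {
  gb <- .read_genbank(path)
  n <- gb$length
  seq <- gb$sequence
  if (is.null(seq)) {
    if (!is.null(reference_fasta)) {
      d <- read_fasta(reference_fasta)
      seq <- d$sequences$residues[1]
    } else {
      # feature table only: a placeholder reference of the declared length
      if (is.na(n)) stop("record has neither sequence nor LOCUS length")
      seq <- strrep("N", n)
    }
  }
  if (is.na(n)) n <- nchar(seq)
  if (nchar(seq) != n) stop("reference length (", nchar(seq),
                            ") does not match LOCUS length (", n, ")")

  keys <- vapply(gb$features, `[[`, character(1), "key")
  cds_genes <- unique(na.omit(vapply(gb$features[keys == "CDS"], `[[`,
                                     character(1), "gene")))
  units <- list()
  for (f in gb$features[keys == "gene"]) {
    sp <- .parse_gb_location(f$location)
    if (nrow(sp) > 1L) stop("origin-spanning gene feature unsupported: ", f$gene)
    units[[length(units) + 1L]] <- data.frame(
      name = if (!is.na(f$gene)) f$gene else paste0("gene_", sp$start[1]),
      kind = "gene", start = sp$start[1], end = sp$end[1],
      coding = !is.na(f$gene) && f$gene %in% cds_genes, frame = 0L,
      stringsAsFactors = FALSE)
  }
  if (!length(units)) stop("no gene features found in ", path)
  genes <- do.call(rbind, units)
  genes <- genes[order(genes$start), , drop = FALSE]

  # control region: D-loop feature (located under misc_feature or D-loop key)
  dloop <- NULL
  for (f in gb$features) {
    txt <- paste(na.omit(c(f$key, f$note, f$product)), collapse = " ")
    if (f$key == "D-loop" || grepl("D-loop|control region", txt, ignore.case = TRUE)) {
      dloop <- .parse_gb_location(f$location); break
    }
  }
  cr <- NULL
  if (!is.null(dloop)) {
    if (nrow(dloop) == 1L && dloop$start[1] > dloop$end[1]) {
      # circular coordinates: end < start means the feature spans the origin
      dloop <- data.frame(start = c(dloop$start[1], 1L), end = c(n, dloop$end[1]))
    }
    dloop <- dloop[order(dloop$start), , drop = FALSE]
    cr <- data.frame(name = paste0("control_region_", seq_len(nrow(dloop))),
                     kind = "control_region_part",
                     start = dloop$start, end = dloop$end,
                     coding = FALSE, frame = 0L, stringsAsFactors = FALSE)
  }

  # non-coding gaps: maximal unannotated intervals inside the coding region
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(genes))) covered[genes$start[i]:genes$end[i]] <- TRUE
  if (!is.null(cr))
    for (i in seq_len(nrow(cr))) covered[cr$start[i]:cr$end[i]] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- data.frame(start = starts[!runs$values], end = ends[!runs$values])
  if (nrow(gaps)) {
    gaps <- data.frame(name = paste0("noncoding_gap_", seq_len(nrow(gaps))),
                       kind = "noncoding_gap", start = gaps$start,
                       end = gaps$end, coding = FALSE, frame = 0L,
                       stringsAsFactors = FALSE)
  } else gaps <- NULL

  units <- rbind(genes, gaps, cr)
  ann <- mt_annotation(gb$accession, seq, units, circular = TRUE)
  # rCRS false gap: the historical placeholder N at canonical 3107
  if (n >= 3107 && substr(seq, 3107, 3107) == "N")
    ann$false_gap_positions <- 3107L
  ann
}

# ---------------------------------------------------------------------------
# Tree output

#' Write a tree in newick format
#'
#' Branch lengths and (node-label) support values are preserved; re-reading
#' the file reproduces the bipartition set, including polytomies.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  # quote labels containing newick-reserved characters
  fix <- function(l) {
    bad <- grepl("[,;:()\\[\\]' ]", l)
    l[bad] <- paste0("'", gsub("'", "''", l[bad]), "'")
    l
  }
  tr$tip.label <- fix(tr$tip.label)
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Write an annotated tree as phyloXML
#'
#' Serializes the topology with branch lengths and supports, attaching each
#' branch's mutation events as `<property>` elements on the child clade
#' (`ref` keys: position, from, to, flags).
#'
#' @param tree an `ape::phylo` tree (rooted).
#' @param path output path.
#' @param events optional event table from [extract_events]/[flag_events];
#'   events are attached by their `child` node id.
#' @return `path`, invisibly.
#' @export
write_phyloxml <- function(tree, path, events = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- if (!is.null(tree$edge.length)) {
    stats::setNames(tree$edge.length, tree$edge[, 2])
  } else NULL
  ev_by_child <- if (!is.null(events) && nrow(events))
    split(events, events$child) else list()

  doc <- xml2::xml_new_root("phyloxml",
    xmlns = "http://www.phyloxml.org",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance")
  phy <- xml2::xml_add_child(doc, "phylogeny", rooted = "true")

  add_clade <- function(parent_node, node_id) {
    cl <- xml2::xml_add_child(parent_node, "clade")
    if (node_id <= ntip)
      xml2::xml_add_child(cl, "name", tree$tip.label[node_id])
    else if (!is.null(tree$node.label)) {
      lab <- tree$node.label[node_id - ntip]
      if (!is.na(lab) && nzchar(lab)) xml2::xml_add_child(cl, "name", lab)
    }
    bi <- if (!is.null(blen)) match(as.character(node_id), names(blen))
          else NA_integer_
    if (!is.na(bi))
      xml2::xml_add_child(cl, "branch_length", format(blen[[bi]], digits = 12))
    evs <- ev_by_child[[as.character(node_id)]]
    if (!is.null(evs)) {
      for (i in seq_len(nrow(evs))) {
        val <- paste0(evs$from[i], ">", evs$to[i])
        if (!is.character(val) || is.na(val))
          stop("unserializable annotation on branch to node ", node_id)
        pos <- if (!is.na(evs$ref_pos[i])) evs$ref_pos[i]
               else paste0("ins@col", evs$column[i])
        flagset <- c("conserved", "back_mutation", "ambiguous", "indel")
        flags <- flagset[unlist(evs[i, flagset])]
        xml2::xml_add_child(cl, "property",
                            paste0(pos, ":", val,
                                   if (length(flags))
                                     paste0(" [", paste(flags, collapse = ","), "]")
                                   else ""),
                            ref = "mtphylo:mutation",
                            applies_to = "parent_branch",
                            datatype = "xsd:string")
      }
    }
    for (ch in kids[[as.character(node_id)]]) add_clade(cl, ch)
  }
  add_clade(phy, ntip + 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read the topology back from a phyloXML file
#'
#' @param path phyloXML file written by [write_phyloxml].
#' @return an `ape::phylo` tree.
#' @export
read_phyloxml_topology <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_find_first(doc, ".//phylogeny/clade")
  nwk <- function(node) {
    ch <- xml2::xml_find_all(node, "./clade")
    name <- xml2::xml_text(xml2::xml_find_first(node, "./name"))
    bl <- xml2::xml_text(xml2::xml_find_first(node, "./branch_length"))
    lab <- if (is.na(name)) "" else name
    blp <- if (is.na(bl)) "" else paste0(":", bl)
    if (length(ch) == 0L) return(paste0(lab, blp))
    paste0("(", paste(vapply(ch, nwk, character(1)), collapse = ","), ")",
           lab, blp)
  }
  ape::read.tree(text = paste0(nwk(root), ";"))
}
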