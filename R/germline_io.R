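# Germline segment libraries, AIRR rearrangement IO, and FACS-style gating.

VALID_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB")
HEAVY_LOCI <- c("IGH", "TRB")
MARKER_NAMES <- c("CD3", "CD4", "CD8", "CD14", "CD19", "CD20", "CD27", "CD38", "CD138")
CELL_STATES <- c("MBC", "prePB", "PB", "PC", "unknown")
REACTIVITIES <- c("LGI1", "CASPR2", "other_CNS", "negative", "untested")

#' Construct a germline segment library
#'
#' A segment library holds annotated germline V/D/J nucleotide segments for
#' one or more immunoglobulin/TCR loci. V and J segments carry the position
#' of the conserved junction-boundary codon (the CDR3-flanking cysteine for
#' V, the tryptophan/phenylalanine for J).
#'
#' @param segment_id Character vector of unique segment names
#'   (e.g. `"IGHV3-23*01"`).
#' @param locus One of `"IGH"`, `"IGK"`, `"IGL"`, `"TRA"`, `"TRB"` per segment.
#' @param segment_type `"V"`, `"D"` or `"J"` per segment.
#' @param sequence Nucleotide strings (A/C/G/T/N).
#' @param cdr3_anchor 1-based start of the conserved junction-boundary codon
#'   within each segment; `NA` for D segments.
#' @return A `data.frame` of class `segment_library`.
#' @seealso [read_segment_fasta()], [write_segment_fasta()]
#' @export
segment_library <- function(segment_id, locus, segment_type, sequence, cdr3_anchor) {
  lib <- data.frame(
    segment_id = as.character(segment_id),
    locus = as.character(locus),
    segment_type = as.character(segment_type),
    sequence = toupper(as.character(sequence)),
    cdr3_anchor = as.integer(cdr3_anchor),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("segment_library", "data.frame")
  validate_segment_library(lib)
  lib
}

#' @keywords internal
validate_segment_library <- function(lib) {
  if (anyDuplicated(lib$segment_id)) {
    dup <- lib$segment_id[duplicated(lib$segment_id)][1]
    stopf("duplicate segment_id in library: '%s'", dup)
  }
  bad_locus <- setdiff(unique(lib$locus), VALID_LOCI)
  if (length(bad_locus)) stopf("invalid locus: '%s'", bad_locus[1])
  bad_type <- setdiff(unique(lib$segment_type), c("V", "D", "J"))
  if (length(bad_type)) stopf("invalid segment_type: '%s'", bad_type[1])
  for (i in seq_len(nrow(lib))) {
    assert_dna(lib$sequence[i], sprintf("segment '%s'", lib$segment_id[i]))
    if (lib$segment_type[i] %in% c("V", "J")) {
      a <- lib$cdr3_anchor[i]
      if (is.na(a) || a < 1L || a + 2L > nchar(lib$sequence[i])) {
        stopf("segment '%s': cdr3_anchor missing or out of bounds", lib$segment_id[i])
      }
    }
  }
  invisible(lib)
}

#' Read a germline segment library from FASTA
#'
#' Headers use a pipe-delimited dialect `segment_id|locus|type|anchor`, where
#' `anchor` is the 0-based offset of the conserved junction-boundary codon
#' (empty for D segments).
#'
#' @param path Path to a FASTA file.
#' @return A [segment_library()].
#' @export
read_segment_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  headers <- names(fa)
  parts <- strsplit(headers, "|", fixed = TRUE)
  # a trailing empty anchor field ("...|D|") is dropped by strsplit; restore it
  parts <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) == 3L && endsWith(headers[i], "|")) c(p, "") else p
  })
  n_fields <- lengths(parts)
  if (any(n_fields != 4L)) {
    bad <- headers[n_fields != 4L][1]
    stopf("malformed FASTA header (expected id|locus|type|anchor): '%s'", bad)
  }
  m <- do.call(rbind, parts)
  anchor0 <- suppressWarnings(as.integer(m[, 4]))
  is_d <- m[, 3] == "D"
  if (any(!is_d & (is.na(anchor0) | !nzchar(m[, 4])))) {
    bad <- headers[!is_d & is.na(anchor0)][1]
    stopf("V/J record missing numeric anchor: '%s'", bad)
  }
  segment_library(
    segment_id = m[, 1],
    locus = m[, 2],
    segment_type = m[, 3],
    sequence = vapply(fa, as.character, character(1)),
    cdr3_anchor = ifelse(is_d, NA_integer_, anchor0 + 1L)
  )
}

#' Write a germline segment library to FASTA
#'
#' @param lib A [segment_library()].
#' @param path Output path.
#' @export
write_segment_fasta <- function(lib, path) {
  validate_segment_library(lib)
  anchor0 <- ifelse(is.na(lib$cdr3_anchor), "", as.character(lib$cdr3_anchor - 1L))
  headers <- paste(lib$segment_id, lib$locus, lib$segment_type, anchor0, sep = "|")
  seqinr::write.fasta(
    sequences = as.list(lib$sequence),
    names = headers, file.out = path, as.string = TRUE, nbchar = 80
  )
  invisible(path)
}

# column order for the per-cell table
CELL_COLUMNS <- c(
  "cell_id", "donor",
  "heavy_sequence", "heavy_v_call", "heavy_d_call", "heavy_j_call",
  "heavy_junction", "heavy_junction_aa", "heavy_c_call", "heavy_n_mask",
  "light_locus", "light_sequence", "light_v_call", "light_j_call",
  "light_junction", "light_junction_aa", "light_c_call", "light_n_mask",
  MARKER_NAMES, "cell_state", "reactivity", "endpoint_conc"
)

AIRR_COLUMNS <- c(
  "cell_id", "locus", "sequence", "v_call", "d_call", "j_call",
  "junction", "junction_aa", "c_call", "n_region_mask"
)

#' Read an AIRR rearrangement table into per-cell records
#'
#' Reads a tab-separated rearrangement file (one row per chain) and groups
#' chains into cells. Heavy chains are those on the IGH/TRB loci. Cells with
#' more than one heavy chain are excluded and reported via the `excluded`
#' attribute; cells lacking a light chain are retained for heavy-chain-only
#' analyses. Optional per-cell metadata (donor, surface markers, cell state,
#' tested reactivity, endpoint concentration) is merged by `cell_id`.
#'
#' The `n_region_mask` column, when present, lists 0-based positions of
#' non-templated nucleotides as a comma-separated string.
#'
#' @param path Path to the AIRR TSV.
#' @param metadata Optional path to a per-cell metadata CSV with a `cell_id`
#'   column.
#' @return A `data.frame` with one row per cell and an `excluded` attribute
#'   (a `data.frame` of excluded cell ids and reasons).
#' @export
read_airr <- function(path, metadata = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) {
    warnf("empty AIRR file: %s", path)
    return(empty_cell_table())
  }
  mandatory <- c("cell_id", "locus", "sequence", "junction", "c_call")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing)) {
    stopf("AIRR file missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in setdiff(AIRR_COLUMNS, names(tab))) tab[[col]] <- NA_character_
  tab$is_heavy <- tab$locus %in% HEAVY_LOCI

  excluded <- data.frame(cell_id = character(0), reason = character(0))
  rows <- split(tab, tab$cell_id)
  cells <- vector("list", length(rows))
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    cr <- rows[[i]]
    n_heavy <- sum(cr$is_heavy)
    if (n_heavy > 1L) {
      excluded <- rbind(excluded, data.frame(
        cell_id = cr$cell_id[1], reason = "multiple heavy chains"
      ))
      next
    }
    if (n_heavy == 0L) {
      excluded <- rbind(excluded, data.frame(
        cell_id = cr$cell_id[1], reason = "no heavy chain"
      ))
      next
    }
    h <- cr[cr$is_heavy, ][1, ]
    l <- cr[!cr$is_heavy, ]
    if (nrow(l) > 1L) l <- l[1, , drop = FALSE]  # keep first light chain
    cells[[i]] <- data.frame(
      cell_id = h$cell_id, donor = NA_character_,
      heavy_sequence = h$sequence, heavy_v_call = h$v_call,
      heavy_d_call = h$d_call, heavy_j_call = h$j_call,
      heavy_junction = h$junction, heavy_junction_aa = h$junction_aa,
      heavy_c_call = h$c_call, heavy_n_mask = na_to_empty(h$n_region_mask),
      light_locus = if (nrow(l)) l$locus else NA_character_,
      light_sequence = if (nrow(l)) l$sequence else NA_character_,
      light_v_call = if (nrow(l)) l$v_call else NA_character_,
      light_j_call = if (nrow(l)) l$j_call else NA_character_,
      light_junction = if (nrow(l)) l$junction else NA_character_,
      light_junction_aa = if (nrow(l)) l$junction_aa else NA_character_,
      light_c_call = if (nrow(l)) l$c_call else NA_character_,
      light_n_mask = if (nrow(l)) na_to_empty(l$n_region_mask) else "",
      stringsAsFactors = FALSE
    )
    keep[i] <- TRUE
  }
  out <- do.call(rbind, cells[keep])
  if (is.null(out)) out <- empty_cell_table()
  if (nrow(excluded)) {
    message(sprintf("read_airr: excluded %d cell(s): %s", nrow(excluded),
                    paste(unique(excluded$reason), collapse = "; ")))
  }
  for (m in MARKER_NAMES) out[[m]] <- NA_real_
  out$cell_state <- "unknown"
  out$reactivity <- "untested"
  out$endpoint_conc <- NA_real_
  if (!is.null(metadata)) out <- merge_cell_metadata(out, metadata)
  out <- out[order(out$cell_id), CELL_COLUMNS]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

na_to_empty <- function(x) ifelse(is.na(x), "", x)

empty_cell_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(CELL_COLUMNS)))
  names(out) <- CELL_COLUMNS
  out
}

merge_cell_metadata <- function(cells, metadata_path) {
  if (!file.exists(metadata_path)) stopf("metadata file not found: %s", metadata_path)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(md)) stopf("metadata CSV must contain a cell_id column")
  idx <- match(cells$cell_id, md$cell_id)
  for (col in intersect(c("donor", MARKER_NAMES, "cell_state", "reactivity",
                          "endpoint_conc"), names(md))) {
    hit <- !is.na(idx)
    cells[[col]][hit] <- md[[col]][idx[hit]]
  }
  bad_state <- setdiff(stats::na.omit(unique(cells$cell_state)), CELL_STATES)
  if (length(bad_state)) stopf("invalid cell_state in metadata: '%s'", bad_state[1])
  bad_react <- setdiff(stats::na.omit(unique(cells$reactivity)), REACTIVITIES)
  if (length(bad_react)) stopf("invalid reactivity in metadata: '%s'", bad_react[1])
  conc <- cells$endpoint_conc
  if (any(!is.na(conc) & conc <= 0)) stopf("endpoint_conc must be > 0 when present")
  cells
}

#' Write per-cell records as an AIRR rearrangement table
#'
#' Inverse of [read_airr()]: one output row per chain, with standard AIRR
#' column names. Cell-level metadata is written separately by
#' [write_cell_metadata()].
#'
#' @param cells Per-cell table as returned by [read_airr()] or
#'   [simulate_repertoire()].
#' @param path Output TSV path.
#' @export
write_airr <- function(cells, path) {
  heavy <- data.frame(
    cell_id = cells$cell_id, locus = "IGH", sequence = cells$heavy_sequence,
    v_call = cells$heavy_v_call, d_call = cells$heavy_d_call,
    j_call = cells$heavy_j_call, junction = cells$heavy_junction,
    junction_aa = cells$heavy_junction_aa, c_call = cells$heavy_c_call,
    n_region_mask = na_to_empty(cells$heavy_n_mask), stringsAsFactors = FALSE
  )
  has_light <- !is.na(cells$light_sequence)
  light <- data.frame(
    cell_id = cells$cell_id[has_light], locus = cells$light_locus[has_light],
    sequence = cells$light_sequence[has_light],
    v_call = cells$light_v_call[has_light], d_call = NA_character_,
    j_call = cells$light_j_call[has_light],
    junction = cells$light_junction[has_light],
    junction_aa = cells$light_junction_aa[has_light],
    c_call = cells$light_c_call[has_light],
    n_region_mask = na_to_empty(cells$light_n_mask[has_light]),
    stringsAsFactors = FALSE
  )
  out <- rbind(heavy, light)
  out <- out[order(out$cell_id, out$locus != "IGH"), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-cell metadata CSV
#'
#' @param cells Per-cell table.
#' @param path Output CSV path.
#' @export
write_cell_metadata <- function(cells, path) {
  md <- cells[, c("cell_id", "donor", MARKER_NAMES, "cell_state",
                  "reactivity", "endpoint_conc")]
  utils::write.csv(md, path, row.names = FALSE)
  invisible(path)
}

#' Rule-based FACS phenotype gate
#'
#' Assigns the sorting phenotype from the nine surface-marker intensities,
#' following the gating rules used for CSF sorting in autoimmune
#' encephalitis: antibody-secreting cells (ASC) are CD3- and either CD138+
#' or CD19+CD20-CD38+; B cells are CD3-CD19+ non-ASCs; CD4 helper T cells
#' are CD3+CD4+CD138-.
#'
#' @param markers Named numeric vector containing all of CD3, CD4, CD8,
#'   CD14, CD19, CD20, CD27, CD38, CD138.
#' @param thresholds Named numeric vector of positivity cutoffs; a single
#'   number is recycled across markers. Default 0.5 on a normalised 0-1
#'   intensity scale.
#' @return One of `"ASC"`, `"B"`, `"CD4T"`, `"other"`.
#' @export
gate_phenotype <- function(markers, thresholds = 0.5) {
  missing <- setdiff(MARKER_NAMES, names(markers))
  if (length(missing)) {
    stopf("gate_phenotype: missing marker(s): %s", paste(missing, collapse = ", "))
  }
  if (length(thresholds) == 1L && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length(MARKER_NAMES)), MARKER_NAMES)
  }
  miss_thr <- setdiff(MARKER_NAMES, names(thresholds))
  if (length(miss_thr)) {
    stopf("gate_phenotype: missing threshold(s): %s", paste(miss_thr, collapse = ", "))
  }
  pos <- function(m) as.numeric(markers[[m]]) > thresholds[[m]]
  if (!pos("CD3") && (pos("CD138") || (pos("CD19") && !pos("CD20") && pos("CD38")))) {
    return("ASC")
  }
  if (!pos("CD3") && pos("CD19")) return("B")
  if (pos("CD3") && pos("CD4") && !pos("CD138")) return("CD4T")
  "other"
}
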