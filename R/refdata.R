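#' Germline reference sets
#'
#' A reference set holds IMGT-gapped germline alleles for antibody V and C
#' domains.  Each allele carries a gapped sequence over the alphabet
#' `[ACDEFGHIKLMNPQRSTVWY.]` (where `.` is an alignment gap at a fixed IMGT
#' column), its ungapped counterpart, the species it comes from, its gene
#' class (`V` or `C`), chain class (`H`, `K`, `L`) and a domain label
#' (`V`, `CH1`, `CH2`, `CH3`, `CH4`, `CL`, `hinge`).  All alleles sharing a
#' `(gene_class, domain_label)` alignment set must have the same gapped
#' width, so a gapped column index is comparable across alleles and can be
#' used as an IMGT-style position label.
#'
#' `read_reference_set()` loads such a set from a gapped FASTA file; `-` is
#' accepted as a gap synonym and normalised to `.`.  Metadata travels either
#' in pipe-delimited headers (`>allele_id|species|gene_class|chain_class|domain_label`)
#' or in a sidecar TSV keyed by `allele_id` with columns
#' `allele_id, species, gene_class, chain_class, domain_label`.
#'
#' @param path Path to a gapped FASTA file.
#' @param metadata_mode `"header_fields"` (default) or `"sidecar_table"`.
#' @param sidecar Path to the sidecar TSV (required for
#'   `metadata_mode = "sidecar_table"`).
#' @return A `ref_set`: a tibble with one row per allele and columns
#'   `allele_id`, `species`, `gene_class`, `chain_class`, `domain_label`,
#'   `gapped_seq`, `ungapped_seq`, plus an `alignment_width` attribute
#'   (tibble of gapped widths per alignment set).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">X|Homo sapiens|C|H|CH1", "A.CD"), fa)
#' rs <- read_reference_set(fa)
#' rs$ungapped_seq
#' @export
read_reference_set <- function(path,
                               metadata_mode = c("header_fields", "sidecar_table"),
                               sidecar = NULL) {
  metadata_mode <- match.arg(metadata_mode)
  if (!file.exists(path)) abort(sprintf("reference FASTA not found: %s", path))
  recs <- parse_fasta(path)
  if (nrow(recs) == 0L) abort(sprintf("no FASTA records in %s", path))

  if (metadata_mode == "header_fields") {
    fields <- strsplit(recs$header, "|", fixed = TRUE)
    bad <- which(lengths(fields) != 5L)
    if (length(bad) > 0L) {
      abort(sprintf(
        "header of record %d ('%s') does not have 5 pipe-delimited fields (allele_id|species|gene_class|chain_class|domain_label)",
        bad[1], recs$header[bad[1]]))
    }
    meta <- tibble(
      allele_id    = map_chr(fields, 1),
      species      = map_chr(fields, 2),
      gene_class   = map_chr(fields, 3),
      chain_class  = map_chr(fields, 4),
      domain_label = map_chr(fields, 5)
    )
  } else {
    if (is.null(sidecar)) abort("metadata_mode = 'sidecar_table' requires a `sidecar` TSV path")
    sc <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
    need <- c("allele_id", "species", "gene_class", "chain_class", "domain_label")
    miss <- setdiff(need, names(sc))
    if (length(miss) > 0L) {
      abort(sprintf("sidecar TSV is missing columns: %s", paste(miss, collapse = ", ")))
    }
    ids <- map_chr(strsplit(recs$header, "|", fixed = TRUE), 1)
    sc <- sc[match(ids, sc$allele_id), need]
    if (anyNA(sc$allele_id)) {
      abort(sprintf("sidecar TSV has no row for allele_id '%s'",
                    ids[which(is.na(sc$allele_id))[1]]))
    }
    meta <- as_tibble(sc)
  }

  gapped <- gsub("-", ".", toupper(recs$seq), fixed = TRUE)
  out <- dplyr::bind_cols(meta, tibble(gapped_seq = gapped))
  new_ref_set(out)
}

#' Construct and validate a reference set from a tibble
#'
#' @param x A data frame with columns `allele_id`, `species`, `gene_class`,
#'   `chain_class`, `domain_label`, `gapped_seq`.
#' @return A validated `ref_set` tibble (see [read_reference_set()]).
#' @export
new_ref_set <- function(x) {
  x <- as_tibble(x)
  need <- c("allele_id", "species", "gene_class", "chain_class",
            "domain_label", "gapped_seq")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))

  if (anyDuplicated(x$allele_id)) {
    abort(sprintf("duplicate allele_id: %s",
                  paste(unique(x$allele_id[duplicated(x$allele_id)]), collapse = ", ")))
  }
  bad_gc <- setdiff(unique(x$gene_class), c("V", "C"))
  if (length(bad_gc) > 0L) abort(sprintf("gene_class must be V or C (got %s)", paste(bad_gc, collapse = ", ")))
  bad_cc <- setdiff(unique(x$chain_class), c("H", "K", "L"))
  if (length(bad_cc) > 0L) abort(sprintf("chain_class must be H, K or L (got %s)", paste(bad_cc, collapse = ", ")))
  bad_dl <- setdiff(unique(x$domain_label),
                    c("V", "CH1", "CH2", "CH3", "CH4", "CL", "hinge", "none"))
  if (length(bad_dl) > 0L) abort(sprintf("unknown domain_label: %s", paste(bad_dl, collapse = ", ")))

  x$gapped_seq <- gsub("-", ".", toupper(x$gapped_seq), fixed = TRUE)
  for (i in seq_len(nrow(x))) {
    letters_i <- setdiff(unique(chars(x$gapped_seq[i])), c(AA_1, "."))
    if (length(letters_i) > 0L) {
      abort(sprintf("allele %s contains unknown amino-acid letters: %s",
                    x$allele_id[i], paste(letters_i, collapse = ", ")))
    }
  }
  x$ungapped_seq <- gsub(".", "", x$gapped_seq, fixed = TRUE)
  if (any(nchar(x$ungapped_seq) < 1L)) {
    abort(sprintf("allele %s has an empty ungapped sequence",
                  x$allele_id[which(nchar(x$ungapped_seq) < 1L)[1]]))
  }

  widths <- x |>
    mutate(width = nchar(.data$gapped_seq)) |>
    group_by(.data$gene_class, .data$domain_label) |>
    summarise(n_widths = dplyr::n_distinct(.data$width),
              width = .data$width[1],
              offenders = paste(.data$allele_id, collapse = ", "),
              .groups = "drop")
  bad <- filter(widths, .data$n_widths > 1L)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "inconsistent gapped lengths within alignment set (%s, %s); alleles: %s",
      bad$gene_class[1], bad$domain_label[1], bad$offenders[1]))
  }

  structure(x,
            alignment_width = select(widths, "gene_class", "domain_label", "width"),
            class = c("ref_set", class(as_tibble(x))))
}

#' @export
print.ref_set <- function(x, ...) {
  w <- attr(x, "alignment_width")
  cat(sprintf("<ref_set> %d alleles, %d species, %d alignment set(s)\n",
              nrow(x), length(unique(x$species)), nrow(w)))
  NextMethod()
}

#' Gapped widths of the alignment sets in a reference set
#' @param refs A `ref_set`.
#' @return Tibble with `gene_class`, `domain_label`, `width`.
#' @export
alignment_width <- function(refs) attr(refs, "alignment_width")

#' Map ungapped residue indices to gapped alignment columns
#'
#' For a gapped sequence, returns for each ungapped residue (1-based) the
#' 1-based gapped column it occupies.  The map is strictly increasing and has
#' one entry per ungapped residue.
#'
#' @param allele A single-row slice of a `ref_set`, or a gapped sequence
#'   string.
#' @return Integer vector; element `i` is the gapped column of ungapped
#'   residue `i`.
#' @examples
#' gapped_position_map("A.CD")  # 1, 3, 4
#' @export
gapped_position_map <- function(allele) {
  gapped <- if (is.character(allele) && length(allele) == 1L) {
    allele
  } else if (is.data.frame(allele) && nrow(allele) == 1L) {
    allele$gapped_seq
  } else {
    abort("`allele` must be a gapped sequence string or a one-row allele table")
  }
  gapped <- gsub("-", ".", gapped, fixed = TRUE)
  which(chars(gapped) != ".")
}

#' Write a reference set back to gapped FASTA
#'
#' @param refs A `ref_set`.
#' @param path Output FASTA path.
#' @param sidecar Optional path; if given, metadata is written there as TSV
#'   and FASTA headers carry only the allele_id.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path, sidecar = NULL) {
  if (is.null(sidecar)) {
    hdr <- sprintf(">%s|%s|%s|%s|%s", refs$allele_id, refs$species,
                   refs$gene_class, refs$chain_class, refs$domain_label)
  } else {
    hdr <- sprintf(">%s", refs$allele_id)
    readr::write_tsv(
      select(as_tibble(refs), "allele_id", "species", "gene_class",
             "chain_class", "domain_label"),
      sidecar)
  }
  writeLines(as.vector(rbind(hdr, refs$gapped_seq)), path)
  invisible(path)
}

## Minimal FASTA record scan with line-numbered errors; sequences may span
## multiple lines.  Gap characters make these records unsuitable for
## Biostrings string sets with default alphabets, so records are assembled
## from raw lines here.
parse_fasta <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) return(tibble(header = character(), seq = character()))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf("malformed FASTA at line %d: expected '>' header, got '%s'",
                  nonblank[1], lines[nonblank[1]]))
  }
  headers <- integer(); seqs <- character(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      if (!is.null(cur) && seqs[length(seqs)] == "") {
        abort(sprintf("malformed FASTA at line %d: record '%s' has no sequence",
                      i, lines[cur]))
      }
      headers <- c(headers, i)
      seqs <- c(seqs, "")
      cur <- i
    } else {
      if (grepl("[^A-Za-z.*-]", ln)) {
        abort(sprintf("malformed FASTA at line %d: unexpected characters in '%s'", i, ln))
      }
      seqs[length(seqs)] <- paste0(seqs[length(seqs)], gsub("\\s", "", ln))
    }
  }
  if (length(seqs) > 0L && seqs[length(seqs)] == "") {
    abort(sprintf("malformed FASTA at line %d: record has no sequence", headers[length(headers)]))
  }
  tibble(header = sub("^>", "", trimws(lines[headers])), seq = seqs)
}
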