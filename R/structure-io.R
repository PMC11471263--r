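#' Read an antibody structure file
#'
#' Parses an mmCIF (primary) or legacy PDB file into per-chain sequences
#' and coordinates.  The deposited polymer sequence (SEQRES equivalent)
#' comes from `_entity_poly` (mmCIF) or SEQRES records (PDB); the
#' ATOM-resolved sequence is derived from residues that actually carry
#' coordinates, ordered by polymer sequence index.  Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken alphabetically
#' by altloc id).  Only the first model of multi-model files is used.
#'
#' For legacy PDB input the residue numbers are taken as polymer sequence
#' indices; files using author-specific numbering schemes should be
#' converted to mmCIF, where `label_seq_id` is authoritative.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return An `ab_structure`: list with `entry_id`, `chains` — a named list
#'   of chain records, each holding `seqres_seq`, `atom_seq`, `atom_map`
#'   (atom_seq position -> seqres index) and `atoms` (tibble:
#'   `seqres_index`, `amino_acid`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `occupancy`).
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("structure file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- if (format == "mmcif") read_structure_cif(path) else read_structure_pdb(path)
  build_ab_structure(raw$entry_id, raw$seqres, raw$atoms, path)
}

read_structure_cif <- function(path) {
  cats <- parse_cif(path, categories = c("entry", "entity_poly", "atom_site"))
  if (is.null(cats$atom_site)) {
    abort(sprintf("mmCIF format error in %s: no _atom_site category", path))
  }
  as <- cats$atom_site
  entry_id <- if (!is.null(cats$entry$id)) cats$entry$id[1] else
    sub("\\.[^.]*$", "", basename(path))

  ## polymer sequences keyed by strand id
  seqres <- list()
  ep <- cats$entity_poly
  if (!is.null(ep) && !is.null(ep$pdbx_seq_one_letter_code) &&
      !is.null(ep$pdbx_strand_id)) {
    for (k in seq_len(nrow(ep))) {
      seq1 <- gsub("[\\s\n]", "", ep$pdbx_seq_one_letter_code[k], perl = TRUE)
      for (strand in strsplit(ep$pdbx_strand_id[k], ",", fixed = TRUE)[[1]]) {
        seqres[[trimws(strand)]] <- toupper(seq1)
      }
    }
  }

  col <- function(nm, default = NA_character_) {
    if (!is.null(as[[nm]])) as[[nm]] else rep(default, nrow(as))
  }
  atoms <- tibble(
    group = col("group_PDB", "ATOM"),
    element = col("type_symbol"),
    atom_name = col("label_atom_id"),
    altloc = col("label_alt_id", "."),
    comp = col("label_comp_id"),
    chain_id = dplyr::coalesce(col("auth_asym_id"), col("label_asym_id")),
    seqres_index = suppressWarnings(as.integer(col("label_seq_id"))),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    occupancy = suppressWarnings(as.numeric(col("occupancy", "1"))),
    model = col("pdbx_PDB_model_num", "1")
  )
  atoms <- filter(atoms, .data$group == "ATOM", .data$model == atoms$model[1])
  list(entry_id = entry_id, seqres = seqres, atoms = atoms)
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort(sprintf("PDB format error in %s: %s",
                                                    path, conditionMessage(e))))
  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres) > 0L) {
    for (ch in unique(names(pdb$seqres))) {
      aa3 <- pdb$seqres[names(pdb$seqres) == ch]
      seqres[[ch]] <- collapse(unname(AA_3TO1[aa3]))
    }
  }
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  atoms <- tibble(
    group = "ATOM",
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1L, 1L), trimws(a$elesy)),
    atom_name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt) | a$alt == "", ".", a$alt),
    comp = a$resid,
    chain_id = a$chain,
    seqres_index = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    model = "1"
  )
  entry_id <- sub("\\.[^.]*$", "", basename(path))
  list(entry_id = entry_id, seqres = seqres, atoms = atoms)
}

build_ab_structure <- function(entry_id, seqres, atoms, path) {
  atoms <- filter(atoms, !is.na(.data$seqres_index),
                  is.finite(.data$x), is.finite(.data$y), is.finite(.data$z))
  ## altloc resolution: per (chain, residue, atom name) keep highest
  ## occupancy, ties by alphabetical altloc ('.' sorts first and wins for
  ## single-conformer atoms)
  atoms <- atoms |>
    arrange(.data$chain_id, .data$seqres_index, .data$atom_name,
            desc(.data$occupancy), .data$altloc) |>
    distinct(.data$chain_id, .data$seqres_index, .data$atom_name, .keep_all = TRUE)

  chain_ids <- unique(atoms$chain_id)
  chains <- list()
  problems <- character()
  for (ch in chain_ids) {
    ca <- filter(atoms, .data$chain_id == ch)
    res <- ca |>
      distinct(.data$seqres_index, .data$comp) |>
      arrange(.data$seqres_index)
    aa1 <- unname(AA_3TO1[res$comp])
    aa1[is.na(aa1)] <- "X"
    sr <- seqres[[ch]]
    if (is.null(sr)) {
      ## no deposited polymer sequence: fall back to the resolved residues
      sr <- collapse(aa1)
      idx_map <- seq_along(aa1)
      ca$seqres_index <- match(ca$seqres_index, res$seqres_index)
      res$seqres_index <- idx_map
    } else {
      bad <- res$seqres_index < 1L | res$seqres_index > nchar(sr)
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "chain %s: residue index %s outside the polymer sequence (length %d)",
          ch, paste(res$seqres_index[bad], collapse = ","), nchar(sr)))
        next
      }
      sr_letters <- chars(sr)[res$seqres_index]
      mism <- which(sr_letters != aa1 & aa1 != "X")
      if (length(mism) > 0L) {
        problems <- c(problems, sprintf(
          "chain %s: residue(s) %s disagree with the polymer sequence (%s vs %s)",
          ch, paste(res$seqres_index[mism], collapse = ","),
          paste(aa1[mism], collapse = ""), paste(sr_letters[mism], collapse = "")))
        next
      }
    }
    atom_map <- sort(unique(res$seqres_index))
    chains[[ch]] <- list(
      chain_id = ch,
      seqres_seq = sr,
      atom_seq = collapse(chars(sr)[atom_map]),
      atom_map = atom_map,
      atoms = select(ca, "seqres_index", "comp", "atom_name", "element",
                     "x", "y", "z", "occupancy") |>
        mutate(amino_acid = unname(AA_3TO1[.data$comp]), .after = "seqres_index")
    )
  }
  if (length(problems) > 0L) {
    abort(paste(c(sprintf("coordinate/polymer inconsistency in %s:", path), problems),
                collapse = "\n  "))
  }
  structure(list(entry_id = entry_id, chains = chains, source = path),
            class = "ab_structure")
}

#' @export
print.ab_structure <- function(x, ...) {
  cat(sprintf("<ab_structure> %s: %d chain(s)\n", x$entry_id, length(x$chains)))
  for (ch in x$chains) {
    cat(sprintf("  chain %s: %d residues deposited, %d resolved\n",
                ch$chain_id, nchar(ch$seqres_seq), nchar(ch$atom_seq)))
  }
  invisible(x)
}

#' C-alpha coordinates of one chain
#'
#' Residues lacking a C-alpha atom are reported via the `has_ca` column and
#' excluded from C-alpha-based geometry.
#'
#' @param chain One element of `ab_structure$chains`.
#' @return Tibble: `seqres_index`, `amino_acid`, `x`, `y`, `z`.
#' @export
calpha_coords <- function(chain) {
  chain$atoms |>
    filter(.data$atom_name == "CA") |>
    select("seqres_index", "amino_acid", "x", "y", "z") |>
    arrange(.data$seqres_index)
}

#' Labeled C-alpha set for detected domains of a chain
#'
#' Joins a chain numbering table (from [number_chain()] run on the chain's
#' `atom_seq`) with the chain's C-alpha coordinates, producing the labeled
#' coordinate sets consumed by the packing-angle and contact-map
#' operations.
#'
#' @param chain One element of `ab_structure$chains`.
#' @param numbering Output of [number_chain()] on `chain$atom_seq`.
#' @return Tibble: `domain_label`, `imgt_label`, `amino_acid`, `x`, `y`,
#'   `z` (rows only for residues with a C-alpha).
#' @export
labeled_calpha <- function(chain, numbering) {
  ca <- calpha_coords(chain)
  numbering |>
    mutate(seqres_index = chain$atom_map[.data$query_pos]) |>
    dplyr::inner_join(select(ca, "seqres_index", "x", "y", "z"),
                      by = "seqres_index") |>
    select("domain_label", "imgt_label", "amino_acid", "x", "y", "z")
}
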