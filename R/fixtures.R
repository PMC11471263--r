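#' Fixture specification
#'
#' Bundles the knobs of the deterministic synthetic-data generators: a
#' seed, the number of species, the substitution fraction between species
#' homologs, domain lengths, and the planted Fab geometry.  Identical
#' specs produce byte-identical fixture files.
#'
#' @param seed Integer seed; every generator derives its streams from it.
#' @param n_species Number of species in reference fixtures (default 2).
#' @param divergence Substitution fraction between species homologs, in
#'   `[0, 0.5]` (default 0.15).
#' @param domain_lengths Named residue counts (>= 20) for `V` and `C`
#'   domains (every C domain shares one ungapped length so CH1 and CL
#'   share the IMGT-style label space needed for packing angles).
#' @param elbow_deg Planted angle between the V- and C-module pseudo-dyad
#'   axes, degrees (default 62).
#' @param ch1_cl_deg Planted CL-onto-CH1 rotation angle, degrees
#'   (default 168: close to, but measurably off, an exact twofold).
#' @param unresolved_spans List of `list(chain, start, end)` residue
#'   spans to omit from ATOM records (present in the polymer sequence).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_species = 2, divergence = 0.15,
                         domain_lengths = c(V = 96, C = 95),
                         elbow_deg = 62, ch1_cl_deg = 168,
                         unresolved_spans = list()) {
  if (divergence < 0 || divergence > 0.5) abort("divergence must be in [0, 0.5]")
  if (any(domain_lengths < 20)) abort("domain lengths must be >= 20")
  structure(list(seed = as.integer(seed), n_species = n_species,
                 divergence = divergence, domain_lengths = domain_lengths,
                 elbow_deg = elbow_deg, ch1_cl_deg = ch1_cl_deg,
                 unresolved_spans = unresolved_spans),
            class = "fixture_spec")
}

FIXTURE_SPECIES <- c("Homo sapiens", "Mus musculus", "Oryctolagus cuniculus",
                     "Macaca mulatta")

random_aa <- function(n) sample(AA_1, n, replace = TRUE)

## substitute each position with probability `rate`, always to a different
## residue
mutate_seq <- function(seq, rate) {
  s <- chars(seq)
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    s[hit] <- map_chr(s[hit], function(a) sample(setdiff(AA_1, a), 1))
  }
  collapse(s)
}

## evenly spaced, deterministic gap columns for a gapped width
fixed_gap_columns <- function(ungapped_len, n_gaps) {
  width <- ungapped_len + n_gaps
  round(seq(width / (n_gaps + 1), width * n_gaps / (n_gaps + 1), length.out = n_gaps))
}

gap_seq <- function(seq, gap_cols, width) {
  out <- rep(".", width)
  out[setdiff(seq_len(width), gap_cols)] <- chars(seq)
  collapse(out)
}

#' Generate a germline reference fixture
#'
#' Builds a deterministic reference allele set: per species, V alleles for
#' heavy, kappa and lambda chains, C-domain alleles for each requested
#' heavy isotype (CH1 plus CH2/CH3 when `full_constant`), and kappa/lambda
#' CL alleles.  Species beyond the first are derived from the first by
#' substitution at rate `spec$divergence`; distinct genes within a species
#' (e.g. the CH1 of different isotypes, or kappa versus lambda) differ at
#' a fixed within-species rate.  Gaps sit at fixed columns so all alleles
#' of a gene class share one gapped width.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @param isotypes Heavy-chain C genes to include (default
#'   `c("IGHG1", "IGHA1")`).
#' @param full_constant Also emit CH2 and CH3 alleles (default `TRUE`).
#' @param sidecar Write metadata as a sidecar TSV instead of FASTA headers.
#' @return List: `refs` (the loaded `ref_set`), `fasta`, `sidecar` paths.
#' @export
make_reference_fixture <- function(spec, dir = tempfile("refs"),
                                   isotypes = c("IGHG1", "IGHA1"),
                                   full_constant = TRUE, sidecar = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, 101L))
  len_v <- unname(spec$domain_lengths["V"])
  len_c <- unname(spec$domain_lengths["C"])
  gap_v <- fixed_gap_columns(len_v, 8L)
  gap_c <- fixed_gap_columns(len_c, 6L)
  width_v <- len_v + 8L
  width_c <- len_c + 6L
  within_rate <- 0.25   # gene-vs-gene divergence inside one species

  anc_v <- collapse(random_aa(len_v))
  anc_c <- collapse(random_aa(len_c))
  c_domains <- if (full_constant) c("CH1", "CH2", "CH3") else "CH1"

  base <- list()  # species-1 ungapped sequences keyed by allele id
  base[["IGHV1*01"]] <- list(seq = anc_v, gc = "V", cc = "H", dl = "V")
  base[["IGKV1*01"]] <- list(seq = mutate_seq(anc_v, within_rate), gc = "V", cc = "K", dl = "V")
  base[["IGLV1*01"]] <- list(seq = mutate_seq(anc_v, within_rate), gc = "V", cc = "L", dl = "V")
  for (iso in isotypes) {
    for (dom in c_domains) {
      base[[sprintf("%s*01_%s", iso, dom)]] <-
        list(seq = mutate_seq(anc_c, within_rate), gc = "C", cc = "H", dl = dom)
    }
  }
  base[["IGKC*01"]] <- list(seq = mutate_seq(anc_c, within_rate), gc = "C", cc = "K", dl = "CL")
  base[["IGLC1*01"]] <- list(seq = mutate_seq(anc_c, within_rate), gc = "C", cc = "L", dl = "CL")

  rows <- list()
  for (sp_i in seq_len(spec$n_species)) {
    sp <- FIXTURE_SPECIES[sp_i]
    for (id in names(base)) {
      b <- base[[id]]
      seq_sp <- if (sp_i == 1L) b$seq else mutate_seq(b$seq, spec$divergence)
      gapped <- if (b$gc == "V") gap_seq(seq_sp, gap_v, width_v) else
        gap_seq(seq_sp, gap_c, width_c)
      rows[[length(rows) + 1L]] <- tibble(
        allele_id = if (sp_i == 1L) id else sub("\\*01", sprintf("*%02d", sp_i), id),
        species = sp, gene_class = b$gc, chain_class = b$cc,
        domain_label = b$dl, gapped_seq = gapped)
    }
  }
  refs <- new_ref_set(bind_rows(rows))
  fasta <- file.path(dir, "references.fasta")
  sc_path <- if (sidecar) file.path(dir, "references_meta.tsv") else NULL
  write_reference_set(refs, fasta, sidecar = sc_path)
  list(refs = refs, fasta = fasta, sidecar = sc_path)
}

## compact random C-alpha cloud: a jittered self-avoiding-ish walk with
## ~3.8 A steps, re-centered at `center`
random_ca_cloud <- function(n, center = c(0, 0, 0)) {
  steps <- matrix(rnorm(3 * n), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  ## bias the walk back toward its running centroid so the cloud stays
  ## compact like a folded domain
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    pull <- -0.12 * pts[i - 1L, ]
    pts[i, ] <- pts[i - 1L, ] + steps[i, ] + pull
  }
  sweep(pts, 2, colMeans(pts)) + matrix(center, n, 3, byrow = TRUE)
}

#' Generate an idealised Fab/full-antibody structure fixture
#'
#' Builds a C-alpha-trace structure (with planted gamma-sulfur atoms on
#' cysteines) whose sequences come from the reference fixture's species-1
#' alleles and whose geometry realises the spec's planted pseudo-dyad
#' axes exactly: the light-chain V and C domains are rigid copies of
#' their heavy partners under rotations about axes subtending the
#' requested elbow angle, so the packing-angle code has an exact ground
#' truth.  Unresolved spans are omitted from ATOM records but stay in the
#' polymer sequence.  A ground-truth JSON sidecar records the planted
#' values.
#'
#' @param spec A [fixture_spec()].
#' @param refs The `ref_set` from [make_reference_fixture()] (species 1
#'   is used for the chain sequences).
#' @param dir Output directory.
#' @param entry_id Entry identifier (also the file stem).
#' @param coverage `"Fab"` (VH+CH1 / VL+CL) or `"full"` (adds CH2+CH3).
#' @param isotype Heavy C gene to build from (default `"IGHG1"`).
#' @param light `"K"` or `"L"` light-chain class.
#' @param format `"mmcif"` or `"pdb"`.
#' @param plant_disulfides Plant 2 intra-domain pairs and 1 inter-chain
#'   pair (default `TRUE`).
#' @return List: `path`, `truth` (the ground-truth list, also written as
#'   JSON next to the structure file).
#' @export
make_structure_fixture <- function(spec, refs, dir = tempfile("structs"),
                                   entry_id = "FX0001",
                                   coverage = c("Fab", "full"),
                                   isotype = "IGHG1", light = "K",
                                   format = c("mmcif", "pdb"),
                                   plant_disulfides = TRUE) {
  coverage <- match.arg(coverage)
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, 202L) + sum(utf8ToInt(entry_id)))

  sp1 <- refs$species[1]
  pick <- function(cc, gc, dl) {
    r <- refs[refs$species == sp1 & refs$chain_class == cc &
              refs$gene_class == gc & refs$domain_label == dl, ]
    if (gc == "C" && cc == "H") r <- r[startsWith(r$allele_id, isotype), ]
    if (nrow(r) == 0L) abort(sprintf("reference fixture lacks a %s/%s/%s allele", cc, gc, dl))
    r[1, ]
  }
  vh <- pick("H", "V", "V"); ch1 <- pick("H", "C", "CH1")
  vl <- pick(light, "V", "V"); cl <- pick(light, "C", "CL")
  h_domains <- list(V = vh, CH1 = ch1)
  if (coverage == "full") {
    h_domains$CH2 <- pick("H", "C", "CH2"); h_domains$CH3 <- pick("H", "C", "CH3")
  }
  l_domains <- list(V = vl, CL = cl)

  ## planted dyad axes: a_V along z, a_C at the requested elbow angle
  a_v <- c(0, 0, 1)
  th <- deg2rad(spec$elbow_deg)
  a_c <- c(sin(th), 0, cos(th))
  R_v <- rotation_matrix(a_v, 180)
  R_c <- rotation_matrix(a_c, spec$ch1_cl_deg)

  ## heavy-chain domain clouds; light-chain partners are rigid images
  centers <- list(V = c(0, 0, 0), CH1 = c(0, 42, 0),
                  CH2 = c(0, 84, 0), CH3 = c(0, 126, 0))
  coords <- list(H = list(), L = list())
  for (dom in names(h_domains)) {
    n <- nchar(h_domains[[dom]]$ungapped_seq)
    coords$H[[dom]] <- random_ca_cloud(n, centers[[dom]])
  }
  offset_v <- c(14, 0, 0); offset_c <- c(14, 0, 0)
  ## the light V/C domains are rigid images of the heavy clouds; all
  ## fixture V alleles (and all C alleles) share gap columns, so residue i
  ## of the light domain carries the same IMGT-style label as residue i of
  ## its heavy partner
  coords$L$V <- sweep(coords$H$V %*% t(R_v), 2, offset_v, "+")
  coords$L$CL <- sweep(sweep(coords$H$CH1, 2, centers$CH1) %*% t(R_c), 2,
                       centers$CH1 + offset_c, "+")

  h_seq <- paste(map_chr(h_domains, "ungapped_seq"), collapse = "")
  l_seq <- paste(map_chr(l_domains, "ungapped_seq"), collapse = "")
  h_ca <- do.call(rbind, coords$H)
  l_ca <- do.call(rbind, unname(coords$L[c("V", "CL")]))

  chains <- list(
    H = list(seq = h_seq, ca = h_ca),
    L = list(seq = l_seq, ca = l_ca)
  )

  ## plant disulfides: two intra-H pairs and one inter-chain pair
  sg <- list()
  if (plant_disulfides) {
    nv <- nchar(vh$ungapped_seq)
    pairs <- list(list(ch = c("H", "H"), res = c(22L, nv - 5L), type = "intra"),
                  list(ch = c("H", "H"), res = c(nv + 20L, nv + 40L), type = "intra"),
                  list(ch = c("H", "L"), res = c(nchar(h_seq), nchar(l_seq)),
                       type = "inter"))
    for (p in pairs) {
      for (k in 1:2) {
        s <- chars(chains[[p$ch[k]]]$seq)
        s[p$res[k]] <- "C"
        chains[[p$ch[k]]]$seq <- collapse(s)
      }
      mid <- (chains[[p$ch[1]]]$ca[p$res[1], ] + chains[[p$ch[2]]]$ca[p$res[2], ]) / 2
      sg[[length(sg) + 1L]] <- list(chain = p$ch[1], res = p$res[1],
                                    xyz = mid - c(1.025, 0, 0))
      sg[[length(sg) + 1L]] <- list(chain = p$ch[2], res = p$res[2],
                                    xyz = mid + c(1.025, 0, 0))
    }
  }

  ## assemble atom records, dropping unresolved spans
  unresolved <- matrix(FALSE, nrow = 2, ncol = max(nchar(h_seq), nchar(l_seq)),
                       dimnames = list(c("H", "L"), NULL))
  for (u in spec$unresolved_spans) {
    unresolved[u$chain, u$start:u$end] <- TRUE
  }
  atom_rows <- list()
  for (ch in c("H", "L")) {
    s <- chars(chains[[ch]]$seq)
    for (i in seq_along(s)) {
      if (unresolved[ch, i]) next
      atom_rows[[length(atom_rows) + 1L]] <- tibble(
        chain = ch, res = i, comp = unname(AA_3[s[i]]), atom = "CA",
        element = "C", x = chains[[ch]]$ca[i, 1], y = chains[[ch]]$ca[i, 2],
        z = chains[[ch]]$ca[i, 3])
    }
  }
  for (g in sg) {
    if (unresolved[g$chain, g$res]) next
    atom_rows[[length(atom_rows) + 1L]] <- tibble(
      chain = g$chain, res = g$res, comp = "CYS", atom = "SG",
      element = "S", x = g$xyz[1], y = g$xyz[2], z = g$xyz[3])
  }
  atoms <- bind_rows(atom_rows) |> arrange(.data$chain, .data$res, .data$atom)

  path <- file.path(dir, sprintf("%s.%s", entry_id,
                                 if (format == "mmcif") "cif" else "pdb"))
  seqres <- list(H = chains$H$seq, L = chains$L$seq)
  if (format == "mmcif") write_fixture_cif(path, entry_id, seqres, atoms)
  else write_fixture_pdb(path, seqres, atoms)

  resolved_domains <- character()
  bounds <- domain_bounds(h_domains, l_domains)
  for (i in seq_len(nrow(bounds))) {
    span <- bounds$start[i]:bounds$end[i]
    if (any(!unresolved[bounds$chain[i], span])) {
      resolved_domains <- c(resolved_domains, bounds$domain[i])
    }
  }
  truth <- list(
    entry_id = entry_id,
    elbow_deg = min(spec$elbow_deg, 180 - spec$elbow_deg),
    ch1_cl_deg = spec$ch1_cl_deg,
    coverage_class = classify_coverage(resolved_domains),
    species = sp1, isotype = isotype, light = light,
    domains = bounds,
    disulfides = if (plant_disulfides)
      list(intra = 2L, inter = 1L, total = 3L) else
      list(intra = 0L, inter = 0L, total = 0L),
    unresolved_spans = spec$unresolved_spans
  )
  truth_path <- file.path(dir, sprintf("%s_truth.json", entry_id))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = 8)
  list(path = path, truth = truth, truth_path = truth_path)
}

domain_bounds <- function(h_domains, l_domains) {
  rows <- list(); pos <- 0L
  for (dom in names(h_domains)) {
    n <- nchar(h_domains[[dom]]$ungapped_seq)
    rows[[length(rows) + 1L]] <- tibble(chain = "H", domain = dom,
                                        start = pos + 1L, end = pos + n)
    pos <- pos + n
  }
  pos <- 0L
  for (dom in names(l_domains)) {
    n <- nchar(l_domains[[dom]]$ungapped_seq)
    rows[[length(rows) + 1L]] <- tibble(chain = "L", domain = dom,
                                        start = pos + 1L, end = pos + n)
    pos <- pos + n
  }
  bind_rows(rows)
}

write_fixture_cif <- function(path, entry_id, seqres, atoms) {
  lines <- c(
    sprintf("data_%s", entry_id), "#",
    sprintf("_entry.id %s", entry_id), "#",
    "loop_",
    "_entity_poly.entity_id", "_entity_poly.type",
    "_entity_poly.pdbx_seq_one_letter_code", "_entity_poly.pdbx_strand_id",
    sprintf("%d 'polypeptide(L)' %s %s", seq_along(seqres),
            unlist(seqres), names(seqres)),
    "#",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s %d %d %.3f %.3f %.3f 1.00 0.00 %d %s 1",
            seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$comp,
            atoms$chain, match(atoms$chain, names(seqres)), atoms$res,
            atoms$x, atoms$y, atoms$z, atoms$res, atoms$chain),
    "#")
  writeLines(lines, path)
  invisible(path)
}

write_fixture_pdb <- function(path, seqres, atoms) {
  lines <- character()
  for (ch in names(seqres)) {
    aa3 <- unname(AA_3[chars(seqres[[ch]])])
    n <- length(aa3)
    ser <- 0L
    for (i in seq(1L, n, by = 13L)) {
      ser <- ser + 1L
      grp <- aa3[i:min(i + 12L, n)]
      lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", ser, ch, n,
                                paste(sprintf("%-3s", grp), collapse = " ")))
    }
  }
  ## fixed PDB columns: serial 7-11, name 13-16, resName 18-20, chain 22,
  ## resSeq 23-26, x/y/z 31-54, occupancy 55-60, B 61-66, element 77-78
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, sprintf(" %-3s", atoms$atom[i]), atoms$comp[i], atoms$chain[i],
      atoms$res[i], atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, atoms$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a repertoire fixture in several dialects
#'
#' Derives `n_cells` paired (and `n_unpaired` unpaired) heavy/light
#' V-region sequences from source sequences by random substitution at
#' `mutation_rate`, then writes the same logical repertoire as AIRR TSV,
#' plain CSV, 10x-style contig CSV, or FASTA, plus a ground-truth pairing
#' JSON.
#'
#' @param spec A [fixture_spec()].
#' @param sources Tibble with `entry_id`, `h_v`, `l_v` source sequences
#'   (e.g. the V views of a [build_index()]).
#' @param dir Output directory.
#' @param dialect One of `"airr_tsv"`, `"csv"`, `"tenx_contig_csv"`,
#'   `"fasta"`.
#' @param n_cells Total cells (default 10).
#' @param n_unpaired How many of them lack the light chain (default 2).
#' @param mutation_rate Per-residue substitution rate (default 0.05).
#' @return List: `path`, `truth` (tibble `cell_id`, `source_entry`,
#'   `paired`), `truth_path`.
#' @export
make_repertoire_fixture <- function(spec, sources, dir = tempfile("rep"),
                                    dialect = c("airr_tsv", "csv",
                                                "tenx_contig_csv", "fasta"),
                                    n_cells = 10, n_unpaired = 2,
                                    mutation_rate = 0.05) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, 303L))
  src_idx <- sample(nrow(sources), n_cells, replace = TRUE)
  unpaired <- if (n_unpaired > 0) sample(n_cells, n_unpaired) else integer()

  cells <- tibble(
    cell_id = sprintf("CELL%03d", seq_len(n_cells)),
    source_entry = sources$entry_id[src_idx],
    heavy_seq = map_chr(src_idx, function(i) mutate_seq(sources$h_v[i], mutation_rate)),
    light_seq = map_chr(src_idx, function(i) mutate_seq(sources$l_v[i], mutation_rate)),
    paired = !seq_len(n_cells) %in% unpaired
  )
  cells$light_seq[!cells$paired] <- NA_character_

  path <- file.path(dir, switch(dialect,
    airr_tsv = "repertoire.tsv", csv = "repertoire.csv",
    tenx_contig_csv = "contigs.csv", fasta = "repertoire.fasta"))

  long <- bind_rows(
    tibble(cell_id = cells$cell_id, locus = "IGH", seq = cells$heavy_seq),
    tibble(cell_id = cells$cell_id, locus = "IGK", seq = cells$light_seq)
  ) |>
    filter(!is.na(.data$seq)) |>
    arrange(.data$cell_id, .data$locus) |>
    mutate(sequence_id = sprintf("%s_%s", .data$cell_id, .data$locus))

  if (dialect == "fasta") {
    hdr <- sprintf(">%s|%s", long$cell_id, ifelse(long$locus == "IGH", "H", "L"))
    writeLines(as.vector(rbind(hdr, long$seq)), path)
  } else if (dialect == "tenx_contig_csv") {
    readr::write_csv(tibble(barcode = long$cell_id, chain = long$locus,
                            sequence_aa = long$seq), path)
  } else {
    tab <- tibble(sequence_id = long$sequence_id, cell_id = long$cell_id,
                  locus = long$locus, sequence_aa = long$seq)
    if (dialect == "airr_tsv") readr::write_tsv(tab, path) else readr::write_csv(tab, path)
  }
  truth_path <- file.path(dir, "repertoire_truth.json")
  jsonlite::write_json(cells[, c("cell_id", "source_entry", "paired")],
                       truth_path, auto_unbox = TRUE)
  list(path = path, truth = cells, truth_path = truth_path)
}

#' Generate mutational-scan score fixtures for three pseudo-isotypes
#'
#' Simulates one shared mutational landscape observed through three noisy
#' scans — two of the same pseudo-isotype (`iso_b`, `ctrl`) and one with
#' per-position shifts planted at `n_planted` positions (`iso_a`) — and
#' writes the three long-form CSVs plus a ground-truth JSON naming the
#' planted positions.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param n_positions Number of V-region positions (default 50).
#' @param n_planted Positions receiving the shift in `iso_a` (default 3).
#' @param shift Planted per-substitution shift (default 2.0).
#' @param noise_sd Observation noise standard deviation (default 0.5).
#' @return List: `paths` (named: iso_a, iso_b, ctrl), `truth` (list with
#'   `planted_positions`), `truth_path`.
#' @export
make_score_fixture <- function(spec, dir = tempfile("scores"),
                               n_positions = 50, n_planted = 3,
                               shift = 2.0, noise_sd = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(spec$seed, 404L))
  labels <- as.character(seq_len(n_positions))
  wt <- random_aa(n_positions)
  planted <- if (n_planted > 0) sort(sample(n_positions, n_planted)) else integer()

  landscape <- matrix(rnorm(n_positions * 20), n_positions, 20,
                      dimnames = list(labels, AA_1))
  noisy <- function(shift_rows = integer()) {
    m <- landscape + matrix(rnorm(length(landscape), sd = noise_sd),
                            nrow = n_positions)
    for (p in shift_rows) {
      subs <- colnames(m) != wt[p]
      m[p, subs] <- m[p, subs] + shift
    }
    m
  }
  mats <- list(iso_a = noisy(planted), iso_b = noisy(), ctrl = noisy())

  paths <- list()
  for (nm in names(mats)) {
    long <- tibble(
      position_label = rep(labels, times = 20),
      wt_aa = rep(wt, times = 20),
      mut_aa = rep(AA_1, each = n_positions),
      score = round(as.vector(mats[[nm]]), 6)
    ) |> arrange(as.integer(.data$position_label), .data$mut_aa)
    paths[[nm]] <- file.path(dir, sprintf("scores_%s.csv", nm))
    readr::write_csv(long, paths[[nm]])
  }
  truth <- list(planted_positions = labels[planted], shift = shift,
                noise_sd = noise_sd)
  truth_path <- file.path(dir, "scores_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE)
  list(paths = paths, truth = truth, truth_path = truth_path)
}

#' Generate a complete fixture workspace
#'
#' Emits references, a handful of structures with varying coverage,
#' isotype and unresolved spans, and score fixtures, under one directory
#' tree (`refs/`, `structures/`, `scores/`), each with its ground-truth
#' sidecars.  A `metadata.json` records the provided (deposition-style)
#' species per entry.  Repertoire fixtures are generated separately with
#' [make_repertoire_fixture()] from an index built over the workspace.
#'
#' @param seed Integer seed.
#' @param dir Workspace directory.
#' @param n_structures Number of structure fixtures (default 5).
#' @return List: `refs`, `refs_fasta`, `structure_paths`, `truths`,
#'   `metadata_path`, `scores`, `spec`, `dir`.
#' @export
make_fixture_workspace <- function(seed, dir = tempfile("fixws"),
                                   n_structures = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture_spec(seed)
  rf <- make_reference_fixture(spec, file.path(dir, "refs"))

  elbows <- c(62, 48, 75, 55, 68, 40, 80, 58, 66, 52)
  ch1cls <- c(168, 155, 172, 150, 163, 158, 170, 148, 166, 160)
  structure_paths <- character(); truths <- list()
  sdir <- file.path(dir, "structures")
  for (i in seq_len(n_structures)) {
    sp_i <- fixture_spec(seed + i, elbow_deg = elbows[(i - 1L) %% 10L + 1L],
                         ch1_cl_deg = ch1cls[(i - 1L) %% 10L + 1L],
                         unresolved_spans = if (i %% 2L == 0L)
                           list(list(chain = "H", start = 30L, end = 41L)) else list())
    fx <- make_structure_fixture(
      sp_i, rf$refs, dir = sdir,
      entry_id = sprintf("FX%04d", i),
      coverage = if (i %% 3L == 0L) "full" else "Fab",
      isotype = if (i %% 2L == 0L) "IGHA1" else "IGHG1",
      light = if (i %% 4L == 0L) "L" else "K")
    structure_paths <- c(structure_paths, fx$path)
    truths[[fx$truth$entry_id]] <- fx$truth
  }
  metadata <- map(truths, function(t) list(species = t$species))
  metadata_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(metadata, metadata_path, auto_unbox = TRUE)

  scores <- make_score_fixture(fixture_spec(seed), file.path(dir, "scores"))
  list(refs = rf$refs, refs_fasta = rf$fasta,
       structure_paths = structure_paths, truths = truths,
       metadata_path = metadata_path, scores = scores, dir = dir,
       spec = spec)
}
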