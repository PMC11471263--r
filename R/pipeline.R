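#' Pipeline configuration
#'
#' @param min_identity,min_length Domain-acceptance thresholds (see
#'   [detect_domains()]).
#' @param override_margin Species-override margin in identity points (see
#'   [consolidate_species()]).
#' @param contact_cutoff C-alpha contact cutoff, Angstroms.
#' @param delta_sasa_threshold Interface membership threshold, square
#'   Angstroms.
#' @param disulfide_cutoff S-S bond cutoff, Angstroms.
#' @param sasa_points Sphere sample points for interface SASA within the
#'   pipeline (coarser than the [sasa()] default to keep batch runs
#'   fast; per-residue membership is insensitive to this at the 1 A^2
#'   threshold).
#' @param compute_interface Compute H-L interfaces (default `TRUE`).
#' @param max_batch Repertoire batch limit (see [parse_repertoire()]).
#' @return A named list of validated settings.
#' @export
pipeline_config <- function(min_identity = 50, min_length = 50,
                            override_margin = 8, contact_cutoff = 8,
                            delta_sasa_threshold = 1,
                            disulfide_cutoff = 2.5,
                            sasa_points = 240,
                            compute_interface = TRUE,
                            max_batch = 200) {
  cfg <- list(min_identity = min_identity, min_length = min_length,
              override_margin = override_margin,
              contact_cutoff = contact_cutoff,
              delta_sasa_threshold = delta_sasa_threshold,
              disulfide_cutoff = disulfide_cutoff,
              sasa_points = sasa_points,
              compute_interface = isTRUE(compute_interface),
              max_batch = max_batch)
  num <- cfg[!names(cfg) %in% "compute_interface"]
  if (any(!map_lgl(num, function(v) is.numeric(v) && length(v) == 1L && v > 0))) {
    abort("all pipeline thresholds must be single positive numbers")
  }
  cfg
}

#' Annotate one antibody structure end-to-end
#'
#' Runs the full per-entry pipeline: domain detection and numbering on
#' both the deposited (SEQRES) and ATOM-resolved sequences, species
#' consolidation with the identity-override rule, engineered-format
#' flagging, isotype/light-type assignment, structural-coverage
#' classification, packing angles, CH1-CL contact matrix, H-L interface
#' and disulfide bonds.
#'
#' @param structure An `ab_structure` from [read_structure()].
#' @param refs A `ref_set`.
#' @param provided_species Deposition-metadata species, or `NA`.
#' @param config A [pipeline_config()].
#' @return A `fab_record` list: `entry_id`, `chain_info` (per-chain
#'   tibble), `numbering` (per role H/L), `pair` (chain ids),
#'   `annotation` (one-row tibble for the collection CSV),
#'   `ch1_cl_contacts`, `interface`, `disulfides`, `notes`.
#' @export
annotate_structure <- function(structure, refs, provided_species = NA_character_,
                               config = pipeline_config()) {
  if (!inherits(structure, "ab_structure")) abort("`structure` must be an ab_structure")
  notes <- character()

  chain_rows <- list(); per_chain <- list()
  for (ch in structure$chains) {
    hits_seqres <- detect_domains(ch$seqres_seq, refs,
                                  min_identity = config$min_identity,
                                  min_length = config$min_length)
    hits_atom <- detect_domains(ch$atom_seq, refs,
                                min_identity = config$min_identity,
                                min_length = config$min_length)
    if (nrow(hits_seqres) == 0L) {
      notes <- c(notes, sprintf("chain %s: no domain hits; skipped", ch$chain_id))
      next
    }
    cls <- classify_chain(hits_seqres)
    has_v <- "V" %in% hits_seqres$domain_label
    has_c <- any(hits_seqres$gene_class == "C")
    if (has_v && !has_c) {
      notes <- c(notes, sprintf("chain %s: V-only, out of V+C collection scope", ch$chain_id))
    }
    sp_hits <- best_hits_by_species(ch$seqres_seq, hits_seqres, refs)
    cons <- consolidate_species(sp_hits, provided_species,
                                override_margin = config$override_margin)
    v_top2 <- sp_hits |>
      filter(.data$domain_label == "V") |>
      arrange(desc(.data$percent_identity)) |>
      head(2L)
    eng <- flag_engineered(cons$per_domain, v_top2 = v_top2)
    iso <- if (has_c) assign_isotype(hits_seqres) else
      list(isotype_or_lctype = NA_character_, c_allele = NA_character_, gene = NA_character_)
    numbering <- number_chain(ch$atom_seq, hits_atom, refs)
    coverage <- structural_coverage(ch$seqres_seq, ch$atom_seq, refs,
                                    min_identity = config$min_identity,
                                    min_length = config$min_length)
    per_chain[[ch$chain_id]] <- list(
      chain = ch, chain_class = cls, hits_seqres = hits_seqres,
      hits_atom = hits_atom, numbering = numbering, coverage = coverage,
      species = cons, engineered = eng, isotype = iso, has_v = has_v,
      has_c = has_c)
    v_hit <- hits_seqres[hits_seqres$domain_label == "V", ]
    c_hit <- hits_seqres[hits_seqres$gene_class == "C", ]
    chain_rows[[ch$chain_id]] <- tibble(
      entry_id = structure$entry_id, chain_id = ch$chain_id,
      chain_class = cls,
      consolidated_species = cons$consolidated_species,
      engineered_flag = eng$flag,
      isotype_or_lctype = iso$isotype_or_lctype,
      c_allele = iso$c_allele,
      v_identity = if (nrow(v_hit) > 0L) max(v_hit$percent_identity) else NA_real_,
      c_identity = if (nrow(c_hit) > 0L) max(c_hit$percent_identity) else NA_real_,
      n_domains = nrow(hits_seqres))
  }

  if (length(per_chain) == 0L) {
    abort(sprintf("%s: no chain with domain hits", structure$entry_id))
  }

  heavy_ids <- names(per_chain)[map_chr(per_chain, "chain_class") == "H"]
  light_ids <- names(per_chain)[map_chr(per_chain, "chain_class") %in% c("K", "L")]
  pair <- pick_hl_pair(per_chain, heavy_ids, light_ids, config)

  geometry <- list(elbow_deg = NA_real_, ch1_cl_deg = NA_real_)
  contacts <- NULL; interface <- NULL
  numbering <- list()
  coverage_class <- "other"
  if (!is.null(pair)) {
    h <- per_chain[[pair$h]]; l <- per_chain[[pair$l]]
    numbering <- list(H = h$numbering, L = l$numbering)
    atom_domains <- c(h$hits_atom$domain_label, l$hits_atom$domain_label)
    coverage_class <- classify_coverage(atom_domains)

    lab_h <- labeled_calpha(h$chain, h$numbering)
    lab_l <- labeled_calpha(l$chain, l$numbering)
    vh <- filter(lab_h, .data$domain_label == "V")
    ch1 <- filter(lab_h, .data$domain_label == "CH1")
    vl <- filter(lab_l, .data$domain_label == "V")
    cl <- filter(lab_l, .data$domain_label == "CL")
    geometry <- tryCatch({
      list(elbow_deg = elbow_angle(vh, vl, ch1, cl),
           ch1_cl_deg = ch1_cl_angle(ch1, cl)$angle_deg)
    }, error = function(e) {
      notes <<- c(notes, sprintf("packing angles unavailable: %s", conditionMessage(e)))
      list(elbow_deg = NA_real_, ch1_cl_deg = NA_real_)
    })
    if (nrow(ch1) > 0L && nrow(cl) > 0L) {
      contacts <- contact_matrix(ch1, cl, cutoff = config$contact_cutoff)
    }
    if (config$compute_interface) {
      interface <- tryCatch(
        hl_interface(h$chain, l$chain,
                     delta_threshold = config$delta_sasa_threshold,
                     n_points = config$sasa_points),
        error = function(e) {
          notes <<- c(notes, sprintf("H-L interface unavailable: %s", conditionMessage(e)))
          NULL
        })
    }
  } else if (length(per_chain) > 0L) {
    one <- per_chain[[1]]
    coverage_class <- classify_coverage(one$hits_atom$domain_label)
    numbering <- setNames(list(one$numbering),
                          if (one$chain_class == "H") "H" else "L")
    notes <- c(notes, "no H-L pair found; structure annotated unpaired")
  }

  ss <- disulfide_bonds(structure, cutoff = config$disulfide_cutoff)

  h_row <- if (!is.null(pair)) chain_rows[[pair$h]] else NULL
  l_row <- if (!is.null(pair)) chain_rows[[pair$l]] else NULL
  species_all <- unique(map_chr(per_chain, function(p) p$species$consolidated_species))
  annotation <- tibble(
    entry_id = structure$entry_id,
    h_chain = pair$h %||% NA_character_,
    l_chain = pair$l %||% NA_character_,
    isotype = h_row$isotype_or_lctype %||% NA_character_,
    light_type = l_row$isotype_or_lctype %||% NA_character_,
    species = if (length(species_all) == 1L) species_all else
      paste(sort(species_all), collapse = "/"),
    engineered_flag = if (!is.null(h_row)) h_row$engineered_flag else
      per_chain[[1]]$engineered$flag,
    coverage_class = coverage_class,
    v_identity_h = h_row$v_identity %||% NA_real_,
    c_identity_h = h_row$c_identity %||% NA_real_,
    v_identity_l = l_row$v_identity %||% NA_real_,
    c_identity_l = l_row$c_identity %||% NA_real_,
    elbow_deg = geometry$elbow_deg,
    ch1_cl_deg = geometry$ch1_cl_deg,
    buried_area = if (!is.null(interface)) interface$buried_area else NA_real_,
    n_interface_residues = if (!is.null(interface)) nrow(interface$interface_residues) else NA_integer_,
    n_disulfides = nrow(ss))

  structure(list(entry_id = structure$entry_id,
                 chain_info = bind_rows(chain_rows),
                 numbering = numbering,
                 pair = pair,
                 annotation = annotation,
                 ch1_cl_contacts = contacts,
                 interface = interface,
                 disulfides = ss,
                 notes = notes),
            class = "fab_record")
}

#' @export
print.fab_record <- function(x, ...) {
  a <- x$annotation
  cat(sprintf("<fab_record> %s: %s/%s %s, %s, coverage %s\n",
              x$entry_id, a$h_chain, a$l_chain,
              a$isotype %||% "?", a$species, a$coverage_class))
  invisible(x)
}

## H-L pairing: trivial when there is one of each; with several
## candidates the pair burying the largest C-alpha contact surface wins
## (a fast proxy for interface area used only to disambiguate pairing).
pick_hl_pair <- function(per_chain, heavy_ids, light_ids, config) {
  if (length(heavy_ids) == 0L || length(light_ids) == 0L) return(NULL)
  if (length(heavy_ids) == 1L && length(light_ids) == 1L) {
    return(list(h = heavy_ids[1], l = light_ids[1]))
  }
  best <- NULL; best_n <- -1
  for (h in heavy_ids) for (l in light_ids) {
    ca_h <- as.matrix(calpha_coords(per_chain[[h]]$chain)[, c("x", "y", "z")])
    ca_l <- as.matrix(calpha_coords(per_chain[[l]]$chain)[, c("x", "y", "z")])
    d2 <- outer(rowSums(ca_h^2), rep(1, nrow(ca_l))) +
      outer(rep(1, nrow(ca_h)), rowSums(ca_l^2)) - 2 * ca_h %*% t(ca_l)
    n <- sum(d2 <= config$contact_cutoff^2)
    if (n > best_n) { best <- list(h = h, l = l); best_n <- n }
  }
  best
}

#' Run the annotation pipeline over a set of structure files
#'
#' Reads, annotates and indexes each structure.  Failures are isolated:
#' a malformed entry is logged and skipped, the rest of the batch
#' completes, and the failure count is reported (batch database builds
#' must not abort on single bad entries).  Output rows are sorted by
#' entry id so results are independent of input ordering.
#'
#' @param structure_paths Character vector of mmCIF/PDB files.
#' @param refs A `ref_set`.
#' @param metadata Optional named list (or JSON path) of per-entry
#'   deposition metadata with `species` elements.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes `annotations.csv` (with a
#'   config metadata comment header), `contacts_<entry>.csv` and
#'   `interfaces.csv`.
#' @param timestamp Include a timestamp line in CSV headers (default
#'   `FALSE` so identical inputs give identical bytes).
#' @return A `fab_pipeline` list: `annotations` (tibble, one row per
#'   entry), `records`, `index` (a `fab_index`), `failures` (tibble
#'   `path`, `error`), `config`.
#' @export
run_pipeline <- function(structure_paths, refs, metadata = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         timestamp = FALSE) {
  if (length(structure_paths) == 0L) abort("no input structures")
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- jsonlite::read_json(metadata)
  }
  records <- list(); failures <- list()
  for (p in structure_paths) {
    rec <- tryCatch({
      st <- read_structure(p)
      sp <- metadata[[st$entry_id]]$species %||% NA_character_
      annotate_structure(st, refs, provided_species = sp, config = config)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <- tibble(path = p,
                                                  error = conditionMessage(rec))
    } else {
      records[[rec$entry_id]] <- rec
    }
  }
  records <- records[order(names(records))]
  annotations <- map(records, "annotation") |> bind_rows()
  idx <- build_index(records)
  out <- structure(list(annotations = annotations, records = records,
                        index = idx,
                        failures = bind_rows(failures) %||%
                          tibble(path = character(), error = character()),
                        config = config),
                   class = "fab_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, timestamp)
  out
}

#' @export
print.fab_pipeline <- function(x, ...) {
  cat(sprintf("<fab_pipeline> %d annotated, %d failed\n",
              nrow(x$annotations), nrow(x$failures)))
  invisible(x)
}

#' @describeIn run_pipeline One-row batch summary.
#' @param x A `fab_pipeline`.
#' @param ... Unused.
#' @export
glance.fab_pipeline <- function(x, ...) {
  tibble(n_annotated = nrow(x$annotations),
         n_failed = nrow(x$failures),
         n_fab = sum(x$annotations$coverage_class == "Fab"),
         n_full = sum(x$annotations$coverage_class == "full"),
         mean_elbow_deg = mean(x$annotations$elbow_deg, na.rm = TRUE))
}

config_header <- function(config, timestamp) {
  vals <- map_chr(config, function(v) format(v, digits = 10))
  c(sprintf("# fabkit %s", as.character(utils::packageVersion("fabkit"))),
    if (timestamp) sprintf("# generated %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("# config %s=%s", names(vals), vals))
}

write_pipeline_outputs <- function(x, out_dir, timestamp = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_header(x$config, timestamp)
  ann_path <- file.path(out_dir, "annotations.csv")
  writeLines(c(hdr, readr::format_csv(x$annotations)), ann_path)
  for (rec in x$records) {
    if (!is.null(rec$ch1_cl_contacts)) {
      writeLines(c(hdr, readr::format_csv(tidy(rec$ch1_cl_contacts))),
                 file.path(out_dir, sprintf("contacts_%s.csv", rec$entry_id)))
    }
  }
  iface <- map(x$records, function(r) {
    if (is.null(r$interface)) return(NULL)
    mutate(r$interface$per_residue, entry_id = r$entry_id, .before = 1)
  }) |> compact() |> bind_rows()
  if (nrow(iface) > 0L) {
    writeLines(c(hdr, readr::format_csv(iface)), file.path(out_dir, "interfaces.csv"))
  }
  invisible(out_dir)
}
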