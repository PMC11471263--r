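#' Consolidate per-domain species calls with an identity override rule
#'
#' Structure depositions sometimes carry a wrong or imprecise species in
#' their metadata.  Per domain, the provided species is kept unless the best
#' germline hit comes from a different species *and* beats the best hit from
#' the provided species by more than `override_margin` percentage points of
#' identity (strict inequality); when the provided species has no reference
#' hit at all for a domain, the best hit's species wins unconditionally.
#'
#' @param domain_hits Tibble of domain hits for one chain (or one structure)
#'   with at least `domain_label`, `species`, `percent_identity`.  Supply
#'   all per-species best hits, e.g. [detect_domains()] output plus
#'   same-species runner-ups from [best_hits_by_species()].
#' @param provided_species Species string from the deposition metadata, or
#'   `NA` when absent (best hit then always wins).
#' @param override_margin Percentage-point margin the foreign hit must
#'   exceed (default 8).
#' @return List with `consolidated_species` (single string; slash-joined
#'   composite when domains disagree) and `per_domain` (tibble:
#'   `domain_label`, `species`, `percent_identity`, `overridden`).
#' @export
consolidate_species <- function(domain_hits, provided_species,
                                override_margin = 8) {
  if (!is.data.frame(domain_hits) || nrow(domain_hits) == 0L) {
    abort("`domain_hits` must contain at least one hit")
  }
  per <- domain_hits |>
    group_by(.data$domain_label) |>
    dplyr::group_modify(function(d, key) {
      best <- d[which.max(d$percent_identity), ]
      if (is.na(provided_species)) {
        return(tibble(species = best$species,
                      percent_identity = best$percent_identity,
                      overridden = FALSE))
      }
      prov <- d[d$species == provided_species, ]
      if (nrow(prov) == 0L) {
        return(tibble(species = best$species,
                      percent_identity = best$percent_identity,
                      overridden = best$species != provided_species))
      }
      prov_best <- max(prov$percent_identity)
      if (best$species != provided_species &&
          best$percent_identity - prov_best > override_margin) {
        tibble(species = best$species,
               percent_identity = best$percent_identity,
               overridden = TRUE)
      } else {
        tibble(species = provided_species,
               percent_identity = prov_best,
               overridden = FALSE)
      }
    }) |>
    ungroup()

  uniq <- unique(per$species)
  consolidated <- if (length(uniq) == 1L) uniq else paste(sort(uniq), collapse = "/")
  list(consolidated_species = consolidated, per_domain = per)
}

#' Best hit per species for each domain span
#'
#' Re-aligns each accepted domain span against every allele of every
#' species, keeping the best hit per (domain, species).  This supplies
#' [consolidate_species()] with the same-species runner-up identities the
#' override rule compares against.
#'
#' @param query Chain amino-acid string.
#' @param hits [detect_domains()] output for that chain.
#' @param refs The `ref_set`.
#' @return Tibble: `domain_label`, `species`, `allele_id`,
#'   `alignment_score`, `percent_identity`.
#' @export
best_hits_by_species <- function(query, hits, refs) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    span <- substr(query, h$query_start, h$query_end)
    cand <- refs[refs$domain_label == h$domain_label &
                 refs$gene_class == h$gene_class, ]
    for (sp in unique(cand$species)) {
      sub <- cand[cand$species == sp, ]
      best <- NULL
      for (a in seq_len(nrow(sub))) {
        al <- align_pair(span, sub$ungapped_seq[a], mode = "local")
        if (is.null(best) || al$score > best$al$score ||
            (al$score == best$al$score &&
             al$percent_identity > best$al$percent_identity)) {
          best <- list(al = al, a = a)
        }
      }
      rows[[length(rows) + 1L]] <- tibble(
        domain_label = h$domain_label, species = sp,
        allele_id = sub$allele_id[best$a],
        alignment_score = best$al$score,
        percent_identity = best$al$percent_identity)
    }
  }
  bind_rows(rows)
}

#' Flag engineered antibody formats
#'
#' Compares per-domain species verdicts on one chain (or H-L pair):
#' all domains from one species is `"none"`; V and C regions from
#' different species is `"chimeric"`; same species throughout but with
#' mixed evidence inside the V domain (top hits from two species within
#' `mixed_margin` identity points) is `"humanized"` (a heuristic call,
#' reported with a confidence note); anything else is `"unresolved"`.
#'
#' @param domain_species Named character vector or tibble
#'   (`domain_label`, `species`) of consolidated per-domain species.
#' @param v_top2 Optional tibble of the top-2 V-domain hits across species
#'   (`species`, `percent_identity`) used for the humanized heuristic.
#' @param mixed_margin Identity window (percentage points) within which a
#'   split V-domain top-2 counts as mixed evidence (default 2).
#' @return List: `flag` in `none`/`chimeric`/`humanized`/`unresolved`,
#'   `note` (character, possibly empty).
#' @export
flag_engineered <- function(domain_species, v_top2 = NULL, mixed_margin = 2) {
  if (is.data.frame(domain_species)) {
    ds <- setNames(domain_species$species, domain_species$domain_label)
  } else ds <- domain_species
  if (length(ds) == 0L) return(list(flag = "unresolved", note = "no domain verdicts"))

  v_sp <- ds[names(ds) == "V"]
  c_sp <- ds[names(ds) != "V"]
  mixed_v <- FALSE
  if (!is.null(v_top2) && nrow(v_top2) >= 2L) {
    o <- order(v_top2$percent_identity, decreasing = TRUE)
    top <- v_top2[o[1:2], ]
    mixed_v <- top$species[1] != top$species[2] &&
      abs(top$percent_identity[1] - top$percent_identity[2]) <= mixed_margin
  }

  if (length(unique(ds)) == 1L) {
    if (mixed_v) {
      return(list(flag = "humanized",
                  note = "heuristic: V-domain top hits split between species within the mixed-evidence margin"))
    }
    return(list(flag = "none", note = ""))
  }
  if (length(v_sp) > 0L && length(c_sp) > 0L &&
      !any(v_sp %in% c_sp)) {
    return(list(flag = "chimeric", note = ""))
  }
  list(flag = "unresolved", note = "domain species disagree without a clean V/C split")
}

## Gene prefix (text before '*', and before any '_' domain suffix used by
## synthetic allele ids) -> isotype / light-chain type.
ISOTYPE_MAP <- c(
  IGHG1 = "IgG1", IGHG2 = "IgG2", IGHG3 = "IgG3", IGHG4 = "IgG4",
  IGHA1 = "IgA1", IGHA2 = "IgA2",
  IGHM = "IgM", IGHD = "IgD", IGHE = "IgE",
  IGKC = "kappa", IGLC = "lambda"
)

gene_prefix <- function(allele_id) sub("\\*.*$", "", allele_id)

isotype_from_allele <- function(allele_id) {
  g <- gene_prefix(allele_id)
  if (g %in% names(ISOTYPE_MAP)) return(unname(ISOTYPE_MAP[g]))
  hit <- names(ISOTYPE_MAP)[startsWith(g, names(ISOTYPE_MAP))]
  if (length(hit) > 0L) return(unname(ISOTYPE_MAP[hit[which.max(nchar(hit))]]))
  g
}

#' Assign isotype or light-chain type from constant-region hits
#'
#' The single C-domain hit with the highest percent identity decides; ties
#' are broken by alignment score, then lexicographic allele id.  The
#' winning allele's gene prefix maps to an isotype (IGHG1 -> IgG1, IGHA1 ->
#' IgA1, IGHM -> IgM, ...) or light-chain type (IGKC -> kappa, IGLC ->
#' lambda).
#'
#' @param c_hits Tibble of C-region hits (`gene_class == "C"`) with
#'   `allele_id`, `percent_identity`, `alignment_score`.
#' @return List: `isotype_or_lctype`, `c_allele`, `gene` (the gene prefix;
#'   allele-level resolution is kept alongside).
#' @export
assign_isotype <- function(c_hits) {
  c_hits <- c_hits[c_hits$gene_class == "C" & c_hits$domain_label != "hinge", ]
  if (nrow(c_hits) == 0L) {
    abort("no constant-region hit: V-only chain, out of scope for isotype assignment")
  }
  o <- order(-c_hits$percent_identity, -c_hits$alignment_score, c_hits$allele_id)
  win <- c_hits[o[1], ]
  list(isotype_or_lctype = isotype_from_allele(win$allele_id),
       c_allele = win$allele_id,
       gene = gene_prefix(win$allele_id))
}

#' Classify structural coverage from ATOM-resolved domains
#'
#' A structure whose coordinates include any of CH2/CH3/CH4 is a full
#' antibody; otherwise V plus CH1 or CL makes a Fab; anything else is
#' `"other"`.  Coverage is decided on domains detected in the
#' ATOM-resolved sequence, not the deposited SEQRES.
#'
#' @param atom_resolved_domains Character vector of domain labels with
#'   resolved coordinates.
#' @return `"full"`, `"Fab"` or `"other"`.
#' @export
classify_coverage <- function(atom_resolved_domains) {
  d <- unique(atom_resolved_domains)
  if (any(c("CH2", "CH3", "CH4") %in% d)) return("full")
  if ("V" %in% d && any(c("CH1", "CL") %in% d)) return("Fab")
  "other"
}

#' Per-domain structural coverage of a chain
#'
#' Detects domains on the ATOM-resolved sequence and reports, per domain,
#' the fraction of the reference domain length that is resolved.
#'
#' @param seqres_seq Full deposited chain sequence.
#' @param atom_seq Subsequence with resolved coordinates (must be a
#'   subsequence of `seqres_seq`).
#' @param refs A `ref_set`.
#' @param ... Passed to [detect_domains()].
#' @return Tibble: one row per detected domain with `domain_label`,
#'   `allele_id`, `query_start`, `query_end` (in `atom_seq` space),
#'   `resolved_residues`, `reference_length`, `fraction_resolved`.
#' @export
structural_coverage <- function(seqres_seq, atom_seq, refs, ...) {
  if (!is_subsequence(atom_seq, seqres_seq)) {
    abort("`atom_seq` is not a subsequence of `seqres_seq`: data inconsistency")
  }
  hits <- detect_domains(atom_seq, refs, ...)
  if (nrow(hits) == 0L) {
    return(tibble(domain_label = character(), allele_id = character(),
                  query_start = integer(), query_end = integer(),
                  resolved_residues = integer(), reference_length = integer(),
                  fraction_resolved = double()))
  }
  ref_len <- nchar(refs$ungapped_seq)[match(hits$allele_id, refs$allele_id)]
  hits |>
    mutate(resolved_residues = .data$query_end - .data$query_start + 1L,
           reference_length = ref_len,
           fraction_resolved = .data$resolved_residues / .data$reference_length) |>
    select("domain_label", "allele_id", "query_start", "query_end",
           "resolved_residues", "reference_length", "fraction_resolved")
}
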