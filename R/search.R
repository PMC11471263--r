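#' Build a search query
#'
#' @param query_id Identifier string.
#' @param heavy_seq,light_seq Amino-acid strings; at least one required.
#' @param region `"V"` (variable region only) or `"VC"` (V plus C).
#' @return One-row tibble with class `search_query` semantics used by
#'   [seq_search()].
#' @export
search_query <- function(query_id, heavy_seq = NA_character_,
                         light_seq = NA_character_, region = c("V", "VC")) {
  region <- match.arg(region)
  if (is.na(heavy_seq) && is.na(light_seq)) {
    abort("a search query needs at least one of heavy_seq / light_seq")
  }
  tibble(query_id = query_id, heavy_seq = heavy_seq,
         light_seq = light_seq, region = region)
}

#' Build a sequence/interface search index from annotated records
#'
#' For every annotated H-L pair the index stores four sequence views
#' (heavy V, heavy V+C, light V, light V+C) reconstructed from the
#' per-chain numbering tables, plus the CH1-CL contact matrix when
#' available.  Records lacking numbering are skipped with a warning.
#'
#' @param records List of annotated records, e.g. elements of
#'   [run_pipeline()]'s `records`, each a list with `entry_id`,
#'   `numbering` (named list of [number_chain()] tables for the H and L
#'   chains) and optionally `ch1_cl_contacts` (a `contact_matrix`).
#' @return A `fab_index`.
#' @export
build_index <- function(records) {
  seqs <- list(); contacts <- list()
  for (rec in records) {
    if (is.null(rec$numbering) || length(rec$numbering) == 0L) {
      warn(sprintf("record %s lacks numbering; skipped", rec$entry_id %||% "?"))
      next
    }
    views <- list(h_v = NA_character_, h_vc = NA_character_,
                  l_v = NA_character_, l_vc = NA_character_)
    for (role in names(rec$numbering)) {
      num <- rec$numbering[[role]]
      if (is.null(num) || nrow(num) == 0L) next
      v_seq <- collapse(num$amino_acid[num$domain_label == "V"])
      vc_seq <- collapse(num$amino_acid)
      key <- if (role == "H") "h" else "l"
      if (nchar(v_seq) > 0L) views[[paste0(key, "_v")]] <- v_seq
      if (nchar(vc_seq) > nchar(v_seq)) views[[paste0(key, "_vc")]] <- vc_seq
    }
    seqs[[length(seqs) + 1L]] <- tibble(entry_id = rec$entry_id,
                                        h_v = views$h_v, h_vc = views$h_vc,
                                        l_v = views$l_v, l_vc = views$l_vc)
    if (!is.null(rec$ch1_cl_contacts)) {
      contacts[[rec$entry_id]] <- rec$ch1_cl_contacts
    }
  }
  structure(list(
    seqs = if (length(seqs) > 0L) bind_rows(seqs) else
      tibble(entry_id = character(), h_v = character(), h_vc = character(),
             l_v = character(), l_vc = character()),
    contacts = contacts
  ), class = "fab_index")
}

#' @export
print.fab_index <- function(x, ...) {
  cat(sprintf("<fab_index> %d entries, %d with CH1-CL contact matrices\n",
              nrow(x$seqs), length(x$contacts)))
  invisible(x)
}

#' Sequence-similarity search over an index
#'
#' Aligns each present query chain (locally, BLOSUM62) against the
#' matching view of every indexed entry and ranks entries by the combined
#' identity: the mean of the present chains' percent identities (weights
#' configurable).  Ties are broken by entry id.
#'
#' @param query A query tibble from [search_query()] (or one row of
#'   [parse_repertoire()] output).
#' @param index A `fab_index`.
#' @param top_k Number of hits to return (default 10).
#' @param weights Length-2 numeric weights for (heavy, light) when both
#'   chains are present (default equal).
#' @return Tibble: `query_id`, `rank`, `entry_id`, `identity_h`,
#'   `identity_l`, `combined_identity`.
#' @export
seq_search <- function(query, index, top_k = 10, weights = c(1, 1)) {
  if (!inherits(index, "fab_index")) abort("`index` must be a fab_index")
  if (nrow(query) != 1L) abort("`query` must be a single query row")
  if (is.na(query$heavy_seq) && is.na(query$light_seq)) {
    abort("query has neither a heavy nor a light sequence")
  }
  db <- index$seqs
  if (nrow(db) == 0L) {
    return(tibble(query_id = character(), rank = integer(),
                  entry_id = character(), identity_h = double(),
                  identity_l = double(), combined_identity = double()))
  }
  region <- query$region %||% "V"
  h_view <- if (region == "V") db$h_v else dplyr::coalesce(db$h_vc, db$h_v)
  l_view <- if (region == "V") db$l_v else dplyr::coalesce(db$l_vc, db$l_v)

  idh <- rep(NA_real_, nrow(db)); idl <- rep(NA_real_, nrow(db))
  for (i in seq_len(nrow(db))) {
    if (!is.na(query$heavy_seq) && !is.na(h_view[i])) {
      idh[i] <- align_pair(query$heavy_seq, h_view[i], mode = "local")$percent_identity
    }
    if (!is.na(query$light_seq) && !is.na(l_view[i])) {
      idl[i] <- align_pair(query$light_seq, l_view[i], mode = "local")$percent_identity
    }
  }
  w <- cbind(ifelse(is.na(idh), 0, weights[1]), ifelse(is.na(idl), 0, weights[2]))
  vals <- cbind(ifelse(is.na(idh), 0, idh), ifelse(is.na(idl), 0, idl))
  combined <- rowSums(vals * w) / pmax(rowSums(w), .Machine$double.eps)

  out <- tibble(query_id = query$query_id, entry_id = db$entry_id,
                identity_h = idh, identity_l = idl,
                combined_identity = combined) |>
    arrange(desc(.data$combined_identity), .data$entry_id) |>
    mutate(rank = row_number(), .after = "query_id")
  head(out, top_k)
}

#' Parse a repertoire file into search queries
#'
#' Supports plain FASTA, AIRR-standard TSV, the same table as CSV, and
#' 10x-Cellranger-style contig CSV.  Chains are paired by cell identifier
#' where the dialect supports it (AIRR `cell_id`, 10x `barcode`, FASTA
#' headers of the form `id|H` / `id|L`); unpairable chains become unpaired
#' queries with a warning.  More than `max_batch` input records is an
#' error unless `no_limit = TRUE` (mirrors the batch limit of the
#' interactive service).
#'
#' @param path Input file.
#' @param dialect `"fasta"`, `"airr_tsv"`, `"csv"` or `"tenx_contig_csv"`.
#' @param max_batch Maximum records per batch (default 200).
#' @param no_limit Disable the batch limit.
#' @param col_map Named list overriding column names for the tabular
#'   dialects: `sequence_id`, `cell_id`, `locus`, `sequence_aa` (AIRR/CSV)
#'   and `barcode`, `chain`, `sequence_aa` (10x).
#' @param region Region tag attached to every query (default `"V"`).
#' @return Tibble of queries: `query_id`, `heavy_seq`, `light_seq`,
#'   `region`, `paired`.
#' @export
parse_repertoire <- function(path,
                             dialect = c("fasta", "airr_tsv", "csv", "tenx_contig_csv"),
                             max_batch = 200, no_limit = FALSE,
                             col_map = list(), region = "V") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("repertoire file not found: %s", path))

  if (dialect == "fasta") {
    recs <- parse_fasta(path)
    check_batch(nrow(recs), max_batch, no_limit)
    parts <- strsplit(recs$header, "|", fixed = TRUE)
    ids <- map_chr(parts, 1)
    chain <- toupper(map_chr(parts, function(p) if (length(p) >= 2L) p[2] else "H"))
    chain[!chain %in% c("H", "L", "K")] <- "H"
    chain[chain == "K"] <- "L"
    tab <- tibble(cell = ids, chain = chain, seq = toupper(recs$seq),
                  rec_id = recs$header)
    return(pair_queries(tab, region, warn_unpaired = FALSE))
  }

  cm <- if (dialect == "tenx_contig_csv") {
    utils::modifyList(list(barcode = "barcode", chain = "chain",
                           sequence_aa = "sequence_aa"), col_map)
  } else {
    utils::modifyList(list(sequence_id = "sequence_id", cell_id = "cell_id",
                           locus = "locus", sequence_aa = "sequence_aa"), col_map)
  }
  tbl <- switch(dialect,
    airr_tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    csv = ,
    tenx_contig_csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  miss <- setdiff(unname(unlist(cm)), names(tbl))
  if (length(miss) > 0L) {
    abort(sprintf("%s file is missing required column(s): %s",
                  dialect, paste(miss, collapse = ", ")))
  }
  check_batch(nrow(tbl), max_batch, no_limit)

  if (dialect == "tenx_contig_csv") {
    tab <- tibble(cell = as.character(tbl[[cm$barcode]]),
                  chain = ifelse(tbl[[cm$chain]] == "IGH", "H", "L"),
                  seq = toupper(tbl[[cm$sequence_aa]]),
                  rec_id = as.character(tbl[[cm$barcode]]))
  } else {
    tab <- tibble(cell = as.character(tbl[[cm$cell_id]]),
                  chain = ifelse(tbl[[cm$locus]] == "IGH", "H", "L"),
                  seq = toupper(tbl[[cm$sequence_aa]]),
                  rec_id = as.character(tbl[[cm$sequence_id]]))
  }
  if (any(is.na(tab$seq) | tab$seq == "")) {
    abort("amino-acid sequence column contains empty values; nucleotide-only input is not supported")
  }
  pair_queries(tab, region)
}

check_batch <- function(n, max_batch, no_limit) {
  if (!no_limit && n > max_batch) {
    abort(sprintf("batch of %d records exceeds the maximum of %d (use no_limit to override)",
                  n, max_batch))
  }
}

pair_queries <- function(tab, region, warn_unpaired = TRUE) {
  out <- list()
  for (cell in unique(tab$cell)) {
    rows <- tab[tab$cell == cell, ]
    h <- rows$seq[rows$chain == "H"]
    l <- rows$seq[rows$chain == "L"]
    if (length(h) > 1L || length(l) > 1L) {
      warn(sprintf("cell %s has multiple contigs for one chain; keeping the first", cell))
      h <- head(h, 1L); l <- head(l, 1L)
    }
    if (length(h) == 1L && length(l) == 1L) {
      out[[length(out) + 1L]] <- tibble(query_id = cell, heavy_seq = h,
                                        light_seq = l, region = region,
                                        paired = TRUE)
    } else {
      if (warn_unpaired) {
        warn(sprintf("cell %s has an unpaired chain; emitted as unpaired query", cell))
      }
      out[[length(out) + 1L]] <- tibble(
        query_id = cell,
        heavy_seq = if (length(h) == 1L) h else NA_character_,
        light_seq = if (length(l) == 1L) l else NA_character_,
        region = region, paired = FALSE)
    }
  }
  bind_rows(out)
}

#' Contact-map similarity between two interfaces
#'
#' Restricts both matrices to their shared label pairs and compares the
#' contact sets.  The default metric is the Jaccard index of the two
#' contact sets on the shared support (1 when both sets are identical,
#' including the both-empty case); `method = "correlation"` instead maps
#' the Pearson correlation of the shared distances to `[0, 1]`.
#' No shared labels yields 0 with a warning.
#'
#' @param a,b `contact_matrix` objects indexed by IMGT labels.
#' @param method `"jaccard"` (default) or `"correlation"`.
#' @return Similarity in `[0, 1]`.
#' @export
interface_similarity <- function(a, b, method = c("jaccard", "correlation")) {
  method <- match.arg(method)
  for (m in list(a, b)) {
    if (!inherits(m, "contact_matrix") || length(m$row_labels) == 0L) {
      abort("`a` and `b` must be non-empty contact_matrix objects")
    }
  }
  rows <- intersect(a$row_labels, b$row_labels)
  cols <- intersect(a$col_labels, b$col_labels)
  if (length(rows) == 0L || length(cols) == 0L) {
    warn("no shared labels between contact matrices; similarity 0")
    return(0)
  }
  ca <- a$contacts[match(rows, a$row_labels), match(cols, a$col_labels), drop = FALSE]
  cb <- b$contacts[match(rows, b$row_labels), match(cols, b$col_labels), drop = FALSE]
  ok <- !is.na(ca) & !is.na(cb)
  if (method == "correlation") {
    da <- a$distances[match(rows, a$row_labels), match(cols, a$col_labels), drop = FALSE]
    db <- b$distances[match(rows, b$row_labels), match(cols, b$col_labels), drop = FALSE]
    if (sum(ok) < 2L) return(0)
    r <- suppressWarnings(stats::cor(da[ok], db[ok]))
    if (is.na(r)) r <- 1  # zero-variance distances on both sides
    return((r + 1) / 2)
  }
  inter <- sum(ca & cb & ok)
  uni <- sum((ca | cb) & ok)
  if (uni == 0L) return(1)
  inter / uni
}

#' Search an index by CH1-CL interface similarity
#'
#' @param query_matrix A `contact_matrix` for the query's CH1-CL
#'   interface.
#' @param index A `fab_index` whose records carry CH1-CL contact matrices.
#' @param top_k Number of hits (default 10).
#' @param method Passed to [interface_similarity()].
#' @return Tibble: `rank`, `entry_id`, `similarity` (descending, ties by
#'   entry id).
#' @export
interface_search <- function(query_matrix, index, top_k = 10,
                             method = "jaccard") {
  if (!inherits(index, "fab_index")) abort("`index` must be a fab_index")
  if (length(index$contacts) == 0L) {
    return(tibble(rank = integer(), entry_id = character(), similarity = double()))
  }
  sims <- map_dbl(index$contacts, function(m) {
    suppressWarnings(interface_similarity(query_matrix, m, method = method))
  })
  out <- tibble(entry_id = names(sims), similarity = unname(sims)) |>
    arrange(desc(.data$similarity), .data$entry_id) |>
    mutate(rank = row_number(), .before = "entry_id")
  head(out, top_k)
}
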