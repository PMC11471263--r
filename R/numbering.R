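#' Detect V and C domains in an amino-acid sequence
#'
#' Greedy non-overlapping decomposition of a query chain into germline
#' domains.  Every allele in the reference set is aligned locally against
#' each still-unassigned segment of the query; the best-scoring hit (ties
#' broken by higher percent identity, then lexicographic allele id) is
#' accepted if it passes the identity and length thresholds, its span is
#' masked, and the search repeats until nothing passes.
#'
#' @param query Amino-acid string.
#' @param refs A `ref_set` (see [read_reference_set()]).
#' @param min_identity Minimum percent identity for an accepted hit.
#' @param min_length Minimum aligned query span (residues) for an accepted
#'   hit, and minimum segment length worth searching.
#' @return Tibble of hits in query order: `query_start`, `query_end`,
#'   `allele_id`, `species`, `gene_class`, `chain_class`, `domain_label`,
#'   `alignment_score`, `percent_identity`, `rank` (1 = accepted first).
#'   Zero rows when nothing passes the thresholds.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">V1|Homo sapiens|V|H|V", "QVQLVQSGAEVKKPGASVKVSCKASGYTFTSYAMHWVRQAPGQRLEWMGW",
#'              ">C1|Homo sapiens|C|H|CH1", "ASTKGPSVFPLAPSSKSTSGGTAALGCLVKDYFPEPVTVSWNSGALTSGV"), fa)
#' refs <- read_reference_set(fa)
#' hits <- detect_domains(paste0(refs$ungapped_seq[1], refs$ungapped_seq[2]), refs)
#' hits$domain_label
#' @export
detect_domains <- function(query, refs, min_identity = 50, min_length = 50) {
  if (!inherits(refs, "ref_set")) abort("`refs` must be a ref_set")
  query <- toupper(query)
  check_aa(query, "query")
  n <- nchar(query)

  free <- rep(TRUE, n)
  hits <- list()
  rank <- 0L
  repeat {
    segs <- free_segments(free, min_length)
    if (nrow(segs) == 0L) break
    best <- NULL
    for (s in seq_len(nrow(segs))) {
      seg_seq <- substr(query, segs$start[s], segs$end[s])
      for (a in seq_len(nrow(refs))) {
        al <- align_pair(seg_seq, refs$ungapped_seq[a], mode = "local")
        cand <- list(align = al, allele = a,
                     qs = segs$start[s] + al$query_start - 1L,
                     qe = segs$start[s] + al$query_end - 1L)
        if (is.null(best) || better_hit(cand, best, refs)) best <- cand
      }
    }
    if (is.null(best)) break
    span_len <- best$qe - best$qs + 1L
    if (best$align$percent_identity < min_identity || span_len < min_length) break
    rank <- rank + 1L
    a <- best$allele
    hits[[rank]] <- tibble(
      query_start = best$qs, query_end = best$qe,
      allele_id = refs$allele_id[a], species = refs$species[a],
      gene_class = refs$gene_class[a], chain_class = refs$chain_class[a],
      domain_label = refs$domain_label[a],
      alignment_score = best$align$score,
      percent_identity = best$align$percent_identity,
      rank = rank)
    free[best$qs:best$qe] <- FALSE
  }

  if (length(hits) == 0L) {
    return(tibble(query_start = integer(), query_end = integer(),
                  allele_id = character(), species = character(),
                  gene_class = character(), chain_class = character(),
                  domain_label = character(), alignment_score = double(),
                  percent_identity = double(), rank = integer()))
  }
  arrange(bind_rows(hits), .data$query_start)
}

free_segments <- function(free, min_length) {
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  tibble(start = starts[keep], end = ends[keep])
}

## Ordering: score desc, then percent identity desc, then allele_id asc.
better_hit <- function(a, b, refs) {
  if (a$align$score != b$align$score) return(a$align$score > b$align$score)
  if (a$align$percent_identity != b$align$percent_identity) {
    return(a$align$percent_identity > b$align$percent_identity)
  }
  refs$allele_id[a$allele] < refs$allele_id[b$allele]
}

#' Transfer IMGT-style position labels onto a query domain
#'
#' Globally aligns the query span of a domain hit to the hit allele's
#' ungapped sequence and labels each query residue with the gapped column
#' index of the reference residue it aligns to.  Query residues that align
#' to a reference gap (insertions) get the preceding numeric label plus
#' consecutive lowercase suffixes `a`, `b`, ...; reference columns skipped
#' by the alignment are simply absent (deletions leave holes).  Hinge
#' domains are not numbered (IMGT C-domain numbering does not cover the
#' hinge).
#'
#' @param query_span The amino-acid subsequence covered by the hit
#'   (`substr(query, hit$query_start, hit$query_end)`).
#' @param hit One row of [detect_domains()] output.
#' @param refs The `ref_set` the hit came from.
#' @return A `numbered_domain`: tibble with columns `imgt_label`,
#'   `amino_acid`, and attributes `domain_label` and `allele_id`.
#' @export
number_domain <- function(query_span, hit, refs) {
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) abort("`hit` must be a single hit row")
  } else abort("`hit` must be a one-row hit table")
  if (hit$domain_label == "hinge") {
    abort("hinge domains are not numbered (no IMGT C-domain columns)")
  }
  allele <- refs[refs$allele_id == hit$allele_id, ]
  if (nrow(allele) != 1L) abort(sprintf("allele %s not in reference set", hit$allele_id))
  query_span <- toupper(query_span)
  if (nchar(query_span) != hit$query_end - hit$query_start + 1L) {
    abort("`query_span` length does not match the hit's query coordinates")
  }

  pmap_cols <- gapped_position_map(allele)
  al <- align_pair(query_span, allele$ungapped_seq, mode = "global")
  qc <- chars(al$query_aligned); rc <- chars(al$ref_aligned)

  labels <- character(0); aas <- character(0)
  r <- 0L              # ungapped reference index consumed so far
  last_num <- 0L       # numeric label of the last reference-aligned residue
  ins <- 0L            # running insertion count at last_num
  for (i in seq_along(qc)) {
    if (rc[i] != "-") r <- r + 1L
    if (qc[i] == "-") next
    if (rc[i] != "-") {
      last_num <- pmap_cols[r]
      ins <- 0L
      labels <- c(labels, as.character(last_num))
    } else {
      ins <- ins + 1L
      labels <- c(labels, paste0(last_num, letters[ins]))
    }
    aas <- c(aas, qc[i])
  }

  structure(tibble(imgt_label = labels, amino_acid = aas),
            domain_label = hit$domain_label,
            allele_id = hit$allele_id,
            class = c("numbered_domain", class(tibble())))
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain> %s via %s, %d residues\n",
              attr(x, "domain_label"), attr(x, "allele_id"), nrow(x)))
  NextMethod()
}

#' Number every detected domain of a chain
#'
#' Convenience wrapper: runs [number_domain()] over all non-hinge hits of
#' one chain and binds the result into a long tibble.
#'
#' @param query The full chain amino-acid string the hits refer to.
#' @param hits Output of [detect_domains()] for that chain.
#' @param refs The `ref_set` used for detection.
#' @return Long tibble: `domain_label`, `allele_id`, `imgt_label`,
#'   `amino_acid`, `query_pos` (1-based index into `query`).
#' @export
number_chain <- function(query, hits, refs) {
  if (nrow(hits) == 0L) {
    return(tibble(domain_label = character(), allele_id = character(),
                  imgt_label = character(), amino_acid = character(),
                  query_pos = integer()))
  }
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$domain_label == "hinge") next
    nd <- number_domain(substr(query, h$query_start, h$query_end), h, refs)
    rows[[length(rows) + 1L]] <- tibble(
      domain_label = h$domain_label, allele_id = h$allele_id,
      imgt_label = nd$imgt_label, amino_acid = nd$amino_acid,
      query_pos = h$query_start - 1L + cumsum(rep(1L, nrow(nd))))
  }
  bind_rows(rows)
}

#' Classify a chain as heavy, kappa or lambda
#'
#' Majority vote of the hits' chain classes weighted by alignment score;
#' returns `"ambiguous"` when the top two classes tie exactly.
#'
#' @param hits Output of [detect_domains()] for one chain (>= 1 row).
#' @return One of `"H"`, `"K"`, `"L"`, `"ambiguous"`.
#' @export
classify_chain <- function(hits) {
  if (!is.data.frame(hits) || nrow(hits) == 0L) {
    abort("`hits` must contain at least one domain hit")
  }
  w <- tapply(hits$alignment_score, hits$chain_class, sum)
  w <- sort(w, decreasing = TRUE)
  if (length(w) > 1L && w[1] == w[2]) return("ambiguous")
  names(w)[1]
}
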