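# Shared builders for search-index records and contact matrices used by
# several test files.  All are deterministic given the caller's seed.

AAS20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_chars <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- runif(length(s)) < rate
  s[hit] <- vapply(s[hit], function(x) sample(setdiff(AAS20, x), 1), "")
  paste(s, collapse = "")
}

fake_numbering <- function(v_seq, c_seq = NULL, c_label = "CH1") {
  v <- tibble::tibble(domain_label = "V",
                      allele_id = "x",
                      imgt_label = as.character(seq_len(nchar(v_seq))),
                      amino_acid = strsplit(v_seq, "")[[1]],
                      query_pos = seq_len(nchar(v_seq)))
  if (is.null(c_seq)) return(v)
  c_tbl <- tibble::tibble(domain_label = c_label,
                          allele_id = "x",
                          imgt_label = as.character(seq_len(nchar(c_seq))),
                          amino_acid = strsplit(c_seq, "")[[1]],
                          query_pos = nchar(v_seq) + seq_len(nchar(c_seq)))
  dplyr::bind_rows(v, c_tbl)
}

# n divergent entries derived from the seed-7 reference fixture; each record
# carries paired H/L numbering (V+C) and no contact matrix
make_test_records <- function(n, seed, divergence = 0.3) {
  refs <- make_reference_fixture(fixture_spec(7))$refs
  vh <- refs$ungapped_seq[refs$allele_id == "IGHV1*01"]
  ch1 <- refs$ungapped_seq[refs$allele_id == "IGHG1*01_CH1"]
  vk <- refs$ungapped_seq[refs$allele_id == "IGKV1*01"]
  clk <- refs$ungapped_seq[refs$allele_id == "IGKC*01"]
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(entry_id = sprintf("DB%03d", i),
         numbering = list(
           H = fake_numbering(mutate_chars(vh, divergence),
                              mutate_chars(ch1, divergence)),
           L = fake_numbering(mutate_chars(vk, divergence),
                              mutate_chars(clk, divergence), c_label = "CL")))
  })
}

# random binary contact matrix over fixed label grids
random_contact_matrix <- function(n_row = 20, n_col = 20, p = 0.15,
                                  cutoff = 8) {
  contacts <- matrix(runif(n_row * n_col) < p, n_row, n_col)
  distances <- ifelse(contacts, 4, 15)
  labs_r <- as.character(seq_len(n_row)); labs_c <- as.character(seq_len(n_col))
  dimnames(distances) <- list(labs_r, labs_c)
  structure(list(row_labels = labs_r, col_labels = labs_c,
                 distances = distances, contacts = distances <= cutoff,
                 cutoff = cutoff),
            class = "contact_matrix")
}

flip_contacts <- function(cm, frac) {
  flip <- matrix(runif(length(cm$contacts)) < frac, nrow(cm$contacts))
  cm$contacts <- xor(cm$contacts, flip)
  cm$distances <- ifelse(cm$contacts, 4, 15)
  dimnames(cm$distances) <- list(cm$row_labels, cm$col_labels)
  cm
}
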