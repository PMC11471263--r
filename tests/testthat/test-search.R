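test_that("the index exposes four sequence views per paired record", {
  recs <- make_test_records(3, seed = 1)
  idx <- build_index(recs)
  expect_equal(nrow(idx$seqs), 3L)
  expect_false(anyNA(idx$seqs[, c("h_v", "h_vc", "l_v", "l_vc")]))
  expect_true(all(nchar(idx$seqs$h_vc) > nchar(idx$seqs$h_v)))

  # V-only chain: no VC view for it
  rec_v <- list(entry_id = "VONLY",
                numbering = list(H = fake_numbering("QVQLVQSGAEVKK")))
  idx2 <- build_index(list(rec_v))
  expect_true(is.na(idx2$seqs$h_vc))
  expect_true(is.na(idx2$seqs$l_v))

  # records without numbering are skipped with a warning
  expect_warning(idx3 <- build_index(list(list(entry_id = "EMPTY"))), "skipped")
  expect_equal(nrow(idx3$seqs), 0L)
  expect_equal(nrow(seq_search(search_query("q", heavy_seq = "QVQLVQSGAEVKK"),
                               idx3)), 0L)
})

test_that("every indexed entry retrieves itself at 100% identity", {
  recs <- make_test_records(8, seed = 2)
  idx <- build_index(recs)
  for (i in seq_len(nrow(idx$seqs))) {
    q <- search_query(idx$seqs$entry_id[i],
                      heavy_seq = idx$seqs$h_v[i],
                      light_seq = idx$seqs$l_v[i], region = "V")
    hits <- seq_search(q, idx, top_k = 3)
    expect_equal(hits$entry_id[1], idx$seqs$entry_id[i])
    expect_equal(hits$combined_identity[1], 100)
    # and over V+C as well
    qvc <- search_query(idx$seqs$entry_id[i],
                        heavy_seq = idx$seqs$h_vc[i],
                        light_seq = idx$seqs$l_vc[i], region = "VC")
    expect_equal(seq_search(qvc, idx, top_k = 1)$entry_id, idx$seqs$entry_id[i])
  }
})

test_that("unpaired heavy-only queries rank by the heavy identity alone", {
  recs <- make_test_records(6, seed = 4)
  idx <- build_index(recs)
  q <- search_query("h_only", heavy_seq = idx$seqs$h_v[3], region = "V")
  hits <- seq_search(q, idx)
  expect_true(all(is.na(hits$identity_l)))
  expect_equal(hits$combined_identity, hits$identity_h)
  expect_equal(hits$entry_id[1], idx$seqs$entry_id[3])
})

test_that("mildly mutated queries still retrieve their source entry first", {
  recs <- make_test_records(20, seed = 47)
  idx <- build_index(recs)
  set.seed(47)
  for (rep in 1:10) {
    qh <- mutate_chars(idx$seqs$h_v[7], 0.05)
    ql <- mutate_chars(idx$seqs$l_v[7], 0.05)
    hits <- seq_search(search_query("q", heavy_seq = qh, light_seq = ql), idx)
    expect_equal(hits$entry_id[1], idx$seqs$entry_id[7])
  }
})

test_that("repertoire dialects pair chains by cell and agree with each other", {
  spec <- fixture_spec(73)
  sources <- tibble::tibble(entry_id = c("E1", "E2"),
                            h_v = c(random_aa_seq(90), random_aa_seq(90)),
                            l_v = c(random_aa_seq(88), random_aa_seq(88)))
  airr <- make_repertoire_fixture(spec, sources, dialect = "airr_tsv",
                                  n_cells = 10, n_unpaired = 2)
  # unpaired cells warn by design; the pairing outcome is what matters here
  q_airr <- suppressWarnings(parse_repertoire(airr$path, dialect = "airr_tsv"))
  expect_equal(sum(q_airr$paired), 8L)
  expect_equal(sum(!q_airr$paired), 2L)
  expect_equal(sort(q_airr$query_id), sort(airr$truth$cell_id))
  expect_equal(q_airr$paired[order(q_airr$query_id)],
               airr$truth$paired[order(airr$truth$cell_id)])

  csvf <- make_repertoire_fixture(spec, sources, dialect = "csv",
                                  n_cells = 10, n_unpaired = 2)
  q_csv <- suppressWarnings(parse_repertoire(csvf$path, dialect = "csv"))
  expect_equal(q_airr, q_csv)

  tenx <- make_repertoire_fixture(spec, sources, dialect = "tenx_contig_csv",
                                  n_cells = 3, n_unpaired = 1)
  q_10x <- suppressWarnings(parse_repertoire(tenx$path, dialect = "tenx_contig_csv"))
  expect_equal(sum(q_10x$paired), 2L)
  expect_equal(sum(!q_10x$paired), 1L)
})

test_that("an AIRR table with two rows sharing a cell pairs into one query", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sequence_id = c("s1", "s2"), cell_id = c("cellA", "cellA"),
    locus = c("IGH", "IGK"),
    sequence_aa = c("QVQLVQSGAEVKK", "DIQMTQSPSSLSA")), f)
  q <- parse_repertoire(f, dialect = "airr_tsv")
  expect_equal(nrow(q), 1L)
  expect_true(q$paired)
  expect_equal(q$heavy_seq, "QVQLVQSGAEVKK")
  expect_equal(q$light_seq, "DIQMTQSPSSLSA")
})

test_that("missing required columns are reported by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sequence_id = "s1", cell_id = "c1",
                                  locus = "IGH", sequence = "caagtt"), f)
  expect_error(parse_repertoire(f, dialect = "airr_tsv"), "sequence_aa")
})

test_that("the batch limit rejects 201 records but is overridable", {
  f <- withr::local_tempfile(fileext = ".fasta")
  hdr <- sprintf(">q%03d", 1:201)
  writeLines(as.vector(rbind(hdr, rep("QVQLVQSGAEVKK", 201))), f)
  expect_error(parse_repertoire(f, dialect = "fasta"), "maximum of 200")
  q <- parse_repertoire(f, dialect = "fasta", no_limit = TRUE)
  expect_equal(nrow(q), 201L)
  # exactly 200 is fine
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(hdr[1:200], rep("QVQLVQSGAEVKK", 200))), f2)
  expect_equal(nrow(parse_repertoire(f2, dialect = "fasta")), 200L)
})

test_that("interface similarity is a Jaccard index on the shared support", {
  set.seed(53)
  a <- random_contact_matrix()
  expect_equal(interface_similarity(a, a), 1)

  b <- a
  b$contacts <- !a$contacts
  b$distances <- ifelse(b$contacts, 4, 15)
  expect_equal(interface_similarity(a, b), 0)

  for (k in 1:10) {
    m1 <- random_contact_matrix(); m2 <- random_contact_matrix()
    s <- interface_similarity(m1, m2)
    inter <- sum(m1$contacts & m2$contacts)
    uni <- sum(m1$contacts | m2$contacts)
    expect_equal(s, if (uni == 0) 1 else inter / uni)
    expect_equal(s, interface_similarity(m2, m1))  # symmetric
  }
})

test_that("similarity decreases in expectation as contacts are flipped", {
  set.seed(59)
  base <- random_contact_matrix()
  mean_sim <- sapply(c(0.05, 0.15, 0.3), function(fr) {
    mean(replicate(20, interface_similarity(base, flip_contacts(base, fr))))
  })
  expect_true(all(diff(mean_sim) < 0))
})

test_that("interface search retrieves the source entry under perturbation", {
  set.seed(59)
  cms <- lapply(1:20, function(i) random_contact_matrix())
  recs <- make_test_records(20, seed = 59)
  for (i in 1:20) recs[[i]]$ch1_cl_contacts <- cms[[i]]
  idx <- build_index(recs)

  self <- interface_search(cms[[5]], idx)
  expect_equal(self$entry_id[1], "DB005")
  expect_equal(self$similarity[1], 1)

  for (k in 1:5) {
    q <- flip_contacts(cms[[5]], 0.10)
    hits <- interface_search(q, idx)
    expect_equal(hits$entry_id[1], "DB005")
  }

  empty <- build_index(list())
  expect_equal(nrow(interface_search(cms[[1]], empty)), 0L)
})
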