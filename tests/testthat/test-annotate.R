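hits_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(domain_label = r[[1]], species = r[[2]],
                   percent_identity = as.numeric(r[[3]]),
                   gene_class = if (r[[1]] == "V") "V" else "C",
                   allele_id = if (length(r) >= 4) r[[4]] else paste0(r[[2]], "-", r[[1]]),
                   alignment_score = as.numeric(r[[3]]) * 5)
  }))
}

test_that("species override follows the strict 8-point margin rule", {
  # foreign best beats same-species best by 15 > 8: override
  h <- hits_tbl(list("V", "Homo sapiens", 95), list("V", "Mus musculus", 80))
  res <- consolidate_species(h, "Mus musculus")
  expect_equal(res$per_domain$species, "Homo sapiens")
  expect_true(res$per_domain$overridden)

  # same species best hit: keep
  h2 <- hits_tbl(list("V", "Homo sapiens", 99))
  res2 <- consolidate_species(h2, "Homo sapiens")
  expect_equal(res2$consolidated_species, "Homo sapiens")
  expect_false(res2$per_domain$overridden)

  # margin 6 <= 8: keep the provided species
  h3 <- hits_tbl(list("V", "Homo sapiens", 86), list("V", "Mus musculus", 80))
  res3 <- consolidate_species(h3, "Mus musculus")
  expect_equal(res3$consolidated_species, "Mus musculus")

  # margin exactly 8: strict inequality, keep
  h4 <- hits_tbl(list("V", "Homo sapiens", 88), list("V", "Mus musculus", 80))
  expect_equal(consolidate_species(h4, "Mus musculus")$consolidated_species,
               "Mus musculus")

  # provided species absent from the references: best hit wins outright
  h5 <- hits_tbl(list("V", "Homo sapiens", 70))
  expect_equal(consolidate_species(h5, "Gallus gallus")$consolidated_species,
               "Homo sapiens")

  expect_error(consolidate_species(hits_tbl(), "Homo sapiens"), "at least one")
})

test_that("override decisions are monotone in the foreign identity", {
  prov_id <- 80
  flipped_at <- NA
  for (foreign in seq(80, 99, by = 1)) {
    h <- hits_tbl(list("V", "Homo sapiens", foreign), list("V", "Mus musculus", prov_id))
    over <- consolidate_species(h, "Mus musculus")$per_domain$overridden
    if (over && is.na(flipped_at)) flipped_at <- foreign
    if (!is.na(flipped_at)) expect_true(over)  # never flips back
  }
  expect_equal(flipped_at, 89)  # first value with margin > 8
})

test_that("an infinite margin always keeps the provided species", {
  h <- hits_tbl(list("V", "Homo sapiens", 100), list("V", "Mus musculus", 40))
  expect_equal(consolidate_species(h, "Mus musculus", override_margin = Inf)$consolidated_species,
               "Mus musculus")
})

test_that("engineered-format flags cover none, chimeric, humanized, unresolved", {
  expect_equal(flag_engineered(c(V = "Homo sapiens", CH1 = "Homo sapiens"))$flag, "none")
  expect_equal(flag_engineered(c(V = "Mus musculus", CH1 = "Homo sapiens"))$flag, "chimeric")
  hum <- flag_engineered(
    c(V = "Homo sapiens", CH1 = "Homo sapiens"),
    v_top2 = tibble::tibble(species = c("Homo sapiens", "Mus musculus"),
                            percent_identity = c(91, 89.5)))
  expect_equal(hum$flag, "humanized")
  expect_match(hum$note, "heuristic")
  expect_equal(flag_engineered(character(0))$flag, "unresolved")
})

test_that("isotype assignment takes the top-identity C hit with score tie-break", {
  h <- hits_tbl(list("CH1", "Homo sapiens", 99.1, "IGHG1*01"),
                list("CH1", "Homo sapiens", 71.2, "IGHA1*01"))
  res <- assign_isotype(h)
  expect_equal(res$isotype_or_lctype, "IgG1")
  expect_equal(res$c_allele, "IGHG1*01")
  expect_equal(res$gene, "IGHG1")

  k <- hits_tbl(list("CL", "Homo sapiens", 100, "IGKC*01"))
  expect_equal(assign_isotype(k)$isotype_or_lctype, "kappa")

  tie <- tibble::tibble(domain_label = "CH1", gene_class = "C",
                        allele_id = c("IGHG1*01", "IGHG2*01"),
                        percent_identity = c(95, 95),
                        alignment_score = c(480, 470),
                        species = "Homo sapiens")
  expect_equal(assign_isotype(tie)$isotype_or_lctype, "IgG1")

  v_only <- hits_tbl(list("V", "Homo sapiens", 99))
  expect_error(assign_isotype(v_only), "V-only")
})

test_that("coverage classification follows the CH2/CH3/CH4 rule and is monotone", {
  expect_equal(classify_coverage(c("V", "CH1", "CL")), "Fab")
  expect_equal(classify_coverage(c("V", "CH1", "CH2", "CH3", "CL")), "full")
  expect_equal(classify_coverage("V"), "other")
  expect_equal(classify_coverage(c("V", "CH4")), "full")

  rank <- c(other = 1, Fab = 2, full = 3)
  domains <- c("V", "CL", "CH1", "CH2", "CH3", "CH4")
  prev <- rank[classify_coverage(character(0))]
  for (k in seq_along(domains)) {
    cur <- rank[classify_coverage(domains[1:k])]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("structural coverage fractions come from the ATOM sequence", {
  refs <- make_reference_fixture(fixture_spec(7))$refs
  vh <- refs$ungapped_seq[refs$allele_id == "IGHV1*01"]
  ch1 <- refs$ungapped_seq[refs$allele_id == "IGHG1*01_CH1"]
  seqres <- paste0(vh, ch1)

  cov_full <- structural_coverage(seqres, seqres, refs)
  expect_equal(cov_full$fraction_resolved, c(1, 1))

  # 12-residue unresolved stretch inside CH1
  mask <- rep(TRUE, nchar(seqres))
  del_start <- nchar(vh) + 30L
  mask[del_start:(del_start + 11L)] <- FALSE
  atom_seq <- paste(strsplit(seqres, "")[[1]][mask], collapse = "")
  cov <- structural_coverage(seqres, atom_seq, refs)
  ch1_row <- cov[cov$domain_label == "CH1", ]
  expect_lt(ch1_row$fraction_resolved, 1)
  # ground truth by brute-force count over the deletion mask
  expect_equal(ch1_row$resolved_residues, sum(mask[(nchar(vh) + 1L):nchar(seqres)]))
  expect_equal(ch1_row$fraction_resolved,
               sum(mask[(nchar(vh) + 1L):nchar(seqres)]) / nchar(ch1))

  expect_error(structural_coverage(seqres, paste0(seqres, "W"), refs),
               "inconsisten")
})
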