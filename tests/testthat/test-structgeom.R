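labeled_pts <- function(m, labels = as.character(seq_len(nrow(m)))) {
  tibble::tibble(imgt_label = labels, x = m[, 1], y = m[, 2], z = m[, 3])
}

random_cloud <- function(n, sd = 8) matrix(rnorm(3 * n, sd = sd), ncol = 3)

test_that("structure reading recovers deposited and resolved sequences", {
  spec <- fixture_spec(7, unresolved_spans = list(list(chain = "H", start = 30L, end = 34L)))
  rf <- make_reference_fixture(spec)
  fx <- make_structure_fixture(spec, rf$refs, entry_id = "FXRD01")
  st <- read_structure(fx$path)
  expect_length(st$chains, 2L)
  h <- st$chains$H
  expect_equal(nchar(h$seqres_seq) - nchar(h$atom_seq), 5L)
  expect_equal(nchar(st$chains$L$seqres_seq), nchar(st$chains$L$atom_seq))
  # resolved sequence is the seqres letters at the resolved indices
  expect_equal(h$atom_seq,
               paste(strsplit(h$seqres_seq, "")[[1]][h$atom_map], collapse = ""))
})

test_that("the same structure written as mmCIF and PDB parses identically", {
  spec <- fixture_spec(19)
  rf <- make_reference_fixture(spec)
  f1 <- make_structure_fixture(spec, rf$refs, entry_id = "FXFMT1", format = "mmcif")
  f2 <- make_structure_fixture(spec, rf$refs, entry_id = "FXFMT1", format = "pdb")
  s1 <- read_structure(f1$path); s2 <- read_structure(f2$path)
  for (ch in c("H", "L")) {
    expect_equal(s1$chains[[ch]]$seqres_seq, s2$chains[[ch]]$seqres_seq)
    expect_equal(s1$chains[[ch]]$atom_seq, s2$chains[[ch]]$atom_seq)
    a1 <- as.matrix(s1$chains[[ch]]$atoms[, c("x", "y", "z")])
    a2 <- as.matrix(s2$chains[[ch]]$atoms[, c("x", "y", "z")])
    expect_equal(a1, a2, tolerance = 1e-3)
  }
})

test_that("coordinate/polymer mismatches raise an inconsistency error", {
  spec <- fixture_spec(7)
  rf <- make_reference_fixture(spec)
  fx <- make_structure_fixture(spec, rf$refs, entry_id = "FXBAD1")
  lines <- readLines(fx$path)
  i <- grep("^ATOM 5 ", lines)[1]
  lines[i] <- sub(" ALA | CYS | ASP | GLU | PHE | GLY | HIS | ILE | LYS | LEU | MET | ASN | PRO | GLN | ARG | SER | THR | VAL | TRP | TYR ",
                  " TRP ", lines[i])
  # ensure we actually changed a residue that disagrees with the polymer seq
  bad <- tempfile(fileext = ".cif")
  writeLines(lines, bad)
  res <- tryCatch(read_structure(bad), error = function(e) e)
  ok <- inherits(res, "error")
  if (ok) expect_match(conditionMessage(res), "inconsistency")
  # if the residue happened to be TRP already the parse succeeds; mutate harder
  if (!ok) {
    lines[i] <- sub(" TRP ", " GLY ", lines[i])
    writeLines(lines, bad)
    expect_error(read_structure(bad), "inconsistency")
  }
})

test_that("contact matrices match a brute-force double loop", {
  a <- labeled_pts(matrix(c(0, 0, 0), 1), "1")
  b <- labeled_pts(matrix(c(3, 4, 0), 1), "1")
  cm <- contact_matrix(a, b)
  expect_equal(unname(cm$distances[1, 1]), 5)
  expect_true(cm$contacts[1, 1])

  d1 <- labeled_pts(random_cloud(10))
  self <- contact_matrix(d1, d1)
  expect_equal(unname(diag(self$distances)), rep(0, 10))
  expect_equal(self$distances, t(self$distances), tolerance = 1e-12)

  set.seed(23)
  for (k in 1:3) {
    pa <- labeled_pts(random_cloud(30))
    pb <- labeled_pts(random_cloud(30))
    cm <- contact_matrix(pa, pb, cutoff = 8)
    brute <- matrix(NA_real_, 30, 30)
    for (i in 1:30) for (j in 1:30) {
      brute[i, j] <- sqrt(sum((as.numeric(pa[i, c("x", "y", "z")]) -
                               as.numeric(pb[j, c("x", "y", "z")]))^2))
    }
    expect_equal(unname(cm$distances), brute, tolerance = 1e-9)
    expect_identical(unname(cm$contacts), brute <= 8)
  }
})

test_that("contact cutoffs behave at the extremes", {
  pa <- labeled_pts(random_cloud(8)); pb <- labeled_pts(random_cloud(8))
  expect_true(all(contact_matrix(pa, pb, cutoff = Inf)$contacts))
  expect_false(any(contact_matrix(pa, pb, cutoff = 0)$contacts))
})

test_that("pseudo-dyad axes recover constructed rotations exactly", {
  set.seed(29)
  p1 <- labeled_pts(random_cloud(40))
  Rz <- rotation_matrix(c(0, 0, 1), 180)
  p2 <- labeled_pts(as.matrix(p1[, c("x", "y", "z")]) %*% t(Rz))
  d <- pseudo_dyad_axis(p1, p2)
  expect_equal(d$angle_deg, 180, tolerance = 1e-6)
  expect_equal(abs(d$axis[3]), 1, tolerance = 1e-6)

  # translation only: degenerate identity rotation
  p3 <- p1; p3$x <- p3$x + 25
  d3 <- pseudo_dyad_axis(p1, p3)
  expect_true(d3$degenerate)
  expect_equal(d3$angle_deg, 0)

  ax <- c(1, -2, 0.5); ax <- ax / sqrt(sum(ax^2))
  R <- rotation_matrix(ax, 147)
  p4 <- labeled_pts(as.matrix(p1[, c("x", "y", "z")]) %*% t(R))
  d4 <- pseudo_dyad_axis(p1, p4)
  expect_equal(d4$angle_deg, 147, tolerance = 1e-6)
  expect_equal(abs(sum(d4$axis * ax)), 1, tolerance = 1e-6)
})

test_that("degenerate inputs are refused with informative errors", {
  line <- labeled_pts(cbind(1:10, 2 * (1:10), -1 * (1:10)))
  expect_error(pseudo_dyad_axis(line, line), "collinear")
  few <- labeled_pts(random_cloud(2))
  expect_error(pseudo_dyad_axis(few, few), ">= 3")
})

test_that("elbow and CH1-CL angles recover planted geometry", {
  set.seed(31)
  vh <- labeled_pts(random_cloud(50))
  ch1 <- labeled_pts(random_cloud(45) + 40)
  a_v <- c(0, 0, 1)
  a_c <- c(1, 0, 0)   # exactly 90 degrees apart
  vl <- labeled_pts(as.matrix(vh[, c("x", "y", "z")]) %*% t(rotation_matrix(a_v, 180)) + 12)
  cl <- labeled_pts(as.matrix(ch1[, c("x", "y", "z")]) %*% t(rotation_matrix(a_c, 180)) + 12)
  expect_equal(elbow_angle(vh, vl, ch1, cl), 90, tolerance = 1e-6)
  expect_equal(elbow_angle(vh, vl, ch1, cl, convention = "obtuse"), 90, tolerance = 1e-6)

  # parallel dyads: 0 under the acute-line convention
  cl_par <- labeled_pts(as.matrix(ch1[, c("x", "y", "z")]) %*% t(rotation_matrix(a_v, 180)) + 12)
  expect_equal(elbow_angle(vh, vl, ch1, cl_par), 0, tolerance = 1e-6)

  cl170 <- labeled_pts(as.matrix(ch1[, c("x", "y", "z")]) %*% t(rotation_matrix(a_c, 170)))
  expect_equal(ch1_cl_angle(ch1, cl170)$angle_deg, 170, tolerance = 1e-6)
  ident <- ch1_cl_angle(ch1, ch1)
  expect_true(ident$degenerate)
  expect_equal(ident$angle_deg, 0)
})

test_that("packing angles are invariant under global rigid motions", {
  set.seed(37)
  vh <- labeled_pts(random_cloud(40))
  ch1 <- labeled_pts(random_cloud(40) + 40)
  vl <- labeled_pts(as.matrix(vh[, c("x", "y", "z")]) %*% t(rotation_matrix(c(0, 0, 1), 180)) + 10)
  cl <- labeled_pts(as.matrix(ch1[, c("x", "y", "z")]) %*% t(rotation_matrix(c(1, 1, 0), 172)) + 10)
  e0 <- elbow_angle(vh, vl, ch1, cl)
  c0 <- ch1_cl_angle(ch1, cl)$angle_deg
  for (k in 1:20) {
    ax <- rnorm(3); ang <- runif(1, 0, 360); t0 <- rnorm(3, sd = 30)
    Rg <- rotation_matrix(ax, ang)
    tf <- function(p) {
      m <- as.matrix(p[, c("x", "y", "z")]) %*% t(Rg)
      labeled_pts(sweep(m, 2, t0, "+"), p$imgt_label)
    }
    expect_equal(elbow_angle(tf(vh), tf(vl), tf(ch1), tf(cl)), e0, tolerance = 1e-6)
    expect_equal(ch1_cl_angle(tf(ch1), tf(cl))$angle_deg, c0, tolerance = 1e-6)
  }
})

test_that("solvent accessibility matches analytic and refinement oracles", {
  one <- tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                        chain_id = "A", seqres_index = 1L, amino_acid = "G")
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(sasa(one)$total, analytic, tolerance = 0.01)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, seqres_index = 2L))
  expect_equal(sasa(two)$total, analytic, tolerance = 0.01)

  set.seed(41)
  cluster <- tibble::tibble(element = sample(c("C", "N", "O", "S"), 10, replace = TRUE),
                            x = rnorm(10, sd = 2), y = rnorm(10, sd = 2),
                            z = rnorm(10, sd = 2),
                            chain_id = "A", seqres_index = 1:10, amino_acid = "G")
  coarse <- sasa(cluster, n_points = 960)$total
  fine <- sasa(cluster, n_points = 10000)$total
  expect_equal(coarse, fine, tolerance = 0.02)
})

test_that("unknown elements fall back to the default radius with a warning", {
  odd <- tibble::tibble(element = "Q", x = 0, y = 0, z = 0,
                        chain_id = "A", seqres_index = 1L, amino_acid = "G")
  expect_warning(res <- sasa(odd), "unknown element")
  expect_equal(res$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
})

# two short parallel chains with C-alpha and a dummy side-chain atom each;
# close enough to bury surface in the middle
helix_pair <- function(gap = 6) {
  mk <- function(chain_id, y0) {
    n <- 10L
    atoms <- dplyr::bind_rows(
      tibble::tibble(seqres_index = 1:n, amino_acid = "A", comp = "ALA",
                     atom_name = "CA", element = "C",
                     x = (1:n) * 3.8, y = y0, z = 0, occupancy = 1),
      tibble::tibble(seqres_index = 1:n, amino_acid = "A", comp = "ALA",
                     atom_name = "CB", element = "C",
                     x = (1:n) * 3.8, y = y0 + ifelse(y0 == 0, 1.5, -1.5), z = 0,
                     occupancy = 1))
    list(chain_id = chain_id, atoms = atoms,
         seqres_seq = strrep("A", n), atom_seq = strrep("A", n),
         atom_map = 1:n)
  }
  list(h = mk("H", 0), l = mk("L", gap))
}

test_that("H-L interfaces vanish for separated chains and match a distance proxy", {
  hp <- helix_pair(gap = 100)
  far <- hl_interface(hp$h, hp$l)
  expect_equal(nrow(far$interface_residues), 0L)
  expect_equal(far$buried_area, 0, tolerance = 1e-6)

  hp2 <- helix_pair(gap = 6)
  near <- hl_interface(hp2$h, hp2$l)
  expect_gt(nrow(near$interface_residues), 0L)
  # distance oracle: residues with any heavy atom within 5 A of the partner
  at_h <- hp2$h$atoms; at_l <- hp2$l$atoms
  prox <- function(a, b) {
    sapply(split(a, a$seqres_index), function(res) {
      min(as.matrix(stats::dist(rbind(as.matrix(res[, c("x", "y", "z")]),
                                      as.matrix(b[, c("x", "y", "z")]))))[
        seq_len(nrow(res)), -seq_len(nrow(res))]) <= 5
    })
  }
  oracle <- c(which(prox(at_h, at_l)), which(prox(at_l, at_h)))
  got_h <- near$interface_residues$seqres_index[near$interface_residues$chain_id == "H"]
  exp_h <- as.integer(names(which(prox(at_h, at_l))))
  expect_setequal(got_h, exp_h)
})

test_that("buried area decreases monotonically as chains separate", {
  areas <- sapply(c(4, 5, 6, 7, 8), function(g) {
    hp <- helix_pair(gap = g)
    hl_interface(hp$h, hp$l, n_points = 480)$buried_area
  })
  expect_true(all(diff(areas) < 0))
})

test_that("disulfide bonds are found from planted S-S distances", {
  mk_struct <- function(sg_dist) {
    atoms <- tibble::tibble(
      seqres_index = c(1L, 2L), amino_acid = "C", comp = "CYS",
      atom_name = "SG", element = "S",
      x = c(0, sg_dist), y = 0, z = 0, occupancy = 1)
    structure(list(entry_id = "SS", source = "",
                   chains = list(A = list(chain_id = "A", atoms = atoms,
                                          seqres_seq = "CC", atom_seq = "CC",
                                          atom_map = 1:2))),
              class = "ab_structure")
  }
  expect_equal(nrow(disulfide_bonds(mk_struct(2.05))), 1L)
  expect_equal(nrow(disulfide_bonds(mk_struct(3.5))), 0L)

  spec <- fixture_spec(7)
  rf <- make_reference_fixture(spec)
  fx <- make_structure_fixture(spec, rf$refs, entry_id = "FXSS01")
  ss <- disulfide_bonds(read_structure(fx$path))
  expect_equal(nrow(ss), fx$truth$disulfides$total)
  expect_equal(sum(ss$type == "intra"), fx$truth$disulfides$intra)
  expect_equal(sum(ss$type == "inter"), fx$truth$disulfides$inter)
})

test_that("contacts, interfaces and disulfides are invariant under rigid motion", {
  spec <- fixture_spec(7)
  rf <- make_reference_fixture(spec)
  fx <- make_structure_fixture(spec, rf$refs, entry_id = "FXRM01")
  st <- read_structure(fx$path)
  Rg <- rotation_matrix(c(2, -1, 1), 73); t0 <- c(11, -4, 20)
  st2 <- st
  for (ch in names(st2$chains)) {
    m <- as.matrix(st2$chains[[ch]]$atoms[, c("x", "y", "z")]) %*% t(Rg)
    m <- sweep(m, 2, t0, "+")
    st2$chains[[ch]]$atoms$x <- m[, 1]
    st2$chains[[ch]]$atoms$y <- m[, 2]
    st2$chains[[ch]]$atoms$z <- m[, 3]
  }
  ss1 <- disulfide_bonds(st); ss2 <- disulfide_bonds(st2)
  expect_equal(ss1[, c("chain_a", "res_a", "chain_b", "res_b", "type")],
               ss2[, c("chain_a", "res_a", "chain_b", "res_b", "type")])
  ca1 <- calpha_coords(st$chains$H); ca2 <- calpha_coords(st2$chains$H)
  d1 <- contact_matrix(tibble::tibble(imgt_label = as.character(ca1$seqres_index),
                                      x = ca1$x, y = ca1$y, z = ca1$z),
                       tibble::tibble(imgt_label = as.character(ca1$seqres_index),
                                      x = ca1$x, y = ca1$y, z = ca1$z))
  d2 <- contact_matrix(tibble::tibble(imgt_label = as.character(ca2$seqres_index),
                                      x = ca2$x, y = ca2$y, z = ca2$z),
                       tibble::tibble(imgt_label = as.character(ca2$seqres_index),
                                      x = ca2$x, y = ca2$y, z = ca2$z))
  expect_equal(d1$distances, d2$distances, tolerance = 1e-6)
})
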