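## Van der Waals radii (Angstroms) used for solvent accessibility.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

## Deterministic, evenly distributed unit sphere points (Fibonacci
## lattice); the same n always yields the same points, so SASA values are
## reproducible across runs and platforms.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a deterministic Fibonacci point lattice.
#' Each atom's accessible area is the fraction of sample points on its
#' solvent-expanded sphere (radius `vdW + probe`) not buried inside any
#' neighbouring atom's expanded sphere, times the sphere area.
#'
#' @param atoms Tibble with columns `element`, `x`, `y`, `z`, and
#'   (for per-residue aggregation) `chain_id`, `seqres_index`,
#'   `amino_acid`.  Unknown elements get the default carbon radius with a
#'   warning.
#' @param probe Probe radius in Angstroms (water, default 1.4).
#' @param n_points Sample points per atom (default 960).
#' @return List: `atom` (input plus `area`), `residue` (tibble
#'   `chain_id`, `seqres_index`, `amino_acid`, `area`), `total`.
#' @examples
#' a <- tibble::tibble(element = "C", x = 0, y = 0, z = 0,
#'                     chain_id = "A", seqres_index = 1, amino_acid = "G")
#' sasa(a)$total  # ~ 4 * pi * (1.70 + 1.4)^2
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L) {
    abort("`atoms` must be a non-empty atom table")
  }
  el <- toupper(substr(trimws(atoms$element), 1L, 1L))
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0L) {
    warn(sprintf("unknown element(s) %s: using default radius %.2f A",
                 paste(unknown, collapse = ", "), VDW_DEFAULT))
  }
  radii <- unname(VDW_RADII[el])
  radii[is.na(radii)] <- VDW_DEFAULT

  X <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(X))) abort("atom coordinates must be finite")
  n <- nrow(X)
  U <- fibonacci_sphere(n_points)
  exp_r <- radii + probe

  ## neighbour lists from the pairwise distance matrix
  D <- as.matrix(dist(X))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < exp_r[i] + exp_r & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * exp_r[i]^2
      next
    }
    P <- sweep(U * exp_r[i], 2, X[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (P[, 1] - X[j, 1])^2 + (P[, 2] - X[j, 2])^2 + (P[, 3] - X[j, 3])^2
      r2 <- exp_r[j]^2
      tol <- 1e-7 * r2
      ## strict burial, with a deterministic tie-break so exactly
      ## coincident spheres assign their shared surface to the
      ## lower-indexed atom instead of double-counting (or zeroing) it
      buried <- buried | dj2 < r2 - tol | (dj2 < r2 + tol & j < i)
      if (all(buried)) break
    }
    area[i] <- 4 * pi * exp_r[i]^2 * mean(!buried)
  }

  atom_out <- mutate(as_tibble(atoms), area = area)
  residue <- NULL
  if (all(c("chain_id", "seqres_index") %in% names(atoms))) {
    residue <- atom_out |>
      group_by(.data$chain_id, .data$seqres_index) |>
      summarise(amino_acid = if ("amino_acid" %in% names(atom_out))
                  .data$amino_acid[1] else NA_character_,
                area = sum(.data$area), .groups = "drop")
  }
  list(atom = atom_out, residue = residue, total = sum(area))
}

chain_atom_table <- function(chain) {
  chain$atoms |>
    mutate(chain_id = chain$chain_id) |>
    select("chain_id", "seqres_index", "amino_acid", "atom_name",
           "element", "x", "y", "z")
}

#' Heavy-light chain interface from solvent accessibility
#'
#' Per-residue buried area on complex formation: `delta_sasa` is the
#' residue's SASA in the isolated chain minus its SASA in the two-chain
#' complex.  Residues with `delta_sasa > delta_threshold` are interface
#' residues; the buried area is the summed `delta_sasa` over both chains,
#' divided by two.
#'
#' @param h_chain,l_chain Chain records from [read_structure()].
#' @param delta_threshold Interface membership threshold in square
#'   Angstroms (default 1.0).
#' @param probe,n_points Passed to [sasa()].
#' @return An `hl_interface`: list with `per_residue` tibble (`chain_id`,
#'   `seqres_index`, `amino_acid`, `sasa_isolated`, `sasa_complex`,
#'   `delta_sasa`, `interface`), `interface_residues` (subset tibble),
#'   `buried_area`, `delta_threshold`.
#' @export
hl_interface <- function(h_chain, l_chain, delta_threshold = 1.0,
                         probe = 1.4, n_points = 960) {
  ah <- chain_atom_table(h_chain); al <- chain_atom_table(l_chain)
  if (nrow(ah) == 0L || nrow(al) == 0L) abort("insufficient atoms in one of the chains")
  iso_h <- sasa(ah, probe, n_points)$residue
  iso_l <- sasa(al, probe, n_points)$residue
  cx <- sasa(bind_rows(ah, al), probe, n_points)$residue
  iso <- bind_rows(iso_h, iso_l) |> rename(sasa_isolated = "area")
  per <- iso |>
    left_join(rename(cx, sasa_complex = "area"),
              by = c("chain_id", "seqres_index", "amino_acid")) |>
    mutate(delta_sasa = .data$sasa_isolated - .data$sasa_complex,
           interface = .data$delta_sasa > delta_threshold)
  structure(list(
    per_residue = per,
    interface_residues = filter(per, .data$interface),
    buried_area = sum(per$delta_sasa) / 2,
    delta_threshold = delta_threshold
  ), class = "hl_interface")
}

#' @export
print.hl_interface <- function(x, ...) {
  cat(sprintf("<hl_interface> %d interface residue(s), buried area %.1f A^2\n",
              nrow(x$interface_residues), x$buried_area))
  invisible(x)
}

#' @describeIn hl_interface Per-residue tibble of the interface annotation.
#' @param x An `hl_interface`.
#' @param ... Unused.
#' @export
tidy.hl_interface <- function(x, ...) x$per_residue

#' Disulfide bonds from sulfur-sulfur distances
#'
#' Cysteine pairs whose gamma-sulfur atoms lie within `cutoff` Angstroms.
#' Intra- and inter-chain bonds are both reported, with a type tag.
#'
#' @param structure An `ab_structure`.
#' @param cutoff S-S distance cutoff in Angstroms (default 2.5).
#' @return Tibble: `chain_a`, `res_a`, `chain_b`, `res_b`, `distance`,
#'   `type` (`"intra"`/`"inter"`).  Zero rows when none found.
#' @export
disulfide_bonds <- function(structure, cutoff = 2.5) {
  sg <- list()
  for (ch in structure$chains) {
    s <- ch$atoms |>
      filter(.data$comp == "CYS", .data$atom_name == "SG") |>
      mutate(chain_id = ch$chain_id)
    if (nrow(s) > 0L) sg[[length(sg) + 1L]] <- s
  }
  empty <- tibble(chain_a = character(), res_a = integer(),
                  chain_b = character(), res_b = integer(),
                  distance = double(), type = character())
  if (length(sg) == 0L) return(empty)
  sg <- bind_rows(sg)
  if (nrow(sg) < 2L) return(empty)
  D <- as.matrix(dist(as.matrix(sg[, c("x", "y", "z")])))
  idx <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  tibble(
    chain_a = sg$chain_id[idx[, 1]], res_a = sg$seqres_index[idx[, 1]],
    chain_b = sg$chain_id[idx[, 2]], res_b = sg$seqres_index[idx[, 2]],
    distance = D[idx],
    type = ifelse(sg$chain_id[idx[, 1]] == sg$chain_id[idx[, 2]],
                  "intra", "inter")
  ) |> arrange(.data$chain_a, .data$res_a)
}
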