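#' Mutational-scan score matrices
#'
#' A `score_matrix` holds per-position scores for all 20 amino-acid
#' substitutions produced by an external scorer (e.g. a Rosetta point
#' mutant scan, a language-model pseudo-log-likelihood, or a missense
#' predictor).  `parse_scores()` reads the long-form CSV interchange
#' format (columns `position_label`, `wt_aa`, `mut_aa`, `score`);
#' `write_scores()` writes it back.
#'
#' @param path CSV file path.
#' @param scorer_tag Free-text tag recording which scorer produced the
#'   table (e.g. `"rosetta_pmut"`, `"antiberty_pll"`).  Tags beginning
#'   with `"rosetta"` mark scores that must not be summed across
#'   positions.
#' @param scaled Whether the table already contains WT-relative scores.
#' @return A `score_matrix`: list with `positions` (tibble
#'   `position_label`, `wt_aa`), `scores` (positions x 20 matrix, `NA`
#'   for missing values), `scorer_tag`, `scaled`.
#' @export
parse_scores <- function(path, scorer_tag, scaled = FALSE) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("position_label", "wt_aa", "mut_aa", "score")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0L) {
    abort(sprintf("score CSV is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(tbl$score)) abort("`score` column must be numeric")
  dup <- duplicated(tbl[, c("position_label", "mut_aa")])
  if (any(dup)) {
    abort(sprintf("duplicate (position, mutant) row(s): %s",
                  paste(unique(paste0(tbl$position_label[dup], ":", tbl$mut_aa[dup])),
                        collapse = ", ")))
  }
  bad_aa <- setdiff(unique(c(tbl$wt_aa, tbl$mut_aa)), AA_1)
  if (length(bad_aa) > 0L) {
    abort(sprintf("unknown amino acid(s) in score CSV: %s", paste(bad_aa, collapse = ", ")))
  }
  new_score_matrix(tbl, scorer_tag = scorer_tag, scaled = scaled)
}

#' Construct a score matrix from a long table
#' @param tbl Tibble with `position_label`, `wt_aa`, `mut_aa`, `score`.
#' @rdname parse_scores
#' @export
new_score_matrix <- function(tbl, scorer_tag, scaled = FALSE) {
  tbl$position_label <- as.character(tbl$position_label)
  pos <- distinct(tbl, .data$position_label, .data$wt_aa)
  if (anyDuplicated(pos$position_label)) {
    abort("a position_label appears with more than one wt_aa")
  }
  scores <- matrix(NA_real_, nrow = nrow(pos), ncol = length(AA_1),
                   dimnames = list(pos$position_label, AA_1))
  scores[cbind(match(tbl$position_label, pos$position_label),
               match(tbl$mut_aa, AA_1))] <- tbl$score
  structure(list(positions = pos, scores = scores,
                 scorer_tag = scorer_tag, scaled = isTRUE(scaled)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s: %d positions x 20 amino acids (%s)\n",
              x$scorer_tag, nrow(x$positions),
              if (x$scaled) "WT-scaled" else "raw"))
  invisible(x)
}

#' @describeIn parse_scores Long-form tibble of a score matrix.
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    position_label = rep(x$positions$position_label, times = ncol(x$scores)),
    wt_aa = rep(x$positions$wt_aa, times = ncol(x$scores)),
    mut_aa = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  ) |>
    filter(!is.na(.data$score)) |>
    arrange(match(.data$position_label, x$positions$position_label), .data$mut_aa)
}

#' @rdname parse_scores
#' @param scores A `score_matrix` to write.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(tidy(scores), path)
  invisible(path)
}

#' Scale raw scores to wild-type-relative values
#'
#' Subtracts the wild-type residue's score from every substitution score
#' at the same position, so that scores read as relative changes versus
#' WT; WT cells become exactly 0.  Scaling an already-scaled matrix is an
#' error.
#'
#' @param raw An unscaled `score_matrix` with a WT score at every
#'   position.
#' @return The scaled `score_matrix`.
#' @export
scale_to_wt <- function(raw) {
  if (!inherits(raw, "score_matrix")) abort("`raw` must be a score_matrix")
  if (raw$scaled) abort("matrix is already WT-scaled; refusing to scale twice")
  wt_scores <- raw$scores[cbind(seq_len(nrow(raw$positions)),
                                match(raw$positions$wt_aa, colnames(raw$scores)))]
  if (anyNA(wt_scores)) {
    abort(sprintf("missing WT score at position(s): %s",
                  paste(raw$positions$position_label[is.na(wt_scores)], collapse = ", ")))
  }
  out <- raw
  out$scores <- sweep(raw$scores, 1, wt_scores)
  out$scores[cbind(seq_len(nrow(raw$positions)),
                   match(raw$positions$wt_aa, colnames(raw$scores)))] <- 0
  out$scaled <- TRUE
  out
}

#' Additive multi-mutant score
#'
#' Sums WT-scaled per-position scores over a set of single mutations,
#' under the assumption that the mutations act independently.  With
#' pseudo-log-likelihood scores a positive sum means the combination is
#' preferable to WT.  Rosetta-style point-scan scores are not additive
#' across positions, so matrices tagged `rosetta*` are refused unless
#' `force = TRUE`.
#'
#' @param scaled A WT-scaled `score_matrix`.
#' @param mutations Tibble or data frame with `position_label` and
#'   `mut_aa` (one row per mutation; positions must be distinct and
#'   non-WT).  An empty table scores 0 (the WT baseline).
#' @param force Allow summation of non-additive scorer output.
#' @return List: `score` (the sum), `per_mutation` tibble, `additivity`
#'   note (metadata echoing the independence assumption).
#' @export
multi_mutant_score <- function(scaled, mutations, force = FALSE) {
  if (!inherits(scaled, "score_matrix")) abort("`scaled` must be a score_matrix")
  if (!scaled$scaled) abort("scores must be WT-scaled before summation")
  if (startsWith(tolower(scaled$scorer_tag), "rosetta") && !force) {
    abort(paste("scorer", scaled$scorer_tag, "produces non-additive point-scan scores;",
                "refusing to sum across positions (use force = TRUE to override)"))
  }
  mutations <- as_tibble(mutations)
  if (nrow(mutations) == 0L) {
    return(list(score = 0,
                per_mutation = tibble(position_label = character(),
                                      mut_aa = character(), score = double()),
                additivity = "sum of independent per-position effects"))
  }
  if (anyDuplicated(mutations$position_label)) {
    abort("duplicate positions in the mutation list")
  }
  idx <- match(mutations$position_label, scaled$positions$position_label)
  if (anyNA(idx)) {
    abort(sprintf("unknown position label(s): %s",
                  paste(mutations$position_label[is.na(idx)], collapse = ", ")))
  }
  wt <- scaled$positions$wt_aa[idx]
  if (any(wt == mutations$mut_aa)) {
    abort("mutation list contains WT residues (no-op mutations)")
  }
  vals <- scaled$scores[cbind(idx, match(mutations$mut_aa, colnames(scaled$scores)))]
  if (anyNA(vals)) {
    abort(sprintf("missing score for mutation(s): %s",
                  paste(paste0(mutations$position_label[is.na(vals)], ":",
                               mutations$mut_aa[is.na(vals)]), collapse = ", ")))
  }
  list(score = sum(vals),
       per_mutation = mutate(mutations, score = vals),
       additivity = "sum of independent per-position effects")
}

#' Per-position isotype sensitivity of mutational-scan scores
#'
#' Compares, per shared V-region position, the mutational-scan scores of
#' the same V region in two isotype contexts against a same-isotype
#' control.  For each position with at least `min_subs` substitutions
#' scored in all three matrices:
#'
#' * `d_iso(m) = score_a(m) - score_b(m)` (isotype contrast),
#' * `d_ctrl(m) = score_control(m) - score_b(m)` (replicate contrast),
#' * `effect = sign(mean d_iso) * log2((mean|d_iso| + eps) / (mean|d_ctrl| + eps))`
#'   (default `method = "mad_ratio"`; `method = "mean_ratio"` uses
#'   `|mean d|` magnitudes with the sign of `mean d_iso - mean d_ctrl`),
#' * a two-sided Wilcoxon signed-rank test of `d_iso` versus `d_ctrl`
#'   paired over substitutions, with Benjamini-Hochberg adjustment across
#'   positions.
#'
#' With scores where lower is better (Rosetta-style), a negative effect
#' means mutations at the position tend to favour the first isotype.
#'
#' @param scores_iso_a,scores_iso_b `score_matrix` objects for the two
#'   isotype contexts (same V region and WT residues).
#' @param scores_control A second structure of isotype b (replicate
#'   control).
#' @param eps Ratio guard (default 1e-6).
#' @param method `"mad_ratio"` (mean absolute difference magnitudes,
#'   default) or `"mean_ratio"` (absolute mean differences).
#' @param min_subs Minimum substitutions per position (default 2;
#'   positions under it are skipped with a note).
#' @return A `sensitivity_result`: tibble with `position_label`, `wt_aa`,
#'   `n_substitutions`, `mean_d_iso`, `mean_d_ctrl`, `effect`, `p_value`,
#'   `q_value`; skipped positions in the `skipped` attribute.
#' @export
isotype_sensitivity <- function(scores_iso_a, scores_iso_b, scores_control,
                                eps = 1e-6,
                                method = c("mad_ratio", "mean_ratio"),
                                min_subs = 2) {
  method <- match.arg(method)
  mats <- list(a = scores_iso_a, b = scores_iso_b, ctrl = scores_control)
  for (m in mats) {
    if (!inherits(m, "score_matrix")) abort("all inputs must be score_matrix objects")
  }
  if (length(unique(map_lgl(mats, function(m) m$scaled))) != 1L) {
    abort("mixed scaled/unscaled inputs; scale all three the same way")
  }
  shared <- Reduce(intersect, map(mats, function(m) m$positions$position_label))
  if (length(shared) == 0L) abort("no shared position labels across the three matrices")
  wt <- map(mats, function(m) {
    m$positions$wt_aa[match(shared, m$positions$position_label)]
  })
  mism <- which(wt$a != wt$b | wt$a != wt$ctrl)
  if (length(mism) > 0L) {
    abort(sprintf("WT residues disagree at shared position(s): %s",
                  paste(shared[mism], collapse = ", ")))
  }

  rows <- list(); skipped <- character()
  for (p in shared) {
    wt_p <- wt$a[match(p, shared)]
    subs <- setdiff(AA_1, wt_p)
    sa <- mats$a$scores[p, subs]; sb <- mats$b$scores[p, subs]
    sc <- mats$ctrl$scores[p, subs]
    ok <- !is.na(sa) & !is.na(sb) & !is.na(sc)
    if (sum(ok) < min_subs) {
      skipped <- c(skipped, p)
      next
    }
    d_iso <- (sa - sb)[ok]; d_ctrl <- (sc - sb)[ok]
    m_iso <- mean(d_iso); m_ctrl <- mean(d_ctrl)
    if (method == "mad_ratio") {
      effect <- sign(m_iso) * log2((mean(abs(d_iso)) + eps) / (mean(abs(d_ctrl)) + eps))
    } else {
      effect <- sign(m_iso - m_ctrl) * log2((abs(m_iso) + eps) / (abs(m_ctrl) + eps))
    }
    p_val <- if (all(d_iso == d_ctrl)) 1 else
      suppressWarnings(stats::wilcox.test(d_iso, d_ctrl, paired = TRUE,
                                          exact = NULL)$p.value)
    rows[[length(rows) + 1L]] <- tibble(
      position_label = p, wt_aa = wt_p, n_substitutions = sum(ok),
      mean_d_iso = m_iso, mean_d_ctrl = m_ctrl,
      effect = effect, p_value = p_val)
  }
  if (length(rows) == 0L) abort("no position had enough substitutions to compare")
  out <- bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  structure(out,
            skipped = skipped, method = method,
            class = c("sensitivity_result", class(tibble())))
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d positions (%s), %d with q < 0.05\n",
              nrow(x), attr(x, "method"), sum(x$q_value < 0.05)))
  NextMethod()
}

#' @describeIn isotype_sensitivity One-row summary of a sensitivity
#'   analysis.
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble(n_positions = nrow(x),
         n_skipped = length(attr(x, "skipped")),
         n_significant_q05 = sum(x$q_value < 0.05),
         max_abs_effect = max(abs(x$effect)),
         method = attr(x, "method"))
}
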