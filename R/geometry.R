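#' Rotation matrix about an axis
#'
#' Rodrigues construction of the 3x3 rotation matrix for a right-handed
#' rotation of `angle_deg` degrees about `axis`.
#'
#' @param axis Numeric length-3 vector (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Kabsch: rotation R (and translation) minimising |R p + t - q| over
## paired points; returns the rotation mapping `from` onto `to`.
kabsch_rotation <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  P <- sweep(from, 2, cf); Q <- sweep(to, 2, ct)
  sv <- svd(crossprod(P, Q))       # t(P) %*% Q
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, singular_values = sv$d)
}

## Axis (unit, sign-fixed) and angle in degrees of a rotation matrix.
## For angles away from 180 the axis sign comes from the skew part (a
## right-handed rotation by a positive angle); near 180 the axis is the
## eigenvector for eigenvalue 1 with its largest-magnitude component made
## positive (the sign is genuinely ambiguous there).
rotation_axis_angle <- function(R, degenerate_tol = 1e-6) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(cth)
  if (th < degenerate_tol) {
    return(list(angle_deg = 0, axis = c(NA_real_, NA_real_, NA_real_),
                degenerate = TRUE))
  }
  if (pi - th > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  } else {
    e <- eigen(R)
    k <- which.min(abs(e$values - 1))
    ax <- Re(e$vectors[, k])
    ax <- ax / sqrt(sum(ax^2))
    j <- which.max(abs(ax))
    if (ax[j] < 0) ax <- -ax
  }
  list(angle_deg = rad2deg(th), axis = ax / sqrt(sum(ax^2)), degenerate = FALSE)
}

#' Pseudo-twofold axis between two domains
#'
#' Superposes the second domain's C-alpha set onto the first over shared
#' IMGT labels (least-squares, Kabsch) and returns the axis and angle of
#' the resulting rotation.  For the VH/VL or CH1/CL pairs of a Fab this
#' rotation is close to a twofold, and its axis is the module's
#' pseudo-dyad.
#'
#' @param domain_1,domain_2 Labeled C-alpha tibbles (`imgt_label`, `x`,
#'   `y`, `z`), e.g. from [labeled_calpha()].
#' @param use_insertions Include insertion-coded labels in the
#'   superposition (default `FALSE`: framework columns only).
#' @return List: `axis` (unit vector; `NA` when degenerate), `angle_deg`
#'   in (0, 180], `n_shared` (label count used), `rmsd`, `degenerate`.
#' @export
pseudo_dyad_axis <- function(domain_1, domain_2, use_insertions = FALSE) {
  d1 <- domain_1; d2 <- domain_2
  if (!use_insertions) {
    d1 <- filter(d1, !grepl("[a-z]$", .data$imgt_label))
    d2 <- filter(d2, !grepl("[a-z]$", .data$imgt_label))
  }
  shared <- intersect(d1$imgt_label, d2$imgt_label)
  if (length(shared) < 3L) {
    abort(sprintf("only %d shared labeled positions; need >= 3 for superposition",
                  length(shared)))
  }
  p1 <- as.matrix(d1[match(shared, d1$imgt_label), c("x", "y", "z")])
  p2 <- as.matrix(d2[match(shared, d2$imgt_label), c("x", "y", "z")])
  ## collinearity check on either point set
  for (p in list(p1, p2)) {
    s <- svd(sweep(p, 2, colMeans(p)))$d
    if (s[2] < 1e-8 * max(s[1], 1)) {
      abort("degenerate geometry: labeled points are collinear")
    }
  }
  k <- kabsch_rotation(p2, p1)
  aa <- rotation_axis_angle(k$R)
  fitted <- sweep(sweep(p2, 2, colMeans(p2)) %*% t(k$R), 2, colMeans(p1), "+")
  list(axis = aa$axis, angle_deg = aa$angle_deg, n_shared = length(shared),
       rmsd = sqrt(mean(rowSums((fitted - p1)^2))), degenerate = aa$degenerate)
}

#' Fab elbow angle
#'
#' The angle between the V-module pseudo-dyad (axis of the VL-onto-VH
#' superposition) and the C-module pseudo-dyad (axis of the CL-onto-CH1
#' superposition).  A twofold axis has no intrinsic direction, so the two
#' dyads are compared as undirected lines: the default convention reports
#' `acos(|a . b|)` in [0, 90] degrees; `convention = "obtuse"` reports the
#' supplement (180 minus the acute angle), closer to the ranges quoted for
#' elbow angles in the structural literature.
#'
#' @param vh,vl,ch1,cl Labeled C-alpha tibbles for the four Fab domains.
#' @param convention `"acute"` (default) or `"obtuse"`.
#' @param use_insertions Passed to [pseudo_dyad_axis()].
#' @return Elbow angle in degrees.
#' @export
elbow_angle <- function(vh, vl, ch1, cl, convention = c("acute", "obtuse"),
                        use_insertions = FALSE) {
  convention <- match.arg(convention)
  dv <- pseudo_dyad_axis(vh, vl, use_insertions = use_insertions)
  dc <- pseudo_dyad_axis(ch1, cl, use_insertions = use_insertions)
  if (dv$degenerate || dc$degenerate) {
    abort("degenerate module superposition (identity rotation): elbow angle undefined")
  }
  cosang <- abs(sum(dv$axis * dc$axis))
  acute <- rad2deg(acos(max(-1, min(1, cosang))))
  if (convention == "acute") acute else 180 - acute
}

#' CH1-CL packing angle
#'
#' The rotation angle of the CL-onto-CH1 superposition (the C-module
#' pseudo-dyad rotation), in (0, 180].  A degenerate (identity) rotation
#' is reported as 0 with `degenerate = TRUE`.
#'
#' @param ch1,cl Labeled C-alpha tibbles.
#' @param use_insertions Passed to [pseudo_dyad_axis()].
#' @return List: `angle_deg`, `degenerate`.
#' @export
ch1_cl_angle <- function(ch1, cl, use_insertions = FALSE) {
  d <- pseudo_dyad_axis(ch1, cl, use_insertions = use_insertions)
  list(angle_deg = d$angle_deg, degenerate = d$degenerate)
}

#' C-alpha contact matrix between two labeled domains
#'
#' All-against-all C-alpha distances between the labeled residues of two
#' domains, with a boolean contact map under a distance cutoff.  Labels
#' without resolved coordinates appear as rows/columns of missing values,
#' never as zeros.
#'
#' @param domain_a,domain_b Labeled C-alpha tibbles (`imgt_label`, `x`,
#'   `y`, `z`; coordinates may be `NA` for unresolved labels).
#' @param cutoff Contact cutoff in Angstroms (default 8.0).
#' @return A `contact_matrix`: list with `row_labels`, `col_labels`,
#'   `distances` (matrix, Angstroms), `contacts` (logical matrix),
#'   `cutoff`.
#' @examples
#' a <- tibble::tibble(imgt_label = "1", x = 0, y = 0, z = 0)
#' b <- tibble::tibble(imgt_label = "1", x = 3, y = 4, z = 0)
#' contact_matrix(a, b)$distances  # 5
#' @export
contact_matrix <- function(domain_a, domain_b, cutoff = 8.0) {
  for (d in list(domain_a, domain_b)) {
    if (!is.data.frame(d) || nrow(d) == 0L || !all(c("imgt_label", "x", "y", "z") %in% names(d))) {
      abort("domains must be non-empty tibbles with imgt_label, x, y, z")
    }
  }
  if (all(is.na(domain_a$x)) || all(is.na(domain_b$x))) {
    abort("no resolved C-alpha coordinates in one of the domains")
  }
  A <- as.matrix(domain_a[, c("x", "y", "z")])
  B <- as.matrix(domain_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 1e-10] <- 0   # cancellation noise for (near-)identical points
  D <- sqrt(d2)
  dimnames(D) <- list(domain_a$imgt_label, domain_b$imgt_label)
  structure(list(row_labels = domain_a$imgt_label,
                 col_labels = domain_b$imgt_label,
                 distances = D,
                 contacts = D <= cutoff,
                 cutoff = cutoff),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d labels, cutoff %.1f A, %d contacts\n",
              length(x$row_labels), length(x$col_labels), x$cutoff,
              sum(x$contacts, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn contact_matrix Long-form tibble (`label_a`, `label_b`,
#'   `distance`, `contact`), the CSV shape used on disk.
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @export
tidy.contact_matrix <- function(x, ...) {
  tibble(
    label_a = rep(x$row_labels, times = length(x$col_labels)),
    label_b = rep(x$col_labels, each = length(x$row_labels)),
    distance = as.vector(x$distances),
    contact = as.vector(x$contacts)
  )
}
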