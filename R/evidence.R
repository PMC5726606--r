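## Statistical termination maps: voxelwise paired comparisons between
## tracts via sign-flip maximum-statistic permutation inference (the
## standard nonparametric FWE correction for a paired design), summed into
## per-tract evidence maps on a 0..T-1 scale.

#' Paired sign-flip permutation comparison of two tracts
#'
#' Tests, voxel by voxel within a mask, whether tract A's termination
#' probability exceeds tract B's across subjects.  The statistic is the
#' one-sample t of the per-subject difference maps `A_s - B_s`; the null is
#' generated by flipping the sign of whole subject difference maps, and
#' familywise error over the mask is controlled with the permutation
#' distribution of the maximum statistic.  A voxel is significant when its
#' FWE p-value is below `alpha / m_bonferroni`.  When `2^n <=
#' n_permutations` all sign patterns are enumerated exhaustively (the
#' p-values are then exact); otherwise `n_permutations` random patterns are
#' sampled and the identity flip is included.
#'
#' Zero-variance voxels are assigned statistic 0 and can never be
#' significant.  The test is one-sided (A greater than B).
#'
#' @param maps_A,maps_B per-subject volumes (or `termination_map`s), paired
#'   by position; un-rescaled maps should be supplied.
#' @param mask binary analysis mask (e.g. the lobe grey-white interface).
#' @param alpha significance level before Bonferroni division.
#' @param n_permutations permutation budget.
#' @param m_bonferroni Bonferroni divisor; 42 corresponds to all ordered
#'   pairs of 7 tracts.
#' @param rng_seed integer seed for sampled permutations.
#' @param pair named character pair `c(A = , B = )` of tract names, for
#'   provenance.
#' @return An object of class `pairwise_result`: `significant` and `p_fwe`
#'   volumes, observed `t` volume, the pair, and permutation metadata.
#' @export
paired_permutation_map <- function(maps_A, maps_B, mask, alpha = 0.05,
                                   n_permutations = 5000L,
                                   m_bonferroni = 42L, rng_seed = 1L,
                                   pair = c(A = "A", B = "B")) {
  vols <- function(ms) lapply(ms, function(m)
    if (inherits(m, "termination_map")) m$proportion else m)
  maps_A <- vols(maps_A); maps_B <- vols(maps_B)
  n <- length(maps_A)
  if (length(maps_B) != n) stop("maps_A and maps_B must be paired by subject")
  if (n < 2) stop("need at least 2 subjects for a paired comparison")
  grid <- attr(maps_A[[1]], "grid")
  sel <- which(mask != 0)
  v <- length(sel)
  if (v == 0) stop("empty analysis mask")
  D <- matrix(0, n, v)
  for (s in seq_len(n)) {
    check_same_grid(maps_A[[s]], mask, "subject map and mask")
    check_same_grid(maps_B[[s]], mask, "subject map and mask")
    D[s, ] <- maps_A[[s]][sel] - maps_B[[s]][sel]
  }
  ss <- colSums(D^2)
  var_tol <- pmax(ss, 1e-300) * 1e-12  # relative floor for zero-variance voxels
  t_of <- function(m) {
    sd2 <- pmax((ss - n * m^2) / (n - 1), 0)
    ifelse(sd2 < var_tol, 0, m / sqrt(sd2 / n))
  }
  t_obs <- t_of(colMeans(D))
  exhaustive <- n <= 30 && 2^n <= n_permutations
  if (exhaustive) {
    B <- as.integer(2^n)
    signs <- matrix(1, n, B)
    for (i in seq_len(n))
      signs[i, ] <- ifelse(bitwAnd(seq_len(B) - 1L, bitwShiftL(1L, i - 1L)) > 0, -1, 1)
  } else {
    B <- as.integer(n_permutations)
    signs <- local_rng_seed(derive_seed(rng_seed, 4243L), {
      matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
    })
    signs[, 1] <- 1  # include the identity flip
  }
  maxstat <- numeric(B)
  chunk <- max(1L, min(B, as.integer(2e7 / max(v, 1))))
  for (b0 in seq(1L, B, by = chunk)) {
    b1 <- min(b0 + chunk - 1L, B)
    M <- crossprod(D, signs[, b0:b1, drop = FALSE]) / n  # v x chunk
    sd2 <- pmax((ss - n * M^2) / (n - 1), 0)
    Tm <- M / sqrt(sd2 / n)
    Tm[sd2 < var_tol] <- 0  # var_tol recycles down columns (voxel-wise)
    Tm[!is.finite(Tm)] <- 0
    maxstat[b0:b1] <- apply(Tm, 2L, max)
  }
  p <- vapply(t_obs, function(t0) sum(maxstat >= t0), 0) / B
  p_vol <- new_volume(if (!is.null(grid)) grid else
                        vol_grid(dim(mask), 1), NA_real_)
  p_vol[sel] <- p
  t_vol <- new_volume(vol_grid_of(p_vol), 0)
  t_vol[sel] <- t_obs
  sig <- new_volume(vol_grid_of(p_vol), FALSE)
  sig[sel] <- p < alpha / m_bonferroni
  structure(list(pair = pair,
                 significant = sig, p_fwe = p_vol, t = t_vol,
                 n_subjects = n, n_permutations = B,
                 exhaustive = exhaustive, alpha = alpha,
                 m_bonferroni = m_bonferroni, mask = mask),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf(
    "<pairwise_result> %s > %s | n = %d subjects | %s%d permutations | %d significant voxels at alpha %g / %d\n",
    if (length(x$pair)) x$pair[1] else "A", if (length(x$pair) > 1) x$pair[2] else "B",
    x$n_subjects, if (x$exhaustive) "exhaustive " else "", x$n_permutations,
    sum(x$significant, na.rm = TRUE), x$alpha, x$m_bonferroni))
  invisible(x)
}

#' Sum pairwise wins into an evidence map
#'
#' For one tract, counts per voxel how many of its pairwise comparisons
#' were significant: 0 = greater than no other tract, T-1 = greater than
#' all other tracts.
#'
#' @param tract tract name.
#' @param pairwise_results list of [paired_permutation_map()] results with
#'   this tract as A; with T tracts there must be exactly T-1 of them.
#' @param n_tracts T, the total number of tracts compared.
#' @return Integer volume with values in 0..T-1, class `evidence_map`.
#' @export
evidence_map <- function(tract, pairwise_results, n_tracts) {
  res <- Filter(function(r) identical(unname(r$pair[1]), tract), pairwise_results)
  if (!length(res)) res <- pairwise_results  # assume pre-filtered, unnamed pairs
  if (length(res) != n_tracts - 1L)
    stop(sprintf("expected %d pairwise results for tract '%s', got %d",
                 n_tracts - 1L, tract, length(res)))
  acc <- res[[1]]$significant * 1L
  for (r in res[-1]) {
    check_same_grid(acc, r$significant, "pairwise significance maps")
    acc <- acc + r$significant
  }
  g <- attr(res[[1]]$significant, "grid")
  out <- with_grid(array(as.integer(acc), dim(acc)), g)
  attr(out, "tract") <- tract
  attr(out, "n_tracts") <- as.integer(n_tracts)
  class(out) <- c("evidence_map", class(out))
  out
}

#' @export
print.evidence_map <- function(x, ...) {
  tb <- table(factor(as.vector(x), levels = 0:(attr(x, "n_tracts") - 1L)))
  cat(sprintf("<evidence_map> tract '%s' (T = %d): counts %s\n",
              attr(x, "tract"), attr(x, "n_tracts"),
              paste(sprintf("%s:%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' Extract a termination ROI from an evidence map
#'
#' The `"top_two"` rule keeps the two highest evidence values, `T-2` and
#' `T-1` (with 7 tracts: 5 and 6) — the greatest-evidence threshold above
#' "greater than half the other tracts".  The `"max"` rule keeps only
#' `T-1` (greater than all other tracts), used for the occipital secondary
#' subdivision.  An empty ROI is allowed: a tract may have no voxel
#' reaching the required level of evidence.
#'
#' @param evidence an [evidence_map()] (or integer volume).
#' @param n_tracts T (taken from the evidence map attribute if absent).
#' @param rule `"top_two"` or `"max"`.
#' @return An object of class `evidence_roi` with a binary `mask`.
#' @export
evidence_roi <- function(evidence, n_tracts = attr(evidence, "n_tracts"),
                         rule = c("top_two", "max")) {
  rule <- match.arg(rule)
  if (is.null(n_tracts)) stop("'n_tracts' required")
  if (n_tracts < 3) stop("need at least 3 tracts for the evidence-ROI rule")
  keep <- if (rule == "top_two") c(n_tracts - 2L, n_tracts - 1L) else n_tracts - 1L
  m <- array(as.vector(evidence) %in% keep, dim(evidence))
  g <- attr(evidence, "grid")
  if (!is.null(g)) m <- with_grid(m, g)
  structure(list(tract = attr(evidence, "tract"), mask = m, rule = rule,
                 n_tracts = as.integer(n_tracts)),
            class = "evidence_roi")
}

#' @export
print.evidence_roi <- function(x, ...) {
  cat(sprintf("<evidence_roi> tract '%s', rule %s: %d voxels%s\n",
              x$tract, x$rule, sum(x$mask),
              if (!any(x$mask)) " (no voxel reached the required evidence)" else ""))
  invisible(x)
}

#' Subdivide a termination ROI into anterior/posterior sections
#'
#' Splits an ROI at a coronal world plane into a posterior section
#' (`y < y_plane_mm`) and an anterior section, which is further divided
#' into superior and inferior parts at `superior_boundary` (a world-mm
#' z-plane, or a binary mask marking the superior part).  The three masks
#' partition the ROI.
#'
#' @param roi an [evidence_roi()] or binary volume.
#' @param grid grid (from the mask attribute if absent).
#' @param y_plane_mm coronal dividing plane, world mm.
#' @param superior_boundary z-plane (world mm) or binary mask.
#' @return Named list of masks `ant_inf`, `ant_sup`, `post`.
#' @export
subdivide_roi <- function(roi, grid = NULL, y_plane_mm = -27,
                          superior_boundary = 0) {
  mask <- if (inherits(roi, "evidence_roi")) roi$mask else roi
  if (is.null(grid)) grid <- vol_grid_of(mask)
  if (!any(mask != 0)) stop("cannot subdivide an empty ROI")
  idx <- mask_indices(mask)
  w <- voxel_to_world(idx, grid)
  lin <- lin_index(idx, grid$shape)
  post <- w[, 2] < y_plane_mm
  if (is.array(superior_boundary)) {
    sup <- superior_boundary[lin] != 0
  } else {
    sup <- w[, 3] >= superior_boundary
  }
  out <- lapply(list(ant_inf = !post & !sup, ant_sup = !post & sup,
                     post = post),
                function(keep) {
                  m <- new_volume(grid, FALSE)
                  m[lin[keep]] <- TRUE
                  m
                })
  empty <- names(out)[!vapply(out, any, TRUE)]
  if (length(empty))
    warning("empty ROI subdivision(s): ", paste(empty, collapse = ", "))
  out
}
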