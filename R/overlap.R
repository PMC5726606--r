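## Overlap between termination ROIs and functional-domain maps: the
## proportion P = |A n B| / |A|, judged against a null of random
## arrangements of grey-matter voxels of the same size as the domain map.

#' Overlap proportion between two masks
#'
#' `P = |A n B| / |A|`, the proportion of the termination ROI covered by
#' the domain map, reported with its exact integer counts.
#'
#' @param A,B binary volumes on a shared grid; `A` must be non-empty.
#' @return List with `P`, `n_A`, `n_B`, `n_intersect`.
#' @export
overlap_proportion <- function(A, B) {
  check_same_grid(A, B, "overlap masks")
  n_A <- sum(A != 0)
  if (n_A == 0) stop("empty ROI: overlap proportion undefined")
  n_int <- sum(A != 0 & B != 0)
  list(P = n_int / n_A, n_A = n_A, n_B = sum(B != 0), n_intersect = n_int)
}

#' Random-arrangement overlap null
#'
#' Draws `size_B` grey-matter voxels uniformly without replacement
#' `n_permutations` times and records the overlap proportion of each draw
#' with `A`.  When `A` is a subset of the grey-matter mask the null is
#' hypergeometric with mean `size_B / |gm|`.
#'
#' @param A binary ROI volume.
#' @param size_B number of voxels per random map (the domain map size).
#' @param gm_mask binary mask the random voxels are drawn from.
#' @param n_permutations number of draws.
#' @param rng_seed integer seed; the null sample is bitwise reproducible.
#' @return Numeric vector of `n_permutations` overlap proportions.
#' @export
permutation_null <- function(A, size_B, gm_mask, n_permutations = 10000L,
                             rng_seed = 1L) {
  check_same_grid(A, gm_mask, "ROI and grey-matter mask")
  gm_lin <- which(gm_mask != 0)
  n_gm <- length(gm_lin)
  if (size_B > n_gm)
    stop(sprintf("domain map size %d exceeds grey-matter mask size %d",
                 size_B, n_gm))
  n_A <- sum(A != 0)
  if (n_A == 0) stop("empty ROI: overlap proportion undefined")
  if (size_B == 0) return(rep(0, n_permutations))
  in_A <- A[gm_lin] != 0
  local_rng_seed(derive_seed(rng_seed, 9091L), {
    vapply(seq_len(n_permutations), function(i)
      sum(in_A[sample.int(n_gm, size_B)]) / n_A, 0)
  })
}

#' Permutation overlap test
#'
#' Computes the observed overlap proportion of a termination ROI with a
#' domain map and compares it with the random-arrangement null: the
#' overlap is significant when it exceeds the empirical
#' `1 - alpha / m_tests` quantile of the null (Bonferroni-corrected
#' familywise gate over `m_tests` matrix cells).
#'
#' @param A binary termination ROI.
#' @param B binary domain map.
#' @param gm_mask binary grey-matter mask for the null draws.
#' @param alpha significance level.
#' @param m_tests Bonferroni divisor (number of matrix cells tested).
#' @param n_permutations null draws.
#' @param rng_seed integer seed.
#' @return An object of class `overlap_test`.
#' @export
overlap_test <- function(A, B, gm_mask, alpha = 0.05, m_tests = 1L,
                         n_permutations = 10000L, rng_seed = 1L) {
  obs <- overlap_proportion(A, B)
  null <- permutation_null(A, obs$n_B, gm_mask,
                           n_permutations = n_permutations,
                           rng_seed = rng_seed)
  lvl <- 1 - alpha / m_tests
  thr <- sort(null)[max(1L, ceiling(lvl * length(null)))]
  structure(list(P = obs$P, n_A = obs$n_A, n_B = obs$n_B,
                 n_intersect = obs$n_intersect, null = null,
                 threshold = thr, level = lvl, alpha = alpha,
                 m_tests = m_tests, significant = obs$P > thr),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> P = %d/%d = %.3f | null mean %.4f, %.1f%% quantile %.4f | %ssignificant\n",
    x$n_intersect, x$n_A, x$P, mean(x$null), 100 * x$level, x$threshold,
    if (x$significant) "" else "not "))
  invisible(x)
}

split_hemisphere <- function(mask, grid, side) {
  idx <- mask_indices(mask)
  if (!nrow(idx)) return(mask & FALSE)
  w <- voxel_to_world(idx, grid)
  keep <- if (side == "left") w[, 1] < 0 else w[, 1] >= 0
  out <- new_volume(grid, FALSE)
  out[lin_index(idx[keep, , drop = FALSE], grid$shape)] <- TRUE
  out
}

#' Overlap matrix of termination ROIs against domain maps
#'
#' Runs one [overlap_test()] per (ROI or subdivision) x domain (x
#' hemisphere when `split_hemispheres`), Bonferroni-corrected over the
#' total number of tests, and assembles the matrix whose cells carry the
#' overlap proportion only where significant.  Empty ROIs are skipped with
#' a warning (a tract may have no voxel at the required evidence level).
#'
#' @param rois named list of binary ROI volumes or [evidence_roi()]s.
#' @param domain_maps named list of binary domain-map volumes.
#' @param gm_mask binary mask for the null draws.
#' @param alpha significance level.
#' @param m_tests Bonferroni divisor; default the number of tests run.
#' @param n_permutations null draws per test.
#' @param rng_seed integer seed.
#' @param split_hemispheres test left (`world x < 0`) and right halves of
#'   every ROI separately.
#' @param grid common grid (from `gm_mask` if absent).
#' @return An object of class `overlap_matrix`: `P` (all proportions),
#'   `significant`, `reported` (P where significant, else `NA`) and the
#'   per-cell `overlap_test`s.
#' @export
overlap_matrix <- function(rois, domain_maps, gm_mask, alpha = 0.05,
                           m_tests = NULL, n_permutations = 10000L,
                           rng_seed = 1L, split_hemispheres = FALSE,
                           grid = NULL) {
  if (is.null(grid)) grid <- vol_grid_of(gm_mask)
  masks <- lapply(rois, function(r) if (inherits(r, "evidence_roi")) r$mask else r)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("'rois' must be a named list")
  if (split_hemispheres) {
    out <- list()
    for (nm in names(masks))
      for (side in c("left", "right"))
        out[[paste(nm, side, sep = ".")]] <-
          split_hemisphere(masks[[nm]], grid, side)
    masks <- out
  }
  empty <- vapply(masks, function(m) !any(m != 0), TRUE)
  if (any(empty)) {
    warning("skipping empty ROI(s): ", paste(names(masks)[empty], collapse = ", "))
    masks <- masks[!empty]
  }
  if (!length(masks)) stop("no non-empty ROIs to test")
  n_tests <- length(masks) * length(domain_maps)
  if (is.null(m_tests)) m_tests <- n_tests
  P <- sig <- matrix(NA_real_, length(masks), length(domain_maps),
                     dimnames = list(names(masks), names(domain_maps)))
  tests <- list()
  for (i in seq_along(masks)) for (j in seq_along(domain_maps)) {
    tst <- overlap_test(masks[[i]], domain_maps[[j]], gm_mask, alpha = alpha,
                        m_tests = m_tests, n_permutations = n_permutations,
                        rng_seed = derive_seed(rng_seed, 31L * i + j))
    P[i, j] <- tst$P
    sig[i, j] <- tst$significant
    tests[[paste(names(masks)[i], names(domain_maps)[j], sep = "|")]] <- tst
  }
  reported <- ifelse(sig == 1, P, NA_real_)
  structure(list(P = P, significant = sig == 1, reported = reported,
                 tests = tests, alpha = alpha, m_tests = m_tests,
                 n_permutations = n_permutations),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 2, ...) {
  cat(sprintf(
    "<overlap_matrix> %d ROI(s) x %d domain(s), alpha %g Bonferroni-corrected over %d tests\n",
    nrow(x$P), ncol(x$P), x$alpha, x$m_tests))
  cat("cells show the overlap proportion where significant:\n")
  m <- matrix(ifelse(is.na(x$reported), ".",
                     formatC(x$reported, digits = digits, format = "f")),
              nrow(x$P), dimnames = dimnames(x$P))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write an overlap matrix as TSV and JSON
#'
#' @param x an [overlap_matrix()].
#' @param tsv,json output paths (`NULL` to skip either).
#' @return Invisibly, the list of written paths.
#' @export
write_overlap_matrix <- function(x, tsv = NULL, json = NULL) {
  paths <- list()
  if (!is.null(tsv)) {
    df <- data.frame(roi = rownames(x$P), x$reported, check.names = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$tsv <- tsv
  }
  if (!is.null(json)) {
    detail <- lapply(x$tests, function(t)
      list(P = t$P, n_A = t$n_A, n_B = t$n_B, n_intersect = t$n_intersect,
           threshold = t$threshold, significant = t$significant))
    jsonlite::write_json(list(alpha = x$alpha, m_tests = x$m_tests,
                              n_permutations = x$n_permutations,
                              reported = as.data.frame(x$reported),
                              tests = detail),
                         json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$json <- json
  }
  invisible(paths)
}
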