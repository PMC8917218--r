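#' Mask low-coverage bins
#'
#' Bins whose marginal count sum (diagonal excluded) is zero or below
#' `min_fraction` of the mean marginal over currently unmasked bins are
#' masked and their stored contacts removed. This is the standard
#' preprocessing step before iterative correction.
#'
#' @param cm raw `contact_matrix`.
#' @param min_fraction marginal-sum threshold as a fraction of the mean
#'   marginal (default 0.02).
#' @return the matrix with its mask extended.
#' @export
mask_low_coverage <- function(cm, min_fraction = 0.02) {
  m <- marginals(cm, exclude_diag = TRUE)
  mu <- mean(m[!cm$mask], na.rm = TRUE)
  bad <- !cm$mask & (is.na(m) | m == 0 | m < min_fraction * mu)
  mask <- cm$mask | bad
  if (all(mask)) stop("matrix empty after masking")
  contact_matrix(cm$bins, cm$counts, balanced = cm$balanced, mask = mask)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by iteratively dividing each bin's
#' bias by its (unit-mean-normalized) marginal until the relative spread
#' `(max - min)/mean` of unmasked marginals drops below `tol`. The diagonal
#' is excluded from the marginals. On convergence the bias vector is
#' renormalized to geometric mean 1 over unmasked bins and the balanced
#' matrix is `W_ij = T_ij / (b_i * b_j)` (all stored entries, including the
#' diagonal). Unmasked row sums of the result are equal within `tol`; total
#' unmasked mass is preserved up to a single global scale factor, reported
#' in the `scale` field.
#'
#' @param cm raw `contact_matrix` (run [mask_low_coverage()] first; bins
#'   with zero marginal are implicitly skipped).
#' @param max_iter maximum number of iterations (default 200).
#' @param tol convergence tolerance on the relative marginal spread
#'   (default 1e-5).
#' @return `list(matrix = balanced contact_matrix, bias = numeric,
#'   converged = logical, iterations = integer, scale = numeric)`. The bias
#'   is `NA` for masked bins. Non-convergence raises a warning and returns
#'   the partial result.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5) {
  n <- n_bins(cm)
  A <- cm_sparse(cm, drop_diag = TRUE)
  unmasked <- !cm$mask
  b <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  degenerate <- Matrix::rowSums(A) == 0 & unmasked
  active <- unmasked & !degenerate
  if (!any(active)) stop("no unmasked bins with contacts to balance")
  repeat {
    marg <- as.vector(A %*% (1 / b)) / b
    ma <- marg[active]
    spread <- (max(ma) - min(ma)) / mean(ma)
    if (spread < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    s <- marg / mean(ma)
    s[!active | s == 0] <- 1
    b <- b * s
  }
  if (!converged)
    warning("ICE did not converge after ", max_iter,
            " iterations (spread ", signif(spread, 3), ")")
  g <- exp(mean(log(b[active])))
  b <- b / g
  cnt <- cm$counts
  w <- cnt$count / (b[cnt$bin1] * b[cnt$bin2])
  bal <- contact_matrix(cm$bins,
                        data.frame(bin1 = cnt$bin1, bin2 = cnt$bin2, count = w),
                        balanced = TRUE, mask = cm$mask)
  scale <- sum(bal$counts$count) / sum(cnt$count)
  b[!unmasked] <- NA_real_
  bal$bias <- b
  list(matrix = bal, bias = b, converged = converged, iterations = iter,
       scale = scale)
}
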