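# Signed Spearman correlation matrices with per-pair two-tailed p-values.
# rho uses average ranks (midranks for ties); p comes from the t
# approximation t = rho * sqrt((n - 2) / (1 - rho^2)) by default, with an
# exact permutation option (all n! orderings) for the small per-group sample
# sizes typical of c-Fos studies. No multiple-testing correction is applied
# across the pair matrix — edges are thresholded on raw p-values, which is
# deliberate and documented.

# All permutations of 1..n as an (n!) x n index matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    out[rows, -1L] <- m
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

spearman_p_t <- function(rho, n) {
  if (is.na(rho) || n < 3L) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

# Exact two-tailed permutation p over all n! orderings of one variable's
# ranks: the fraction of permutations with |rho| at least the observed.
spearman_p_exact <- function(x, y, perms = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  n <- length(rx)
  if (is.null(perms)) perms <- all_permutations(n)
  obs <- cor(rx, ry)
  scale <- (n - 1) * sd(rx) * sd(ry)
  s <- matrix(rx[perms], nrow = nrow(perms)) %*% ry
  rho_all <- (s - n * mean(rx) * mean(ry)) / scale
  mean(abs(rho_all) >= abs(obs) - 1e-12)
}

#' Spearman correlation matrix for one group's activation table
#'
#' Computes the signed Spearman correlation between every pair of regions
#' across the animals of one group, with two-tailed p-values. Animals with
#' any missing region value are dropped (and reported); a region with
#' constant values has undefined rank correlations — its pairs are recorded
#' as missing, never as zero, and are excluded from the possible-edge count
#' downstream.
#'
#' @param table Activation table for a single group (`animal_id`, optional
#'   `group`, region columns). At least 4 animals.
#' @param p_method `"t"` (default) for the t-distribution approximation, or
#'   `"exact"` for the full permutation distribution (all `n!` orderings;
#'   only for 9 or fewer animals).
#' @param id_cols Non-region columns.
#' @return An object of class `coact_cormat`: list with `regions`, `rho`
#'   and `p` (symmetric matrices; diagonal 1 and 0), `n` (animals used),
#'   `p_method`, `dropped_animals`, `constant_regions`.
#' @seealso [build_network()]
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact"),
                            id_cols = c("animal_id", "group")) {
  p_method <- match.arg(p_method)
  if ("group" %in% names(table) && dplyr::n_distinct(table$group) > 1L) {
    abort("`spearman_matrix()` expects a single group; filter first.")
  }
  regions <- region_columns(table, id_cols)
  if (length(regions) < 2L) abort("need at least 2 region columns.")
  vals <- as.matrix(table[, regions, drop = FALSE])
  keep <- complete.cases(vals)
  dropped <- if ("animal_id" %in% names(table)) table$animal_id[!keep] else which(!keep)
  if (any(!keep)) {
    inform(sprintf("dropped %d animal(s) with missing region values.", sum(!keep)))
  }
  vals <- vals[keep, , drop = FALSE]
  n <- nrow(vals)
  if (n < 4L) abort("need at least 4 animals with complete data.")
  if (p_method == "exact" && n > 9L) {
    abort("exact permutation p is only available for 9 or fewer animals.")
  }
  k <- length(regions)
  ranks <- apply(vals, 2, rank)
  rsd <- apply(ranks, 2, sd)
  constant <- regions[rsd == 0]
  if (p_method == "t") {
    ok <- rsd > 0
    rho <- matrix(NA_real_, k, k)
    rho[ok, ok] <- cor(ranks[, ok, drop = FALSE])
    # two-tailed p from t = rho * sqrt((n-2)/(1-rho^2)); p = 0 at |rho| = 1
    r2 <- pmin(rho^2, 1 - 1e-15)
    p <- 2 * pt(abs(rho) * sqrt((n - 2) / (1 - r2)), df = n - 2,
                lower.tail = FALSE)
    p[abs(rho) >= 1 - 1e-12] <- 0
    diag(rho) <- 1
    diag(p) <- 0
    dimnames(rho) <- dimnames(p) <- list(regions, regions)
  } else {
    rho <- diag(1, k); p <- matrix(0, k, k)
    dimnames(rho) <- dimnames(p) <- list(regions, regions)
    perms <- all_permutations(n)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        r <- spearman_rho(vals[, i], vals[, j])
        pv <- if (is.na(r)) NA_real_ else spearman_p_exact(vals[, i], vals[, j], perms)
        rho[i, j] <- rho[j, i] <- r
        p[i, j] <- p[j, i] <- pv
      }
    }
  }
  if (length(constant) > 0L) {
    inform(sprintf(
      "region(s) with constant values (rho undefined): %s",
      paste(constant, collapse = ", ")
    ))
  }
  structure(
    list(
      regions = regions, rho = rho, p = p, n = n, p_method = p_method,
      dropped_animals = dropped, constant_regions = constant
    ),
    class = "coact_cormat"
  )
}

#' @export
print.coact_cormat <- function(x, ...) {
  cat(sprintf(
    "<coact_cormat> %d regions, n = %d animals, p method: %s\n",
    length(x$regions), x$n, x$p_method
  ))
  invisible(x)
}

#' @describeIn spearman_matrix Long tibble of the upper-triangle pairs
#'   (`region_i`, `region_j`, `rho`, `p`).
#' @param x A `coact_cormat`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.coact_cormat <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    region_i = x$regions[idx[, 1]],
    region_j = x$regions[idx[, 2]],
    rho = x$rho[idx],
    p = x$p[idx]
  )
}
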