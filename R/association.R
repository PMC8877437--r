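#' Spearman rank correlation coefficient
#'
#' Computes Spearman's rho as the Pearson correlation of average-ranked
#' values, so ties receive average ranks. The statistic is symmetric and
#' invariant under strictly increasing transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return rho in \[-1, 1\], or `NA` when either vector is constant
#'   (rank correlation undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3) stop("need n >= 3 paired observations, got ", length(x))
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Cache of exact two-sided null distributions of |rho| for untied ranks
# 1..n, n <= 9 (n! up to 362880 permutations).
.rho_null_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

.exact_rho_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.rho_null_cache[[key]])) return(.rho_null_cache[[key]])
  perms <- .permutations(n)
  r <- seq_len(n)
  mu <- mean(r)
  ss <- sum((r - mu)^2)
  # rho for each permutation p of untied ranks: cor(r, p)
  rho <- (perms %*% r - n * mu * mu) / ss
  .rho_null_cache[[key]] <- as.numeric(rho)
  .rho_null_cache[[key]]
}

#' Two-sided p-value for Spearman's rho
#'
#' For n > 9 the t-distribution approximation is used:
#' t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees of freedom.
#' For n <= 9 the exact permutation null is enumerated over all n!
#' permutations of untied ranks 1..n and the p-value is the fraction of
#' permutations with |rho| at least as large as observed. (With tied data
#' the exact null would depend on the tie structure, which rho and n do not
#' carry; the approximation is then the caller's responsibility at small n.)
#' A p-value of exactly zero is never returned: perfect correlations map to
#' the smallest representable positive double under the approximation, and
#' to 2/n! under exact enumeration.
#'
#' @param rho Spearman correlation in \[-1, 1\] (`NA` gives `NA`).
#' @param n Number of paired samples, n >= 3.
#' @return Two-sided p-value in (0, 1].
#' @export
spearman_pvalue <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (n < 3) stop("need n >= 3, got ", n)
  if (abs(rho) > 1 + 1e-12) stop("|rho| > 1: ", rho)
  rho <- max(-1, min(1, rho))
  if (n <= 9) {
    null <- .exact_rho_null(n)
    return(mean(abs(null) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(.Machine$double.xmin)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  max(p, .Machine$double.xmin)
}

#' Build the molecule-microbe association network
#'
#' Computes Spearman's correlation between every molecular feature and every
#' microbial feature across the shared samples and keeps the pairs with
#' `p_value < p_threshold` and `|rho| > rho_threshold`. The null hypothesis
#' for each pair is that the intensity of the molecular feature and the
#' count of the microbial feature are independent across samples. Raw
#' p-values are thresholded by default (no multiple-testing correction);
#' `adjust = "BH"` switches the p filter to Benjamini-Hochberg adjusted
#' values over all tested pairs.
#'
#' Constant features (identical value in every sample) have no defined rank
#' correlation and are skipped, with a message giving the count.
#'
#' @param mol An `intensity_matrix`.
#' @param mic A `count_matrix` with identical sample columns (see
#'   [align_samples()]).
#' @param p_threshold Keep pairs with p strictly below this (default 1e-4).
#' @param rho_threshold Keep pairs with |rho| strictly above this
#'   (default 0.1).
#' @param adjust `"none"` (default, raw p-values) or `"BH"`.
#' @return A data.frame of association edges with columns
#'   `molecular_feature_id`, `microbial_feature_id`, `rho`, `p_value`, `n`,
#'   sorted by molecular then microbial id. The number of skipped constant
#'   features is attached as `attr(, "n_constant")`.
#' @export
build_association_network <- function(mol, mic, p_threshold = 1e-4,
                                      rho_threshold = 0.1,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(mol, "intensity_matrix"), inherits(mic, "count_matrix"))
  if (!identical(colnames(mol$values), colnames(mic$values)))
    stop("matrices are not sample-aligned; run align_samples() first")
  n <- ncol(mol$values)
  if (n < 3) stop("need at least 3 shared samples, got ", n)

  rank_rows <- function(v) t(apply(v, 1, rank))
  rmol <- rank_rows(mol$values)
  rmic <- rank_rows(mic$values)
  const_mol <- apply(rmol, 1, function(r) all(r == r[1]))
  const_mic <- apply(rmic, 1, function(r) all(r == r[1]))
  n_constant <- sum(const_mol) + sum(const_mic)
  if (n_constant > 0)
    message("build_association_network: skipped ", n_constant,
            " constant feature(s)")
  rmol <- rmol[!const_mol, , drop = FALSE]
  rmic <- rmic[!const_mic, , drop = FALSE]
  if (nrow(rmol) == 0 || nrow(rmic) == 0) {
    edges <- .empty_assoc_edges()
    attr(edges, "n_constant") <- n_constant
    return(edges)
  }

  rho <- stats::cor(t(rmol), t(rmic))  # Pearson on ranks = Spearman
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  if (n <= 9) {
    p <- apply(rho, c(1, 2), spearman_pvalue, n = n)
  } else {
    tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    p[abs(rho) >= 1] <- .Machine$double.xmin
    p <- pmax(p, .Machine$double.xmin)
  }
  p_filter <- if (adjust == "BH") matrix(stats::p.adjust(p, "BH"), nrow(p)) else p

  keep <- which(p_filter < p_threshold & abs(rho) > rho_threshold,
                arr.ind = TRUE)
  edges <- data.frame(
    molecular_feature_id = rownames(rho)[keep[, 1]],
    microbial_feature_id = colnames(rho)[keep[, 2]],
    rho = rho[keep],
    p_value = p[keep],
    n = rep.int(n, nrow(keep)),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$molecular_feature_id, edges$microbial_feature_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_constant") <- n_constant
  edges
}

.empty_assoc_edges <- function() {
  data.frame(molecular_feature_id = character(0),
             microbial_feature_id = character(0),
             rho = numeric(0), p_value = numeric(0), n = integer(0),
             stringsAsFactors = FALSE)
}

#' Write/read an association edge list as CSV
#'
#' @param edges Edge data.frame from [build_association_network()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the edge data.frame (reader).
#' @export
write_association_edges <- function(edges, path) {
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_edges
#' @export
read_association_edges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecular_feature_id", "microbial_feature_id", "rho", "p_value", "n")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  df$molecular_feature_id <- as.character(df$molecular_feature_id)
  df$microbial_feature_id <- as.character(df$microbial_feature_id)
  df
}
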