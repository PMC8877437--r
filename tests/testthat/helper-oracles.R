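# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own code paths.

# average ranks computed from scratch (no rank())
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Spearman rho as Pearson on hand-computed average ranks, explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = k - 1L)
  }
  out
}

# exhaustive two-sided permutation p-value for Spearman rho
oracle_perm_pvalue <- function(x, y) {
  obs <- abs(oracle_spearman(x, y))
  hits <- 0L
  total <- 0L
  for (p in oracle_perms(length(y))) {
    total <- total + 1L
    if (abs(oracle_spearman(x, y[p])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# brute-force modified cosine: enumerate every one-to-one assignment over
# the candidate peak pairs (direct or precursor-shifted) and take the
# maximum total normalized sqrt-intensity product
oracle_modified_cosine <- function(a, b, fragment_tol, shift = TRUE) {
  norm_w <- function(v) { w <- sqrt(v); w / sqrt(sum(w^2)) }
  na <- norm_w(a$peaks[, 2])
  nb <- norm_w(b$peaks[, 2])
  delta <- b$precursor_mz - a$precursor_mz
  cand <- list()
  for (i in seq_len(nrow(a$peaks))) for (j in seq_len(nrow(b$peaks))) {
    d <- a$peaks[i, 1] - b$peaks[j, 1]
    if (abs(d) <= fragment_tol || (shift && abs(d + delta) <= fragment_tol))
      cand[[length(cand) + 1]] <- c(i, j)
  }
  best <- 0
  best_n <- 0L
  explore <- function(k, used_i, used_j, acc, nacc) {
    if (k > length(cand)) {
      if (acc > best + 1e-12 || (acc > best - 1e-12 && nacc > best_n)) {
        best <<- acc
        best_n <<- nacc
      }
      return(invisible())
    }
    p <- cand[[k]]
    if (!(p[1] %in% used_i) && !(p[2] %in% used_j))
      explore(k + 1L, c(used_i, p[1]), c(used_j, p[2]),
              acc + na[p[1]] * nb[p[2]], nacc + 1L)
    explore(k + 1L, used_i, used_j, acc, nacc)
  }
  explore(1L, integer(0), integer(0), 0, 0L)
  list(score = min(1, best), matched_peaks = best_n)
}

# exhaustive golden-triangle enumeration (canonical mode): loop over all
# (microbe, network edge) combinations and check conditions directly
oracle_triangles <- function(assoc, net, feature_map, rules, tol) {
  mapped <- merge(assoc, feature_map[c("feature_id", "node_id")],
                  by.x = "molecular_feature_id", by.y = "feature_id")
  # best edge per (microbe, node): min p, then max |rho|, then feature id
  pick <- function(m, nd) {
    sub <- mapped[mapped$microbial_feature_id == m & mapped$node_id == nd, ]
    if (nrow(sub) == 0) return(NULL)
    sub[order(sub$p_value, -abs(sub$rho), sub$molecular_feature_id), ][1, ]
  }
  node_mz <- sapply(net$nodes, function(n) n$precursor_mz)
  microbes <- unique(mapped$microbial_feature_id)
  out <- list()
  for (m in microbes) for (e in seq_len(nrow(net$edges))) {
    for (orient in 1:2) {
      s <- if (orient == 1) net$edges$node_a[e] else net$edges$node_b[e]
      p <- if (orient == 1) net$edges$node_b[e] else net$edges$node_a[e]
      es <- pick(m, s)
      ep <- pick(m, p)
      if (is.null(es) || is.null(ep)) next
      if (!(es$rho < 0 && ep$rho > 0)) next
      mr <- match_rule(node_mz[[s]], node_mz[[p]], rules, tol)
      out[[length(out) + 1]] <- data.frame(
        microbial_feature_id = m, substrate_node_id = s,
        product_node_id = p, rho_s = es$rho, rho_p = ep$rho,
        n_rules = nrow(mr), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(microbial_feature_id = character(0),
                      substrate_node_id = character(0),
                      product_node_id = character(0),
                      rho_s = numeric(0), rho_p = numeric(0),
                      n_rules = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$microbial_feature_id, df$substrate_node_id,
           df$product_node_id), ]
}

# compact spectrum constructor for toy fixtures
toy_spectrum <- function(id, prec, mz, intensity = rep(1, length(mz)),
                         cohort = NA_character_) {
  spectrum(id, prec, cbind(mz, intensity), cohort = cohort)
}
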