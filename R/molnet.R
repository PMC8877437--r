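# Spectral similarity, consensus clustering and molecular network assembly.
#
# All precursor arithmetic is on the m/z axis under a uniform singly charged
# [M+H]+ assumption; multiply charged species are out of scope.

.sqrt_norm <- function(intensity) {
  w <- sqrt(intensity)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) rep(0, length(w)) else w / nrm
}

# Exact maximum-total-weight one-to-one matching over a sparse candidate
# pair list, by branch and bound over pairs sorted by weight (descending).
# Candidate lists from real spectra are small and near conflict-free, so
# the search is shallow in practice. Among equal-weight optima the one with
# more matched pairs is preferred (deterministic given pair order).
.max_weight_matching <- function(i, j, w) {
  m <- length(w)
  if (m == 0) return(list(score = 0, n = 0L))
  ord <- order(-w, i, j)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  # conflict-free fast path
  if (!anyDuplicated(i) && !anyDuplicated(j))
    return(list(score = sum(w), n = m))
  suffix <- rev(cumsum(rev(w)))
  best_score <- -1
  best_n <- 0L
  used_i <- integer(0)
  used_j <- integer(0)
  rec <- function(k, acc_w, acc_n, used_i, used_j) {
    if (k > m) {
      if (acc_w > best_score + 1e-12 ||
          (acc_w > best_score - 1e-12 && acc_n > best_n)) {
        best_score <<- acc_w
        best_n <<- acc_n
      }
      return(invisible())
    }
    if (acc_w + suffix[k] < best_score - 1e-12) return(invisible())
    if (!(i[k] %in% used_i) && !(j[k] %in% used_j)) {
      rec(k + 1L, acc_w + w[k], acc_n + 1L, c(used_i, i[k]), c(used_j, j[k]))
    }
    rec(k + 1L, acc_w, acc_n, used_i, used_j)
    invisible()
  }
  rec(1L, 0, 0L, used_i, used_j)
  list(score = best_score, n = best_n)
}

.cosine_impl <- function(a, b, fragment_tol, shift) {
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0)
    stop("cosine of a spectrum with an empty peak list")
  na <- .sqrt_norm(a$peaks[, 2])
  nb <- .sqrt_norm(b$peaks[, 2])
  d <- outer(a$peaks[, 1], b$peaks[, 1], "-")
  cand <- abs(d) <= fragment_tol
  if (shift) {
    delta <- b$precursor_mz - a$precursor_mz
    cand <- cand | (abs(d + delta) <= fragment_tol)
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(score = 0, matched_peaks = 0L))
  w <- na[idx[, 1]] * nb[idx[, 2]]
  pos <- w > 0
  res <- .max_weight_matching(idx[pos, 1], idx[pos, 2], w[pos])
  list(score = min(1, res$score), matched_peaks = res$n)
}

#' Modification-tolerant (modified) cosine between two spectra
#'
#' Fragment peaks of `a` may match peaks of `b` either directly
#' (|mz_a - mz_b| <= `fragment_tol`) or shifted by the precursor mass
#' difference, which lets a spectrum match a structural analog whose single
#' modification displaces a subset of its fragments. Peak weights are
#' square-root intensities, unit-normalized per spectrum; the score is the
#' total weight of an exact maximum one-to-one assignment of candidate peak
#' pairs, so it lies in \[0, 1\], is symmetric, and reduces to the plain
#' cosine when both precursors are equal.
#'
#' @param a,b [spectrum()] objects with at least one peak each.
#' @param fragment_tol Fragment m/z tolerance in Da.
#' @return A list with `score` and `matched_peaks` (pairs in the optimal
#'   assignment).
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.02) {
  .cosine_impl(a, b, fragment_tol, shift = TRUE)
}

#' Plain spectral cosine (no modification shift)
#'
#' As [modified_cosine()] but fragment peaks match directly only; used when
#' merging replicate spectra of the same molecule into consensus nodes.
#'
#' @inheritParams modified_cosine
#' @return A list with `score` and `matched_peaks`.
#' @export
plain_cosine <- function(a, b, fragment_tol = 0.02) {
  .cosine_impl(a, b, fragment_tol, shift = FALSE)
}

# ---------------------------------------------------------------------------
# Consensus nodes

.make_node <- function(node_id, members, fragment_tol) {
  precs <- vapply(members, function(s) s$precursor_mz, numeric(1))
  tags <- unique(stats::na.omit(vapply(members, function(s) s$cohort,
                                       character(1))))
  pooled <- do.call(rbind, lapply(members, function(s) s$peaks))
  structure(list(node_id = node_id,
                 precursor_mz = stats::median(precs),
                 representative_peaks = .bin_peaks(pooled, fragment_tol),
                 member_ids = vapply(members, function(s) s$spectrum_id,
                                     character(1)),
                 member_precursors = precs,
                 cohort_tags = sort(tags)),
            class = "consensus_node")
}

# Intensity-weighted merge of pooled member peaks, binned at the fragment
# tolerance: scan ascending, start a new bin when the gap to the bin's
# weighted mean exceeds the tolerance.
.bin_peaks <- function(peaks, fragment_tol) {
  if (nrow(peaks) == 0) return(peaks)
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  out_mz <- numeric(0)
  out_int <- numeric(0)
  cur_mz <- peaks[1, 1]
  cur_int <- peaks[1, 2]
  if (nrow(peaks) > 1) for (k in 2:nrow(peaks)) {
    mzk <- peaks[k, 1]
    intk <- peaks[k, 2]
    if (mzk - cur_mz <= fragment_tol) {
      tot <- cur_int + intk
      cur_mz <- if (tot > 0) (cur_mz * cur_int + mzk * intk) / tot else
        (cur_mz + mzk) / 2
      cur_int <- tot
    } else {
      out_mz <- c(out_mz, cur_mz)
      out_int <- c(out_int, cur_int)
      cur_mz <- mzk
      cur_int <- intk
    }
  }
  out_mz <- c(out_mz, cur_mz)
  out_int <- c(out_int, cur_int)
  cbind(mz = out_mz, intensity = out_int)
}

#' @export
print.consensus_node <- function(x, ...) {
  cat("Consensus node ", x$node_id, ": precursor m/z ",
      format(x$precursor_mz, digits = 8), ", ", length(x$member_ids),
      " member spectrum(a), cohorts {", paste(x$cohort_tags, collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

# node representative as a spectrum object, for cosine scoring
.node_spectrum <- function(node) {
  structure(list(spectrum_id = node$node_id,
                 precursor_mz = node$precursor_mz,
                 retention_time = NULL, cohort = NA_character_,
                 peaks = node$representative_peaks),
            class = "spectrum")
}

#' Cluster near-identical spectra into consensus nodes
#'
#' Greedy single-pass clustering in the spirit of spectral pre-merging:
#' spectra are processed in descending total-intensity order (ties broken
#' by spectrum id); each spectrum joins the earliest-created node whose
#' consensus precursor lies within `precursor_tol` and whose representative
#' spectrum scores at least `merge_cosine` under the plain (unshifted)
#' cosine, otherwise it seeds a new node. The node's precursor is the median
#' of its members' precursors and its representative peak list is the
#' intensity-weighted merge of member peaks binned at `fragment_tol`.
#' The output partitions the input: every spectrum belongs to exactly one
#' node, and the procedure is deterministic.
#'
#' @param spectra Nonempty list of [spectrum()] objects.
#' @param precursor_tol Precursor m/z tolerance in Da (default 0.02, the
#'   standard qTOF setting).
#' @param merge_cosine Minimum plain cosine to join a node (default 0.7).
#' @param fragment_tol Fragment tolerance used in cosine scoring and peak
#'   binning.
#' @return List of `consensus_node` objects, ids `N001`, `N002`, ... in
#'   creation order.
#' @export
cluster_spectra <- function(spectra, precursor_tol = 0.02, merge_cosine = 0.7,
                            fragment_tol = 0.02) {
  if (length(spectra) == 0) stop("no spectra to cluster")
  tot <- vapply(spectra, function(s) sum(s$peaks[, 2]), numeric(1))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  ord <- order(-tot, ids)
  spectra <- spectra[ord]

  members <- list()      # list of lists of spectra per node
  node_prec <- numeric(0)
  reps <- list()         # representative spectrum per node
  for (s in spectra) {
    joined <- FALSE
    if (length(members) > 0) {
      near <- which(abs(node_prec - s$precursor_mz) <= precursor_tol)
      for (nd in near) {
        sc <- plain_cosine(reps[[nd]], s, fragment_tol)$score
        if (sc >= merge_cosine) {
          members[[nd]] <- c(members[[nd]], list(s))
          node <- .make_node("tmp", members[[nd]], fragment_tol)
          node_prec[nd] <- node$precursor_mz
          reps[[nd]] <- .node_spectrum(node)
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      members[[length(members) + 1]] <- list(s)
      node_prec[length(members)] <- s$precursor_mz
      reps[[length(members)]] <- s
    }
  }
  lapply(seq_along(members), function(k)
    .make_node(sprintf("N%03d", k), members[[k]], fragment_tol))
}

# ---------------------------------------------------------------------------
# Molecular network

.empty_network_edges <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             cosine = numeric(0), matched_peaks = integer(0),
             mass_delta = numeric(0), stringsAsFactors = FALSE)
}

.new_network <- function(nodes, edges, params) {
  names(nodes) <- vapply(nodes, function(n) n$node_id, character(1))
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  tags <- table(vapply(x$nodes, function(n)
    paste(n$cohort_tags, collapse = "+"), character(1)))
  cat("Molecular network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  cat("  cohorts:", paste(names(tags), tags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build a molecular network from consensus nodes
#'
#' Scores every node pair with the modified cosine on representative
#' spectra; an undirected edge is formed iff the score is at least
#' `cosine_threshold` and at least `min_matched_peaks` peak pairs are
#' matched. Each edge carries the absolute precursor mass difference, the
#' candidate mass shift of a chemical modification between the two
#' molecules.
#'
#' @param nodes Nonempty list of `consensus_node` objects.
#' @param cosine_threshold Minimum modified cosine (default 0.7, the
#'   standard molecular-networking default).
#' @param fragment_tol Fragment m/z tolerance in Da.
#' @param min_matched_peaks Minimum matched peak pairs per edge (default 6,
#'   guarding against spurious single-peak matches).
#' @return A `molecular_network`: list with `nodes` (named by node id),
#'   `edges` (data.frame `node_a`, `node_b`, `cosine`, `matched_peaks`,
#'   `mass_delta`) and `params`.
#' @export
build_molecular_network <- function(nodes, cosine_threshold = 0.7,
                                    fragment_tol = 0.02,
                                    min_matched_peaks = 6) {
  if (length(nodes) == 0) stop("no nodes")
  params <- list(cosine_threshold = cosine_threshold,
                 fragment_tol = fragment_tol,
                 min_matched_peaks = min_matched_peaks)
  n <- length(nodes)
  reps <- lapply(nodes, .node_spectrum)
  rows <- list()
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cs <- modified_cosine(reps[[i]], reps[[j]], fragment_tol)
    if (cs$score >= cosine_threshold && cs$matched_peaks >= min_matched_peaks) {
      rows[[length(rows) + 1]] <- data.frame(
        node_a = nodes[[i]]$node_id, node_b = nodes[[j]]$node_id,
        cosine = cs$score, matched_peaks = cs$matched_peaks,
        mass_delta = abs(nodes[[i]]$precursor_mz - nodes[[j]]$precursor_mz),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else .empty_network_edges()
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  .new_network(nodes, edges, params)
}

#' Merge cohort molecular networks (e.g. gut and food)
#'
#' A node from `gut` and a node from `food` are unified into a single
#' intersection node when their consensus precursors agree within `mass_tol`
#' and (unless `match = "mass_only"`) their representative spectra score at
#' least `cosine_threshold` under the plain cosine. Candidate pairs are
#' unified greedily by ascending precursor difference, one-to-one. Surviving
#' nodes are relabeled `M001`, `M002`, ... by ascending precursor m/z, carry
#' the union of member spectra and cohort tags, and get a `label` of
#' `"intersection"`, `"gut-unique"` or `"food-unique"`. Edges are recomputed
#' across the merged node set with the `gut` network's build parameters.
#'
#' @param gut,food `molecular_network` objects whose nodes carry cohort tags.
#' @param mass_tol Precursor agreement tolerance in Da (default 0.02).
#' @param fragment_tol Fragment tolerance for rebinning and cosine.
#' @param cosine_threshold Minimum cosine for node unification.
#' @param match `"mass_cosine"` (default) or `"mass_only"`.
#' @return A `molecular_network` over the merged node set; each node has a
#'   `label` field.
#' @export
merge_networks <- function(gut, food, mass_tol = 0.02, fragment_tol = 0.02,
                           cosine_threshold = 0.7,
                           match = c("mass_cosine", "mass_only")) {
  match <- match.arg(match)
  gn <- unname(gut$nodes)
  fn <- unname(food$nodes)
  # candidate unifications sorted by |precursor difference|
  cand <- list()
  for (i in seq_along(gn)) for (j in seq_along(fn)) {
    dm <- abs(gn[[i]]$precursor_mz - fn[[j]]$precursor_mz)
    if (dm <= mass_tol)
      cand[[length(cand) + 1]] <- c(i = i, j = j, dm = dm)
  }
  pair_i <- integer(0)
  pair_j <- integer(0)
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, "dm"], cand[, "i"], cand[, "j"]), , drop = FALSE]
    used_i <- logical(length(gn))
    used_j <- logical(length(fn))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (used_i[i] || used_j[j]) next
      ok <- match == "mass_only" ||
        plain_cosine(.node_spectrum(gn[[i]]), .node_spectrum(fn[[j]]),
                     fragment_tol)$score >= cosine_threshold
      if (ok) {
        used_i[i] <- TRUE
        used_j[j] <- TRUE
        pair_i <- c(pair_i, i)
        pair_j <- c(pair_j, j)
      }
    }
  }

  merged <- list()
  labels <- character(0)
  unify <- function(a, b) {
    pooled <- rbind(a$representative_peaks, b$representative_peaks)
    structure(list(node_id = "tmp",
                   precursor_mz = stats::median(c(a$member_precursors,
                                                  b$member_precursors)),
                   representative_peaks = .bin_peaks(pooled, fragment_tol),
                   member_ids = c(a$member_ids, b$member_ids),
                   member_precursors = c(a$member_precursors,
                                         b$member_precursors),
                   cohort_tags = sort(unique(c(a$cohort_tags, b$cohort_tags)))),
              class = "consensus_node")
  }
  for (k in seq_along(pair_i)) {
    merged[[length(merged) + 1]] <- unify(gn[[pair_i[k]]], fn[[pair_j[k]]])
    labels <- c(labels, "intersection")
  }
  for (i in setdiff(seq_along(gn), pair_i)) {
    merged[[length(merged) + 1]] <- gn[[i]]
    labels <- c(labels, "gut-unique")
  }
  for (j in setdiff(seq_along(fn), pair_j)) {
    merged[[length(merged) + 1]] <- fn[[j]]
    labels <- c(labels, "food-unique")
  }
  ord <- order(vapply(merged, function(n) n$precursor_mz, numeric(1)),
               vapply(merged, function(n) n$member_ids[1], character(1)))
  merged <- merged[ord]
  labels <- labels[ord]
  for (k in seq_along(merged)) {
    merged[[k]]$node_id <- sprintf("M%03d", k)
    merged[[k]]$label <- labels[k]
  }
  p <- gut$params
  net <- build_molecular_network(merged,
                                 cosine_threshold = p$cosine_threshold,
                                 fragment_tol = p$fragment_tol,
                                 min_matched_peaks = p$min_matched_peaks)
  net
}

#' Map molecular features onto network nodes by precursor mass
#'
#' Each feature is assigned to the node with the smallest absolute precursor
#' m/z difference within `mass_tol`; ties are broken by larger node member
#' count, then lexicographic node id. Unmatched features are omitted and
#' counted in `attr(, "n_unmatched")`.
#'
#' @param m An `intensity_matrix` carrying feature m/z.
#' @param net A `molecular_network`.
#' @param mass_tol Mass tolerance in Da (default 0.02).
#' @return data.frame with columns `feature_id`, `node_id`, `mass_error`.
#' @export
match_features_to_nodes <- function(m, net, mass_tol = 0.02) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(net, "molecular_network"))
  node_ids <- names(net$nodes)
  node_mz <- vapply(net$nodes, function(n) n$precursor_mz, numeric(1))
  node_size <- vapply(net$nodes, function(n) length(n$member_ids), integer(1))
  fids <- rownames(m$values)
  rows <- vector("list", length(fids))
  n_unmatched <- 0L
  for (k in seq_along(fids)) {
    err <- m$mz[k] - node_mz
    ok <- which(abs(err) <= mass_tol)
    if (length(ok) == 0) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    ok <- ok[order(abs(err[ok]), -node_size[ok], node_ids[ok])]
    best <- ok[1]
    rows[[k]] <- data.frame(feature_id = fids[k], node_id = node_ids[best],
                            mass_error = err[best], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(feature_id = character(0), node_id = character(0),
               mass_error = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

# ---------------------------------------------------------------------------
# Export

#' Export a molecular network
#'
#' `export_graphml()` writes nodes (precursor m/z, cohort label, member
#' count) and edges (cosine, matched peaks, mass delta) as GraphML via
#' igraph; `export_network_edges()` writes the flat CSV edge list.
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  nodes_df <- data.frame(
    name = names(net$nodes),
    precursor_mz = vapply(net$nodes, function(n) n$precursor_mz, numeric(1)),
    cohort = vapply(net$nodes, function(n)
      paste(n$cohort_tags, collapse = "+"), character(1)),
    label = vapply(net$nodes, function(n)
      if (is.null(n$label)) NA_character_ else n$label, character(1)),
    n_members = vapply(net$nodes, function(n) length(n$member_ids),
                       integer(1)),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges) > 0) net$edges else
      data.frame(node_a = character(0), node_b = character(0)),
    directed = FALSE, vertices = nodes_df)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_network_edges <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
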