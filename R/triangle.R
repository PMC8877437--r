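# Golden-triangle extraction: integration of the association network, the
# molecular network, and the mass-delta rule base.
#
# A golden triangle is a triplet (microbe, substrate node, product node)
# with (i) a positive microbe-product correlation, (ii) a negative
# microbe-substrate correlation, and (iii) a molecular-network edge between
# substrate and product. Correlation signs orient the undirected spectral
# edge into substrate -> product.

.empty_triangles <- function(mode) {
  out <- data.frame(
    microbial_feature_id = character(0),
    substrate_node_id = character(0), product_node_id = character(0),
    substrate_mz = numeric(0), product_mz = numeric(0),
    rho_s = numeric(0), p_s = numeric(0),
    rho_p = numeric(0), p_p = numeric(0),
    edge_cosine = numeric(0), mass_delta = numeric(0),
    matched_rules = character(0), rule_mass_error = numeric(0),
    rule_unmatched = logical(0), gut_unique_product = logical(0),
    mode = character(0), stringsAsFactors = FALSE)
  class(out) <- c("golden_triangles", "data.frame")
  out
}

#' Extract golden-triangle biotransformation candidates
#'
#' Enumerates triplets (microbial feature m, substrate node s, product node
#' p) such that (a) (s, p) is an edge of the molecular network, (b) the
#' association network links m to both endpoints with the canonical sign
#' pattern rho_s < 0 and rho_p > 0 (`mode = "canonical"`), and (c) at least
#' one biotransformation rule explains the precursor mass difference within
#' `tol`. Triplets failing (c) are retained with `rule_unmatched = TRUE`
#' unless `require_rule = TRUE`. `mode = "same_sign"` additionally admits
#' pairs of correlations sharing a sign (substrate-limited reactions where
#' more substrate also means more product); its output is a superset of the
#' canonical output.
#'
#' Orientation of the undirected spectral edge is decided by the sign
#' pattern first (the negatively correlated endpoint is the substrate); for
#' same-sign triplets, by which endpoint is annotated in `compound_db`
#' (when given), then by larger precursor mass as substrate.
#'
#' Association edges are expressed at node level through `feature_map`;
#' edges whose molecular feature is absent from the map are skipped with a
#' message. When several features map to one node, the (microbe, node) pair
#' is represented by the feature with the smallest p-value (then largest
#' |rho|, then feature id).
#'
#' Products observed only in the gut cohort (never in food) are flagged
#' `gut_unique_product`, marking in-host production; it is a flag, not a
#' filter.
#'
#' @param assoc Association edge data.frame
#'   (see [build_association_network()]).
#' @param net A `molecular_network`.
#' @param feature_map data.frame `feature_id`, `node_id` from
#'   [match_features_to_nodes()].
#' @param rules Rule data.frame (default [builtin_rules()]).
#' @param tol Rule mass tolerance in Da (default 0.02).
#' @param mode `"canonical"` (default) or `"same_sign"`.
#' @param require_rule Drop triplets not explained by any rule
#'   (default FALSE).
#' @param compound_db Optional compound table used only as an orientation
#'   tie-break for same-sign triplets.
#' @param parent_tol Parent-mass tolerance for the orientation tie-break.
#' @return A `golden_triangles` data.frame, one row per triplet, sorted by
#'   `max(|rho_s|, |rho_p|)` descending then ids.
#' @export
find_golden_triangles <- function(assoc, net, feature_map,
                                  rules = builtin_rules(), tol = 0.02,
                                  mode = c("canonical", "same_sign"),
                                  require_rule = FALSE,
                                  compound_db = NULL, parent_tol = 0.002) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "molecular_network"))
  if (nrow(assoc) == 0 || nrow(net$edges) == 0 || nrow(feature_map) == 0)
    return(.empty_triangles(mode))

  mapped <- merge(assoc, feature_map[c("feature_id", "node_id")],
                  by.x = "molecular_feature_id", by.y = "feature_id")
  n_skipped <- nrow(assoc) - nrow(mapped)
  if (n_skipped > 0)
    message("find_golden_triangles: ", n_skipped,
            " association edge(s) reference unmapped features; skipped")
  if (nrow(mapped) == 0) return(.empty_triangles(mode))

  # best association per (microbe, node): smallest p, then largest |rho|,
  # then feature id
  mapped <- mapped[order(mapped$microbial_feature_id, mapped$node_id,
                         mapped$p_value, -abs(mapped$rho),
                         mapped$molecular_feature_id), , drop = FALSE]
  key <- paste(mapped$microbial_feature_id, mapped$node_id, sep = "\r")
  mapped <- mapped[!duplicated(key), , drop = FALSE]
  key <- paste(mapped$microbial_feature_id, mapped$node_id, sep = "\r")
  lut <- split(seq_len(nrow(mapped)), mapped$node_id)

  node_mz <- vapply(net$nodes, function(n) n$precursor_mz, numeric(1))
  node_tags <- lapply(net$nodes, function(n) n$cohort_tags)
  annotated <- function(node_id) {
    if (is.null(compound_db)) return(FALSE)
    nrow(.derep_mz(node_mz[[node_id]], compound_db, parent_tol)) > 0
  }

  rows <- list()
  for (e in seq_len(nrow(net$edges))) {
    u <- net$edges$node_a[e]
    v <- net$edges$node_b[e]
    au <- mapped[lut[[u]], , drop = FALSE]
    av <- mapped[lut[[v]], , drop = FALSE]
    if (nrow(au) == 0 || nrow(av) == 0) next
    shared <- intersect(au$microbial_feature_id, av$microbial_feature_id)
    for (m in shared) {
      eu <- au[au$microbial_feature_id == m, ][1, ]
      ev <- av[av$microbial_feature_id == m, ][1, ]
      if (eu$rho == 0 || ev$rho == 0) next
      s_id <- p_id <- NULL
      if (eu$rho < 0 && ev$rho > 0) { s_id <- u; p_id <- v }
      else if (ev$rho < 0 && eu$rho > 0) { s_id <- v; p_id <- u }
      else if (mode == "same_sign") {
        ann_u <- annotated(u)
        ann_v <- annotated(v)
        if (ann_u != ann_v) {
          if (ann_u) { s_id <- u; p_id <- v } else { s_id <- v; p_id <- u }
        } else if (node_mz[[u]] >= node_mz[[v]]) { s_id <- u; p_id <- v }
        else { s_id <- v; p_id <- u }
      } else next
      es <- if (s_id == u) eu else ev
      ep <- if (s_id == u) ev else eu
      s_mz <- node_mz[[s_id]]
      p_mz <- node_mz[[p_id]]
      mr <- match_rule(s_mz, p_mz, rules, tol)
      if (require_rule && nrow(mr) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        microbial_feature_id = m,
        substrate_node_id = s_id, product_node_id = p_id,
        substrate_mz = s_mz, product_mz = p_mz,
        rho_s = es$rho, p_s = es$p_value,
        rho_p = ep$rho, p_p = ep$p_value,
        edge_cosine = net$edges$cosine[e],
        mass_delta = p_mz - s_mz,
        matched_rules = paste(mr$rule_name, collapse = ";"),
        rule_mass_error = if (nrow(mr) > 0) mr$mass_error[1] else NA_real_,
        rule_unmatched = nrow(mr) == 0,
        gut_unique_product = identical(node_tags[[p_id]], "gut"),
        mode = mode, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(.empty_triangles(mode))
  out <- do.call(rbind, rows)
  strength <- pmax(abs(out$rho_s), abs(out$rho_p))
  out <- out[order(-strength, out$microbial_feature_id,
                   out$substrate_node_id, out$product_node_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("golden_triangles", "data.frame")
  out
}

#' @export
print.golden_triangles <- function(x, ...) {
  # column subsets lose the full schema; print those as plain data.frames
  show <- c("microbial_feature_id", "substrate_node_id", "product_node_id",
            "rho_s", "rho_p", "edge_cosine", "matched_rules")
  if (!all(c(show, "rule_unmatched", "gut_unique_product") %in% names(x)))
    return(print.data.frame(x, ...))
  cat("Golden triangles:", nrow(x), "candidate biotransformation(s)\n")
  if (nrow(x) > 0) {
    cat("  rule-matched:", sum(!x$rule_unmatched),
        "| gut-unique products:", sum(x$gut_unique_product), "\n")
    print.data.frame(utils::head(as.data.frame(x)[show], 10))
  }
  invisible(x)
}

#' Annotate triangle substrates against a compound database
#'
#' Parent-mass dereplication of each triangle's substrate node; triangles
#' whose substrate matches no compound keep an empty annotation (they are
#' never dropped). Adds columns `substrate_name` (all matches, `;`-joined,
#' best first), `substrate_mass_error` (best match) and
#' `n_substrate_annotations`.
#'
#' @param triangles A `golden_triangles` data.frame.
#' @param db Compound table from [compound_db()].
#' @param parent_tol Parent mass tolerance in Da (default 0.002).
#' @return The annotated `golden_triangles` data.frame.
#' @export
annotate_triangles <- function(triangles, db, parent_tol = 0.002) {
  n <- nrow(triangles)
  triangles$substrate_name <- rep(NA_character_, n)
  triangles$substrate_mass_error <- rep(NA_real_, n)
  triangles$n_substrate_annotations <- rep(0L, n)
  if (n == 0 || nrow(db) == 0) return(triangles)
  for (k in seq_len(n)) {
    ann <- .derep_mz(triangles$substrate_mz[k], db, parent_tol)
    if (nrow(ann) > 0) {
      triangles$substrate_name[k] <- paste(ann$compound_name, collapse = ";")
      triangles$substrate_mass_error[k] <- ann$mass_error[1]
      triangles$n_substrate_annotations[k] <- nrow(ann)
    }
  }
  triangles
}

#' Write golden triangles to CSV
#'
#' One row per triangle mirroring the candidate-table layout: substrate
#' annotation, matched rule(s), microbial feature, the two correlations with
#' p-values, spectral cosine, mass delta and rule mass error, flags and mode.
#' An empty input yields a header-only CSV.
#'
#' @param triangles A `golden_triangles` data.frame (annotated or not).
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
report_triangles <- function(triangles, out_path) {
  df <- as.data.frame(triangles)
  if (is.null(df$substrate_name)) {
    df$substrate_name <- rep(NA_character_, nrow(df))
    df$substrate_mass_error <- rep(NA_real_, nrow(df))
  }
  cols <- c("substrate_name", "matched_rules", "microbial_feature_id",
            "substrate_node_id", "product_node_id", "substrate_mz",
            "product_mz", "rho_s", "p_s", "rho_p", "p_p", "edge_cosine",
            "mass_delta", "rule_mass_error", "substrate_mass_error",
            "rule_unmatched", "gut_unique_product", "mode")
  ok <- tryCatch({
    utils::write.csv(df[cols], out_path, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write triangle report to '", out_path, "': ",
         conditionMessage(ok))
  invisible(out_path)
}

#' Read a triangle report back
#' @param path CSV path written by [report_triangles()].
#' @return data.frame.
#' @export
read_triangle_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
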