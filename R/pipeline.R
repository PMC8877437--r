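#' Run the full biotransformation discovery pipeline
#'
#' Convenience wrapper chaining the individual stages: rare-feature
#' filtering, sample alignment, Spearman association network, spectral
#' clustering into consensus nodes, molecular network construction (with
#' optional food-cohort merging), feature-to-node mass matching,
#' golden-triangle extraction and substrate annotation.
#'
#' @param molecules An `intensity_matrix` of molecular features.
#' @param microbes A `count_matrix` of microbial (or enzymatic) features;
#'   an enzyme-kind matrix flows through identically.
#' @param gut_spectra List of [spectrum()] objects from the host cohort.
#' @param food_spectra Optional list of spectra from the diet cohort; when
#'   given, the two molecular networks are merged and products absent from
#'   food are flagged gut-unique.
#' @param compound_db Optional compound table for substrate annotation.
#' @param rules Biotransformation rules (default [builtin_rules()]).
#' @param p_threshold,rho_threshold Association filters (defaults 1e-4
#'   and 0.1).
#' @param cosine_threshold Molecular network edge threshold (default 0.7).
#' @param precursor_tol Precursor/cluster/feature-map mass tolerance in Da
#'   (default 0.02).
#' @param fragment_tol Fragment tolerance in Da (default 0.02).
#' @param min_matched_peaks Minimum matched peaks per network edge
#'   (default 6).
#' @param rule_tol Rule-matching tolerance in Da (default 0.02).
#' @param parent_tol Dereplication parent-mass tolerance in Da
#'   (default 0.002).
#' @param mode Triangle mode, `"canonical"` or `"same_sign"`.
#' @param require_rule Drop rule-unmatched triangles (default FALSE).
#' @return List of class `biotrans_result` with `triangles`, `network`,
#'   `assoc`, `feature_map`, and the filtered/aligned inputs.
#' @export
discover_biotransformations <- function(molecules, microbes, gut_spectra,
                                        food_spectra = NULL,
                                        compound_db = NULL,
                                        rules = builtin_rules(),
                                        p_threshold = 1e-4,
                                        rho_threshold = 0.1,
                                        cosine_threshold = 0.7,
                                        precursor_tol = 0.02,
                                        fragment_tol = 0.02,
                                        min_matched_peaks = 6,
                                        rule_tol = 0.02,
                                        parent_tol = 0.002,
                                        mode = c("canonical", "same_sign"),
                                        require_rule = FALSE) {
  mode <- match.arg(mode)
  molecules <- filter_rare_features(molecules)
  aligned <- align_samples(molecules, microbes)
  assoc <- build_association_network(aligned$molecules, aligned$microbes,
                                     p_threshold = p_threshold,
                                     rho_threshold = rho_threshold)
  gut_nodes <- cluster_spectra(gut_spectra, precursor_tol = precursor_tol,
                               merge_cosine = cosine_threshold,
                               fragment_tol = fragment_tol)
  net <- build_molecular_network(gut_nodes,
                                 cosine_threshold = cosine_threshold,
                                 fragment_tol = fragment_tol,
                                 min_matched_peaks = min_matched_peaks)
  if (!is.null(food_spectra) && length(food_spectra) > 0) {
    food_nodes <- cluster_spectra(food_spectra,
                                  precursor_tol = precursor_tol,
                                  merge_cosine = cosine_threshold,
                                  fragment_tol = fragment_tol)
    food_net <- build_molecular_network(food_nodes,
                                        cosine_threshold = cosine_threshold,
                                        fragment_tol = fragment_tol,
                                        min_matched_peaks = min_matched_peaks)
    net <- merge_networks(net, food_net, mass_tol = precursor_tol,
                          fragment_tol = fragment_tol,
                          cosine_threshold = cosine_threshold)
  }
  feature_map <- match_features_to_nodes(aligned$molecules, net,
                                         mass_tol = precursor_tol)
  triangles <- find_golden_triangles(assoc, net, feature_map, rules = rules,
                                     tol = rule_tol, mode = mode,
                                     require_rule = require_rule,
                                     compound_db = compound_db,
                                     parent_tol = parent_tol)
  if (!is.null(compound_db))
    triangles <- annotate_triangles(triangles, compound_db,
                                    parent_tol = parent_tol)
  structure(list(triangles = triangles, network = net, assoc = assoc,
                 feature_map = feature_map, molecules = aligned$molecules,
                 microbes = aligned$microbes),
            class = "biotrans_result")
}

#' @export
print.biotrans_result <- function(x, ...) {
  cat("Biotransformation discovery result\n")
  cat("  association edges:", nrow(x$assoc), "\n")
  cat("  network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges\n", sep = "")
  cat("  mapped features:", nrow(x$feature_map), "\n")
  print(x$triangles)
  invisible(x)
}
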