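test_that("modified cosine is 1 on self, 0 with no candidates, and errors on empty", {
  s <- toy_spectrum("s", 300.1, c(80.1, 120.2, 150.3), c(5, 10, 2))
  self <- modified_cosine(s, s)
  expect_equal(self$score, 1)
  expect_equal(self$matched_peaks, 3L)

  far <- toy_spectrum("f", 300.1, c(90.5, 130.9), c(1, 1))
  none <- modified_cosine(s, far, fragment_tol = 0.02)
  expect_equal(none$score, 0)
  expect_equal(none$matched_peaks, 0L)

  empty <- suppressWarnings(spectrum("e", 100, matrix(numeric(0), 0, 2)))
  expect_error(modified_cosine(s, empty), "empty peak list")
})

test_that("modified cosine equals the brute-force assignment oracle", {
  set.seed(77)
  for (k in 1:30) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    # crowded m/z range + generous tolerance forces assignment conflicts
    a <- toy_spectrum("a", runif(1, 95, 105),
                      sort(runif(na, 50, 60)), runif(na, 1, 100))
    b <- toy_spectrum("b", runif(1, 95, 105),
                      sort(runif(nb, 50, 60)), runif(nb, 1, 100))
    got <- modified_cosine(a, b, fragment_tol = 1.5)
    want <- oracle_modified_cosine(a, b, fragment_tol = 1.5)
    expect_equal(got$score, want$score, tolerance = 1e-10)
    expect_equal(got$matched_peaks, want$matched_peaks)
    # symmetry and bounds
    rev <- modified_cosine(b, a, fragment_tol = 1.5)
    expect_equal(rev$score, got$score, tolerance = 1e-10)
    expect_true(got$score >= 0 && got$score <= 1 + 1e-12)
  }
})

test_that("modified cosine reduces to the plain cosine at equal precursors", {
  set.seed(8)
  a <- toy_spectrum("a", 250, sort(runif(5, 60, 200)), runif(5, 1, 50))
  b <- toy_spectrum("b", 250, sort(runif(5, 60, 200)), runif(5, 1, 50))
  expect_equal(modified_cosine(a, b, 5)$score, plain_cosine(a, b, 5)$score,
               tolerance = 1e-12)
})

test_that("clustering merges replicates and separates distinct precursors", {
  s <- toy_spectrum("s1", 300.1, c(80.1, 120.2, 150.3), c(5, 10, 2))
  copies <- lapply(1:4, function(k) {
    s2 <- s; s2$spectrum_id <- paste0("copy", k); s2
  })
  nodes <- cluster_spectra(copies)
  expect_length(nodes, 1)
  expect_length(nodes[[1]]$member_ids, 4)
  expect_equal(nodes[[1]]$precursor_mz, 300.1)

  other <- toy_spectrum("other", 310.1, c(80.1, 120.2, 150.3), c(5, 10, 2))
  nodes2 <- cluster_spectra(list(s, other), precursor_tol = 0.02)
  expect_length(nodes2, 2)
})

test_that("clustering recovers a planted partition and partitions the input", {
  set.seed(21)
  groups <- list(
    list(prec = 180.08, mz = sort(runif(6, 60, 160))),
    list(prec = 264.12, mz = sort(runif(6, 60, 240))),
    list(prec = 342.17, mz = sort(runif(6, 60, 320))))
  spectra <- list()
  for (g in seq_along(groups)) for (r in 1:4) {
    ints <- rlnorm(6, log(100), 0.1)  # near-identical within group
    spectra[[length(spectra) + 1]] <- toy_spectrum(
      sprintf("g%d_r%d", g, r), groups[[g]]$prec + runif(1, -0.005, 0.005),
      groups[[g]]$mz, ints)
  }
  nodes <- cluster_spectra(spectra, precursor_tol = 0.02, merge_cosine = 0.7)
  expect_length(nodes, 3)
  planted <- sub("_r\\d+$", "", vapply(spectra, function(s) s$spectrum_id,
                                       character(1)))
  for (nd in nodes) {
    expect_length(unique(sub("_r\\d+$", "", nd$member_ids)), 1)
    expect_length(nd$member_ids, 4)
  }
  # partition: every input spectrum in exactly one node
  all_members <- unlist(lapply(nodes, function(n) n$member_ids))
  expect_setequal(all_members, vapply(spectra, function(s) s$spectrum_id,
                                      character(1)))
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("network edges obey the cosine threshold boundary and match brute force", {
  set.seed(31)
  # 8 nodes: 4 related pairs + mutual strangers
  spectra <- list()
  base_prec <- c(200, 260, 320, 380)
  for (g in 1:4) {
    mz <- sort(runif(8, 60, base_prec[g] - 20))
    ints <- rlnorm(8, log(100), 0.3)
    spectra[[2 * g - 1]] <- toy_spectrum(sprintf("p%da", g), base_prec[g],
                                         mz, ints)
    # analog: same fragments, 3 shifted by +14.0157
    mz2 <- mz; mz2[6:8] <- mz2[6:8] + 14.0157
    spectra[[2 * g]] <- toy_spectrum(sprintf("p%db", g),
                                     base_prec[g] + 14.0157, sort(mz2), ints)
  }
  nodes <- cluster_spectra(spectra, precursor_tol = 0.02)
  expect_length(nodes, 8)
  net <- build_molecular_network(nodes, cosine_threshold = 0.7,
                                 min_matched_peaks = 6)
  expect_equal(nrow(net$edges), 4L)
  # brute-force all-pairs check
  reps <- net$nodes
  ids <- names(reps)
  want <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    s1 <- toy_spectrum(ids[i], reps[[i]]$precursor_mz,
                       reps[[i]]$representative_peaks[, 1],
                       reps[[i]]$representative_peaks[, 2])
    s2 <- toy_spectrum(ids[j], reps[[j]]$precursor_mz,
                       reps[[j]]$representative_peaks[, 1],
                       reps[[j]]$representative_peaks[, 2])
    cs <- oracle_modified_cosine(s1, s2, 0.02)
    if (cs$score >= 0.7 && cs$matched_peaks >= 6) want <- want + 1L
  }
  expect_equal(nrow(net$edges), want)
  # a node and its uniformly shifted analog connect with score 1
  twin <- cluster_spectra(list(spectra[[1]],
                               toy_spectrum("twin", 225,
                                            spectra[[1]]$peaks[, 1] + 25,
                                            spectra[[1]]$peaks[, 2])))
  net2 <- build_molecular_network(twin, min_matched_peaks = 6)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$cosine, 1, tolerance = 1e-9)
  # boundary: a threshold just above an edge's score removes it
  sc <- net$edges$cosine[1]
  net3 <- build_molecular_network(nodes, cosine_threshold = min(sc + 1e-6, 1),
                                  min_matched_peaks = 6)
  expect_lt(nrow(net3$edges), nrow(net$edges) + 1)
  net4 <- build_molecular_network(nodes, cosine_threshold = 0.99999,
                                  min_matched_peaks = 6)
  key <- function(e) paste(e$node_a, e$node_b)
  expect_true(all(key(net4$edges) %in% key(net$edges)))
})

test_that("cohort networks merge on shared precursors and label uniqueness", {
  set.seed(41)
  mk <- function(prec, tag, id) {
    toy_spectrum(id, prec, sort(runif(7, 60, prec - 20)),
                 rlnorm(7, log(50), 0.2), cohort = tag)
  }
  shared1 <- mk(210.10, "gut", "g1")
  shared2 <- mk(330.15, "gut", "g2")
  g3 <- mk(452.19, "gut", "g3")
  f_shared1 <- shared1; f_shared1$spectrum_id <- "f1"; f_shared1$cohort <- "food"
  f_shared2 <- shared2; f_shared2$spectrum_id <- "f2"; f_shared2$cohort <- "food"
  f3 <- mk(140.06, "food", "f3")

  gut <- build_molecular_network(cluster_spectra(list(shared1, shared2, g3)))
  food <- build_molecular_network(cluster_spectra(list(f_shared1, f_shared2,
                                                       f3)))
  merged <- merge_networks(gut, food)
  labels <- vapply(merged$nodes, function(n) n$label, character(1))
  expect_equal(sum(labels == "intersection"), 2L)
  expect_equal(sum(labels == "gut-unique"), 1L)
  expect_equal(sum(labels == "food-unique"), 1L)
  expect_equal(length(merged$nodes), 4L)
  inter <- merged$nodes[[which(labels == "intersection")[1]]]
  expect_setequal(inter$cohort_tags, c("food", "gut"))

  # disjoint mass ranges: node count is the sum, no intersections
  lo <- build_molecular_network(cluster_spectra(list(mk(150.1, "gut", "a"),
                                                     mk(170.2, "gut", "b"))))
  hi <- build_molecular_network(cluster_spectra(list(mk(400.3, "food", "c"),
                                                     mk(420.4, "food", "d"))))
  dis <- merge_networks(lo, hi)
  expect_equal(length(dis$nodes), 4L)
  expect_true(all(vapply(dis$nodes, function(n) n$label, character(1)) !=
                    "intersection"))

  # a network merged with a relabeled copy of itself is all intersection
  dup <- merge_networks(gut, gut)
  expect_true(all(vapply(dup$nodes, function(n) n$label,
                         character(1)) == "intersection"))
  expect_equal(length(dup$nodes), length(gut$nodes))
})

test_that("features map to the nearest node within tolerance", {
  set.seed(51)
  s <- lapply(1:3, function(k)
    toy_spectrum(paste0("s", k), c(165.060, 165.10, 280.2)[k],
                 sort(runif(6, 60, 150)), rlnorm(6)))
  net <- build_molecular_network(cluster_spectra(s))
  vals <- matrix(1:9, 3, dimnames = list(c("fA", "fB", "fC"),
                                         c("x", "y", "z")))
  m <- intensity_matrix(vals, mz = c(165.054, 165.095, 500.0))
  map <- match_features_to_nodes(m, net, mass_tol = 0.02)
  expect_equal(nrow(map), 2L)
  expect_equal(attr(map, "n_unmatched"), 1L)
  # fA sits 0.006 from node at 165.060 and 0.041 from 165.10
  nd_mz <- vapply(net$nodes, function(n) n$precursor_mz, numeric(1))
  expect_equal(nd_mz[[map$node_id[map$feature_id == "fA"]]], 165.060)
  expect_equal(nd_mz[[map$node_id[map$feature_id == "fB"]]], 165.10)

  # planted 1:1 recovery under jitter < tol/2
  prec <- seq(200, 400, length.out = 50)
  sp <- lapply(seq_along(prec), function(k)
    toy_spectrum(paste0("n", k), prec[k], sort(runif(6, 60, 180)), rlnorm(6)))
  net50 <- build_molecular_network(cluster_spectra(sp),
                                   cosine_threshold = 1.01)
  jit <- prec + runif(50, -0.009, 0.009)
  m50 <- intensity_matrix(matrix(1, 50, 3,
                                 dimnames = list(sprintf("f%02d", 1:50),
                                                 c("a", "b", "c"))),
                          mz = jit)
  map50 <- match_features_to_nodes(m50, net50, mass_tol = 0.02)
  expect_equal(nrow(map50), 50L)
  got_mz <- vapply(map50$node_id, function(id) net50$nodes[[id]]$precursor_mz,
                   numeric(1))
  expect_equal(unname(got_mz), prec, tolerance = 1e-9)
})

test_that("networks export to GraphML and CSV", {
  set.seed(61)
  s1 <- toy_spectrum("a", 200, sort(runif(7, 60, 180)), rlnorm(7),
                     cohort = "gut")
  s2 <- s1; s2$spectrum_id <- "b"; s2$precursor_mz <- 200.001
  net <- build_molecular_network(cluster_spectra(list(s1, s2)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_network_edges(net, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(net$edges))
})
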