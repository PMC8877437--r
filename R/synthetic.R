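# Synthetic paired microbiome/metabolome cohorts with planted
# biotransformations, so the whole pipeline is testable without external
# data. The generator embodies the golden-triangle hypothesis generatively:
# for each planted triplet, substrate intensity decreases and product
# intensity increases monotonically with the abundance of one microbe, and
# the substrate/product spectra share fragments with a subset shifted by the
# rule's mass delta.

# run expr under a private RNG stream seeded once; global .Random.seed is
# restored afterwards (no global state)
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Reference phenolic compounds for examples and simulations
#'
#' A small table of dietary phenolics (plus riboflavin) commonly observed in
#' gut metabolomes, with monoisotopic masses computed from their molecular
#' formulas via element monoisotopic masses.
#'
#' @return A compound table (see [compound_db()]) with a `formula` column.
#' @export
example_compounds <- function() {
  tab <- rbind(
    c("p-coumaric acid", "C9H8O3"),
    c("caffeic acid", "C9H8O4"),
    c("ferulic acid", "C10H10O4"),
    c("4-hydroxybenzoic acid", "C7H6O3"),
    c("protocatechuic acid", "C7H6O4"),
    c("vanillic acid", "C8H8O4"),
    c("3-phenylpropionic acid", "C9H10O2"),
    c("dihydrocaffeic acid", "C9H10O4"),
    c("matairesinol", "C20H22O6"),
    c("riboflavin", "C17H20N4O6"))
  df <- data.frame(compound_name = tab[, 1],
                   monoisotopic_mass = vapply(paste0("+", tab[, 2]),
                                              formula_mass_delta, numeric(1)),
                   stringsAsFactors = FALSE)
  out <- compound_db(df)
  out$formula <- tab[, 2]
  out
}

# draw k values in [lo, hi] pairwise (and vs `avoid`) separated by > spacing
.spaced_uniform <- function(k, lo, hi, spacing, avoid = numeric(0)) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < k) {
    x <- stats::runif(1, lo, hi)
    if (all(abs(x - c(out, avoid)) > spacing)) out <- c(out, x)
    guard <- guard + 1L
    if (guard > 10000L * k)
      stop("cannot place ", k, " m/z values with spacing ", spacing)
  }
  out
}

# random fragment spectrum for a molecule at precursor `mz`; when `delta`
# and `shift_idx` are given, those fragments must stay clear of the others
# after shifting (so direct and shifted matches are unambiguous)
.synth_fragments <- function(mz, n_peaks, delta = 0) {
  lo <- 60
  hi <- max(lo + 10, mz - 20)
  repeat {
    frags <- sort(.spaced_uniform(n_peaks, lo, hi, spacing = 0.5))
    if (delta == 0) return(frags)
    shifted <- frags + delta
    if (all(shifted > 1) &&
        min(abs(outer(shifted, frags, "-"))) > 0.1) return(frags)
  }
}

#' Simulate a paired microbiome/metabolome cohort with planted
#' biotransformations
#'
#' Microbial abundances are lognormal per sample (counts Poisson-sampled
#' from the lognormal means). Each of the `n_planted` triplets takes a
#' reference phenolic compound as substrate, one built-in rule, and one
#' microbe: with `g` a Hill-type saturating function of microbe abundance
#' (exponent 2, half-saturation at the microbe's median abundance), the
#' substrate intensity is `baseline * (1 - effect_strength * g)` and the
#' product intensity `baseline * effect_strength * g`, both under
#' multiplicative lognormal noise of scale `noise_sd`. Unplanted molecules
#' are drawn independently of all microbes. Substrate and product spectra
#' share `n_peaks` fragments, half of them shifted by the rule's mass delta,
#' so their modified cosine is ~1; unplanted spectra carry unrelated random
#' fragments. Food-cohort spectra contain the substrates and unplanted
#' molecules but never planted products, making products gut-unique.
#'
#' Rules are assigned to substrates cyclically from [builtin_rules()],
#' skipping any assignment whose product m/z would land within 0.06 Da of an
#' existing feature (so every synthetic molecule is mass-resolvable at the
#' 0.02 Da tolerance).
#'
#' The cohort is fully reproducible from its parameters and `seed`; the
#' generator uses one private pseudo-random stream and leaves the global RNG
#' state untouched.
#'
#' @param n_samples Number of subjects (>= 10).
#' @param n_microbes Number of microbial features.
#' @param n_molecules Number of molecular features (>= 2 * n_planted).
#' @param n_planted Number of planted biotransformations
#'   (<= min(n_microbes, n_molecules / 2) and <= available substrates).
#' @param noise_sd Scale of multiplicative lognormal intensity noise
#'   (0 = noise-free).
#' @param effect_strength Planted effect size in (0, 1].
#' @param n_peaks Fragment peaks per spectrum.
#' @param seed Integer seed.
#' @return An object of class `synthetic_cohort`: list with `molecules`
#'   (intensity_matrix), `microbes` (count_matrix), `spectra_gut`,
#'   `spectra_food`, `compound_db`, `rules`, `truth` (data.frame of planted
#'   triplets) and `seed`.
#' @export
simulate_cohort <- function(n_samples = 200, n_microbes = 30,
                            n_molecules = 100, n_planted = 5,
                            noise_sd = 0.2, effect_strength = 0.8,
                            n_peaks = 8, seed = 1) {
  if (n_samples < 10) stop("need n_samples >= 10, got ", n_samples)
  if (n_planted > min(n_microbes, n_molecules / 2))
    stop("infeasible: n_planted (", n_planted,
         ") > min(n_microbes, n_molecules/2)")
  if (effect_strength <= 0 || effect_strength > 1)
    stop("effect_strength must be in (0, 1]")
  db <- example_compounds()
  if (n_planted > nrow(db))
    stop("at most ", nrow(db), " planted substrates available")
  rules <- builtin_rules()

  .with_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    microbe_ids <- sprintf("microbe_%02d", seq_len(n_microbes))
    mol_ids <- sprintf("mol_%03d", seq_len(n_molecules))

    # --- microbes: lognormal abundance, Poisson counts ---
    mu <- stats::runif(n_microbes, log(20), log(200))
    abund <- matrix(0, n_microbes, n_samples,
                    dimnames = list(microbe_ids, sample_ids))
    for (y in seq_len(n_microbes))
      abund[y, ] <- stats::rlnorm(n_samples, mu[y], sdlog = 1)
    counts <- matrix(stats::rpois(length(abund), abund), n_microbes,
                     dimnames = dimnames(abund))

    # --- planted triplets: compound, rule (collision-free), microbe ---
    sub_mz <- db$adduct_mz[seq_len(n_planted)]
    rule_idx <- integer(n_planted)
    prod_mz <- numeric(n_planted)
    taken <- db$adduct_mz[seq_len(n_planted)]
    for (i in seq_len(n_planted)) {
      found <- FALSE
      for (off in 0:(nrow(rules) - 1)) {
        r <- (i - 1 + off) %% nrow(rules) + 1
        pm <- sub_mz[i] + rules$mass_delta[r]
        if (pm > 50 && all(abs(pm - taken) > 0.06)) {
          rule_idx[i] <- r
          prod_mz[i] <- pm
          taken <- c(taken, pm)
          found <- TRUE
          break
        }
      }
      if (!found)
        stop("infeasible: no rule yields a mass-resolvable product for ",
             db$compound_name[i])
    }
    planted_microbe <- seq_len(n_planted)  # microbe i drives triplet i

    # --- molecule features: planted substrates/products + unplanted ---
    n_unpl <- n_molecules - 2 * n_planted
    unpl_mz <- .spaced_uniform(n_unpl, 150, 500, spacing = 0.1, avoid = taken)
    mol_mz <- numeric(n_molecules)
    pos <- sample.int(n_molecules)
    sub_pos <- pos[seq_len(n_planted)]
    prod_pos <- pos[n_planted + seq_len(n_planted)]
    unpl_pos <- pos[2 * n_planted + seq_len(n_unpl)]
    mol_mz[sub_pos] <- sub_mz
    mol_mz[prod_pos] <- prod_mz
    mol_mz[unpl_pos] <- unpl_mz

    # --- intensities ---
    intens <- matrix(0, n_molecules, n_samples,
                     dimnames = list(mol_ids, sample_ids))
    baseline <- stats::rlnorm(n_molecules, log(1e5), 0.5)
    noise <- function() if (noise_sd > 0)
      exp(stats::rnorm(n_samples, 0, noise_sd)) else 1
    for (i in seq_len(n_planted)) {
      a <- abund[planted_microbe[i], ]
      K <- exp(mu[planted_microbe[i]])
      g <- a^2 / (a^2 + K^2)
      intens[sub_pos[i], ] <- baseline[sub_pos[i]] *
        (1 - effect_strength * g) * noise()
      intens[prod_pos[i], ] <- baseline[prod_pos[i]] *
        effect_strength * g * noise()
    }
    for (k in unpl_pos)
      intens[k, ] <- baseline[k] * exp(stats::rnorm(n_samples, 0, 0.5))

    # --- spectra ---
    spectra_gut <- vector("list", n_molecules)
    spectra_food <- list()
    frag_int <- function(n) stats::rlnorm(n, log(1000), 0.7)
    prod_frags <- vector("list", n_planted)
    for (i in seq_len(n_planted)) {
      delta <- prod_mz[i] - sub_mz[i]
      frags <- .synth_fragments(sub_mz[i], n_peaks, delta = delta)
      ints <- frag_int(n_peaks)
      shift_set <- seq_len(n_peaks) > n_peaks / 2  # shift the upper half
      pfr <- frags
      pfr[shift_set] <- pfr[shift_set] + delta
      spectra_gut[[sub_pos[i]]] <- spectrum(
        paste0("gut_", mol_ids[sub_pos[i]]), sub_mz[i],
        cbind(frags, ints), cohort = "gut")
      spectra_gut[[prod_pos[i]]] <- spectrum(
        paste0("gut_", mol_ids[prod_pos[i]]), prod_mz[i],
        cbind(pfr, ints), cohort = "gut")
      prod_frags[[i]] <- list(frags = frags, ints = ints)
    }
    for (k in unpl_pos)
      spectra_gut[[k]] <- spectrum(paste0("gut_", mol_ids[k]), mol_mz[k],
                                   cbind(.synth_fragments(mol_mz[k], n_peaks),
                                         frag_int(n_peaks)), cohort = "gut")
    # food: substrates + unplanted molecules, slight replicate jitter
    for (i in seq_len(n_planted)) {
      f <- prod_frags[[i]]
      spectra_food[[length(spectra_food) + 1]] <- spectrum(
        paste0("food_", mol_ids[sub_pos[i]]), sub_mz[i],
        cbind(f$frags, f$ints * exp(stats::rnorm(n_peaks, 0, 0.05))),
        cohort = "food")
    }
    for (k in unpl_pos) {
      g <- spectra_gut[[k]]
      spectra_food[[length(spectra_food) + 1]] <- spectrum(
        paste0("food_", mol_ids[k]), mol_mz[k],
        cbind(g$peaks[, 1],
              g$peaks[, 2] * exp(stats::rnorm(n_peaks, 0, 0.05))),
        cohort = "food")
    }

    truth <- data.frame(
      microbe_id = microbe_ids[planted_microbe],
      substrate_feature_id = mol_ids[sub_pos],
      product_feature_id = mol_ids[prod_pos],
      compound_name = db$compound_name[seq_len(n_planted)],
      rule_name = rules$rule_name[rule_idx],
      substrate_mz = sub_mz, product_mz = prod_mz,
      effect_strength = rep(effect_strength, n_planted),
      stringsAsFactors = FALSE)

    structure(list(
      molecules = intensity_matrix(intens, mz = mol_mz),
      microbes = count_matrix(counts, feature_kind = "taxon"),
      spectra_gut = spectra_gut,
      spectra_food = spectra_food,
      compound_db = db,
      rules = rules,
      truth = truth,
      seed = seed,
      params = list(n_samples = n_samples, n_microbes = n_microbes,
                    n_molecules = n_molecules, n_planted = n_planted,
                    noise_sd = noise_sd, effect_strength = effect_strength,
                    n_peaks = n_peaks)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat("Synthetic cohort (seed ", x$seed, "): ", p$n_samples, " samples, ",
      p$n_microbes, " microbes, ", p$n_molecules, " molecules, ",
      p$n_planted, " planted biotransformation(s), noise_sd ", p$noise_sd,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `molecules.csv`, `microbes.csv`, `gut.mgf`, `food.mgf`,
#' `compounds.csv`, `rules.csv` and `truth.csv` into `outdir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_matrix(cohort$molecules, file.path(outdir, "molecules.csv"))
  write_count_matrix(cohort$microbes, file.path(outdir, "microbes.csv"))
  write_mgf(cohort$spectra_gut, file.path(outdir, "gut.mgf"))
  write_mgf(cohort$spectra_food, file.path(outdir, "food.mgf"))
  utils::write.csv(cohort$compound_db[c("compound_name", "monoisotopic_mass",
                                        "smiles")],
                   file.path(outdir, "compounds.csv"), row.names = FALSE)
  write_rules(cohort$rules, file.path(outdir, "rules.csv"))
  utils::write.csv(cohort$truth, file.path(outdir, "truth.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' Score recovered triangles against the planted truth
#'
#' A found triangle is a true positive iff its microbe equals a planted
#' triplet's microbe and its substrate and product node precursors match the
#' planted substrate and product m/z within `mass_tol`. Recall is the
#' fraction of planted triplets recovered; precision the fraction of found
#' triangles that are true positives.
#'
#' @param truth Truth data.frame from [simulate_cohort()].
#' @param found A `golden_triangles` data.frame.
#' @param mass_tol m/z matching tolerance in Da.
#' @return List with `precision`, `recall` (`NA` when undefined), and a
#'   `confusion` list (`tp`, `fp`, `fn`).
#' @export
evaluate_recovery <- function(truth, found, mass_tol = 0.02) {
  n_truth <- nrow(truth)
  n_found <- nrow(found)
  found_tp <- logical(n_found)
  truth_hit <- logical(n_truth)
  if (n_found > 0 && n_truth > 0) for (k in seq_len(n_found)) {
    hit <- which(truth$microbe_id == found$microbial_feature_id[k] &
                   abs(truth$substrate_mz - found$substrate_mz[k]) <= mass_tol &
                   abs(truth$product_mz - found$product_mz[k]) <= mass_tol)
    if (length(hit) > 0) {
      found_tp[k] <- TRUE
      truth_hit[hit] <- TRUE
    }
  }
  tp <- sum(found_tp)
  fp <- n_found - tp
  fn <- sum(!truth_hit)
  list(precision = if (n_found == 0) NA_real_ else tp / n_found,
       recall = if (n_truth == 0) NA_real_ else sum(truth_hit) / n_truth,
       confusion = list(tp = tp, fp = fp, fn = fn))
}
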